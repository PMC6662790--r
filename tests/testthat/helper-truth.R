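# Truth-segment utilities shared by the IBD acceptance checks: merge the
# pairwise shared intervals (>= 1 common founder haplotype) from gene-drop
# ground truth.

truth_pair_segments <- function(truth, idA, idB, chroms) {
  out <- list()
  for (ch in chroms) {
    sa <- truth[truth$id == idA & truth$chrom == ch, ]
    sb <- truth[truth$id == idB & truth$chrom == ch, ]
    labs <- intersect(sa$founder_hap, sb$founder_hap)
    ivs <- list()
    for (lab in labs) {
      ia <- sa[sa$founder_hap == lab, ]; ib <- sb[sb$founder_hap == lab, ]
      for (i in seq_len(nrow(ia))) for (k in seq_len(nrow(ib))) {
        s <- max(ia$start[i], ib$start[k]); e <- min(ia$end[i], ib$end[k])
        if (e > s) ivs[[length(ivs) + 1L]] <- c(s, e)
      }
    }
    if (!length(ivs)) next
    iv <- do.call(rbind, ivs)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    cs <- iv[1, 1]; ce <- iv[1, 2]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= ce) ce <- max(ce, iv[i, 2])
      else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
        cs <- iv[i, 1]; ce <- iv[i, 2]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}
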