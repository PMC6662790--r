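# Pairwise identity-by-descent segment calling from unphased genotypes. A
# transparent stand-in for likelihood-based toolkits: maximal runs of markers
# free of opposite homozygotes (AA vs aa excludes IBD at a locus), with a
# small error tolerance, emitted above length/marker thresholds. When marker
# allele frequencies are supplied, run boundaries are refined by maximising
# the cumulative per-marker log-likelihood ratio of IBD1 vs IBD0 genotype
# pairs, which localises the true boundary to a few markers rather than the
# (much longer) gap to the next chance opposite homozygote.

# log P(gA,gB | IBD1) - log P(gA,gB | IBD0) for genotype pairs at alt freq p;
# a small error mixture keeps the ratio finite at opposite homozygotes
pair_llr <- function(gA, gB, p, err = 1e-3) {
  q <- 1 - p
  hw <- function(g) ifelse(g == 0L, q^2, ifelse(g == 1L, 2 * p * q, p^2))
  # P(g | one allele fixed to a): a = ref with prob q, alt with prob p
  cond <- function(g, alt) {
    if (alt) ifelse(g == 0L, 0, ifelse(g == 1L, q, p))
    else ifelse(g == 0L, q, ifelse(g == 1L, p, 0))
  }
  p0 <- hw(gA) * hw(gB)
  p1 <- q * cond(gA, FALSE) * cond(gB, FALSE) +
    p * cond(gA, TRUE) * cond(gB, TRUE)
  p1 <- (1 - err) * p1 + err * p0
  log(p1) - log(p0)
}

# Changepoint estimate for one segment edge: the marker maximising the
# cumulative LLR walking outward from inside the run (the maximum-likelihood
# changepoint between the IBD and non-IBD genotype-pair distributions).
refine_boundary <- function(llr, from, to, forward = TRUE) {
  cs <- if (forward) cumsum(llr[from:to]) else cumsum(rev(llr[from:to]))
  k <- which.max(cs)
  if (forward) from + k - 1L else to - k + 1L
}

#' Call pairwise IBD segments from unphased genotypes
#'
#' Within each chromosome, finds maximal runs of informative markers (both
#' genotypes observed) containing at most `max_opposite_homozygotes` opposite
#' homozygote pairs; runs spanning at least `min_length_bp` and
#' `min_markers` markers are emitted, ordered by position and non-overlapping.
#' Runs where both individuals agree (IBS2) at `>= ibd2_ibs2_frac` of
#' informative markers are upgraded to IBD2. With `freqs` supplied, segment
#' boundaries are refined by the IBD1/IBD0 likelihood-ratio changepoint.
#'
#' @param genoA,genoB genotype dosage vectors (0/1/2/NA) over the same map.
#' @param map a [marker_map()]; must be the map of both vectors.
#' @param min_length_bp,min_markers,max_opposite_homozygotes caller
#'   parameters (defaults 2.5 Mb, 100, 1).
#' @param ibd2_ibs2_frac IBS2 fraction for the IBD2 upgrade (default 0.99).
#' @param freqs optional per-marker alternative allele frequencies enabling
#'   boundary refinement.
#' @return data.frame of class `ibd_segments`: `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `state` (`"IBD1"`/`"IBD2"`), `length_bp`.
#' @export
call_ibd_segments <- function(genoA, genoB, map,
                              min_length_bp = 2.5e6, min_markers = 100L,
                              max_opposite_homozygotes = 1L,
                              ibd2_ibs2_frac = 0.99, freqs = NULL) {
  if (length(genoA) != nrow(map) || length(genoB) != nrow(map))
    stop_fs("genotype vectors and map differ in length")
  if (!is.null(freqs) && length(freqs) != nrow(map))
    stop_fs("freqs and map differ in length")
  out <- list()
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    inf <- j[!is.na(genoA[j]) & !is.na(genoB[j])]
    if (length(inf) < 2L) next
    a <- genoA[inf]; b <- genoB[inf]
    pos <- map$pos[inf]
    opp <- (a == 0L & b == 2L) | (a == 2L & b == 0L)
    llr <- if (!is.null(freqs)) pair_llr(a, b, pmin(pmax(freqs[inf], 1e-4),
                                                    1 - 1e-4)) else NULL
    runs <- opposite_hom_runs(opp, max_opposite_homozygotes)
    # a true segment's raw run always spans it (no opposite homozygotes
    # inside), so short raw runs can be dropped before refinement; this also
    # stops spurious runs from climbing into a neighbouring real segment
    runs <- Filter(function(r) r[2] > r[1] &&
                     pos[r[2]] - pos[r[1]] >= min_length_bp, runs)
    for (ri in seq_along(runs)) {
      r <- runs[[ri]]
      s <- r[1]; e <- r[2]
      if (!is.null(llr)) {
        lo <- if (ri > 1L) runs[[ri - 1L]][2] + 1L else 1L
        hi <- if (ri < length(runs)) runs[[ri + 1L]][1] - 1L else length(inf)
        mid <- s + (e - s) %/% 2L
        e <- refine_boundary(llr, mid, min(hi, e + 300L), forward = TRUE)
        s <- refine_boundary(llr, max(lo, s - 300L), mid, forward = FALSE)
      }
      if (e <= s) next
      len <- pos[e] - pos[s]
      nmk <- e - s + 1L
      if (len < min_length_bp || nmk < min_markers) next
      ibs2 <- mean(a[s:e] == b[s:e])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos[s], end_bp = pos[e], n_markers = nmk,
        state = if (ibs2 >= ibd2_ibs2_frac) "IBD2" else "IBD1",
        length_bp = len, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start_bp = numeric(0),
               end_bp = numeric(0), n_markers = integer(0),
               state = character(0), length_bp = numeric(0))
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res <- merge_overlapping_segments(res)
  class(res) <- c("ibd_segments", "data.frame")
  res
}

# greedy left-to-right decomposition into non-overlapping runs with at most m
# tolerated opposite homozygotes each; runs are trimmed so they never start or
# end on an opposite homozygote
opposite_hom_runs <- function(opp, m) {
  n <- length(opp)
  runs <- list()
  s <- 1L; tol <- 0L
  i <- 1L
  while (i <= n) {
    if (opp[i]) {
      if (tol < m) tol <- tol + 1L
      else {
        if (i - 1L >= s) runs[[length(runs) + 1L]] <- c(s, i - 1L)
        s <- i + 1L; tol <- 0L
      }
    }
    i <- i + 1L
  }
  if (s <= n) runs[[length(runs) + 1L]] <- c(s, n)
  lapply(runs, function(r) {
    s <- r[1]; e <- r[2]
    while (s <= e && opp[s]) s <- s + 1L
    while (e >= s && opp[e]) e <- e - 1L
    c(s, e)
  })
}

# refinement can make neighbouring runs touch or cross; keep them disjoint
merge_overlapping_segments <- function(segs) {
  if (nrow(segs) < 2L) return(segs)
  keep <- rep(TRUE, nrow(segs))
  for (i in 2:nrow(segs)) {
    if (segs$chrom[i] == segs$chrom[i - 1L] &&
        segs$start_bp[i] <= segs$end_bp[i - 1L]) {
      segs$end_bp[i - 1L] <- max(segs$end_bp[i - 1L], segs$end_bp[i])
      segs$length_bp[i - 1L] <- segs$end_bp[i - 1L] - segs$start_bp[i - 1L]
      segs$n_markers[i - 1L] <- segs$n_markers[i - 1L] + segs$n_markers[i]
      keep[i] <- FALSE
    }
  }
  segs[keep, , drop = FALSE]
}

#' Summarise pairwise IBD sharing by length bands
#'
#' Totals, counts and the longest segment above the upper threshold (default
#' 5 Mb), the band between the two thresholds (default 2.5-5 Mb), and the
#' segment containing the focal position, if any. Lengths are reported in Mb
#' (bp / 1e6).
#'
#' @param segments an `ibd_segments` data.frame.
#' @param thresholds two descending thresholds in bp (default `c(5e6, 2.5e6)`).
#' @param focal optional list(`chrom`, `position_bp`).
#' @return a `sharing_summary` list: `total_mb_over_5`, `n_segments_over_5`,
#'   `longest_mb`, `total_mb_2p5_to_5`, `n_segments_2p5_to_5`,
#'   `focal_segment`.
#' @export
summarize_sharing <- function(segments, thresholds = c(5e6, 2.5e6),
                              focal = NULL) {
  hi <- max(thresholds); lo <- min(thresholds)
  len <- segments$length_bp
  over <- len >= hi
  band <- len >= lo & len < hi
  focal_segment <- NULL
  if (!is.null(focal) && nrow(segments)) {
    hit <- segments$chrom == focal$chrom &
      segments$start_bp <= focal$position_bp &
      focal$position_bp <= segments$end_bp
    if (any(hit)) focal_segment <- segments[which(hit)[1L], ]
  }
  structure(list(
    total_mb_over_5 = sum(len[over]) / 1e6,
    n_segments_over_5 = sum(over),
    longest_mb = if (any(over)) max(len[over]) / 1e6 else
      if (length(len)) max(len) / 1e6 else 0,
    total_mb_2p5_to_5 = sum(len[band]) / 1e6,
    n_segments_2p5_to_5 = sum(band),
    focal_segment = focal_segment), class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %.1f Mb in %d segments (>= 5 Mb), longest %.1f Mb;\n",
              x$total_mb_over_5, x$n_segments_over_5, x$longest_mb))
  cat(sprintf("  %.1f Mb in %d segments (2.5-5 Mb); focal segment: %s\n",
              x$total_mb_2p5_to_5, x$n_segments_2p5_to_5,
              if (is.null(x$focal_segment)) "none" else
                sprintf("%.1f Mb", x$focal_segment$length_bp / 1e6)))
  invisible(x)
}

# haplotype-weighted sharing: sum over the four haplotype pairings of the
# length with equal founder labels, over twice the genome. IBD1 regions count
# half, IBD2 regions count in full; the expectation for degree-d cousins is
# (1/2)^(2d + 1) (1/128 for third cousins) and 1/2 for full siblings.
truth_hap_fraction <- function(truth, idA, idB, genome) {
  total <- 0
  for (hx in 1:2) for (hy in 1:2) {
    tA <- truth[truth$id == idA & truth$hap == hx, ]
    tB <- truth[truth$id == idB & truth$hap == hy, ]
    for (ch in genome$chrom) {
      sa <- tA[tA$chrom == ch, ]; sb <- tB[tB$chrom == ch, ]
      labs <- intersect(sa$founder_hap, sb$founder_hap)
      for (lab in labs) {
        ia <- sa[sa$founder_hap == lab, ]; ib <- sb[sb$founder_hap == lab, ]
        for (i in seq_len(nrow(ia))) for (k in seq_len(nrow(ib)))
          total <- total + max(0, min(ia$end[i], ib$end[k]) -
                                 max(ia$start[i], ib$start[k]))
      }
    }
  }
  total / (2 * sum(genome$length_bp))
}

# genome fraction where the pair shares >= 1 founder haplotype, from truth
truth_ibd_fraction <- function(truth, idA, idB, genome) {
  tA <- truth[truth$id == idA, ]
  tB <- truth[truth$id == idB, ]
  total <- 0
  for (ch in genome$chrom) {
    sa <- tA[tA$chrom == ch, ]; sb <- tB[tB$chrom == ch, ]
    labs <- intersect(sa$founder_hap, sb$founder_hap)
    if (length(labs) == 0L) next
    # union over labels of intersections of the two individuals' intervals
    ivs <- list()
    for (lab in labs) {
      ia <- sa[sa$founder_hap == lab, c("start", "end")]
      ib <- sb[sb$founder_hap == lab, c("start", "end")]
      for (i in seq_len(nrow(ia))) for (k in seq_len(nrow(ib))) {
        s <- max(ia$start[i], ib$start[k]); e <- min(ia$end[i], ib$end[k])
        if (e > s) ivs[[length(ivs) + 1L]] <- c(s, e)
      }
    }
    if (length(ivs) == 0L) next
    iv <- do.call(rbind, ivs)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    cur_s <- iv[1L, 1L]; cur_e <- iv[1L, 2L]
    for (i in seq_len(nrow(iv))[-1L]) {
      if (iv[i, 1L] <= cur_e) cur_e <- max(cur_e, iv[i, 2L])
      else { total <- total + (cur_e - cur_s); cur_s <- iv[i, 1L]; cur_e <- iv[i, 2L] }
    }
    total <- total + (cur_e - cur_s)
  }
  total / sum(genome$length_bp)
}

#' Calibrate genomic sharing against simulated cousin pairs
#'
#' Simulates `n_pairs` cousin pairs of the requested degree by gene dropping
#' through [cousin_pair_pedigree()] and summarises two sharing conventions:
#' the genome fraction where the pair shares at least one haplotype
#' (expectation `(1/2)^(2 degree)` for cousins, `3/4` for full siblings) and
#' the haplotype-weighted fraction in which one-haplotype sharing counts half
#' (expectation `(1/2)^(2 degree + 1)`; `1/128` for third cousins, `1/2` for
#' siblings -- the number genealogists quote as percent shared DNA).
#' `method = "truth"` measures from the ground-truth segments;
#' `method = "caller"` genotypes the pair and runs [call_ibd_segments()]
#' (at-least-one-haplotype convention only, since the caller is unphased).
#'
#' @param degree cousin degree (0 = full siblings).
#' @param n_pairs number of simulated pairs (>= 1).
#' @param config a [sim_config()] supplying genome and rates.
#' @param seed seed for the simulation stream.
#' @param method `"truth"` or `"caller"`.
#' @param ... further arguments passed to [call_ibd_segments()].
#' @return list `mean`, `se`, `fractions`, `expected` (at-least-one-haplotype
#'   convention) and `hap_mean`, `hap_se`, `hap_fractions`, `hap_expected`
#'   (haplotype-weighted; `NA` for the caller method).
#' @export
relationship_calibration <- function(degree, n_pairs, config = sim_config(),
                                     seed = 1L, method = c("truth", "caller"),
                                     ...) {
  method <- match.arg(method)
  if (!is_count(n_pairs) || n_pairs < 1) stop_fs("n_pairs must be >= 1")
  if (!is_count(degree)) stop_fs("degree must be a non-negative integer")
  ped <- cousin_pair_pedigree(degree)
  pair <- attr(ped, "pair")
  expected <- if (degree == 0) 0.75 else (1 / 2)^(2 * degree)
  hap_expected <- if (degree == 0) 0.5 else (1 / 2)^(2 * degree + 1)
  founders <- if (method == "caller")
    simulate_founders(config, n_founders = length(pedigree_founders(ped)),
                      seed = substream_seed(seed, "calib_founders")) else NULL
  fr <- matrix(NA_real_, n_pairs, 2L)
  for (i in seq_len(n_pairs)) {
    gd <- gene_drop(ped, founders, config,
                    seed = substream_seed(seed, paste0("calib", degree, "_", i)))
    if (method == "truth") {
      fr[i, 1L] <- truth_ibd_fraction(gd$truth, pair[1], pair[2],
                                      config$genome)
      fr[i, 2L] <- truth_hap_fraction(gd$truth, pair[1], pair[2],
                                      config$genome)
    } else {
      g <- genotype_matrix(gd$cohort)
      segs <- call_ibd_segments(g[pair[1], ], g[pair[2], ], gd$map,
                                freqs = founders$freq, ...)
      fr[i, 1L] <- sum(segs$length_bp) / sum(config$genome$length_bp)
    }
  }
  list(mean = mean(fr[, 1L]), se = stats::sd(fr[, 1L]) / sqrt(n_pairs),
       fractions = fr[, 1L], expected = expected,
       hap_mean = mean(fr[, 2L]),
       hap_se = stats::sd(fr[, 2L]) / sqrt(n_pairs),
       hap_fractions = fr[, 2L], hap_expected = hap_expected)
}
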