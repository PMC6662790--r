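# Fixture builders and independent brute-force oracles. Oracles are written
# from first principles (explicit enumeration / string comparison) and never
# call the implementation paths they check.

mk_map <- function(n, chrom = "chr1", start = 1e6, step = 1e4) {
  marker_map(rep(chrom, n), seq(start, by = step, length.out = n))
}

# build a cohort from allele-string rows; "." = missing
toy_cohort <- function(h1_strings, h2_strings,
                       ids = paste0("I", seq_along(h1_strings))) {
  conv <- function(s) {
    v <- strsplit(s, "")[[1]]
    ifelse(v == ".", NA_integer_, as.integer(v))
  }
  phased_cohort(ids,
                do.call(rbind, lapply(h1_strings, conv)),
                do.call(rbind, lapply(h2_strings, conv)))
}

mk_focal <- function(chrom, pos, known = character(0)) {
  structure(list(chrom = chrom, position_bp = pos,
                 carrier_ids = character(0), known_carrier_ids = known),
            class = "focal_variant")
}

rand_cohort <- function(n, m, p = 0.5, miss = 0, ids = sprintf("R%02d", 1:n)) {
  h <- function() {
    x <- matrix(rbinom(n * m, 1L, p), n, m)
    if (miss > 0) x[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
    x
  }
  phased_cohort(ids, h(), h())
}

# --- exact HWE oracle: direct log-factorial enumeration ---------------------
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * nbb + nab
  nb <- 2 * naa + nab
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    xaa <- (nb - h) / 2; xbb <- (na - h) / 2
    lgamma(n + 1) - lgamma(xaa + 1) - lgamma(h + 1) - lgamma(xbb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  sum(p[p <= p[match(nab, hets)] * (1 + 1e-10)]) / sum(p)
}

# --- haplotype matching oracles: literal string comparison ------------------
wild_eq <- function(a, b) all(a == b | is.na(a) | is.na(b))

oracle_define <- function(cohort, carriers, idx) {
  k <- length(carriers)
  rows <- lapply(carriers, function(id) {
    i <- match(id, cohort$ids)
    list(cohort$hap1[i, idx], cohort$hap2[i, idx])
  })
  strings <- list(); n_ok <- 0L
  for (a in seq_len(2^k) - 1L) {
    pick <- bitwAnd(a %/% 2^(seq_len(k) - 1L), 1L) + 1L
    hs <- lapply(seq_len(k), function(c) rows[[c]][[pick[c]]])
    ok <- TRUE
    for (i in seq_len(k)) for (j in seq_len(k))
      if (!wild_eq(hs[[i]], hs[[j]])) ok <- FALSE
    if (ok) {
      n_ok <- n_ok + 1L
      cons <- Reduce(function(x, y) ifelse(is.na(x), y, x), hs)
      strings[[length(strings) + 1L]] <- cons
    }
  }
  list(n_ok = n_ok, strings = unique(strings))
}

oracle_scan <- function(cohort, alleles, idx, exclude) {
  hit <- character(0)
  for (i in seq_along(cohort$ids)) {
    if (cohort$ids[i] %in% exclude) next
    if (wild_eq(cohort$hap1[i, idx], alleles) ||
        wild_eq(cohort$hap2[i, idx], alleles))
      hit <- c(hit, cohort$ids[i])
  }
  hit
}

oracle_fine <- function(a, b, pos, focal) {
  agree <- a == b | is.na(a) | is.na(b)
  four <- order(abs(pos - focal))[1:4]
  if (!all(agree[four]))
    return(list(start_bp = NA_real_, end_bp = NA_real_,
                n_matching_markers = 0L, length_bp = 0))
  left <- rev(which(pos < focal)); right <- which(pos >= focal)
  takel <- c(); for (i in left) { if (!agree[i]) break; takel <- c(takel, i) }
  taker <- c(); for (i in right) { if (!agree[i]) break; taker <- c(taker, i) }
  keep <- c(takel, taker)
  list(start_bp = min(pos[keep]), end_bp = max(pos[keep]),
       n_matching_markers = length(keep),
       length_bp = max(pos[keep]) - min(pos[keep]))
}

# --- Mendelian oracle: allele-set enumeration over all trio combinations ----
oracle_mendel_possible <- function(gf, gm) {
  tx <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)  # transmittable alleles
  sort(unique(outer(tx(gf), tx(gm), "+")))
}
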