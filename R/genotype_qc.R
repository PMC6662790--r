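# Array genotype QC mirroring standard isolate-cohort practice: call-rate
# filters at 98%, the exact conditional Hardy-Weinberg test at p < 1e-6,
# Mendelian-error masking against the pedigree, and a 6 SD rule on the first
# two genotype principal components. Filter order is fixed (individuals ->
# markers -> HWE -> Mendel mask -> ancestry PCs) because it affects results.

#' Call-rate filter
#'
#' @param geno genotype dosage matrix (individuals x markers, 0/1/2/NA) with
#'   row and column names.
#' @param axis `"individuals"` (rows) or `"markers"` (columns).
#' @param threshold minimum call rate in (0, 1].
#' @return list with `retained` (names), `removed` (data.frame `id`,
#'   `call_rate`, `reason`).
#' @export
call_rate_filter <- function(geno, axis = c("individuals", "markers"),
                             threshold = 0.98) {
  axis <- match.arg(axis)
  if (length(geno) == 0L || nrow(geno) == 0L || ncol(geno) == 0L)
    stop_fs("empty genotype matrix")
  if (!(threshold > 0 && threshold <= 1)) stop_fs("threshold must be in (0,1]")
  cr <- if (axis == "individuals") rowMeans(!is.na(geno)) else
    colMeans(!is.na(geno))
  nm <- if (axis == "individuals") rownames(geno) else colnames(geno)
  bad <- cr < threshold
  list(retained = nm[!bad],
       removed = data.frame(id = nm[bad], call_rate = unname(cr[bad]),
                            reason = rep(paste0(substr(axis, 1, nchar(axis) - 1),
                                                "_call_rate"), sum(bad)),
                            stringsAsFactors = FALSE))
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts no more probable than the observed one (the standard
#' exact test used in array QC). Monomorphic markers return p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop_fs("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0L) stop_fs("no genotypes")
  na <- 2 * n_hom_alt + n_het        # minor-side allele count (either side works)
  nb <- 2 * n_hom_ref + n_het
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # relative probabilities by the recurrence
  # P(h+2)/P(h) = 4 n_aa(h) n_bb(h) / ((h+2)(h+1)),
  # n_aa(h) = (na - h)/2, n_bb(h) = (nb - h)/2
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    naa <- (na - h) / 2; nbb <- (nb - h) / 2
    logp[k] <- logp[k - 1] + log(4 * naa * nbb) - log((h + 2) * (h + 1))
  }
  p_rel <- exp(logp - max(logp))
  p_rel <- p_rel / sum(p_rel)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop_fs("heterozygote count incompatible with allele counts")
  min(1, sum(p_rel[p_rel <= p_rel[obs] * (1 + 1e-10)]))
}

#' Scan a genotype matrix for Mendelian inconsistencies
#'
#' Flags biallelic trio/duo impossibilities: a homozygous parent whose allele
#' the child lacks, two identically homozygous parents with a non-matching
#' child, and opposite-homozygous parents with a homozygous child. Absent or
#' missing parents simply limit the applicable rules.
#'
#' @param pedigree a `pedigree` (or data.frame with `id`, `father`, `mother`).
#' @param geno genotype dosage matrix with ids as row names.
#' @return data.frame `individual` (the child), `marker`.
#' @export
mendel_error_scan <- function(pedigree, geno) {
  markers <- colnames(geno)
  out <- list()
  for (i in seq_len(nrow(pedigree))) {
    id <- pedigree$id[i]
    fa <- pedigree$father[i]; mo <- pedigree$mother[i]
    if (!(id %in% rownames(geno))) next
    gc <- geno[id, ]
    gf <- if (!is.na(fa) && fa %in% rownames(geno)) geno[fa, ] else
      rep(NA_integer_, length(gc))
    gm <- if (!is.na(mo) && mo %in% rownames(geno)) geno[mo, ] else
      rep(NA_integer_, length(gc))
    err <- mendel_rule(gc, gf, gm)
    if (any(err))
      out[[length(out) + 1L]] <- data.frame(individual = id,
                                            marker = markers[err],
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(individual = character(0), marker = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# vectorised trio rule table (NA-safe: a rule only fires when its genotypes
# are observed)
mendel_rule <- function(gc, gf, gm) {
  tr <- function(x) !is.na(x)
  err <- rep(FALSE, length(gc))
  ok <- tr(gc)
  # duo rules: homozygous parent, child opposite homozygote
  err <- err | (ok & tr(gf) & ((gf == 0L & gc == 2L) | (gf == 2L & gc == 0L)))
  err <- err | (ok & tr(gm) & ((gm == 0L & gc == 2L) | (gm == 2L & gc == 0L)))
  both <- ok & tr(gf) & tr(gm)
  err <- err | (both & gf == 0L & gm == 0L & gc != 0L)
  err <- err | (both & gf == 2L & gm == 2L & gc != 2L)
  err <- err | (both & ((gf == 0L & gm == 2L) | (gf == 2L & gm == 0L)) &
                  gc != 1L)
  err
}

#' Mask Mendelian errors to missing
#'
#' Sets the child and both (present) parents to missing at each flagged
#' marker; the source of the error is unidentifiable, so the whole trio is
#' masked.
#'
#' @param geno genotype dosage matrix.
#' @param pedigree the pedigree used for the scan.
#' @param errors output of [mendel_error_scan()].
#' @return the masked matrix.
#' @export
apply_mendel_mask <- function(geno, pedigree, errors) {
  if (nrow(errors) == 0L) return(geno)
  for (i in seq_len(nrow(errors))) {
    id <- errors$individual[i]; mk <- errors$marker[i]
    row <- pedigree[pedigree$id == id, ]
    ids <- c(id, row$father, row$mother)
    ids <- ids[!is.na(ids) & ids %in% rownames(geno)]
    geno[ids, mk] <- NA_integer_
  }
  geno
}

#' Ancestry outliers on genotype principal components
#'
#' Standardises markers (zero-variance markers dropped, missing calls imputed
#' to the marker mean), computes the leading principal components of the
#' cohort itself, and flags individuals more than `sd_threshold` standard
#' deviations from the mean on any of the first `n_pcs` components.
#'
#' @param geno genotype dosage matrix.
#' @param n_pcs number of components to inspect (default 2).
#' @param sd_threshold deviation rule in SD units (default 6).
#' @return character vector of outlier ids.
#' @export
ancestry_outliers <- function(geno, n_pcs = 2, sd_threshold = 6) {
  if (nrow(geno) <= n_pcs)
    stop_fs("need more individuals than requested principal components")
  x <- geno
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  sdv <- apply(x, 2L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) return(character(0))
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  out <- rep(FALSE, nrow(x))
  for (k in seq_len(min(n_pcs, ncol(pc$x)))) {
    s <- pc$x[, k]
    out <- out | abs(s - mean(s)) > sd_threshold * stats::sd(s)
  }
  rownames(geno)[out]
}

#' Run the full genotype QC pipeline
#'
#' Fixed filter order: individual call rate, marker call rate (recomputed on
#' retained individuals), exact HWE, Mendelian masking, ancestry PC outliers.
#'
#' @param geno genotype dosage matrix (individuals x markers).
#' @param pedigree optional `pedigree` for the Mendelian scan.
#' @param mind,geno_thr call-rate thresholds for individuals and markers.
#' @param hwe_p HWE removal threshold.
#' @param pc_sd ancestry outlier rule in SD units.
#' @param n_pcs principal components inspected.
#' @return list of class `qc_report`: `geno` (filtered, masked matrix),
#'   `retained_ids`, `retained_markers`, `removed_individuals`,
#'   `removed_markers`, `mendel_masked`, `ancestry_outliers`, `counts`.
#' @export
run_qc <- function(geno, pedigree = NULL, mind = 0.98, geno_thr = 0.98,
                   hwe_p = 1e-6, pc_sd = 6, n_pcs = 2) {
  f1 <- call_rate_filter(geno, "individuals", mind)
  g <- geno[f1$retained, , drop = FALSE]
  f2 <- call_rate_filter(g, "markers", geno_thr)
  g <- g[, f2$retained, drop = FALSE]

  hwe <- apply(g, 2L, function(col) {
    hwe_exact_test(sum(col == 0L, na.rm = TRUE), sum(col == 1L, na.rm = TRUE),
                   sum(col == 2L, na.rm = TRUE))
  })
  hwe_bad <- colnames(g)[hwe < hwe_p]
  g <- g[, setdiff(colnames(g), hwe_bad), drop = FALSE]

  masked <- data.frame(individual = character(0), marker = character(0))
  if (!is.null(pedigree)) {
    masked <- mendel_error_scan(pedigree, g)
    g <- apply_mendel_mask(g, pedigree, masked)
  }

  outl <- ancestry_outliers(g, n_pcs = n_pcs, sd_threshold = pc_sd)
  g <- g[setdiff(rownames(g), outl), , drop = FALSE]

  removed_individuals <- rbind(
    f1$removed[, c("id", "reason")],
    data.frame(id = outl, reason = rep("ancestry_pc", length(outl)),
               stringsAsFactors = FALSE))
  removed_markers <- rbind(
    f2$removed[, c("id", "reason")],
    data.frame(id = hwe_bad, reason = rep("hwe", length(hwe_bad)),
               stringsAsFactors = FALSE))
  structure(list(
    geno = g,
    retained_ids = rownames(g), retained_markers = colnames(g),
    removed_individuals = removed_individuals,
    removed_markers = removed_markers,
    mendel_masked = masked, ancestry_outliers = outl,
    counts = list(individuals_removed_call_rate = nrow(f1$removed),
                  markers_removed_call_rate = nrow(f2$removed),
                  markers_removed_hwe = length(hwe_bad),
                  mendel_masked = nrow(masked),
                  ancestry_outliers = length(outl))),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  retained: %d individuals x %d markers\n",
              length(x$retained_ids), length(x$retained_markers)))
  invisible(x)
}
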