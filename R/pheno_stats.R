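# QTc phenotype and cohort-frequency statistics for carrier reporting.

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR)` with RR in seconds, the conventional form; at
#' RR = 1 s the correction is the identity.
#'
#' @param qt_ms QT interval in milliseconds (> 0).
#' @param rr_s RR interval in seconds (> 0). Alternatively supply `hr_bpm`.
#' @param hr_bpm heart rate in beats per minute; used as `rr_s = 60 / hr_bpm`
#'   when `rr_s` is missing.
#' @return QTc in milliseconds (vectorised).
#' @export
bazett_qtc <- function(qt_ms, rr_s = NULL, hr_bpm = NULL) {
  if (is.null(rr_s)) {
    if (is.null(hr_bpm)) stop_fs("supply rr_s or hr_bpm")
    rr_s <- 60 / hr_bpm
  }
  if (any(!is.finite(qt_ms)) || any(qt_ms <= 0)) stop_fs("qt_ms must be > 0")
  if (any(!is.finite(rr_s)) || any(rr_s <= 0)) stop_fs("rr_s must be > 0")
  qt_ms / sqrt(rr_s)
}

#' Carrier allele frequency among diploid individuals
#'
#' Heterozygous carriers contribute one allele each out of `2 n` chromosomes.
#'
#' @param n_het_carriers number of heterozygous carriers.
#' @param n_individuals cohort size (diploid individuals, > 0).
#' @return allele frequency.
#' @export
carrier_allele_frequency <- function(n_het_carriers, n_individuals) {
  if (!is_count(n_het_carriers) || !is_count(n_individuals))
    stop_fs("counts must be non-negative integers")
  if (n_individuals == 0) stop_fs("n_individuals must be > 0")
  if (n_het_carriers > n_individuals)
    stop_fs("more carriers than individuals")
  n_het_carriers / (2 * n_individuals)
}

#' Fold enrichment of a cohort allele frequency over a reference
#'
#' @param f_cohort cohort allele frequency.
#' @param f_reference reference allele frequency (> 0), e.g. a large
#'   outbred-population estimate.
#' @return ratio `f_cohort / f_reference`.
#' @export
fold_enrichment <- function(f_cohort, f_reference) {
  if (!is.finite(f_reference) || f_reference <= 0)
    stop_fs("reference frequency must be > 0")
  f_cohort / f_reference
}

#' Per-group QTc summary and carrier penetrance at a cut-off
#'
#' Means and ranges of QTc per carrier group, plus penetrance defined as the
#' fraction of carriers with QTc above a prolongation cut-off (clinical
#' convention 450 ms for males, 470 ms for females when sex is given; a
#' single 450 ms otherwise).
#'
#' @param ecg data.frame with `id` and either `qtc_ms` or both `qt_ms` and
#'   `rr_s` (QTc then computed with [bazett_qtc()]).
#' @param carrier_ids ids labelled as carriers; everyone else is a
#'   non-carrier.
#' @param cutoff_ms prolongation cut-off(s); either a single value or
#'   `c(male = 450, female = 470)` used with `sex`.
#' @param sex optional vector (1 = male, 2 = female) aligned with `ecg$id`.
#' @return list of class `qtc_summary`: `groups` (data.frame `group`, `n`,
#'   `mean`, `min`, `max`; a group with no members is absent) and
#'   `penetrance`.
#' @export
group_qtc_summary <- function(ecg, carrier_ids, cutoff_ms = 450, sex = NULL) {
  qtc <- if ("qtc_ms" %in% names(ecg)) ecg$qtc_ms else
    bazett_qtc(ecg$qt_ms, ecg$rr_s)
  carrier <- ecg$id %in% carrier_ids
  groups <- list()
  for (g in c("carrier", "noncarrier")) {
    sel <- if (g == "carrier") carrier else !carrier
    if (!any(sel)) next
    groups[[g]] <- data.frame(group = g, n = sum(sel), mean = mean(qtc[sel]),
                              min = min(qtc[sel]), max = max(qtc[sel]),
                              stringsAsFactors = FALSE)
  }
  cut <- if (!is.null(sex) && length(cutoff_ms) == 2L)
    ifelse(sex == 1L, cutoff_ms[["male"]], cutoff_ms[["female"]])
  else rep(cutoff_ms[[1L]], nrow(ecg))
  penetrance <- if (any(carrier)) mean(qtc[carrier] > cut[carrier]) else NA_real_
  structure(list(groups = do.call(rbind, groups), penetrance = penetrance),
            class = "qtc_summary")
}

#' Cohort carrier statistics
#'
#' Bundles the frequency and enrichment arithmetic with the QTc group
#' summary into one report object.
#'
#' @param n_het_carriers,n_individuals see [carrier_allele_frequency()].
#' @param f_reference reference allele frequency for [fold_enrichment()].
#' @param ecg,carrier_ids,cutoff_ms,sex see [group_qtc_summary()]; optional.
#' @return list of class `carrier_stats`.
#' @export
carrier_stats <- function(n_het_carriers, n_individuals, f_reference = NULL,
                          ecg = NULL, carrier_ids = NULL, cutoff_ms = 450,
                          sex = NULL) {
  f <- carrier_allele_frequency(n_het_carriers, n_individuals)
  out <- list(n_carriers = n_het_carriers, n_individuals = n_individuals,
              allele_frequency = f,
              fold_enrichment = if (!is.null(f_reference))
                fold_enrichment(f, f_reference) else NA_real_)
  if (!is.null(ecg))
    out$qtc <- group_qtc_summary(ecg, carrier_ids, cutoff_ms, sex)
  structure(out, class = "carrier_stats")
}

#' @export
print.carrier_stats <- function(x, ...) {
  cat(sprintf("<carrier_stats> %d carriers / %d individuals; allele frequency %.5f",
              x$n_carriers, x$n_individuals, x$allele_frequency))
  if (is.finite(x$fold_enrichment))
    cat(sprintf(" (%.0f-fold over reference)", x$fold_enrichment))
  cat("\n")
  if (!is.null(x$qtc)) {
    print(x$qtc$groups, row.names = FALSE)
    cat(sprintf("  penetrance at cut-off: %.2f\n", x$qtc$penetrance))
  }
  invisible(x)
}
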