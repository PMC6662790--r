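# The core carrier-haplotype method. Coarse route: define a consensus
# haplotype over physical windows grown in fixed increments around the
# array-absent focal variant from the known carriers' phased haplotypes, and
# scan the whole cohort for it. Fine route: measure the shared haplotype
# between two single haplotypes at variant-level resolution by adding the
# physically nearest markers one at a time until each side mismatches.
#
# Matching convention: alleles are 0/1; a missing allele is a wildcard (it
# matches anything) unless `missing_match = FALSE`. Windows of total length L
# are half-open [pos - L/2, pos + L/2) centred on the focal position.

window_marker_idx <- function(map, chrom, center, length_bp) {
  which(map$chrom == chrom & map$pos >= center - length_bp / 2 &
          map$pos < center + length_bp / 2)
}

alleles_match <- function(a, b, missing_match = TRUE) {
  if (missing_match) all(a == b | is.na(a) | is.na(b)) else
    all(!is.na(a) & !is.na(b) & a == b)
}

# rows compatible: at every column the observed values agree
rows_consistent <- function(mat, missing_match = TRUE) {
  if (!missing_match && anyNA(mat)) return(FALSE)
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]; v <- v[!is.na(v)]
    if (length(v) > 1L && any(v != v[1L])) return(FALSE)
  }
  TRUE
}

carrier_hap_matrix <- function(cohort, carrier_ids, idx) {
  i <- match(carrier_ids, cohort$ids)
  if (anyNA(i)) stop_fs("unknown carrier ids: ",
                        paste(carrier_ids[is.na(i)], collapse = ", "))
  if (any(!cohort$phased[i]))
    stop_fs("haplotype matching requires phased individuals")
  list(h1 = cohort$hap1[i, idx, drop = FALSE],
       h2 = cohort$hap2[i, idx, drop = FALSE])
}

#' Define the consensus carrier haplotype over a window
#'
#' Searches for an assignment of one haplotype per known carrier such that all
#' chosen haplotypes are identical over the markers inside the window (missing
#' alleles are wildcards). If one exists, the consensus allele string is
#' returned; window positions missing in every carrier stay unresolved (`NA`).
#' With a single carrier both haplotypes are valid candidates and the result
#' is flagged ambiguous. If no assignment exists, a `no_consensus` report
#' names the first discordant marker, in order of physical distance from the
#' focal position.
#'
#' @param cohort a [phased_cohort()].
#' @param map matching [marker_map()].
#' @param focal a `focal_variant` (uses `chrom`, `position_bp`,
#'   `known_carrier_ids`).
#' @param window_length_bp total window length L; the window is
#'   `[pos - L/2, pos + L/2)`.
#' @param missing_match treat missing alleles as wildcards (default) or as
#'   mismatches.
#' @param prefer_choice optional named haplotype assignment (as in
#'   `hap_choice`) used to break ties between valid assignments; the sweep
#'   uses it to keep consensus choices stable across growing windows.
#' @return a `carrier_haplotype` (fields `chrom`, `window`, `marker_idx`,
#'   `marker_ids`, `alleles`, `carriers`, `hap_choice`, `ambiguous`,
#'   `candidates`, `focal_pos`) or a `no_consensus` report (fields
#'   `first_discordant_marker`, `first_discordant_pos`, `window`).
#' @export
define_carrier_haplotype <- function(cohort, map, focal, window_length_bp,
                                     missing_match = TRUE,
                                     prefer_choice = NULL) {
  carriers <- focal$known_carrier_ids
  if (length(carriers) < 1L) stop_fs("need at least one known carrier")
  idx <- window_marker_idx(map, focal$chrom, focal$position_bp,
                           window_length_bp)
  if (length(idx) == 0L)
    stop_fs("window too small: no markers inside ",
            format(window_length_bp, scientific = FALSE), " bp window",
            class = "founderscan_window_error")
  hm <- carrier_hap_matrix(cohort, carriers, idx)
  k <- length(carriers)
  if (k > 16L) stop_fs("consensus search supports at most 16 known carriers")
  choices <- as.matrix(expand.grid(rep(list(1:2), k)))
  ok <- logical(nrow(choices))
  cons <- vector("list", nrow(choices))
  for (a in seq_len(nrow(choices))) {
    m <- matrix(NA_integer_, k, length(idx))
    for (c in seq_len(k))
      m[c, ] <- if (choices[a, c] == 1L) hm$h1[c, ] else hm$h2[c, ]
    if (rows_consistent(m, missing_match)) {
      ok[a] <- TRUE
      cons[[a]] <- apply(m, 2L, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) v[1L] else NA_integer_
      })
    }
  }
  if (!any(ok)) {
    # first discordant marker by distance from the focal position
    dist_ord <- idx[order(abs(map$pos[idx] - focal$position_bp))]
    alive <- rep(TRUE, nrow(choices))
    first_bad <- NA_integer_
    for (j in dist_ord) {
      col <- match(j, idx)
      for (a in which(alive)) {
        vals <- vapply(seq_len(k), function(c)
          if (choices[a, c] == 1L) hm$h1[c, col] else hm$h2[c, col],
          integer(1))
        vals <- vals[!is.na(vals)]
        if (!missing_match && anyNA(c(hm$h1[, col], hm$h2[, col])))
          alive[a] <- FALSE
        else if (length(vals) > 1L && any(vals != vals[1L])) alive[a] <- FALSE
      }
      if (!any(alive)) { first_bad <- j; break }
    }
    return(structure(list(
      first_discordant_marker = map$id[first_bad],
      first_discordant_pos = map$pos[first_bad],
      window = c(focal$position_bp - window_length_bp / 2,
                 focal$position_bp + window_length_bp / 2),
      carriers = carriers), class = "no_consensus"))
  }
  strings <- unique(lapply(which(ok), function(a) cons[[a]]))
  first <- which(ok)[1L]
  if (!is.null(prefer_choice)) {
    pc <- as.integer(prefer_choice[carriers])
    hit <- which(ok & apply(choices, 1L, function(r) all(r == pc)))
    if (length(hit)) first <- hit[1L]
  }
  structure(list(
    chrom = focal$chrom,
    window = c(focal$position_bp - window_length_bp / 2,
               focal$position_bp + window_length_bp / 2),
    window_length_bp = window_length_bp,
    marker_idx = idx, marker_ids = map$id[idx],
    alleles = cons[[first]],
    carriers = carriers,
    hap_choice = stats::setNames(as.integer(choices[first, ]), carriers),
    ambiguous = length(strings) > 1L,
    candidates = strings,
    focal_pos = focal$position_bp,
    missing_match = missing_match), class = "carrier_haplotype")
}

#' @export
print.carrier_haplotype <- function(x, ...) {
  cat(sprintf("<carrier_haplotype> %s:[%s,%s) %d markers, %d carriers%s\n",
              x$chrom, format(x$window[1], scientific = FALSE),
              format(x$window[2], scientific = FALSE),
              length(x$marker_idx), length(x$carriers),
              if (x$ambiguous) " (ambiguous)" else ""))
  invisible(x)
}

# logical matrix: does each haplotype of each individual match the consensus
match_matrix <- function(cohort, hap, missing_match = TRUE) {
  idx <- hap$marker_idx
  target <- matrix(hap$alleles, nrow = length(cohort$ids),
                   ncol = length(idx), byrow = TRUE)
  mism <- function(h) {
    d <- h[, idx, drop = FALSE] != target
    if (missing_match) d[is.na(d)] <- FALSE else d[is.na(d)] <- TRUE
    rowSums(d) == 0L
  }
  cbind(h1 = mism(cohort$hap1), h2 = mism(cohort$hap2))
}

#' Scan a cohort for a carrier haplotype
#'
#' Returns every individual (beyond the source carriers) with at least one
#' haplotype identical to the consensus over the in-window markers, missing
#' alleles matching anything. An individual whose two haplotypes both match
#' counts once; the matched haplotype index is reported (1 preferred).
#'
#' @param cohort a [phased_cohort()].
#' @param map matching [marker_map()].
#' @param hap a `carrier_haplotype`.
#' @param include_carriers also report the source carriers (sanity checks).
#' @return data.frame `id`, `hap` (1 or 2), `both` (logical).
#' @export
scan_cohort <- function(cohort, map, hap, include_carriers = FALSE) {
  stopifnot(inherits(hap, "carrier_haplotype"))
  if (any(!cohort$phased))
    stop_fs("haplotype scanning requires a fully phased cohort")
  mm <- match_matrix(cohort, hap, hap$missing_match)
  sel <- mm[, 1L] | mm[, 2L]
  if (!include_carriers) sel <- sel & !(cohort$ids %in% hap$carriers)
  data.frame(id = cohort$ids[sel],
             hap = ifelse(mm[sel, 1L], 1L, 2L),
             both = mm[sel, 1L] & mm[sel, 2L],
             stringsAsFactors = FALSE)
}

#' Background frequency of a carrier haplotype
#'
#' Fraction of haplotypes among individuals outside `exclude` (defaulting to
#' the source carriers) that match the consensus. A consensus with zero
#' resolved markers matches vacuously (frequency 1).
#'
#' @param cohort a [phased_cohort()].
#' @param map matching [marker_map()].
#' @param hap a `carrier_haplotype`.
#' @param exclude ids excluded from the denominator (default: the source
#'   carriers).
#' @return fraction in `[0, 1]`.
#' @export
haplotype_background_frequency <- function(cohort, map, hap,
                                           exclude = hap$carriers) {
  keep <- !(cohort$ids %in% exclude)
  if (!any(keep)) return(NaN)
  mm <- match_matrix(cohort, hap, hap$missing_match)[keep, , drop = FALSE]
  sum(mm) / (2L * sum(keep))
}

#' Coarse incremental-window sweep
#'
#' Runs [define_carrier_haplotype()] + [scan_cohort()] at window lengths
#' `increment_bp, 2 increment_bp, ...`, stopping at `max_length_bp`, when the
#' non-carrier match set becomes empty, or on a no-consensus window. Match
#' sets are nested by construction (growing a window can only remove matches);
#' the sweep verifies this.
#'
#' @param cohort a [phased_cohort()].
#' @param map matching [marker_map()].
#' @param focal a `focal_variant` with known carriers.
#' @param increment_bp window growth step (default 0.2 Mb).
#' @param max_length_bp largest window to try (default 5 Mb).
#' @param missing_match wildcard behaviour, see
#'   [define_carrier_haplotype()].
#' @return a `sweep_result`: data.frame `window_bp`, `window_mb`, `n_markers`,
#'   `n_matches`, `ids` (comma-separated non-carrier matches),
#'   `background_freq`; attributes `match_sets` (list), `haplotypes` (list),
#'   `stopped` (reason).
#' @export
coarse_sweep <- function(cohort, map, focal, increment_bp = 200000,
                         max_length_bp = 5e6, missing_match = TRUE) {
  if (increment_bp <= 0) stop_fs("increment must be > 0")
  lens <- seq(increment_bp, max_length_bp, by = increment_bp)

  # Pass 1: resolve consensus ambiguity by survival. An assignment valid at a
  # long window is valid at every shorter one (the constraints are a subset),
  # so the assignment that stays consistent deepest can be used at every
  # window, which is what makes the match sets nested. Small windows alone
  # can be ambiguous (e.g. the known carriers also share their other parental
  # haplotype over a few markers).
  deep_choice <- NULL
  for (L in rev(lens)) {
    hap <- tryCatch(
      define_carrier_haplotype(cohort, map, focal, L, missing_match),
      founderscan_window_error = function(e) NULL)
    if (inherits(hap, "carrier_haplotype")) { deep_choice <- hap$hap_choice; break }
  }

  rows <- list(); sets <- list(); haps <- list()
  stopped <- "max_length"
  prev <- NULL
  for (L in lens) {
    hap <- tryCatch(
      define_carrier_haplotype(cohort, map, focal, L, missing_match,
                               prefer_choice = deep_choice),
      founderscan_window_error = function(e) e)
    if (inherits(hap, "error")) next   # window smaller than marker spacing
    if (inherits(hap, "no_consensus")) {
      stopped <- sprintf("no_consensus_at_%d", as.integer(L))
      break
    }
    m <- scan_cohort(cohort, map, hap)
    ids <- sort(m$id)
    if (!is.null(prev) && !all(ids %in% prev))
      stop_fs("nestedness violated at window ", L)  # cannot happen by construction
    prev <- ids
    rows[[length(rows) + 1L]] <- data.frame(
      window_bp = L, window_mb = round(L / 1e6, 2),
      n_markers = length(hap$marker_idx), n_matches = length(ids),
      ids = paste(ids, collapse = ","),
      background_freq = haplotype_background_frequency(cohort, map, hap),
      stringsAsFactors = FALSE)
    sets[[length(sets) + 1L]] <- ids
    haps[[length(haps) + 1L]] <- hap
    if (length(ids) == 0L) { stopped <- "empty_match_set"; break }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window_bp = numeric(0), window_mb = numeric(0),
               n_markers = integer(0), n_matches = integer(0),
               ids = character(0), background_freq = numeric(0))
  structure(res, match_sets = sets, haplotypes = haps, stopped = stopped,
            class = c("sweep_result", "data.frame"))
}

#' Variant-resolution shared-haplotype measurement between two haplotypes
#'
#' Starting from the four markers physically closest to the focal position
#' (all four must match, else the shared interval is empty), markers are added
#' one at a time in order of increasing distance. A mismatch on one side
#' freezes that side; extension continues on the other until it too
#' mismatches or the chromosome ends. The reported interval spans the
#' outermost matching markers.
#'
#' @param hapA,hapB single haplotype allele vectors over the whole marker set
#'   (0/1/NA; missing is a wildcard).
#' @param map the [marker_map()].
#' @param chrom,focal_pos focal coordinates; `focal_pos` must lie within the
#'   chromosome's mapped range.
#' @return list `start_bp`, `end_bp`, `n_matching_markers`, `length_bp`
#'   (0 with `NA` bounds when empty).
#' @export
fine_extend <- function(hapA, hapB, map, chrom, focal_pos) {
  j <- which(map$chrom == chrom)
  if (length(j) == 0L) stop_fs("no markers on chromosome ", chrom)
  pos <- map$pos[j]
  if (focal_pos < min(pos) || focal_pos > max(pos))
    stop_fs("focal position outside the mapped range of ", chrom)
  a <- hapA[j]; b <- hapB[j]
  agree <- a == b | is.na(a) | is.na(b)
  ord <- order(abs(pos - focal_pos))
  if (length(ord) < 4L || !all(agree[ord[1:4]]))
    return(list(start_bp = NA_real_, end_bp = NA_real_,
                n_matching_markers = 0L, length_bp = 0))
  left <- which(pos < focal_pos)
  right <- which(pos >= focal_pos)
  run_extent <- function(side_idx, outward_order) {
    sel <- side_idx[outward_order]
    bad <- which(!agree[sel])
    if (length(bad)) sel <- sel[seq_len(bad[1L] - 1L)]
    sel
  }
  lsel <- run_extent(left, order(abs(pos[left] - focal_pos)))
  rsel <- run_extent(right, order(abs(pos[right] - focal_pos)))
  keep <- c(lsel, rsel)
  list(start_bp = min(pos[keep]), end_bp = max(pos[keep]),
       n_matching_markers = length(keep),
       length_bp = max(pos[keep]) - min(pos[keep]))
}
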