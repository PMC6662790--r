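#' @keywords internal
"_PACKAGE"

# Derive a reproducible 31-bit substream seed from a master seed and a label.
# All stochastic operations in the package draw their seed through this, so a
# single top-level seed fixes every module's stream independently of call order.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stop_fs <- function(..., class = "founderscan_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
is_rate  <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' Construct a phased cohort container
#'
#' The substrate of all haplotype matching: two allele matrices (individuals by
#' markers), coded `0` = reference, `1` = alternative, `NA` = missing. By
#' convention haplotype 1 is the paternal transmission where known.
#'
#' @param ids character vector of individual ids (unique).
#' @param hap1,hap2 integer matrices, rows = individuals, columns = markers.
#' @param phased logical vector per individual; `FALSE` marks individuals whose
#'   genotypes were read with unknown phase ("/" calls). Unphased individuals
#'   are usable for IBD calling but rejected by haplotype matching.
#' @return an object of class `phased_cohort`.
#' @export
phased_cohort <- function(ids, hap1, hap2, phased = rep(TRUE, length(ids))) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_fs("duplicate individual ids in cohort")
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2))) stop_fs("hap1/hap2 dimensions differ")
  if (nrow(hap1) != length(ids)) stop_fs("ids length != haplotype rows")
  bad <- c(hap1, hap2); bad <- bad[!is.na(bad)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop_fs("allele codes must be 0, 1 or NA")
  rownames(hap1) <- rownames(hap2) <- ids
  structure(list(ids = ids, hap1 = hap1, hap2 = hap2,
                 phased = as.logical(phased)),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("<phased_cohort> %d individuals x %d markers (%d unphased)\n",
              length(x$ids), ncol(x$hap1), sum(!x$phased)))
  invisible(x)
}

#' Number of individuals / markers in a phased cohort
#' @param x a `phased_cohort`.
#' @return integer count.
#' @export
n_individuals <- function(x) length(x$ids)

#' @rdname n_individuals
#' @export
n_markers <- function(x) ncol(x$hap1)

#' Diploid genotype dosage matrix from a phased cohort
#'
#' @param cohort a `phased_cohort`.
#' @return integer matrix individuals x markers with values 0/1/2 (`NA` when
#'   either allele is missing).
#' @export
genotype_matrix <- function(cohort) {
  g <- cohort$hap1 + cohort$hap2
  storage.mode(g) <- "integer"
  g
}

subset_cohort <- function(cohort, ids = cohort$ids, markers = NULL) {
  i <- match(ids, cohort$ids)
  if (anyNA(i)) stop_fs("unknown ids: ", paste(ids[is.na(i)], collapse = ", "))
  j <- if (is.null(markers)) seq_len(ncol(cohort$hap1)) else markers
  phased_cohort(cohort$ids[i],
                cohort$hap1[i, j, drop = FALSE],
                cohort$hap2[i, j, drop = FALSE],
                cohort$phased[i])
}

#' Construct and validate a marker map
#'
#' @param chrom character chromosome per marker.
#' @param pos integer 1-based physical position (bp), strictly increasing
#'   within chromosome.
#' @param id marker ids (defaults to `chrom:pos`).
#' @return a `data.frame` with class `marker_map`.
#' @export
marker_map <- function(chrom, pos, id = paste0(chrom, ":", pos)) {
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  id = as.character(id), stringsAsFactors = FALSE)
  validate_marker_map(m)
  class(m) <- c("marker_map", "data.frame")
  m
}

validate_marker_map <- function(m) {
  if (!all(c("chrom", "pos", "id") %in% names(m))) stop_fs("map needs chrom, pos, id")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (any(diff(p) <= 0)) {
      k <- which(diff(p) <= 0)[1]
      stop_fs(sprintf("map positions not strictly increasing on %s: %s then %s",
                      ch, format(p[k], scientific = FALSE),
                      format(p[k + 1], scientific = FALSE)))
    }
  }
  invisible(m)
}
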