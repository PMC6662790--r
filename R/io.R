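# Readers and writers for the interchange formats: phased VCF (GT only,
# biallelic), PLINK .fam, tab-separated marker map and truth-segment lists,
# and the ECG CSV. Coordinates in files are 1-based (VCF convention);
# internal half-open windows convert only at this boundary.

#' Write a phased cohort as a minimal VCF
#'
#' Emits a VCFv4.2 file with contig headers, one biallelic record per marker
#' (`REF=A`, `ALT=C` as carriers of the 0/1 codes) and GT-only sample
#' columns, `|`-separated for phased individuals, `/`-separated otherwise;
#' missing alleles are written as `.`.
#'
#' @param cohort a [phased_cohort()].
#' @param map matching [marker_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(cohort, map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in unique(map$chrom)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(max(map$pos[map$chrom == ch]) + 1L)), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$ids), collapse = "\t"), con)
  sep <- ifelse(cohort$phased, "|", "/")
  code <- function(h) ifelse(is.na(h), ".", as.character(h))
  a1 <- code(cohort$hap1); a2 <- code(cohort$hap2)
  for (j in seq_len(nrow(map))) {
    gt <- paste0(a1[, j], sep, a2[, j])
    writeLines(paste(c(map$chrom[j], format(map$pos[j], scientific = FALSE),
                       map$id[j], "A", "C", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phased VCF into a cohort and marker map
#'
#' Parses GT fields of biallelic records: `|`-separated calls are phased,
#' `/`-separated calls mark the individual phase-unknown (usable for IBD
#' calling, rejected by haplotype matching), `.` alleles are missing.
#' Multiallelic records are skipped and counted. Malformed lines raise an
#' error naming the line number.
#'
#' @param path a VCF file.
#' @return list: `cohort` (a [phased_cohort()]), `map` (a [marker_map()]),
#'   `n_multiallelic_skipped`.
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop_fs("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop_fs("VCF has no sample columns")
  ids <- cols[-(1:9)]
  body <- which(seq_along(lines) > hdr & nzchar(lines))
  n <- length(body)
  chrom <- character(n); pos <- numeric(n); mid <- character(n)
  h1 <- matrix(NA_integer_, length(ids), n)
  h2 <- matrix(NA_integer_, length(ids), n)
  unphased <- rep(FALSE, length(ids))
  keep <- rep(TRUE, n); n_multi <- 0L
  parse_allele <- function(x) ifelse(x == ".", NA_integer_,
                                     suppressWarnings(as.integer(x)))
  for (k in seq_len(n)) {
    ln <- body[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(cols))
      stop_fs(sprintf("malformed VCF line %d: expected %d fields, found %d",
                      ln, length(cols), length(f)))
    if (grepl(",", f[5L], fixed = TRUE)) { # multiallelic
      keep[k] <- FALSE; n_multi <- n_multi + 1L; next
    }
    gt <- sub(":.*$", "", f[-(1:9)])
    phased_call <- grepl("|", gt, fixed = TRUE)
    parts <- strsplit(gt, "[|/]")
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop_fs(sprintf("malformed VCF line %d: bad GT '%s'", ln,
                      gt[which(bad)[1L]]))
    al <- matrix(parse_allele(unlist(parts)), nrow = 2L)
    if (any(!is.na(al) & !(al %in% c(0L, 1L))))
      stop_fs(sprintf("malformed VCF line %d: non-biallelic allele index", ln))
    chrom[k] <- f[1L]
    pos[k] <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(pos[k])) stop_fs(sprintf("malformed VCF line %d: bad POS", ln))
    mid[k] <- f[3L]
    h1[, k] <- al[1L, ]; h2[, k] <- al[2L, ]
    unphased <- unphased | (!phased_call & !(is.na(al[1L, ]) & is.na(al[2L, ])))
  }
  chrom <- chrom[keep]; pos <- pos[keep]; mid <- mid[keep]
  map <- marker_map(chrom, pos, mid)
  cohort <- phased_cohort(ids, h1[, keep, drop = FALSE],
                          h2[, keep, drop = FALSE], phased = !unphased)
  colnames(cohort$hap1) <- colnames(cohort$hap2) <- map$id
  list(cohort = cohort, map = map, n_multiallelic_skipped = n_multi)
}

#' Read / write a PLINK-style .fam pedigree
#'
#' Columns FID IID PAT MAT SEX PHENO, whitespace-separated; `"0"` parents
#' denote founders. Duplicate IIDs are an error.
#'
#' @param path file path.
#' @return for `read_fam`, a `pedigree` data.frame.
#' @export
read_fam <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("fid", "iid", "pat", "mat", "sex",
                                       "pheno"))
  if (anyDuplicated(d$iid))
    stop_fs("duplicate IID in ", path, ": ",
            d$iid[duplicated(d$iid)][1L])
  ped <- data.frame(id = as.character(d$iid),
                    father = ifelse(d$pat == "0", NA, as.character(d$pat)),
                    mother = ifelse(d$mat == "0", NA, as.character(d$mat)),
                    sex = as.integer(d$sex),
                    kindred = as.character(d$fid),
                    gen = NA_integer_, recorded = TRUE, married_in = FALSE,
                    stringsAsFactors = FALSE)
  ped <- sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname read_fam
#' @param ped a `pedigree`.
#' @param pheno optional named phenotype vector (default `-9`).
#' @export
write_fam <- function(ped, path, pheno = NULL) {
  ph <- if (is.null(pheno)) rep(-9, nrow(ped)) else pheno[ped$id]
  utils::write.table(
    data.frame(fid = ifelse(is.na(ped$kindred), "0", ped$kindred),
               iid = ped$id,
               pat = ifelse(is.na(ped$father), "0", ped$father),
               mat = ifelse(is.na(ped$mother), "0", ped$mother),
               sex = ped$sex, pheno = ph),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read / write a tab-separated marker map (chrom, pos, id)
#'
#' Positions must be strictly increasing within chromosome; an unsorted map
#' is rejected naming the offending pair.
#'
#' @param path file path.
#' @return for `read_map`, a [marker_map()].
#' @export
read_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  marker_map(d$chrom, d$pos, d$id)
}

#' @rdname read_map
#' @param map a [marker_map()].
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "pos", "id")], path,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read / write an ECG table (CSV: id, qt_ms, rr_s)
#'
#' @param path file path.
#' @return for `read_ecg`, a data.frame with `id`, `qt_ms`, `rr_s` and a
#'   computed `qtc_ms`.
#' @export
read_ecg <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "qt_ms", "rr_s") %in% names(d)))
    stop_fs("ECG table needs columns id, qt_ms, rr_s")
  d$qtc_ms <- bazett_qtc(d$qt_ms, d$rr_s)
  d
}

#' @rdname read_ecg
#' @param ecg a data.frame with `id`, `qt_ms`, `rr_s`.
#' @export
write_ecg <- function(ecg, path) {
  utils::write.csv(ecg[, c("id", "qt_ms", "rr_s")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write truth IBD segment lists (tab-separated)
#'
#' @param path file path.
#' @return for `read_truth_ibd`, the truth data.frame of [gene_drop()].
#' @export
read_truth_ibd <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_truth_ibd
#' @param truth a truth data.frame.
#' @export
write_truth_ibd <- function(truth, path) {
  utils::write.table(truth, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
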