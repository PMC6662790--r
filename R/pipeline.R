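# End-to-end discovery pipeline mirroring the study design: QC -> consensus
# definition / coarse sweep -> cohort scan -> confirmation -> fine extension
# -> IBD sharing summaries -> carrier report. In simulation the confirmatory
# assay (in practice targeted sequencing of matched individuals) is a lookup
# in the simulator's truth carrier set.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_fs("pipeline stage '", name, "' failed: ", conditionMessage(e),
            class = "founderscan_stage_error"))
}

#' Run the full carrier-discovery pipeline on a simulated cohort
#'
#' @param config a [sim_config()] describing the cohort, or an existing
#'   result of [simulate_cohort()].
#' @param out_dir optional directory; when given, inputs, intermediate tables,
#'   the report and a machine-readable run manifest are written there.
#' @param confirm confirmation oracle: a function mapping ids to logical
#'   carrier status. Defaults to the simulation truth (the stand-in for
#'   confirmatory sequencing).
#' @param f_reference reference allele frequency for the enrichment report.
#' @param increment_bp,max_length_bp sweep geometry.
#' @return list of class `pipeline_result`: `sim`, `qc`, `sweep`,
#'   `nomination` (`window_bp`, `ids`), `fine` (per nominated id), `ibd`
#'   (`segments`, `summary`), `report` (a `carrier_stats`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, confirm = NULL,
                         f_reference = 8.1e-6, increment_bp = 200000,
                         max_length_bp = 5e6) {
  sim <- if (inherits(config, "sim_config"))
    stage("simulate", simulate_cohort(config)) else config
  cfg <- sim$config

  if (is.null(confirm))
    confirm <- function(ids) ids %in% sim$focal$carrier_ids

  qc <- stage("qc", run_qc(genotype_matrix(sim$cohort), sim$pedigree))
  cohort_qc <- stage("qc", {
    cq <- subset_cohort(sim$cohort, qc$retained_ids,
                        match(qc$retained_markers, sim$map$id))
    if (nrow(qc$mendel_masked)) {
      for (i in seq_len(nrow(qc$mendel_masked))) {
        r <- match(qc$mendel_masked$individual[i], cq$ids)
        c <- match(qc$mendel_masked$marker[i], qc$retained_markers)
        if (!is.na(r) && !is.na(c)) {
          cq$hap1[r, c] <- NA_integer_; cq$hap2[r, c] <- NA_integer_
        }
      }
    }
    cq
  })
  map_qc <- sim$map[match(qc$retained_markers, sim$map$id), , drop = FALSE]
  class(map_qc) <- class(sim$map)

  focal <- sim$focal
  focal$known_carrier_ids <- intersect(focal$known_carrier_ids, cohort_qc$ids)
  if (length(focal$known_carrier_ids) == 0L)
    stop_fs("pipeline stage 'sweep' failed: no known carriers survived QC",
            class = "founderscan_stage_error")

  sweep <- stage("sweep",
                 coarse_sweep(cohort_qc, map_qc, focal, increment_bp,
                              max_length_bp))

  # Matches at every window are put through the confirmation assay, as the
  # study did with its shorter-haplotype sharers; nominated carriers are the
  # union of confirmed matches over the windows up to the first window whose
  # entire match set confirms (the uniqueness window).
  nomination <- stage("scan", {
    sets <- attr(sweep, "match_sets")
    win <- NA_real_; ids <- character(0)
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      ids <- union(ids, s[confirm(s)])
      if (length(s) > 0L && all(confirm(s))) {
        win <- sweep$window_bp[i]
        break
      }
    }
    list(window_bp = win, ids = sort(ids))
  })

  fine <- stage("fine_extend", {
    if (length(nomination$ids) == 0L) list() else {
      haps <- attr(sweep, "haplotypes")
      anchor <- focal$known_carrier_ids[1L]
      a_row <- match(anchor, cohort_qc$ids)
      a_h <- haps[[1L]]$hap_choice[[anchor]]
      hapA <- if (a_h == 1L) cohort_qc$hap1[a_row, ] else cohort_qc$hap2[a_row, ]
      out <- list()
      for (id in nomination$ids) {
        # use the matched haplotype at the last window where the id matched
        b_h <- NA_integer_
        for (i in rev(seq_along(haps))) {
          m <- scan_cohort(cohort_qc, map_qc, haps[[i]])
          k <- match(id, m$id)
          if (!is.na(k)) { b_h <- m$hap[k]; break }
        }
        if (is.na(b_h)) next
        b_row <- match(id, cohort_qc$ids)
        hapB <- if (b_h == 1L) cohort_qc$hap1[b_row, ] else
          cohort_qc$hap2[b_row, ]
        out[[id]] <- fine_extend(hapA, hapB, map_qc, focal$chrom,
                                 focal$position_bp)
      }
      out
    }
  })

  ibd <- stage("ibd", {
    if (length(nomination$ids) == 0L) NULL else {
      g <- genotype_matrix(cohort_qc)
      freqs <- colMeans(g, na.rm = TRUE) / 2
      idA <- focal$known_carrier_ids[1L]; idB <- nomination$ids[1L]
      segs <- call_ibd_segments(g[idA, ], g[idB, ], map_qc, freqs = freqs)
      list(pair = c(idA, idB), segments = segs,
           summary = summarize_sharing(segs, focal = list(
             chrom = focal$chrom, position_bp = focal$position_bp)))
    }
  })

  report <- stage("report", {
    all_carriers <- union(focal$known_carrier_ids, nomination$ids)
    carrier_stats(length(all_carriers), length(cohort_qc$ids),
                  f_reference = f_reference, ecg = sim$ecg,
                  carrier_ids = all_carriers)
  })

  manifest <- list(
    package = "founderscan",
    package_version = as.character(utils::packageVersion("founderscan")),
    r_version = R.version.string,
    seed = cfg$seed,
    stages = c("simulate", "qc", "sweep", "scan", "fine_extend", "ibd",
               "report"),
    parameters = list(increment_bp = increment_bp,
                      max_length_bp = max_length_bp,
                      f_reference = f_reference),
    n_individuals = length(cohort_qc$ids),
    n_markers = length(qc$retained_markers),
    nomination = nomination)

  res <- structure(list(sim = sim, qc = qc, sweep = sweep,
                        nomination = nomination, fine = fine, ibd = ibd,
                        report = report, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, map_qc, out_dir)
  res
}

write_pipeline_outputs <- function(res, map_qc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- res$sim
  write_phased_vcf(sim$cohort, sim$map, file.path(out_dir, "cohort.vcf"))
  write_map(sim$map, file.path(out_dir, "markers.tsv"))
  write_fam(sim$pedigree, file.path(out_dir, "pedigree.fam"))
  write_ecg(sim$ecg, file.path(out_dir, "ecg.csv"))
  write_truth_ibd(sim$truth, file.path(out_dir, "truth_ibd.tsv"))
  utils::write.table(as.data.frame(res$sweep), file.path(out_dir, "sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$ibd))
    utils::write.table(res$ibd$segments, file.path(out_dir, "ibd_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(nominated = res$nomination$ids,
         nomination_window_bp = res$nomination$window_bp,
         allele_frequency = res$report$allele_frequency,
         fold_enrichment = res$report$fold_enrichment),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
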