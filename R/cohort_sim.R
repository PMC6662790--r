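# Synthetic isolate-cohort simulator: founder haplotypes, gene dropping down a
# pedigree under a Haldane (no-interference) crossover model, ground-truth
# identity-by-descent bookkeeping, a focal variant planted on one founder
# haplotype, array-style ascertainment/corruption, and QTc phenotypes.
#
# Coordinates: marker positions are 1-based bp; truth segments are half-open
# [start, end) on the 0-based line, tiling [0, chrom_length) exactly. A marker
# at 1-based position p falls in the segment containing offset p - 1.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate founder haplotypes and a marker map
#'
#' Marker positions are drawn uniformly (then sorted, unique) along each
#' chromosome at `marker_density` per Mb; per-marker alternative allele
#' frequencies are drawn uniformly from the founder MAF spectrum; founder
#' alleles are i.i.d. Bernoulli draws (no background linkage disequilibrium,
#' which keeps haplotype-uniqueness arithmetic analytic).
#'
#' @param config a [sim_config()].
#' @param n_founders number of diploid founders; defaults to
#'   `config$n_founders`.
#' @param seed optional seed (defaults to a substream of `config$seed`).
#' @return list with `map` (a [marker_map()]), `freq` (alt allele frequency per
#'   marker) and `haps` (2 x n_founders by markers 0/1 matrix; rows `2i-1`,
#'   `2i` belong to founder `i`).
#' @export
simulate_founders <- function(config, n_founders = config$n_founders,
                              seed = NULL) {
  if (is.null(n_founders) || !is_count(n_founders) || n_founders < 1)
    stop_fs("n_founders must be a positive count")
  if (config$marker_density <= 0) stop_fs("marker_density must be > 0")
  if (any(config$genome$length_bp <= 0)) stop_fs("zero-length chromosome")
  seed <- seed %||% substream_seed(config$seed, "founders")
  with_seed(seed, {
    maps <- lapply(seq_len(nrow(config$genome)), function(i) {
      L <- config$genome$length_bp[i]
      n <- max(1L, round(config$marker_density * L / 1e6))
      pos <- sort(sample.int(L, n))
      data.frame(chrom = config$genome$chrom[i], pos = pos,
                 stringsAsFactors = FALSE)
    })
    mp <- do.call(rbind, maps)
    map <- marker_map(mp$chrom, mp$pos,
                      id = sprintf("snp_%s_%d", mp$chrom, mp$pos))
    m <- nrow(map)
    freq <- stats::runif(m, config$founder_maf[1], config$founder_maf[2])
    haps <- matrix(stats::rbinom(2L * n_founders * m, 1L,
                                 rep(freq, each = 2L * n_founders)),
                   nrow = 2L * n_founders, ncol = m)
    storage.mode(haps) <- "integer"
    list(map = map, freq = freq, haps = haps)
  })
}

# one meiosis on one chromosome: Haldane model, crossover count Poisson with
# mean = genetic length in Morgans, positions uniform
meiosis_breaks <- function(L, cm_per_mb) {
  morgans <- L / 1e6 * cm_per_mb / 100
  k <- stats::rpois(1L, morgans)
  list(breaks = sort(stats::runif(k, 0, L)),
       start = sample.int(2L, 1L))
}

# recombine truth segment lists (vectors start/end/lab) of the two parental
# haplotypes according to crossover breakpoints
recombine_truth <- function(t1, t2, breaks, start, L) {
  bnd <- c(0, breaks, L)
  ni <- length(bnd) - 1L
  src <- ((start - 1L + seq_len(ni) - 1L) %% 2L) + 1L
  os <- vector("list", ni); oe <- vector("list", ni); ol <- vector("list", ni)
  for (i in seq_len(ni)) {
    a <- bnd[i]; b <- bnd[i + 1L]
    if (a >= b) next
    tt <- if (src[i] == 1L) t1 else t2
    keep <- tt$end > a & tt$start < b
    os[[i]] <- pmax(tt$start[keep], a)
    oe[[i]] <- pmin(tt$end[keep], b)
    ol[[i]] <- tt$lab[keep]
  }
  list(start = unlist(os), end = unlist(oe), lab = unlist(ol))
}

recombine_alleles <- function(h1, h2, pos, breaks, start) {
  idx <- findInterval(pos - 0.5, breaks)
  src <- ((start - 1L + idx) %% 2L) + 1L
  ifelse(src == 1L, h1, h2)
}

truth_covers <- function(tr, pos0, lab, span = 0) {
  # one segment with the label must cover [pos0 - span/2, pos0 + span/2]
  any(tr$start <= pos0 - span / 2 & pos0 + span / 2 < tr$end & tr$lab == lab)
}

#' Gene-drop founder haplotypes down a pedigree
#'
#' Transmits recombined parental haplotypes to every non-founder (haplotype 1
#' paternal, haplotype 2 maternal) under the Haldane model at the configured
#' uniform cM/Mb rate, recording the founder origin of every transmitted
#' segment. With `founders = NULL` only the truth segments are propagated
#' (fast mode for calibration).
#'
#' @param pedigree a `pedigree` (parents precede children).
#' @param founders output of [simulate_founders()], or `NULL` for truth-only.
#' @param config a [sim_config()].
#' @param seed optional seed (defaults to a substream of `config$seed`).
#' @param condition optional list(`chrom`, `position_bp`, `founder_hap`,
#'   `ids`): for each id listed, the transmission from its carrier parent is
#'   redrawn until the child inherits the named founder haplotype at the
#'   position (ascertainment conditioning; see the methods vignette).
#' @return list with `cohort` (a [phased_cohort()] over all pedigree members,
#'   `NULL` in truth-only mode), `truth` (data.frame `id`, `hap`, `chrom`,
#'   `start`, `end`, `founder_hap`; half-open 0-based segments tiling each
#'   chromosome) and `map`.
#' @export
gene_drop <- function(pedigree, founders, config, seed = NULL,
                      condition = NULL) {
  seed <- seed %||% substream_seed(config$seed, "genedrop")
  genome <- config$genome
  have_alleles <- !is.null(founders)
  map <- if (have_alleles) founders$map else NULL
  chroms <- genome$chrom
  chrom_idx <- if (have_alleles)
    lapply(chroms, function(ch) which(map$chrom == ch)) else NULL
  fids <- pedigree_founders(pedigree)
  if (have_alleles && nrow(founders$haps) < 2L * length(fids))
    stop_fs("founder pool smaller than the number of pedigree founders")

  with_seed(seed, {
    haps <- new.env(parent = emptyenv())
    truth <- new.env(parent = emptyenv())

    for (fi in seq_along(fids)) {
      id <- fids[fi]
      if (have_alleles)
        assign(id, list(founders$haps[2L * fi - 1L, ],
                        founders$haps[2L * fi, ]), envir = haps)
      tr <- lapply(1:2, function(h)
        lapply(seq_along(chroms), function(ci)
          list(start = 0, end = genome$length_bp[ci],
               lab = paste0(id, ":", h))))
      assign(id, tr, envir = truth)
    }

    transmit <- function(parent_id) {
      pt <- get(parent_id, envir = truth)
      ph <- if (have_alleles) get(parent_id, envir = haps) else NULL
      out_t <- vector("list", length(chroms))
      out_a <- if (have_alleles) vector("list", length(chroms)) else NULL
      for (ci in seq_along(chroms)) {
        mb <- meiosis_breaks(genome$length_bp[ci], config$cm_per_mb)
        out_t[[ci]] <- recombine_truth(pt[[1]][[ci]], pt[[2]][[ci]],
                                       mb$breaks, mb$start,
                                       genome$length_bp[ci])
        if (have_alleles) {
          j <- chrom_idx[[ci]]
          out_a[[ci]] <- recombine_alleles(ph[[1]][j], ph[[2]][j],
                                           map$pos[j], mb$breaks, mb$start)
        }
      }
      list(truth = out_t, alleles = if (have_alleles) unlist(out_a))
    }

    cond_ci <- if (!is.null(condition))
      match(condition$chrom, chroms) else NA_integer_
    if (!is.null(condition) && is.na(cond_ci))
      stop_fs("condition chromosome not in genome")

    nonf <- pedigree[!(pedigree$id %in% fids), , drop = FALSE]
    for (i in seq_len(nrow(nonf))) {
      id <- nonf$id[i]; fa <- nonf$father[i]; mo <- nonf$mother[i]
      if (!exists(fa, envir = truth) || !exists(mo, envir = truth))
        stop_fs("missing parent haplotypes for ", id)
      tf <- transmit(fa)
      tm <- transmit(mo)
      if (!is.null(condition) && id %in% condition$ids) {
        pos0 <- condition$position_bp - 1
        lab <- condition$founder_hap
        span <- condition$span_bp %||% 0
        par_has <- function(pid, sp) {
          pt <- get(pid, envir = truth)
          truth_covers(pt[[1]][[cond_ci]], pos0, lab, sp) ||
            truth_covers(pt[[2]][[cond_ci]], pos0, lab, sp)
        }
        # condition on the ascertained span where the parent can provide it,
        # else on bare coverage of the focal position
        redraw_from <- if (par_has(fa, 0)) "f" else
          if (par_has(mo, 0)) "m" else NA
        if (!is.na(redraw_from)) {
          sp <- if (par_has(if (redraw_from == "f") fa else mo, span))
            span else 0
          tries <- 0L
          repeat {
            got <- if (redraw_from == "f")
              truth_covers(tf$truth[[cond_ci]], pos0, lab, sp)
            else truth_covers(tm$truth[[cond_ci]], pos0, lab, sp)
            if (got || tries >= 200L) break
            if (redraw_from == "f") tf <- transmit(fa) else tm <- transmit(mo)
            tries <- tries + 1L
          }
        }
      }
      assign(id, lapply(1:2, function(h)
        (if (h == 1L) tf else tm)$truth), envir = truth)
      if (have_alleles)
        assign(id, list(tf$alleles, tm$alleles), envir = haps)
    }

    ids <- pedigree$id
    cohort <- NULL
    if (have_alleles) {
      h1 <- t(vapply(ids, function(id) get(id, envir = haps)[[1]],
                     integer(nrow(map))))
      h2 <- t(vapply(ids, function(id) get(id, envir = haps)[[2]],
                     integer(nrow(map))))
      cohort <- phased_cohort(ids, h1, h2)
      colnames(cohort$hap1) <- colnames(cohort$hap2) <- map$id
    }
    truth_df <- do.call(rbind, lapply(ids, function(id) {
      tr <- get(id, envir = truth)
      do.call(rbind, lapply(1:2, function(h)
        do.call(rbind, lapply(seq_along(chroms), function(ci) {
          t <- tr[[h]][[ci]]
          if (length(t$start) == 0L) return(NULL)
          data.frame(id = id, hap = h, chrom = chroms[ci],
                     start = t$start, end = t$end, founder_hap = t$lab,
                     stringsAsFactors = FALSE)
        }))))
    }))
    rownames(truth_df) <- NULL
    list(cohort = cohort, truth = truth_df, map = map)
  })
}

#' Determine the truth carrier set of a planted focal variant
#'
#' The focal variant lives on one named founder haplotype at a position that
#' is deliberately not part of the marker set (the array-absent "unmeasured
#' SNP of interest"). An individual is a truth carrier iff at least one of its
#' haplotypes traces to that founder haplotype at the focal position.
#'
#' @param truth truth data.frame from [gene_drop()].
#' @param founder_hap founder haplotype label, e.g. `"K1_G1M1:1"`.
#' @param chrom,position_bp focal coordinates (1-based bp).
#' @return a `focal_variant` list: `chrom`, `position_bp`, `carrier_ids`
#'   (truth), `founder_hap`, and `known_carrier_ids` (initially empty).
#' @export
plant_variant <- function(truth, founder_hap, chrom, position_bp) {
  if (!founder_hap %in% truth$founder_hap)
    stop_fs("unknown founder haplotype label: ", founder_hap)
  pos0 <- position_bp - 1
  hit <- truth$chrom == chrom & truth$start <= pos0 & pos0 < truth$end &
    truth$founder_hap == founder_hap
  if (!any(truth$chrom == chrom))
    stop_fs("focal position outside simulated genome: ", chrom)
  structure(list(chrom = chrom, position_bp = position_bp,
                 carrier_ids = unique(truth$id[hit]),
                 founder_hap = founder_hap,
                 known_carrier_ids = character(0)),
            class = "focal_variant")
}

#' Ascertain array markers and inject realistic corruption
#'
#' Drops markers whose cohort minor allele frequency falls below
#' `array_maf_min` (emulating array content: the rare focal variant itself is
#' never on the array), then injects per-allele genotype errors, per-genotype
#' missingness, and per-marker phase switch errors (each switch flips the
#' maternal/paternal assignment downstream within the chromosome).
#'
#' @param cohort a [phased_cohort()].
#' @param map matching [marker_map()].
#' @param config a [sim_config()] supplying the rates.
#' @param seed optional seed (defaults to a substream of `config$seed`).
#' @return list with corrupted `cohort` and reduced `map`.
#' @export
ascertain_and_corrupt <- function(cohort, map, config, seed = NULL) {
  seed <- seed %||% substream_seed(config$seed, "array")
  n <- length(cohort$ids); m <- ncol(cohort$hap1)
  f <- colMeans(rbind(cohort$hap1, cohort$hap2), na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  keep <- which(maf >= config$array_maf_min)
  if (length(keep) == 0L) stop_fs("array ascertainment dropped all markers")
  h1 <- cohort$hap1[, keep, drop = FALSE]
  h2 <- cohort$hap2[, keep, drop = FALSE]
  map2 <- map[keep, , drop = FALSE]
  class(map2) <- class(map)
  m2 <- length(keep)
  with_seed(seed, {
    if (config$genotype_error_rate > 0) {
      e1 <- matrix(stats::rbinom(n * m2, 1L, config$genotype_error_rate), n, m2)
      e2 <- matrix(stats::rbinom(n * m2, 1L, config$genotype_error_rate), n, m2)
      h1 <- abs(h1 - e1); h2 <- abs(h2 - e2)
      storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
    }
    if (config$missing_rate > 0) {
      mis <- matrix(stats::rbinom(n * m2, 1L, config$missing_rate), n, m2) == 1L
      h1[mis] <- NA_integer_; h2[mis] <- NA_integer_
    }
    if (config$switch_error_rate > 0) {
      flips <- matrix(stats::rbinom(n * m2, 1L, config$switch_error_rate), n, m2)
      parity <- matrix(0L, n, m2)
      for (ch in unique(map2$chrom)) {
        j <- which(map2$chrom == ch)
        parity[, j] <- t(apply(flips[, j, drop = FALSE], 1L, cumsum)) %% 2L
      }
      sw <- parity == 1L
      tmp <- h1[sw]; h1[sw] <- h2[sw]; h2[sw] <- tmp
    }
  })
  out <- phased_cohort(cohort$ids, h1, h2, cohort$phased)
  colnames(out$hap1) <- colnames(out$hap2) <- map2$id
  list(cohort = out, map = map2)
}

#' Simulate QT/RR electrocardiogram records with a carrier QTc shift
#'
#' Penetrant carriers draw QTc from the carrier mean, everyone else from the
#' non-carrier mean (normal, common sd). RR intervals are drawn uniformly on
#' 0.75-1.10 s and QT is back-computed so that Bazett's correction recovers
#' the drawn QTc exactly.
#'
#' @param ids individual ids.
#' @param carrier_ids subset of `ids` that carry the variant.
#' @param config a [sim_config()] (uses `qtc_model`).
#' @param seed optional seed (defaults to a substream of `config$seed`).
#' @return data.frame: `id`, `qt_ms`, `rr_s`, `qtc_ms`, `carrier`.
#' @export
simulate_qtc <- function(ids, carrier_ids, config, seed = NULL) {
  qm <- config$qtc_model
  if (!is_rate(qm$penetrance)) stop_fs("penetrance must be in [0,1]")
  if (qm$sd < 0) stop_fs("qtc sd must be >= 0")
  seed <- seed %||% substream_seed(config$seed, "qtc")
  with_seed(seed, {
    n <- length(ids)
    carrier <- ids %in% carrier_ids
    penetrant <- carrier & stats::rbinom(n, 1L, qm$penetrance) == 1L
    mu <- ifelse(penetrant, qm$carrier_mean, qm$noncarrier_mean)
    qtc <- stats::rnorm(n, mu, qm$sd)
    rr <- stats::runif(n, 0.75, 1.10)
    data.frame(id = ids, qt_ms = qtc * sqrt(rr), rr_s = rr, qtc_ms = qtc,
               carrier = carrier, stringsAsFactors = FALSE)
  })
}

#' Simulate a full synthetic isolate cohort
#'
#' Orchestrates [build_pedigree()], [simulate_founders()], [gene_drop()],
#' [plant_variant()], [ascertain_and_corrupt()] and [simulate_qtc()] under
#' named substreams of one master seed. When the pedigree contains a hidden
#' third-cousin link, the focal variant is planted on haplotype 1 of the first
#' link's hidden ancestral father and its transmission down both hidden chains
#' (plus to two children of the first chain bottom and one child of the
#' second) is conditioned on, emulating how such variants are ascertained in
#' practice: a sequenced proband with two confirmed relatives in one kindred,
#' and a cryptic carrier parent-offspring pair in another. The three
#' conditioned kindred-1 carriers become the known carriers.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `pedigree`, `founders`, `truth` (truth IBD
#'   segments), `cohort_true` (error-free phased cohort over recorded
#'   individuals), `cohort` + `map` (array-ascertained, corrupted),
#'   `map_full`, `focal` (with `known_carrier_ids` filled), `ecg`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$pedigree
  linked <- spec$n_third_cousin_links > 0

  ped <- NULL; bottoms <- NULL
  for (attempt in 0:49) {
    # a kindred can die out stochastically (Poisson sibship of zero);
    # retry deterministically on the next substream
    p <- tryCatch(
      build_pedigree(spec, substream_seed(config$seed,
                                          paste0("pedigree", attempt))),
      founderscan_error = function(e) NULL)
    if (is.null(p)) next
    if (!linked) { ped <- p; break }
    lp <- attr(p, "link_pairs")
    kids_a <- p$id[!is.na(p$father) &
                     (p$father == lp$bottom_a[1] | p$mother == lp$bottom_a[1])]
    kids_b <- p$id[!is.na(p$father) &
                     (p$father == lp$bottom_b[1] | p$mother == lp$bottom_b[1])]
    if (length(kids_a) >= 2L && length(kids_b) >= 1L) {
      ped <- p
      bottoms <- list(a = lp$bottom_a[1], b = lp$bottom_b[1],
                      kids_a = sort(kids_a)[1:2], kids_b = sort(kids_b)[1],
                      hidden_father = lp$hidden_father[1])
      break
    }
  }
  if (is.null(ped))
    stop_fs("could not build a pedigree satisfying the link conditioning")

  n_found <- config$n_founders %||% length(pedigree_founders(ped))
  founders <- simulate_founders(config, n_founders = n_found)

  condition <- NULL
  label <- paste0(pedigree_founders(ped)[1], ":1")
  if (linked) {
    label <- paste0(bottoms$hidden_father, ":1")
    chain_ids <- grep("^L1_[AB][1-4]$", ped$id, value = TRUE)
    condition <- list(chrom = config$focal$chrom,
                      position_bp = config$focal$position_bp,
                      founder_hap = label,
                      span_bp = config$focal$min_shared_bp %||% 1.22e6,
                      ids = c(chain_ids, bottoms$kids_a, bottoms$kids_b))
  }
  gd <- gene_drop(ped, founders, config, condition = condition)
  focal <- plant_variant(gd$truth, label, config$focal$chrom,
                         config$focal$position_bp)
  recorded <- ped$id[ped$recorded]
  known <- if (linked) c(bottoms$a, bottoms$kids_a) else
    utils::head(intersect(recorded, focal$carrier_ids), 3L)
  focal$known_carrier_ids <- known

  cohort_true <- subset_cohort(gd$cohort, recorded)
  arr <- ascertain_and_corrupt(cohort_true, gd$map, config)
  ecg <- simulate_qtc(recorded, intersect(focal$carrier_ids, recorded), config)

  list(config = config, pedigree = ped, founders = founders,
       truth = gd$truth, cohort_true = cohort_true,
       cohort = arr$cohort, map = arr$map, map_full = gd$map,
       focal = focal, ecg = ecg)
}
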