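# Simulator: pedigree construction, founder draws, gene dropping, variant
# planting, array corruption, QTc phenotypes, and the module invariants.

count_meioses <- function(ped, a, b) {
  # shortest path up-down through the unique shared ancestral couple
  up <- function(id) {
    out <- c(); frontier <- c(stats::setNames(0L, id))
    while (length(frontier)) {
      nxt <- c()
      for (i in seq_along(frontier)) {
        r <- ped[ped$id == names(frontier)[i], ]
        for (p in c(r$father, r$mother)) if (!is.na(p))
          nxt <- c(nxt, stats::setNames(frontier[[i]] + 1L, p))
      }
      out <- c(out, frontier); frontier <- nxt
    }
    out
  }
  ua <- up(a); ub <- up(b)
  shared <- intersect(names(ua), names(ub))
  min(ua[shared] + ub[shared])
}

test_that("pedigree generator honours degenerate and linked specs", {
  # one generation: founders only, no matings
  p1 <- build_pedigree(pedigree_spec(
    kindreds = list(kindred_spec(generations = 1, n_founder_couples = 5)),
    n_third_cousin_links = 0, n_unrelated = 0), seed = 1)
  expect_equal(nrow(p1), 10L)
  expect_setequal(pedigree_founders(p1), p1$id)

  # a hidden link puts the two chain bottoms exactly 8 meioses apart,
  # sharing one great-great-grandparental couple
  p2 <- build_pedigree(pedigree_spec(n_unrelated = 0), seed = 2)
  lp <- attr(p2, "link_pairs")
  expect_equal(count_meioses(p2, lp$bottom_a, lp$bottom_b), 8L)
  # great-great-grandparents of each bottom include the hidden couple
  anc <- function(id, k) {
    ids <- id
    for (i in seq_len(k)) {
      ids <- unlist(lapply(ids, function(x) {
        r <- p2[p2$id == x, ]; c(r$father, r$mother)
      }))
      ids <- ids[!is.na(ids)]
    }
    ids
  }
  shared4 <- intersect(anc(lp$bottom_a, 4), anc(lp$bottom_b, 4))
  expect_setequal(shared4, c(lp$hidden_father, lp$hidden_mother))
  for (k in 1:3)
    expect_length(intersect(anc(lp$bottom_a, k), anc(lp$bottom_b, k)), 0)
  # linking ancestors are unrecorded
  expect_false(any(p2$recorded[p2$id %in% c(lp$hidden_father, lp$hidden_mother)]))

  expect_error(kindred_spec(generations = 3, mean_sibship = 0),
               "impossible")
})

test_that("kindred member count equals an independent replay of the sampling rules", {
  spec <- pedigree_spec(kindreds = list(kindred_spec(3, 2.5)),
                        n_third_cousin_links = 0, n_unrelated = 0)
  ped <- build_pedigree(spec, seed = 7)
  # replay: same RNG sequence, counting members by the documented rules
  set.seed(7)
  n <- 2L                                  # founder couple
  couples <- 1L
  for (g in 1:2) {
    nxt <- 0L
    for (cpl in seq_len(couples)) {
      kids <- rpois(1, 2.5)
      for (j in seq_len(kids)) {
        rbinom(1, 1, 0.5)                  # sex draw
        n <- n + 1L
        if (g + 1L < 3L) { n <- n + 1L; nxt <- nxt + 1L }  # spouse
      }
    }
    couples <- nxt
  }
  expect_equal(nrow(ped), n)
})

test_that("founder simulation matches its frequency spectrum and is deterministic", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length_bp = 34e6),
                    marker_density = 30, founder_maf = c(0.5, 0.5), seed = 11)
  f <- simulate_founders(cfg, n_founders = 40)
  m <- nrow(f$map)
  expect_true(all(diff(f$map$pos) > 0))
  # mean allele frequency ~ 0.5 within 3 binomial SE over 80*m draws
  se <- sqrt(0.25 / (80 * m))
  expect_lt(abs(mean(f$haps) - 0.5), 3 * se)

  f1 <- simulate_founders(cfg, n_founders = 1)
  expect_equal(nrow(f1$haps), 2L)

  f2a <- simulate_founders(cfg, n_founders = 5, seed = 99)
  f2b <- simulate_founders(cfg, n_founders = 5, seed = 99)
  expect_identical(f2a, f2b)

  expect_error(simulate_founders(
    sim_config(genome = data.frame(chrom = "c", length_bp = 1e6),
               marker_density = -1), n_founders = 2), "marker_density")
  expect_error(sim_config(genome = data.frame(chrom = "c", length_bp = 0)),
               "length")
})

test_that("gene dropping transmits whole haplotypes at zero recombination", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length_bp = 20e6),
                    cm_per_mb = 0, pedigree = pedigree_spec(
                      kindreds = list(kindred_spec(2, 3)),
                      n_third_cousin_links = 0, n_unrelated = 0),
                    seed = 5)
  ped <- build_pedigree(cfg$pedigree, seed = 5)
  fo <- simulate_founders(cfg, n_founders = length(pedigree_founders(ped)))
  gd <- gene_drop(ped, fo, cfg)
  kids <- setdiff(ped$id, pedigree_founders(ped))
  for (id in kids) {
    r <- ped[ped$id == id, ]
    i <- match(id, gd$cohort$ids)
    fi <- match(r$father, gd$cohort$ids)
    child_pat <- gd$cohort$hap1[i, ]
    expect_true(identical(child_pat, gd$cohort$hap1[fi, ]) ||
                  identical(child_pat, gd$cohort$hap2[fi, ]))
  }
})

test_that("truth segments tile every chromosome and Mendelian errors are absent", {
  cfg <- sim_config(seed = 21,
                    pedigree = pedigree_spec(n_unrelated = 5))
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  set.seed(1)
  for (id in sample(unique(tr$id), 10)) {
    for (h in 1:2) for (ci in seq_len(nrow(cfg$genome))) {
      ch <- cfg$genome$chrom[ci]
      s <- tr[tr$id == id & tr$hap == h & tr$chrom == ch, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 0)
      expect_equal(s$end[nrow(s)], cfg$genome$length_bp[ci])
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
    }
  }
  # error-free gene-drop output has zero Mendelian flags
  err <- mendel_error_scan(sim$pedigree, genotype_matrix(sim$cohort_true))
  expect_equal(nrow(err), 0L)
})

test_that("simulate_cohort is deterministic given its config", {
  cfg <- sim_config(seed = 33, pedigree = pedigree_spec(n_unrelated = 10))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ecg, b$ecg)
  expect_identical(a$focal, b$focal)
})

test_that("planted variant follows founder-haplotype descent", {
  cfg <- sim_config(seed = 13, pedigree = pedigree_spec(n_unrelated = 2))
  ped <- build_pedigree(cfg$pedigree, seed = 13)
  fo <- simulate_founders(cfg, n_founders = length(pedigree_founders(ped)))
  gd <- gene_drop(ped, fo, cfg)
  lab <- paste0(pedigree_founders(ped)[1], ":1")
  fv <- plant_variant(gd$truth, lab, "chr2", 25e6)
  # the founder itself is a carrier
  expect_true(pedigree_founders(ped)[1] %in% fv$carrier_ids)
  # children: carrier iff their truth segment at the locus has the label
  founder <- pedigree_founders(ped)[1]
  kids <- ped$id[!is.na(ped$father) &
                   (ped$father == founder | ped$mother == founder)]
  for (id in kids) {
    seg <- gd$truth[gd$truth$id == id & gd$truth$chrom == "chr2" &
                      gd$truth$start <= 25e6 - 1 & gd$truth$end > 25e6 - 1, ]
    expect_equal(id %in% fv$carrier_ids, lab %in% seg$founder_hap)
  }
  expect_error(plant_variant(gd$truth, "nonsense:9", "chr2", 25e6), "unknown")
})

test_that("a carrier parent transmits the focal allele to about half its offspring", {
  # repeated meioses from one carrier parent; binomial check at n = 2000
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length_bp = 50e6),
                    seed = 2)
  ped <- structure(data.frame(
    id = c("F", "M", paste0("C", 1:2000)),
    father = c(NA, NA, rep("F", 2000)),
    mother = c(NA, NA, rep("M", 2000)),
    sex = c(1L, 2L, rep(1L, 2000)), kindred = "K", gen = c(1L, 1L, rep(2L, 2000)),
    recorded = TRUE, married_in = FALSE, stringsAsFactors = FALSE),
    class = c("pedigree", "data.frame"))
  gd <- gene_drop(ped, NULL, cfg, seed = 77)
  fv <- plant_variant(gd$truth, "F:1", "chr1", 25e6)
  frac <- mean(paste0("C", 1:2000) %in% fv$carrier_ids)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("array ascertainment and corruption behave as configured", {
  cfg0 <- sim_config(seed = 41, array_maf_min = 0,
                     pedigree = pedigree_spec(n_unrelated = 30))
  ped <- build_pedigree(cfg0$pedigree, seed = 41)
  fo <- simulate_founders(cfg0, n_founders = length(pedigree_founders(ped)))
  gd <- gene_drop(ped, fo, cfg0)

  # all rates 0, no MAF filter: identity
  arr0 <- ascertain_and_corrupt(gd$cohort, gd$map, cfg0)
  expect_identical(arr0$cohort$hap1, gd$cohort$hap1)
  expect_identical(arr0$map$pos, gd$map$pos)

  # MAF filter postcondition
  cfg1 <- cfg0; cfg1$array_maf_min <- 0.05
  arr1 <- ascertain_and_corrupt(gd$cohort, gd$map, cfg1)
  f <- colMeans(rbind(arr1$cohort$hap1, arr1$cohort$hap2))
  expect_true(all(pmin(f, 1 - f) >= 0.05))

  # missingness rate within 3 binomial SE (genotype-level calls)
  cfg2 <- cfg0; cfg2$missing_rate <- 0.02
  arr2 <- ascertain_and_corrupt(gd$cohort, gd$map, cfg2)
  n_calls <- length(arr2$cohort$ids) * ncol(arr2$cohort$hap1)
  miss <- mean(is.na(arr2$cohort$hap1))
  expect_lt(abs(miss - 0.02), 3 * sqrt(0.02 * 0.98 / n_calls))

  cfg_all <- cfg0; cfg_all$array_maf_min <- 0.9
  expect_error(ascertain_and_corrupt(gd$cohort, gd$map, cfg_all),
               "dropped all")
})

test_that("QTc simulation matches its model and round-trips through Bazett", {
  cfg <- sim_config(seed = 8,
                    qtc_model = list(carrier_mean = 456, noncarrier_mean = 413,
                                     sd = 0, penetrance = 1))
  ids <- sprintf("P%03d", 1:50)
  ecg <- simulate_qtc(ids, ids[1:10], cfg)
  expect_equal(ecg$qtc_ms[1:10], rep(456, 10))
  expect_equal(ecg$qtc_ms[11:50], rep(413, 40))
  expect_equal(bazett_qtc(ecg$qt_ms, ecg$rr_s), ecg$qtc_ms, tolerance = 1e-12)

  cfg2 <- sim_config(seed = 9,
                     qtc_model = list(carrier_mean = 456, noncarrier_mean = 413,
                                      sd = 15, penetrance = 1))
  ids2 <- sprintf("Q%03d", 1:500)
  ecg2 <- simulate_qtc(ids2, ids2, cfg2)
  expect_lt(abs(mean(ecg2$qtc_ms) - 456), 3 * 15 / sqrt(500))

  cfg_bad <- cfg; cfg_bad$qtc_model$penetrance <- 2
  expect_error(simulate_qtc(ids, ids, cfg_bad), "penetrance")
})

test_that("offspring allele frequency matches parental frequency (no selection)", {
  # one marker, many offspring of one couple: transmission is fair
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length_bp = 1e6),
                    marker_density = 5, seed = 3)
  n_off <- 5000
  ped <- structure(data.frame(
    id = c("F", "M", paste0("C", seq_len(n_off))),
    father = c(NA, NA, rep("F", n_off)), mother = c(NA, NA, rep("M", n_off)),
    sex = c(1L, 2L, rep(1L, n_off)), kindred = "K",
    gen = c(1L, 1L, rep(2L, n_off)), recorded = TRUE, married_in = FALSE,
    stringsAsFactors = FALSE), class = c("pedigree", "data.frame"))
  fo <- simulate_founders(cfg, n_founders = 2, seed = 4)
  gd <- gene_drop(ped, fo, cfg, seed = 5)
  off <- paste0("C", seq_len(n_off))
  i <- match(off, gd$cohort$ids)
  for (j in 1:2) {
    parental <- mean(c(fo$haps[, j]))
    observed <- mean(c(gd$cohort$hap1[i, j], gd$cohort$hap2[i, j]))
    expect_lt(abs(observed - parental), 3 * sqrt(0.25 / (2 * n_off)) + 1e-12)
  }
})
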