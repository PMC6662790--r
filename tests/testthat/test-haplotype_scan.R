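# Consensus definition, cohort scanning, incremental sweep and fine
# extension, checked against literal string-comparison oracles.

test_that("consensus over a single carrier is ambiguous with both candidates", {
  map <- mk_map(10)
  co <- toy_cohort(c("0101010101"), c("1111100000"), ids = "A")
  fv <- mk_focal("chr1", map$pos[5], "A")
  hap <- define_carrier_haplotype(co, map, fv, 2e5)
  expect_s3_class(hap, "carrier_haplotype")
  expect_true(hap$ambiguous)
  expect_equal(length(hap$candidates), 2L)
})

test_that("three carriers sharing a planted founder segment recover it exactly", {
  set.seed(5)
  m <- 60
  map <- mk_map(m)
  founder <- rbinom(m, 1, 0.5)
  h1 <- matrix(rbinom(5 * m, 1, 0.5), 5, m)
  h2 <- matrix(rbinom(5 * m, 1, 0.5), 5, m)
  h1[1, ] <- founder; h2[2, ] <- founder; h1[3, ] <- founder
  co <- phased_cohort(paste0("C", 1:5), h1, h2)
  fv <- mk_focal("chr1", map$pos[30], paste0("C", 1:3))
  hap <- define_carrier_haplotype(co, map, fv, 4e5)
  expect_false(inherits(hap, "no_consensus"))
  expect_equal(hap$alleles, founder[hap$marker_idx])
  expect_equal(unname(hap$hap_choice), c(1L, 2L, 1L))
})

test_that("a recombination breakpoint yields a no-consensus report at the right marker", {
  m <- 20
  map <- mk_map(m)
  base <- rep(0L, m)
  mk <- function(x) paste(x, collapse = "")
  # carrier 3 diverges from marker 15 outward on both of its haplotypes
  brk <- replace(base, 15:20, 1L)
  co <- toy_cohort(c(mk(base), mk(base), mk(brk)),
                   c(mk(rep(1L, m)), mk(rep(1L, m)), mk(brk)),
                   ids = c("A", "B", "C"))
  fv <- mk_focal("chr1", map$pos[10], c("A", "B", "C"))
  res <- define_carrier_haplotype(co, map, fv, 2.2e5)  # markers 1..20
  expect_s3_class(res, "no_consensus")
  # oracle: exhaustive over the 8 assignments, adding markers by distance
  orc <- oracle_define(co, c("A", "B", "C"), 1:20)
  expect_equal(orc$n_ok, 0L)
  expect_equal(res$first_discordant_pos, map$pos[15])
})

test_that("scan matches the string-comparison oracle and the carriers themselves", {
  set.seed(11)
  for (rep in 1:5) {
    co <- rand_cohort(12, 40, miss = 0.05)
    map <- mk_map(40)
    # plant a shared haplotype in 3 carriers + 2 cryptic matches
    founder <- rbinom(40, 1, 0.5)
    for (i in 1:3) co$hap1[i, ] <- founder
    co$hap2[4, 10:25] <- founder[10:25]
    co$hap1[5, 12:22] <- founder[12:22]
    fv <- mk_focal("chr1", map$pos[17], co$ids[1:3])
    hap <- define_carrier_haplotype(co, map, fv, 1.0e5)  # markers 13..22
    m <- scan_cohort(co, map, hap)
    expect_setequal(m$id, oracle_scan(co, hap$alleles, hap$marker_idx,
                                      co$ids[1:3]))
    ms <- scan_cohort(co, map, hap, include_carriers = TRUE)
    expect_true(all(co$ids[1:3] %in% ms$id))
  }
})

test_that("background frequency follows the i.i.d. product formula", {
  # vacuous haplotype matches everything
  map <- mk_map(6)
  co <- toy_cohort(c("......", "010101"), c("101010", "......"),
                   ids = c("A", "B"))
  fv <- mk_focal("chr1", map$pos[3], "A")
  hap <- define_carrier_haplotype(co, map, fv, 1.2e5)
  expect_true(all(is.na(hap$alleles)))
  expect_equal(haplotype_background_frequency(co, map, hap), 1)

  # i.i.d. cohort: frequency within 3 binomial SE of prod(p_match)
  set.seed(21)
  p <- 0.6
  n <- 400; m <- 8
  co2 <- rand_cohort(n, m, p = p)
  map2 <- mk_map(m)
  target <- rep(1L, m)
  co2$hap1[1, ] <- target; co2$hap2[1, ] <- target
  fv2 <- mk_focal("chr1", map2$pos[4], co2$ids[1])
  hap2 <- define_carrier_haplotype(co2, map2, fv2, 2e5)
  expect_equal(hap2$alleles, target)
  bg <- haplotype_background_frequency(co2, map2, hap2)
  exp_match <- p^m
  se <- sqrt(exp_match * (1 - exp_match) / (2 * (n - 1)))
  expect_lt(abs(bg - exp_match), 3 * se)
})

test_that("hand-built fixture: two matches at 0.4 Mb, none at 0.8 Mb", {
  # 81 markers at 10 kb spacing; focal at marker 41
  m <- 81
  map <- mk_map(m)
  founder <- rep(c(0L, 1L), length.out = m)
  h1 <- matrix(0L, 8, m); h2 <- matrix(1L, 8, m)
  for (i in 1:3) h1[i, ] <- founder                     # carriers
  h1[4, 21:60] <- founder[21:60]                        # covers the 0.4 Mb window
  h1[5, 19:62] <- founder[19:62]                        # ditto, not the 0.8 Mb one
  co <- phased_cohort(paste0("I", 1:8), h1, h2)
  fv <- mk_focal("chr1", map$pos[41], paste0("I", 1:3))
  hap04 <- define_carrier_haplotype(co, map, fv, 4e5)   # markers 22..60
  m04 <- scan_cohort(co, map, hap04)
  expect_setequal(m04$id, c("I4", "I5"))
  expect_setequal(m04$id, oracle_scan(co, hap04$alleles, hap04$marker_idx,
                                      paste0("I", 1:3)))
  hap08 <- define_carrier_haplotype(co, map, fv, 8e5)
  expect_equal(nrow(scan_cohort(co, map, hap08)), 0L)
})

test_that("sweep is nested, reports carrier-only sets, and terminates", {
  set.seed(31)
  cfg <- sim_config(seed = 31, pedigree = pedigree_spec(n_unrelated = 60))
  sim <- simulate_cohort(cfg)
  sw <- coarse_sweep(sim$cohort, sim$map, sim$focal)
  sets <- attr(sw, "match_sets")
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # carriers all sharing a long truth segment: scanning them matches
  hap <- attr(sw, "haplotypes")[[1]]
  self <- scan_cohort(sim$cohort, sim$map, hap, include_carriers = TRUE)
  expect_true(all(sim$focal$known_carrier_ids %in% self$id))
  expect_error(coarse_sweep(sim$cohort, sim$map, sim$focal, increment_bp = 0),
               "increment")
})

test_that("fine extension matches the outward-run oracle", {
  m <- 12
  map <- mk_map(m)
  pos <- map$pos
  focal <- (pos[6] + pos[7]) / 2
  a <- rep(0L, m)
  # identical haplotypes: interval spans the whole chromosome
  fe <- fine_extend(a, a, map, "chr1", focal)
  expect_equal(fe$start_bp, pos[1])
  expect_equal(fe$end_bp, pos[m])

  # mismatches at markers 2 (left flank) and 11 (right flank)
  b <- a; b[2] <- 1L; b[11] <- 1L
  fe2 <- fine_extend(a, b, map, "chr1", focal)
  expect_equal(fe2$start_bp, pos[3])
  expect_equal(fe2$end_bp, pos[10])
  expect_equal(fe2, oracle_fine(a, b, pos, focal))

  # a mismatch within the four closest markers: empty interval
  c <- a; c[6] <- 1L
  fe3 <- fine_extend(a, c, map, "chr1", focal)
  expect_equal(fe3$n_matching_markers, 0L)
  expect_equal(fe3$length_bp, 0)

  expect_error(fine_extend(a, a, map, "chr1", 1e9), "outside")
})

test_that("define/scan/fine agree with oracles on random small cohorts", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1); m <- sample(20:60, 1)
    co <- rand_cohort(n, m, p = runif(1, 0.3, 0.7), miss = 0.08)
    map <- mk_map(m)
    k <- sample(2:3, 1)
    carriers <- sample(co$ids, k)
    fv <- mk_focal("chr1", map$pos[sample(5:(m - 5), 1)], carriers)
    L <- sample(c(1e5, 2e5, 3e5), 1)
    idx <- window_idx <- which(map$pos >= fv$position_bp - L / 2 &
                                 map$pos < fv$position_bp + L / 2)
    orc <- oracle_define(co, carriers, idx)
    hap <- define_carrier_haplotype(co, map, fv, L)
    if (orc$n_ok == 0) {
      expect_s3_class(hap, "no_consensus")
    } else {
      expect_s3_class(hap, "carrier_haplotype")
      expect_true(any(vapply(orc$strings, identical, logical(1),
                             y = hap$alleles)))
      sc <- scan_cohort(co, map, hap)
      expect_setequal(sc$id, oracle_scan(co, hap$alleles, idx, carriers))
    }
    # fine extension on a random haplotype pair
    i <- sample(n, 2)
    a <- co$hap1[i[1], ]; b <- co$hap2[i[2], ]
    expect_equal(fine_extend(a, b, map, "chr1", fv$position_bp),
                 oracle_fine(a, b, map$pos, fv$position_bp))
  }
})
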