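#' Kindred descriptor for the pedigree generator
#'
#' A kindred starts from `n_founder_couples` founder couples. Every individual
#' in a non-terminal generation marries a new married-in founder and the couple
#' has a Poisson(`mean_sibship`) number of children; the terminal generation
#' does not reproduce. `generations` counts layers of individuals including the
#' founders, so `generations = 1` yields founders only.
#'
#' @param generations integer >= 1.
#' @param mean_sibship Poisson mean number of children per couple.
#' @param n_founder_couples founder couples in generation 1.
#' @return a `kindred_spec` list.
#' @export
kindred_spec <- function(generations = 3, mean_sibship = 2.5,
                         n_founder_couples = 1) {
  if (!is_count(generations) || generations < 1) stop_fs("generations must be >= 1")
  if (generations > 1 && mean_sibship <= 0)
    stop_fs("impossible kindred spec: mean_sibship <= 0 with > 1 generation")
  structure(list(generations = generations, mean_sibship = mean_sibship,
                 n_founder_couples = n_founder_couples), class = "kindred_spec")
}

#' Pedigree descriptor: kindreds plus unrecorded third-cousin links
#'
#' Each third-cousin link installs a hidden (unrecorded) ancestral couple with
#' two descent chains of four meioses each; the two chain-bottom individuals
#' are third cousins (they share exactly that great-great-grandparental couple
#' and no closer ancestor, eight meioses apart) and marry into two different
#' kindreds, so the recorded genealogy shows no connection between the
#' kindreds. `n_unrelated` adds recorded singleton founders emulating the rest
#' of the cohort.
#'
#' @param kindreds list of [kindred_spec()] descriptors.
#' @param n_third_cousin_links number of hidden links; link `j` joins kindreds
#'   `j` and `j + 1`.
#' @param n_unrelated recorded singleton founders.
#' @return a `pedigree_spec` list.
#' @export
pedigree_spec <- function(kindreds = list(kindred_spec(), kindred_spec()),
                          n_third_cousin_links = 1, n_unrelated = 150) {
  if (n_third_cousin_links > 0 && length(kindreds) < 2)
    stop_fs("third-cousin links need at least two kindreds")
  if (n_third_cousin_links > max(0L, length(kindreds) - 1L))
    stop_fs("at most length(kindreds) - 1 links supported")
  structure(list(kindreds = kindreds,
                 n_third_cousin_links = n_third_cousin_links,
                 n_unrelated = n_unrelated), class = "pedigree_spec")
}

#' Full recipe for a synthetic isolate cohort
#'
#' Defaults describe the desk-scale stated world used throughout the test
#' suite: a 4 x 50 Mb autosomal genome at 30 array markers per Mb, a uniform
#' sex-averaged map of 1 cM/Mb, founder marker alleles i.i.d. with minor
#' allele frequency uniform on `founder_maf`, two 3-generation kindreds joined
#' by one unrecorded third-cousin link, a focal variant planted on one
#' haplotype of the hidden ancestral couple (never part of the array), and a
#' QTc model with carrier mean 456 ms vs non-carrier 413 ms (sd 15 ms).
#'
#' @param genome data.frame with columns `chrom`, `length_bp`.
#' @param cm_per_mb uniform recombination rate (centimorgan per megabase).
#' @param n_founders founder haplotype pool size; `NULL` = derived from the
#'   pedigree.
#' @param founder_maf length-2 range of the uniform founder minor allele
#'   frequency spectrum.
#' @param marker_density simulated markers per Mb.
#' @param array_maf_min markers below this cohort MAF are dropped at array
#'   ascertainment.
#' @param pedigree a [pedigree_spec()].
#' @param genotype_error_rate per-allele-call flip probability.
#' @param missing_rate per-genotype-call missing probability.
#' @param switch_error_rate per-marker phase flip probability (flips the
#'   maternal/paternal assignment downstream of each flip point).
#' @param qtc_model list: `carrier_mean`, `noncarrier_mean`, `sd` (all ms) and
#'   `penetrance` (fraction of carriers drawn from the carrier distribution).
#' @param focal list: `chrom`, `position_bp` of the array-absent focal
#'   variant; optional `min_shared_bp` (default 1.22 Mb) is the haplotype span
#'   around the variant that the ascertainment conditioning guarantees the
#'   conditioned carriers share, mirroring the uniqueness window observed in
#'   cascade-ascertained carrier sets.
#' @param seed master seed; all module substreams derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome = data.frame(chrom = paste0("chr", 1:4),
                                           length_bp = rep(50e6, 4)),
                       cm_per_mb = 1.0,
                       n_founders = NULL,
                       founder_maf = c(0.1, 0.5),
                       marker_density = 30,
                       array_maf_min = 0.05,
                       pedigree = pedigree_spec(),
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       switch_error_rate = 0,
                       qtc_model = list(carrier_mean = 456,
                                        noncarrier_mean = 413,
                                        sd = 15, penetrance = 1),
                       focal = list(chrom = "chr2", position_bp = 25e6),
                       seed = 1L) {
  if (any(genome$length_bp <= 0)) stop_fs("chromosome lengths must be > 0")
  if (cm_per_mb < 0) stop_fs("cm_per_mb must be >= 0")
  for (r in c(genotype_error_rate, missing_rate, switch_error_rate))
    if (!is_rate(r)) stop_fs("error/missing/switch rates must be in [0,1]")
  if (!is_rate(qtc_model$penetrance)) stop_fs("penetrance must be in [0,1]")
  if (qtc_model$sd < 0) stop_fs("qtc sd must be >= 0")
  if (marker_density <= 0) stop_fs("marker_density must be > 0")
  if (length(founder_maf) != 2 || founder_maf[1] > founder_maf[2] ||
      founder_maf[1] < 0 || founder_maf[2] > 0.5)
    stop_fs("founder_maf must be an increasing range within [0, 0.5]")
  structure(list(genome = genome, cm_per_mb = cm_per_mb,
                 n_founders = n_founders, founder_maf = founder_maf,
                 marker_density = marker_density,
                 array_maf_min = array_maf_min, pedigree = pedigree,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 switch_error_rate = switch_error_rate,
                 qtc_model = qtc_model, focal = focal,
                 seed = as.integer(seed)),
            class = "sim_config")
}
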