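test_that("allele ratio is the exact quotient and rejects zero depth", {
  expect_equal(allele_ratio(10, 20), 0.5)
  expect_equal(allele_ratio(0, 30), 0)
  expect_equal(allele_ratio(18, 20), 0.9)
  expect_error(allele_ratio(0, 0), "zero depth")
  expect_error(allele_ratio(5, 4), "alt_reads")
})

test_that("allele-ratio QC bounds are inclusive exactly at the thresholds", {
  # het band [0.35, 0.65]
  expect_true(passes_allele_ratio("het", 35L, 100L))
  expect_false(passes_allele_ratio("het", 34L, 100L))
  expect_true(passes_allele_ratio("het", 65L, 100L))
  expect_false(passes_allele_ratio("het", 66L, 100L))
  # hom floor 0.9
  expect_true(passes_allele_ratio("hom_alt", 18L, 20L))
  expect_false(passes_allele_ratio("hom_alt", 89L, 100L))
  expect_true(passes_allele_ratio("hom_alt", 20L, 20L))
})

test_that("functional consensus requires all predictors and strict MAF", {
  base <- toy_variant(100)
  base$variant_class <- "SNV"
  cases <- list(
    list(mod = function(v) v, pass = TRUE),
    list(mod = function(v) { v$predictsnp2_benign <- 1L; v }, pass = TRUE),
    list(mod = function(v) { v$predictsnp2_benign <- 2L; v }, pass = FALSE),
    list(mod = function(v) { v$sift <- NA_real_; v }, pass = FALSE),
    list(mod = function(v) { v$sift <- 0.05; v }, pass = TRUE),
    list(mod = function(v) { v$sift <- 0.051; v }, pass = FALSE),
    list(mod = function(v) { v$polyphen <- 0.909; v }, pass = TRUE),
    list(mod = function(v) { v$polyphen <- 0.9; v }, pass = FALSE),
    list(mod = function(v) { v$mutation_taster <- "benign"; v },
         pass = FALSE),
    list(mod = function(v) { v$mutation_taster <- NA_character_; v },
         pass = FALSE),
    list(mod = function(v) { v$maf <- 0.0009; v }, pass = TRUE),
    list(mod = function(v) { v$maf <- 0.001; v }, pass = FALSE),
    list(mod = function(v) { v$maf <- NA_real_; v }, pass = TRUE))
  for (cs in cases)
    expect_identical(passes_functional_consensus(cs$mod(base)), cs$pass)

  indel <- toy_variant(200, ref = "A", alt = "AT")
  indel$variant_class <- "indel"
  expect_error(passes_functional_consensus(indel), "SNV")
})

test_that("indel filter is rarity-only with strict bound and missing-as-zero", {
  indel <- toy_variant(100, ref = "A", alt = "AT")
  indel$variant_class <- "indel"
  for (case in list(c(0.0005, TRUE), c(0.001, FALSE), c(NA, TRUE))) {
    indel$maf <- case[1]
    expect_identical(passes_indel_filter(indel), as.logical(case[2]))
  }
  snv <- toy_variant(200)
  snv$variant_class <- "SNV"
  expect_error(passes_indel_filter(snv), "SNV")
})

test_that("recurrence filter removes whole variants above the carrier cap", {
  samples <- sprintf("s%02d", 1:50)
  v <- rbind(toy_variant(100), toy_variant(200, gene = "GENE2"),
             toy_variant(300, gene = "GENE3"))
  g <- rbind(
    do.call(rbind, lapply(samples[1:6], function(s) toy_call(v[1, ], s))),
    do.call(rbind, lapply(samples[1:5], function(s) toy_call(v[2, ], s))),
    toy_call(v[3, ], samples[1]))
  cohort <- cohort_table(v, g, samples)
  out <- recurrence_filter(cohort, max_samples = 5)
  expect_false("1:100:A:G" %in% out$genotypes$variant_id)  # 6 carriers
  expect_equal(sum(out$genotypes$variant_id == "1:200:A:G"), 5)
  expect_equal(sum(out$genotypes$variant_id == "1:300:A:G"), 1)
})

test_that("prioritization reproduces generator truth labels", {
  for (seed in c(3, 17)) {
    spec <- cohort_sim_spec(n_genes = 40, sites_per_gene = 6,
                            control_f = 5e-4,
                            multiplier = c(rep(25, 4), rep(1, 36)),
                            artifact_fraction = 0.25,
                            n_recurrent_sites = 4, p_damaging = 0.6,
                            indel_fraction = 0.1, seed = seed)
    sim <- simulate_cohort(spec)
    pr <- prioritize(sim$cohort)
    got <- sort(paste(pr$pairs$variant_id, pr$pairs$sample_id))
    want <- with(sim$truth$pairs,
                 sort(paste(variant_id, sample_id)[survives]))
    expect_identical(got, want)
    expect_setequal(pr$genes,
                    unique(sim$truth$variants$gene[
                      sim$truth$variants$passes_prioritization]))
  }
})

test_that("attrition ledger conserves the input call count", {
  spec <- cohort_sim_spec(n_genes = 30, sites_per_gene = 5,
                          control_f = 0.005, multiplier = 10,
                          artifact_fraction = 0.3, n_recurrent_sites = 3,
                          p_damaging = 0.5, seed = 5)
  sim <- simulate_cohort(spec)
  pr <- prioritize(sim$cohort)
  expect_equal(sum(pr$attrition) + pr$n_surviving, pr$n_input)
  expect_equal(pr$n_input, nrow(sim$cohort$genotypes))
  expect_false(any(duplicated(pr$genes)))
})

test_that("prioritization is idempotent on its own survivors", {
  spec <- cohort_sim_spec(n_genes = 25, sites_per_gene = 5,
                          control_f = 5e-4, multiplier = 15,
                          artifact_fraction = 0.2, p_damaging = 0.7,
                          seed = 9)
  sim <- simulate_cohort(spec)
  pr1 <- prioritize(sim$cohort)
  surv_ids <- unique(pr1$pairs$variant_id)
  cohort2 <- cohort_table(
    sim$cohort$variants[sim$cohort$variants$variant_id %in% surv_ids, ],
    pr1$pairs[, c("variant_id", "sample_id", "zygosity", "alt_reads",
                  "depth")],
    sim$cohort$samples)
  pr2 <- prioritize(cohort2)
  expect_equal(sum(pr2$attrition), 0L)
  expect_setequal(paste(pr2$pairs$variant_id, pr2$pairs$sample_id),
                  paste(pr1$pairs$variant_id, pr1$pairs$sample_id))
})

test_that("variant-level predicates commute: filter order does not matter", {
  spec <- cohort_sim_spec(n_genes = 20, sites_per_gene = 5,
                          control_f = 8e-4, multiplier = 8,
                          artifact_fraction = 0.3, p_damaging = 0.5,
                          seed = 13)
  sim <- simulate_cohort(spec)
  v <- sim$cohort$variants
  g <- sim$cohort$genotypes
  func <- passes_functional_consensus(v[v$variant_class == "SNV", ])
  names(func) <- v$variant_id[v$variant_class == "SNV"]
  ar <- passes_allele_ratio(g$zygosity, g$alt_reads, g$depth)

  a_then_b <- which(func[g$variant_id])[ar[which(func[g$variant_id])]]
  b_then_a <- which(ar)[func[g$variant_id][which(ar)]]
  expect_setequal(a_then_b, b_then_a)
})

test_that("loosening thresholds never shrinks the surviving set", {
  spec <- cohort_sim_spec(n_genes = 30, sites_per_gene = 5,
                          control_f = 6e-4, multiplier = 12,
                          artifact_fraction = 0.25, n_recurrent_sites = 2,
                          p_damaging = 0.6, seed = 21)
  sim <- simulate_cohort(spec)
  tight <- prioritize(sim$cohort)
  keys <- function(pr) paste(pr$pairs$variant_id, pr$pairs$sample_id)
  loosened <- list(
    prioritize(sim$cohort,
               prioritization_criteria(maf_max_snv = 0.01,
                                       maf_max_indel = 0.01)),
    prioritize(sim$cohort,
               prioritization_criteria(recurrence_max = 50L)),
    prioritize(sim$cohort,
               prioritization_criteria(sift_deleterious_max = 0.5,
                                       polyphen_deleterious_min = 0.5,
                                       predictsnp2_benign_max = 10L)),
    # widening the AR band can only grow the set if the recurrence cap is
    # lifted too: resurrected calls raise carrier counts at their own sites
    prioritize(sim$cohort, prioritization_criteria(recurrence_max = 50L),
               ar_bounds(0.05, 0.85, 0.86)))
  for (loose in loosened)
    expect_true(all(keys(tight) %in% keys(loose)))
})

test_that("empty and all-failing cohorts yield empty results, not errors", {
  empty <- cohort_table(toy_variant(100), data.frame(
    variant_id = character(), sample_id = character(),
    zygosity = character(), alt_reads = integer(), depth = integer()),
    "s1")
  pr <- prioritize(empty)
  expect_equal(pr$n_surviving, 0L)
  expect_equal(length(pr$genes), 0L)

  v <- toy_variant(100, maf = 0.2)  # common variant: fails MAF
  cohort <- cohort_table(v, toy_call(v, "s1"), "s1")
  pr2 <- prioritize(cohort)
  expect_equal(length(pr2$genes), 0L)
  expect_equal(pr2$attrition[["functional"]], 1L)
})
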