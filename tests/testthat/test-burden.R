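test_that("qualifying selection applies every boundary as printed", {
  sets <- list(
    list(v = toy_variant(100, sift = 0.05, polyphen = 0.8, maf = 0.009),
         depth = 15L, q = TRUE),                  # all bounds exactly met
    list(v = toy_variant(101, sift = 0.06), depth = 15L, q = FALSE),
    list(v = toy_variant(102, polyphen = 0.79), depth = 15L, q = FALSE),
    list(v = toy_variant(103, maf = 0.01), depth = 15L, q = FALSE),
    list(v = toy_variant(104, maf = 0.0099), depth = 15L, q = TRUE),
    list(v = toy_variant(105), depth = 11L, q = TRUE),   # depth > 10
    list(v = toy_variant(106), depth = 10L, q = FALSE),  # exclusive bound
    list(v = toy_variant(107, ref = "A", alt = "AT"), depth = 15L,
         q = FALSE),                              # indel excluded
    list(v = toy_variant(108, sift = NA), depth = 15L, q = FALSE))
  v <- do.call(rbind, lapply(sets, `[[`, "v"))
  g <- do.call(rbind, lapply(sets, function(s)
    toy_call(s$v, "s1", alt_reads = min(10L, s$depth %/% 2L),
             depth = s$depth)))
  cohort <- cohort_table(v, g, "s1")
  qual <- select_qualifying(cohort)
  want <- v$pos[vapply(sets, `[[`, logical(1), "q")]
  expect_setequal(as.integer(sub(".*?:(\\d+):.*", "\\1",
                                 qual$variant_id)), want)
})

test_that("depth qualifies per carrier call, not per variant", {
  v <- toy_variant(100)
  g <- rbind(toy_call(v, "s1", depth = 30L, alt_reads = 15L),
             toy_call(v, "s2", depth = 10L, alt_reads = 5L))
  cohort <- cohort_table(v, g, c("s1", "s2"))
  qual <- select_qualifying(cohort)
  expect_equal(qual$sample_id, "s1")
})

test_that("case model counting classifies hom, compound het and het", {
  v <- rbind(toy_variant(100), toy_variant(200), toy_variant(300))
  calls <- rbind(
    toy_call(v[1, ], "ch_sample"), toy_call(v[2, ], "ch_sample"),
    toy_call(v[1, ], "het_sample"),
    toy_call(v[3, ], "hom_sample", zygosity = "hom_alt", alt_reads = 19L),
    toy_call(v[1, ], "hom_plus", zygosity = "hom_alt", alt_reads = 19L),
    toy_call(v[2, ], "hom_plus"))
  calls$gene <- "GENE1"
  cc <- count_case_models(calls, n_cases = 10)
  expect_equal(cc$ch_carriers, 1)       # ch_sample only; hom_plus is hom
  expect_equal(cc$hom_carriers, 2)      # hom_sample, hom_plus
  expect_equal(cc$het_carriers, 2)      # ch_sample, het_sample
  expect_equal(cc$dom_carriers, 4)
  expect_equal(cc$rec_carriers, 3)
  expect_equal(cc$total_ac, 8)          # 4 het calls + 2 hom calls * 2
  expect_equal(count_case_models(calls[0, ], 10)$dom_carriers, 0)
})

test_that("a sample het at two sites counts once in ch and once in het", {
  v <- rbind(toy_variant(100), toy_variant(200))
  calls <- rbind(toy_call(v[1, ], "s1"), toy_call(v[2, ], "s1"))
  calls$gene <- "GENE1"
  cc <- count_case_models(calls, n_cases = 5)
  expect_equal(cc$ch_carriers, 1)
  expect_equal(cc$het_carriers, 1)
  expect_equal(cc$hom_carriers, 0)
  expect_equal(cc$rec_carriers, 1)
})

test_that("dominant contingency uses allele count as control carriers, capped", {
  tab <- dominant_contingency(18, 7943, 50, 125748)
  expect_equal(unname(tab), matrix(c(18, 32, 7943, 117805), 2,
                                   byrow = TRUE))
  tab0 <- dominant_contingency(0, 100, 50, 125748)
  expect_equal(tab0[1, ], c(carrier = 0, non_carrier = 50))
  capped <- dominant_contingency(5, 200000, 50, 125748)
  expect_equal(capped[2, 1], 125748)
  expect_equal(capped[2, 2], 0)
  expect_error(dominant_contingency(60, 10, 50, 125748), "exceed")
})

test_that("recessive contingency supports both control constructions", {
  ctrl <- list(control_nhom_sum = 0, control_freqs = c(0.01, 0.02))
  tab <- recessive_contingency(7, ctrl, 50, 125748, "reported_hom")
  expect_equal(unname(tab), matrix(c(7, 43, 0, 125748), 2, byrow = TRUE))

  q <- 1 - (1 - 0.01) * (1 - 0.02)
  want <- round(125748 * q^2)
  tab2 <- recessive_contingency(7, ctrl, 50, 125748, "expected_biallelic")
  expect_equal(tab2[2, 1], want)
  expect_error(recessive_contingency(7, ctrl, 50, 125748, "nope"))
})

test_that("expected_biallelic control count dominates reported homozygotes", {
  # on generated summaries (nhom = round(N f^2)) the pairwise estimate can
  # only exceed the summed homozygote count
  set.seed(403)
  N <- 125748
  for (i in 1:50) {
    f <- stats::runif(sample(1:8, 1), 0, 0.05)
    ctrl <- list(control_nhom_sum = sum(round(N * f^2)),
                 control_freqs = f)
    a <- recessive_contingency(0, ctrl, 50, N, "reported_hom")[2, 1]
    b <- recessive_contingency(0, ctrl, 50, N, "expected_biallelic")[2, 1]
    expect_gte(b, a)
  }
})

test_that("one-sided Fisher equals exhaustive enumeration", {
  # hand-derived: P(X >= 2) = (C(3,2)C(3,1) + C(3,3)C(3,0)) / C(6,3) = 0.5
  expect_equal(fisher_one_sided_greater(matrix(c(2, 1, 1, 2), 2,
                                               byrow = TRUE)), 0.5)
  expect_equal(fisher_one_sided_greater(matrix(0, 2, 2)), 1)
  expect_equal(fisher_one_sided_greater(matrix(c(0, 50, 0, 125748), 2,
                                               byrow = TRUE)), 1)

  set.seed(404)
  for (i in 1:300) {
    tot <- sample(4:200, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- tot - cuts[3]
    tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expect_equal(fisher_one_sided_greater(tab),
                 enum_fisher(a, b, c, d, "greater"), tolerance = 1e-9,
                 label = paste(a, b, c, d))
    # cross-check against the independent stats implementation
    if (sum(tab) > 0)
      expect_equal(fisher_one_sided_greater(tab),
                   stats::fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
  }
})

test_that("dominant p is non-increasing in case carriers at fixed margins", {
  ps <- vapply(0:50, function(a)
    fisher_one_sided_greater(dominant_contingency(a, 5000, 50, 125748)),
    numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("burden scan finds a spiked gene and respects gene subsets", {
  spec <- cohort_sim_spec(n_genes = 40, sites_per_gene = 10,
                          control_f = 5e-4,
                          multiplier = c(20, rep(1, 39)), seed = 55)
  sim <- simulate_cohort(spec)
  ctrl <- simulate_control_summary(spec)
  scan <- run_burden_scan(sim$cohort, ctrl, control_n = spec$control_n)
  expect_equal(scan$gene[1], "G0001")
  expect_true(scan$sig_dom[1])
  expect_equal(attr(scan, "m"), nrow(scan))

  sub <- run_burden_scan(sim$cohort, ctrl, control_n = spec$control_n,
                         gene_subset = setdiff(scan$gene, "G0001"))
  expect_false("G0001" %in% sub$gene)
  expect_equal(attr(sub, "m"), nrow(scan) - 1)
})

test_that("qualifying sites missing from the control summary contribute zero", {
  v <- rbind(toy_variant(100), toy_variant(200))
  g <- rbind(toy_call(v[1, ], "s1"), toy_call(v[2, ], "s2"))
  cohort <- cohort_table(v, g, c("s1", "s2"))
  ctrl <- toy_control_row(v[1, ], ac = 40)     # site 200 absent
  scan <- run_burden_scan(cohort, ctrl, control_n = 125748)
  expect_equal(scan$control_ac, 40)
  expect_equal(attr(scan, "missing_control_sites"), 1L)
})

test_that("implied_m recovers the BH family size from p/FDR pairs", {
  # convex p sequence: p_j/j increases, so no step-up minimum binds and
  # every row's fdr * rank / p equals the family size exactly
  p <- (1:30)^2 * 1e-6
  expect_equal(implied_m(p, bh_adjust(p, m_total = 263)), 263)
  expect_equal(implied_m(p, bh_adjust(p)), 30)
  expect_true(is.na(implied_m(numeric(0), numeric(0))))
})
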