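test_that("cov_stat matches hand values and is scale invariant", {
  expect_equal(cov_stat(c(5, 5, 5)), 0)
  expect_equal(cov_stat(c(1, 2, 3)), 0.5)
  set.seed(42)
  for (i in 1:5) {
    v <- stats::rlnorm(20)
    expect_equal(cov_stat(v), cov_oracle(v), tolerance = 1e-12)
    expect_equal(cov_stat(3.7 * v), cov_stat(v), tolerance = 1e-12)
  }
  expect_error(cov_stat(c(1)), "at least 2")
  expect_error(cov_stat(c(0, 0)), "mean must be positive")
  expect_error(cov_stat(c(-1, 2)), "non-negative")
})

test_that("stage grouping follows the Wanek windows", {
  expect_equal(stage_group(c(1, 4, 5, 8, 9)),
               c("ES", "ES", "LS", "LS", NA))
  expect_error(stage_group(0), "1..15")
})

test_that("stage CoV summaries recover generator structure", {
  tab <- generate_qpcr_table(litter_effect_sd = 0, seed = 11)
  covs <- stage_cov_summaries(tab)
  expect_setequal(unique(covs$group), c("ES", "LS"))
  # 4 Wanek-stage replicates per stage group and gene
  reps <- dplyr::count(covs, .data$gene, .data$group)
  expect_true(all(reps$n == 4))
  means <- summarize_cov(covs)
  expect_equal(means$mean_cov,
               (covs |>
                  dplyr::group_by(gene, group) |>
                  dplyr::summarise(m = mean(cov), .groups = "drop"))$m)
  # litter replicate unit is available as the alternate configuration
  covs_l <- stage_cov_summaries(tab, replicate_unit = "litter")
  expect_true(all(covs_l$replicate %in% paste0("L", 1:9)))
})

test_that("identically distributed ES and LS levels give similar CoVs", {
  panel <- qpcr_gene_panel()[1:2, ]
  panel$ls_mean <- panel$es_mean
  panel$ls_cov <- panel$es_cov
  tab <- generate_qpcr_table(panel, n_individuals = 4000, n_litters = 8,
                             litter_effect_sd = 0, seed = 7)
  means <- summarize_cov(stage_cov_summaries(tab))
  wide <- tidyr::pivot_wider(means[c("gene", "group", "mean_cov")],
                             names_from = "group",
                             values_from = "mean_cov")
  expect_equal(wide$ES, wide$LS, tolerance = 0.1)
})

test_that("Bartlett test matches the textbook formula oracle", {
  tab <- generate_qpcr_table(seed = 3)
  ht <- bartlett_variance_test(tab, "ES")
  expect_s3_class(ht, "limbnet_htest")
  # 5 genes + control -> DF = number of genes - 1
  expect_equal(ht$df, length(unique(tab$gene)) - 1)

  # oracle equivalence on random fixtures
  set.seed(99)
  for (i in 1:5) {
    groups <- lapply(1:4, function(j) stats::rnorm(5 + i, sd = j))
    values <- unlist(groups)
    labels <- rep(seq_along(groups), lengths(groups))
    ours <- stats::bartlett.test(values, factor(labels))
    orc <- bartlett_oracle(groups)
    expect_equal(unname(ours$statistic), orc$statistic, tolerance = 1e-12)
    expect_equal(ours$p.value, orc$p, tolerance = 1e-12)
  }
})

test_that("litter ANOVA has litters-minus-one df and matches the oracle", {
  tab <- generate_qpcr_table(seed = 5)
  ht <- litter_anova(tab, "Bmp4")
  expect_equal(ht$df, 9 - 1)
  sub <- tab[tab$gene == "Bmp4", ]
  orc <- anova_oracle(sub$level, sub$litter)
  expect_equal(ht$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(ht$p_value, orc$p, tolerance = 1e-12)

  const <- sub
  const$level <- 1
  expect_error(litter_anova(const, "Bmp4"), "undefined")
  expect_error(litter_anova(tab, "NoSuchGene"), "not present")
})

test_that("litter ANOVA F is near 1 without litter effects in expectation", {
  f <- vapply(1:40, function(s) {
    tab <- generate_qpcr_table(qpcr_gene_panel()[1, ],
                               litter_effect_sd = 0, seed = s)
    litter_anova(tab, "Bmp4")$statistic
  }, numeric(1))
  expect_gt(mean(f), 0.6)
  expect_lt(mean(f), 1.6)
})

test_that("mc shuffle test is deterministic, bounded, and sane on ties", {
  covs <- c(0.4, 0.5, 0.6, 0.7)
  ht1 <- mc_cov_shuffle_test(covs, covs, reps = 999, seed = 42)
  ht2 <- mc_cov_shuffle_test(covs, covs, reps = 999, seed = 42)
  expect_identical(ht1$p_value, ht2$p_value)
  expect_equal(ht1$observed, 0)
  expect_gte(ht1$p_value, 0.4)
  expect_gte(ht1$p_value, 1 / (999 + 1))
  expect_lte(ht1$p_value, 1)
  expect_error(mc_cov_shuffle_test(covs, covs, reps = 0), "positive")
  expect_error(mc_cov_shuffle_test(numeric(0), covs), "non-empty")
})

test_that("mc shuffle test detects a planted two-SD shift most of the time", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    es <- stats::rlnorm(4, log(0.5), 0.2)
    shift <- 2 * stats::sd(c(es, es))
    ls <- es + shift
    mc_cov_shuffle_test(es, ls, reps = 999, seed = s)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
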