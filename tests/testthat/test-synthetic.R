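test_that("qpcr generator is deterministic and respects the design", {
  t1 <- generate_qpcr_table(seed = 4)
  t2 <- generate_qpcr_table(seed = 4)
  expect_identical(t1, t2)
  t3 <- generate_qpcr_table(seed = 5)
  expect_false(identical(t1$level, t3$level))

  expect_equal(length(unique(t1$individual)), 71)
  expect_equal(length(unique(t1$litter)), 9)
  expect_setequal(unique(t1$wanek_stage), 1:8)
  # every (gene x stage) cell is filled with at least 2 individuals
  cells <- dplyr::count(t1, .data$gene, .data$wanek_stage)
  expect_equal(nrow(cells), length(unique(t1$gene)) * 8)
  expect_true(all(cells$n >= 2))
  expect_true(all(t1$level > 0))
  expect_error(generate_qpcr_table(n_individuals = 10), "infeasible")
})

test_that("zero CoV collapses each litter cell to its adjusted mean", {
  panel <- qpcr_gene_panel()[1, ]
  panel$es_cov <- 0
  panel$ls_cov <- 0
  tab <- generate_qpcr_table(panel, litter_effect_sd = 0.4, seed = 2)
  spread <- tab |>
    dplyr::group_by(.data$litter, .data$wanek_stage) |>
    dplyr::summarise(sd = stats::sd(.data$level), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2)
  expect_true(all(spread$sd < 1e-12))
})

test_that("large-n realized CoV is within 5% of target", {
  panel <- qpcr_gene_panel()[c(1, 3), ]
  tab <- generate_qpcr_table(panel, n_individuals = 16000,
                             n_litters = 10,
                             litter_effect_sd = 0, seed = 6)
  tab$group <- stage_group(tab$wanek_stage)
  real <- tab |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(cov = cov_stat(.data$level), .groups = "drop")
  target <- tidyr::pivot_longer(
    panel[c("gene", "es_cov", "ls_cov")], -"gene",
    names_to = "group", values_to = "target")
  target$group <- ifelse(target$group == "es_cov", "ES", "LS")
  j <- dplyr::inner_join(real, target, by = c("gene", "group"))
  expect_true(all(abs(j$cov - j$target) / j$target < 0.05))
})

test_that("litter effects drive the litter ANOVA as planted", {
  panel <- tibble::tibble(gene = "Bmp4", es_mean = 2, es_cov = 0.3,
                          ls_mean = 2, ls_cov = 0.3, is_control = FALSE)
  p_with <- vapply(1:20, function(s) {
    tab <- generate_qpcr_table(panel, litter_effect_sd = 0.5,
                               seed = 100 + s)
    litter_anova(tab, "Bmp4")$p_value
  }, numeric(1))
  expect_gt(mean(p_with < 0.05), 0.9)
})

test_that("ortholog generator hits its conservation targets", {
  orth <- generate_ortholog_matrices(n_genes = 1500, seed = 17)
  ach <- attr(orth, "achieved_rho")
  expect_lt(abs(ach[["ES"]] - 0.5667), 0.01)
  expect_lt(abs(ach[["LS"]] - 0.5612), 0.01)
  expect_equal(dim(orth$es), c(1500, 5))
  expect_setequal(names(orth$es), c("gene", "bat", "mouse", "opossum",
                                    "pig"))
  # different seeds: different values, same achieved targets
  orth2 <- generate_ortholog_matrices(n_genes = 1500, seed = 18)
  expect_false(identical(orth$es$bat, orth2$es$bat))
  expect_lt(abs(attr(orth2, "achieved_rho")[["ES"]] - 0.5667), 0.01)
})

test_that("zero noise gives perfect conservation; targets can fail loudly", {
  orth <- generate_ortholog_matrices(n_genes = 50, target_rho = NULL,
                                     gene_noise_scale = rep(0, 50),
                                     seed = 3)
  expect_equal(mean_pairwise_spearman(orth$es)$mean_rho, 1)
  expect_error(
    generate_ortholog_matrices(n_genes = 50,
                               target_rho = c(ES = 0.99, LS = 0.5),
                               gene_noise_scale = rep(0, 50), seed = 3),
    "unreachable|failed")
})

test_that("generator randomness is scoped: the caller RNG is untouched", {
  set.seed(77)
  before <- stats::runif(1)
  set.seed(77)
  invisible(generate_qpcr_table(seed = 9))
  after <- stats::runif(1)
  expect_identical(before, after)
})
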