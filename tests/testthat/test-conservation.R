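make_orth <- function(n = 30, species = c("bat", "mouse", "opossum", "pig"),
                      seed = 1) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n * length(species)), n,
                 dimnames = list(NULL, species))
  dplyr::bind_cols(tibble::tibble(gene = paste0("g", seq_len(n))),
                   tibble::as_tibble(vals))
}

test_that("mean pairwise Spearman handles identity and reversal", {
  m <- make_orth(10)
  same <- m
  for (sp in c("mouse", "opossum", "pig")) same[[sp]] <- same[["bat"]]
  cs <- mean_pairwise_spearman(same)
  expect_equal(nrow(cs$pairs), 6)
  expect_equal(cs$pairs$rho, rep(1, 6))
  expect_equal(cs$mean_rho, 1)

  two <- tibble::tibble(gene = paste0("g", 1:5),
                        a = c(1, 2, 3, 4, 5), b = c(5, 4, 3, 2, 1))
  expect_equal(mean_pairwise_spearman(two)$mean_rho, -1)

  const <- m
  const$mouse <- 1
  expect_error(mean_pairwise_spearman(const), "mouse")
})

test_that("mean pairwise Spearman equals the rank-then-Pearson oracle", {
  m <- make_orth(50, seed = 8)
  # inject ties to exercise average-rank handling
  m$bat[1:5] <- m$bat[6:10]
  cs <- mean_pairwise_spearman(m)
  expect_equal(cs$mean_rho, mean_pairwise_spearman_oracle(m),
               tolerance = 1e-12)
})

test_that("Spearman scores are invariant to monotone transforms", {
  m <- make_orth(40, seed = 2)
  m2 <- m
  m2$bat <- exp(m2$bat / 2)
  expect_equal(mean_pairwise_spearman(m)$mean_rho,
               mean_pairwise_spearman(m2)$mean_rho, tolerance = 1e-12)
})

test_that("subsampling at intensity 1 is a point mass at the full score", {
  es <- make_orth(25, seed = 3)
  ls <- make_orth(25, seed = 4)
  out <- subsample_conservation(es, ls, n_sets = 5, intensities = 1,
                                seed = 9)
  full_es <- mean_pairwise_spearman(es)$mean_rho
  sc <- out$scores
  expect_equal(sc$mean_rho[sc$stage == "ES"], rep(full_es, 5))
  expect_equal(stats::sd(sc$mean_rho[sc$stage == "ES"]), 0)
  expect_true(is.na(out$summary$p_value[1]) ||
                out$summary$p_value[1] >= 0)
  expect_error(subsample_conservation(es, ls, intensities = 1.5),
               "0, 1")
})

test_that("subsample bookkeeping matches a hand enumeration at tiny n", {
  es <- make_orth(6, seed = 5)
  ls <- make_orth(6, seed = 6)
  out <- subsample_conservation(es, ls, n_sets = 2,
                                intensities = c(0.5, 1), seed = 123)
  expect_equal(nrow(out$scores), 2 * 2 * 2)
  expect_equal(nrow(out$summary), 2)
  # paired draws: reproduce the subsets with the same RNG protocol
  set.seed(123)
  for (f in c(0.5, 1)) {
    size <- max(3L, round(f * 6))
    for (s in 1:2) {
      idx <- sample.int(6, size)
      expected <- mean_pairwise_spearman(es[idx, ])$mean_rho
      got <- out$scores$mean_rho[out$scores$intensity == f &
                                   out$scores$set == s &
                                   out$scores$stage == "ES"]
      expect_equal(got, expected)
    }
  }
})

test_that("a planted conservation gap is detected at high intensity", {
  orth <- generate_ortholog_matrices(
    n_genes = 300, target_rho = c(ES = 0.60, LS = 0.45), seed = 21)
  out <- subsample_conservation(orth$es, orth$ls, n_sets = 80,
                                intensities = c(0.9), seed = 22)
  expect_lt(out$summary$p_value[1], 0.05)
  expect_gt(out$summary$es_mean[1], out$summary$ls_mean[1])
})

test_that("gene divergence matches hand computation and quartile rule", {
  m <- tibble::tibble(gene = c("flat", "spread", "mid1", "mid2"),
                      a = c(1, 1, 1, 2), b = c(1, 1, 2, 3),
                      c = c(1, 1, 3, 4), d = c(1, 5, 4, 5))
  dv <- gene_divergence(m)
  expect_equal(dv$divergence_sd[dv$gene == "flat"], 0)
  # (1,1,1,5)/2 = (0.5, 0.5, 0.5, 2.5), sample SD = 1
  expect_equal(dv$divergence_sd[dv$gene == "spread"], 1)
  expect_equal(dv$class[dv$gene == "flat"], "top-25% conserved")
  expect_equal(dv$class[dv$gene == "spread"], "top-25% divergent")
  expect_equal(sum(dv$class == "top-25% conserved"), 1)
  expect_equal(sum(dv$class == "top-25% divergent"), 1)

  # per-gene row scaling leaves the mean-standardized SD unchanged
  m2 <- m
  m2[m2$gene == "spread", c("a", "b", "c", "d")] <-
    m2[m2$gene == "spread", c("a", "b", "c", "d")] * 100
  dv2 <- gene_divergence(m2)
  expect_equal(dv2$divergence_sd, dv$divergence_sd, tolerance = 1e-12)
  # scaling one SPECIES column is NOT neutral in general
  m3 <- m
  m3$d <- m3$d * 10
  expect_false(isTRUE(all.equal(gene_divergence(m3)$divergence_sd,
                                dv$divergence_sd)))

  # population SD option
  dvn <- gene_divergence(m, sd_denominator = "n")
  expect_equal(dvn$divergence_sd[dvn$gene == "spread"],
               1 * sqrt(3 / 4))

  m4 <- m
  m4[1, c("a", "b", "c", "d")] <- 0
  expect_warning(dv4 <- gene_divergence(m4), "zero cross-species mean")
  expect_equal(nrow(dv4), 3)
})

test_that("planted high-noise genes land in the divergent quartile", {
  n <- 200
  scale <- rep(1, n)
  noisy <- 1:20
  scale[noisy] <- 5
  orth <- generate_ortholog_matrices(n_genes = n, target_rho = NULL,
                                     gene_noise_scale = scale, seed = 31)
  dv <- gene_divergence(orth$es)
  hit <- mean(dv$class[match(sprintf("gene%05d", noisy), dv$gene)] ==
                "top-25% divergent")
  expect_gt(hit, 0.9)
})
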