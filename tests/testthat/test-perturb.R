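test_that("flag_changes implements the boundary-inclusive relative rule", {
  base <- c(2, 1, 0.013, 0)
  expect_equal(flag_changes(base, base), rep(FALSE, 4))
  # boundary: exactly 10% counts as affected
  expect_true(flag_changes(c(1.8), c(2.0))[1])
  expect_false(flag_changes(c(1.81), c(2.0))[1])
  # small baselines still use the relative rule
  expect_false(flag_changes(c(0.014), c(0.013))[1])
  expect_true(flag_changes(c(0.068), c(0.013))[1])
  # zero baseline uses the absolute floor
  expect_true(flag_changes(c(0.01), c(0))[1])
  expect_false(flag_changes(c(1e-9), c(0))[1])
  # absolute mode
  expect_equal(flag_changes(c(1.05, 1.2), c(1, 1), threshold = 0.1,
                            mode = "absolute"), c(FALSE, TRUE))
  expect_error(flag_changes(1:3, 1:2), "different lengths")
  expect_error(flag_changes(1:2, c(-1, 1)), ">= 0")
})

test_that("screen totals are monotone in the threshold and vanish at Inf", {
  topo <- build_topology("ESN")
  params <- default_parameters("ESN")
  scr10 <- screen_links(topo, params, threshold = 0.10)
  states <- as.matrix(scr10$results[topo$genes])
  tot <- vapply(c(0.05, 0.10, 0.25, Inf), function(th) {
    sum(vapply(seq_len(nrow(states)), function(i) {
      sum(flag_changes(states[i, ], unname(scr10$baseline), th))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(tot) <= 0))
  expect_equal(tot[length(tot)], 0)
})

test_that("screen summaries equal an independent recount of stored states", {
  topo <- build_topology("ESN")
  params <- default_parameters("ESN")
  scr <- screen_links(topo, params)
  genes <- topo$genes
  # brute-force pass over the stored per-row steady states
  recount <- matrix(FALSE, nrow(scr$results), length(genes))
  for (i in seq_len(nrow(scr$results))) {
    for (j in seq_along(genes)) {
      x <- scr$results[[genes[j]]][i]
      b <- unname(scr$baseline[genes[j]])
      recount[i, j] <- abs(x - b) / b >= scr$threshold
    }
  }
  expect_equal(unname(colSums(recount)), unname(scr$per_gene_flagged))
  expect_equal(rowSums(recount), scr$results$n_affected)
  expect_equal(sum(recount), scr$total_affected)
  expect_equal(scr$total_cells, nrow(topo$links) * length(genes))
})

test_that("gene space modes behave and genes without outgoing links score 0", {
  topo <- build_topology("ESN")
  params <- default_parameters("ESN")
  scr <- screen_links(topo, params)
  for (mode in c("mean", "union")) {
    sp <- gene_space(scr, mode = mode)
    # Gli3R's only regulator is Shh; HoxAD receives nothing
    expect_equal(sp$sensitivity[sp$gene == "HoxAD"], 0)
    expect_true(all(sp$impact >= 0))
  }
  # union counts distinct genes, so it caps the mean
  sp_mean <- gene_space(scr, mode = "mean")
  sp_union <- gene_space(scr, mode = "union")
  expect_true(all(sp_union$impact >= sp_mean$impact - 1e-12))
  sp_sim <- gene_space(scr, mode = "simultaneous", topology = topo,
                       params = params)
  expect_true(all(sp_sim$impact >= 0 & sp_sim$impact <= 6))
  expect_error(gene_space(scr, mode = "simultaneous"), "required")
})

test_that("tidy/glance expose the screen as tables", {
  topo <- build_topology("ESN")
  scr <- screen_links(topo, default_parameters("ESN"))
  td <- tidy(scr)
  expect_equal(nrow(td), 11 * 7)
  expect_equal(sum(td$flagged), scr$total_affected)
  gl <- glance(scr)
  expect_equal(gl$total_affected, scr$total_affected)
  expect_equal(gl$total_cells, 77)
})
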