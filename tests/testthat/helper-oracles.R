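# Independent brute-force oracles used to validate the statistical
# implementations. Written from textbook formulas, deliberately naive.

cov_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) / m
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average-rank assignment without rank()
ranks_oracle <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

spearman_oracle <- function(x, y) {
  pearson_oracle(ranks_oracle(x), ranks_oracle(y))
}

mean_pairwise_spearman_oracle <- function(mat) {
  sp <- setdiff(colnames(mat), "gene")
  vals <- c()
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j > i) {
        vals <- c(vals, spearman_oracle(mat[[sp[i]]], mat[[sp[j]]]))
      }
    }
  }
  mean(vals)
}

bartlett_oracle <- function(groups) {
  k <- length(groups)
  ni <- vapply(groups, length, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- num / C
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  levs <- unique(groups)
  ssb <- 0
  ssw <- 0
  for (g in levs) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- length(levs) - 1
  df2 <- length(values) - length(levs)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = df1, df_resid = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# two-gene toy model: constitutive driver feeding one Hill-activated
# target; the steady state has a closed form used to enumerate the
# parameter screen by hand
toy_topology <- function() {
  structure(list(
    stage = "ESN",
    genes = c("Bmp4", "Grem1"),
    links = tibble::tibble(source = "Bmp4", target = "Grem1",
                           sign = "activation", mechanism = "additive")
  ), class = "limbnet_topology")
}

toy_values <- function() {
  c(a_grem1.bmp4 = 1.2, K_grem1.bmp4 = 0.8, n_grem1.bmp4 = 2,
    b_bmp4 = 1.0, d_bmp4 = 1.0, b_grem1 = 0.05, d_grem1 = 1.0)
}

toy_steady_oracle <- function(v) {
  b <- v[["b_bmp4"]] / v[["d_bmp4"]]
  hill <- b^v[["n_grem1.bmp4"]] /
    (v[["K_grem1.bmp4"]]^v[["n_grem1.bmp4"]] + b^v[["n_grem1.bmp4"]])
  g <- (v[["b_grem1"]] + v[["a_grem1.bmp4"]] * hill) / v[["d_grem1"]]
  c(Bmp4 = b, Grem1 = g)
}
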