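#' Pearson correlation between within-population variation and
#' among-species divergence
#'
#' Product-moment correlation of per-gene CoV (among individuals)
#' against per-gene divergence (among species).
#'
#' @param pairs Data frame with columns `cov` and `divergence` (one row
#'   per gene); extra columns (`gene`, `stage`) pass through untouched.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(pairs) {
  pairs <- validate_pairs(pairs)
  stats::cor(pairs$cov, pairs$divergence, method = "pearson")
}

validate_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("cov", "divergence") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 gene pairs", call. = FALSE)
  if (any(!is.finite(pairs$cov)) || any(!is.finite(pairs$divergence))) {
    stop("non-finite values in `cov`/`divergence`", call. = FALSE)
  }
  if (stats::sd(pairs$cov) == 0 || stats::sd(pairs$divergence) == 0) {
    stop("zero variance on one axis; correlation undefined", call. = FALSE)
  }
  pairs
}

#' Bootstrap significance of the CoV-divergence correlation
#'
#' Resamples genes (their CoV-divergence pairs jointly) with
#' replacement, recomputes the Pearson correlation for each replicate,
#' and reports the proportion of replicates with R <= 0 as the p-like
#' significance measure for a positive observed correlation. The
#' complementary proportion with R >= 0 is also returned. Degenerate
#' replicates (zero variance on an axis) are redrawn and counted.
#'
#' @param pairs Data frame with `cov` and `divergence` columns.
#' @param reps Number of bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return A `limbnet_bootstrap` list: `observed_r`, `prop_r_le_0`,
#'   `prop_r_ge_0`, `reps`, `n_degenerate_redrawn`.
#' @export
bootstrap_significance <- function(pairs, reps = 10000, seed = 1) {
  if (reps <= 0) stop("`reps` must be positive", call. = FALSE)
  pairs <- validate_pairs(pairs)
  n <- nrow(pairs)
  observed <- stats::cor(pairs$cov, pairs$divergence)
  r <- numeric(reps)
  n_degenerate <- 0L
  with_seed(seed, {
    for (b in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(pairs$cov[idx]) > 0 &&
            stats::sd(pairs$divergence[idx]) > 0) break
        n_degenerate <- n_degenerate + 1L
      }
      r[b] <- stats::cor(pairs$cov[idx], pairs$divergence[idx])
    }
  })
  structure(list(observed_r = observed,
                 prop_r_le_0 = mean(r <= 0),
                 prop_r_ge_0 = mean(r >= 0),
                 reps = reps,
                 n_degenerate_redrawn = n_degenerate,
                 replicates = r),
            class = "limbnet_bootstrap")
}

#' @export
print.limbnet_bootstrap <- function(x, ...) {
  cat("<limbnet_bootstrap> observed R =", format(x$observed_r, digits = 4),
      "\n  proportion of", x$reps, "replicates with R <= 0:",
      format(x$prop_r_le_0, digits = 4),
      "\n  proportion with R >= 0:", format(x$prop_r_ge_0, digits = 4), "\n")
  if (x$n_degenerate_redrawn > 0) {
    cat("  degenerate replicates redrawn:", x$n_degenerate_redrawn, "\n")
  }
  invisible(x)
}
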