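#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; the mean-standardized
#' measure of among-individual expression variation.
#'
#' @param values Numeric vector of non-negative values, length >= 2,
#'   with positive mean.
#' @return A single non-negative number.
#' @examples
#' cov_stat(c(1, 2, 3)) # 0.5
#' @export
cov_stat <- function(values) {
  if (length(values) < 2) {
    stop("coefficient of variation needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  m <- mean(values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

#' Assign Wanek stages to early/late stage groups
#'
#' Wanek stages 1-4 (limb ridge through bud) form the early stage group
#' (ES); stages 5-8 (paddle) the late group (LS).
#'
#' @param wanek_stage Integer vector in 1..15.
#' @return Character vector, `"ES"`, `"LS"`, or `NA` for stages > 8.
#' @export
stage_group <- function(wanek_stage) {
  if (any(wanek_stage < 1 | wanek_stage > 15, na.rm = TRUE)) {
    stop("Wanek stages must lie in 1..15", call. = FALSE)
  }
  dplyr::case_when(
    wanek_stage <= 4 ~ "ES",
    wanek_stage <= 8 ~ "LS",
    TRUE ~ NA_character_
  )
}

#' Per-gene CoV summaries by stage group
#'
#' Computes, for every gene and stage group (ES = Wanek 1-4, LS = Wanek
#' 5-8), one replicate CoV per Wanek stage and their average. The
#' per-stage CoVs are the replicate unit used by
#' [mc_cov_shuffle_test()]; `replicate_unit = "litter"` computes
#' per-litter CoVs instead.
#'
#' @param table Expression table: data frame with columns `gene`,
#'   `individual`, `litter`, `wanek_stage`, `level`.
#' @param min_n Cells with fewer individuals are skipped with a warning.
#' @param replicate_unit `"stage"` (default) or `"litter"`.
#' @return Tibble: `gene`, `group`, `replicate` (Wanek stage or litter),
#'   `n`, `cov`; use [summarize_cov()] for the per-gene averages.
#' @export
stage_cov_summaries <- function(table, min_n = 2,
                                replicate_unit = c("stage", "litter")) {
  replicate_unit <- match.arg(replicate_unit)
  table <- validate_expression_table(table)
  table$group <- stage_group(table$wanek_stage)
  table <- table[!is.na(table$group), ]
  table$replicate <- if (replicate_unit == "stage") {
    as.character(table$wanek_stage)
  } else {
    as.character(table$litter)
  }
  out <- table |>
    dplyr::group_by(.data$gene, .data$group, .data$replicate) |>
    dplyr::summarise(n = dplyr::n(),
                     cov = if (dplyr::n() >= min_n && mean(.data$level) > 0) {
                       cov_stat(.data$level)
                     } else NA_real_,
                     .groups = "drop")
  skipped <- sum(is.na(out$cov))
  if (skipped > 0) {
    warning(skipped, " under-filled (gene x ", replicate_unit,
            ") cell(s) skipped", call. = FALSE)
    out <- out[!is.na(out$cov), ]
  }
  out
}

#' Average replicate CoVs per gene and stage group
#'
#' @param cov_table Output of [stage_cov_summaries()].
#' @return Tibble: `gene`, `group`, `n_replicates`, `mean_cov`.
#' @export
summarize_cov <- function(cov_table) {
  cov_table |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_cov = mean(.data$cov), .groups = "drop")
}

#' Bartlett test of variance homogeneity across genes
#'
#' Tests whether mean-standardized expression levels (each value divided
#' by its gene's mean within the stage group) have equal variances
#' across genes. With k genes the statistic has k - 1 degrees of
#' freedom.
#'
#' @param table Expression table (see [stage_cov_summaries()]).
#' @param group `"ES"` or `"LS"`.
#' @return A `limbnet_htest` list: `statistic`, `df`, `p_value`,
#'   `method`, `group`.
#' @export
bartlett_variance_test <- function(table, group = c("ES", "LS")) {
  group <- match.arg(group)
  table <- validate_expression_table(table)
  table$group <- stage_group(table$wanek_stage)
  sub <- table[!is.na(table$group) & table$group == group, ]
  sub <- sub |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(dplyr::n() >= 2, mean(.data$level) > 0) |>
    dplyr::mutate(std_level = .data$level / mean(.data$level)) |>
    dplyr::ungroup()
  if (length(unique(sub$gene)) < 2) {
    stop("need at least 2 genes with >= 2 observations each", call. = FALSE)
  }
  ht <- stats::bartlett.test(sub$std_level, g = factor(sub$gene))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, method = "Bartlett", group = group),
            class = "limbnet_htest")
}

#' One-way ANOVA of expression level on litter membership
#'
#' Quantifies the contribution of litter (i.e. heredity) to
#' among-individual variation for one gene. With k litters the F
#' statistic has k - 1 numerator degrees of freedom.
#'
#' @param table Expression table.
#' @param gene Gene to test.
#' @return A `limbnet_htest` list: `statistic` (F), `df` (numerator),
#'   `df_resid`, `p_value`.
#' @export
litter_anova <- function(table, gene) {
  table <- validate_expression_table(table)
  sub <- table[table$gene == gene, ]
  if (nrow(sub) == 0) stop("gene not present: ", gene, call. = FALSE)
  counts <- table(sub$litter)
  if (sum(counts >= 2) < 2) {
    stop("need at least 2 litters with at least 2 individuals", call. = FALSE)
  }
  if (stats::var(sub$level) == 0) {
    stop("expression levels are constant; F is undefined", call. = FALSE)
  }
  fit <- stats::aov(level ~ factor(litter), data = sub)
  s <- summary(fit)[[1]]
  structure(list(statistic = s[["F value"]][1], df = s[["Df"]][1],
                 df_resid = s[["Df"]][2], p_value = s[["Pr(>F)"]][1],
                 method = "litter ANOVA", gene = gene),
            class = "limbnet_htest")
}

#' @export
print.limbnet_htest <- function(x, ...) {
  cat("<limbnet_htest> ", x$method,
      if (!is.null(x$gene)) paste0(" (", x$gene, ")"),
      ": statistic = ", format(x$statistic, digits = 4),
      ", df = ", x$df,
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo shuffle test for an early/late CoV difference
#'
#' Tests whether the mean replicate CoV is greater in late than early
#' development. All replicate CoVs are pooled irrespective of stage
#' group; two samples of the original sizes are then drawn with
#' replacement from the pool, and the null difference of their means is
#' recorded. The p-value is the proportion of replicates whose null
#' difference is greater than or equal to the observed
#' `mean(ls_covs) - mean(es_covs)` (with the add-one correction, so p is
#' never exactly 0 and the test is deterministic given `seed`).
#'
#' @param es_covs,ls_covs Replicate CoVs for the early and late groups.
#' @param reps Number of Monte-Carlo replicates (default 10000).
#' @param seed Integer seed.
#' @return A `limbnet_htest` list with `observed` (LS - ES difference),
#'   `p_value`, `reps`.
#' @export
mc_cov_shuffle_test <- function(es_covs, ls_covs, reps = 10000, seed = 1) {
  if (reps <= 0) stop("`reps` must be positive", call. = FALSE)
  if (length(es_covs) == 0 || length(ls_covs) == 0) {
    stop("both CoV vectors must be non-empty", call. = FALSE)
  }
  observed <- mean(ls_covs) - mean(es_covs)
  pool <- c(es_covs, ls_covs)
  n_es <- length(es_covs)
  n_ls <- length(ls_covs)
  draws <- with_seed(seed, matrix(
    sample(pool, (n_es + n_ls) * reps, replace = TRUE), nrow = reps))
  null_diff <- rowMeans(draws[, n_es + seq_len(n_ls), drop = FALSE]) -
    rowMeans(draws[, seq_len(n_es), drop = FALSE])
  p <- (sum(null_diff >= observed) + 1) / (reps + 1)
  structure(list(observed = observed, p_value = p, reps = reps,
                 statistic = observed, df = NA_real_,
                 method = "Monte-Carlo CoV shuffle"),
            class = "limbnet_htest")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so all package randomness flows from named seeds.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
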