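#' Validate an ortholog expression matrix
#'
#' Accepts a data frame with a `gene` column plus one numeric column per
#' species, or a numeric matrix with gene rownames; returns the tibble
#' form used throughout.
#'
#' @param matrix Ortholog expression table (genes x species).
#' @return Tibble with `gene` plus species columns.
#' @export
as_ortholog_matrix <- function(matrix) {
  if (is.matrix(matrix)) {
    matrix <- tibble::as_tibble(matrix, rownames = "gene")
  }
  stopifnot(is.data.frame(matrix), "gene" %in% names(matrix))
  species <- setdiff(names(matrix), "gene")
  if (length(species) < 2) stop("need at least 2 species", call. = FALSE)
  if (nrow(matrix) < 3) stop("need at least 3 genes", call. = FALSE)
  vals <- as.matrix(matrix[species])
  if (any(!is.finite(vals))) stop("missing/non-finite cells", call. = FALSE)
  if (any(vals < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (anyDuplicated(matrix$gene)) stop("duplicated gene ids", call. = FALSE)
  tibble::as_tibble(matrix[c("gene", species)])
}

ortholog_species <- function(matrix) setdiff(names(matrix), "gene")

#' Cross-species conservation score of an expression matrix
#'
#' Computes the Spearman rank correlation over the gene expression
#' vector for every unordered species pair (average-rank tie handling)
#' and their arithmetic mean, the stage's conservation score.
#'
#' @param matrix Ortholog matrix (see [as_ortholog_matrix()]).
#' @return A `limbnet_conservation` list: `pairs` (tibble with
#'   `species_1`, `species_2`, `rho`) and `mean_rho`.
#' @export
mean_pairwise_spearman <- function(matrix) {
  matrix <- as_ortholog_matrix(matrix)
  species <- ortholog_species(matrix)
  vals <- as.matrix(matrix[species])
  for (sp in species) {
    if (stats::sd(vals[, sp]) == 0) {
      stop("species ", sp, " has a constant expression vector; ",
           "ranks are undefined", call. = FALSE)
    }
  }
  combos <- utils::combn(species, 2)
  rho <- apply(combos, 2, function(pr) {
    stats::cor(vals[, pr[1]], vals[, pr[2]], method = "spearman")
  })
  structure(list(
    pairs = tibble::tibble(species_1 = combos[1, ], species_2 = combos[2, ],
                           rho = rho),
    mean_rho = mean(rho)
  ), class = "limbnet_conservation")
}

#' @export
print.limbnet_conservation <- function(x, ...) {
  cat("<limbnet_conservation> mean pairwise Spearman:",
      format(x$mean_rho, digits = 4), "\n")
  print(x$pairs)
  invisible(x)
}

#' Subsampled conservation comparison between two stages
#'
#' Draws `n_sets` random gene subsets at each subsampling intensity,
#' scores the mean pairwise Spearman conservation of each subset at both
#' stages, and compares the resulting ES and LS score distributions with
#' a two-sample t-test per intensity. The same gene subset is applied to
#' both stages within a draw (paired design; set `paired = FALSE` for
#' independent draws).
#'
#' @param es,ls Ortholog matrices sharing the same gene universe.
#' @param n_sets Number of random subsets per intensity (default 500).
#' @param intensities Subsampling fractions in (0, 1].
#' @param seed Integer seed.
#' @param paired Use the same subset for both stages within a draw.
#' @param var_equal Passed to [stats::t.test()]; default `FALSE`
#'   (Welch).
#' @return A `limbnet_subsample` list: `scores` (tibble with `intensity`,
#'   `set`, `stage`, `mean_rho`) and `summary` (per intensity: mean and
#'   95% interval of each stage's scores, t statistic and p-value).
#' @export
subsample_conservation <- function(es, ls, n_sets = 500,
                                   intensities = seq(0.5, 1, by = 0.1),
                                   seed = 1, paired = TRUE,
                                   var_equal = FALSE) {
  es <- as_ortholog_matrix(es)
  ls <- as_ortholog_matrix(ls)
  if (!setequal(es$gene, ls$gene)) {
    stop("`es` and `ls` must share the same gene universe", call. = FALSE)
  }
  if (any(intensities <= 0 | intensities > 1)) {
    stop("intensities must lie in (0, 1]", call. = FALSE)
  }
  ls <- ls[match(es$gene, ls$gene), ]
  n_genes <- nrow(es)
  score_rows <- list()
  with_seed(seed, {
    for (f in intensities) {
      size <- max(3L, round(f * n_genes))
      for (s in seq_len(n_sets)) {
        idx_es <- sample.int(n_genes, size)
        idx_ls <- if (paired) idx_es else sample.int(n_genes, size)
        score_rows[[length(score_rows) + 1L]] <- tibble::tibble(
          intensity = f, set = s,
          stage = c("ES", "LS"),
          mean_rho = c(mean_pairwise_spearman(es[idx_es, ])$mean_rho,
                       mean_pairwise_spearman(ls[idx_ls, ])$mean_rho)
        )
      }
    }
  })
  scores <- dplyr::bind_rows(score_rows)
  summary <- scores |>
    tidyr::pivot_wider(names_from = "stage", values_from = "mean_rho") |>
    dplyr::group_by(.data$intensity) |>
    dplyr::summarise(
      es_mean = mean(.data$ES), ls_mean = mean(.data$LS),
      es_lo = stats::quantile(.data$ES, 0.025),
      es_hi = stats::quantile(.data$ES, 0.975),
      ls_lo = stats::quantile(.data$LS, 0.025),
      ls_hi = stats::quantile(.data$LS, 0.975),
      t_statistic = if (stats::sd(.data$ES) == 0 &&
                        stats::sd(.data$LS) == 0) NA_real_ else
        stats::t.test(.data$ES, .data$LS,
                      var.equal = var_equal)$statistic,
      p_value = if (stats::sd(.data$ES) == 0 &&
                    stats::sd(.data$LS) == 0) NA_real_ else
        stats::t.test(.data$ES, .data$LS, var.equal = var_equal)$p.value,
      .groups = "drop"
    )
  structure(list(scores = scores, summary = summary, n_sets = n_sets,
                 paired = paired, seed = seed),
            class = "limbnet_subsample")
}

#' @export
print.limbnet_subsample <- function(x, ...) {
  cat("<limbnet_subsample> ", x$n_sets, " sets per intensity\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Per-gene expression divergence across species
#'
#' Standardizes each gene's expression by its cross-species mean, takes
#' the standard deviation of the standardized values as the gene's
#' divergence score, and classifies the lowest-SD quartile as
#' `"top-25% conserved"` and the highest as `"top-25% divergent"`.
#'
#' @param matrix Ortholog matrix.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return Tibble: `gene`, `divergence_sd`, `rank` (1 = most conserved),
#'   `class`.
#' @export
gene_divergence <- function(matrix, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  matrix <- as_ortholog_matrix(matrix)
  species <- ortholog_species(matrix)
  vals <- as.matrix(matrix[species])
  means <- rowMeans(vals)
  zero <- means == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero cross-species mean excluded",
            call. = FALSE)
    vals <- vals[!zero, , drop = FALSE]
    matrix <- matrix[!zero, ]
    means <- means[!zero]
  }
  std <- vals / means
  sds <- apply(std, 1, stats::sd)
  if (sd_denominator == "n") {
    k <- ncol(vals)
    sds <- sds * sqrt((k - 1) / k)
  }
  n <- length(sds)
  rank_sd <- rank(sds, ties.method = "first")
  q <- ceiling(n / 4)
  tibble::tibble(
    gene = matrix$gene,
    divergence_sd = unname(sds),
    rank = rank_sd,
    class = dplyr::case_when(
      rank_sd <= q ~ "top-25% conserved",
      rank_sd > n - q ~ "top-25% divergent",
      TRUE ~ "middle"
    )
  )
}
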