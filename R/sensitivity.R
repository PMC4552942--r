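#' Default parameter grid for the sensitivity screen
#'
#' Tests every positive, non-degradation-fixed parameter at a set of
#' fold changes of its baseline value.
#'
#' @param params Parameter tibble (see [make_parameters()]).
#' @param multipliers Fold changes applied to each baseline value
#'   (default 0.5, 0.75, 1.25, 1.5, 2).
#' @return Grid tibble: `name`, `owner`, `value` (tested value),
#'   `baseline`.
#' @export
default_parameter_grid <- function(params,
                                   multipliers = c(0.5, 0.75, 1.25,
                                                   1.5, 2)) {
  if (any(multipliers <= 0)) {
    stop("grid multipliers must be positive", call. = FALSE)
  }
  grid <- params[params$value > 0, c("name", "owner", "value")]
  grid <- tidyr::crossing(grid, multiplier = multipliers)
  tibble::tibble(name = grid$name, owner = grid$owner,
                 value = grid$value * grid$multiplier,
                 baseline = grid$value)
}

#' Screen one-at-a-time parameter changes of a network model
#'
#' Re-solves the model steady state for every (parameter, tested value)
#' combination, one parameter modified per run, and flags genes whose
#' level changes by `threshold` (relative) or more versus the unaltered
#' baseline. Per-gene summaries report the fraction of a gene's own
#' parameter changes that flag at least one OTHER gene (affects-others
#' %) and the fraction of other genes' parameter changes that flag the
#' gene (is-affected %). Non-converged runs are excluded from
#' denominators with a warning.
#'
#' @inheritParams screen_links
#' @param grid Grid tibble (see [default_parameter_grid()]); defaults to
#'   the multiplier grid over all parameters.
#' @return A `limbnet_sensitivity`: list with `stage`, `genes`,
#'   `baseline`, `results` (one row per run with per-gene flags),
#'   `per_gene` (tibble: `gene`, `affects_others_pct`,
#'   `is_affected_pct`, denominators), and `threshold`.
#' @export
screen_parameters <- function(topology, params, grid = NULL,
                              threshold = 0.10,
                              init = rep(1, length(topology$genes)),
                              tol = 1e-8, t_max = 2000) {
  stopifnot(inherits(topology, "limbnet_topology"))
  if (is.null(grid)) grid <- default_parameter_grid(params)
  stopifnot(all(c("name", "owner", "value") %in% names(grid)))
  if (any(grid$value <= 0)) {
    stop("tested parameter values must be positive", call. = FALSE)
  }
  unknown <- setdiff(grid$name, params$name)
  if (length(unknown) > 0) {
    stop("grid names not in the parameter set: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  base <- find_steady_state(topology, params, init = init, tol = tol,
                            t_max = t_max)
  if (!base$converged) {
    stop("unaltered model did not converge", call. = FALSE)
  }
  genes <- topology$genes
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p2 <- params
    p2$value[p2$name == grid$name[i]] <- grid$value[i]
    ss <- tryCatch(
      find_steady_state(topology, p2, init = init, tol = tol,
                        t_max = t_max),
      error = function(e) NULL
    )
    if (is.null(ss) || !ss$converged) {
      flags <- rep(NA, length(genes))
      state <- rep(NA_real_, length(genes))
      converged <- FALSE
    } else {
      state <- unname(ss$state)
      flags <- flag_changes(state, unname(base$state), threshold)
      converged <- TRUE
    }
    rows[[i]] <- tibble::as_tibble(c(
      list(name = grid$name[i], owner = grid$owner[i],
           value = grid$value[i]),
      stats::setNames(as.list(state), genes),
      stats::setNames(as.list(flags), paste0("flag_", genes)),
      list(converged = converged)
    ))
  }
  results <- dplyr::bind_rows(rows)
  n_failed <- sum(!results$converged)
  if (n_failed > 0) {
    warning(n_failed, " non-converged run(s) excluded from denominators",
            call. = FALSE)
  }
  ok <- results[results$converged, , drop = FALSE]
  flag_mat <- as.matrix(ok[paste0("flag_", genes)])
  per_gene <- dplyr::bind_rows(lapply(genes, function(g) {
    own <- ok$owner == g
    other_cols <- genes != g
    affects <- if (any(own)) {
      mean(rowSums(flag_mat[own, other_cols, drop = FALSE]) > 0)
    } else NA_real_
    affected <- if (any(!own)) {
      mean(flag_mat[!own, !other_cols, drop = TRUE])
    } else NA_real_
    tibble::tibble(gene = g,
                   affects_others_pct = 100 * affects,
                   n_own_runs = sum(own),
                   is_affected_pct = 100 * affected,
                   n_other_runs = sum(!own))
  }))
  structure(list(stage = topology$stage, genes = genes,
                 baseline = base$state, results = results,
                 per_gene = per_gene, threshold = threshold),
            class = "limbnet_sensitivity")
}

#' @export
print.limbnet_sensitivity <- function(x, ...) {
  cat("<limbnet_sensitivity> ", x$stage, ": ", nrow(x$results),
      " parameter runs (threshold ", format(100 * x$threshold), "%)\n",
      sep = "")
  print(x$per_gene)
  invisible(x)
}

#' Per-gene sensitivity-space coordinates
#'
#' One point per gene: the percentage of the gene's parameter changes
#' that alter another gene's expression (impact, Y) against the
#' percentage of other genes' parameter changes that alter the gene's
#' expression (sensitivity, X). Quadrants split the fixed 0-100% axes
#' at 50%.
#'
#' @param sensitivity A `limbnet_sensitivity` (see
#'   [screen_parameters()]).
#' @return Tibble: `gene`, `impact` (affects-others %), `sensitivity`
#'   (is-affected %), `quadrant`, `on_boundary`.
#' @export
sensitivity_space <- function(sensitivity) {
  stopifnot(inherits(sensitivity, "limbnet_sensitivity"))
  pg <- sensitivity$per_gene
  impact <- pg$affects_others_pct
  sens <- pg$is_affected_pct
  quadrant <- paste0(ifelse(impact > 50, "upper", "lower"), "-",
                     ifelse(sens > 50, "right", "left"))
  tibble::tibble(gene = pg$gene, impact = impact, sensitivity = sens,
                 quadrant = quadrant,
                 on_boundary = impact == 50 | sens == 50)
}
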