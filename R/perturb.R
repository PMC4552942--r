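#' Flag expression levels that changed by at least a threshold fraction
#'
#' A gene is flagged when its perturbed level differs from the unaltered
#' (baseline) level by `threshold` or more, relative to baseline:
#' \eqn{|x' - x| / x \ge threshold}. The boundary counts as affected.
#' Genes whose baseline is exactly zero are flagged when the perturbed
#' level exceeds a small absolute floor.
#'
#' @param perturbed,baseline Numeric vectors in the same gene order.
#' @param threshold Relative-change threshold (default 0.10).
#' @param mode `"relative"` (default) or `"absolute"` (flag when
#'   `|x' - x| >= threshold`).
#' @param zero_floor Absolute floor used when a baseline entry is 0.
#' @return Logical vector, one flag per gene.
#' @export
flag_changes <- function(perturbed, baseline, threshold = 0.10,
                         mode = c("relative", "absolute"),
                         zero_floor = 1e-6) {
  mode <- match.arg(mode)
  if (length(perturbed) != length(baseline)) {
    stop("`perturbed` and `baseline` have different lengths", call. = FALSE)
  }
  if (any(baseline < 0)) stop("baseline entries must be >= 0", call. = FALSE)
  delta <- abs(perturbed - baseline)
  if (mode == "absolute") return(unname(delta >= threshold))
  # small epsilon so the exact-boundary case is counted as affected
  # despite floating-point representation of the quotient
  flags <- ifelse(baseline == 0,
                  abs(perturbed) > zero_floor,
                  delta / baseline >= threshold - 1e-9)
  unname(flags)
}

#' Screen all single-link removals of a network model
#'
#' Removes each regulatory link in turn, re-solves the model to steady
#' state from the same initial condition and with the same solver
#' settings as the unaltered baseline, and flags every gene whose level
#' changes by `threshold` (relative) or more. Row and column totals
#' summarize how many of the (links x genes) readouts are affected.
#'
#' @inheritParams find_steady_state
#' @param threshold Relative-change threshold for flagging (default 0.10).
#' @return A `limbnet_screen`: list with `stage`, `genes`, `baseline`
#'   (named vector), `results` (tibble: one row per removal with the
#'   steady state, per-gene flags, `n_affected` and `converged`),
#'   `per_gene_flagged` (column sums), `total_affected`, `total_cells`,
#'   and `threshold`.
#' @examples
#' \donttest{
#' scr <- screen_links(build_topology("ESN"), default_parameters("ESN"))
#' scr$total_affected # 14
#' }
#' @export
screen_links <- function(topology, params, threshold = 0.10,
                         init = rep(1, length(topology$genes)),
                         tol = 1e-8, t_max = 2000) {
  stopifnot(inherits(topology, "limbnet_topology"))
  base <- find_steady_state(topology, params, init = init, tol = tol,
                            t_max = t_max)
  if (!base$converged) {
    stop("unaltered model did not converge (residual ",
         format(base$residual_norm), ")", call. = FALSE)
  }
  genes <- topology$genes
  rows <- vector("list", nrow(topology$links))
  for (i in seq_len(nrow(topology$links))) {
    link <- topology$links[i, ]
    sub <- remove_link(topology, link$source, link$target)
    ss <- tryCatch(
      find_steady_state(sub, params, init = init, tol = tol, t_max = t_max),
      error = function(e) NULL
    )
    if (is.null(ss)) {
      state <- rep(NA_real_, length(genes))
      flags <- rep(NA, length(genes))
      converged <- FALSE
    } else {
      state <- unname(ss$state)
      flags <- flag_changes(state, unname(base$state), threshold)
      converged <- ss$converged
    }
    lv <- stats::setNames(as.list(state), genes)
    fl <- stats::setNames(as.list(flags), paste0("flag_", genes))
    rows[[i]] <- tibble::as_tibble(c(
      list(removed_source = link$source, removed_target = link$target),
      lv, fl,
      list(n_affected = sum(flags), converged = converged)
    ))
  }
  results <- dplyr::bind_rows(rows)
  flag_mat <- as.matrix(results[, paste0("flag_", genes)])
  structure(list(
    stage = topology$stage,
    genes = genes,
    baseline = base$state,
    results = results,
    per_gene_flagged = stats::setNames(colSums(flag_mat, na.rm = TRUE), genes),
    total_affected = sum(flag_mat, na.rm = TRUE),
    total_cells = nrow(results) * length(genes),
    threshold = threshold
  ), class = "limbnet_screen")
}

#' @export
print.limbnet_screen <- function(x, ...) {
  cat("<limbnet_screen> ", x$stage, ": ", x$total_affected, " of ",
      x$total_cells, " readouts affected (threshold ",
      format(100 * x$threshold), "%)\n", sep = "")
  cat(format_screen(x), sep = "\n")
  invisible(x)
}

#' Render a link-removal screen as a reference-style text table
#'
#' One row per removal with the steady-state level of every gene,
#' affected cells suffixed `*`, plus the per-row and per-gene totals.
#'
#' @param screen A `limbnet_screen`.
#' @param digits Decimal places for levels.
#' @return Character vector of table lines.
#' @export
format_screen <- function(screen, digits = 3) {
  stopifnot(inherits(screen, "limbnet_screen"))
  genes <- screen$genes
  fmt <- function(v, f) paste0(formatC(v, format = "f", digits = digits),
                               ifelse(f, "*", ""))
  lines <- c(paste(c(screen$stage, genes, "SUM"), collapse = "\t"),
             paste(c("Unaltered model",
                     formatC(unname(screen$baseline), format = "f",
                             digits = digits), ""), collapse = "\t"))
  for (i in seq_len(nrow(screen$results))) {
    r <- screen$results[i, ]
    vals <- unlist(r[genes])
    flags <- unlist(r[paste0("flag_", genes)])
    lines <- c(lines, paste(c(
      paste0(r$removed_source, " to ", r$removed_target),
      fmt(vals, flags), r$n_affected
    ), collapse = "\t"))
  }
  c(lines, paste(c("SUM", unname(screen$per_gene_flagged),
                   paste0(screen$total_affected, " of ",
                          screen$total_cells)), collapse = "\t"))
}

#' Per-gene impact/sensitivity coordinates of a link-removal screen
#'
#' Summarizes a screen into one point per gene: how strongly removing
#' the gene's outgoing links perturbs the rest of the network (impact,
#' Y) versus how often the gene's own level is perturbed by removals
#' (sensitivity, X).
#'
#' Modes for the impact coordinate:
#' * `"mean"` (default): the mean number of OTHER genes flagged per
#'   removal of one of the gene's outgoing links,
#' * `"union"`: the number of distinct other genes flagged across those
#'   removals,
#' * `"simultaneous"`: the number of other genes flagged in a single
#'   solve with ALL of the gene's outgoing links removed (requires
#'   `topology` and `params`).
#'
#' The sensitivity coordinate is the number of removal simulations in
#' which the gene is flagged (the screen's per-gene column total).
#' Quadrants are assigned by comparing each coordinate to half the axis
#' maximum; pass `axis_max` to place two screens on a shared scale.
#'
#' @param screen A `limbnet_screen`.
#' @param mode `"mean"`, `"union"` or `"simultaneous"`.
#' @param axis_max Optional length-2 numeric `(sensitivity, impact)` axis
#'   maxima; defaults to the maxima observed in this screen.
#' @param topology,params Needed for `mode = "simultaneous"` only.
#' @return Tibble: `gene`, `impact`, `sensitivity`, `quadrant`
#'   (`"lower-left"`, `"upper-left"`, `"lower-right"`, `"upper-right"`),
#'   plus `on_boundary` marking genes sitting exactly on a quadrant
#'   boundary.
#' @export
gene_space <- function(screen, mode = c("mean", "union", "simultaneous"),
                       axis_max = NULL, topology = NULL, params = NULL) {
  stopifnot(inherits(screen, "limbnet_screen"))
  mode <- match.arg(mode)
  genes <- screen$genes
  res <- screen$results
  flag_cols <- paste0("flag_", genes)
  sensitivity <- unname(screen$per_gene_flagged)

  impact <- vapply(genes, function(g) {
    out_rows <- which(res$removed_source == g)
    if (length(out_rows) == 0) return(0)
    other <- setdiff(flag_cols, paste0("flag_", g))
    counts <- rowSums(as.matrix(res[out_rows, other]), na.rm = TRUE)
    switch(mode,
      mean = mean(counts),
      union = sum(vapply(other, function(cl)
        any(unlist(res[out_rows, cl]), na.rm = TRUE), logical(1))),
      simultaneous = {
        if (is.null(topology) || is.null(params)) {
          stop("`topology` and `params` are required for simultaneous mode",
               call. = FALSE)
        }
        sub <- topology
        for (i in out_rows) {
          sub <- remove_link(sub, res$removed_source[i], res$removed_target[i])
        }
        ss <- find_steady_state(sub, params)
        fl <- flag_changes(unname(ss$state), unname(screen$baseline),
                           screen$threshold)
        sum(fl[genes != g])
      })
  }, numeric(1))

  if (is.null(axis_max)) axis_max <- c(max(sensitivity), max(impact))
  half <- axis_max / 2
  quadrant <- paste0(ifelse(impact > half[2], "upper", "lower"), "-",
                     ifelse(sensitivity > half[1], "right", "left"))
  tibble::tibble(
    gene = genes,
    impact = unname(impact),
    sensitivity = sensitivity,
    quadrant = quadrant,
    on_boundary = impact == half[2] | sensitivity == half[1]
  )
}
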