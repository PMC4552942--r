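#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a link-removal screen into one row per (removal, gene)
#'
#' @param x A `limbnet_screen`.
#' @param ... Unused.
#' @return Tibble: `removed_source`, `removed_target`, `gene`,
#'   `baseline`, `level`, `rel_change`, `flagged`.
#' @method tidy limbnet_screen
#' @export
tidy.limbnet_screen <- function(x, ...) {
  genes <- x$genes
  long <- tidyr::pivot_longer(
    x$results[c("removed_source", "removed_target", genes)],
    cols = dplyr::all_of(genes), names_to = "gene", values_to = "level")
  flags <- tidyr::pivot_longer(
    x$results[c("removed_source", "removed_target",
                paste0("flag_", genes))],
    cols = dplyr::starts_with("flag_"), names_to = "gene",
    values_to = "flagged")
  long$flagged <- flags$flagged
  long$baseline <- rep(unname(x$baseline[genes]),
                       times = nrow(x$results))
  long$rel_change <- abs(long$level - long$baseline) /
    pmax(long$baseline, .Machine$double.eps)
  long[c("removed_source", "removed_target", "gene", "baseline",
         "level", "rel_change", "flagged")]
}

#' @method glance limbnet_screen
#' @export
glance.limbnet_screen <- function(x, ...) {
  tibble::tibble(stage = x$stage,
                 n_links = nrow(x$results),
                 n_genes = length(x$genes),
                 total_affected = x$total_affected,
                 total_cells = x$total_cells,
                 affected_fraction = x$total_affected / x$total_cells,
                 threshold = x$threshold)
}

#' @method tidy limbnet_sensitivity
#' @export
tidy.limbnet_sensitivity <- function(x, ...) {
  x$per_gene
}

#' @method glance limbnet_sensitivity
#' @export
glance.limbnet_sensitivity <- function(x, ...) {
  flag_mat <- as.matrix(
    x$results[x$results$converged, paste0("flag_", x$genes)])
  tibble::tibble(stage = x$stage,
                 n_runs = nrow(x$results),
                 n_converged = sum(x$results$converged),
                 total_flagged = sum(flag_mat),
                 threshold = x$threshold)
}

#' @method tidy limbnet_htest
#' @export
tidy.limbnet_htest <- function(x, ...) {
  tibble::tibble(method = x$method,
                 statistic = x$statistic,
                 df = if (is.null(x$df)) NA_real_ else x$df,
                 p_value = x$p_value)
}

#' @method tidy limbnet_conservation
#' @export
tidy.limbnet_conservation <- function(x, ...) {
  x$pairs
}

#' @method glance limbnet_conservation
#' @export
glance.limbnet_conservation <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), mean_rho = x$mean_rho)
}

#' @method tidy limbnet_subsample
#' @export
tidy.limbnet_subsample <- function(x, ...) {
  x$summary
}

#' @method tidy limbnet_bootstrap
#' @export
tidy.limbnet_bootstrap <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$reps), r = x$replicates)
}

#' @method glance limbnet_bootstrap
#' @export
glance.limbnet_bootstrap <- function(x, ...) {
  tibble::tibble(observed_r = x$observed_r,
                 prop_r_le_0 = x$prop_r_le_0,
                 prop_r_ge_0 = x$prop_r_ge_0,
                 reps = x$reps,
                 n_degenerate_redrawn = x$n_degenerate_redrawn)
}

#' @method tidy limbnet_steady_state
#' @export
tidy.limbnet_steady_state <- function(x, ...) {
  tibble::tibble(gene = names(x$state), level = unname(x$state))
}
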