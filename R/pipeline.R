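#' Configuration for the full analysis pipeline
#'
#' Collects every tunable of [run_pipeline()] in one list. Every
#' stochastic stage draws from its own named seed; `run_pipeline()`
#' refuses to start if one is missing. Defaults run the pipeline at a
#' demonstration scale (reduced gene count and resampling depth);
#' `reps`, `n_sets` and `n_genes` can be raised to study scale.
#'
#' @param threshold Relative-change threshold for both screens.
#' @param grid_multipliers Fold changes for the parameter screen.
#' @param reps Monte-Carlo / bootstrap replicates.
#' @param n_sets Subsets per subsampling intensity.
#' @param intensities Subsampling fractions.
#' @param n_individuals,n_litters,litter_effect_sd qPCR generator size.
#' @param n_genes Ortholog generator size.
#' @param target_rho Target mean pairwise Spearman per stage.
#' @param seeds Named list of integer seeds: `qpcr`, `orthologs`,
#'   `variation`, `conservation`, `correlation`.
#' @param expression_table Optional observed expression table; replaces
#'   the synthetic qPCR table.
#' @param ortholog_es,ortholog_ls Optional observed ortholog matrices.
#' @param out_dir Optional output directory for per-stage TSVs and the
#'   run summary.
#' @return A `limbnet_config` list.
#' @export
pipeline_config <- function(threshold = 0.10,
                            grid_multipliers = c(0.5, 0.75, 1.25, 1.5, 2),
                            reps = 2000, n_sets = 200,
                            intensities = seq(0.5, 1, by = 0.1),
                            n_individuals = 71, n_litters = 9,
                            litter_effect_sd = 0.3,
                            n_genes = 1000,
                            target_rho = c(ES = 0.5667, LS = 0.5612),
                            seeds = list(qpcr = 101, orthologs = 202,
                                         variation = 303,
                                         conservation = 404,
                                         correlation = 505),
                            expression_table = NULL,
                            ortholog_es = NULL, ortholog_ls = NULL,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "limbnet_config")
}

check_pipeline_config <- function(config) {
  stopifnot(inherits(config, "limbnet_config"))
  needed <- c("qpcr", "orthologs", "variation", "conservation",
              "correlation")
  got <- names(config$seeds)
  missing <- setdiff(needed, got[!vapply(config$seeds, is.null,
                                         logical(1))])
  if (length(missing) > 0) {
    stop("missing seed(s) for stochastic stage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

#' Run the full network-to-divergence analysis pipeline
#'
#' Executes, in order: model build and steady states, the link-removal
#' screen, the parameter-sensitivity screen, among-individual variation
#' statistics, cross-species conservation, and the variation-divergence
#' correlation, on either supplied data tables or the synthetic
#' generators. All randomness flows from the named seeds in the config;
#' rerunning with an identical config reproduces the summary exactly.
#'
#' @param config A `limbnet_config` (see [pipeline_config()]).
#' @return A `limbnet_pipeline` list with components `models`,
#'   `screens`, `sensitivity`, `variation`, `conservation`,
#'   `correlation`, and a flat machine-readable `summary` list
#'   (counts, percentages, p-values, correlation coefficients, seeds).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  check_pipeline_config(config)
  seeds <- config$seeds

  # -- models and screens ------------------------------------------------
  models <- lapply(c(ESN = "ESN", LSN = "LSN"), function(st) {
    topo <- build_topology(st)
    params <- default_parameters(st)
    list(topology = topo, params = params,
         steady = find_steady_state(topo, params))
  })
  screens <- lapply(models, function(m)
    screen_links(m$topology, m$params, threshold = config$threshold))
  sens <- lapply(models, function(m)
    screen_parameters(m$topology, m$params,
                      grid = default_parameter_grid(
                        m$params, config$grid_multipliers),
                      threshold = config$threshold))
  space_axis <- c(
    max(vapply(screens, function(s) max(s$per_gene_flagged), numeric(1))),
    max(vapply(screens, function(s)
      max(gene_space(s)$impact), numeric(1)))
  )
  spaces <- lapply(screens, gene_space, axis_max = space_axis)
  sens_spaces <- lapply(sens, sensitivity_space)

  # -- among-individual variation ---------------------------------------
  qpcr <- config$expression_table
  if (is.null(qpcr)) {
    qpcr <- generate_qpcr_table(
      n_individuals = config$n_individuals, n_litters = config$n_litters,
      litter_effect_sd = config$litter_effect_sd, seed = seeds$qpcr)
  } else {
    qpcr <- validate_expression_table(qpcr)
  }
  covs <- stage_cov_summaries(qpcr)
  cov_means <- summarize_cov(covs)
  bartlett <- lapply(c(ES = "ES", LS = "LS"), function(g)
    bartlett_variance_test(qpcr, g))
  anovas <- lapply(stats::setNames(nm = sort(unique(qpcr$gene))),
                   function(g) litter_anova(qpcr, g))
  mc <- lapply(stats::setNames(nm = sort(unique(covs$gene))), function(g) {
    es <- covs$cov[covs$gene == g & covs$group == "ES"]
    ls <- covs$cov[covs$gene == g & covs$group == "LS"]
    mc_cov_shuffle_test(es, ls, reps = config$reps,
                        seed = seeds$variation)
  })

  # -- cross-species conservation ---------------------------------------
  if (is.null(config$ortholog_es)) {
    focal <- cov_means |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(mean_cov = mean(.data$mean_cov))
    n_genes <- max(config$n_genes, nrow(focal) + 10)
    # plant divergence proportional to within-population CoV for the
    # focal genes so the CoV-divergence link is recoverable
    scale <- with_seed(seeds$orthologs,
                       stats::rlnorm(n_genes, -0.125, 0.5))
    scale[seq_len(nrow(focal))] <-
      focal$mean_cov / stats::median(focal$mean_cov)
    names_vec <- c(focal$gene,
                   sprintf("gene%05d", seq_len(n_genes - nrow(focal))))
    orth <- generate_ortholog_matrices(
      n_genes = n_genes, target_rho = config$target_rho,
      gene_noise_scale = scale, gene_names = names_vec,
      seed = seeds$orthologs)
  } else {
    orth <- list(es = as_ortholog_matrix(config$ortholog_es),
                 ls = as_ortholog_matrix(config$ortholog_ls))
  }
  cons <- list(ES = mean_pairwise_spearman(orth$es),
               LS = mean_pairwise_spearman(orth$ls))
  subsamp <- subsample_conservation(
    orth$es, orth$ls, n_sets = config$n_sets,
    intensities = config$intensities, seed = seeds$conservation)
  diverg <- list(ES = gene_divergence(orth$es),
                 LS = gene_divergence(orth$ls))

  # -- variation vs divergence correlation ------------------------------
  correlation <- lapply(c(ES = "ES", LS = "LS"), function(g) {
    cm <- cov_means[cov_means$group == g, ]
    dv <- diverg[[g]]
    pairs <- dplyr::inner_join(
      tibble::tibble(gene = cm$gene, cov = cm$mean_cov),
      tibble::tibble(gene = dv$gene, divergence = dv$divergence_sd),
      by = "gene")
    if (nrow(pairs) < 3) return(NULL)
    boot <- bootstrap_significance(pairs, reps = config$reps,
                                   seed = seeds$correlation)
    list(pairs = pairs, bootstrap = boot)
  })

  summary <- list(
    screens = lapply(screens, function(s) list(
      total_affected = s$total_affected, total_cells = s$total_cells,
      affected_pct = round(100 * s$total_affected / s$total_cells, 1),
      per_gene_flagged = as.list(s$per_gene_flagged))),
    sensitivity = lapply(sens, function(s)
      stats::setNames(as.list(round(s$per_gene$affects_others_pct, 1)),
                      s$per_gene$gene)),
    variation = list(
      mean_cov = stats::setNames(
        as.list(round(cov_means$mean_cov, 4)),
        paste0(cov_means$gene, "_", cov_means$group)),
      bartlett_p = lapply(bartlett, function(b) b$p_value),
      litter_anova_p = lapply(anovas, function(a) a$p_value),
      mc_shuffle_p = lapply(mc, function(m) m$p_value)),
    conservation = list(
      mean_rho = lapply(cons, function(cc) round(cc$mean_rho, 4)),
      subsample_p = stats::setNames(
        as.list(signif(subsamp$summary$p_value, 4)),
        paste0("intensity_", subsamp$summary$intensity))),
    correlation = lapply(correlation, function(cr) if (is.null(cr)) NULL
      else list(r = round(cr$bootstrap$observed_r, 4),
                prop_r_le_0 = cr$bootstrap$prop_r_le_0)),
    seeds = seeds
  )

  out <- structure(list(
    config = config, models = models, screens = screens,
    sensitivity = sens, gene_spaces = spaces,
    sensitivity_spaces = sens_spaces,
    expression_table = qpcr, cov_replicates = covs,
    cov_means = cov_means, bartlett = bartlett, litter_anovas = anovas,
    mc_tests = mc, orthologs = orth, conservation = cons,
    subsample = subsamp, divergence = diverg,
    correlation = correlation, summary = summary
  ), class = "limbnet_pipeline")

  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(result$screens)) {
    writeLines(format_screen(result$screens[[st]]),
               file.path(dir, paste0("screen_", tolower(st), ".tsv")))
    readr::write_tsv(result$sensitivity[[st]]$per_gene,
                     file.path(dir, paste0("sensitivity_", tolower(st),
                                           ".tsv")))
  }
  readr::write_tsv(result$expression_table,
                   file.path(dir, "expression_table.tsv"))
  readr::write_tsv(result$cov_replicates, file.path(dir, "cov_replicates.tsv"))
  readr::write_tsv(result$subsample$summary,
                   file.path(dir, "conservation_subsample.tsv"))
  yaml::write_yaml(result$summary, file.path(dir, "summary.yaml"))
  invisible(dir)
}

#' @export
print.limbnet_pipeline <- function(x, ...) {
  cat("<limbnet_pipeline>\n")
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}
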