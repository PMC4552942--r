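#' Default gene panel for the qPCR-style generator
#'
#' Per-gene true scaled expression means and within-litter CoVs for the
#' early (ES) and late (LS) stage groups. Defaults are the study
#' conditions of the five limb network genes assayed in both stage
#' groups, plus the beta-actin housekeeping control (`is_control`).
#'
#' @return Tibble: `gene`, `es_mean`, `es_cov`, `ls_mean`, `ls_cov`,
#'   `is_control`.
#' @export
qpcr_gene_panel <- function() {
  tibble::tribble(
    ~gene,    ~es_mean, ~es_cov, ~ls_mean, ~ls_cov, ~is_control,
    "Bmp4",   2.02,     0.567,   2.29,     1.037,   FALSE,
    "Fgf8",   2.58,     0.474,   0.83,     1.701,   FALSE,
    "Grem1",  2.19,     0.531,   1.92,     0.703,   FALSE,
    "Shh",    1.68,     0.847,   2.32,     1.523,   FALSE,
    "Gli3",   0.02,     0.380,   0.02,     0.910,   FALSE,
    "Actb",   1.00,     0.832,   1.00,     0.929,   TRUE
  )
}

# deterministic embryo allocation: stages 1..8 evenly filled, litters as
# consecutive age groups (litter and stage covary, as in a real sampling
# of litters at increasing gestational ages)
allocate_embryos <- function(n_individuals, n_litters) {
  stages <- sort(rep_len(1:8, n_individuals))
  litter_sizes <- rep(n_individuals %/% n_litters, n_litters) +
    c(rep(1, n_individuals %% n_litters),
      rep(0, n_litters - n_individuals %% n_litters))
  litters <- rep(paste0("L", seq_len(n_litters)), litter_sizes)
  tibble::tibble(
    individual = paste0("ind", seq_len(n_individuals)),
    litter = litters,
    wanek_stage = stages
  )
}

#' Generate a qPCR-style per-individual expression table
#'
#' Emulates the study design: `n_individuals` embryos from `n_litters`
#' litters spread evenly over Wanek stages 1-8 (stages 1-4 = ES, 5-8 =
#' LS; litters are consecutive age groups so litter and stage covary as
#' in a real collection). Each observation is
#' `group mean x litter multiplier x lognormal noise`; the litter
#' multiplier has CoV `litter_effect_sd` and the noise dispersion is set
#' so the within-litter CoV equals the gene's configured CoV for that
#' stage group. Lognormal multipliers are mean-1, so large-sample
#' realized CoVs match their targets. Deterministic given `seed`.
#'
#' @param genes Gene panel tibble (see [qpcr_gene_panel()]).
#' @param n_individuals Number of embryos (default 71).
#' @param n_litters Number of litters (default 9).
#' @param litter_effect_sd CoV of the shared per-litter multiplier
#'   (fraction of the mean; default 0.3).
#' @param seed Integer seed.
#' @return Long tibble: `gene`, `individual`, `litter`, `wanek_stage`,
#'   `level`.
#' @export
generate_qpcr_table <- function(genes = qpcr_gene_panel(),
                                n_individuals = 71, n_litters = 9,
                                litter_effect_sd = 0.3, seed = 1) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "es_mean", "es_cov", "ls_mean", "ls_cov") %in%
                  names(genes)))
  if (any(genes$es_mean <= 0) || any(genes$ls_mean <= 0)) {
    stop("gene means must be positive", call. = FALSE)
  }
  if (any(genes$es_cov < 0) || any(genes$ls_cov < 0) || litter_effect_sd < 0) {
    stop("CoVs must be non-negative", call. = FALSE)
  }
  if (n_individuals < 2 * 8 || n_litters < 2) {
    stop("allocation infeasible: need >= 16 individuals and >= 2 litters",
         call. = FALSE)
  }
  design <- allocate_embryos(n_individuals, n_litters)
  sdlog_l <- sqrt(log(1 + litter_effect_sd^2))
  with_seed(seed, {
    litter_mult <- stats::setNames(
      exp(stats::rnorm(n_litters, -sdlog_l^2 / 2, sdlog_l)),
      paste0("L", seq_len(n_litters))
    )
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      grp <- stage_group(design$wanek_stage)
      mu <- ifelse(grp == "ES", g$es_mean, g$ls_mean)
      cv <- ifelse(grp == "ES", g$es_cov, g$ls_cov)
      sdlog_e <- sqrt(log(1 + cv^2))
      noise <- exp(stats::rnorm(nrow(design), -sdlog_e^2 / 2, sdlog_e))
      tibble::tibble(
        gene = g$gene,
        individual = design$individual,
        litter = design$litter,
        wanek_stage = design$wanek_stage,
        level = mu * unname(litter_mult[design$litter]) * noise
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate paired ortholog expression matrices with a target
#' conservation level
#'
#' Builds early- and late-stage genes x species matrices from a shared
#' latent log-expression vector plus species-specific rank-perturbing
#' noise. The per-stage noise mixing weight is found by bisection so the
#' realized mean pairwise Spearman correlation approaches
#' `target_rho[stage]`; per-gene noise scales are drawn from a lognormal
#' distribution (or supplied), so high-noise genes are the planted
#' divergent genes. Deterministic given `seed`.
#'
#' @param n_genes Number of orthologous genes (default 6583).
#' @param species Species labels (default bat, mouse, opossum, pig).
#' @param target_rho Named vector with `ES` and `LS` target mean
#'   pairwise Spearman coefficients (defaults 0.5667 / 0.5612), or
#'   `NULL` to skip tuning and use a unit noise-mixing weight.
#' @param divergence_sdlog Log-SD of the per-gene noise-scale
#'   distribution (default 0.5).
#' @param gene_noise_scale Optional length-`n_genes` vector overriding
#'   the drawn per-gene noise scales (relative weights).
#' @param gene_names Optional gene labels.
#' @param seed Integer seed.
#' @param tol Tolerance on the achieved mean Spearman (default 0.01).
#' @return List with `es` and `ls` ortholog tibbles; attributes
#'   `achieved_rho` (named) and `noise_scale` record the realized
#'   conservation and the per-gene scales.
#' @export
generate_ortholog_matrices <- function(n_genes = 6583,
                                       species = c("bat", "mouse",
                                                   "opossum", "pig"),
                                       target_rho = c(ES = 0.5667,
                                                      LS = 0.5612),
                                       divergence_sdlog = 0.5,
                                       gene_noise_scale = NULL,
                                       gene_names = NULL,
                                       seed = 1, tol = 0.01) {
  if (n_genes < 10) stop("need at least 10 genes", call. = FALSE)
  if (!is.null(target_rho)) {
    if (any(target_rho <= -1 | target_rho >= 1)) {
      stop("target Spearman must lie in (-1, 1)", call. = FALSE)
    }
    stopifnot(all(c("ES", "LS") %in% names(target_rho)))
  }
  if (is.null(gene_names)) {
    gene_names <- sprintf("gene%05d", seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes)
  with_seed(seed, {
    latent <- stats::rnorm(n_genes, mean = 3, sd = 1.5)
    scale <- if (is.null(gene_noise_scale)) {
      stats::rlnorm(n_genes, -divergence_sdlog^2 / 2, divergence_sdlog)
    } else {
      stopifnot(length(gene_noise_scale) == n_genes,
                all(gene_noise_scale >= 0))
      gene_noise_scale
    }
    build_stage <- function(stage) {
      eps <- matrix(stats::rnorm(n_genes * length(species)), n_genes)
      if (is.null(target_rho)) {
        # no tuning: unit mixing weight
        m <- matrix_from_latent(latent, scale, eps, 1, species, gene_names)
        return(list(m = m, achieved = mean_pairwise_spearman(m)$mean_rho))
      }
      achieved <- function(w) {
        mean_pairwise_spearman(
          matrix_from_latent(latent, scale, eps, w, species, gene_names)
        )$mean_rho
      }
      w_lo <- 0; w_hi <- 1
      while (achieved(w_hi) > target_rho[[stage]] && w_hi < 64) {
        w_hi <- w_hi * 2
      }
      if (achieved(w_hi) > target_rho[[stage]]) {
        stop("target Spearman ", target_rho[[stage]], " unreachable; ",
             "achieved ", round(achieved(w_hi), 4), " at maximum noise",
             call. = FALSE)
      }
      for (i in 1:40) {
        w_mid <- (w_lo + w_hi) / 2
        if (achieved(w_mid) > target_rho[[stage]]) w_lo <- w_mid
        else w_hi <- w_mid
      }
      w <- (w_lo + w_hi) / 2
      a <- achieved(w)
      if (abs(a - target_rho[[stage]]) > tol) {
        stop("bisection failed to reach target ", target_rho[[stage]],
             "; achieved ", round(a, 4), call. = FALSE)
      }
      list(m = matrix_from_latent(latent, scale, eps, w, species,
                                  gene_names),
           achieved = a)
      }
    es <- build_stage("ES")
    ls <- build_stage("LS")
    out <- list(es = es$m, ls = ls$m)
    attr(out, "achieved_rho") <- c(ES = es$achieved, LS = ls$achieved)
    attr(out, "noise_scale") <- stats::setNames(scale, gene_names)
    out
  })
}

matrix_from_latent <- function(latent, scale, eps, w, species, gene_names) {
  vals <- exp(pmin(latent + w * scale * eps, 300))
  colnames(vals) <- species
  out <- tibble::as_tibble(vals)
  out <- dplyr::bind_cols(tibble::tibble(gene = gene_names), out)
  out
}
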