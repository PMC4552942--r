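#' Parameter sets for the limb network ODE models
#'
#' Parameters are kept in a long tibble with columns `name`, `value`,
#' `owner` (the gene the parameter is assigned to) and `role`. Naming
#' convention, with short gene codes (`aer`, `bmp4`, `fgf10`, `gli3r`,
#' `grem1`, `hoxad`, `shh`, `repx`):
#'
#' * `a_<target>.<source>`: production amplitude of the additive Hill
#'   term the source gene contributes to the target gene,
#' * `K_<target>.<source>`: Hill threshold (half-saturation level) of a
#'   link, assigned to the TARGET gene,
#' * `n_<target>.<source>`: Hill exponent of a link,
#' * `b_<gene>`: basal (link-independent) production rate,
#' * `d_<gene>`: first-order degradation rate.
#'
#' All values are positive; expression levels are dimensionless activity
#' units on a roughly 0-2 scale.
#'
#' @name parameters
NULL

link_param_names <- function(link_row) {
  key <- paste0(gene_code(link_row$target), ".", gene_code(link_row$source))
  if (link_row$mechanism == "gate") {
    paste0(c("K_", "n_"), key)
  } else {
    paste0(c("a_", "K_", "n_"), key)
  }
}

param_role <- function(name) {
  prefix <- substr(name, 1, 1)
  c(a = "production rate", K = "Hill threshold", n = "Hill exponent",
    b = "basal production", d = "degradation rate")[[prefix]]
}

#' Build a parameter table for a topology
#'
#' Creates the complete parameter skeleton a topology requires, filled
#' from a named numeric vector. Link parameters are owned by the target
#' gene; basal production and degradation by the gene itself.
#'
#' @param topology A `limbnet_topology`.
#' @param values Named numeric vector supplying every required parameter.
#' @return Tibble with columns `name`, `value`, `owner`, `role`.
#' @export
make_parameters <- function(topology, values) {
  stopifnot(inherits(topology, "limbnet_topology"))
  rows <- list()
  for (i in seq_len(nrow(topology$links))) {
    link <- topology$links[i, ]
    for (nm in link_param_names(link)) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(name = nm, owner = link$target)
    }
  }
  for (g in topology$genes) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(name = paste0("b_", gene_code(g)), owner = g)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(name = paste0("d_", gene_code(g)), owner = g)
  }
  out <- dplyr::bind_rows(rows)
  missing <- setdiff(out$name, names(values))
  if (length(missing) > 0) {
    stop("missing parameter value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$value <- unname(values[out$name])
  if (any(!is.finite(out$value)) || any(out$value < 0)) {
    stop("parameter values must be finite and non-negative", call. = FALSE)
  }
  out$role <- vapply(out$name, param_role, character(1))
  out[, c("name", "value", "owner", "role")]
}

#' Default (calibrated) parameters for the ESN and LSN models
#'
#' Hill-kinetics constants calibrated by least squares so that the
#' unaltered models reproduce the reference steady-state expression
#' levels of both networks (see [reference_screen()]) and the
#' link-removal screen reproduces the reference pattern of >=10%
#' expression changes.
#'
#' @param stage `"ESN"` or `"LSN"`.
#' @return Parameter tibble as produced by [make_parameters()].
#' @export
default_parameters <- function(stage) {
  stage <- check_stage(stage)
  values <- if (stage == "ESN") esn_default_values else lsn_default_values
  make_parameters(build_topology(stage), values)
}

params_to_vector <- function(params) {
  stats::setNames(params$value, params$name)
}

# Calibrated constants (see the methods vignette for the fitting
# procedure). Decay rates are fixed at 1 so levels equal net production
# at steady state; time is in units of the common protein lifetime.
esn_default_values <- c(
  # AER-Fgfs <- Bmp4 (repression), <- Fgf10 (activation)
  a_aer.bmp4 = 0.990061, K_aer.bmp4 = 6.514367, n_aer.bmp4 = 1.021747,
  a_aer.fgf10 = 1.050782, K_aer.fgf10 = 0.12248, n_aer.fgf10 = 1.005916,
  # Bmp4 <- Grem1 (repression; a steep switch around the Grem1 set point)
  a_bmp4.grem1 = 0.055003, K_bmp4.grem1 = 1.909207,
  n_bmp4.grem1 = 43.605357,
  # Fgf10 <- AER-Fgfs, HoxAD (activation)
  a_fgf10.aer = 1.055597, K_fgf10.aer = 0.137349, n_fgf10.aer = 1.006631,
  a_fgf10.hoxad = 1.129396, K_fgf10.hoxad = 0.854827,
  n_fgf10.hoxad = 2.612378,
  # Gli3R <- Shh (repression)
  a_gli3r.shh = 1.158283, K_gli3r.shh = 0.402176, n_gli3r.shh = 2.978262,
  # Grem1 <- Bmp4 (act), Gli3R (rep), HoxAD (act)
  a_grem1.bmp4 = 0.282307, K_grem1.bmp4 = 3.01488,
  n_grem1.bmp4 = 0.684611,
  a_grem1.gli3r = 0.984715, K_grem1.gli3r = 3.689091,
  n_grem1.gli3r = 1.257459,
  a_grem1.hoxad = 1.090778, K_grem1.hoxad = 0.829674,
  n_grem1.hoxad = 2.760909,
  # HoxAD: constitutive (no incoming links in the early network)
  # Shh <- AER-Fgfs, HoxAD (activation)
  a_shh.aer = 0.983319, K_shh.aer = 0.243975, n_shh.aer = 1.46252,
  a_shh.hoxad = 1.085226, K_shh.hoxad = 0.834859,
  n_shh.hoxad = 2.704297,
  # basal production and degradation
  b_aer = 0, d_aer = 1,
  b_bmp4 = 0.002982, d_bmp4 = 1,
  b_fgf10 = 0, d_fgf10 = 1,
  b_gli3r = 0.002956, d_gli3r = 1,
  b_grem1 = 0.022697, d_grem1 = 1,
  b_hoxad = 1.798, d_hoxad = 1,
  b_shh = 0.06953, d_shh = 1
)

lsn_default_values <- c(
  # AER-Fgfs <- Bmp4 (repression; sole production pathway)
  a_aer.bmp4 = 1.982588, K_aer.bmp4 = 0.824906, n_aer.bmp4 = 3.793056,
  # Bmp4 <- Grem1 (repression; sole production pathway)
  a_bmp4.grem1 = 2.180996, K_bmp4.grem1 = 0.267675,
  n_bmp4.grem1 = 2.313919,
  # Gli3R <- Shh (repression)
  a_gli3r.shh = 1.000282, K_gli3r.shh = 0.36811, n_gli3r.shh = 2.937116,
  # Grem1 <- Bmp4 (act), Gli3R (rep), HoxAD (act); RepressorX gate
  a_grem1.bmp4 = 1.993729, K_grem1.bmp4 = 0.731434,
  n_grem1.bmp4 = 1.732284,
  a_grem1.gli3r = 1.189107, K_grem1.gli3r = 0.570516,
  n_grem1.gli3r = 4.97318,
  a_grem1.hoxad = 1.867947, K_grem1.hoxad = 2.33916,
  n_grem1.hoxad = 1.893091,
  K_grem1.repx = 0.005734, n_grem1.repx = 1.009947,
  # HoxAD <- AER-Fgfs (act), Gli3R (rep)
  a_hoxad.aer = 1.015126, K_hoxad.aer = 0.253915, n_hoxad.aer = 3.408727,
  a_hoxad.gli3r = 0.951551, K_hoxad.gli3r = 0.438329,
  n_hoxad.gli3r = 3.305026,
  # RepressorX <- AER-Fgfs (act)
  a_repx.aer = 0.052016, K_repx.aer = 0.16058, n_repx.aer = 7.524806,
  # Shh <- AER-Fgfs, HoxAD (act)
  a_shh.aer = 0.889969, K_shh.aer = 0.341467, n_shh.aer = 3.166881,
  a_shh.hoxad = 0.933641, K_shh.hoxad = 0.882947, n_shh.hoxad = 17.236121,
  b_aer = 0, d_aer = 1,
  b_bmp4 = 0, d_bmp4 = 1,
  b_gli3r = 0, d_gli3r = 1,
  b_grem1 = 0, d_grem1 = 1,
  b_hoxad = 0, d_hoxad = 1,
  b_shh = 0.001555, d_shh = 1,
  b_repx = 0, d_repx = 1
)
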