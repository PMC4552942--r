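#' Reference steady-state levels for the limb network screens
#'
#' Published steady-state expression levels of the ESN and LSN models:
#' the unaltered model plus one row per single-link removal, with a flag
#' for every level that differs from the unaltered model by 10% or more.
#' The unaltered rows are the calibration targets for
#' [default_parameters()]; the flag pattern is the reference the
#' link-removal screen is validated against (14 of 77 affected cells for
#' the ESN, 52 of 84 for the LSN).
#'
#' @param stage `"ESN"` or `"LSN"`.
#' @return Tibble with columns `removed_source`, `removed_target` (both
#'   `NA` for the unaltered row), one column per gene, and a matching set
#'   of `flag_<gene>` logical columns.
#' @export
reference_screen <- function(stage) {
  stage <- check_stage(stage)
  if (stage == "ESN") esn_reference() else lsn_reference()
}

ref_row <- function(genes, src, tgt, values, flags) {
  lv <- stats::setNames(as.list(values), genes)
  fl <- stats::setNames(as.list(flags), paste0("flag_", genes))
  tibble::as_tibble(c(list(removed_source = src, removed_target = tgt),
                      lv, fl))
}

esn_reference <- function() {
  g <- network_genes("ESN")
  F_ <- FALSE; T_ <- TRUE
  dplyr::bind_rows(
    ref_row(g, NA, NA,
            c(1.979, 0.011, 1.976, 0.013, 1.988, 1.798, 1.973), rep(F_, 7)),
    ref_row(g, "AER-Fgfs", "Fgf10",
            c(1.926, 0.011, 0.989, 0.013, 1.988, 1.798, 1.972),
            c(F_, F_, T_, F_, F_, F_, F_)),
    ref_row(g, "AER-Fgfs", "Shh",
            c(1.979, 0.012, 1.976, 0.068, 1.981, 1.798, 0.990),
            c(F_, F_, F_, T_, F_, F_, T_)),
    ref_row(g, "Bmp4", "AER-Fgfs",
            c(0.989, 0.011, 1.921, 0.014, 1.988, 1.798, 1.897),
            c(T_, F_, F_, F_, F_, F_, F_)),
    ref_row(g, "Bmp4", "Grem1",
            c(1.975, 0.013, 1.975, 0.013, 1.977, 1.798, 1.972), rep(F_, 7)),
    ref_row(g, "Fgf10", "AER-Fgfs",
            c(0.990, 0.012, 1.908, 0.016, 1.986, 1.798, 1.882),
            c(T_, F_, F_, F_, F_, F_, F_)),
    ref_row(g, "Gli3R", "Grem1",
            c(1.976, 0.058, 1.976, 0.013, 1.006, 1.798, 1.973),
            c(F_, T_, F_, F_, T_, F_, F_)),
    ref_row(g, "Grem1", "Bmp4",
            c(1.982, 0.003, 1.976, 0.013, 1.985, 1.798, 1.973),
            c(F_, T_, F_, F_, F_, F_, F_)),
    ref_row(g, "HoxAD", "Grem1",
            c(1.972, 0.058, 1.975, 0.013, 1.016, 1.798, 1.972),
            c(F_, T_, F_, F_, T_, F_, F_)),
    ref_row(g, "HoxAD", "Shh",
            c(1.979, 0.012, 1.976, 0.074, 1.969, 1.798, 0.983),
            c(F_, F_, F_, T_, F_, F_, T_)),
    ref_row(g, "HoxAD", "Fgf10",
            c(1.923, 0.011, 0.988, 0.013, 1.988, 1.798, 1.971),
            c(F_, F_, T_, F_, F_, F_, F_)),
    ref_row(g, "Shh", "Gli3R",
            c(1.979, 0.011, 1.976, 0.003, 1.991, 1.798, 1.973),
            c(F_, F_, F_, T_, F_, F_, F_))
  )
}

lsn_reference <- function() {
  g <- network_genes("LSN")  # AER-Fgfs Bmp4 Gli3R Grem1 HoxAD Shh RepressorX
  F_ <- FALSE; T_ <- TRUE
  dplyr::bind_rows(
    ref_row(g, NA, NA,
            c(0.791, 0.919, 0.010, 0.307, 1.946, 1.767, 0.052), rep(F_, 7)),
    ref_row(g, "AER-Fgfs", "HoxAD",
            c(0.599, 1.056, 0.017, 0.273, 1.000, 1.431, 0.052),
            c(T_, T_, T_, T_, T_, T_, F_)),
    ref_row(g, "AER-Fgfs", "RepressorX",
            c(2.000, 0.018, 0.009, 1.910, 1.992, 1.925, 0.000),
            c(T_, T_, F_, T_, F_, F_, T_)),
    ref_row(g, "AER-Fgfs", "Shh",
            c(0.787, 0.922, 0.068, 0.306, 1.930, 0.957, 0.052),
            c(F_, F_, T_, F_, F_, T_, F_)),
    ref_row(g, "Bmp4", "AER-Fgfs",
            c(0.000, 0.400, 1.000, 0.635, 0.060, 0.006, 0.000), rep(T_, 7)),
    ref_row(g, "Bmp4", "Grem1",
            c(0.054, 1.989, 1.000, 0.072, 0.063, 0.001, 0.000), rep(T_, 7)),
    ref_row(g, "Gli3R", "Grem1",
            c(0.222, 1.477, 0.029, 0.208, 1.400, 1.112, 0.049),
            c(T_, T_, T_, T_, T_, T_, F_)),
    ref_row(g, "Gli3R", "HoxAD",
            c(0.597, 1.063, 0.017, 0.267, 0.892, 1.397, 0.052),
            c(T_, T_, T_, T_, T_, T_, F_)),
    ref_row(g, "Grem1", "Bmp4",
            c(2.000, 0.000, 0.009, 0.192, 1.992, 1.925, 0.054),
            c(T_, T_, F_, T_, F_, F_, F_)),
    ref_row(g, "HoxAD", "Grem1",
            c(0.430, 1.210, 0.014, 0.240, 1.776, 1.453, 0.052),
            c(T_, T_, T_, T_, F_, T_, F_)),
    ref_row(g, "HoxAD", "Shh",
            c(0.798, 0.916, 0.083, 0.307, 1.940, 0.813, 0.052),
            c(F_, F_, T_, F_, F_, T_, F_)),
    ref_row(g, "RepressorX", "Grem1",
            c(2.000, 0.018, 0.009, 1.910, 1.992, 1.925, 0.052),
            c(T_, T_, F_, T_, F_, F_, F_)),
    ref_row(g, "Shh", "Gli3R",
            c(0.721, 0.966, 0.000, 0.295, 1.932, 1.730, 0.053),
            c(F_, F_, T_, F_, F_, F_, F_))
  )
}
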