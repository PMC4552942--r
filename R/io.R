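#' Read a per-individual expression table
#'
#' Reads a TSV (or CSV, by file extension) with header columns `gene`,
#' `individual`, `litter`, `wanek_stage`, `level` and validates every
#' record: strict types, Wanek stage in 1..15, non-negative finite
#' levels, no duplicate (gene, individual) rows. Errors name the
#' offending data row.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_expression_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, show_col_types = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  validate_expression_table(raw, from_file = TRUE)
}

validate_expression_table <- function(table, from_file = FALSE) {
  needed <- c("gene", "individual", "litter", "wanek_stage", "level")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    stop("expression table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  stage_num <- suppressWarnings(as.numeric(table$wanek_stage))
  level_num <- suppressWarnings(as.numeric(table$level))
  bad <- which(is.na(stage_num) | is.na(level_num) |
                 stage_num != round(stage_num) |
                 stage_num < 1 | stage_num > 15 |
                 level_num < 0 | !is.finite(level_num) |
                 is.na(table$gene) | is.na(table$individual) |
                 is.na(table$litter))
  if (length(bad) > 0) {
    stop("malformed expression record(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  }
  dup <- duplicated(table[c("gene", "individual")])
  if (any(dup)) {
    stop("duplicate (gene, individual) record(s) at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  table$wanek_stage <- as.integer(stage_num)
  table$level <- level_num
  table$gene <- as.character(table$gene)
  table$individual <- as.character(table$individual)
  table$litter <- as.character(table$litter)
  table
}

#' Write an expression table / ortholog matrix as TSV
#'
#' Tab-delimited, UTF-8, header row: the canonical dialect used by every
#' reader in the package.
#'
#' @param x Tibble to write.
#' @param path Destination file.
#' @return `x`, invisibly.
#' @export
write_limbnet_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Read an ortholog expression matrix
#'
#' TSV/CSV with a `gene` column plus one numeric column per species.
#'
#' @param path File path.
#' @return Validated ortholog tibble.
#' @export
read_ortholog_matrix <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  as_ortholog_matrix(reader(path, show_col_types = FALSE))
}

#' Serialize a topology and parameter set to a YAML model config
#'
#' Schema: `stage`, `genes` (ordered), `links` (list of
#' `{source, target, sign, mechanism}`), `params`
#' (`name: {value, owner, role}`). [read_model_config()] restores both
#' objects, so link signs and constants can be audited or overridden
#' without code changes.
#'
#' @param topology A `limbnet_topology`.
#' @param params Parameter tibble.
#' @param path Destination YAML file.
#' @export
write_model_config <- function(topology, params, path) {
  stopifnot(inherits(topology, "limbnet_topology"))
  cfg <- list(
    stage = topology$stage,
    genes = as.list(topology$genes),
    links = lapply(seq_len(nrow(topology$links)), function(i) {
      as.list(topology$links[i, ])
    }),
    params = stats::setNames(lapply(seq_len(nrow(params)), function(i) {
      list(value = params$value[i], owner = params$owner[i],
           role = params$role[i])
    }), params$name)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @return `read_model_config()`: list with `topology` and `params`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$stage), !is.null(cfg$links), !is.null(cfg$params))
  links <- dplyr::bind_rows(lapply(cfg$links, tibble::as_tibble))
  topology <- structure(
    list(stage = check_stage(cfg$stage), genes = unlist(cfg$genes),
         links = links),
    class = "limbnet_topology"
  )
  params <- tibble::tibble(
    name = names(cfg$params),
    value = vapply(cfg$params, function(p) as.numeric(p$value), numeric(1)),
    owner = vapply(cfg$params, function(p) p$owner, character(1)),
    role = vapply(cfg$params, function(p) p$role, character(1))
  )
  list(topology = topology, params = params)
}
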