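#' Gene identifiers used by the limb network models
#'
#' The early stage network (ESN; limb outgrowth, ~E9.5-E11) contains
#' AER-Fgfs, Bmp4, Fgf10, Gli3R, Grem1, HoxAD and Shh. The late stage
#' network (LSN; expansion/elongation, ~E11-E13) drops Fgf10 and adds an
#' unidentified repressor of Grem1, RepressorX. Gene order is the fixed
#' column order used for every state vector and output table.
#'
#' @param stage `"ESN"` or `"LSN"`.
#' @return Character vector of gene names in canonical order.
#' @export
network_genes <- function(stage) {
  stage <- check_stage(stage)
  if (stage == "ESN") {
    c("AER-Fgfs", "Bmp4", "Fgf10", "Gli3R", "Grem1", "HoxAD", "Shh")
  } else {
    c("AER-Fgfs", "Bmp4", "Gli3R", "Grem1", "HoxAD", "Shh", "RepressorX")
  }
}

check_stage <- function(stage) {
  if (!is.character(stage) || length(stage) != 1L) {
    stop("`stage` must be a single string, \"ESN\" or \"LSN\"", call. = FALSE)
  }
  stage <- toupper(stage)
  if (!stage %in% c("ESN", "LSN")) {
    stop("unknown stage label: ", stage, " (expected \"ESN\" or \"LSN\")",
         call. = FALSE)
  }
  stage
}

# Link tables. `sign` is the regulatory sign (activation/repression);
# `mechanism` says how the link enters the target's production:
#   "additive": its own Hill production term (increasing for activation,
#               decreasing for repression),
#   "gate":     a multiplicative repression factor on total production.
esn_link_table <- function() {
  tibble::tribble(
    ~source,     ~target,      ~sign,        ~mechanism,
    "AER-Fgfs",  "Fgf10",      "activation", "additive",
    "AER-Fgfs",  "Shh",        "activation", "additive",
    "Bmp4",      "AER-Fgfs",   "repression", "additive",
    "Bmp4",      "Grem1",      "activation", "additive",
    "Fgf10",     "AER-Fgfs",   "activation", "additive",
    "Gli3R",     "Grem1",      "repression", "additive",
    "Grem1",     "Bmp4",       "repression", "additive",
    "HoxAD",     "Fgf10",      "activation", "additive",
    "HoxAD",     "Grem1",      "activation", "additive",
    "HoxAD",     "Shh",        "activation", "additive",
    "Shh",       "Gli3R",      "repression", "additive"
  )
}

lsn_link_table <- function() {
  tibble::tribble(
    ~source,      ~target,      ~sign,        ~mechanism,
    "AER-Fgfs",   "HoxAD",      "activation", "additive",
    "AER-Fgfs",   "RepressorX", "activation", "additive",
    "AER-Fgfs",   "Shh",        "activation", "additive",
    "Bmp4",       "AER-Fgfs",   "repression", "additive",
    "Bmp4",       "Grem1",      "activation", "additive",
    "Gli3R",      "Grem1",      "repression", "additive",
    "Gli3R",      "HoxAD",      "repression", "additive",
    "Grem1",      "Bmp4",       "repression", "additive",
    "HoxAD",      "Grem1",      "activation", "additive",
    "HoxAD",      "Shh",        "activation", "additive",
    "RepressorX", "Grem1",      "repression", "gate",
    "Shh",        "Gli3R",      "repression", "additive"
  )
}

#' Build the regulatory topology of a limb network stage
#'
#' Returns the signed, directed interaction graph of the early (ESN) or
#' late (LSN) stage limb network: 11 links among 7 genes for the ESN and
#' 12 links among 7 genes for the LSN.
#'
#' @param stage `"ESN"` or `"LSN"`.
#' @return A `limbnet_topology` object: a list with elements `stage`,
#'   `genes` (ordered character vector) and `links` (tibble with columns
#'   `source`, `target`, `sign`, `mechanism`).
#' @examples
#' top <- build_topology("ESN")
#' nrow(top$links) # 11
#' @export
build_topology <- function(stage) {
  stage <- check_stage(stage)
  links <- if (stage == "ESN") esn_link_table() else lsn_link_table()
  structure(
    list(stage = stage, genes = network_genes(stage), links = links),
    class = "limbnet_topology"
  )
}

#' @export
print.limbnet_topology <- function(x, ...) {
  cat("<limbnet_topology> ", x$stage, ": ", length(x$genes), " genes, ",
      nrow(x$links), " links\n", sep = "")
  print(x$links, n = Inf)
  invisible(x)
}

#' Remove a single regulatory link from a topology
#'
#' Deletes one directed interaction, leaving all others intact. An
#' additive link's production term is dropped from the target's equation;
#' a gate link's repression factor reverts to its neutral value of 1.
#'
#' @param topology A `limbnet_topology`.
#' @param source,target Gene names identifying the link.
#' @return The topology without the named link.
#' @export
remove_link <- function(topology, source, target) {
  stopifnot(inherits(topology, "limbnet_topology"))
  hit <- topology$links$source == source & topology$links$target == target
  if (!any(hit)) {
    stop("link ", source, " -> ", target, " is not present in the ",
         topology$stage, " topology", call. = FALSE)
  }
  topology$links <- topology$links[!hit, , drop = FALSE]
  topology
}

#' Add a regulatory link to a topology
#'
#' Inverse of [remove_link()]; mainly useful for round-trip manipulation
#' and for exploring variant topologies.
#'
#' @inheritParams remove_link
#' @param sign `"activation"` or `"repression"`.
#' @param mechanism `"additive"` or `"gate"`.
#' @export
add_link <- function(topology, source, target, sign = "activation",
                     mechanism = "additive") {
  stopifnot(inherits(topology, "limbnet_topology"))
  if (!source %in% topology$genes || !target %in% topology$genes) {
    stop("both `source` and `target` must be genes of the topology",
         call. = FALSE)
  }
  if (source == target) stop("self-links are not allowed", call. = FALSE)
  if (any(topology$links$source == source & topology$links$target == target)) {
    stop("link ", source, " -> ", target, " already present", call. = FALSE)
  }
  sign <- match.arg(sign, c("activation", "repression"))
  mechanism <- match.arg(mechanism, c("additive", "gate"))
  topology$links <- dplyr::bind_rows(
    topology$links,
    tibble::tibble(source = source, target = target, sign = sign,
                   mechanism = mechanism)
  )
  # keep a stable canonical ordering so removal/re-addition round-trips
  topology$links <- dplyr::arrange(topology$links, .data$source, .data$target)
  topology
}

# short machine-friendly gene codes used in parameter names
gene_code <- function(gene) {
  codes <- c("AER-Fgfs" = "aer", "Bmp4" = "bmp4", "Fgf10" = "fgf10",
             "Gli3R" = "gli3r", "Grem1" = "grem1", "HoxAD" = "hoxad",
             "Shh" = "shh", "RepressorX" = "repx")
  unname(codes[gene])
}
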