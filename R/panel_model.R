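#' Construct a panel definition
#'
#' A targeted panel is a named gene set with a captured-region size in
#' megabases and a counting rule (whether synonymous mutations contribute to
#' the panel TMB numerator, as the F1CDx and TSO500 scores do).
#'
#' @param name Panel name.
#' @param genes Character vector of HUGO symbols (unique, non-empty).
#' @param size_mb Captured region size in megabases (> 0).
#' @param include_synonymous Logical counting rule; default `FALSE`.
#' @return A `panel_definition` object.
#' @export
panel_definition <- function(name, genes, size_mb, include_synonymous = FALSE) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("panel '", name, "' has an empty gene list")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("panel '", name, "' lists duplicated gene symbol(s): ",
         paste(dup, collapse = ", "))
  }
  if (!is.numeric(size_mb) || length(size_mb) != 1 || !is.finite(size_mb) ||
      size_mb <= 0) {
    stop("panel '", name, "' must have size_mb > 0")
  }
  stopifnot(is.logical(include_synonymous), length(include_synonymous) == 1)
  structure(
    list(name = as.character(name), genes = genes, size_mb = as.numeric(size_mb),
         include_synonymous = include_synonymous),
    class = "panel_definition"
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition> ", x$name, ": ", length(x$genes), " genes, ",
      format(x$size_mb), " Mb, synonymous ",
      if (x$include_synonymous) "included" else "excluded", "\n", sep = "")
  invisible(x)
}

#' Load a panel definition from a YAML config
#'
#' The config declares `name`, `genes` (an inline list or a path — relative
#' to the config file — to a one-symbol-per-line text file), `size_mb` and
#' `include_synonymous`. Vendor gene lists and captured sizes are user data:
#' the package ships no hard-coded commercial panel content.
#'
#' @param path Path to the YAML config.
#' @return A `panel_definition`.
#' @export
load_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("name", "genes", "size_mb", "include_synonymous")) {
    if (is.null(cfg[[key]])) stop("panel config is missing key: ", key)
  }
  genes <- cfg$genes
  if (is.character(genes) && length(genes) == 1 && !file.exists(genes)) {
    relative <- file.path(dirname(path), genes)
    if (file.exists(relative)) genes <- relative
  }
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    genes <- readLines(genes)
    genes <- genes[nzchar(trimws(genes))]
  } else {
    genes <- unlist(genes, use.names = FALSE)
  }
  panel_definition(cfg$name, genes, cfg$size_mb,
                   isTRUE(cfg$include_synonymous))
}

#' Serialize a panel definition to YAML
#'
#' @param panel A `panel_definition`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(
    list(name = panel$name, genes = as.list(panel$genes),
         size_mb = panel$size_mb,
         include_synonymous = panel$include_synonymous),
    path
  )
  invisible(path)
}

#' Read a gene coding-length table
#'
#' @param path Two-column TSV with header `gene`, `coding_length_bases`.
#' @return A tibble with those two columns.
#' @export
read_gene_lengths <- function(path) {
  gl <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", .default = "d"
  ), progress = FALSE)
  missing <- setdiff(c("gene", "coding_length_bases"), names(gl))
  if (length(missing) > 0) {
    stop("gene length table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  gl
}

#' Build a virtual panel from a gene set and coding lengths
#'
#' Used by the random-panel experiment: the captured size of an in-silico
#' panel is taken as the summed coding length (CDS bases) of its member
#' genes, converted to megabases. Coding length is a proxy for a capture
#' footprint; it is isolated here so a different denominator can be swapped
#' in.
#'
#' @param genes Character vector of member genes.
#' @param gene_lengths Tibble (`gene`, `coding_length_bases`) or a named
#'   numeric vector of coding lengths in bases.
#' @param include_synonymous Counting rule; default `FALSE`.
#' @param name Optional panel name; auto-generated when `NULL`.
#' @return A `panel_definition` with `size_mb` = total coding length / 1e6.
#' @export
make_virtual_panel <- function(genes, gene_lengths, include_synonymous = FALSE,
                               name = NULL) {
  if (length(genes) == 0) stop("virtual panel needs a non-empty gene set")
  lengths <- as_length_vector(gene_lengths)
  missing <- setdiff(genes, names(lengths))
  if (length(missing) > 0) {
    stop("gene(s) missing from the length table: ",
         paste(sort(missing), collapse = ", "))
  }
  if (is.null(name)) {
    name <- sprintf("virtual_%dg", length(genes))
  }
  panel_definition(name, genes, sum(lengths[genes]) / 1e6,
                   include_synonymous)
}

as_length_vector <- function(gene_lengths) {
  if (is.numeric(gene_lengths) && !is.null(names(gene_lengths))) {
    return(gene_lengths)
  }
  stopifnot(all(c("gene", "coding_length_bases") %in% names(gene_lengths)))
  stats::setNames(gene_lengths$coding_length_bases, gene_lengths$gene)
}
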