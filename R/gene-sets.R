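#' Construct a gene set
#'
#' A gene set is a labelled set of canonical gene identifiers.  Identifiers
#' are opaque strings; Entrez-style integer ids serialized as strings are the
#' recommended convention but nothing is enforced beyond uniqueness.  The
#' resultant gene set of an experiment (e.g. differentially expressed genes)
#' and the background universe of a platform are both represented this way.
#'
#' @param label short display label.
#' @param genes character vector of gene identifiers; duplicates are collapsed.
#' @return An object of class `GeneSet` with elements `label` and `genes`
#'   (sorted, unique).
#' @examples
#' gene_set("resultant", c("10", "20", "10"))
#' @export
gene_set <- function(label, genes) {
  stopifnot(is.character(label), length(label) == 1L)
  genes <- as.character(genes)
  genes <- genes[!is.na(genes) & nzchar(genes)]
  structure(list(label = label, genes = sort_ids(unique(genes))),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$label, length(x$genes)))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

as_gene_set <- function(x, label = "genes") {
  if (inherits(x, "GeneSet")) return(x)
  if (is.character(x)) return(gene_set(label, x))
  stop("expected a GeneSet or a character vector of gene identifiers")
}

#' Read a one-identifier-per-line gene list
#'
#' Blank lines and lines starting with `#` are ignored; surrounding
#' whitespace is stripped; duplicates are collapsed.
#'
#' @param path file path.
#' @param label label for the resulting set; defaults to the file name.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- basename(path)
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  gene_set(label, x)
}

#' Write a gene list, one identifier per line
#'
#' @param gs a [gene_set()] or character vector.
#' @param path output file path.
#' @export
write_gene_list <- function(gs, path) {
  gs <- as_gene_set(gs)
  writeLines(gs$genes, path)
  invisible(path)
}
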