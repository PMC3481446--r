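#' Construct a genome-wide interaction network
#'
#' Undirected, simple protein-protein interaction graph over gene
#' identifiers.  Self-loops are dropped and duplicate / reversed edges are
#' collapsed.  The genome universe used by the hypergeometric expectation is
#' the union of the edge endpoints and an optional explicit universe (e.g.
#' all pathway genes plus the platform background), so the expectation is
#' well-posed for every gene it is applied to even when that gene has no
#' recorded interaction.
#'
#' @param edges two-column character matrix or data frame of gene pairs.
#' @param universe optional [gene_set()] or character vector extending the
#'   genome universe beyond the edge endpoints.
#' @return An object of class `InteractionNetwork` with fields `graph`
#'   (igraph), `nodes` (endpoint genes, sorted), `universe` (full genome
#'   universe) and `n_genome`.
#' @examples
#' net <- interaction_network(cbind(c("A", "B"), c("B", "C")))
#' net_degree(net, c("A", "B", "Z"))
#' @export
interaction_network <- function(edges, universe = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || nrow2(edges) == 0L) {
    em <- matrix(character(0), ncol = 2)
  } else {
    stopifnot(ncol(edges) == 2L)
    em <- cbind(as.character(edges[, 1]), as.character(edges[, 2]))
  }
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    em <- em[!loops, , drop = FALSE]
  }
  # canonical unordered orientation, then dedupe
  a <- pmin(em[, 1], em[, 2])
  b <- pmax(em[, 1], em[, 2])
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]; b <- b[!dup]
  nodes <- sort_ids(unique(c(a, b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(a)) g <- igraph::add_edges(g, rbind(a, b))
  uni <- nodes
  if (!is.null(universe))
    uni <- sort_ids(unique(c(nodes, as_gene_set(universe)$genes)))
  structure(list(graph = g, nodes = nodes, universe = uni,
                 n_genome = length(uni)),
            class = "InteractionNetwork")
}

nrow2 <- function(x) if (is.null(dim(x))) 0L else nrow(x)

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges (genome universe %d)\n",
              length(x$nodes), igraph::ecount(x$graph), x$n_genome))
  invisible(x)
}

#' Interaction degree of genes
#'
#' Number of distinct interaction partners per gene.  Genes absent from the
#' network have degree 0.
#'
#' @param net an [interaction_network()].
#' @param genes character vector of gene ids.
#' @return Integer vector parallel to `genes`.
#' @export
net_degree <- function(net, genes) {
  d <- integer(length(genes))
  present <- genes %in% net$nodes
  if (any(present))
    d[present] <- as.integer(igraph::degree(net$graph, genes[present]))
  d
}

#' Interaction partners of a gene
#'
#' @param net an [interaction_network()].
#' @param gene a single gene id.
#' @return Character vector of partners (empty if the gene is absent).
#' @export
net_neighbors <- function(net, gene) {
  if (!gene %in% net$nodes) return(character(0))
  igraph::neighbors(net$graph, gene)$name
}

# adjacency as a named list of character vectors; built once per algorithm call
net_adj_list <- function(net) {
  if (!length(net$nodes)) return(list())
  adj <- igraph::as_adj_list(net$graph)
  lapply(adj, function(v) v$name)
}

# count edges with both endpoints in `genes`
net_edges_within <- function(net, genes) {
  v <- intersect(genes, net$nodes)
  if (length(v) < 2L) return(0L)
  as.integer(igraph::ecount(igraph::induced_subgraph(net$graph, v)))
}

#' Read a protein-protein interaction edge list
#'
#' Two-column tab-separated file of gene pairs, one interaction per line.
#' The graph is undirected and deduplicated; self-loops are dropped with a
#' logged count.
#'
#' @param path TSV file path.
#' @param universe optional gene universe (see [interaction_network()]).
#'   With an empty edge file the genome size is the universe size.
#' @return An [interaction_network()].
#' @export
read_interactions <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(interaction_network(NULL, universe))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge line %d: expected exactly 2 tab-separated columns",
                 bad[1]))
  em <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  interaction_network(em, universe)
}

#' Write an interaction network as a two-column edge list
#' @param net an [interaction_network()].
#' @param path output path.
#' @export
write_interactions <- function(net, path) {
  em <- igraph::as_edgelist(net$graph)
  a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
  o <- order_ids(a, b)
  writeLines(paste(a[o], b[o], sep = "\t"), path)
  invisible(path)
}

#' Construct a gene-to-annotation-term map
#'
#' Maps each gene to a set of annotation-term identifiers (GO-Slim term ids
#' in the intended use).  Genes with an empty term set are dropped.
#'
#' @param x named list: gene id -> character vector of term ids.
#' @return An object of class `AnnotationMap` (a named list) with attribute
#'   `terms`, the term universe.
#' @export
annotation_map <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)))
  x <- lapply(x, function(t) sort_ids(unique(as.character(t))))
  x <- x[lengths(x) >= 1L]
  structure(x, terms = sort_ids(unique(unlist(x, use.names = FALSE))),
            class = "AnnotationMap")
}

#' @export
print.AnnotationMap <- function(x, ...) {
  cat(sprintf("AnnotationMap: %d genes, %d terms\n",
              length(x), length(attr(x, "terms"))))
  invisible(x)
}

#' Read a gene-to-GO-Slim TSV
#'
#' Two-column tab-separated file: gene id, term id; one pair per line.
#' A gene maps to the union of its terms.
#'
#' @param path TSV file path.
#' @return An [annotation_map()].
#' @export
read_gene2slim <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(annotation_map(structure(list(), names = character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("malformed gene2slim line %d: expected exactly 2 tab-separated columns",
                 bad[1]))
  m <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  annotation_map(split(m[, 2], m[, 1]))
}

#' Write a gene-to-term map as TSV
#' @param map an [annotation_map()].
#' @param path output path.
#' @export
write_gene2slim <- function(map, path) {
  genes <- sort_ids(names(map))
  lines <- unlist(lapply(genes, function(g) paste(g, map[[g]], sep = "\t")),
                  use.names = FALSE)
  writeLines(lines %||% character(0), path)
  invisible(path)
}

# ---- OBO / GAF derivation ---------------------------------------------------

# Minimal OBO 1.2 term parser: [Term] stanzas, id / is_a / relationship:
# part_of; obsolete terms skipped.  Returns named list term -> parent terms.
parse_obo_parents <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  parents <- list()
  id <- NULL; par <- character(0); in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (in_term && !obsolete && !is.null(id))
      parents[[id]] <<- unique(par)
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)      # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); in_term <- TRUE; id <- NULL; par <- character(0); obsolete <- FALSE
    } else if (startsWith(ln, "[")) {
      flush(); in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        par <- c(par, trimws(sub("^is_a:", "", ln)))
      } else if (startsWith(ln, "relationship:")) {
        rel <- strsplit(trimws(sub("^relationship:", "", ln)), "[[:space:]]+")[[1]]
        if (length(rel) >= 2 && rel[1] == "part_of") par <- c(par, rel[2])
      } else if (startsWith(ln, "is_obsolete:") &&
                 grepl("true", ln, fixed = TRUE)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  parents
}

# transitive ancestors (including the term itself) via is_a/part_of
obo_ancestors <- function(term, parents, memo) {
  if (!is.null(memo[[term]])) return(memo[[term]])
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        seen)
  }
  memo[[term]] <- unique(seen)
  memo[[term]]
}

# GAF 2.x: comment lines start with '!'; column 2 = DB object id,
# column 4 = qualifier, column 5 = GO id.
parse_gaf <- function(path, gene_col = 2L) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines))
    return(data.frame(gene = character(0), term = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5L)
  if (length(bad))
    stop(sprintf("malformed GAF line %d: fewer than 5 tab-separated columns",
                 bad[1]))
  gene <- vapply(fields, `[[`, "", gene_col)
  qual <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  data.frame(gene = gene[keep], term = term[keep])
}

#' Derive a gene-to-GO-Slim map from a GAF annotation file and an OBO ontology
#'
#' Each gene maps to the slim terms reachable from its annotated GO terms by
#' upward closure over `is_a` and `part_of` (a term is an ancestor of
#' itself), intersected with `slim_terms`.  Annotated terms absent from the
#' ontology raise a warning and are skipped.  The precomputed two-column
#' gene-to-slim TSV ([read_gene2slim()]) is the canonical input for the
#' clustering machinery; this derivation is a convenience.
#'
#' @param gaf path to a GAF 2.x annotation file (rows with a `NOT` qualifier
#'   are skipped).
#' @param obo path to an OBO 1.2 ontology file.
#' @param slim_terms character vector of slim term ids.
#' @param gene_col GAF column used as the gene identifier (default 2, the DB
#'   object id; use 3 for symbols).
#' @return An [annotation_map()].
#' @export
slim_from_ontology <- function(gaf, obo, slim_terms, gene_col = 2L) {
  parents <- parse_obo_parents(obo)
  ann <- parse_gaf(gaf, gene_col = gene_col)
  known <- ann$term %in% names(parents)
  if (any(!known)) {
    warning(sum(!known), " annotation term(s) absent from the ontology; skipped: ",
            paste(head(unique(ann$term[!known]), 5), collapse = ", "))
    ann <- ann[known, , drop = FALSE]
  }
  memo <- new.env(parent = emptyenv())
  term_slim <- lapply(unique(ann$term), function(t)
    intersect(obo_ancestors(t, parents, memo), slim_terms))
  names(term_slim) <- unique(ann$term)
  by_gene <- split(ann$term, ann$gene)
  annotation_map(lapply(by_gene, function(ts)
    unique(unlist(term_slim[unique(ts)], use.names = FALSE))))
}
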