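#' Construct a pathway database
#'
#' A pathway database is an ordered collection of pathways, each reduced to
#' its gene membership: an id, a display name, a source label (typically the
#' database of origin) and a set of gene identifiers.  Reducing pathways to
#' gene sets is deliberately the simplest common representation when merging
#' heterogeneous sources; topology, direction and stoichiometry are dropped.
#'
#' Ordering is stable: database order equals construction (file) order, and
#' all downstream tie-breaks refer to this order plus byte-lexicographic id.
#'
#' @param ids character vector of unique pathway ids.
#' @param genes list of character vectors, one per pathway; duplicate gene
#'   tokens within a pathway are collapsed.  Empty gene sets are permitted
#'   (see [remove_empty()]).
#' @param names display names; defaults to `ids`.
#' @param sources source labels, recycled if length 1.
#' @param provenance free-text metadata carried along unmodified.
#' @return An object of class `PathwayDatabase` with fields `ids`, `names`,
#'   `sources`, `genes` (named list) and `provenance`.
#' @examples
#' db <- pathway_db(c("P1", "P2"), list(c("A", "B"), c("B", "C")))
#' db
#' @export
pathway_db <- function(ids, genes, names = ids, sources = "unknown",
                       provenance = "") {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(genes) != length(ids))
    stop("`genes` must have one element per pathway id")
  if (length(sources) == 1L) sources <- rep(sources, length(ids))
  stopifnot(length(names) == length(ids), length(sources) == length(ids))
  genes <- lapply(genes, function(g) sort_ids(unique(as.character(g))))
  names(genes) <- ids
  structure(list(ids = ids, names = as.character(names),
                 sources = as.character(sources), genes = genes,
                 provenance = provenance),
            class = "PathwayDatabase")
}

#' @export
print.PathwayDatabase <- function(x, ...) {
  sz <- lengths(x$genes)
  cat(sprintf("PathwayDatabase: %d pathways, %d distinct genes\n",
              length(x$ids), length(unique(unlist(x$genes, use.names = FALSE)))))
  if (length(sz))
    cat(sprintf("  gene-set sizes: min %d, median %g, max %d; %d empty\n",
                min(sz), stats::median(sz), max(sz), sum(sz == 0L)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.PathwayDatabase <- function(x) length(x$ids)

#' Number of pathways in a database
#' @param db a [pathway_db()].
#' @return Integer count.
#' @export
n_pathways <- function(db) length(db$ids)

db_all_genes <- function(db) {
  sort_ids(unique(unlist(db$genes, use.names = FALSE)))
}

db_subset <- function(db, ids) {
  keep <- match(ids, db$ids)
  pathway_db(db$ids[keep], db$genes[keep], db$names[keep], db$sources[keep],
             db$provenance)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one pathway per line; tab-separated fields `name`, `source`,
#' then zero or more gene identifiers.  Field 1 is used as both id and name,
#' field 2 as the source label.  Duplicate gene tokens within a line are
#' collapsed; empty gene columns are allowed, so pathways with zero genes are
#' representable at read time (filter them with [remove_empty()]).
#'
#' @param path GMT file path.
#' @param provenance optional provenance string; defaults to the path.
#' @return A [pathway_db()] in file order.
#' @export
read_gmt <- function(path, provenance = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(pathway_db(character(0), list(),
                      provenance = provenance %||% path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 2 tab-separated fields",
                 lineno[bad[1]]))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sources <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  })
  pathway_db(ids, genes, sources = sources,
             provenance = provenance %||% path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pathway database as GMT
#'
#' Emits one line per pathway (id, source, genes) with genes sorted
#' lexicographically, so output is bit-identical for databases with the same
#' gene-set content regardless of the gene order they were built with.
#'
#' @param db a [pathway_db()].
#' @param path output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(seq_along(db$ids), function(i) {
    paste(c(db$ids[i], db$sources[i], db$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Drop pathways with no gene members
#'
#' Merged multi-source collections routinely contain pathways whose members
#' could not be mapped to the canonical identifier space, leaving empty sets
#' that no enrichment or similarity computation can use.
#'
#' @param db a [pathway_db()].
#' @return The database restricted to pathways with at least one gene,
#'   original order preserved.
#' @export
remove_empty <- function(db) {
  keep <- lengths(db$genes) >= 1L
  pathway_db(db$ids[keep], db$genes[keep], db$names[keep], db$sources[keep],
             db$provenance)
}

gene_set_keys <- function(db) {
  vapply(db$genes, function(g) paste(g, collapse = "\r"), "")
}

#' Group pathways with exactly identical gene sets
#'
#' Finds all groups of two or more pathways whose gene memberships are exactly
#' equal.  Collapsing each group to a single representative gives the
#' consolidated pathway count `total - members_in_groups + n_groups`.
#'
#' @param db a [pathway_db()].
#' @return A list with `groups` (list of character id vectors, each of size
#'   >= 2, ordered by first appearance), `n_groups`, `n_grouped` (pathways
#'   belonging to any group) and `consolidated_count`.
#' @export
group_identical <- function(db) {
  keys <- gene_set_keys(db)
  grp <- split(db$ids, factor(keys, levels = unique(keys)))
  grp <- unname(grp[lengths(grp) >= 2L])
  n_grouped <- sum(lengths(grp))
  list(groups = grp,
       n_groups = length(grp),
       n_grouped = n_grouped,
       consolidated_count = length(db$ids) - n_grouped + length(grp))
}

#' Find pathways contained in another pathway
#'
#' Returns the ids of every pathway whose gene set is a subset (proper or
#' equal) of at least one *other* pathway's gene set.  Two pathways with
#' identical gene sets therefore count each other as subsets.  Aggregated
#' collections mix general pathways with their specific sub-pathways, so this
#' containment structure is extensive in practice.
#'
#' Uses an inverted gene-to-pathway index so each pathway is only compared
#' against candidates containing all of its genes.
#'
#' @param db a [pathway_db()].
#' @return Character vector of pathway ids, in database order.
#' @export
find_subsets <- function(db) {
  n <- length(db$ids)
  if (n < 2L) return(character(0))
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (g in db$genes[[i]]) {
      assign(g, c(idx[[g]], i), envir = idx)
    }
  }
  is_sub <- logical(n)
  for (i in seq_len(n)) {
    gs <- db$genes[[i]]
    if (!length(gs)) {        # empty set is a subset of any other pathway
      is_sub[i] <- TRUE
      next
    }
    cand <- idx[[gs[1]]]
    for (g in gs[-1]) {
      if (length(cand) <= 1L) break
      cand <- intersect(cand, idx[[g]])
    }
    is_sub[i] <- any(cand != i)
  }
  db$ids[is_sub]
}

#' Merge same-named pathways across sources
#'
#' Optional pre-processing for source aggregation: pathways whose display
#' names match case-insensitively are combined into a single pathway whose
#' gene set is the union of the members.  The merged pathway keeps the id and
#' name of the first occurrence (file order) and concatenates the distinct
#' source labels with `+`.  This changes gene-set contents, so it is never
#' applied implicitly.
#'
#' @param db a [pathway_db()].
#' @return A [pathway_db()] with one pathway per distinct lower-cased name.
#' @export
merge_named_pathways <- function(db) {
  key <- tolower(db$names)
  first <- !duplicated(key)
  ids <- db$ids[first]
  nms <- db$names[first]
  genes <- vector("list", sum(first))
  sources <- character(sum(first))
  pos <- match(key, key[first])
  for (j in seq_along(ids)) {
    members <- which(pos == j)
    genes[[j]] <- unique(unlist(db$genes[members], use.names = FALSE))
    sources[j] <- paste(unique(db$sources[members]), collapse = "+")
  }
  pathway_db(ids, genes, nms, sources, db$provenance)
}
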