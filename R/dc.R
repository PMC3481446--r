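#' Attribute set of a pathway
#'
#' The de novo consolidation compares pathways through attribute sets built
#' from their gene members under one of three modes:
#'
#' * `membership`: the gene set itself;
#' * `goslim` ("guilt-by-function"): the union of the GO-Slim terms of the
#'   member genes -- a function vocabulary; gene ids themselves are excluded
#'   and genes with no slim terms contribute nothing;
#' * `ppi` ("guilt-by-association"): the member genes augmented with every
#'   gene known to interact with them; genes with no interactants contribute
#'   themselves.
#'
#' @param genes character vector, the pathway's gene set.
#' @param mode one of `"membership"`, `"goslim"`, `"ppi"`.
#' @param slim an [annotation_map()] (required for `goslim`).
#' @param net an [interaction_network()] (required for `ppi`).
#' @return Character vector of attribute identifiers (sorted, unique).
#' @examples
#' attribute_set(c("A", "B"), "membership")
#' @export
attribute_set <- function(genes, mode = c("membership", "goslim", "ppi"),
                          slim = NULL, net = NULL) {
  mode <- match.arg(mode)
  genes <- unique(as.character(genes))
  switch(mode,
    membership = sort_ids(genes),
    goslim = {
      if (is.null(slim)) stop("goslim mode requires a gene-to-slim annotation map")
      sort_ids(unique(unlist(unclass(slim)[intersect(genes, names(slim))],
                             use.names = FALSE)))
    },
    ppi = {
      if (is.null(net)) stop("ppi mode requires an interaction network")
      nb <- unlist(lapply(intersect(genes, net$nodes),
                          function(g) net_neighbors(net, g)),
                   use.names = FALSE)
      sort_ids(unique(c(genes, nb)))
    })
}

#' Attribute sets for every pathway in a database
#'
#' @param db a [pathway_db()].
#' @inheritParams attribute_set
#' @return Named list of attribute sets (names = pathway ids), with
#'   attribute `mode`.
#' @export
attribute_sets <- function(db, mode = c("membership", "goslim", "ppi"),
                           slim = NULL, net = NULL) {
  mode <- match.arg(mode)
  out <- lapply(db$genes, attribute_set, mode = mode, slim = slim, net = net)
  names(out) <- db$ids
  attr(out, "mode") <- mode
  out
}

#' Pairwise Jaccard distance matrix of attribute sets
#'
#' `J(A_i, A_j) = |A_i intersect A_j| / |A_i union A_j|` and
#' `d_ij = 1 - J`.  Two empty sets are defined to have `J = 0` (`d = 1`):
#' pathways with no attributes carry no evidence of relatedness.  The
#' diagonal is 0 by convention.
#'
#' Computed through a sparse attribute-by-pathway incidence matrix
#' cross-product, so it scales to thousands of pathways.
#'
#' @param sets named list of attribute sets (e.g. from [attribute_sets()]).
#' @return An object of class `DistanceMatrix`: list with `ids`, `dist`
#'   (symmetric matrix of Jaccard distances with dimnames) and `mode`.
#' @export
jaccard_matrix <- function(sets) {
  ids <- names(sets)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(sets)
  attrs <- unique(unlist(sets, use.names = FALSE))
  if (length(attrs) && n) {
    i <- match(unlist(sets, use.names = FALSE), attrs)
    j <- rep(seq_len(n), lengths(sets))
    inc <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                dims = c(length(attrs), n))
    inter <- as.matrix(Matrix::crossprod(inc))
  } else {
    inter <- matrix(0, n, n)
  }
  sz <- lengths(sets)
  uni <- outer(sz, sz, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  d <- 1 - J
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, dist = d, mode = attr(sets, "mode") %||% "custom"),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix [%s]: %d pathways\n", x$mode, length(x$ids)))
  invisible(x)
}

#' Hierarchical de novo clustering of pathways
#'
#' Agglomerative hierarchical clustering (single linkage by default;
#' `average` and `complete` selectable) on a Jaccard [jaccard_matrix()]
#' distance matrix, cut either to at most `n_clusters` clusters or at a
#' distance `cutoff` -- a horizontal cut of the dendrogram.  The cuts are
#' nested: the partition at `k` clusters refines the partition at `k - 1`.
#'
#' This consolidation uses all gene members and no resultant set, so it can
#' be precomputed once per database, independent of any experiment
#' ([precompute_denovo()]).
#'
#' @param dm a [jaccard_matrix()].
#' @param n_clusters requested maximum number of clusters (capped at the
#'   number of pathways).  Exactly one of `n_clusters` and `cutoff` must be
#'   given.
#' @param cutoff distance threshold in `[0, 1]`; merges at distance up to
#'   the cutoff are applied.  Lower cutoffs never increase the cluster
#'   count.
#' @param linkage linkage criterion for [stats::hclust()].
#' @param enrichment optional [enrich_all()] table; when supplied, each
#'   concept's representative is its most enriched member and its score the
#'   lowest member p-value; otherwise the representative is the
#'   byte-lexicographically first member and the score is `NA`.
#' @param method_label label stored on the clustering; default
#'   `"<mode><k>"` or `"<mode>@<cutoff>"`.
#' @return A [pathway_clustering()] covering every pathway (no unassigned).
#' @export
cluster_pathways <- function(dm, n_clusters = NULL, cutoff = NULL,
                             linkage = c("single", "average", "complete"),
                             enrichment = NULL, method_label = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(dm, "DistanceMatrix"))
  if (is.null(n_clusters) == is.null(cutoff))
    stop("give exactly one of `n_clusters` and `cutoff`")
  n <- length(dm$ids)
  if (n == 0L)
    return(pathway_clustering(method_label %||% dm$mode, list()))
  if (!is.null(n_clusters)) {
    if (n_clusters < 1L) stop("n_clusters must be >= 1")
    k <- min(as.integer(n_clusters), n)
  } else if (cutoff < 0 || cutoff > 1) {
    stop("cutoff must be in [0, 1]")
  }
  if (n == 1L) {
    memb <- structure(1L, names = dm$ids)
  } else {
    hc <- hclust(as.dist(dm$dist), method = linkage)
    memb <- if (!is.null(n_clusters)) cutree(hc, k = k)
            else cutree(hc, h = cutoff)
    names(memb) <- dm$ids
  }
  if (is.null(method_label))
    method_label <- if (!is.null(n_clusters)) paste0(dm$mode, n_clusters)
                    else sprintf("%s@%g", dm$mode, cutoff)
  pathway_clustering(method_label,
                     concepts_from_membership(memb, enrichment),
                     mode = dm$mode,
                     n_clusters = if (!is.null(n_clusters)) n_clusters else NA,
                     cutoff = if (!is.null(cutoff)) cutoff else NA)
}

#' Precompute the de novo clustering menu
#'
#' Runs [cluster_pathways()] for every attribute mode crossed with a menu of
#' cluster-count thresholds (default 5, 10, 20, 40, 50, 100, 200 and 500,
#' giving fine-tuned control from coarse to specific concepts; counts are
#' capped at the number of pathways).  Being independent of any resultant
#' gene set, the full menu can be computed once per pathway collection and
#' reused across experiments.
#'
#' @param db a [pathway_db()].
#' @param slim an [annotation_map()] (needed for mode `goslim`).
#' @param net an [interaction_network()] (needed for mode `ppi`).
#' @param cutoffs integer vector of cluster-count thresholds.
#' @param modes attribute modes to include.
#' @param linkage linkage criterion.
#' @return Named list of [pathway_clustering()] objects, names
#'   `"<mode><count>"` (e.g. `"goslim10"`); `length(modes) * length(cutoffs)`
#'   entries.
#' @export
precompute_denovo <- function(db, slim = NULL, net = NULL,
                              cutoffs = c(5, 10, 20, 40, 50, 100, 200, 500),
                              modes = c("membership", "goslim", "ppi"),
                              linkage = "single") {
  out <- list()
  for (mode in modes) {
    dm <- jaccard_matrix(attribute_sets(db, mode, slim = slim, net = net))
    for (k in cutoffs) {
      out[[paste0(mode, k)]] <-
        cluster_pathways(dm, n_clusters = k, linkage = linkage)
    }
  }
  out
}

#' Serialize de novo clusterings as a long TSV
#'
#' Columns: `pathway_id`, `mode`, `cutoff`, `cluster_id`.
#'
#' @param clusterings named list from [precompute_denovo()] (or a single
#'   [pathway_clustering()]).
#' @param path output path.
#' @export
write_denovo <- function(clusterings, path) {
  if (inherits(clusterings, "PathwayClustering"))
    clusterings <- list(clusterings)
  rows <- lapply(clusterings, function(cl) {
    m <- concept_membership(cl)
    data.frame(pathway_id = names(m),
               mode = cl$mode %||% cl$method,
               cutoff = cl$n_clusters %||% NA,
               cluster_id = as.integer(m))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
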