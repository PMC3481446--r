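#' Interaction weight of a gene within a pathway
#'
#' Under no specific functional association, the number of interactions `X`
#' between a gene and the other members of a pathway follows a
#' hypergeometric distribution with expectation `E(X) = M * K / N`, where
#' `M` is the gene's interaction degree in the genome, `K` the pathway size
#' and `N` the genome size.  The excess `w = X - E(X)` is rescaled to the
#' relative association strength
#' `W = log2(w + 2)` when `w > 0` and `W = 1` otherwise, so `W >= 1` always.
#'
#' Genes absent from the network get `M = 0`, `X = 0`.
#'
#' @param gene a gene id; must be a member of `pathway_genes`.
#' @param pathway_genes character vector, the pathway's gene set.
#' @param net an [interaction_network()].
#' @param n_genome genome size `N`; defaults to the network universe size.
#' @return A one-row data frame with columns `gene`, `X`, `M`, `K`, `E`,
#'   `w`, `W`.
#' @examples
#' net <- interaction_network(cbind("A", "B"), universe = c("A", "B", "C", "D"))
#' gene_pathway_weight("A", c("A", "B", "C"), net)
#' @export
gene_pathway_weight <- function(gene, pathway_genes, net,
                                n_genome = net$n_genome) {
  pathway_genes <- unique(as.character(pathway_genes))
  if (!gene %in% pathway_genes)
    stop("gene ", gene, " is not a member of the pathway")
  K <- length(pathway_genes)
  M <- net_degree(net, gene)
  X <- length(intersect(net_neighbors(net, gene),
                        setdiff(pathway_genes, gene)))
  E <- M * K / n_genome
  w <- X - E
  data.frame(gene = gene, X = X, M = M, K = K, E = E, w = w,
             W = rescale_weight(w))
}

rescale_weight <- function(w) ifelse(w > 0, log2(w + 2), 1)

#' Per-(gene, pathway) interaction weight table
#'
#' Computes [gene_pathway_weight()] entries for every incidence of the given
#' genes in the database's pathways.  The table can be dumped as TSV for
#' diagnostics and is the input of [pair_similarity()].
#'
#' @param db a [pathway_db()].
#' @param net an [interaction_network()].
#' @param genes optional restriction: only incidences of these genes are
#'   tabulated (the similarity score only needs resultant genes).  Default:
#'   all pathway genes.
#' @param n_genome genome size `N`; default: union of the network universe
#'   and all database genes (plus `genes`), the smallest universe for which
#'   the expectation is well-posed everywhere it is used.
#' @return Data frame with columns `gene`, `pathway`, `X`, `M`, `K`, `E`,
#'   `w`, `W`.
#' @export
wc_weight_table <- function(db, net, genes = NULL, n_genome = NULL) {
  if (is.null(n_genome))
    n_genome <- length(unique(c(net$universe, db_all_genes(db),
                                as.character(genes %||% character(0)))))
  adj <- net_adj_list(net)
  deg <- lengths(adj)
  rows <- lapply(seq_along(db$ids), function(i) {
    pg <- db$genes[[i]]
    gg <- if (is.null(genes)) pg else intersect(pg, as.character(genes))
    if (!length(gg)) return(NULL)
    K <- length(pg)
    M <- ifelse(gg %in% names(deg), deg[gg], 0L)
    X <- vapply(gg, function(g) {
      nb <- adj[[g]]
      if (is.null(nb)) 0L else length(intersect(nb, setdiff(pg, g)))
    }, 0L)
    E <- M * K / n_genome
    w <- X - E
    data.frame(gene = gg, pathway = db$ids[i], X = as.integer(X),
               M = as.integer(M), K = K, E = E, w = w, W = rescale_weight(w),
               row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene = character(0), pathway = character(0),
                      X = integer(0), M = integer(0), K = integer(0),
                      E = numeric(0), w = numeric(0), W = numeric(0)))
  out <- do.call(rbind, rows)
  attr(out, "n_genome") <- n_genome
  out
}

#' Similarity of a pathway pair over resultant genes
#'
#' Weighted overlap proportion confined to the resultant gene set: the
#' numerator sums, for each resultant gene in *both* pathways, the mean of
#' its two pathway-specific rescaled weights `W`; the denominator adds, for
#' each resultant gene in exactly one pathway, that pathway's `W`.  Since
#' every `W >= 1`, the score lies in `[0, 1]`, is symmetric, equals 1 when
#' the two pathways contain the same resultant genes, and reduces to the
#' Jaccard index of the resultant-gene overlaps when all weights are equal.
#' Pairs sharing no resultant gene score 0, as do pairs where neither
#' pathway contains a resultant gene.
#'
#' @param db a [pathway_db()].
#' @param id_i,id_j pathway ids.
#' @param resultant resultant [gene_set()] or character vector.
#' @param weights a [wc_weight_table()] covering the resultant-gene
#'   incidences of both pathways.
#' @return Similarity in `[0, 1]`.
#' @export
pair_similarity <- function(db, id_i, id_j, resultant, weights) {
  resultant <- as_gene_set(resultant, "resultant")
  Wi <- weight_lookup(weights, id_i, db, resultant$genes)
  Wj <- weight_lookup(weights, id_j, db, resultant$genes)
  pair_similarity_w(Wi, Wj)
}

weight_lookup <- function(weights, id, db, D) {
  gg <- intersect(db$genes[[id]], D)
  w <- weights$W[weights$pathway == id][match(gg, weights$gene[weights$pathway == id])]
  if (anyNA(w)) stop("weight table does not cover pathway ", id)
  names(w) <- gg
  w
}

# core of the similarity score: Wi, Wj are named weight vectors over each
# pathway's resultant genes
pair_similarity_w <- function(Wi, Wj) {
  shared <- intersect(names(Wi), names(Wj))
  num <- sum((Wi[shared] + Wj[shared]) / 2)
  den <- num + sum(Wi[setdiff(names(Wi), shared)]) +
    sum(Wj[setdiff(names(Wj), shared)])
  if (den == 0) 0 else num / den
}

#' Weighted Consolidation (greedy clustering of scored pathway pairs)
#'
#' Clusters all pathways containing at least one resultant gene -- enriched
#' or not -- using interaction-weighted overlap of resultant genes.  Every
#' unordered pathway pair is scored with [pair_similarity()]; pairs are then
#' visited in descending similarity (ties broken by byte-lexicographic pair
#' id), skipping pairs with similarity 0, and greedily merged:
#'
#' * neither pathway clustered: open a new cluster with the pair;
#' * exactly one clustered: add the other to its partner's cluster;
#' * both clustered: do nothing.
#'
#' Every concept therefore has at least 2 members; pathways never touched by
#' a positive-similarity pair remain unassigned singletons.
#'
#' @param db a [pathway_db()]; internally restricted to pathways with at
#'   least one resultant gene.
#' @param resultant resultant [gene_set()] or character vector.
#' @param net an [interaction_network()] providing the weights.
#' @param background optional background [gene_set()] used only to compute
#'   concept scores/representatives via [enrich_all()].
#' @param n_genome genome size override (see [wc_weight_table()]).
#' @return A [pathway_clustering()] with method `"wc"`, concepts in creation
#'   order; each concept's representative is its most enriched member and
#'   its score the lowest member p-value.  Attributes `"weights"` (the
#'   weight table) and `"enrichment"` are attached.
#' @export
consolidate_weighted <- function(db, resultant, net, background = NULL,
                                 n_genome = NULL) {
  resultant <- as_gene_set(resultant, "resultant")
  keep <- vapply(db$genes, function(g) any(g %in% resultant$genes), TRUE)
  if (!any(keep)) {
    message("no pathway contains a resultant gene; empty clustering")
    return(pathway_clustering("wc", list(), unassigned = character(0)))
  }
  dbr <- db_subset(db, db$ids[keep])
  wt <- wc_weight_table(dbr, net, genes = resultant$genes,
                        n_genome = n_genome)
  Wlist <- lapply(split(seq_len(nrow(wt)), wt$pathway), function(ix)
    structure(wt$W[ix], names = wt$gene[ix]))
  dg <- lapply(Wlist, names)                 # resultant genes per pathway
  # candidate pairs: pathways sharing at least one resultant gene
  inv <- split(rep(names(dg), lengths(dg)), unlist(dg, use.names = FALSE))
  pairs <- unique(do.call(rbind, lapply(inv, function(ids) {
    if (length(ids) < 2L) return(NULL)
    ids <- sort_ids(ids)
    t(utils::combn(ids, 2L))
  })))
  if (is.null(pairs) || !nrow(pairs)) {
    cl <- pathway_clustering("wc", list(), unassigned = dbr$ids)
    attr(cl, "weights") <- wt
    return(cl)
  }
  sim <- vapply(seq_len(nrow(pairs)), function(r)
    pair_similarity_w(Wlist[[pairs[r, 1]]], Wlist[[pairs[r, 2]]]), 0)
  ord <- order_ids(-sim, pairs[, 1], pairs[, 2])
  cluster_of <- structure(rep(NA_integer_, length(dbr$ids)), names = dbr$ids)
  n_cl <- 0L
  for (r in ord) {
    if (sim[r] <= 0) break
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ci <- cluster_of[[i]]; cj <- cluster_of[[j]]
    if (is.na(ci) && is.na(cj)) {
      n_cl <- n_cl + 1L
      cluster_of[c(i, j)] <- n_cl
    } else if (is.na(cj)) {
      cluster_of[[j]] <- ci
    } else if (is.na(ci)) {
      cluster_of[[i]] <- cj
    }                                        # both clustered: do nothing
  }
  assigned <- !is.na(cluster_of)
  enr <- tryCatch(enrich_all(dbr, resultant, background),
                  error = function(e) NULL)
  membership <- cluster_of[assigned]
  ids <- names(membership)
  p <- rep(Inf, length(ids))
  if (!is.null(enr) && nrow(enr)) {
    m <- match(ids, enr$pathway_id)
    p[!is.na(m)] <- enr$p_value[m[!is.na(m)]]
  }
  names(p) <- ids
  membership <- factor(membership, levels = sort(unique(membership)))
  concepts <- lapply(split(ids, membership), function(mem) {
    mem <- mem[order_ids(p[mem], mem)]
    sc <- min(p[mem])
    list(representative = mem[1], members = mem,
         score = if (is.finite(sc)) sc else NA_real_)
  })
  cl <- pathway_clustering("wc", unname(concepts),
                           unassigned = names(cluster_of)[!assigned])
  attr(cl, "weights") <- wt
  attr(cl, "enrichment") <- enr
  cl
}
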