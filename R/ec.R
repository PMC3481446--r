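#' Enrichment Consolidation (iterative peel-off of enriched pathways)
#'
#' Consolidates the pathways significantly enriched for a resultant gene set
#' into pathway concepts by iterative gene removal.  Starting from the set of
#' enriched pathways, each round (i) selects the currently most enriched
#' pathway as a new concept representative, (ii) removes its genes from the
#' working resultant set and from the effective gene set of every remaining
#' pathway, (iii) recomputes the Fisher p-values on the reduced sets, and
#' (iv) absorbs into the new concept every pathway that is no longer
#' significant (including pathways whose effective overlap dropped to zero,
#' which can no longer be enriched).  The loop stops when no enriched pathway
#' remains; because each round removes at least the representative, it always
#' terminates within the initial number of enriched pathways.
#'
#' Because gene removal order is driven by the enrichment ranking of the
#' supplied resultant set, the consolidation is specific to that experiment.
#' Only initially enriched pathways are ever consolidated; all others are
#' reported as unassigned.
#'
#' The background universe is never reduced across iterations: recomputed
#' table margins use the reduced resultant set and reduced pathway sets but
#' the original background size, so later p-values stay comparable.
#'
#' @param db a [pathway_db()].
#' @param resultant resultant [gene_set()] (or character vector).
#' @param background optional background [gene_set()]; defaults as in
#'   [enrich_all()].
#' @param alpha significance threshold on the raw one-sided Fisher p-value
#'   (default 0.05); selection and absorption compare `p <= alpha` /
#'   `p > alpha` exactly.
#' @return A [pathway_clustering()] with method `"ec"`.  Concepts appear in
#'   selection order; each concept's score is the lowest *original*
#'   enrichment p-value among its members and its representative is the
#'   pathway selected in step (i).  Pathways not enriched at `alpha`
#'   initially are in `$unassigned`.  The initial enrichment table is
#'   attached as attribute `"enrichment"`.
#' @examples
#' db <- pathway_db(c("P1", "P2"), list(c("A", "B", "C"), c("A", "B", "D")))
#' bg <- gene_set("bg", c(LETTERS, letters))
#' consolidate_enrichment(db, c("A", "B", "C"), bg)
#' @export
consolidate_enrichment <- function(db, resultant, background = NULL,
                                   alpha = 0.05) {
  resultant <- as_gene_set(resultant, "resultant")
  if (is.null(background)) background <- gene_set("background", db_all_genes(db))
  background <- as_gene_set(background, "background")
  res0 <- enrich_all(db, resultant, background)
  sig <- res0[res0$p_value <= alpha, , drop = FALSE]
  if (!nrow(sig)) {
    message("no pathway enriched at alpha = ", alpha, "; empty clustering")
    out <- pathway_clustering("ec", list(), unassigned = db$ids)
    attr(out, "enrichment") <- res0
    return(out)
  }
  bgg <- background$genes
  bg_size <- length(bgg)
  S <- sig$pathway_id
  orig_p <- structure(sig$p_value, names = S)
  eff <- lapply(db$genes[S], intersect, bgg)   # effective (reduced) gene sets
  D <- intersect(resultant$genes, bgg)
  p_cur <- orig_p
  ov_cur <- structure(sig$overlap, names = S)
  concepts <- list()
  while (length(S)) {
    pick <- S[order_ids(p_cur[S], -ov_cur[S], S)][1]
    members <- pick
    g_rep <- eff[[pick]]
    S <- setdiff(S, pick)
    D <- setdiff(D, g_rep)
    if (length(S)) {
      eff[S] <- lapply(eff[S], setdiff, g_rep)
      rs <- length(D)
      K <- lengths(eff[S])
      ov <- vapply(eff[S], function(g) length(intersect(g, D)), 0L)
      p <- fisher_p(ov, K, rs, bg_size)
      names(p) <- S; names(ov) <- S
      absorb <- S[ov == 0L | p > alpha]
      members <- c(pick, absorb)
      S <- setdiff(S, absorb)
      p_cur[S] <- p[S]
      ov_cur[S] <- ov[S]
    }
    concepts[[length(concepts) + 1L]] <-
      list(representative = pick, members = members,
           score = min(orig_p[members]),
           selection_p = unname(p_cur[pick]))
  }
  out <- pathway_clustering("ec", concepts,
                            unassigned = setdiff(db$ids, sig$pathway_id))
  attr(out, "enrichment") <- res0
  out
}
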