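#' Pathway concept clusterings
#'
#' All three consolidation methods return the same container: a list of
#' *pathway concepts* -- disjoint groups of pathways, each labelled by a
#' representative (the most enriched member when enrichment information is
#' available) and scored by the lowest enrichment p-value among its members
#' -- plus the ids left unassigned by the method.
#'
#' @param method method label (e.g. `"ec"`, `"wc"`, `"membership100"`).
#' @param concepts list of concepts; each a list with `representative`
#'   (pathway id), `members` (character vector including the representative)
#'   and `score` (lowest member enrichment p-value, or `NA`).
#' @param unassigned pathway ids in no concept.
#' @param ... extra fields stored on the object (e.g. `mode`, `cutoff`).
#' @return An object of class `PathwayClustering`.
#' @export
pathway_clustering <- function(method, concepts, unassigned = character(0), ...) {
  for (cc in concepts) {
    stopifnot(cc$representative %in% cc$members, length(cc$members) >= 1L)
  }
  members <- unlist(lapply(concepts, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(members))
    stop("concepts are not disjoint")
  structure(list(method = method, concepts = concepts,
                 unassigned = unassigned, ...),
            class = "PathwayClustering")
}

#' @export
print.PathwayClustering <- function(x, ...) {
  sz <- vapply(x$concepts, function(cc) length(cc$members), 0L)
  cat(sprintf("PathwayClustering [%s]: %d concept(s), %d unassigned pathway(s)\n",
              x$method, length(x$concepts), length(x$unassigned)))
  if (length(sz))
    cat(sprintf("  concept sizes: min %d, max %d\n", min(sz), max(sz)))
  invisible(x)
}

#' Number of concepts in a clustering
#' @param cl a [pathway_clustering()].
#' @return Integer count.
#' @export
n_concepts <- function(cl) length(cl$concepts)

#' Concept membership as a named vector
#' @param cl a [pathway_clustering()].
#' @return Named integer vector mapping pathway id to concept rank;
#'   unassigned pathways are absent.
#' @export
concept_membership <- function(cl) {
  if (!length(cl$concepts)) return(structure(integer(0), names = character(0)))
  m <- rep(seq_along(cl$concepts),
           vapply(cl$concepts, function(cc) length(cc$members), 0L))
  names(m) <- unlist(lapply(cl$concepts, `[[`, "members"), use.names = FALSE)
  m
}

#' @export
as.data.frame.PathwayClustering <- function(x, ...) {
  if (!length(x$concepts)) {
    return(data.frame(concept_rank = integer(0), representative_id = character(0),
                      score = numeric(0), member_count = integer(0),
                      members = character(0)))
  }
  data.frame(
    concept_rank = seq_along(x$concepts),
    representative_id = vapply(x$concepts, `[[`, "", "representative"),
    score = vapply(x$concepts, function(cc) as.numeric(cc$score %||% NA_real_), 0),
    member_count = vapply(x$concepts, function(cc) length(cc$members), 0L),
    members = vapply(x$concepts, function(cc)
      paste(cc$members, collapse = ";"), "")
  )
}

#' Write a clustering as the shared concept TSV
#'
#' Columns: `concept_rank`, `representative_id`, `score`, `member_count`,
#' `members` (semicolon-joined ids).  The schema is identical across the
#' three consolidation methods.
#'
#' @param cl a [pathway_clustering()].
#' @param path output path.
#' @export
write_clustering <- function(cl, path) {
  utils::write.table(as.data.frame(cl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# shared helper: build concepts from a membership (cluster id per pathway id),
# choosing representative & score from an enrichment table when available.
concepts_from_membership <- function(membership, enrichment = NULL) {
  ids <- names(membership)
  p <- rep(Inf, length(ids))
  if (!is.null(enrichment) && nrow(enrichment)) {
    m <- match(ids, enrichment$pathway_id)
    p[!is.na(m)] <- enrichment$p_value[m[!is.na(m)]]
  }
  names(p) <- ids
  concepts <- lapply(split(ids, membership), function(mem) {
    mem <- mem[order_ids(p[mem], mem)]
    sc <- min(p[mem])
    list(representative = mem[1], members = mem,
         score = if (is.finite(sc)) sc else NA_real_)
  })
  # deterministic concept order: score ascending, then representative id
  sc <- vapply(concepts, function(cc) cc$score %||% NA_real_, 0)
  rep_id <- vapply(concepts, `[[`, "", "representative")
  unname(concepts[order_ids(ifelse(is.na(sc), Inf, sc), rep_id)])
}
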