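#' Interaction-density randomization test for a pathway concept
#'
#' Assesses whether the genes collected in a pathway concept interact with
#' each other more than expected by chance: the observed number of network
#' edges with both endpoints in the concept's gene union is compared with
#' the edge counts of repeated uniform draws (without replacement) of the
#' same number of genes from the network universe.
#'
#' Two p-values are reported.  The add-one empirical p-value
#' `(1 + #draws >= observed) / (1 + reps)` is an honest resampling bound
#' that can never reach 0 (its floor is `1 / (reps + 1)`).  Because strongly
#' interacting concepts sit far outside anything a finite number of draws
#' can represent, a normal-tail approximation from the null mean and
#' standard deviation is reported alongside; it is clamped below at 1e-150
#' and printed as `< 1e-150` beyond that.
#'
#' @param concept a concept (list with `members`), a [pathway_clustering()]
#'   concept entry, or a character vector of pathway ids.  The tested gene
#'   set is the union of the member pathways' genes.
#' @param db the [pathway_db()] the members refer to.
#' @param net an [interaction_network()]; draws are taken from its node set
#'   (the genome).
#' @param reps number of random draws (default 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @param concept_id label for reporting; defaults to the concept
#'   representative or first member.
#' @return An object of class `RandomizationResult`: list with
#'   `concept_id`, `n_genes`, `observed_interactions`, `null_draws`,
#'   `null_mean`, `null_sd`, `empirical_p`, `z_score`, `normal_approx_p`,
#'   `seed`.
#' @export
interaction_randomization_test <- function(concept, db, net, reps = 1000L,
                                           seed = 1L, concept_id = NULL) {
  stopifnot(reps >= 1L)
  members <- if (is.character(concept)) concept else concept$members
  if (is.null(members)) stop("cannot extract member pathway ids from `concept`")
  missing_ids <- setdiff(members, db$ids)
  if (length(missing_ids))
    stop("member pathway(s) not in database: ",
         paste(missing_ids, collapse = ", "))
  if (is.null(concept_id))
    concept_id <- if (!is.character(concept) && !is.null(concept$representative))
      concept$representative else members[1]
  u <- unique(unlist(db$genes[members], use.names = FALSE))
  n_genes <- length(u)
  nn <- length(net$nodes)
  if (n_genes > nn)
    stop("concept gene union (", n_genes, ") exceeds the network universe (",
         nn, ")")
  em <- igraph::as_edgelist(net$graph)
  e1 <- match(em[, 1], net$nodes)
  e2 <- match(em[, 2], net$nodes)
  memb <- logical(nn)
  memb[match(intersect(u, net$nodes), net$nodes)] <- TRUE
  observed <- sum(memb[e1] & memb[e2])
  set.seed(seed)
  counts <- vapply(seq_len(reps), function(r) {
    s <- logical(nn)
    s[sample.int(nn, n_genes)] <- TRUE
    sum(s[e1] & s[e2])
  }, 0L)
  mu <- mean(counts)
  sdv <- sd(counts)
  if (reps == 1L) sdv <- 0
  emp <- (1 + sum(counts >= observed)) / (1 + reps)
  if (is.na(sdv) || sdv == 0) {
    z <- if (observed > mu) Inf else -Inf
    np <- if (observed <= mu) 1 else 0
  } else {
    z <- (observed - mu) / sdv
    np <- pnorm(z, lower.tail = FALSE)
  }
  np <- max(np, 1e-150)
  structure(list(concept_id = concept_id, n_genes = n_genes,
                 observed_interactions = observed, null_draws = reps,
                 null_mean = mu, null_sd = sdv, empirical_p = emp,
                 z_score = z, normal_approx_p = np, seed = seed),
            class = "RandomizationResult")
}

format_normal_p <- function(p) {
  if (p <= 1e-150) "< 1e-150" else format(p, digits = 4)
}

#' @export
print.RandomizationResult <- function(x, ...) {
  cat(sprintf(
    "RandomizationResult '%s': %d genes, %d observed interactions\n",
    x$concept_id, x$n_genes, x$observed_interactions))
  cat(sprintf("  null (n = %d draws): mean %.2f, sd %.2f\n",
              x$null_draws, x$null_mean, x$null_sd))
  cat(sprintf("  empirical p = %.4g, z = %.2f, normal-approx p = %s\n",
              x$empirical_p, x$z_score, format_normal_p(x$normal_approx_p)))
  invisible(x)
}

#' Randomization test for every concept of a clustering
#'
#' @param cl a [pathway_clustering()].
#' @inheritParams interaction_randomization_test
#' @return List of `RandomizationResult`, one per concept.
#' @export
randomize_clustering <- function(cl, db, net, reps = 1000L, seed = 1L) {
  lapply(seq_along(cl$concepts), function(i)
    interaction_randomization_test(cl$concepts[[i]], db, net, reps = reps,
                                   seed = seed + i - 1L))
}

#' Write randomization results as TSV
#'
#' Columns: `concept_id`, `n_genes`, `observed`, `null_mean`, `null_sd`,
#' `empirical_p`, `normal_approx_p`; the seed is recorded in a header
#' comment.
#'
#' @param results a `RandomizationResult` or list of them.
#' @param path output path.
#' @export
write_randomization <- function(results, path) {
  if (inherits(results, "RandomizationResult")) results <- list(results)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d reps=%d", results[[1]]$seed,
                     results[[1]]$null_draws), con)
  writeLines(paste(c("concept_id", "n_genes", "observed", "null_mean",
                     "null_sd", "empirical_p", "normal_approx_p"),
                   collapse = "\t"), con)
  for (x in results) {
    writeLines(paste(c(x$concept_id, x$n_genes, x$observed_interactions,
                       format(x$null_mean, digits = 6),
                       format(x$null_sd, digits = 6),
                       format(x$empirical_p, digits = 6),
                       format_normal_p(x$normal_approx_p)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
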