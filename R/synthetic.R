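#' Simulation configuration for synthetic pathway benchmarks
#'
#' Describes a synthetic multi-source pathway collection with planted
#' concept structure: disjoint gene *pools* play the role of true pathway
#' concepts; each pathway samples a random fraction of its pool plus a few
#' noise genes, which reproduces the redundancy of aggregated databases
#' (heavily overlapping pathways, near-subsets); exact duplicates and strict
#' subsets can additionally be injected at configured counts.  The
#' interaction network has elevated edge density within pools
#' (`p_in`) versus between (`p_out`); each pool carries pool-specific
#' annotation terms; and the resultant gene set favours the genes of the
#' `enriched_pools`.
#'
#' @param seed integer seed (mandatory); the generator is fully
#'   deterministic given the seed.
#' @param n_genes genome size.
#' @param n_pools number of planted concepts.
#' @param pathways_per_pool pathways sampled per pool.
#' @param pool_size genes per pool (`n_pools * pool_size <= n_genes`).
#' @param subset_fraction length-2 range; each pathway samples a uniform
#'   fraction of its pool in this range.
#' @param noise_genes off-pool genes added to each pathway.
#' @param p_in,p_out within- / between-pool edge probabilities.
#' @param n_slim_terms annotation terms per pool.
#' @param enriched_pools integer indices of pools favoured by the resultant
#'   set; default: the first two pools (or the single pool when
#'   `n_pools = 1`).
#' @param resultant_hit_rate,background_rate inclusion probability of
#'   enriched-pool genes / all other genes in the resultant set.
#' @param n_empty empty pathways appended (no gene members).
#' @param duplicate_group_sizes integer vector; for each entry `g >= 2` a
#'   distinct base pathway is copied `g - 1` times, planting an
#'   identical-set group of exactly `g` pathways.
#' @param n_subset_pairs strict-subset pathways injected (each a proper
#'   subset of a distinct base pathway).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 1000L, n_pools = 5L,
                       pathways_per_pool = 4L, pool_size = 30L,
                       subset_fraction = c(0.5, 0.9), noise_genes = 2L,
                       p_in = 0.3, p_out = 0.005, n_slim_terms = 3L,
                       enriched_pools = NULL,
                       resultant_hit_rate = 0.6, background_rate = 0.02,
                       n_empty = 0L, duplicate_group_sizes = integer(0),
                       n_subset_pairs = 0L) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (is.null(enriched_pools))
    enriched_pools <- seq_len(min(2L, as.integer(n_pools)))
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_pools = as.integer(n_pools),
              pathways_per_pool = as.integer(pathways_per_pool),
              pool_size = as.integer(pool_size),
              subset_fraction = as.numeric(subset_fraction),
              noise_genes = as.integer(noise_genes),
              p_in = p_in, p_out = p_out,
              n_slim_terms = as.integer(n_slim_terms),
              enriched_pools = as.integer(enriched_pools),
              resultant_hit_rate = resultant_hit_rate,
              background_rate = background_rate,
              n_empty = as.integer(n_empty),
              duplicate_group_sizes = as.integer(duplicate_group_sizes),
              n_subset_pairs = as.integer(n_subset_pairs))
  probs <- c(cfg$p_in, cfg$p_out, cfg$resultant_hit_rate, cfg$background_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (length(cfg$subset_fraction) != 2L ||
      any(cfg$subset_fraction < 0 | cfg$subset_fraction > 1) ||
      diff(cfg$subset_fraction) < 0)
    stop("subset_fraction must be an increasing pair in [0, 1]")
  if (cfg$n_pools * cfg$pool_size > cfg$n_genes)
    stop("pool_size * n_pools exceeds n_genes")
  if (any(cfg$enriched_pools < 1L | cfg$enriched_pools > cfg$n_pools))
    stop("enriched_pools out of range")
  if (any(cfg$duplicate_group_sizes < 2L))
    stop("duplicate group sizes must be >= 2")
  if (length(cfg$duplicate_group_sizes) >
      cfg$n_pools * cfg$pathways_per_pool)
    stop("more duplicate groups than base pathways")
  structure(cfg, class = "sim_config")
}

# one sub-seed per generator component, derived deterministically from the
# master seed, so changing one component's parameters never perturbs the
# draws of the others
sim_substreams <- function(seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 4L)
}

#' Simulate a pathway database with planted concept structure
#'
#' See [sim_config()] for the generative model.  Pathway ids are `P<k>`;
#' injected subsets append `s<i>`, duplicates `d<i>`, empty pathways use
#' `E<i>`.  All base and subset pathways are guaranteed to have pairwise
#' distinct gene sets (rejection sampling), so identical-set groups in the
#' output are exactly the injected duplicate groups.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `pathway_simulation`: `db` ([pathway_db()]),
#'   `net` ([interaction_network()] over the full genome), `slim`
#'   ([annotation_map()]), `labels` (data frame `pathway_id`, `pool`),
#'   `gene_pools` (named vector gene -> pool, `NA` off-pool) and `config`.
#' @export
simulate_database <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sub <- sim_substreams(cfg$seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  gene_pools <- rep(NA_character_, cfg$n_genes)
  pool_names <- sprintf("pool%02d", seq_len(cfg$n_pools))
  for (k in seq_len(cfg$n_pools))
    gene_pools[((k - 1L) * cfg$pool_size + 1L):(k * cfg$pool_size)] <-
      pool_names[k]
  names(gene_pools) <- genes

  ## --- pathways -------------------------------------------------------------
  set.seed(sub[1])
  seen <- new.env(parent = emptyenv())
  key_of <- function(g) paste(sort_ids(g), collapse = "\r")
  ids <- character(0); glist <- list(); pools <- character(0)
  counter <- 0L
  for (k in seq_len(cfg$n_pools)) {
    pg <- genes[gene_pools %in% pool_names[k] & !is.na(gene_pools)]
    off <- setdiff(genes, pg)
    for (j in seq_len(cfg$pathways_per_pool)) {
      for (try in 1:200) {
        frac <- runif(1, cfg$subset_fraction[1], cfg$subset_fraction[2])
        m <- max(1L, round(frac * cfg$pool_size))
        gs <- sample(pg, m)
        if (cfg$noise_genes > 0L) gs <- c(gs, sample(off, cfg$noise_genes))
        gs <- sort_ids(unique(gs))
        if (is.null(seen[[key_of(gs)]])) break
        if (try == 200) stop("could not sample a distinct pathway; pool too small")
      }
      seen[[key_of(gs)]] <- TRUE
      counter <- counter + 1L
      ids <- c(ids, sprintf("P%04d", counter))
      glist[[length(glist) + 1L]] <- gs
      pools <- c(pools, pool_names[k])
    }
  }
  n_base <- length(ids)
  if (cfg$n_subset_pairs > 0L) {
    eligible <- which(lengths(glist[seq_len(n_base)]) >= 2L)
    parents <- sample(eligible, cfg$n_subset_pairs, replace = TRUE)
    for (t in seq_len(cfg$n_subset_pairs)) {
      pg <- glist[[parents[t]]]
      for (try in 1:200) {
        m <- sample.int(length(pg) - 1L, 1L)
        gs <- sort_ids(sample(pg, m))
        if (is.null(seen[[key_of(gs)]])) break
        if (try == 200) stop("could not sample a distinct subset pathway")
      }
      seen[[key_of(gs)]] <- TRUE
      ids <- c(ids, sprintf("%ss%d", ids[parents[t]], t))
      glist[[length(glist) + 1L]] <- gs
      pools <- c(pools, pools[parents[t]])
    }
  }
  if (length(cfg$duplicate_group_sizes)) {
    src <- sample.int(n_base, length(cfg$duplicate_group_sizes))
    for (t in seq_along(cfg$duplicate_group_sizes)) {
      for (c in seq_len(cfg$duplicate_group_sizes[t] - 1L)) {
        ids <- c(ids, sprintf("%sd%d", ids[src[t]], c))
        glist[[length(glist) + 1L]] <- glist[[src[t]]]
        pools <- c(pools, pools[src[t]])
      }
    }
  }
  if (cfg$n_empty > 0L) {
    ids <- c(ids, sprintf("E%04d", seq_len(cfg$n_empty)))
    glist <- c(glist, rep(list(character(0)), cfg$n_empty))
    pools <- c(pools, rep(NA_character_, cfg$n_empty))
  }
  sources <- sprintf("src%d", ((seq_along(ids) - 1L) %% 3L) + 1L)
  db <- pathway_db(ids, glist, sources = sources,
                   provenance = sprintf("simulated (seed %d)", cfg$seed))

  ## --- interaction network --------------------------------------------------
  set.seed(sub[2])
  within <- lapply(seq_len(cfg$n_pools), function(k) {
    pg <- genes[gene_pools %in% pool_names[k] & !is.na(gene_pools)]
    if (length(pg) < 2L) return(NULL)
    pr <- t(utils::combn(pg, 2L))
    pr[runif(nrow(pr)) < cfg$p_in, , drop = FALSE]
  })
  within <- do.call(rbind, within[!vapply(within, is.null, TRUE)])
  n_pairs_total <- choose(cfg$n_genes, 2)
  n_within_pairs <- cfg$n_pools * choose(cfg$pool_size, 2)
  n_cross <- n_pairs_total - n_within_pairs
  m <- rbinom(1L, n_cross, cfg$p_out)
  cross <- matrix(character(0), ncol = 2)
  got <- character(0)
  while (length(got) < m) {
    batch <- 2L * (m - length(got)) + 10L
    a <- sample.int(cfg$n_genes, batch, replace = TRUE)
    b <- sample.int(cfg$n_genes, batch, replace = TRUE)
    ok <- a != b
    i <- pmin(a[ok], b[ok]); j <- pmax(a[ok], b[ok])
    same_pool <- !is.na(gene_pools[i]) & !is.na(gene_pools[j]) &
      gene_pools[i] == gene_pools[j]
    i <- i[!same_pool]; j <- j[!same_pool]
    key <- paste(i, j)
    new <- !duplicated(key) & !(key %in% got)
    got <- c(got, key[new])
  }
  if (m > 0L) {
    got <- got[seq_len(m)]
    ij <- matrix(as.integer(unlist(strsplit(got, " ", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
    cross <- cbind(genes[ij[, 1]], genes[ij[, 2]])
  }
  edges <- rbind(within, cross)
  net <- interaction_network(edges, universe = genes)

  ## --- annotations ----------------------------------------------------------
  set.seed(sub[3])
  slim_list <- list()
  for (k in seq_len(cfg$n_pools)) {
    pg <- genes[gene_pools %in% pool_names[k] & !is.na(gene_pools)]
    terms <- sprintf("%s_T%d", pool_names[k], seq_len(cfg$n_slim_terms))
    for (g in pg) {
      pick <- terms[runif(cfg$n_slim_terms) < 0.7]
      if (!length(pick)) pick <- sample(terms, 1L)
      slim_list[[g]] <- pick
    }
  }
  slim <- annotation_map(slim_list)

  labels <- data.frame(pathway_id = ids, pool = pools)
  structure(list(db = db, net = net, slim = slim, labels = labels,
                 gene_pools = gene_pools, config = cfg),
            class = "pathway_simulation")
}

#' @export
print.pathway_simulation <- function(x, ...) {
  cat(sprintf("pathway_simulation (seed %d): %d pathways, %d genes, %d edges\n",
              x$config$seed, length(x$db$ids), x$config$n_genes,
              igraph::ecount(x$net$graph)))
  invisible(x)
}

#' Simulate a resultant gene set and its background
#'
#' The background is the full simulated genome.  The resultant set includes
#' each gene of an enriched pool independently with probability
#' `resultant_hit_rate` and every other gene with `background_rate`.  Draws
#' come from a sub-stream of the master seed that is untouched by database,
#' network and annotation generation, so the same configuration always
#' produces the same resultant set.
#'
#' @param cfg a [sim_config()].
#' @param gene_pools named gene -> pool vector from [simulate_database()]
#'   (or a `pathway_simulation` object).
#' @return List with `resultant` and `background` [gene_set()]s.
#' @export
simulate_resultant_set <- function(cfg, gene_pools) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(gene_pools, "pathway_simulation"))
    gene_pools <- gene_pools$gene_pools
  sub <- sim_substreams(cfg$seed)
  set.seed(sub[4])
  enr <- sprintf("pool%02d", cfg$enriched_pools)
  p <- ifelse(!is.na(gene_pools) & gene_pools %in% enr,
              cfg$resultant_hit_rate, cfg$background_rate)
  incl <- runif(length(gene_pools)) < p
  list(resultant = gene_set("resultant", names(gene_pools)[incl]),
       background = gene_set("background", names(gene_pools)))
}

#' Write a simulation to disk in the formats the readers consume
#'
#' Emits `pathways.gmt`, `edges.tsv`, `gene2slim.tsv`, `labels.tsv`
#' (pathway -> planted pool, for test oracles), `config.txt` (flat
#' key=value) and, when a resultant set is supplied, `resultant.txt` and
#' `background.txt`.
#'
#' @param sim a `pathway_simulation`.
#' @param dir output directory (created if needed).
#' @param resultant optional output of [simulate_resultant_set()].
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir, resultant = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(sim$db, file.path(dir, "pathways.gmt"))
  write_interactions(sim$net, file.path(dir, "edges.tsv"))
  write_gene2slim(sim$slim, file.path(dir, "gene2slim.tsv"))
  lab <- sim$labels
  lab$pool[is.na(lab$pool)] <- "none"
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  writeLines(vapply(names(cfg), function(k)
    sprintf("%s=%s", k, paste(cfg[[k]], collapse = ",")), ""),
    file.path(dir, "config.txt"))
  if (!is.null(resultant)) {
    write_gene_list(resultant$resultant, file.path(dir, "resultant.txt"))
    write_gene_list(resultant$background, file.path(dir, "background.txt"))
  }
  invisible(dir)
}
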