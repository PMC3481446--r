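test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, n_genes = 200, n_pools = 2,
                    pathways_per_pool = 3, pool_size = 15)
  s1 <- simulate_database(cfg)
  s2 <- simulate_database(cfg)
  expect_identical(s1$db$genes, s2$db$genes)
  expect_identical(igraph::as_edgelist(s1$net$graph),
                   igraph::as_edgelist(s2$net$graph))
  expect_identical(unclass(s1$slim), unclass(s2$slim))
  r1 <- simulate_resultant_set(cfg, s1)
  r2 <- simulate_resultant_set(cfg, s2)
  expect_identical(r1$resultant$genes, r2$resultant$genes)
})

test_that("component sub-streams are independent of each other's parameters", {
  base <- sim_config(seed = 31, n_genes = 200, n_pools = 2,
                     pathways_per_pool = 3, pool_size = 15)
  denser <- sim_config(seed = 31, n_genes = 200, n_pools = 2,
                       pathways_per_pool = 3, pool_size = 15, p_in = 0.9)
  s1 <- simulate_database(base)
  s2 <- simulate_database(denser)
  expect_identical(s1$db$genes, s2$db$genes)         # pathways untouched
  expect_identical(unclass(s1$slim), unclass(s2$slim))
  expect_identical(simulate_resultant_set(base, s1)$resultant$genes,
                   simulate_resultant_set(denser, s2)$resultant$genes)
})

test_that("injected duplicates and subsets are recovered by the database operations", {
  cfg <- sim_config(seed = 41, n_genes = 300, n_pools = 3,
                    pathways_per_pool = 4, pool_size = 20,
                    duplicate_group_sizes = c(3, 2, 2), n_subset_pairs = 4,
                    n_empty = 5)
  sim <- simulate_database(cfg)
  expect_equal(length(sim$db$ids), 12 + (2 + 1 + 1) + 4 + 5)
  nonempty <- remove_empty(sim$db)
  expect_equal(length(nonempty$ids), length(sim$db$ids) - 5L)
  gi <- group_identical(nonempty)
  expect_equal(gi$n_groups, 3L)
  expect_equal(sort(lengths(gi$groups)), c(2L, 2L, 3L))
  expect_equal(gi$consolidated_count, length(nonempty$ids) - 7L + 3L)
  # every injected subset id is flagged as a subset of its parent
  subs <- find_subsets(nonempty)
  injected <- grep("s[0-9]+$", nonempty$ids, value = TRUE)
  expect_true(all(injected %in% subs))
})

test_that("extreme resultant rates give the forced resultant sets", {
  cfg1 <- sim_config(seed = 51, n_genes = 150, n_pools = 3,
                     pathways_per_pool = 2, pool_size = 10,
                     enriched_pools = c(1, 3),
                     resultant_hit_rate = 1, background_rate = 0)
  sim <- simulate_database(cfg1)
  rs <- simulate_resultant_set(cfg1, sim)
  pools_of <- sim$gene_pools
  expected <- names(pools_of)[!is.na(pools_of) &
                                pools_of %in% c("pool01", "pool03")]
  expect_setequal(rs$resultant$genes, expected)
  expect_equal(length(rs$background), 150L)
})

test_that("pathways from enriched pools dominate the top of the enrichment ranking", {
  cfg <- sim_config(seed = 61, n_genes = 400, n_pools = 4,
                    pathways_per_pool = 4, pool_size = 25,
                    enriched_pools = 1:2)
  sim <- simulate_database(cfg)
  rs <- simulate_resultant_set(cfg, sim)
  res <- enrich_all(sim$db, rs$resultant, rs$background)
  top <- head(res$pathway_id, 8)
  top_pools <- sim$labels$pool[match(top, sim$labels$pathway_id)]
  expect_gte(mean(top_pools %in% c("pool01", "pool02")), 0.75)
})

test_that("p_in = p_out gives statistically indistinguishable densities", {
  # pooled within/between edge counts over a few seeds, chi-squared check
  n_in <- 0; n_out <- 0; pairs_in <- 0; pairs_out <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 900 + s, n_genes = 120, n_pools = 3,
                      pathways_per_pool = 2, pool_size = 20,
                      p_in = 0.05, p_out = 0.05)
    sim <- simulate_database(cfg)
    em <- igraph::as_edgelist(sim$net$graph)
    pl <- sim$gene_pools
    same <- !is.na(pl[em[, 1]]) & !is.na(pl[em[, 2]]) &
      pl[em[, 1]] == pl[em[, 2]]
    n_in <- n_in + sum(same); n_out <- n_out + sum(!same)
    pairs_in <- pairs_in + 3 * choose(20, 2)
    pairs_out <- pairs_out + choose(120, 2) - 3 * choose(20, 2)
  }
  tab <- rbind(c(n_in, pairs_in - n_in), c(n_out, pairs_out - n_out))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(), "mandatory")
  expect_error(sim_config(seed = 1, p_in = 1.2), "probabilities")
  expect_error(sim_config(seed = 1, n_pools = 10, pool_size = 200,
                          n_genes = 100), "exceeds")
  expect_error(sim_config(seed = 1, enriched_pools = 99), "out of range")
  expect_error(sim_config(seed = 1, duplicate_group_sizes = 1), ">= 2")
})

test_that("write_simulation emits files the readers parse back losslessly", {
  cfg <- sim_config(seed = 71, n_genes = 150, n_pools = 2,
                    pathways_per_pool = 3, pool_size = 15)
  sim <- simulate_database(cfg)
  rs <- simulate_resultant_set(cfg, sim)
  dir <- tempfile("simout")
  write_simulation(sim, dir, resultant = rs)
  db2 <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_identical(db2$genes, sim$db$genes)
  net2 <- read_interactions(file.path(dir, "edges.tsv"))
  expect_equal(igraph::ecount(net2$graph), igraph::ecount(sim$net$graph))
  slim2 <- read_gene2slim(file.path(dir, "gene2slim.tsv"))
  gs <- sort(names(slim2))
  expect_setequal(names(slim2), names(sim$slim))
  expect_identical(slim2[gs], sim$slim[gs])
  expect_identical(read_gene_list(file.path(dir, "resultant.txt"))$genes,
                   rs$resultant$genes)
})
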