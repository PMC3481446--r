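test_that("gene_pathway_weight follows the hypergeometric-expectation rescaling", {
  uni <- sprintf("u%02d", 1:20)
  net <- interaction_network(cbind(c("u01", "u01"), c("u02", "u03")),
                             universe = uni)
  # gene with no interactions: X = 0, w <= 0, W = 1
  w <- gene_pathway_weight("u05", c("u05", "u06", "u07"), net)
  expect_equal(w$X, 0L)
  expect_gte(w$E, 0)
  expect_lte(w$w, 0)
  expect_equal(w$W, 1)
  # hub gene: X = 2 partners inside the pathway, E = M*K/N
  w2 <- gene_pathway_weight("u01", c("u01", "u02", "u03", "u08"), net)
  expect_equal(w2$X, 2L)
  expect_equal(w2$E, 2 * 4 / 20)
  expect_equal(w2$w, 2 - 0.4)
  expect_equal(w2$W, log2(2 - 0.4 + 2))
  expect_error(gene_pathway_weight("u09", c("u05", "u06"), net), "not a member")
})

test_that("rescaled weight is 1 for w <= 0 and log2(w+2) for w > 0; w = 2 gives W = 2", {
  expect_equal(pathconsol:::rescale_weight(2), 2)          # log2(4)
  expect_equal(pathconsol:::rescale_weight(0), 1)
  expect_equal(pathconsol:::rescale_weight(-3.7), 1)
  expect_equal(pathconsol:::rescale_weight(6), 3)          # log2(8)
})

test_that("within-pathway interaction counts X equal brute-force edge counting", {
  # 12-gene toy graph
  set.seed(77)
  genes <- sprintf("t%02d", 1:12)
  em <- t(combn(genes, 2))
  em <- em[runif(nrow(em)) < 0.3, , drop = FALSE]
  net <- interaction_network(em, universe = genes)
  db <- make_db(list(PA = genes[1:5], PB = genes[4:10], PC = genes[c(1, 11, 12)]))
  wt <- wc_weight_table(db, net)
  for (r in seq_len(nrow(wt))) {
    pg <- db$genes[[wt$pathway[r]]]
    x_oracle <- sum((em[, 1] == wt$gene[r] & em[, 2] %in% setdiff(pg, wt$gene[r])) |
                    (em[, 2] == wt$gene[r] & em[, 1] %in% setdiff(pg, wt$gene[r])))
    expect_equal(wt$X[r], x_oracle)
    expect_equal(wt$E[r], wt$M[r] * wt$K[r] / attr(wt, "n_genome"))
    expect_gte(wt$W[r], 1)
  }
})

sim_for_wc <- function() {
  db <- make_db(list(Pa = c("d1", "d2", "x1"), Pb = c("d2", "d3", "x2"),
                     Pc = c("d4", "x3")))
  net <- interaction_network(NULL, universe = c(sprintf("d%d", 1:8),
                                                sprintf("x%d", 1:3)))
  list(db = db, net = net, D = gene_set("D", sprintf("d%d", 1:8)))
}

test_that("pair_similarity matches hand evaluation of the weighted-overlap score", {
  x <- sim_for_wc()
  wt <- wc_weight_table(x$db, x$net, genes = x$D$genes)
  expect_true(all(wt$W == 1))    # empty network: every weight rescales to 1
  # shared = {d2}: num = 1, den = 1 + W(d1) + W(d3) = 3
  expect_equal(pair_similarity(x$db, "Pa", "Pb", x$D, wt), 1 / 3)
  expect_equal(pair_similarity(x$db, "Pa", "Pc", x$D, wt), 0)
  # identical resultant overlap: similarity 1
  db2 <- make_db(list(Q1 = c("d1", "d2", "x1"), Q2 = c("d1", "d2", "x2")))
  wt2 <- wc_weight_table(db2, x$net, genes = x$D$genes)
  expect_equal(pair_similarity(db2, "Q1", "Q2", x$D, wt2), 1)
})

test_that("greedy pair clustering applies the new/attach/skip rules in score order", {
  # chain: a-b strong, b-c weaker, a-c weak; single growing cluster expected
  db <- make_db(list(
    a = c("d1", "d2", "d3", "d4", "d5"),
    b = c("d1", "d2", "d3", "d4", "d6"),   # sim(a,b) = 4/6
    c = c("d4", "d6", "d7", "d8")))        # sim(b,c) = 2/7 > sim(a,c) = 1/8
  D <- gene_set("D", sprintf("d%d", 1:8))
  net <- interaction_network(NULL, universe = D$genes)
  cl <- consolidate_weighted(db, D, net)
  expect_equal(n_concepts(cl), 1L)
  expect_setequal(cl$concepts[[1]]$members, c("a", "b", "c"))
})

test_that("exactly one positive-similarity pair yields one concept of size 2", {
  x <- sim_for_wc()
  cl <- consolidate_weighted(x$db, x$D, x$net)
  expect_equal(n_concepts(cl), 1L)
  expect_setequal(cl$concepts[[1]]$members, c("Pa", "Pb"))
  expect_equal(cl$unassigned, "Pc")      # untouched singleton stays out
})

test_that("no positive-similarity pair yields no concepts", {
  db <- make_db(list(P1 = c("d1", "x1"), P2 = c("d2", "x2")))
  D <- gene_set("D", c("d1", "d2"))
  net <- interaction_network(NULL, universe = c("d1", "d2", "x1", "x2"))
  cl <- consolidate_weighted(db, D, net)
  expect_equal(n_concepts(cl), 0L)
  expect_setequal(cl$unassigned, c("P1", "P2"))
})

test_that("WC similarity reduces to Jaccard of resultant overlaps under equal weights", {
  set.seed(55)
  uni <- sprintf("g%03d", 1:60)
  db <- random_db(12, universe = uni, min_size = 2, max_size = 12)
  D <- gene_set("D", sample(uni, 25))
  net <- interaction_network(NULL, universe = uni)     # all W = 1
  wt <- wc_weight_table(db, net, genes = D$genes)
  for (i in 1:6) {
    pick <- sample(db$ids, 2)
    a <- intersect(db$genes[[pick[1]]], D$genes)
    b <- intersect(db$genes[[pick[2]]], D$genes)
    jac <- if (!length(union(a, b))) 0 else
      length(intersect(a, b)) / length(union(a, b))
    if (length(a) && length(b))
      expect_equal(pair_similarity(db, pick[1], pick[2], D, wt), jac)
  }
})

test_that("WC concepts are disjoint with every size >= 2 on simulated data", {
  for (s in 1:5) {
    cfg <- sim_config(seed = 700 + s, n_genes = 300, n_pools = 3,
                      pathways_per_pool = 4, pool_size = 20)
    sim <- simulate_database(cfg)
    rs <- simulate_resultant_set(cfg, sim)
    cl <- consolidate_weighted(sim$db, rs$resultant, sim$net, rs$background)
    sizes <- vapply(cl$concepts, function(cc) length(cc$members), 0L)
    expect_true(all(sizes >= 2L))
    members <- unlist(lapply(cl$concepts, `[[`, "members"))
    expect_false(anyDuplicated(members) > 0)
    # concepts + unassigned = all pathways with >= 1 resultant gene
    with_d <- sim$db$ids[vapply(sim$db$genes,
                                function(g) any(g %in% rs$resultant$genes), TRUE)]
    expect_setequal(c(members, cl$unassigned), with_d)
  }
})
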