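test_that("attribute sets follow the three mode definitions", {
  net <- interaction_network(cbind("A", "B"), universe = c("A", "B", "C"))
  slim <- annotation_map(list(A = c("T1"), B = c("T1", "T2")))
  expect_equal(attribute_set(c("B", "A"), "membership"), c("A", "B"))
  # ppi: own genes plus interactants; genes without partners contribute themselves
  expect_equal(attribute_set("A", "ppi", net = net), c("A", "B"))
  expect_equal(attribute_set("C", "ppi", net = net), "C")
  # goslim: term vocabulary only; unannotated genes contribute nothing
  expect_equal(attribute_set(c("A", "B", "C"), "goslim", slim = slim),
               c("T1", "T2"))
  expect_equal(attribute_set("C", "goslim", slim = slim), character(0))
  expect_error(attribute_set("A", "goslim"), "requires")
  expect_error(attribute_set("A", "ppi"), "requires")
})

test_that("goslim attribute sets equal the union of the member slim sets", {
  slim <- annotation_map(list(g1 = c("T1", "T2"), g2 = "T2", g3 = "T3"))
  got <- attribute_set(c("g1", "g2", "g3"), "goslim", slim = slim)
  oracle <- sort(unique(c(slim[["g1"]], slim[["g2"]], slim[["g3"]])))
  expect_equal(got, oracle)
})

test_that("jaccard_matrix computes the cardinality formula with the empty-set convention", {
  dm <- jaccard_matrix(list(P1 = c("a", "b", "c"), P2 = c("b", "c", "d"),
                            P3 = c("a", "b", "c"), P4 = c("x", "y"),
                            P5 = character(0), P6 = character(0)))
  d <- dm$dist
  expect_equal(d["P1", "P2"], 1 - 2 / 4)         # J = 0.5
  expect_equal(d["P1", "P3"], 0)                 # identical sets
  expect_equal(d["P1", "P4"], 1)                 # disjoint
  expect_equal(d["P5", "P6"], 1)                 # empty vs empty: J defined 0
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("jaccard_matrix agrees with brute-force set computation", {
  set.seed(13)
  sets <- lapply(1:40, function(i) sample(letters, sample(0:10, 1)))
  names(sets) <- sprintf("S%02d", 1:40)
  dm <- jaccard_matrix(sets)
  for (i in 1:40) for (j in 1:40) {
    if (i == j) next
    u <- union(sets[[i]], sets[[j]])
    J <- if (!length(u)) 0 else length(intersect(sets[[i]], sets[[j]])) / length(u)
    expect_equal(dm$dist[i, j], 1 - J)
  }
})

test_that("membership-mode Jaccard on raw GMT lines matches the matrix", {
  f <- write_tmp(c("P1\ts\tA\tB\tC", "P2\ts\tB\tC\tD"), ext = ".gmt")
  db <- read_gmt(f)
  dm <- jaccard_matrix(attribute_sets(db, "membership"))
  expect_equal(dm$dist["P1", "P2"], 1 - 2 / 4)
})

test_that("cluster_pathways respects the requested cluster count", {
  sets <- list(P1 = c("a", "b"), P2 = c("a", "b"), P3 = c("x", "y"))
  dm <- jaccard_matrix(sets)
  # n_clusters = n: every pathway its own cluster
  all_single <- cluster_pathways(dm, n_clusters = 3)
  expect_equal(n_concepts(all_single), 3L)
  # identical pair merges first at k = 2
  two <- cluster_pathways(dm, n_clusters = 2)
  m <- concept_membership(two)
  expect_equal(m[["P1"]], m[["P2"]])
  expect_false(m[["P1"]] == m[["P3"]])
  # requested count larger than n is capped
  expect_equal(n_concepts(cluster_pathways(dm, n_clusters = 500)), 3L)
  expect_error(cluster_pathways(dm, n_clusters = 2, cutoff = 0.5), "exactly one")
  expect_error(cluster_pathways(dm, cutoff = 1.5), "cutoff")
})

test_that("planted pools are recovered exactly at the right cluster count", {
  skip_if_not_installed("mclust")
  # 40 pathways in 5 pools of 8; within-pool J >> between-pool J
  set.seed(99)
  pools <- lapply(1:5, function(k) sprintf("p%d_%02d", k, 1:20))
  sets <- list(); labels <- integer(0)
  for (k in 1:5) for (j in 1:8) {
    nm <- sprintf("C%dP%d", k, j)
    sets[[nm]] <- sample(pools[[k]], 14)
    labels <- c(labels, k)
  }
  dm <- jaccard_matrix(sets)
  cl <- cluster_pathways(dm, n_clusters = 5)
  m <- concept_membership(cl)[names(sets)]
  expect_equal(mclust::adjustedRandIndex(m, labels), 1)
})

test_that("partitions are nested across the agglomeration and cutoff behaves monotonically", {
  set.seed(17)
  sets <- lapply(1:30, function(i) sample(sprintf("a%02d", 1:25), sample(3:10, 1)))
  names(sets) <- sprintf("N%02d", 1:30)
  dm <- jaccard_matrix(sets)
  prev <- NULL
  for (k in c(2, 5, 10, 20, 30)) {
    m <- concept_membership(cluster_pathways(dm, n_clusters = k))[names(sets)]
    expect_lte(length(unique(m)), k)
    if (!is.null(prev)) {
      # partition at larger k refines the one at smaller k
      expect_true(all(tapply(prev, m, function(v) length(unique(v))) == 1L))
    }
    prev <- m
  }
  ks <- vapply(c(0.9, 0.6, 0.3),
               function(h) n_concepts(cluster_pathways(dm, cutoff = h)), 0L)
  expect_false(is.unsorted(ks))   # lower cutoff, fewer clusters
})

test_that("precompute_denovo emits the full mode x cut-off menu", {
  cfg <- sim_config(seed = 3, n_genes = 200, n_pools = 3,
                    pathways_per_pool = 3, pool_size = 15)
  sim <- simulate_database(cfg)
  cls <- precompute_denovo(sim$db, slim = sim$slim, net = sim$net)
  expect_equal(length(cls), 24L)
  expect_setequal(names(cls),
                  as.vector(outer(c("membership", "goslim", "ppi"),
                                  c(5, 10, 20, 40, 50, 100, 200, 500), paste0)))
  # cut-offs above the pathway count collapse to n clusters
  expect_equal(n_concepts(cls$membership500), 9L)
  for (cl in cls) {
    m <- concept_membership(cl)
    expect_setequal(names(m), sim$db$ids)     # every pathway assigned once
  }
  # serialization round trip: long TSV with 24 * n rows
  f <- tempfile(fileext = ".tsv")
  write_denovo(cls, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 24L * 9L)
})

test_that("restricting a de novo clustering to an experiment's pathways counts concepts correctly", {
  # filter-and-count: concepts with at least one pathway touching a gene set
  sets <- list(P1 = c("a", "b"), P2 = c("a", "c"), P3 = c("x", "y"),
               P4 = c("x", "z"), P5 = c("q", "r"))
  dm <- jaccard_matrix(sets)
  cl <- cluster_pathways(dm, n_clusters = 3)
  touched <- c("P1", "P4")   # pathways overlapping some resultant set
  m <- concept_membership(cl)
  hit <- unique(m[touched])
  oracle <- sum(vapply(split(names(m), m),
                       function(mem) any(mem %in% touched), TRUE))
  expect_equal(length(hit), oracle)
})
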