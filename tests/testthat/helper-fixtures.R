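# in-code fixtures shared across test files

# quick database from a (possibly named) list of gene vectors
make_db <- function(genes, ids = NULL, sources = "test") {
  if (is.null(ids))
    ids <- names(genes) %||% sprintf("P%02d", seq_along(genes))
  pathconsol::pathway_db(ids, genes, sources = sources)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random database for property tests: n pathways over a gene universe
random_db <- function(n, universe = sprintf("g%03d", 1:40),
                      min_size = 0L, max_size = 8L) {
  genes <- lapply(seq_len(n), function(i) {
    k <- sample(min_size:max_size, 1)
    if (k == 0) character(0) else sample(universe, k)
  })
  make_db(genes, ids = sprintf("R%03d", seq_len(n)))
}

# brute-force upper-tail hypergeometric by direct pmf enumeration with
# choose(); independent of phyper
hyper_tail_oracle <- function(overlap, pathway_size, resultant_size,
                              background_size) {
  xs <- overlap:min(pathway_size, resultant_size)
  sum(choose(pathway_size, xs) *
        choose(background_size - pathway_size, resultant_size - xs)) /
    choose(background_size, resultant_size)
}

# brute-force O(n^2) pairwise subset oracle
subset_oracle <- function(db) {
  n <- length(db$ids)
  out <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && all(db$genes[[i]] %in% db$genes[[j]])) out[i] <- TRUE
  }
  db$ids[out]
}

# small toy network: triangle A-B-C plus pendant C-D
toy_net <- function(universe = NULL) {
  pathconsol::interaction_network(
    cbind(c("A", "B", "C", "C"), c("B", "C", "A", "D")), universe = universe)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
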