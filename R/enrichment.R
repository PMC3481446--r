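#' One-sided Fisher's exact enrichment p-value
#'
#' Upper-tail probability `P(X >= overlap)` of the hypergeometric
#' distribution for the 2x2 table (in-pathway x in-resultant) over a
#' background universe: the chance that a uniform draw of `resultant_size`
#' genes from the background hits at least `overlap` of the
#' `pathway_size` pathway genes.  This is the p-value of the one-sided
#' Fisher's exact test on the table.
#'
#' Vectorized over all four arguments.
#'
#' @param overlap observed intersection size of pathway, resultant set and
#'   background.
#' @param pathway_size number of pathway genes in the background.
#' @param resultant_size number of resultant genes in the background.
#' @param background_size size of the background universe.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_p(3, 5, 10, 50)
#' @export
fisher_p <- function(overlap, pathway_size, resultant_size, background_size) {
  n <- max(length(overlap), length(pathway_size), length(resultant_size),
           length(background_size))
  overlap <- rep_len(as.numeric(overlap), n)
  pathway_size <- rep_len(as.numeric(pathway_size), n)
  resultant_size <- rep_len(as.numeric(resultant_size), n)
  background_size <- rep_len(as.numeric(background_size), n)
  if (any(overlap < 0 | pathway_size < 0 | resultant_size < 0 |
          background_size < 0))
    stop("all table margins must be non-negative")
  if (any(overlap > pmin(pathway_size, resultant_size)))
    stop("overlap exceeds min(pathway_size, resultant_size)")
  if (any(pathway_size > background_size | resultant_size > background_size))
    stop("pathway_size and resultant_size must not exceed background_size")
  phyper(overlap - 1, pathway_size, background_size - pathway_size,
         resultant_size, lower.tail = FALSE)
}

#' Enrich every pathway for a resultant gene set
#'
#' Tests each pathway containing at least one resultant gene with the
#' one-sided Fisher's exact test against the background universe.  Genes
#' outside the background are removed from the resultant set and from each
#' pathway before the table is built, so all margins live in the measured
#' universe.  Pathways with zero overlap are excluded.
#'
#' Results are sorted ascending by p-value with a deterministic tie-break:
#' larger overlap first, then byte-lexicographic pathway id; the ranking is
#' therefore invariant to pathway file order.
#'
#' @param db a [pathway_db()].
#' @param resultant [gene_set()] (or character vector) of resultant genes
#'   (e.g. differentially expressed genes).
#' @param background optional background [gene_set()]; defaults to all genes
#'   appearing in any pathway of `db`, a proxy for the genome when no
#'   platform universe is supplied.
#' @return A data frame with columns `pathway_id`, `name`, `source`,
#'   `p_value`, `fdr` (Benjamini-Hochberg, informational only -- the
#'   consolidation procedures use raw p-values), `overlap`,
#'   `pathway_in_background`, `genes` (overlapping gene ids, comma-joined,
#'   sorted).  Attribute `background_size` records the universe size.
#' @export
enrich_all <- function(db, resultant, background = NULL) {
  resultant <- as_gene_set(resultant, "resultant")
  if (is.null(background)) background <- gene_set("background", db_all_genes(db))
  background <- as_gene_set(background, "background")
  bgg <- background$genes
  if (!length(bgg)) stop("background gene set is empty")
  D <- intersect(resultant$genes, bgg)
  if (!length(D))
    stop("resultant gene set is empty after restriction to the background")
  bg_size <- length(bgg)
  rows <- lapply(seq_along(db$ids), function(i) {
    pg <- intersect(db$genes[[i]], bgg)
    ov <- intersect(pg, D)
    if (!length(ov)) return(NULL)
    data.frame(pathway_id = db$ids[i], name = db$names[i],
               source = db$sources[i],
               p_value = fisher_p(length(ov), length(pg), length(D), bg_size),
               overlap = length(ov), pathway_in_background = length(pg),
               genes = paste(sort_ids(ov), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    res <- data.frame(pathway_id = character(0), name = character(0),
                      source = character(0), p_value = numeric(0),
                      fdr = numeric(0), overlap = integer(0),
                      pathway_in_background = integer(0), genes = character(0))
    attr(res, "background_size") <- bg_size
    return(res)
  }
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  o <- order_ids(res$p_value, -res$overlap, res$pathway_id)
  res <- res[o, c("pathway_id", "name", "source", "p_value", "fdr",
                  "overlap", "pathway_in_background", "genes")]
  rownames(res) <- NULL
  attr(res, "background_size") <- bg_size
  res
}

#' Write an enrichment table as TSV
#' @param res result of [enrich_all()].
#' @param path output path.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
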