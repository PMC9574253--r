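#' Assign SNPs to genes by position
#'
#' A SNP inside a gene body ([start, end], 1-based inclusive) gets that
#' gene's id. Otherwise, genes whose nearer boundary lies strictly within
#' `flank_bp` of the SNP are candidates: the nearest one (ties by smaller
#' distance then lexicographic id) is assigned with a trailing `*`
#' (near-gene convention); when two genes flank the SNP within range, the
#' two nearest are joined by `-` (e.g. `DSC2-DSC3*`). SNPs without a
#' chromosome/position, or beyond the flank of every gene, get `"-"`.
#'
#' @param records A `gwas_result` (or any data frame with `marker_id`,
#'   `chrom`, `pos`).
#' @param genes Gene table from [read_gene_table()].
#' @param flank_bp Flank width in bp (strict inequality; default 10000).
#' @return `records` with a `gene` column.
#' @export
map_snps_to_genes <- function(records, genes, flank_bp = 10000L) {
  gene <- rep("-", nrow(records))
  if (nrow(records) && nrow(genes)) {
    for (i in seq_len(nrow(records))) {
      chrom <- records$chrom[i]
      pos <- records$pos[i]
      if (is.na(chrom) || chrom == "NA" || is.na(pos)) next
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      if (!nrow(g)) next
      dist <- pmax(g$start - pos, pos - g$end, 0L)
      inside <- dist == 0L
      if (any(inside)) {
        hit <- g$gene_id[inside][order(g$gene_id[inside])][1L]
        gene[i] <- hit
        next
      }
      near <- which(dist < flank_bp)
      if (!length(near)) next
      ord <- near[order(dist[near], g$gene_id[near])]
      ids <- g$gene_id[ord[seq_len(min(2L, length(ord)))]]
      gene[i] <- paste0(paste(ids, collapse = "-"), "*")
    }
  }
  records$gene <- gene
  records
}

#' Hypergeometric over-representation test for gene sets
#'
#' For each gene set, tests whether its overlap with a gene list drawn
#' from a finite universe is larger than expected: one-sided
#' hypergeometric tail `P(X >= k)`, with Benjamini-Hochberg correction
#' across sets. Gene sets are intersected with the universe first.
#'
#' @param gene_list Character vector of genes of interest (must lie in
#'   `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: all genes that could have appeared.
#' @return Data frame with one row per set: `set_id`, `overlap`,
#'   `set_size`, `list_size`, `universe_size`, `pvalue`, `qvalue`.
#' @export
hypergeom_enrichment <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_validation("empty gene universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) {
    stop_validation("gene_list contains genes outside the universe")
  }
  N <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(names(gene_sets), function(id) {
    s <- intersect(unique(gene_sets[[id]]), universe)
    k <- length(intersect(s, gene_list))
    p <- stats::phyper(k - 1L, length(s), N - length(s), n_l,
                       lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = length(s),
               list_size = n_l, universe_size = N,
               pvalue = min(1, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(set_id = character(), overlap = integer(),
               set_size = integer(), list_size = integer(),
               universe_size = integer(), pvalue = numeric())
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out
}
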