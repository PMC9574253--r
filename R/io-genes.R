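#' Read a gene table from BED or GFF3
#'
#' Uses \pkg{rtracklayer} to parse the file and normalizes every interval
#' to the package-wide 1-based inclusive convention (BED's 0-based
#' half-open starts are shifted at this boundary).
#'
#' @param path Path to the file.
#' @param dialect `"BED"` (4+ columns; the 4th column names the gene) or
#'   `"GFF3"` (rows of type `gene` are used when present, otherwise all
#'   rows; `ID`/`Name`/`gene_id` attributes name the gene).
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive; `strand` in `+`, `-`, `.`).
#' @export
read_gene_table <- function(path, dialect = c("BED", "GFF3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(content)) return(empty)

  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "BED") "bed" else "gff3"),
    error = function(e) stop_format("failed to parse ", dialect, ": ",
                                    conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty)

  if (dialect == "BED") {
    gene_id <- as.character(df$name %||% seq_len(nrow(df)))
  } else {
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", , drop = FALSE]
    }
    gene_id <- rep(NA_character_, nrow(df))
    for (key in c("ID", "Name", "gene_id", "locus_tag")) {
      if (key %in% names(df)) {
        use <- is.na(gene_id) & !is.na(df[[key]])
        gene_id[use] <- as.character(df[[key]][use])
      }
    }
    gene_id[is.na(gene_id)] <- paste0("gene_", which(is.na(gene_id)))
  }

  out <- data.frame(gene_id = gene_id,
                    chrom = as.character(df$seqnames),
                    start = as.integer(df$start),   # GRanges is already 1-based
                    end = as.integer(df$end),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "."
  if (any(out$end < out$start)) stop_validation("gene with end < start")
  if (anyDuplicated(out$gene_id)) stop_validation("duplicate gene ids")
  rownames(out) <- NULL
  out
}

#' Write a gene table as BED
#'
#' Inverse of [read_gene_table()] for the BED dialect: internal 1-based
#' inclusive intervals are converted back to 0-based half-open.
#'
#' @param genes Gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
               0L, ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
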