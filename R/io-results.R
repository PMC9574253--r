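#' Write pipeline result tables
#'
#' Emits the two publication-style tables as deterministic TSV files:
#' the candidate-SNP association table (columns `SNP ID`, `Chr`, `Pos`,
#' `Ref`, `Alt`, `Effect`, `Lod`, `pvalue`, `Status`, `Gene`; Lod and
#' Effect to 2 decimals, p-values in scientific notation) and the
#' per-group diversity table (`Group`, `No.`, `Hexp`, `Ia`, `rbarD`).
#' An optional tree is written as Newick text.
#'
#' @param gwas Data frame of association records ([marker_scan()] output,
#'   possibly annotated) or `NULL`.
#' @param diversity Data frame from [diversity_table()] or `NULL`.
#' @param path Output directory (created if absent).
#' @param tree Optional `phylo` tree (e.g. from [nj_tree()]).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results_tables <- function(gwas = NULL, diversity = NULL, path = ".",
                                 tree = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  if (!is.null(gwas)) {
    f <- file.path(path, "gwas_candidates.tsv")
    out <- data.frame(
      `SNP ID` = gwas$marker_id %||% character(),
      Chr = gwas$chrom %||% character(),
      Pos = ifelse(is.na(gwas$pos), "-", format(gwas$pos, scientific = FALSE,
                                                trim = TRUE)),
      Ref = gwas$ref, Alt = gwas$alt,
      Effect = sprintf("%.2f", gwas$effect),
      Lod = sprintf("%.2f", gwas$lod),
      pvalue = sprintf("%.2e", gwas$pvalue),
      Status = gwas$status %||% rep("NS", nrow(gwas)),
      Gene = gwas$gene %||% rep("-", nrow(gwas)),
      check.names = FALSE, stringsAsFactors = FALSE)
    if (!nrow(gwas)) {
      out <- out[0, c("SNP ID", "Chr", "Pos", "Ref", "Alt", "Effect",
                      "Lod", "pvalue", "Status", "Gene")]
    }
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written["gwas"] <- f
  }

  if (!is.null(diversity)) {
    f <- file.path(path, "diversity.tsv")
    out <- data.frame(
      Group = diversity$group,
      `No.` = diversity$n,
      Hexp = sprintf("%.3f", diversity$Hexp),
      Ia = sprintf("%.3f", diversity$Ia),
      rbarD = sprintf("%.5f", diversity$rbarD),
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written["diversity"] <- f
  }

  if (!is.null(tree)) {
    f <- file.path(path, "fst_nj_tree.nwk")
    ape::write.tree(tree, f)
    written["tree"] <- f
  }

  invisible(written)
}
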