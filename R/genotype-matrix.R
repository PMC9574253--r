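#' Genotype matrix container
#'
#' Bundles a samples-by-markers dosage matrix (counts of the Alt allele,
#' `NA` for missing calls) with its marker map and sample metadata. This is
#' the container every downstream stage of the pipeline consumes.
#'
#' @param calls Integer matrix, samples in rows and markers in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param map Data frame with columns `marker_id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per marker, in column order of `calls`. `chrom` may be
#'   `"NA"` and `pos` may be `NA` for unplaced markers.
#' @param samples Data frame with column `sample_id` and optional `breed`
#'   and `location` columns; one row per sample, in row order of `calls`.
#' @param sort_markers Sort placed markers by chromosome then position
#'   (unplaced markers keep their relative order at the end).
#'
#' @return An object of class `geno_matrix` with elements `calls`, `map`
#'   and `samples`.
#' @examples
#' g <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                  dimnames = list(c("s1", "s2"), c("m1", "m2"))),
#'   map = data.frame(marker_id = c("m1", "m2"), chrom = "1",
#'                    pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' n_samples(g)
#' @export
genotype_matrix <- function(calls, map, samples = NULL, sort_markers = TRUE) {
  if (!is.matrix(calls)) stop_validation("calls must be a matrix")
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop_validation("non-missing dosages must be 0, 1 or 2")
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("marker_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(map))
  if (length(miss)) stop_validation("map lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(map) != ncol(calls)) {
    stop_validation("map rows (", nrow(map), ") != markers (", ncol(calls), ")")
  }
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- suppressWarnings(as.integer(map$pos))
  if (anyDuplicated(map$marker_id)) stop_validation("duplicate marker ids")
  if (any(!is.na(map$pos) & map$pos < 1L)) stop_validation("positions must be >= 1")

  if (is.null(samples)) {
    ids <- rownames(calls) %||% paste0("sample_", seq_len(nrow(calls)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) stop_validation("samples lacks sample_id")
  samples$sample_id <- as.character(samples$sample_id)
  if (nrow(samples) != nrow(calls)) {
    stop_validation("samples rows (", nrow(samples), ") != calls rows (", nrow(calls), ")")
  }
  if (anyDuplicated(samples$sample_id)) stop_validation("duplicate sample ids")

  dimnames(calls) <- list(samples$sample_id, map$marker_id)

  if (sort_markers && nrow(map) > 1L) {
    placed <- !is.na(map$pos) & map$chrom != "NA"
    ord <- c(which(placed)[order(map$chrom[placed], map$pos[placed])], which(!placed))
    calls <- calls[, ord, drop = FALSE]
    map <- map[ord, , drop = FALSE]
    rownames(map) <- NULL
  }

  structure(list(calls = calls, map = map, samples = samples),
            class = "geno_matrix")
}

#' @rdname genotype_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname genotype_matrix
#' @export
n_markers <- function(x) ncol(x$calls)

#' @method print geno_matrix
#' @export
print.geno_matrix <- function(x, ...) {
  nm <- sum(is.na(x$calls))
  cat(sprintf("geno_matrix: %d samples x %d markers (%.2f%% missing)\n",
              n_samples(x), n_markers(x),
              100 * nm / max(1L, length(x$calls))))
  meta <- intersect(c("breed", "location"), names(x$samples))
  if (length(meta)) cat("sample metadata:", paste(meta, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param i Sample index (logical, integer or sample ids).
#' @param j Marker index (logical, integer or marker ids).
#' @param ... Ignored.
#' @return A `geno_matrix` restricted to the selected samples/markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_markers(x))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$map$marker_id)
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$map[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE],
                  sort_markers = FALSE)
}

# Per-sample group labels for a metadata key ("breed" or "location").
group_labels <- function(geno, grouping) {
  if (length(grouping) == n_samples(geno) && !all(grouping %in% names(geno$samples))) {
    return(as.character(grouping))
  }
  grouping <- as.character(grouping[[1L]])
  if (!grouping %in% names(geno$samples)) {
    stop_validation("unknown grouping key '", grouping,
                    "': not a sample metadata column")
  }
  as.character(geno$samples[[grouping]])
}
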