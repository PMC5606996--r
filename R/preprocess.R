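# Second-stage normalization, probe summarization and homolog mapping

#' Quantile-normalize an expression matrix
#'
#' Forces every column to the same empirical distribution: the reference is
#' the row-wise mean of the column-sorted values, and each column's values
#' are replaced by the reference values at their ranks.  Tied input values
#' receive the mean of the reference values they span (average-rank
#' convention).  Delegates to `limma::normalizeQuantiles(..., ties = TRUE)`.
#'
#' @param m Numeric matrix with at least 2 columns; finite values.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(cbind(a = c(2, 4, 6), b = c(1, 3, 5)))
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("matrix must be finite", call. = FALSE)
  if (ncol(m) < 2L) {
    warning("single column: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probe-level rows to gene-level rows
#'
#' Each gene's row is the arithmetic mean of the rows of its probes.
#' Probes absent from the map are dropped and counted.
#'
#' @param m Numeric matrix, probes as rows (rownames = probe ids).
#' @param probe_map Data frame with columns `probe_id`, `gene_id`; a probe
#'   may not map to two genes.
#' @param quiet Suppress the dropped-probe message.
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(m, probe_map, quiet = FALSE) {
  m <- as.matrix(m)
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  pm <- unique(probe_map[, c("probe_id", "gene_id")])
  if (anyDuplicated(pm$probe_id)) {
    stop("probe(s) mapped to more than one gene: ",
         paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "),
         call. = FALSE)
  }
  probes <- rownames(m)
  if (is.null(probes)) stop("matrix must carry probe ids as rownames",
                            call. = FALSE)
  keep <- probes %in% pm$probe_id
  if (!any(keep)) {
    stop("no probes in common between matrix and probe map", call. = FALSE)
  }
  if (!quiet && any(!keep)) {
    message(sum(!keep), " unmapped probe(s) dropped")
  }
  msub <- m[keep, , drop = FALSE]
  genes <- pm$gene_id[match(rownames(msub), pm$probe_id)]
  sums <- rowsum(msub, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Map a gene list through a homology table
#'
#' Inner join of `genes` with a source-to-target homology table (direction
#' declared by the table's column order).  One-to-many pairs expand with a
#' warning; duplicated pairs are deduplicated; unmapped genes are logged.
#'
#' @param genes Character vector of source-species gene ids.
#' @param homology Data frame with columns `source`, `target`.
#' @param quiet Suppress the unmapped-gene message.
#' @return Character vector of mapped target gene ids (unique, input order).
#' @export
map_homologs <- function(genes, homology, quiet = FALSE) {
  stopifnot(all(c("source", "target") %in% names(homology)))
  genes <- as.character(genes)
  if (length(genes) == 0L) return(character())
  hm <- unique(homology[, c("source", "target")])
  hit <- genes %in% hm$source
  if (!quiet && any(!hit)) {
    message(sum(!hit), " gene(s) without homolog dropped")
  }
  multi <- intersect(genes, hm$source[duplicated(hm$source)])
  if (length(multi) > 0L) {
    warning(length(multi), " gene(s) map to multiple homologs; expanding")
  }
  out <- hm$target[hm$source %in% genes]
  unique(out[order(match(hm$source[hm$source %in% genes], genes))])
}
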