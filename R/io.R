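# Readers and writers for the plain-text formats the pipeline consumes.

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column holds gene (or probe) ids; remaining header fields are
#' sample ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 1L) stop("malformed expression file: no columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")   # NAs validated just below
  bad <- which(apply(m, 1L, function(r) any(is.na(r))))
  if (length(bad) > 0L) {
    stop("non-numeric or missing value(s) in expression file at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write an expression (or any numeric) matrix to TSV
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Header name of the id column.
#' @export
write_expression_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata (sample id + grade label) from TSV
#'
#' @param path File path; requires columns `sample_id` and `grade`.
#' @return Data frame with character columns `sample_id`, `grade`.
#' @export
read_metadata_tsv <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (!all(c("sample_id", "grade") %in% names(df))) {
    stop("metadata file must have columns 'sample_id' and 'grade'",
         call. = FALSE)
  }
  df[, c("sample_id", "grade")]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then member gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT line(s): ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Read a BED-like peak file with M-values
#'
#' Tab-separated with header `chrom`, `start`, `end`, `m_value`; 0-based
#' half-open coordinates.
#'
#' @param path File path.
#' @return Data frame validated against `start < end` and finite M-values.
#' @export
read_peaks <- function(path) {
  df <- .read_tsv(path)
  need <- c("chrom", "start", "end", "m_value")
  if (!all(need %in% names(df))) {
    stop("peak file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  bad <- which(df$start >= df$end | !is.finite(df$m_value))
  if (length(bad) > 0L) {
    stop("invalid peak record(s) at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read promoter/TSS annotations from TSV or GTF
#'
#' A `.tsv` file must have columns `gene_id`, `chrom`, `tss` (0-based),
#' `strand`.  A `.gtf`/`.gff` file is parsed via `rtracklayer`; the TSS of
#' each gene is taken strand-aware from its first `transcript` record
#' (falling back to `gene` records): the interval start for `+` genes and
#' the interval end for `-` genes, converted to a 0-based coordinate.
#'
#' @param path File path.
#' @return Data frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_promoters <- function(path) {
  if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF promoters requires the 'rtracklayer' package",
           call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    type <- as.character(gr$type)
    use <- gr[type == "transcript"]
    if (length(use) == 0L) use <- gr[type == "gene"]
    if (length(use) == 0L) use <- gr
    df <- data.frame(gene_id = as.character(use$gene_id),
                     chrom = as.character(GenomicRanges::seqnames(use)),
                     start = GenomicRanges::start(use),
                     end = GenomicRanges::end(use),
                     strand = as.character(GenomicRanges::strand(use)),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start - 1L)
    out <- df[, c("gene_id", "chrom", "tss", "strand")]
    rownames(out) <- NULL
    return(out)
  }
  df <- .read_tsv(path)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop("promoter TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-") | !is.finite(df$tss))
  if (length(bad) > 0L) {
    stop("invalid promoter record(s) at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Write a result table to TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
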