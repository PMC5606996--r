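# Ordinal phenotype container and grade mapping

#' Construct an ordinal phenotype
#'
#' Holds one ordered category label per sample, coded as integers `0..k`.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param grades Integer grades in `0..k`, one per sample.
#' @param level_labels Ordered display names, length `k + 1`.
#' @return An object of class `"ordinal_phenotype"`.
#' @export
ordinal_phenotype <- function(sample_ids, grades,
                              level_labels = as.character(sort(unique(grades)))) {
  sample_ids <- as.character(sample_ids)
  grades <- as.integer(grades)
  stopifnot(length(sample_ids) == length(grades), !anyNA(grades))
  k <- length(level_labels) - 1L
  if (any(grades < 0L) || any(grades > k)) {
    stop("grades must lie in 0..", k, call. = FALSE)
  }
  if (length(unique(grades)) < 2L) {
    stop("at least 2 distinct grade levels required", call. = FALSE)
  }
  structure(list(sample_ids = sample_ids, grades = grades,
                 level_labels = as.character(level_labels)),
            class = "ordinal_phenotype")
}

#' @export
print.ordinal_phenotype <- function(x, ...) {
  cat("Ordinal phenotype:", length(x$sample_ids), "samples,",
      length(x$level_labels), "ordered levels\n")
  tab <- table(factor(x$grades, levels = seq_along(x$level_labels) - 1L,
                      labels = x$level_labels))
  print(tab)
  invisible(x)
}

#' @export
length.ordinal_phenotype <- function(x) length(x$sample_ids)

#' Map raw clinical grade labels to ordinal categories
#'
#' Applies an order-preserving mapping from raw labels (e.g. Vonsattel
#' grades plus controls) to contiguous integer categories `0..k`.  The
#' *order of the names* of `mapping` states the intended clinical order;
#' mapped values must be nondecreasing in that order, so an entry that sends
#' a later label below an earlier one is rejected.  Non-contiguous mapped
#' values are recoded to `0..k` preserving order.
#'
#' @param raw_grades Character vector of raw labels, one per sample.
#' @param mapping Named integer vector or named list, label -> category, in
#'   clinical order.
#' @param sample_ids Optional sample identifiers (default `names(raw_grades)`
#'   or `sample_1..n`).
#' @param quiet Suppress the per-level count message.
#' @return An [ordinal_phenotype()].
#' @examples
#' map_grades(c("control", "g2", "g1"),
#'            c(control = 0, g1 = 1, g2 = 2, g3 = 3))$grades # 0 2 1
#' @export
map_grades <- function(raw_grades, mapping, sample_ids = NULL, quiet = FALSE) {
  mapping <- unlist(mapping)
  if (is.null(names(mapping)) || anyNA(names(mapping))) {
    stop("'mapping' must be named", call. = FALSE)
  }
  if (any(diff(as.numeric(mapping)) < 0)) {
    stop("order-violating mapping: mapped categories must be nondecreasing ",
         "in the stated label order", call. = FALSE)
  }
  raw_grades <- as.character(raw_grades)
  if (is.null(sample_ids)) {
    sample_ids <- names(raw_grades)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_along(raw_grades))
  }
  miss <- !(raw_grades %in% names(mapping))
  if (any(miss)) {
    stop("unmapped grade label(s) for sample(s): ",
         paste(sample_ids[miss], collapse = ", "), call. = FALSE)
  }
  vals <- as.integer(mapping[raw_grades])
  lv <- sort(unique(as.integer(mapping)))
  grades <- match(vals, lv) - 1L
  labels <- vapply(lv, function(v) {
    paste(names(mapping)[mapping == v], collapse = "/")
  }, character(1))
  ph <- ordinal_phenotype(sample_ids, grades, labels)
  if (!quiet) {
    cnt <- table(factor(grades, levels = seq_along(labels) - 1L))
    message("grade levels (", paste(labels, collapse = " < "), "): counts ",
            paste(cnt, collapse = "/"))
  }
  ph
}

#' Default Huntington's disease grade mapping
#'
#' A configurable default collapsing controls and Vonsattel grades 0-4 into
#' four ordered categories: controls, grades 0-1, grade 2, grades 3-4.
#' This grouping is an assumption of the package, exposed so it can be
#' edited or replaced wholesale.
#'
#' @return Named integer vector suitable for [map_grades()].
#' @export
default_hd_mapping <- function() {
  c(control = 0L, grade_0 = 1L, grade_1 = 1L,
    grade_2 = 2L, grade_3 = 3L, grade_4 = 3L)
}
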