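# Seedable generators with the statistical structure each analysis stage
# assumes.  All cohort-level defaults mirror the postmortem caudate study
# design the screen targets: 70 samples (32 controls + 38 patients split
# over three disease strata), four ordered severity levels, a small
# fraction of truly associated genes.

#' Simulate an expression cohort with an ordinal phenotype
#'
#' Generates a gene x sample matrix and a shared ordinal grade vector under
#' the cumulative-probit generative model.  A latent severity `s ~ N(0, 1)`
#' is drawn once per sample and cut at thresholds `tau` (from
#' `grade_probs`, or supplied via `alphas`) to give the shared grades.  For
#' an associated gene with slope `beta`, expression is
#' `x = mu + rho s + sqrt(1 - rho^2) eps` with `rho = beta / sqrt(1 +
#' beta^2)`, which is exactly the latent-variable relation `z* = beta (x -
#' mu) + eps'` cut at `alpha_i = tau_i sqrt(1 + beta^2)`: the conditional
#' of grade given expression is the cumulative probit model with the
#' recorded `beta`.  Null genes are independent of grade.  Gene-level
#' means are drawn uniformly on `mean_range` (log2 microarray scale), so
#' fitted intercepts sit far from zero as in real data.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (default 70).
#' @param n_levels Number of ordered severity levels (default 4).
#' @param pag_fraction Fraction of genes truly associated (default 0.045).
#' @param beta_range Magnitude range for true slopes; signs are random
#'   (default `c(1.5, 3)`).
#' @param alphas Optional latent severity thresholds (`n_levels - 1`,
#'   increasing); overrides `grade_probs`.
#' @param grade_probs Marginal probability of each level.  For 4 levels the
#'   default is `c(0.457, 0.181, 0.181, 0.181)`, mirroring 32 controls and
#'   38 patients split evenly over three disease strata; otherwise equal
#'   probabilities.
#' @param mean_range Range of gene mean expression (default `c(6, 12)`).
#' @param seed RNG seed; the same seed reproduces the cohort bit-for-bit.
#' @return List with `expr` (matrix), `phenotype`
#'   ([ordinal_phenotype()]) and `truth` (data frame: `gene_id`, `beta`,
#'   `is_pag`, `mu`, plus per-gene implied intercepts as a matrix
#'   attribute `"alphas"`; latent thresholds in attribute `"tau"`).
#' @export
simulate_ordinal_cohort <- function(n_genes, n_samples = 70, n_levels = 4,
                                    pag_fraction = 0.045,
                                    beta_range = c(1.5, 3),
                                    alphas = NULL, grade_probs = NULL,
                                    mean_range = c(6, 12), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_levels >= 2, pag_fraction >= 0, pag_fraction <= 1)
  k <- n_levels - 1L
  if (!is.null(alphas)) {
    if (length(alphas) != k || any(diff(alphas) <= 0)) {
      stop("'alphas' must be increasing with length n_levels - 1",
           call. = FALSE)
    }
    tau <- alphas
  } else {
    if (is.null(grade_probs)) {
      grade_probs <- if (n_levels == 4L) c(0.457, 0.181, 0.181, 0.181) else
        rep(1 / n_levels, n_levels)
    }
    if (length(grade_probs) != n_levels || any(grade_probs <= 0)) {
      stop("'grade_probs' must have n_levels positive entries", call. = FALSE)
    }
    grade_probs <- grade_probs / sum(grade_probs)
    tau <- stats::qnorm(cumsum(grade_probs)[seq_len(k)])
  }
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  s <- stats::rnorm(n_samples)
  grades <- findInterval(s, tau)           # 0..k: grade i iff tau_i < s
  # guarantee >= 2 observed levels for a usable phenotype
  if (length(unique(grades)) < 2L && n_samples >= 2L) {
    grades[1L] <- if (grades[2L] == 0L) 1L else 0L
  }
  gene_ids <- sprintf("gene_%05d", seq_len(max(n_genes, 0L)))
  if (n_genes == 0L) {
    expr <- matrix(numeric(), nrow = 0L, ncol = n_samples,
                   dimnames = list(NULL, sample_ids))
    truth <- data.frame(gene_id = character(), beta = numeric(),
                        is_pag = logical(), mu = numeric(),
                        stringsAsFactors = FALSE)
    attr(truth, "tau") <- tau
    return(list(expr = expr,
                phenotype = ordinal_phenotype(sample_ids, grades,
                                              as.character(seq_len(n_levels) - 1L)),
                truth = truth))
  }
  n_pag <- round(n_genes * pag_fraction)
  is_pag <- rep(FALSE, n_genes)
  if (n_pag > 0L) is_pag[sample.int(n_genes, n_pag)] <- TRUE
  beta <- numeric(n_genes)
  beta[is_pag] <- sample(c(-1, 1), n_pag, replace = TRUE) *
    stats::runif(n_pag, beta_range[1L], beta_range[2L])
  mu <- stats::runif(n_genes, mean_range[1L], mean_range[2L])
  rho <- beta / sqrt(1 + beta^2)
  noise <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  expr <- mu + rho %o% s + sqrt(1 - rho^2) * noise
  dimnames(expr) <- list(gene_ids, sample_ids)
  truth <- data.frame(gene_id = gene_ids, beta = beta, is_pag = is_pag,
                      mu = mu, stringsAsFactors = FALSE)
  attr(truth, "tau") <- tau
  attr(truth, "alphas") <- outer(sqrt(1 + beta^2), tau) + beta * mu
  list(expr = expr,
       phenotype = ordinal_phenotype(sample_ids, grades,
                                     as.character(seq_len(n_levels) - 1L)),
       truth = truth)
}

#' Simulate a two-group expression experiment
#'
#' Gaussian log-expression with a fraction of genes mean-shifted between
#' the two groups, supporting the differential-test machinery.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (default 10).
#' @param de_fraction Fraction of truly differential genes (default 0.1).
#' @param effect_size Mean shift of differential genes in units of the
#'   within-group SD (default 2); signs random.
#' @param sd Within-group standard deviation (default 1).
#' @param seed RNG seed.
#' @return List with `expr` (matrix), `labels` (character, `"control"` /
#'   `"disease"`) and `truth` (data frame: `gene_id`, `is_de`, `shift`).
#' @export
simulate_two_groups <- function(n_genes, n_per_group = 10, de_fraction = 0.1,
                                effect_size = 2, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(c("control", "disease"), each = n_per_group)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  n_de <- round(n_genes * de_fraction)
  is_de <- rep(FALSE, n_genes)
  if (n_de > 0L) is_de[sample.int(n_genes, n_de)] <- TRUE
  shift <- numeric(n_genes)
  shift[is_de] <- sample(c(-1, 1), n_de, replace = TRUE) * effect_size * sd
  expr <- matrix(stats::rnorm(n_genes * 2 * n_per_group, sd = sd),
                 n_genes, 2 * n_per_group)
  expr[, labels == "disease"] <- expr[, labels == "disease"] + shift
  dimnames(expr) <- list(gene_ids,
                         paste0(labels, "_", sequence(c(n_per_group,
                                                        n_per_group))))
  list(expr = expr, labels = labels,
       truth = data.frame(gene_id = gene_ids, is_de = is_de, shift = shift,
                          stringsAsFactors = FALSE))
}

#' Simulate a promoter/peak landscape with known per-gene scores
#'
#' Places gene TSSs far apart on one chromosome, drops a random number of
#' signal peaks inside each promoter window and decoy peaks outside every
#' window, and records the true summed M-value per gene.
#'
#' @param n_genes Number of genes.
#' @param peaks_per_gene_lambda Poisson mean of in-window peaks per gene
#'   (default 2).
#' @param decoys_per_gene Decoy peaks per gene placed outside all windows
#'   (default 1).
#' @param m_value_mean,m_value_sd Normal parameters of peak M-values
#'   (default 0.5, 1).
#' @param window Promoter half-width used for placement (default 10000).
#' @param seed RNG seed.
#' @return List with `peaks` (data frame), `promoters` (data frame) and
#'   `truth` (data frame: `gene_id`, `true_score`, `n_peaks`).
#' @export
simulate_peak_landscape <- function(n_genes, peaks_per_gene_lambda = 2,
                                    decoys_per_gene = 1,
                                    m_value_mean = 0.5, m_value_sd = 1,
                                    window = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  spacing <- as.integer(window * 25)
  tss <- 5L * window + spacing * (seq_len(n_genes) - 1L)
  promoters <- data.frame(gene_id = gene_ids, chrom = "chr1", tss = tss,
                          strand = sample(c("+", "-"), n_genes, replace = TRUE),
                          stringsAsFactors = FALSE)
  peak_rows <- list()
  true_score <- numeric(n_genes)
  n_in <- integer(n_genes)
  width <- 200L
  for (g in seq_len(n_genes)) {
    np <- stats::rpois(1L, peaks_per_gene_lambda)
    n_in[g] <- np
    if (np > 0L) {
      # fully inside [tss - window, tss + window)
      st <- tss[g] - window +
        floor(stats::runif(np, 0, 2 * window - width))
      m <- stats::rnorm(np, m_value_mean, m_value_sd)
      true_score[g] <- sum(m)
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(chrom = "chr1", start = st, end = st + width, m_value = m,
                   stringsAsFactors = FALSE)
    }
    if (decoys_per_gene > 0L) {
      # midway between windows: > window away from every TSS
      st <- tss[g] + spacing %/% 2L +
        floor(stats::runif(decoys_per_gene, 0, window))
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(chrom = "chr1", start = st, end = st + width,
                   m_value = stats::rnorm(decoys_per_gene, m_value_mean,
                                          m_value_sd),
                   stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               m_value = numeric(), stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  list(peaks = peaks, promoters = promoters,
       truth = data.frame(gene_id = gene_ids, true_score = true_score,
                          n_peaks = n_in, stringsAsFactors = FALSE))
}
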