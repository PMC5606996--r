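# Promoter-window peak assignment, H3K9ac score, interaction effect.

test_that("peak assignment respects half-open window boundaries", {
  prom <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000,
                     strand = "+")
  peaks <- data.frame(
    chrom = "chr1",
    start = c(89950, 110000, 89900, 109990),
    end   = c(90010, 110100, 90000, 110050),
    m_value = c(1, 1, 1, 1))
  got <- assign_peaks(peaks, prom, window = 10000)
  # [89950, 90010) touches the window start; [110000, ...) is excluded by
  # the half-open end; [89900, 90000) ends before the window; [109990, ...)
  # straddles the end and is included
  expect_equal(got$g1, c(1L, 4L))
})

test_that("peak assignment equals the brute-force all-pairs oracle", {
  set.seed(91)
  n_peaks <- 200; n_genes <- 50
  chroms <- c("chr1", "chr2")
  prom <- data.frame(gene_id = sprintf("g%02d", 1:n_genes),
                     chrom = sample(chroms, n_genes, replace = TRUE),
                     tss = sample(20000:300000, n_genes),
                     strand = sample(c("+", "-"), n_genes, TRUE))
  st <- sample(0:320000, n_peaks)
  peaks <- data.frame(chrom = sample(chroms, n_peaks, replace = TRUE),
                      start = st, end = st + sample(50:5000, n_peaks, TRUE),
                      m_value = rnorm(n_peaks))
  # exercise exact boundary cases too
  peaks$start[1] <- prom$tss[1] + 10000; peaks$end[1] <- peaks$start[1] + 100
  peaks$chrom[1] <- prom$chrom[1]
  peaks$start[2] <- prom$tss[2] - 10100; peaks$end[2] <- prom$tss[2] - 10000
  peaks$chrom[2] <- prom$chrom[2]
  expect_identical(assign_peaks(peaks, prom), assign_oracle(peaks, prom))
})

test_that("assignment warns and returns empty on chromosome mismatch", {
  prom <- data.frame(gene_id = "g", chrom = "chr1", tss = 5000, strand = "+")
  peaks <- data.frame(chrom = "1", start = 4000, end = 4500, m_value = 1)
  expect_warning(got <- assign_peaks(peaks, prom), "chromosome")
  expect_length(got$g, 0L)
  expect_error(assign_peaks(data.frame(chrom = "chr1", start = 10, end = 5,
                                       m_value = 1), prom), "start < end")
})

test_that("the H3K9ac score sums assigned M-values", {
  prom <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                     tss = c(50000, 200000, 400000), strand = "+")
  peaks <- data.frame(chrom = "chr1",
                      start = c(49000, 51000, 52000, 199000),
                      end = c(49500, 51500, 52500, 199500),
                      m_value = c(0.5, -0.2, 1.0, 1.2))
  sc <- h3k9ac_score(assign_peaks(peaks, prom), peaks)
  expect_equal(sc[["a"]], 1.3)
  expect_equal(sc[["b"]], 1.2)
  expect_false("c" %in% names(sc))   # no peaks: excluded from candidates
  # additivity: splitting a peak into adjacent halves preserves the score
  split_peaks <- rbind(peaks[-3, ],
                       data.frame(chrom = "chr1", start = c(52000, 52250),
                                  end = c(52250, 52500),
                                  m_value = c(0.4, 0.6)))
  sc2 <- h3k9ac_score(assign_peaks(split_peaks, prom), split_peaks)
  expect_equal(sc2[["a"]], sc[["a"]])
})

test_that("scores on a simulated landscape match the recorded truth", {
  land <- simulate_peak_landscape(25, decoys_per_gene = 0, seed = 7)
  sc <- h3k9ac_score(assign_peaks(land$peaks, land$promoters), land$peaks)
  with_peaks <- land$truth[land$truth$n_peaks > 0, ]
  expect_setequal(names(sc), with_peaks$gene_id)
  expect_equal(unname(sc[with_peaks$gene_id]), with_peaks$true_score)
  # decoys only: every score absent
  land0 <- simulate_peak_landscape(10, peaks_per_gene_lambda = 0,
                                   decoys_per_gene = 2, seed = 8)
  sc0 <- h3k9ac_score(assign_peaks(land0$peaks, land0$promoters), land0$peaks)
  expect_length(sc0, 0L)
  # mixed landscape: decoys never perturb the in-window truth
  land2 <- simulate_peak_landscape(25, decoys_per_gene = 2, seed = 9)
  sc2 <- h3k9ac_score(assign_peaks(land2$peaks, land2$promoters), land2$peaks)
  wp2 <- land2$truth[land2$truth$n_peaks > 0, ]
  expect_equal(unname(sc2[wp2$gene_id]), wp2$true_score)
})

test_that("the interaction effect and its z-score follow the formula", {
  expect_equal(interaction_effect(c(0, 1), c(0, 0))$ie, c(1, 0))
  one <- interaction_effect(c(1, 0), c(2, 0))
  expect_equal(one$ie[one$gene_id == "gene_1"], 1 + 2 + 2) # = 5
  tab <- interaction_effect(c(0, 5, 10), c(0, 0, 0),
                            gammas = c(0, 1, 1, 1), gene_ids = c("a", "b", "c"))
  # ie = (0, 5, 10) standardized with population SD
  expect_equal(sort(tab$ie), c(0, 5, 10))
  expect_equal(sort(tab$ie_z), c(-5, 0, 5) / sqrt(50 / 3), tolerance = 1e-12)
  # strictly positive z required: the central gene is NOT selected
  expect_equal(tab$gene_id[tab$selected], "c")
  expect_equal(tab$rank, 1:3)
  expect_error(interaction_effect(1, 2), "at least 2")
})

test_that("the selected set is invariant to affine rescalings of IE", {
  set.seed(15)
  x1 <- runif(30, -1, 3); x2 <- runif(30, -0.5, 2)
  base <- interaction_effect(x1, x2)
  for (a in c(0.2, 1, 7)) {
    scaled <- interaction_effect(x1, x2, gammas = c(0, a, a, a))
    expect_equal(scaled$selected[match(base$gene_id, scaled$gene_id)],
                 base$selected)
    shifted <- interaction_effect(x1, x2, gammas = c(5.5, a, a, a))
    expect_equal(shifted$selected[match(base$gene_id, shifted$gene_id)],
                 base$selected)
  }
})

test_that("gamma robustness is deterministic and honours scaling invariance", {
  set.seed(3)
  x1 <- c(runif(12, 2, 3), runif(12, 0.05, 0.2))
  x2 <- c(runif(12, 1.5, 2.5), runif(12, 0.05, 0.2))
  # common positive scaling of (g1, g2, g3) with g0 = 0 never changes the set
  expect_equal(gamma_robustness(x1, x2, sampler = function() 2.5 * c(1, 1, 1),
                                seed = 1), 1.0)
  f1 <- gamma_robustness(x1, x2, n_iter = 50, seed = 42)
  f2 <- gamma_robustness(x1, x2, n_iter = 50, seed = 42)
  expect_identical(f1, f2)
  # well-separated candidates are stable under random gammas
  expect_gte(f1, 0.9)
})
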