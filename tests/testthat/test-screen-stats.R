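# Screen scoring: normalization, enrichment scores, gene scores, Poisson and
# Fisher statistics, Bonferroni correction and ranking.

test_that("normalization divides by the matched library reads per lane", {
  m <- toy_manifest(3)
  cm <- toy_counts(matrix(c(2L, 3L, 5L), 3, 1,
                          dimnames = list(m$guide_id, "rep1_pos")))
  norm <- normalize_counts(cm)
  expect_equal(unname(norm$values[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(norm$values)), 1, tolerance = 1e-12)
  # depth invariance
  cm2 <- toy_counts(2L * cm$counts)
  expect_equal(normalize_counts(cm2)$values, norm$values)
  # single guide owning the lane
  one <- toy_counts(matrix(10L, 1, 1, dimnames = list(m$guide_id[1], "rep1_pos")))
  expect_equal(unname(normalize_counts(one)$values[1, 1]), 1.0)

  zero <- toy_counts(matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 3, 2,
                            dimnames = list(m$guide_id, c("rep1_pos", "rep1_neg"))))
  expect_error(normalize_counts(zero), "rep1_pos")
})

test_that("enrichment scores apply the depletion floor and cap and average geometrically", {
  m <- toy_manifest(3)
  counts <- matrix(c(0L, 4L, 8L,    # pos: first guide fully depleted
                     5L, 0L, 4L),   # neg: second guide absent
                   3, 2, dimnames = list(m$guide_id, c("rep1_pos", "rep1_neg")))
  suppressMessages(et <- enrichment_scores(normalize_counts(toy_counts(counts))))
  expect_identical(unname(et$ratios[1, 1]), 1e-3)
  expect_identical(unname(et$ratios[2, 1]), 1e3)
  expect_true(et$floored[1, 1] && et$capped[2, 1])

  # geometric mean: equal ratios are a fixed point; (1, 2, 4) averages to 2
  counts3 <- cbind(rep1_pos = c(10L, 10L), rep1_neg = c(10L, 10L),
                   rep2_pos = c(20L, 10L), rep2_neg = c(10L, 10L),
                   rep3_pos = c(40L, 10L), rep3_neg = c(10L, 10L))
  rownames(counts3) <- c("gene0001.1", "gene0002.1")
  norm3 <- normalize_counts(toy_counts(counts3))
  et3 <- enrichment_scores(norm3)
  # normalization makes lanes sum to one, so use the ratio of fractions
  expect_equal(unname(et3$aes[2]),
               geometric_mean(et3$ratios[2, ]))
  r <- et3$ratios[1, ] / et3$ratios[2, ]   # depth-free contrast: (1, 2, 4)
  expect_equal(unname(r), c(1, 2, 4))
  expect_equal(unname(et3$aes[1] / et3$aes[2]), 2)

  bad <- toy_counts(matrix(1L, 3, 1, dimnames = list(m$guide_id, "rep1_pos")))
  expect_error(enrichment_scores(normalize_counts(bad)), "exactly one pos and one neg")
})

test_that("AES is invariant to lane depth and flips under gate swap", {
  m <- build_manifest(10, c(1, 2), seed = 51)
  sim <- simulate_screen(m, screen_sim_params(
    n_replicates = 3, n_cells = 5000, reads_per_sample = 5000, seed = 52))
  et <- enrichment_scores(normalize_counts(sim$counts))
  scaled <- sim$counts$counts
  scaled[, "rep2_pos"] <- scaled[, "rep2_pos"] * 7L
  et_scaled <- enrichment_scores(normalize_counts(count_matrix(scaled)))
  expect_equal(et_scaled$aes, et$aes)

  swapped <- sim$counts$counts
  colnames(swapped) <- sub("pos$", "tmp", colnames(swapped))
  colnames(swapped) <- sub("neg$", "pos", colnames(swapped))
  colnames(swapped) <- sub("tmp$", "neg", colnames(swapped))
  et_swap <- enrichment_scores(normalize_counts(count_matrix(swapped)))
  nonzero <- rowSums(sim$counts$counts == 0L) == 0L
  expect_equal(et_swap$aes[nonzero], 1 / et$aes[nonzero])
  # single-guide genes: exact log-score sign flip
  gs <- gene_scores(et, m)$genes
  gs_swap <- gene_scores(et_swap, m)$genes
  single <- gs$n_guides == 1 & nonzero[match(paste0(gs$gene_id, ".1"),
                                             rownames(sim$counts$counts))]
  expect_equal(gs_swap$log_gene_score[single], -gs$log_gene_score[single])
})

test_that("gene scores sum guide AES and report the natural log", {
  m <- data.frame(guide_id = c("a.1", "a.2", "a.3", "b.1", "c.1"),
                  gene_id = c("a", "a", "a", "b", "CTRL"),
                  guide_seq = random22(5), is_control = c(F, F, F, F, T),
                  stringsAsFactors = FALSE)
  et <- structure(list(guide_id = m$guide_id,
                       ratios = matrix(c(1, 2, 3, exp(1), 5), 5, 1),
                       aes = c(1, 2, 3, exp(1), 5),
                       floored = matrix(FALSE, 5, 1),
                       capped = matrix(FALSE, 5, 1)),
                  class = "enrichment_table")
  gs <- gene_scores(et, m)
  a <- gs$genes[gs$genes$gene_id == "a", ]
  expect_equal(a$gene_score, 6)
  expect_equal(a$log_gene_score, log(6))
  expect_equal(a$n_guides, 3L)
  b <- gs$genes[gs$genes$gene_id == "b", ]
  expect_equal(b$log_gene_score, 1)               # AES = e
  # controls reported separately, never scored
  expect_false("CTRL" %in% gs$genes$gene_id)
  expect_equal(gs$controls$aes, 5)
  # mean mode differs by log(n_guides)
  gm <- gene_scores(et, m, mode = "mean")$genes
  expect_equal(gm$log_gene_score[gm$gene_id == "a"], log(6) - log(3))

  et$guide_id[1] <- "zz.9"
  expect_error(gene_scores(et, m), "zz.9")
})

test_that("Poisson P-values match the series-summation oracle", {
  m <- toy_manifest(3)
  counts <- cbind(rep1_pos = c(10L, 0L, 90L), rep1_neg = c(5L, 5L, 90L))
  rownames(counts) <- m$guide_id
  p <- poisson_pvalues(toy_counts(counts))
  # equal depths: lambda for guide 1 is its neg count, 5; observed 10
  oracle <- 1 - sum(exp(-5) * 5^(0:9) / factorial(0:9))
  expect_equal(unname(p[1, 1]), oracle, tolerance = 1e-12)
  expect_equal(unname(p[2, 1]), 1)       # observed 0: upper tail is 1
  expect_true(all(p > 0 & p <= 1))

  # large equal counts sit near the Poisson median
  big <- cbind(rep1_pos = c(1000L, 1000L), rep1_neg = c(1000L, 1000L))
  rownames(big) <- m$guide_id[1:2]
  expect_lt(abs(unname(poisson_pvalues(toy_counts(big))[1, 1]) - 0.5), 0.05)

  # zero reference count floors lambda instead of zeroing it
  z <- cbind(rep1_pos = c(3L, 7L), rep1_neg = c(0L, 10L))
  rownames(z) <- m$guide_id[1:2]
  pz <- poisson_pvalues(toy_counts(z))
  lam <- 0.5
  expect_equal(unname(pz[1, 1]), 1 - sum(exp(-lam) * lam^(0:2) / factorial(0:2)))
})

test_that("Poisson P-values and AES respond monotonically to the positive count", {
  m <- toy_manifest(3)
  base <- cbind(rep1_pos = c(10L, 20L, 30L), rep1_neg = c(15L, 20L, 25L))
  rownames(base) <- m$guide_id
  aes_prev <- -Inf; p_prev <- Inf
  for (add in c(0L, 10L, 40L)) {
    counts <- base; counts[1, 1] <- counts[1, 1] + add
    cm <- toy_counts(counts)
    aes <- enrichment_scores(normalize_counts(cm))$aes[1]
    p <- poisson_pvalues(cm)[1, 1]
    expect_gte(aes, aes_prev); expect_lte(p, p_prev)
    aes_prev <- aes; p_prev <- p
  }
})

test_that("Fisher's method matches the even-df chi-squared survival oracle", {
  one <- fisher_combine(0.2)
  expect_equal(one$p_value, 0.2, tolerance = 1e-12)
  expect_equal(one$df, 2L)

  all1 <- fisher_combine(c(1, 1, 1))
  expect_equal(all1$statistic, 0)
  expect_equal(all1$p_value, 1)

  two <- fisher_combine(c(0.05, 0.05))
  expect_equal(two$statistic, -2 * 2 * log(0.05))
  expect_equal(two$df, 4L)
  expect_equal(two$p_value, chisq_even_df_survival(two$statistic, 4), tolerance = 1e-12)

  set.seed(61)
  for (i in 1:50) {
    k <- sample(1:8, 1)
    p <- runif(k)
    fc <- fisher_combine(p)
    expect_equal(fc$p_value, chisq_even_df_survival(fc$statistic, fc$df),
                 tolerance = 1e-10)
  }
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(1.2), "\\(0, 1\\]")
})

test_that("Fisher combination of uniform nulls is uniform (Monte-Carlo check)", {
  set.seed(62)
  combined <- replicate(2000, fisher_combine(runif(3))$p_value)
  d <- suppressWarnings(stats::ks.test(combined, "punif")$statistic)
  expect_lt(unname(d), 0.05)
})

test_that("gene-level combination pools guide x replicate tests with Bonferroni", {
  m <- data.frame(guide_id = c("a.1", "a.2", "b.1"),
                  gene_id = c("a", "a", "b"),
                  guide_seq = random22(3), is_control = FALSE,
                  stringsAsFactors = FALSE)
  pois <- matrix(c(0.01, 0.2, 0.5, 0.03, 0.4, 0.9), 3, 2,
                 dimnames = list(m$guide_id, c("rep1", "rep2")))
  gp <- gene_pvalues(pois, m)
  a <- gp[gp$gene_id == "a", ]
  expect_equal(a$fisher_df, 8L)                       # 2 guides x 2 reps x 2
  expect_equal(a$combined_p, fisher_combine(c(0.01, 0.2, 0.03, 0.4))$p_value)
  expect_equal(a$bonferroni_p, min(1, a$combined_p * 2))
  expect_true(all(gp$bonferroni_p <= 1))
  # the worked multiplication: p = 1e-4 over 1010 genes
  expect_equal(min(1, 1e-4 * 1010), 0.101)
  expect_equal(gene_pvalues(pois, m, m = 1)$combined_p,
               gene_pvalues(pois, m, m = 1)$bonferroni_p)
})

test_that("ranking orders by log score with documented tie-breaks", {
  scores <- data.frame(gene_id = c("a", "b", "c"), n_guides = 1L,
                       gene_score = c(2, 2, 0.5),
                       log_gene_score = log(c(2, 2, 0.5)),
                       stringsAsFactors = FALSE)
  pv <- data.frame(gene_id = c("a", "b", "c"),
                   fisher_statistic = 1, fisher_df = 2L,
                   combined_p = c(0.5, 0.01, 0.2),
                   bonferroni_p = c(1, 0.03, 0.6), stringsAsFactors = FALSE)
  tab <- rank_genes(scores, pv)
  expect_equal(tab$gene_id, c("b", "a", "c"))         # tie broken by smaller p
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$direction, c("positive", "positive", "negative"))
  expect_equal(tab$significance, -log10(tab$combined_p))

  single <- rank_genes(scores[1, ], pv[1, ])
  expect_equal(single$rank, 1L)
  expect_error(rank_genes(scores, pv[1:2, ]), "mismatched gene sets")
})

test_that("null screens centre log gene scores on zero", {
  m <- build_manifest(50, c(4, 6), n_controls = 4, seed = 71)
  sim <- simulate_screen(m, screen_sim_params(
    n_replicates = 5, n_cells = 550L * nrow(m), reads_per_sample = 2e5,
    hit_gene_fraction = 0, seed = 72))
  sc <- suppressMessages(score_screen(sim$counts, m))
  expect_lt(abs(mean(sc$gene_table$log_gene_score) -
                  log(mean(sc$gene_table$n_guides))), 0.15)
  # with the mean-mode score the centre is zero itself
  gs <- gene_scores(enrichment_scores(normalize_counts(sim$counts)), m,
                    mode = "mean")$genes
  expect_lt(abs(mean(gs$log_gene_score)), 0.1)
})
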