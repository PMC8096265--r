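# The synthetic-data generators: manifests, sorted screens, FASTQ, titrations
# and Cq tables.

test_that("manifest construction respects composition, invariants and seed", {
  m <- build_manifest(10, c(4, 6), n_controls = 3, seed = 11)
  expect_silent(validate_manifest(m))
  n_target <- sum(!m$is_control)
  expect_gte(n_target, 40)
  expect_lte(n_target, 60)
  expect_equal(sum(m$is_control), 3)
  expect_true(all(nchar(m$guide_seq) == 22))
  expect_false(any(m$gene_id[m$is_control] %in% m$gene_id[!m$is_control]))
  # deterministic under seed
  expect_identical(m, build_manifest(10, c(4, 6), n_controls = 3, seed = 11))
  expect_false(identical(m, build_manifest(10, c(4, 6), n_controls = 3, seed = 12)))

  one <- build_manifest(1, c(1, 1), n_controls = 0, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(length(unique(one$gene_id)), 1)

  expect_error(build_manifest(10, c(6, 4), seed = 1), "lower > upper")
  expect_error(build_manifest(10, c(4, 6)), "seed")
})

test_that("an exact target-guide total can be requested", {
  m <- build_manifest(100, c(4, 6), n_controls = 2, seed = 7, n_guides_total = 541)
  expect_equal(sum(!m$is_control), 541)
  counts <- table(m$gene_id[!m$is_control])
  expect_true(all(counts >= 4 & counts <= 6))
  expect_error(build_manifest(10, c(4, 6), seed = 1, n_guides_total = 100),
               "must lie in")
})

test_that("screen simulation is reproducible with fixed column sums and valid gates", {
  m <- build_manifest(10, c(2, 2), seed = 3)
  p <- screen_sim_params(n_replicates = 3, n_cells = 5000,
                         reads_per_sample = 20000, seed = 5)
  sim <- simulate_screen(m, p)
  expect_true(all(colSums(sim$counts$counts) == 20000))
  expect_equal(ncol(sim$counts$counts), 6)
  expect_identical(sim$counts$counts, simulate_screen(m, p)$counts$counts)
  # defaults sit inside the sorting windows used at the bench
  d <- screen_sim_params()
  expect_true(d$pos_gate_fraction >= 0.06 && d$pos_gate_fraction <= 0.08)
  expect_true(d$neg_gate_fraction >= 0.75 && d$neg_gate_fraction <= 0.80)
  expect_error(screen_sim_params(pos_gate_fraction = 0.4, neg_gate_fraction = 0.7),
               "overlap")
})

test_that("null screens are symmetric between the gates", {
  m <- build_manifest(20, c(2, 2), seed = 3)
  sim <- simulate_screen(m, screen_sim_params(
    n_replicates = 1, n_cells = 4e5, reads_per_sample = 4e5,
    hit_gene_fraction = 0, background_escape_prob = 0.07, seed = 9))
  ratio <- (sim$counts$counts[, "rep1_pos"] + 0.5) /
    (sim$counts$counts[, "rep1_neg"] + 0.5)
  expect_lt(abs(mean(log(ratio))), 0.05)
})

test_that("sorting probabilities match the closed-form oracle for a planted guide", {
  # one fully escaping guide among uniform background; gates take the top 7%
  # (entirely escapers) and bottom 77.5% (entirely silenced cells)
  G <- 50L
  m <- build_manifest(G, c(1, 1), seed = 13)
  n_cells <- 2e5; reads <- 1e5
  sim <- simulate_screen(m, screen_sim_params(
    n_replicates = 1, n_cells = n_cells, reads_per_sample = reads,
    hit_gene_fraction = 1 / G, hit_escape_prob = 1.0,
    background_escape_prob = 0.07, seed = 17))
  hit_guide <- sim$truth$guides$guide_id[sim$truth$guides$escape_prob == 1.0]
  expect_length(hit_guide, 1)

  p_bar <- (1 + 0.07 * (G - 1)) / G          # overall escaper fraction
  f_pos_hit <- (1 / G) / p_bar               # escaper-gate share of the hit
  obs <- sim$counts$counts[hit_guide, "rep1_pos"] / reads
  mc_se <- sqrt(f_pos_hit * (1 - f_pos_hit) * (1 / reads + 2 / (0.07 * n_cells)))
  expect_lt(abs(obs - f_pos_hit), 3 * mc_se)
  # a fully escaping guide leaves no silenced cells for the negative gate
  expect_equal(unname(sim$counts$counts[hit_guide, "rep1_neg"]), 0L)

  # background guides: pos:neg frequency ratio equals the sorting-probability ratio
  bg <- setdiff(rownames(sim$counts$counts), hit_guide)
  exp_ratio <- (0.07 / p_bar) / ((1 - 0.07) / (1 - p_bar))
  obs_ratio <- sum(sim$counts$counts[bg, "rep1_pos"]) /
    sum(sim$counts$counts[bg, "rep1_neg"])
  expect_lt(abs(obs_ratio / exp_ratio - 1), 0.05)
})

test_that("emitted FASTQ embeds each guide at the requested offset", {
  m <- toy_manifest(2)
  cm <- toy_counts(matrix(c(3L, 0L), 2, 1,
                          dimnames = list(m$guide_id, "rep1_pos")))
  d <- withr::local_tempdir()
  paths <- emit_fastq(cm, m, d, read_length = 60, guide_offset = 21, seed = 1)
  lines <- readLines(paths[["rep1_pos"]])
  expect_length(lines, 12)
  reads <- lines[seq(2, 12, by = 4)]
  expect_true(all(substr(reads, 21, 42) == m$guide_seq[1]))
  expect_true(all(nchar(reads) == 60))
  # identical seed, identical bytes
  d2 <- withr::local_tempdir()
  paths2 <- emit_fastq(cm, m, d2, read_length = 60, guide_offset = 21, seed = 1)
  expect_identical(readLines(paths2[["rep1_pos"]]), lines)
  expect_error(emit_fastq(cm, m, d, read_length = 30, guide_offset = 21),
               "too short")
})

test_that("titration simulation obeys the binding equation at zero noise", {
  s <- simulate_titration(82, 0.10, 0.05, c(0, 82), noise_sd = 0,
                          n_replicates = 1, seed = 1)
  expect_equal(s$signal[s$concentration_nM == 0], 0.05)
  expect_equal(s$signal[s$concentration_nM == 82], 0.05 + 0.10 / 2)
  expect_identical(simulate_titration(82, 0.1, 0.05, kd_grid, noise_sd = 0.01, seed = 4),
                   simulate_titration(82, 0.1, 0.05, kd_grid, noise_sd = 0.01, seed = 4))
  expect_error(simulate_titration(-1, 0.1, 0, c(0, 1, 2, 3)), "kd")
  expect_error(simulate_titration(82, 0.1, 0, c(3, 1, 2)), "sorted")
})

test_that("simulated Cq tables encode enrichment as cycles of the efficiency", {
  cq <- simulate_cq(true_enrichments = c(untreated = 1, treated = 4),
                    efficiency = 2, spike_recovery = 1, noise_sd = 0, seed = 2)
  s <- cq[cq$sample_id == "treated_rep1", ]
  adj_input <- s$cq[s$role == "input"] - log2(1 / 0.1)
  expect_equal(s$cq[s$role == "IP"], adj_input - 2)   # enrichment 4 = 2 cycles
  expect_setequal(unique(cq$role), c("IP", "input", "IgG", "spike_in"))
  expect_error(simulate_cq(roles = c("IP", "IgG")), "missing role")
  expect_error(simulate_cq(efficiency = 1), "efficiency")
})
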