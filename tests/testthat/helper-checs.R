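# Shared fixtures, built in code.

# a tiny deterministic manifest with explicit sequences
toy_manifest <- function(n = 3L, n_controls = 0L) {
  build_manifest(n, c(1L, 1L), n_controls = n_controls, seed = 42L)
}

# count matrix from a plain named matrix spec
toy_counts <- function(counts) {
  count_matrix(counts)
}

# independent survival oracle for chi-squared with even df = 2k:
# the Erlang upper tail exp(-x/2) * sum_{j<k} (x/2)^j / j!
chisq_even_df_survival <- function(x, df) {
  k <- df / 2
  j <- seq_len(k) - 1
  exp(-x / 2) * sum(exp(j * log(x / 2) - lgamma(j + 1)))
}

# throwaway 22-mers for hand-built manifests
random22 <- function(n) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = ""), "")
}

# single-site binding curve
binding_signal <- function(conc, bl, f, kd) bl + f * conc / (conc + kd)

kd_grid <- c(1, 2, 5, 10, 25, 50, 100, 250, 500, 1000, 1500, 2000)
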