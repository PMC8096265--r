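# Simulation of a FACS-sorted pooled shRNA reporter screen.

#' Parameters for a sorted-screen simulation
#'
#' Bundles and validates the tunables of [simulate_screen()]. The defaults are
#' the conditions of a five-replicate reporter screen: sorting gates at the
#' midpoints of the 6-8% (reporter-positive) and 75-80% (reporter-negative)
#' windows, library coverage of 550 cells per guide (30e6 cells at 10%
#' transduction over a 5459-guide library), and 2e6 reads per sorted sample.
#' A cell carrying a guide against a hit gene stays reporter-positive
#' ("escapes" silencing) with probability `hit_escape_prob`; all other cells
#' escape with `background_escape_prob`.
#'
#' @param n_replicates number of independent screen replicates.
#' @param n_cells cells per replicate; `NULL` means 550 per library guide.
#' @param pos_gate_fraction fraction of cells sorted into the reporter-positive
#'   gate (top of the latent reporter distribution); default 0.07.
#' @param neg_gate_fraction fraction sorted into the reporter-negative gate
#'   (bottom of the distribution); default 0.775.
#' @param hit_gene_fraction fraction of target genes planted as hits.
#' @param hit_escape_prob escape probability for cells carrying hit-gene guides.
#' @param background_escape_prob escape probability for all other guides
#'   (controls included).
#' @param reads_per_sample sequencing reads per sorted sample.
#' @param latent_noise_sd standard deviation of the Gaussian noise on the
#'   latent reporter value (escapers centred at 1, silenced cells at 0).
#' @param seed integer seed.
#' @return a list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_replicates = 5L,
                              n_cells = NULL,
                              pos_gate_fraction = 0.07,
                              neg_gate_fraction = 0.775,
                              hit_gene_fraction = 0.05,
                              hit_escape_prob = 0.9,
                              background_escape_prob = 0.05,
                              reads_per_sample = 2e6,
                              latent_noise_sd = 0.1,
                              seed = 1L) {
  check_count(n_replicates, "n_replicates")
  if (!is.null(n_cells)) check_count(n_cells, "n_cells")
  check_fraction(pos_gate_fraction, "pos_gate_fraction")
  check_fraction(neg_gate_fraction, "neg_gate_fraction")
  check_fraction(hit_gene_fraction, "hit_gene_fraction")
  check_fraction(hit_escape_prob, "hit_escape_prob")
  check_fraction(background_escape_prob, "background_escape_prob")
  check_count(reads_per_sample, "reads_per_sample")
  if (pos_gate_fraction + neg_gate_fraction > 1) {
    stop("gate fractions overlap: pos_gate_fraction + neg_gate_fraction > 1",
         call. = FALSE)
  }
  structure(list(n_replicates = as.integer(n_replicates), n_cells = n_cells,
                 pos_gate_fraction = pos_gate_fraction,
                 neg_gate_fraction = neg_gate_fraction,
                 hit_gene_fraction = hit_gene_fraction,
                 hit_escape_prob = hit_escape_prob,
                 background_escape_prob = background_escape_prob,
                 reads_per_sample = reads_per_sample,
                 latent_noise_sd = latent_noise_sd,
                 seed = seed),
            class = "screen_sim_params")
}

#' Simulate a FACS-sorted pooled shRNA screen
#'
#' For each replicate, cells are assigned guides uniformly at random; each
#' cell remains reporter-positive with its guide's escape probability. Cells
#' get a latent reporter value (1 for escapers, 0 for silenced, plus Gaussian
#' noise) and are sorted: the positive sample is the top `pos_gate_fraction`
#' of cells, the negative sample the bottom `neg_gate_fraction`. Read counts
#' per sample are a multinomial draw of `reads_per_sample` reads over the
#' guide frequencies of the gated cells (sequencing noise only; no PCR-bias
#' model).
#'
#' @param manifest library manifest (see [build_manifest()]).
#' @param params a [screen_sim_params()] object.
#' @return list with elements
#'   \describe{
#'     \item{counts}{a [count_matrix()] of guides x (replicate, population).}
#'     \item{truth}{ground truth: `genes` (gene_id, is_hit, escape_prob) and
#'       `guides` (guide_id, gene_id, is_control, escape_prob).}
#'   }
#' @examples
#' m <- build_manifest(5, c(2, 2), seed = 1)
#' sim <- simulate_screen(m, screen_sim_params(
#'   n_replicates = 2, n_cells = 2000, reads_per_sample = 5000, seed = 2))
#' colSums(sim$counts$counts)
#' @export
simulate_screen <- function(manifest, params = screen_sim_params()) {
  validate_manifest(manifest)
  stopifnot(inherits(params, "screen_sim_params"))
  n_guides <- nrow(manifest)
  n_cells <- if (is.null(params$n_cells)) 550L * n_guides else params$n_cells

  target_genes <- unique(manifest$gene_id[!manifest$is_control])
  with_seed(params$seed, {
    n_hits <- round(params$hit_gene_fraction * length(target_genes))
    hit_genes <- if (n_hits > 0) sample(target_genes, n_hits) else character(0)
    escape <- ifelse(!manifest$is_control & manifest$gene_id %in% hit_genes,
                     params$hit_escape_prob, params$background_escape_prob)

    n_pos <- round(params$pos_gate_fraction * n_cells)
    n_neg <- round(params$neg_gate_fraction * n_cells)
    counts <- matrix(0L, n_guides, 2L * params$n_replicates)
    sample_ids <- as.vector(t(outer(seq_len(params$n_replicates),
                                    c("pos", "neg"),
                                    function(r, p) paste0("rep", r, "_", p))))
    for (r in seq_len(params$n_replicates)) {
      g <- sample.int(n_guides, n_cells, replace = TRUE)
      escaper <- stats::runif(n_cells) < escape[g]
      latent <- as.numeric(escaper) +
        stats::rnorm(n_cells, 0, params$latent_noise_sd)
      ord <- order(latent, decreasing = TRUE)
      f_pos <- tabulate(g[ord[seq_len(n_pos)]], n_guides) / n_pos
      f_neg <- tabulate(g[ord[seq.int(n_cells - n_neg + 1L, n_cells)]],
                        n_guides) / n_neg
      counts[, 2L * r - 1L] <- stats::rmultinom(1L, params$reads_per_sample, f_pos)[, 1L]
      counts[, 2L * r]      <- stats::rmultinom(1L, params$reads_per_sample, f_neg)[, 1L]
    }
    dimnames(counts) <- list(manifest$guide_id, sample_ids)
    cm <- count_matrix(counts)
    truth <- list(
      genes = data.frame(gene_id = target_genes,
                         is_hit = target_genes %in% hit_genes,
                         escape_prob = ifelse(target_genes %in% hit_genes,
                                              params$hit_escape_prob,
                                              params$background_escape_prob),
                         stringsAsFactors = FALSE),
      guides = data.frame(guide_id = manifest$guide_id,
                          gene_id = manifest$gene_id,
                          is_control = manifest$is_control,
                          escape_prob = escape,
                          stringsAsFactors = FALSE))
    list(counts = cm, truth = truth)
  })
}
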