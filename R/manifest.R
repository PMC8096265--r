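# Guide library manifests: construction, validation and TSV I/O.

GUIDE_LENGTH <- 22L
CONTROL_GENE <- "CTRL"

#' Build a synthetic shRNA library manifest
#'
#' Generates a guide catalogue with the composition of a chromatin-focused
#' shRNAmir library: each target gene carries a number of guides drawn
#' uniformly from `guides_per_gene`, plus a set of neutral control shRNAs
#' filed under the reserved gene id `"CTRL"`. Guide strands are unique random
#' 22-nt sequences over A/C/G/T.
#'
#' When `n_guides_total` is given, the per-gene guide counts are first drawn
#' from the range and then adjusted one guide at a time (staying within the
#' range) until the number of target guides equals the requested total, so a
#' library of 1010 genes at 4-6 guides each can reproduce an exact published
#' composition such as 5451 target shRNAs plus 8 controls.
#'
#' @param n_genes number of target genes (>= 1).
#' @param guides_per_gene integer range `c(lower, upper)` of guides per gene.
#' @param n_controls number of control shRNA records.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param n_guides_total optional exact total of target (non-control) guides.
#' @return a `data.frame` with columns `guide_id`, `gene_id`, `guide_seq`
#'   (22-nt), `is_control` (logical).
#' @examples
#' m <- build_manifest(10, c(4, 6), n_controls = 2, seed = 1)
#' table(m$is_control)
#' @export
build_manifest <- function(n_genes, guides_per_gene = c(4L, 6L),
                           n_controls = 0L, seed, n_guides_total = NULL) {
  check_count(n_genes, "n_genes")
  if (length(guides_per_gene) == 1L) guides_per_gene <- rep(guides_per_gene, 2L)
  lo <- as.integer(guides_per_gene[1]); hi <- as.integer(guides_per_gene[2])
  if (is.na(lo) || is.na(hi) || lo < 1L) {
    stop("`guides_per_gene` bounds must be >= 1", call. = FALSE)
  }
  if (lo > hi) stop("invalid `guides_per_gene` range: lower > upper", call. = FALSE)
  if (n_controls < 0) stop("`n_controls` must be >= 0", call. = FALSE)
  if (missing(seed)) stop("`seed` must be given", call. = FALSE)

  with_seed(seed, {
    k <- if (lo == hi) rep(lo, n_genes) else sample(lo:hi, n_genes, replace = TRUE)
    if (!is.null(n_guides_total)) {
      if (n_guides_total < n_genes * lo || n_guides_total > n_genes * hi) {
        stop(sprintf("`n_guides_total` must lie in [%d, %d]",
                     n_genes * lo, n_genes * hi), call. = FALSE)
      }
      while (sum(k) > n_guides_total) {
        i <- sample(which(k > lo), 1L)
        k[i] <- k[i] - 1L
      }
      while (sum(k) < n_guides_total) {
        i <- sample(which(k < hi), 1L)
        k[i] <- k[i] + 1L
      }
    }
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    gene_col <- rep(gene_ids, k)
    guide_id <- paste0(gene_col, ".", unlist(lapply(k, seq_len), use.names = FALSE))
    if (n_controls > 0) {
      gene_col <- c(gene_col, rep(CONTROL_GENE, n_controls))
      guide_id <- c(guide_id, paste0("ctrl.", seq_len(n_controls)))
    }
    seqs <- random_guide_seqs(length(guide_id))
    data.frame(guide_id = guide_id, gene_id = gene_col, guide_seq = seqs,
               is_control = gene_col == CONTROL_GENE,
               stringsAsFactors = FALSE)
  })
}

# unique random 22-mers; regenerates the (vanishingly rare) duplicates
random_guide_seqs <- function(n) {
  draw <- function(m) {
    apply(matrix(sample(c("A", "C", "G", "T"), m * GUIDE_LENGTH, replace = TRUE),
                 nrow = m), 1L, paste0, collapse = "")
  }
  seqs <- draw(n)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- draw(length(dup))
  }
  seqs
}

#' Validate a library manifest
#'
#' Checks the manifest invariants: unique guide ids and sequences, 22-nt
#' sequences over A/C/G/T, and control records filed under the reserved
#' control gene id.
#'
#' @param manifest manifest `data.frame`.
#' @return the manifest, invisibly; errors describe the first violation.
#' @export
validate_manifest <- function(manifest) {
  need <- c("guide_id", "gene_id", "guide_seq", "is_control")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  if (anyDuplicated(manifest$guide_id)) {
    stop("duplicate guide_id: ",
         manifest$guide_id[duplicated(manifest$guide_id)][1], call. = FALSE)
  }
  if (anyDuplicated(manifest$guide_seq)) {
    stop("duplicate guide_seq for guide ",
         manifest$guide_id[duplicated(manifest$guide_seq)][1], call. = FALSE)
  }
  bad <- !grepl(sprintf("^[ACGT]{%d}$", GUIDE_LENGTH), manifest$guide_seq)
  if (any(bad)) {
    stop("guide_seq must be 22 nt over {A,C,G,T}; offending guide: ",
         manifest$guide_id[bad][1], call. = FALSE)
  }
  if (any(manifest$is_control & manifest$gene_id %in%
          manifest$gene_id[!manifest$is_control])) {
    stop("control records must use a reserved gene_id distinct from targets",
         call. = FALSE)
  }
  invisible(manifest)
}

#' Read / write a manifest TSV
#'
#' Tab-separated with header `guide_id  gene_id  guide_seq  is_control`.
#'
#' @param path file path.
#' @return `read_manifest()` returns the manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  m$is_control <- as.logical(m$is_control)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cells per guide at a given transduction
#'
#' Library-representation arithmetic for screen planning: the expected number
#' of transduced cells carrying each shRNA when `n_cells` are infected at
#' `transduction` efficiency over a library of `n_guides` constructs.
#'
#' @param n_cells number of cells infected.
#' @param transduction transduction efficiency (fraction of cells transduced).
#' @param n_guides library size.
#' @return expected cells per guide.
#' @examples
#' cells_per_guide(30e6, 0.10, 5459)
#' @export
cells_per_guide <- function(n_cells, transduction, n_guides) {
  check_count(n_cells, "n_cells")
  check_fraction(transduction, "transduction")
  check_count(n_guides, "n_guides")
  n_cells * transduction / n_guides
}
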