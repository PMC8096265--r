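# Screen scoring: per-lane normalization, enrichment scores with a depletion
# floor, gene scores, per-replicate Poisson tests, Fisher combination and
# Bonferroni-corrected gene P-values.

#' Normalize counts to the library-specific reads per lane
#'
#' Each sample (lane) column is divided by its total of matched library reads,
#' turning counts into per-guide fractions; unmatched reads are excluded from
#' the denominator.
#'
#' @param counts a [count_matrix()].
#' @return object of class `normalized_counts`: list with `values` (numeric
#'   matrix, columns summing to 1), `samples`, and the original `counts`.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tot <- colSums(counts$counts)
  if (any(tot == 0)) {
    stop("sample has no matched reads: ", names(tot)[tot == 0][1], call. = FALSE)
  }
  structure(list(values = sweep(counts$counts, 2L, tot, "/"),
                 samples = counts$samples, counts = counts$counts),
            class = "normalized_counts")
}

#' Per-guide enrichment scores across replicates
#'
#' For every replicate, the guide's normalized abundance in the
#' reporter-positive sample is divided by its abundance in the matched
#' reporter-negative sample. A ratio whose numerator count is zero (a fully
#' depleted guide) is set to the depletion `floor` of 1e-3; a ratio whose
#' denominator count is zero is set to the symmetric `cap`. The average
#' enrichment score (AES) is the geometric mean of the per-replicate ratios.
#'
#' @param norm a [normalize_counts()] result.
#' @param floor fold value assigned when the positive-population count is 0.
#' @param cap fold value assigned when the negative-population count is 0
#'   (and the positive count is not).
#' @return object of class `enrichment_table`: list with `guide_id`, `ratios`
#'   (guides x replicates), `aes`, and logical flag matrices `floored`,
#'   `capped`.
#' @export
enrichment_scores <- function(norm, floor = 1e-3, cap = 1e3) {
  stopifnot(inherits(norm, "normalized_counts"))
  reps <- sort(unique(norm$samples$replicate))
  pos_cols <- character(length(reps)); neg_cols <- character(length(reps))
  for (i in seq_along(reps)) {
    p <- norm$samples$sample_id[norm$samples$replicate == reps[i] &
                                  norm$samples$population == "pos"]
    n <- norm$samples$sample_id[norm$samples$replicate == reps[i] &
                                  norm$samples$population == "neg"]
    if (length(p) != 1L || length(n) != 1L) {
      stop("replicate ", reps[i], " must have exactly one pos and one neg sample",
           call. = FALSE)
    }
    pos_cols[i] <- p; neg_cols[i] <- n
  }
  ratios <- norm$values[, pos_cols, drop = FALSE] /
    norm$values[, neg_cols, drop = FALSE]
  floored <- norm$counts[, pos_cols, drop = FALSE] == 0L
  capped <- norm$counts[, neg_cols, drop = FALSE] == 0L & !floored
  ratios[capped] <- cap
  ratios[floored] <- floor          # numerator rule takes precedence
  colnames(ratios) <- paste0("rep", reps)
  if (any(floored)) message(sum(floored), " ratio(s) set to depletion floor ", floor)
  if (any(capped)) message(sum(capped), " ratio(s) set to cap ", cap)
  structure(list(guide_id = rownames(norm$values), ratios = ratios,
                 aes = exp(rowMeans(log(ratios))),
                 floored = floored, capped = capped),
            class = "enrichment_table")
}

#' Gene scores from guide enrichment scores
#'
#' The gene score summarizes the average enrichment scores of all shRNAs per
#' gene -- by default their sum -- and is reported on a natural-log scale.
#' Control guides are excluded from gene scoring and returned separately.
#'
#' @param enrich an [enrichment_scores()] result.
#' @param manifest library manifest mapping guides to genes.
#' @param mode `"sum"` (default) or `"mean"` of the per-guide AES; the two
#'   differ by `log(n_guides)` on the log scale.
#' @return list with `genes` (`data.frame`: gene_id, n_guides, gene_score,
#'   log_gene_score) and `controls` (per-control-guide AES).
#' @export
gene_scores <- function(enrich, manifest, mode = c("sum", "mean")) {
  stopifnot(inherits(enrich, "enrichment_table"))
  mode <- match.arg(mode)
  idx <- match(enrich$guide_id, manifest$guide_id)
  if (anyNA(idx)) {
    stop("guide absent from manifest: ", enrich$guide_id[is.na(idx)][1],
         call. = FALSE)
  }
  gene <- manifest$gene_id[idx]
  ctrl <- manifest$is_control[idx]
  agg <- if (mode == "sum") sum else mean
  score <- tapply(enrich$aes[!ctrl], gene[!ctrl], agg)
  genes <- data.frame(gene_id = names(score),
                      n_guides = as.integer(table(gene[!ctrl])[names(score)]),
                      gene_score = as.numeric(score),
                      log_gene_score = log(as.numeric(score)),
                      stringsAsFactors = FALSE)
  controls <- data.frame(guide_id = enrich$guide_id[ctrl],
                         aes = enrich$aes[ctrl], stringsAsFactors = FALSE)
  list(genes = genes, controls = controls)
}

#' Per-guide, per-replicate Poisson enrichment P-values
#'
#' For guide i in replicate r, the expected positive-population count under
#' the negative-population frequency is
#' `lambda = neg_count / neg_total * pos_total`; the one-sided P-value is the
#' upper tail `P(Poisson(lambda) >= observed pos count)`, testing enrichment
#' of the guide in the reporter-positive gate. A zero negative count floors
#' `lambda` at `lambda_floor` so that P-values stay in (0, 1].
#'
#' @param counts a [count_matrix()].
#' @param lambda_floor small positive expectation used when the negative count
#'   is zero; default 0.5.
#' @return numeric matrix guides x replicates of P-values in (0, 1].
#' @export
poisson_pvalues <- function(counts, lambda_floor = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(counts$counts < 0)) stop("negative count", call. = FALSE)
  reps <- sort(unique(counts$samples$replicate))
  p <- matrix(NA_real_, nrow(counts$counts), length(reps),
              dimnames = list(rownames(counts$counts), paste0("rep", reps)))
  for (i in seq_along(reps)) {
    pos <- counts$counts[, counts$samples$sample_id[
      counts$samples$replicate == reps[i] & counts$samples$population == "pos"]]
    neg <- counts$counts[, counts$samples$sample_id[
      counts$samples$replicate == reps[i] & counts$samples$population == "neg"]]
    lambda <- neg / sum(neg) * sum(pos)
    lambda[neg == 0L] <- lambda_floor
    # extreme enrichment underflows the upper tail; clamp to keep p in (0, 1]
    p[, i] <- pmax(stats::ppois(pos - 1L, lambda, lower.tail = FALSE),
                   .Machine$double.xmin)
  }
  p
}

#' Combine P-values with Fisher's method
#'
#' The statistic is `-2 * sum(log(p))`, distributed as chi-squared with `2k`
#' degrees of freedom under the null, where `k` is the number of tests
#' combined; the combined P-value is its upper tail.
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @return list with `statistic`, `df` and `p_value`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no P-values to combine", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Gene-level combined and Bonferroni-adjusted P-values
#'
#' All of a gene's per-guide, per-replicate Poisson P-values are pooled into a
#' single Fisher combination (`k = n_guides * n_replicates`), followed by a
#' Bonferroni correction over the `m` genes scored (controls excluded).
#'
#' @param pois matrix from [poisson_pvalues()].
#' @param manifest library manifest.
#' @param m number of tests for the Bonferroni correction; defaults to the
#'   number of genes scored.
#' @return `data.frame`: gene_id, fisher_statistic, fisher_df, combined_p,
#'   bonferroni_p.
#' @export
gene_pvalues <- function(pois, manifest, m = NULL) {
  idx <- match(rownames(pois), manifest$guide_id)
  if (anyNA(idx)) {
    stop("guide absent from manifest: ", rownames(pois)[is.na(idx)][1],
         call. = FALSE)
  }
  keep <- !manifest$is_control[idx]
  gene <- manifest$gene_id[idx][keep]
  pois <- pois[keep, , drop = FALSE]
  empty <- setdiff(unique(manifest$gene_id[!manifest$is_control]), gene)
  if (length(empty)) {
    warning("gene(s) with zero guides excluded: ", paste(empty, collapse = ", "))
  }
  fits <- lapply(split(seq_along(gene), gene),
                 function(i) fisher_combine(as.vector(pois[i, , drop = FALSE])))
  if (is.null(m)) m <- length(fits)
  data.frame(gene_id = names(fits),
             fisher_statistic = vapply(fits, `[[`, 1, "statistic"),
             fisher_df = vapply(fits, `[[`, 1L, "df"),
             combined_p = vapply(fits, `[[`, 1, "p_value"),
             bonferroni_p = pmin(1, vapply(fits, `[[`, 1, "p_value") * m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ranked gene-score table
#'
#' Merges gene scores and gene P-values and ranks genes by descending log
#' gene score; ties break by smaller combined P-value, then lexicographic
#' gene id. Genes with positive log score are flagged as positive regulators
#' of reporter silencing (enriched in the reporter-positive gate), negative
#' log scores as negative regulators. `significance` is `-log10(combined_p)`
#' for plotting.
#'
#' @param scores `genes` `data.frame` from [gene_scores()].
#' @param pvalues `data.frame` from [gene_pvalues()].
#' @return `data.frame`: gene_id, n_guides, gene_score, log_gene_score,
#'   fisher_statistic, fisher_df, combined_p, bonferroni_p, significance,
#'   direction, rank -- ordered by rank.
#' @export
rank_genes <- function(scores, pvalues) {
  if (!setequal(scores$gene_id, pvalues$gene_id)) {
    only_s <- setdiff(scores$gene_id, pvalues$gene_id)
    only_p <- setdiff(pvalues$gene_id, scores$gene_id)
    stop("mismatched gene sets; only in scores: ",
         paste(only_s, collapse = ", "), "; only in pvalues: ",
         paste(only_p, collapse = ", "), call. = FALSE)
  }
  tab <- merge(scores, pvalues, by = "gene_id")
  ord <- order(-tab$log_gene_score, tab$combined_p, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab$significance <- -log10(tab$combined_p)
  tab$direction <- ifelse(tab$log_gene_score > 0, "positive", "negative")
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Score a screen count matrix end to end
#'
#' Convenience wrapper chaining [normalize_counts()], [enrichment_scores()],
#' [gene_scores()], [poisson_pvalues()], [gene_pvalues()] and [rank_genes()].
#'
#' @inheritParams enrichment_scores
#' @inheritParams gene_scores
#' @param counts a [count_matrix()].
#' @param manifest library manifest.
#' @return list with `gene_table` (ranked [rank_genes()] output),
#'   `guide_table` (per-replicate ratios, AES, floor/cap flags) and
#'   `controls`.
#' @export
score_screen <- function(counts, manifest, floor = 1e-3, cap = 1e3,
                         mode = c("sum", "mean")) {
  norm <- normalize_counts(counts)
  enrich <- enrichment_scores(norm, floor = floor, cap = cap)
  gs <- gene_scores(enrich, manifest, mode = mode)
  gp <- gene_pvalues(poisson_pvalues(counts), manifest)
  guide_table <- data.frame(guide_id = enrich$guide_id,
                            gene_id = manifest$gene_id[
                              match(enrich$guide_id, manifest$guide_id)],
                            enrich$ratios, aes = enrich$aes,
                            n_floored = rowSums(enrich$floored),
                            n_capped = rowSums(enrich$capped),
                            row.names = NULL, stringsAsFactors = FALSE)
  list(gene_table = rank_genes(gs$genes, gp), guide_table = guide_table,
       controls = gs$controls)
}
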