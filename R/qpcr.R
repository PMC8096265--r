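# Relative quantification for ChIP-/DRIP-qPCR: percent-input with optional
# spike-in normalization, treated-vs-control replicate scaling, the one-tailed
# unpaired t-test used for reporting, and a ground-truth Cq simulator.

CQ_ROLES <- c("IP", "input", "IgG", "spike_in")

#' Simulate a Cq table with known enrichments
#'
#' Generates quantification-cycle records for a treated-vs-control qPCR
#' design such that the full relative-quantification chain
#' ([percent_input()] then [scale_to_control()]) recovers `true_enrichments`
#' in expectation (exactly at `noise_sd = 0`). Each (condition, replicate)
#' sample carries IP, input and IgG rows for the target amplicon plus
#' spike-in rows (role `"spike_in"`, `material` `"IP"`/`"input"`) for a
#' foreign-genome amplicon whose IP recovery is shared across samples, so
#' spike-in normalization cancels it.
#'
#' @param conditions character vector of condition labels; the first is
#'   treated as the untreated/control condition by downstream scaling.
#' @param n_replicates replicates per condition.
#' @param true_enrichments named numeric vector of per-condition fold
#'   enrichments (names matching `conditions`).
#' @param efficiency amplification factor per cycle (> 1); default 2.
#' @param input_fraction fraction of material taken as input; default 0.1.
#' @param spike_recovery common IP recovery of the spike-in amplicon.
#' @param noise_sd Gaussian noise on Cq values, cycles.
#' @param roles roles to emit; must include `"IP"` and `"input"`.
#' @param seed integer seed.
#' @return Cq `data.frame`: `sample_id`, `condition`, `replicate`, `target`,
#'   `role`, `material`, `cq`.
#' @export
simulate_cq <- function(conditions = c("untreated", "treated"),
                        n_replicates = 3L,
                        true_enrichments = c(untreated = 1, treated = 4),
                        efficiency = 2, input_fraction = 0.1,
                        spike_recovery = 0.2, noise_sd = 0,
                        roles = CQ_ROLES, seed = 1L) {
  if (efficiency <= 1) stop("`efficiency` must be > 1", call. = FALSE)
  miss <- setdiff(c("IP", "input"), roles)
  if (length(miss)) {
    stop("missing role in design: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(conditions %in% names(true_enrichments))) {
    stop("`true_enrichments` must name every condition", call. = FALSE)
  }
  adj <- log(1 / input_fraction, base = efficiency)
  with_seed(seed, {
    rows <- list()
    for (cond in conditions) for (r in seq_len(n_replicates)) {
      sid <- paste0(cond, "_rep", r)
      input_cq <- stats::rnorm(1, 24, 0.5)          # target amplicon, input material
      adj_input <- input_cq - adj
      enr <- true_enrichments[[cond]]
      ip_cq <- adj_input - log(enr * spike_recovery, base = efficiency)
      spike_input_cq <- stats::rnorm(1, 26, 0.5)
      spike_ip_cq <- (spike_input_cq - adj) - log(spike_recovery, base = efficiency)
      rec <- data.frame(
        sample_id = sid, condition = cond, replicate = r,
        target = c("locus", "locus", "locus", "spike", "spike"),
        role = c("IP", "input", "IgG", "spike_in", "spike_in"),
        material = c("IP", "input", "IgG", "IP", "input"),
        cq = c(ip_cq, input_cq,
               adj_input - log(0.02 * spike_recovery, base = efficiency),
               spike_ip_cq, spike_input_cq),
        stringsAsFactors = FALSE)
      rec <- rec[rec$role %in% roles, , drop = FALSE]
      rows[[length(rows) + 1L]] <- rec
    }
    out <- do.call(rbind, rows)
    out$cq <- out$cq + stats::rnorm(nrow(out), 0, noise_sd)
    rownames(out) <- NULL
    out
  })
}

#' Percent-input enrichment with optional spike-in normalization
#'
#' Per sample, the input Cq is first adjusted for the fraction of material
#' taken as input (`adjusted = input_cq - log_efficiency(1/input_fraction)`);
#' enrichment is `efficiency^(adjusted_input_cq - ip_cq)`. When spike-in rows
#' are present (role `"spike_in"`, `material` `"IP"`/`"input"`), the target
#' enrichment is divided by the same quantity computed for the spike-in
#' amplicon, cancelling global IP-efficiency factors. IgG rows are carried
#' through for reporting, not used in normalization.
#'
#' @param table Cq `data.frame` as produced by [simulate_cq()] or read from a
#'   TSV with the same columns.
#' @param efficiency amplification factor per cycle; default 2.
#' @param input_fraction fraction of the sample taken as input; default 0.1.
#' @return `data.frame`: `sample_id`, `condition`, `replicate`, `enrichment`,
#'   `spike_normalized`, `igg_enrichment` (NA when absent).
#' @export
percent_input <- function(table, efficiency = 2, input_fraction = 0.1) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("`input_fraction` must be in (0, 1]", call. = FALSE)
  }
  need <- c("sample_id", "condition", "replicate", "role", "cq")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("Cq table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(table$cq)) || any(table$cq <= 0)) {
    stop("Cq values must be finite and > 0", call. = FALSE)
  }
  adj <- log(1 / input_fraction, base = efficiency)
  out <- lapply(split(table, table$sample_id), function(s) {
    cq_of <- function(role, material = role) {
      v <- s$cq[s$role == role & (!("material" %in% names(s)) |
                                    s$material == material)]
      if (length(v) == 0L) NA_real_ else v[1]
    }
    ip <- cq_of("IP"); input <- cq_of("input")
    if (is.na(ip) || is.na(input)) {
      stop("sample ", s$sample_id[1], " is missing an IP or input Cq",
           call. = FALSE)
    }
    enr <- efficiency^((input - adj) - ip)
    spike_ip <- cq_of("spike_in", "IP"); spike_input <- cq_of("spike_in", "input")
    spiked <- !is.na(spike_ip) && !is.na(spike_input)
    if (spiked) enr <- enr / efficiency^((spike_input - adj) - spike_ip)
    igg <- cq_of("IgG")
    data.frame(sample_id = s$sample_id[1], condition = s$condition[1],
               replicate = s$replicate[1], enrichment = enr,
               spike_normalized = spiked,
               igg_enrichment = if (is.na(igg)) NA_real_ else
                 efficiency^((input - adj) - igg),
               stringsAsFactors = FALSE)
  })
  spiked <- vapply(out, `[[`, TRUE, "spike_normalized")
  if (any(spiked) && !all(spiked)) {
    stop("spike-in present for some but not all samples in the comparison",
         call. = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scale per-replicate quantities to the untreated average
#'
#' Two-step scaling of matched treated-vs-control sets: each replicate's
#' values are first divided by that replicate's mean across its samples, then
#' all values are divided by the mean of the untreated values, so the
#' untreated replicates average exactly 1.
#'
#' @param values `data.frame` with `condition`, `replicate` and a `value`
#'   column (defaults to `enrichment` when present).
#' @param control_condition label of the untreated/control condition.
#' @param value_col name of the value column.
#' @return the input with a `scaled` column appended; attribute `scaling`
#'   records the per-replicate means and the control mean.
#' @export
scale_to_control <- function(values, control_condition = "untreated",
                             value_col = if ("enrichment" %in% names(values))
                               "enrichment" else "value") {
  v <- values[[value_col]]
  if (is.null(v)) stop("no `", value_col, "` column", call. = FALSE)
  if (any(v <= 0)) stop("values must be > 0", call. = FALSE)
  if (!any(values$condition == control_condition)) {
    stop("no untreated samples (condition == '", control_condition, "')",
         call. = FALSE)
  }
  rep_means <- tapply(v, values$replicate, mean)
  step1 <- v / as.numeric(rep_means[as.character(values$replicate)])
  ctrl_mean <- mean(step1[values$condition == control_condition])
  values$scaled <- step1 / ctrl_mean
  attr(values, "scaling") <- list(replicate_means = rep_means,
                                  control_mean = ctrl_mean)
  values
}

#' One-tailed unpaired t-test with significance stars
#'
#' Two-sample pooled-variance t-test; the one-tailed P-value is taken in the
#' direction of the observed difference of means, so identical groups give
#' `t = 0`, `P = 0.5`. Stars follow the reporting thresholds
#' `**** <= 1e-4`, `*** <= 1e-3`, `** <= 0.01`, `* <= 0.05`, else `n.s.`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p_value`, `stars`.
#' @export
one_tailed_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  t <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- stats::pt(abs(t), df, lower.tail = FALSE)
  list(statistic = t, df = df, p_value = p, stars = significance_stars(p))
}

#' @rdname one_tailed_ttest
#' @param p P-value.
#' @export
significance_stars <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "n.s."
}

#' Read / write a Cq TSV
#'
#' Tab-separated with columns `sample_id`, `condition`, `replicate`, `target`,
#' `role`, `material`, `cq`.
#'
#' @param path file path.
#' @return `read_cq()` returns the Cq `data.frame`.
#' @export
read_cq <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$role), CQ_ROLES)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  df
}

#' @rdname read_cq
#' @param table Cq `data.frame`.
#' @export
write_cq <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
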