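# End-to-end screen runs: configuration, staging, logging and provenance.

run_config_defaults <- function() {
  list(manifest = NULL, counts = NULL, fastqs = NULL, out_dir = "results",
       offset = "scan", orientation = "forward",
       floor = 1e-3, cap = 1e3, gene_score_mode = "sum")
}

#' Read a plain-text key-value run configuration
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a comment.
#' Unknown keys are rejected. `fastqs` is a comma-separated list of
#' `sample_id=path` entries.
#'
#' @param path config file path.
#' @return a validated config list (defaults filled in).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*([^=[:space:]].*)$", lines))
  if (any(lengths(kv) != 3L)) {
    stop("malformed config line: ", lines[lengths(kv) != 3L][1], call. = FALSE)
  }
  cfg <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  for (k in c("floor", "cap")) out[[k]] <- as.numeric(out[[k]])
  if (!is.null(out$fastqs) && is.character(out$fastqs) && length(out$fastqs) == 1L &&
      grepl("=", out$fastqs)) {
    parts <- strsplit(strsplit(out$fastqs, ",")[[1]], "=")
    out$fastqs <- stats::setNames(trimws(vapply(parts, `[`, "", 2L)),
                                  trimws(vapply(parts, `[`, "", 1L)))
  }
  if (!identical(out$offset, "scan")) out$offset <- as.integer(out$offset)
  out
}

#' Run the screen-scoring pipeline
#'
#' Executes count (when FASTQs are given) -> normalize -> enrichment -> gene
#' scores -> Poisson/Fisher/Bonferroni P-values -> ranked gene table, writing
#' every intermediate table, a log and the echoed configuration into
#' `out_dir`. Outputs are pure functions of the config and inputs, so
#' re-running a config reproduces the files byte for byte.
#'
#' @param config a config list (see [read_run_config()] for the keys); must
#'   provide `manifest` and either `counts` (TSV path or [count_matrix()]) or
#'   `fastqs` (named vector of FASTQ paths).
#' @return path of the results directory, invisibly. Files written:
#'   `counts.tsv`, `guide_scores.tsv`, `gene_scores.tsv`, `control_guides.tsv`,
#'   `run_config.txt`, `run_log.txt`.
#' @export
run_screen_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  manifest <- stage("manifest",
                    if (is.character(cfg$manifest)) read_manifest(cfg$manifest)
                    else validate_manifest(cfg$manifest))
  say("manifest: ", nrow(manifest), " guides, ",
      length(unique(manifest$gene_id[!manifest$is_control])), " target genes")

  counts <- stage("count", {
    if (!is.null(cfg$counts)) {
      if (is.character(cfg$counts)) read_counts(cfg$counts) else cfg$counts
    } else if (!is.null(cfg$fastqs)) {
      count_fastq_samples(cfg$fastqs, manifest, offset = cfg$offset,
                          orientation = cfg$orientation)
    } else stop("config must provide `counts` or `fastqs`")
  })
  say("counts: ", nrow(counts$counts), " guides x ", ncol(counts$counts),
      " samples; unmatched reads: ", sum(counts$unmatched))

  scored <- stage("score",
                  score_screen(counts, manifest, floor = cfg$floor,
                               cap = cfg$cap, mode = cfg$gene_score_mode))
  say("scored ", nrow(scored$gene_table), " genes; ",
      sum(scored$guide_table$n_floored), " floored and ",
      sum(scored$guide_table$n_capped), " capped replicate ratios")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(counts, file.path(cfg$out_dir, "counts.tsv"))
  wt <- function(df, f) utils::write.table(
    df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(scored$guide_table, "guide_scores.tsv")
  wt(scored$gene_table, "gene_scores.tsv")
  wt(scored$controls, "control_guides.tsv")
  echo <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", if (is.null(v)) "" else paste(
      if (!is.null(names(v)) && any(nzchar(names(v))))
        paste0(names(v), "=", v) else as.character(v), collapse = ","))
  }, "")
  writeLines(echo, file.path(cfg$out_dir, "run_config.txt"))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  invisible(cfg$out_dir)
}
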