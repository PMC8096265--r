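# The guides x samples count container and its TSV schema.

#' Construct a count matrix of guides by sorted samples
#'
#' Wraps an integer matrix of read counts (rows: guides; columns: samples
#' named `rep<k>_<pos|neg>`) together with the parsed sample metadata and the
#' per-sample number of unmatched reads.
#'
#' @param counts integer matrix with guide ids as rownames and sample ids of
#'   the form `rep<k>_<pos|neg>` as colnames.
#' @param unmatched optional named integer vector of unmatched reads per
#'   sample; defaults to zero.
#' @return an object of class `count_matrix`: list with `counts`, `samples`
#'   (`data.frame` of sample_id, replicate, population) and `unmatched`.
#' @export
count_matrix <- function(counts, unmatched = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs guide rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated guide row: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("counts must be non-negative integers; offending cell: guide %s, sample %s",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  samples <- parse_sample_ids(colnames(counts))
  if (is.null(unmatched)) {
    unmatched <- stats::setNames(integer(ncol(counts)), colnames(counts))
  }
  structure(list(counts = counts, samples = samples,
                 unmatched = unmatched[colnames(counts)]),
            class = "count_matrix")
}

# sample ids follow `rep<k>_<pos|neg>`
parse_sample_ids <- function(ids) {
  ok <- grepl("^rep[0-9]+_(pos|neg)$", ids)
  if (!all(ok)) {
    stop("unknown sample column pattern (expected rep<k>_<pos|neg>): ",
         ids[!ok][1], call. = FALSE)
  }
  data.frame(sample_id = ids,
             replicate = sub("^rep([0-9]+)_.*$", "\\1", ids),
             population = sub("^rep[0-9]+_", "", ids),
             stringsAsFactors = FALSE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples (%d replicates)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$replicate))))
  cat("column sums:", paste(colSums(x$counts), collapse = " "), "\n")
  invisible(x)
}

#' Read / write the count-matrix TSV
#'
#' Tab-separated, first column `guide_id`, remaining columns named
#' `rep<k>_<pos|neg>`. Per-sample unmatched-read totals, when present, travel
#' in a `#unmatched` comment line so that write/read round-trips are exact.
#'
#' @param path file path.
#' @return `read_counts()` returns a [count_matrix()].
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  unmatched <- NULL
  skip <- 0L
  if (startsWith(first, "#unmatched")) {
    fields <- strsplit(sub("^#unmatched\t", "", first), "\t")[[1]]
    kv <- strsplit(fields, "=")
    unmatched <- stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                                 vapply(kv, `[`, "", 1L))
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "guide_id") stop("first column must be guide_id", call. = FALSE)
  if (anyDuplicated(df$guide_id)) {
    stop("duplicated guide row: ", df$guide_id[duplicated(df$guide_id)][1],
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    bad <- which(is.na(m) | m != round(m) | m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at guide %s, column %s",
                 df$guide_id[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  rownames(m) <- df$guide_id
  count_matrix(m, unmatched = unmatched)
}

#' @rdname read_counts
#' @param x a [count_matrix()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (any(x$unmatched > 0)) {
    writeLines(paste0("#unmatched\t", paste0(names(x$unmatched), "=",
                                             x$unmatched, collapse = "\t")), con)
  }
  df <- data.frame(guide_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
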