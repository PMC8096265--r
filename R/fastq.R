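# FASTQ emission for simulated screens and exact-match guide counting.

# fixed 8-nt vector anchors flanking the guide window, so offset-scan
# matching has realistic constant context
ANCHOR_LEFT  <- "AGGCTCGA"
ANCHOR_RIGHT <- "TGCCTACT"

#' Emit FASTQ reads for each sample of a count matrix
#'
#' Writes one FASTQ file per sample. Each read is `read_length` nt: the
#' guide's 22-nt sequence placed at `guide_offset` (1-based), flanked by fixed
#' 8-nt vector anchors where space allows, with uniform-random filler bases
#' elsewhere. A sample's file contains exactly its column-sum reads, in
#' shuffled order; the quality line is constant high quality.
#'
#' @param counts a [count_matrix()].
#' @param manifest library manifest supplying the guide sequences.
#' @param dir output directory (created if needed).
#' @param read_length read length in nt; default 150.
#' @param guide_offset 1-based start of the guide within the read; default 31.
#' @param seed integer seed.
#' @param gzip write gzip-compressed files (`.fastq.gz`).
#' @return named character vector of file paths, one per sample, invisibly.
#' @export
emit_fastq <- function(counts, manifest, dir, read_length = 150L,
                       guide_offset = 31L, seed = 1L, gzip = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  validate_manifest(manifest)
  if (read_length < guide_offset + GUIDE_LENGTH - 1L) {
    stop("read_length too short for the guide window at guide_offset",
         call. = FALSE)
  }
  idx <- match(rownames(counts$counts), manifest$guide_id)
  if (anyNA(idx)) {
    stop("guide absent from manifest: ",
         rownames(counts$counts)[is.na(idx)][1], call. = FALSE)
  }
  guide_seq <- manifest$guide_seq[idx]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  left_len <- guide_offset - 1L
  anchor_l <- if (left_len >= nchar(ANCHOR_LEFT)) ANCHOR_LEFT else ""
  fill_l <- left_len - nchar(anchor_l)
  right_len <- read_length - (guide_offset + GUIDE_LENGTH - 1L)
  anchor_r <- if (right_len >= nchar(ANCHOR_RIGHT)) ANCHOR_RIGHT else ""
  fill_r <- right_len - nchar(anchor_r)
  qual <- strrep("I", read_length)

  paths <- character(ncol(counts$counts))
  names(paths) <- colnames(counts$counts)
  with_seed(seed, {
    for (s in colnames(counts$counts)) {
      n <- sum(counts$counts[, s])
      path <- file.path(dir, paste0(s, if (gzip) ".fastq.gz" else ".fastq"))
      con <- if (gzip) gzfile(path, "w") else file(path, "w")
      if (n > 0) {
        g <- sample(rep.int(seq_along(guide_seq), counts$counts[, s]))
        reads <- paste0(random_filler(n, fill_l), anchor_l, guide_seq[g],
                        anchor_r, random_filler(n, fill_r))
        out <- character(4L * n)
        out[seq(1L, by = 4L, length.out = n)] <- paste0("@", s, ":", seq_len(n))
        out[seq(2L, by = 4L, length.out = n)] <- reads
        out[seq(3L, by = 4L, length.out = n)] <- "+"
        out[seq(4L, by = 4L, length.out = n)] <- qual
        writeLines(out, con)
      }
      close(con)
      paths[s] <- path
    }
  })
  invisible(paths)
}

random_filler <- function(n, width) {
  if (width <= 0L) return(rep("", n))
  apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
               nrow = n), 1L, paste0, collapse = "")
}

#' Count library guides in a FASTQ file by exact matching
#'
#' A read increments exactly one guide when a 22-nt window of the read equals
#' a manifest guide sequence: at the fixed 1-based `offset`, or, with
#' `offset = "scan"` (the default, for libraries whose vector context is not
#' known), at any position, the leftmost match winning. All other reads --
#' including reads shorter than 22 nt, which trigger a warning -- count as
#' unmatched, so matched plus unmatched equals the number of reads. Matching
#' is exact (no mismatch tolerance): 22-mers distinguish library guides.
#'
#' @param fastq path to a FASTQ file (gzip accepted).
#' @param manifest library manifest; guide sequences must be unique.
#' @param offset `"scan"` or a 1-based integer window start.
#' @param orientation `"forward"` matches the read as sequenced; `"both"` also
#'   tries the reverse complement of reads that did not match forward.
#' @return a `guide_counts` object: list with `counts` (named integer vector
#'   over manifest guides) and `unmatched` (count).
#' @export
count_guides <- function(fastq, manifest, offset = "scan",
                         orientation = c("forward", "both")) {
  validate_manifest(manifest)
  orientation <- match.arg(orientation)
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  n_reads <- length(reads)
  counts <- stats::setNames(integer(nrow(manifest)), manifest$guide_id)
  if (n_reads == 0L) {
    return(structure(list(counts = counts, unmatched = 0L),
                     class = "guide_counts"))
  }
  short <- Biostrings::width(reads) < GUIDE_LENGTH
  if (any(short)) {
    warning(sum(short), " read(s) shorter than 22 nt counted as unmatched")
    reads <- reads[!short]
  }
  hit <- match_guides(reads, manifest, offset)
  if (orientation == "both" && anyNA(hit)) {
    miss <- is.na(hit)
    hit[miss] <- match_guides(Biostrings::reverseComplement(reads[miss]),
                              manifest, offset)
  }
  tab <- tabulate(hit, nbins = nrow(manifest))
  counts[] <- tab
  structure(list(counts = counts,
                 unmatched = as.integer(n_reads - sum(tab))),
            class = "guide_counts")
}

# per-read manifest row index or NA
match_guides <- function(reads, manifest, offset) {
  if (identical(offset, "scan")) {
    pd <- Biostrings::PDict(manifest$guide_seq)
    hits <- Biostrings::vwhichPDict(pd, reads)
    n_hits <- lengths(hits)
    out <- rep(NA_integer_, length(reads))
    out[n_hits == 1L] <- unlist(hits[n_hits == 1L], use.names = FALSE)
    multi <- which(n_hits > 1L)
    for (i in multi) {                     # leftmost match wins; logged
      cand <- hits[[i]]
      starts <- vapply(cand, function(j) {
        m <- Biostrings::matchPattern(manifest$guide_seq[j], reads[[i]])
        min(Biostrings::start(m))
      }, 1L)
      out[i] <- cand[which.min(starts)]
      message("read ", names(reads)[i] %||% i,
              " matches several guides; leftmost match used")
    }
    out
  } else {
    offset <- as.integer(offset)
    if (is.na(offset) || offset < 1L) stop("invalid `offset`", call. = FALSE)
    too_short <- Biostrings::width(reads) < offset + GUIDE_LENGTH - 1L
    win <- substr(as.character(reads), offset, offset + GUIDE_LENGTH - 1L)
    out <- match(win, manifest$guide_seq)
    out[too_short] <- NA_integer_
    out
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || !nzchar(a)) b else a

#' Count guides across several FASTQ samples into a count matrix
#'
#' @param fastqs named character vector of FASTQ paths; names must follow the
#'   `rep<k>_<pos|neg>` sample-id scheme.
#' @inheritParams count_guides
#' @return a [count_matrix()] with per-sample unmatched-read totals.
#' @export
count_fastq_samples <- function(fastqs, manifest, offset = "scan",
                                orientation = c("forward", "both")) {
  if (is.null(names(fastqs))) stop("`fastqs` must be named by sample id", call. = FALSE)
  cols <- lapply(fastqs, count_guides, manifest = manifest, offset = offset,
                 orientation = orientation)
  m <- do.call(cbind, lapply(cols, `[[`, "counts"))
  colnames(m) <- names(fastqs)
  count_matrix(m, unmatched = vapply(cols, `[[`, 1L, "unmatched"))
}
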