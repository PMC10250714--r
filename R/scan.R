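# reverse complement of a plain character string; N maps to N
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# mismatch counts at every start of a run of position sets over a sequence
# held as UTF-8 integer codes; sets with NULL or all four bases are free
# (contribute 0). Returns an integer vector of length
# length(ints) - length(sets) + 1 (empty if negative). A 256-row lookup
# table per position marks the disallowed codes, so N (or anything else)
# mismatches informative positions. The position sweep is compiled code.
mismatch_profile <- function(ints, sets) {
  .mismatch_profile_cpp(ints, bad_matrix(sets))
}

# reverse complement of a UTF-8 integer-coded sequence
revcomp_ints <- function(ints) {
  comp <- integer(256L)
  comp[utf8ToInt("ACGTN")] <- utf8ToInt("TGCAN")
  out <- comp[rev(ints)]
  out[out == 0L] <- utf8ToInt("N")
  out
}

# 256-row disallowed-code lookup, one column per pattern position; free
# (spacer / any-base) positions stay all-FALSE
bad_matrix <- function(sets) {
  bad <- matrix(FALSE, nrow = 256L, ncol = length(sets))
  for (j in seq_along(sets)) {
    s <- sets[[j]]
    if (is.null(s) || length(s) == 4L) next
    bad[, j] <- TRUE
    bad[utf8ToInt(paste(s, collapse = "")) + 1L, j] <- FALSE
  }
  bad
}

scan_one_strand <- function(ints, pattern) {
  # returns data.frame(start0, width, spacer, mismatches) on this orientation
  if (inherits(pattern, "tre_halfsite")) {
    k <- .scan_kernel_cpp(ints, bad_matrix(pattern$sets),
                          matrix(FALSE, 256L, 0L), -1L, -1L,
                          pattern$max_mismatches)
    width <- rep(length(pattern$sets), length(k$start0))
  } else {
    k <- .scan_kernel_cpp(ints, bad_matrix(pattern$half_a),
                          bad_matrix(pattern$half_b),
                          pattern$spacer_min, pattern$spacer_max,
                          pattern$max_mismatches)
    width <- length(pattern$half_a) + length(pattern$half_b) + k$spacer
  }
  data.frame(start0 = k$start0, width = width, spacer = k$spacer,
             mismatches = k$mismatches)
}

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), pattern = character(0),
             spacer = integer(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan sequences for degenerate motif hits on both strands
#'
#' Slides a compiled halfsite or direct-repeat pattern over every position
#' of every sequence, over every spacer length in range, and (by default)
#' over both strands, reporting each placement whose mismatch count does
#' not exceed the pattern budget. Minus-strand matching is performed on
#' the reverse complement; coordinates are reported on the forward
#' sequence, 0-based half-open. Exact duplicate placements
#' (same sequence, interval, strand and pattern) are merged keeping the
#' lowest mismatch count; overlapping but distinct placements (e.g. the
#' same locus at two spacers) are all retained.
#'
#' @param seqs A named character vector of sequences or a
#'   [Biostrings::DNAStringSet] (e.g. from [read_genome()]).
#' @param pattern A `tre_pattern` from [compile_pattern()] or
#'   [tre_patterns()].
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return A data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `strand`, `pattern`, `spacer` (`NA` for halfsite hits)
#'   and `mismatches`, sorted by sequence, start and strand.
#' @examples
#' hits <- scan_sequence(c(chr1 = "AGGTCACCCCAGGTCA"), tre_patterns()$dr4)
#' @export
scan_sequence <- function(seqs, pattern, both_strands = TRUE) {
  stopifnot(inherits(pattern, "tre_pattern"))
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named with their seq_id")
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sid <- names(seqs)[i]
    ints <- utf8ToInt(toupper(seqs[[i]]))
    L <- length(ints)
    h <- scan_one_strand(ints, pattern)
    hit_list <- list()
    if (nrow(h))
      hit_list[[1L]] <- data.frame(
        seq_id = sid, start = h$start0, end = h$start0 + h$width,
        strand = "+", pattern = pattern$name, spacer = h$spacer,
        mismatches = h$mismatches, stringsAsFactors = FALSE)
    if (both_strands) {
      hr <- scan_one_strand(revcomp_ints(ints), pattern)
      if (nrow(hr)) {
        start_fwd <- L - hr$start0 - hr$width
        hit_list[[length(hit_list) + 1L]] <- data.frame(
          seq_id = sid, start = start_fwd, end = start_fwd + hr$width,
          strand = "-", pattern = pattern$name, spacer = hr$spacer,
          mismatches = hr$mismatches, stringsAsFactors = FALSE)
      }
    }
    res[[i]] <- if (length(hit_list)) do.call(rbind, hit_list) else empty_hits()
  }
  hits <- do.call(rbind, res)
  if (!nrow(hits)) return(empty_hits())
  # deduplicate identical placements, keeping the lowest mismatch count
  key <- paste(hits$seq_id, hits$start, hits$end, hits$strand, hits$pattern)
  hits <- hits[order(key, hits$mismatches), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$seq_id, hits$start, hits$end,
                                 hits$strand, hits$pattern)), , drop = FALSE]
  hits <- hits[order(hits$seq_id, hits$start, hits$end, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write and read motif hit tables
#'
#' `write_hits()` writes a hit data.frame (as produced by
#' [scan_sequence()]) to CSV, optionally also as BED6 with the pattern
#' name in the name column and the mismatch count as score.
#' `read_hits()` reads the CSV back, reproducing the hit table exactly.
#'
#' @param hits Hit data.frame from [scan_sequence()].
#' @param path Output CSV path.
#' @param bed_path Optional BED6 output path.
#' @return `write_hits()` returns `path` invisibly; `read_hits()` returns
#'   the hit data.frame.
#' @export
write_hits <- function(hits, path, bed_path = NULL) {
  cols <- c("seq_id", "start", "end", "strand", "pattern", "spacer",
            "mismatches")
  stopifnot(all(cols %in% names(hits)))
  utils::write.csv(hits[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(hits$seq_id, hits$start, hits$end, hits$pattern,
                      hits$mismatches, hits$strand)
    utils::write.table(bed, bed_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  hits <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character",
                                         strand = "character",
                                         pattern = "character"))
  hits$start <- as.integer(hits$start)
  hits$end <- as.integer(hits$end)
  hits$spacer <- as.integer(hits$spacer)
  hits$mismatches <- as.integer(hits$mismatches)
  hits
}
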