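#' Tally motif hits inside promoter windows
#'
#' Credits a motif hit to a gene whenever the hit's start coordinate lies
#' inside the gene's promoter window (0-based half-open containment). A
#' hit may be credited to several genes when windows overlap; genes with
#' no hits receive explicit zeros so the gene universe of downstream
#' enrichment denominators is fixed. Counts are kept separately per
#' pattern, and the smallest absolute strand-aware TSS distance among
#' credited hits is recorded per gene and pattern.
#'
#' @param hits Hit data.frame from [scan_sequence()] (possibly several
#'   patterns row-bound together).
#' @param windows Window data.frame from [promoter_windows()].
#' @param patterns Character vector of pattern names to tally; defaults
#'   to those present in `hits`. Patterns named here but absent from
#'   `hits` yield all-zero columns.
#' @param seq_ids Optional vector of valid sequence ids (e.g. genome
#'   names); a window on an unlisted sequence is an error.
#' @return data.frame with one row per gene x pattern: `gene_id`,
#'   `pattern`, `count`, `min_abs_distance` (`NA` when `count` is 0).
#' @export
associate <- function(hits, windows, patterns = NULL, seq_ids = NULL) {
  stopifnot(all(c("seq_id", "start", "strand", "pattern") %in% names(hits)),
            all(c("gene_id", "seq_id", "start", "end", "strand", "tss")
                %in% names(windows)))
  if (!is.null(seq_ids)) {
    unknown <- setdiff(windows$seq_id, seq_ids)
    if (length(unknown))
      stop("window referencing unknown seq_id: ",
           paste(unknown, collapse = ", "))
  }
  if (is.null(patterns)) patterns <- sort(unique(hits$pattern))
  if (!length(patterns))
    patterns <- character(0)
  genes <- windows$gene_id
  base <- expand.grid(gene_id = genes, pattern = patterns,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$count <- 0L
  base$min_abs_distance <- NA_integer_
  if (!nrow(hits) || !length(patterns)) {
    base <- base[order(base$pattern, match(base$gene_id, genes)), ]
    rownames(base) <- NULL
    return(base)
  }
  # point-in-interval overlap per sequence via IRanges
  w_ir <- IRanges::IRanges(start = windows$start + 1L, end = windows$end)
  h_ir <- IRanges::IRanges(start = hits$start + 1L, width = 1L)
  ov <- IRanges::findOverlaps(h_ir, w_ir)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  same_seq <- hits$seq_id[qh] == windows$seq_id[sh]
  qh <- qh[same_seq]; sh <- sh[same_seq]
  if (length(qh)) {
    d <- distance_to_tss(hits$start[qh], windows$tss[sh], windows$strand[sh])
    key <- paste(windows$gene_id[sh], hits$pattern[qh])
    tab <- tapply(rep(1L, length(qh)), key, sum)
    mind <- tapply(abs(d), key, min)
    base_key <- paste(base$gene_id, base$pattern)
    m <- match(base_key, names(tab))
    base$count <- ifelse(is.na(m), 0L, as.integer(tab[m]))
    base$min_abs_distance <- ifelse(is.na(m), NA_integer_,
                                    as.integer(mind[match(base_key,
                                                          names(mind))]))
  }
  base <- base[order(base$pattern, match(base$gene_id, genes)), ]
  rownames(base) <- NULL
  base
}

#' Strand-aware signed distance from a motif hit to a TSS
#'
#' Negative distances are upstream of the gene in its own orientation:
#' on the plus strand the distance is `start - tss`, on the minus strand
#' `tss - start`.
#'
#' @param hit_start Hit start coordinate(s), 0-based.
#' @param tss TSS coordinate(s), 0-based.
#' @param strand Gene strand(s), `"+"` or `"-"`.
#' @return Integer vector of signed distances in bases.
#' @examples
#' distance_to_tss(900, 1000, "+")   # -100 (upstream)
#' distance_to_tss(1100, 1000, "-")  # -100 (upstream)
#' @export
distance_to_tss <- function(hit_start, tss, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  as.integer(ifelse(strand == "+", hit_start - tss, tss - hit_start))
}

#' Write an association count table as TSV
#'
#' @param counts data.frame from [associate()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character",
                                   pattern = "character"))
}
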