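#' Read a genome FASTA
#'
#' Loads a multi-record FASTA as a [Biostrings::DNAStringSet]. Residues are
#' uppercased and any character outside `{A,C,G,T,N}` is replaced by `N`
#' with a warning (ambiguity codes and assembly artifacts are treated as
#' unknown). Sequence ids are the first whitespace-delimited word of each
#' header.
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet`, one entry per record.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences found in '", path, "'")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate seq_id in '", path, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chr <- toupper(as.character(seqs))
  n_other <- sum(vapply(chr, function(s)
    nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (n_other > 0) {
    warning(n_other, " non-ACGTN residue(s) replaced by N")
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  out
}

#' Read gene models from GFF3
#'
#' Extracts one gene object per record of `feature_kind` (default `mRNA`,
#' so each mRNA locus is a gene object) with a strand-aware 0-based
#' transcription start coordinate: plus-strand features start at
#' `GFF start - 1`, minus-strand features at `GFF end - 1`. Ids come from
#' the `ID` attribute; records lacking strand or `ID` are skipped with a
#' warning.
#'
#' @param path GFF3 file path (1-based inclusive coordinates).
#' @param feature_kind Feature type to extract (default `"mRNA"`).
#' @param seq_lengths Optional named vector of sequence lengths; when
#'   supplied, a TSS outside its sequence is an error.
#' @return data.frame with columns `gene_id`, `seq_id`, `strand`, `tss`.
#' @export
read_gene_models <- function(path, feature_kind = "mRNA",
                             seq_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_kind]
  if (length(gr) == 0L)
    stop("no '", feature_kind, "' features found in '", path, "'")
  ids <- as.character(gr$ID)
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- is.na(ids) | ids == "" | !(strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " ", feature_kind,
            " record(s) missing strand or ID skipped")
    gr <- gr[!bad]; ids <- ids[!bad]; strand <- strand[!bad]
  }
  if (length(gr) == 0L) stop("all '", feature_kind, "' records were skipped")
  if (anyDuplicated(ids))
    stop("duplicate gene ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tss <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr) - 1L)
  seq_id <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[seq_id]
    if (anyNA(len))
      stop("gene(s) on sequence(s) absent from seq_lengths: ",
           paste(unique(seq_id[is.na(len)]), collapse = ", "))
    out_of_range <- tss < 0L | tss >= len
    if (any(out_of_range))
      stop("TSS outside its sequence for: ",
           paste(ids[out_of_range], collapse = ", "))
  }
  data.frame(gene_id = ids, seq_id = seq_id, strand = strand,
             tss = as.integer(tss), stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' Emits one `mRNA` record per gene with the `ID` attribute set to the
#' gene id. The record anchors the strand-aware TSS (plus strand: GFF
#' start; minus strand: GFF end) and extends `transcript_length` bases
#' into the gene body, truncated at position 1.
#'
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path Output GFF3 path.
#' @param transcript_length Nominal transcript span in bases (default 300).
#' @param feature_kind Feature type to write (default `"mRNA"`).
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, transcript_length = 300L,
                              feature_kind = "mRNA") {
  stopifnot(all(c("gene_id", "seq_id", "strand", "tss") %in% names(genes)))
  start1 <- ifelse(genes$strand == "+", genes$tss + 1L,
                   pmax(1L, genes$tss + 2L - transcript_length))
  end1 <- ifelse(genes$strand == "+", genes$tss + transcript_length,
                 genes$tss + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_id,
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = genes$strand)
  gr$source <- "trescan"
  gr$type <- feature_kind
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Promoter windows around transcription start sites
#'
#' Builds the strand-aware promoter window used for all motif-gene
#' association: `upstream` bases upstream of the TSS through `downstream`
#' bases downstream, inclusive of the TSS base itself (width
#' `upstream + downstream + 1` when unclamped). Windows are clamped to
#' their sequence, never discarded, so the gene universe stays fixed.
#'
#' @param genes data.frame with `gene_id`, `seq_id`, `strand`, `tss`.
#' @param seq_lengths Named vector of sequence lengths (e.g.
#'   `Biostrings::width()` of a genome by seq id).
#' @param upstream,downstream Non-negative extents in bases
#'   (defaults 500 and 20).
#' @return data.frame with `gene_id`, `seq_id`, `start`, `end` (0-based
#'   half-open), `strand`, `tss`.
#' @examples
#' g <- data.frame(gene_id = "g1", seq_id = "chr1", strand = "+", tss = 600)
#' promoter_windows(g, c(chr1 = 10000))
#' @export
promoter_windows <- function(genes, seq_lengths, upstream = 500L,
                             downstream = 20L) {
  stopifnot(upstream >= 0L, downstream >= 0L,
            all(c("gene_id", "seq_id", "strand", "tss") %in% names(genes)))
  len <- seq_lengths[genes$seq_id]
  if (anyNA(len))
    stop("window referencing unknown seq_id: ",
         paste(unique(genes$seq_id[is.na(len)]), collapse = ", "))
  start <- ifelse(genes$strand == "+", genes$tss - upstream,
                  genes$tss - downstream)
  end <- ifelse(genes$strand == "+", genes$tss + downstream + 1L,
                genes$tss + upstream + 1L)
  data.frame(gene_id = genes$gene_id, seq_id = genes$seq_id,
             start = as.integer(pmax(0L, start)),
             end = as.integer(pmin(as.numeric(len), end)),
             strand = genes$strand, tss = as.integer(genes$tss),
             stringsAsFactors = FALSE)
}

#' Export promoter windows as BED6
#'
#' Writes windows in 6-column BED (0-based half-open); the name column
#' carries the gene id, the score column a small numeric hash of the gene
#' id, and the strand column the gene strand.
#'
#' @param windows data.frame from [promoter_windows()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
windows_to_bed <- function(windows, path) {
  score <- vapply(windows$gene_id,
                  function(g) sum(utf8ToInt(g)) %% 1000L, numeric(1),
                  USE.NAMES = FALSE)
  bed <- data.frame(windows$seq_id, windows$start, windows$end,
                    windows$gene_id, score, windows$strand)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
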