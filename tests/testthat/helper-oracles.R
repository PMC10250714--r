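# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's scanning internals:
# comparisons are done substring by substring with their own logic.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# position sets of a concrete-width placement; NULL marks a free slot
oracle_sets <- function(pattern, spacer = NA) {
  if (inherits(pattern, "tre_halfsite")) return(pattern$sets)
  c(pattern$half_a, rep(list(NULL), spacer), pattern$half_b)
}

oracle_mismatches <- function(chars, sets) {
  mm <- 0L
  for (j in seq_along(sets)) {
    s <- sets[[j]]
    if (is.null(s) || length(s) == 4L) next
    if (!(chars[j] %in% s)) mm <- mm + 1L
  }
  mm
}

# exhaustive enumeration over every (start, spacer, strand)
oracle_scan <- function(seq, pattern, seq_id = "chr", both_strands = TRUE) {
  fwd <- strsplit(toupper(seq), "")[[1]]
  L <- length(fwd)
  spacers <- if (inherits(pattern, "tre_halfsite")) NA else
    seq.int(pattern$spacer_min, pattern$spacer_max)
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    chars <- if (strand == "+") fwd else
      strsplit(oracle_revcomp(seq), "")[[1]]
    for (sp in spacers) {
      sets <- oracle_sets(pattern, sp)
      w <- length(sets)
      if (L < w) next
      for (s0 in 0:(L - w)) {
        mm <- oracle_mismatches(chars[(s0 + 1):(s0 + w)], sets)
        if (mm <= pattern$max_mismatches) {
          start_fwd <- if (strand == "+") s0 else L - s0 - w
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = seq_id, start = start_fwd, end = start_fwd + w,
            strand = strand, pattern = pattern$name,
            spacer = if (is.na(sp)) NA_integer_ else sp,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      pattern = character(0), spacer = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  # merge duplicate placements keeping the lowest mismatch count
  key <- paste(hits$seq_id, hits$start, hits$end, hits$strand, hits$pattern)
  hits <- hits[order(key, hits$mismatches), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$seq_id, hits$start, hits$end,
                                 hits$strand, hits$pattern)), , drop = FALSE]
  hits[order(hits$seq_id, hits$start, hits$end, hits$strand), , drop = FALSE]
}

# canonical-form comparison of two hit tables
expect_same_hits <- function(got, want) {
  canon <- function(h) {
    h <- h[order(h$seq_id, h$start, h$end, h$strand, h$spacer), , drop = FALSE]
    rownames(h) <- NULL
    h$spacer <- as.integer(h$spacer)
    h
  }
  expect_equal(canon(got), canon(want))
}

# Same enumeration over every (start, spacer, strand) as oracle_scan, but
# the per-start mismatch sum is assembled with rowSums over explicitly
# shifted position columns so sequences of tens of kilobases stay cheap.
oracle_scan_fast <- function(seq, pattern, seq_id = "chr") {
  fwd <- strsplit(toupper(seq), "")[[1]]
  L <- length(fwd)
  spacers <- if (inherits(pattern, "tre_halfsite")) NA else
    seq.int(pattern$spacer_min, pattern$spacer_max)
  rows <- list()
  for (strand in c("+", "-")) {
    chars <- if (strand == "+") fwd else
      strsplit(oracle_revcomp(seq), "")[[1]]
    for (sp in spacers) {
      sets <- oracle_sets(pattern, sp)
      w <- length(sets)
      n <- L - w + 1
      if (n < 1) next
      cols <- vapply(seq_len(w), function(j) {
        s <- sets[[j]]
        if (is.null(s) || length(s) == 4L) rep(FALSE, n)
        else !(chars[j:(j + n - 1)] %in% s)
      }, logical(n))
      mm <- if (n == 1) sum(cols) else rowSums(cols)
      hit <- which(mm <= pattern$max_mismatches)
      if (length(hit)) {
        s0 <- hit - 1L
        start_fwd <- if (strand == "+") s0 else L - s0 - w
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq_id, start = start_fwd, end = start_fwd + w,
          strand = strand, pattern = pattern$name,
          spacer = if (anyNA(sp)) NA_integer_ else sp,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      pattern = character(0), spacer = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  key <- paste(hits$seq_id, hits$start, hits$end, hits$strand, hits$pattern)
  hits <- hits[order(key, hits$mismatches), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$seq_id, hits$start, hits$end,
                                 hits$strand, hits$pattern)), , drop = FALSE]
  hits[order(hits$seq_id, hits$start, hits$end, hits$strand), , drop = FALSE]
}

# O(hits x windows) containment oracle for associate()
oracle_associate <- function(hits, windows, patterns) {
  out <- expand.grid(gene_id = windows$gene_id, pattern = patterns,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- 0L
  for (r in seq_len(nrow(out))) {
    w <- windows[windows$gene_id == out$gene_id[r], ]
    sel <- hits$pattern == out$pattern[r] & hits$seq_id == w$seq_id &
      hits$start >= w$start & hits$start < w$end
    out$count[r] <- sum(sel)
  }
  out
}

# independent textbook Welch computation
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# small gene set on one chromosome for association tests
toy_genes <- function(n = 4, seq_id = "chr1", spacing = 2000, tss0 = 1000) {
  data.frame(gene_id = paste0("g", seq_len(n)), seq_id = seq_id,
             strand = rep(c("+", "-"), length.out = n),
             tss = tss0 + (seq_len(n) - 1) * spacing,
             stringsAsFactors = FALSE)
}
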