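# pull the per-gene count vector for one pattern out of a long count table
pattern_counts <- function(counts, pattern = NULL) {
  stopifnot(all(c("gene_id", "pattern", "count") %in% names(counts)))
  if (!is.null(pattern)) {
    counts <- counts[counts$pattern == pattern, , drop = FALSE]
    if (!nrow(counts)) stop("pattern '", pattern, "' not present in counts")
  } else if (length(unique(counts$pattern)) > 1L) {
    stop("counts contain several patterns; supply `pattern`")
  }
  if (anyDuplicated(counts$gene_id))
    stop("duplicate gene_id within one pattern")
  stats::setNames(counts$count, counts$gene_id)
}

#' Two-tailed Welch t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p value — the comparison used by
#' every enrichment statistic in this package, where group sizes and
#' variances are typically very unequal (tens vs thousands of genes).
#' When both samples have zero variance the statistic is degenerate:
#' equal constants give `t = 0, p = 1` with a warning, different
#' constants give an infinite statistic and `p = 0`.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @return List with `t_stat`, `p_value`, `df`.
#' @examples
#' welch_t_two_tailed(c(1, 2, 3), c(1.5, 2.5, 3.5, 4.5))
#' @export
welch_t_two_tailed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample must contain at least 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("zero variance in both groups; p value is degenerate")
    if (mean(x) == mean(y)) return(list(t_stat = 0, p_value = 1, df = NA_real_))
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                df = NA_real_))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Choose the high-TRE count threshold from a DEG set
#'
#' Returns the largest integer `K` such that at least `min_degs`
#' differentially expressed genes carry `K` or more motif hits in their
#' promoter window, so the high-TRE group is as selective as the DEG
#' sample size allows. If even `K = 1` leaves fewer than `min_degs` DEGs,
#' `1` is returned with a warning.
#'
#' @param counts Long count table from [associate()], or one pattern of it.
#' @param degs Character vector of DEG gene ids.
#' @param pattern Pattern name to use when `counts` holds several.
#' @param min_degs Minimum number of DEGs the high group must contain
#'   (default 50).
#' @return Integer threshold `K`.
#' @export
choose_threshold <- function(counts, degs, pattern = NULL, min_degs = 50L) {
  stopifnot(min_degs >= 1L)
  if (!length(degs)) stop("empty DEG set")
  cnt <- pattern_counts(counts, pattern)
  deg_cnt <- cnt[names(cnt) %in% degs]
  if (!length(deg_cnt)) stop("no DEG appears in the count table")
  ks <- seq_len(max(deg_cnt, 1L))
  ok <- vapply(ks, function(k) sum(deg_cnt >= k) >= min_degs, logical(1))
  if (!any(ok)) {
    warning("fewer than ", min_degs,
            " DEGs at every threshold; falling back to K = 1")
    return(1L)
  }
  as.integer(max(ks[ok]))
}

#' Regulation strength of high-TRE vs zero-TRE genes
#'
#' Compares the magnitude of the log2 fold change between genes whose
#' promoter window carries at least `K` motif hits and genes with none,
#' for one pattern and one contrast: group means of `|log2FC|`, their
#' ratio (the fold-enrichment of regulation strength), and a two-tailed
#' Welch t test. With `use_abs = FALSE` the signed log2FC is compared
#' instead.
#'
#' @param counts Long count table from [associate()].
#' @param expression Expression data.frame with `gene_id`, `contrast`,
#'   `log2fc`, `padj`.
#' @param contrast Contrast label to select from `expression`.
#' @param pattern Pattern name to select from `counts`.
#' @param K High-group threshold (count >= K), e.g. from
#'   [choose_threshold()].
#' @param use_abs Compare `|log2FC|` (default) or signed log2FC.
#' @return One-row data.frame: `pattern`, `contrast`, `threshold_k`,
#'   `n_high`, `n_zero`, `mean_abs_lfc_high`, `mean_abs_lfc_zero`,
#'   `fold_ratio`, `t_stat`, `p_value`.
#' @export
lfc_by_tre_class <- function(counts, expression, contrast, pattern, K,
                             use_abs = TRUE) {
  stopifnot(K >= 1L,
            all(c("gene_id", "contrast", "log2fc") %in% names(expression)))
  cnt <- pattern_counts(counts, pattern)
  expr <- expression[expression$contrast == contrast, , drop = FALSE]
  if (!nrow(expr)) stop("no expression records for contrast '", contrast, "'")
  m <- match(names(cnt), expr$gene_id)
  keep <- !is.na(m)
  cnt <- cnt[keep]
  lfc <- expr$log2fc[m[keep]]
  val <- if (use_abs) abs(lfc) else lfc
  high <- val[cnt >= K]
  zero <- val[cnt == 0L]
  if (!length(high)) stop("high-TRE group (count >= ", K, ") is empty")
  if (!length(zero)) stop("zero-TRE group is empty")
  tt <- welch_t_two_tailed(high, zero)
  data.frame(pattern = pattern, contrast = contrast,
             threshold_k = as.integer(K),
             n_high = length(high), n_zero = length(zero),
             mean_abs_lfc_high = mean(high), mean_abs_lfc_zero = mean(zero),
             fold_ratio = if (mean(zero) > 0) mean(high) / mean(zero)
                          else NA_real_,
             t_stat = tt$t_stat, p_value = tt$p_value,
             stringsAsFactors = FALSE)
}

#' Motif enrichment near differentially expressed genes
#'
#' Defines DEGs as genes with `padj < alpha` and `|log2FC| >=
#' log2(fold_cut)` in the chosen contrast, then compares DEGs with the
#' remaining genes: mean promoter motif count in each group and their
#' ratio, the proportion of each group with at least one motif, and
#' two-tailed Welch t tests on the counts and on the presence
#' indicators (a two-proportion z test is available for the latter).
#'
#' @inheritParams lfc_by_tre_class
#' @param alpha Adjusted-p cutoff defining a DEG (default 0.05).
#' @param fold_cut Fold-change cutoff; the default 2 implements
#'   "at least 2-fold regulated" as `|log2FC| >= 1`.
#' @param prop_test `"t"` (default; Welch t on 0/1 indicators) or `"z"`
#'   (two-proportion z test) for the presence comparison.
#' @return One-row data.frame: `pattern`, `contrast`, `n_deg`,
#'   `n_nondeg`, `mean_count_deg`, `mean_count_nondeg`, `count_fold`,
#'   `prop_deg_with_tre`, `prop_nondeg_with_tre`, `p_count`, `p_prop`.
#' @export
deg_tre_enrichment <- function(counts, expression, contrast, pattern,
                               alpha = 0.05, fold_cut = 2,
                               prop_test = c("t", "z")) {
  stopifnot(fold_cut > 1,
            all(c("gene_id", "contrast", "log2fc", "padj")
                %in% names(expression)))
  prop_test <- match.arg(prop_test)
  cnt <- pattern_counts(counts, pattern)
  expr <- expression[expression$contrast == contrast, , drop = FALSE]
  if (!nrow(expr)) stop("no expression records for contrast '", contrast, "'")
  m <- match(names(cnt), expr$gene_id)
  keep <- !is.na(m)
  cnt <- cnt[keep]
  expr <- expr[m[keep], , drop = FALSE]
  is_deg <- expr$padj < alpha & abs(expr$log2fc) >= log2(fold_cut)
  if (!any(is_deg))
    stop("no DEGs at padj < ", alpha, " and |log2FC| >= ", log2(fold_cut),
         " for contrast '", contrast, "'")
  deg_cnt <- cnt[is_deg]
  non_cnt <- cnt[!is_deg]
  if (length(non_cnt) < 2L) stop("non-DEG group too small")
  p_count <- welch_t_two_tailed(deg_cnt, non_cnt)$p_value
  deg_pres <- as.numeric(deg_cnt > 0)
  non_pres <- as.numeric(non_cnt > 0)
  p_prop <- if (prop_test == "t") {
    suppressWarnings(welch_t_two_tailed(deg_pres, non_pres)$p_value)
  } else {
    stats::prop.test(c(sum(deg_pres), sum(non_pres)),
                     c(length(deg_pres), length(non_pres)),
                     correct = FALSE)$p.value
  }
  data.frame(pattern = pattern, contrast = contrast,
             n_deg = length(deg_cnt), n_nondeg = length(non_cnt),
             mean_count_deg = mean(deg_cnt),
             mean_count_nondeg = mean(non_cnt),
             count_fold = if (mean(non_cnt) > 0)
               mean(deg_cnt) / mean(non_cnt) else NA_real_,
             prop_deg_with_tre = mean(deg_pres),
             prop_nondeg_with_tre = mean(non_pres),
             p_count = p_count, p_prop = p_prop,
             stringsAsFactors = FALSE)
}

#' Gene ids passing the DEG definition for one contrast
#'
#' @inheritParams deg_tre_enrichment
#' @return Character vector of DEG gene ids.
#' @export
deg_set <- function(expression, contrast, alpha = 0.05, fold_cut = 2) {
  expr <- expression[expression$contrast == contrast, , drop = FALSE]
  expr$gene_id[expr$padj < alpha & abs(expr$log2fc) >= log2(fold_cut)]
}
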