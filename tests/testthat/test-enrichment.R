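make_counts <- function(cnt, pattern = "halfsite") {
  data.frame(gene_id = paste0("g", seq_along(cnt)), pattern = pattern,
             count = as.integer(cnt), min_abs_distance = NA_integer_,
             stringsAsFactors = FALSE)
}

make_expr <- function(lfc, padj = rep(0.01, length(lfc)),
                      contrast = "T4_27d") {
  data.frame(gene_id = paste0("g", seq_along(lfc)), contrast = contrast,
             log2fc = lfc, padj = padj, stringsAsFactors = FALSE)
}

test_that("Welch test matches a textbook computation and is symmetric", {
  x <- c(2.1, 1.9, 2.4, 2.0, 2.2, 1.8, 2.3, 2.5, 1.7, 2.6)
  y <- c(1.1, 1.4, 0.9, 1.2, 1.5, 1.0, 1.3, 0.8, 1.6, 1.05)
  got <- welch_t_two_tailed(x, y)
  want <- oracle_welch(x, y)
  expect_equal(got$t_stat, want$t, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  swapped <- welch_t_two_tailed(y, x)
  expect_equal(swapped$t_stat, -got$t_stat)
  expect_equal(swapped$p_value, got$p_value)
  expect_error(welch_t_two_tailed(1, y), "at least 2")
})

test_that("identical constant samples give t = 0, p = 1 with a warning", {
  expect_warning(r <- welch_t_two_tailed(rep(2, 5), rep(2, 8)),
                 "zero variance")
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
})

test_that("threshold selection keeps at least the required DEG count", {
  # 60 DEGs with >= 10 sites but only 40 with >= 11: K must be 10
  cnt <- c(rep(10, 20), rep(12, 40), rep(0, 140))
  counts <- make_counts(cnt)
  degs <- paste0("g", 1:100)
  expect_equal(choose_threshold(counts, degs), 10)
  expect_warning(k0 <- choose_threshold(make_counts(rep(0, 100)),
                                        paste0("g", 1:60)), "falling back")
  expect_equal(k0, 1)
  expect_error(choose_threshold(counts, character(0)), "empty DEG set")
})

test_that("threshold selection matches an exhaustive maximization", {
  set.seed(21)
  for (rep in 1:25) {
    n <- 300
    cnt <- rpois(n, sample(2:8, 1))
    counts <- make_counts(cnt)
    degs <- paste0("g", sample(n, sample(60:150, 1)))
    min_degs <- sample(c(20L, 50L), 1)
    got <- suppressWarnings(choose_threshold(counts, degs,
                                             min_degs = min_degs))
    deg_cnt <- cnt[match(degs, paste0("g", 1:n))]
    feasible <- Filter(function(k) sum(deg_cnt >= k) >= min_degs,
                       seq_len(max(1, max(deg_cnt))))
    want <- if (length(feasible)) max(feasible) else 1L
    expect_equal(got, want)
  }
})

test_that("identical constant |log2FC| in both classes gives ratio 1, p 1", {
  counts <- make_counts(c(rep(11, 10), rep(0, 10)))
  expr <- make_expr(rep(1.5, 20))
  r <- suppressWarnings(
    lfc_by_tre_class(counts, expr, "T4_27d", "halfsite", K = 10))
  expect_equal(r$fold_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$n_high, 10)
  expect_equal(r$n_zero, 10)
})

test_that("empty comparison groups are reported by name", {
  counts <- make_counts(c(rep(11, 10), rep(1, 10)))
  expr <- make_expr(rnorm(20))
  expect_error(lfc_by_tre_class(counts, expr, "T4_27d", "halfsite", K = 50),
               "high-TRE")
  expect_error(lfc_by_tre_class(counts, expr, "T4_27d", "halfsite", K = 1),
               "zero-TRE")
})

test_that("planted additive effects reproduce the folded-normal fold ratio", {
  # Monte-Carlo oracle for E|N(delta, sigma)| / E|N(0, sigma)|
  set.seed(22)
  sigma <- 0.5
  z <- rnorm(1e6)
  for (delta in c(0.5, 1.0)) {
    expected <- mean(abs(delta + sigma * z)) / mean(abs(sigma * z))
    n_high <- 400; n_zero <- 4000
    counts <- make_counts(c(rep(11, n_high), rep(0, n_zero)))
    sgn <- sample(c(-1, 1), n_high, replace = TRUE)
    lfc <- c(rnorm(n_high, sgn * delta, sigma), rnorm(n_zero, 0, sigma))
    r <- lfc_by_tre_class(make_counts(c(rep(11, n_high), rep(0, n_zero))),
                          make_expr(lfc), "T4_27d", "halfsite", K = 11)
    expect_equal(r$fold_ratio, expected, tolerance = 0.08)
    expect_lt(r$p_value, 1e-6)
  }
  # the ratio grows with the planted effect
  ratios <- sapply(c(0.25, 0.5, 1.0), function(delta) {
    sgn <- sample(c(-1, 1), 400, replace = TRUE)
    lfc <- c(rnorm(400, sgn * delta, sigma), rnorm(4000, 0, sigma))
    lfc_by_tre_class(make_counts(c(rep(11, 400), rep(0, 4000))),
                     make_expr(lfc), "T4_27d", "halfsite", K = 11)$fold_ratio
  })
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios >= 1))
})

test_that("identical count distributions give a DEG count fold of 1", {
  cnt <- c(0:9, 0:9)
  counts <- make_counts(cnt)
  padj <- c(rep(0.001, 10), rep(0.9, 10))
  expr <- make_expr(c(rep(2, 10), rep(0, 10)), padj = padj)
  r <- suppressWarnings(
    deg_tre_enrichment(counts, expr, "T4_27d", "halfsite"))
  expect_equal(r$count_fold, 1)
  expect_equal(r$prop_deg_with_tre, r$prop_nondeg_with_tre)
  expect_equal(r$n_deg, 10)
})

test_that("the DEG definition combines padj and fold-change cutoffs", {
  expr <- make_expr(c(2, 0.5, -1.2, 1.8), padj = c(0.01, 0.01, 0.2, 0.04))
  expect_setequal(deg_set(expr, "T4_27d"), c("g1", "g4"))
  # fold_cut = 4 means |log2FC| >= 2, excluding g4 at 1.8
  expect_setequal(deg_set(expr, "T4_27d", fold_cut = 4), "g1")
  counts <- make_counts(rep(1, 4))
  expect_error(deg_tre_enrichment(counts, make_expr(rep(0.1, 4)),
                                  "T4_27d", "halfsite"), "no DEGs")
})

test_that("DEG enrichment is invariant to gene order and pattern labels", {
  set.seed(23)
  n <- 200
  cnt <- rpois(n, 2)
  lfc <- rnorm(n, 0, 1.2)
  padj <- runif(n)
  counts <- make_counts(cnt)
  expr <- make_expr(lfc, padj = padj)
  r1 <- deg_tre_enrichment(counts, expr, "T4_27d", "halfsite")
  perm <- sample(n)
  r2 <- deg_tre_enrichment(counts[perm, ], expr, "T4_27d", "halfsite")
  counts3 <- counts; counts3$pattern <- "renamed"
  r3 <- deg_tre_enrichment(counts3, expr, "T4_27d", "renamed")
  expect_equal(r1$count_fold, r2$count_fold)
  expect_equal(r1$p_count, r2$p_count)
  expect_equal(r1$count_fold, r3$count_fold)
  expect_equal(r1$p_prop, r3$p_prop)
})
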