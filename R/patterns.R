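#' Compile a degenerate motif pattern from bracket notation
#'
#' Parses a dash-separated pattern specification into a structured motif
#' object. Tokens are single bases (`G`), bracketed alternatives (`[AG]`),
#' `N` (any base at an informative position), or a single spacer token
#' `N(min,max)` separating the two halfsites of a direct repeat.
#'
#' A pattern without a spacer token compiles to a *halfsite* pattern (one
#' run of position sets). A pattern with exactly one spacer token compiles
#' to a *direct repeat*: two halfsites separated by `min`..`max` arbitrary
#' bases. Spacer bases and plain-`N` positions never contribute mismatches;
#' the mismatch budget `max_mismatches` is spent jointly across all
#' informative positions of the whole pattern.
#'
#' @param spec Character scalar, e.g. `"[AG]-G-G-N-C-A"` or
#'   `"[AG]-[G]-G-[AT]-C-A-N(0,6)-[AG]-[G]-G-[AT]-C-A"`.
#' @param name Name to record on the pattern (defaults to `spec`).
#' @param max_mismatches Non-negative integer mismatch budget (default 0).
#' @return An object of class `tre_halfsite` or `tre_direct_repeat`, both
#'   inheriting from `tre_pattern`.
#' @examples
#' hs <- compile_pattern("[AG]-G-G-N-C-A", name = "halfsite")
#' dr <- compile_pattern("[AG]-[G]-G-[AT]-C-A-N(0,6)-[AG]-[G]-G-[AT]-C-A",
#'                       name = "dr0_6", max_mismatches = 2)
#' @export
compile_pattern <- function(spec, name = spec, max_mismatches = 0L) {
  stopifnot(is.character(spec), length(spec) == 1L, nchar(spec) > 0L)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer")
  tokens <- strsplit(spec, "-", fixed = TRUE)[[1]]
  sets <- list()
  spacer <- NULL  # c(min, max), at most one
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^N\\(([0-9]+),([0-9]+)\\)$", tok))[[1]]
    if (length(m) == 3L) {
      if (!is.null(spacer))
        stop("malformed pattern: more than one spacer token in '", spec, "'")
      spacer <- c(as.integer(m[2]), as.integer(m[3]))
      if (spacer[1] > spacer[2])
        stop("malformed spacer token '", tok, "': min exceeds max")
      sets <- c(sets, list("SPACER"))
    } else if (tok == "N") {
      sets <- c(sets, list(c("A", "C", "G", "T")))
    } else if (grepl("^[ACGT]$", tok)) {
      sets <- c(sets, list(tok))
    } else if (grepl("^\\[[ACGT]+\\]$", tok)) {
      ch <- unique(strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]])
      sets <- c(sets, list(ch))
    } else {
      stop("malformed pattern token '", tok, "' in '", spec, "'")
    }
  }
  if (is.null(spacer)) {
    structure(
      list(name = name, sets = sets, max_mismatches = max_mismatches),
      class = c("tre_halfsite", "tre_pattern"))
  } else {
    idx <- which(vapply(sets, function(s) identical(s, "SPACER"), logical(1)))
    if (idx == 1L || idx == length(sets))
      stop("malformed pattern: spacer token cannot start or end '", spec, "'")
    structure(
      list(name = name,
           half_a = sets[seq_len(idx - 1L)],
           half_b = sets[seq(idx + 1L, length(sets))],
           spacer_min = spacer[1], spacer_max = spacer[2],
           max_mismatches = max_mismatches),
      class = c("tre_direct_repeat", "tre_pattern"))
  }
}

#' Built-in thyroid hormone response element search patterns
#'
#' The three canonical TRE searches: the single halfsite
#' `[AG]-G-G-N-C-A` with no mismatches; the canonical DR4 direct repeat
#' (two halfsites spaced by exactly 4 bases, no mismatches); and the
#' permissive DR0-6 direct repeat `[AG]-[G]-G-[AT]-C-A` twice with a
#' 0-6 base spacer and a joint budget of two mismatches.
#'
#' @return Named list of `tre_pattern` objects: `halfsite`, `dr4`, `dr0_6`.
#' @examples
#' names(tre_patterns())
#' @export
tre_patterns <- function() {
  list(
    halfsite = compile_pattern("[AG]-G-G-N-C-A",
                               name = "halfsite", max_mismatches = 0L),
    dr4 = compile_pattern("[AG]-[G]-G-N-C-A-N(4,4)-[AG]-[G]-G-N-C-A",
                          name = "dr4", max_mismatches = 0L),
    dr0_6 = compile_pattern("[AG]-[G]-G-[AT]-C-A-N(0,6)-[AG]-[G]-G-[AT]-C-A",
                            name = "dr0_6", max_mismatches = 2L))
}

#' @export
print.tre_halfsite <- function(x, ...) {
  cat("<tre halfsite pattern '", x$name, "'> length ", length(x$sets),
      ", max mismatches ", x$max_mismatches, "\n", sep = "")
  invisible(x)
}

#' @export
print.tre_direct_repeat <- function(x, ...) {
  cat("<tre direct-repeat pattern '", x$name, "'> halfsites ",
      length(x$half_a), "+", length(x$half_b), ", spacer ", x$spacer_min,
      "-", x$spacer_max, ", max mismatches ", x$max_mismatches, "\n",
      sep = "")
  invisible(x)
}

# width of a concrete match; direct repeats need the realized spacer
pattern_width <- function(pattern, spacer = NULL) {
  if (inherits(pattern, "tre_halfsite")) return(length(pattern$sets))
  stopifnot(!is.null(spacer))
  length(pattern$half_a) + spacer + length(pattern$half_b)
}

# per-position allowed sets of a concrete-width instance; NULL = spacer slot
instance_sets <- function(pattern, spacer = NULL) {
  if (inherits(pattern, "tre_halfsite")) return(pattern$sets)
  stopifnot(!is.null(spacer))
  c(pattern$half_a, rep(list(NULL), spacer), pattern$half_b)
}

#' Count mismatches of a sequence window against a pattern
#'
#' Compares a residue string position by position with a compiled pattern.
#' Spacer positions and any-base (`N`) pattern positions contribute no
#' mismatches; a residue outside the allowed set at an informative position
#' contributes one. The residue `N` never satisfies an informative position,
#' so assembly gaps count as mismatches.
#'
#' @param window Character scalar whose length equals the pattern width
#'   (halfsite length, or halfsites plus `spacer` for a direct repeat).
#' @param pattern A `tre_pattern`.
#' @param spacer Realized spacer length, required for direct repeats.
#' @return Integer mismatch count.
#' @examples
#' count_mismatches("AGGTCA", tre_patterns()$halfsite)
#' @export
count_mismatches <- function(window, pattern, spacer = NULL) {
  stopifnot(inherits(pattern, "tre_pattern"),
            is.character(window), length(window) == 1L)
  if (inherits(pattern, "tre_direct_repeat")) {
    if (is.null(spacer)) stop("spacer is required for direct-repeat patterns")
    spacer <- as.integer(spacer)
    if (spacer < pattern$spacer_min || spacer > pattern$spacer_max)
      stop("spacer ", spacer, " outside pattern range [",
           pattern$spacer_min, ", ", pattern$spacer_max, "]")
  }
  sets <- instance_sets(pattern, spacer)
  if (nchar(window) != length(sets))
    stop("window length ", nchar(window),
         " does not match pattern width ", length(sets))
  chars <- strsplit(toupper(window), "")[[1]]
  mm <- 0L
  for (j in seq_along(sets)) {
    s <- sets[[j]]
    if (is.null(s) || length(s) == 4L) next  # spacer / any-base: free
    if (!chars[j] %in% s) mm <- mm + 1L
  }
  mm
}
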