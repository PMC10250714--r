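# sample one concrete zero-mismatch instance of a pattern; direct repeats
# draw a spacer uniformly from the allowed range. Returns list(seq, spacer).
sample_instance <- function(pattern) {
  draw <- function(sets) vapply(sets, function(s) {
    if (is.null(s)) sample(c("A", "C", "G", "T"), 1L) else
      s[sample.int(length(s), 1L)]
  }, character(1))
  if (inherits(pattern, "tre_halfsite")) {
    list(seq = paste(draw(pattern$sets), collapse = ""), spacer = NA_integer_)
  } else {
    choices <- seq.int(pattern$spacer_min, pattern$spacer_max)
    sp <- choices[sample.int(length(choices), 1L)]
    list(seq = paste(draw(instance_sets(pattern, sp)), collapse = ""),
         spacer = sp)
  }
}

#' Generate a random genome with regularly spaced gene models
#'
#' Emits one chromosome of i.i.d. bases at the requested GC content with
#' `n_genes` gene models placed one per `gene_spacing`-base block,
#' strands alternating. Each gene's promoter window (see
#' [promoter_windows()]) falls wholly inside its own block, so windows of
#' neighbouring genes never overlap. Deterministic given `seed`.
#'
#' @param n_genes Number of genes (default 2000).
#' @param gene_spacing Block size per gene in bases (default 1000); must
#'   accommodate the promoter window.
#' @param gc_content GC fraction in (0, 1) (default 0.5, which keeps
#'   motif occurrence probabilities analytic).
#' @param seed Integer seed (required; no silent global randomness).
#' @param upstream,downstream Promoter window extents used to place the
#'   genes (defaults 500 and 20).
#' @param seq_id Chromosome name (default `"chr1"`).
#' @return List with `genome` (a one-sequence `DNAStringSet`) and
#'   `genes` (data.frame `gene_id`, `seq_id`, `strand`, `tss`).
#' @export
gen_genome_and_genes <- function(n_genes = 2000L, gene_spacing = 1000L,
                                 gc_content = 0.5, seed,
                                 upstream = 500L, downstream = 20L,
                                 seq_id = "chr1") {
  stopifnot(n_genes >= 1L, gc_content > 0, gc_content < 1)
  if (missing(seed)) stop("an explicit seed is required")
  width <- upstream + downstream + 1L
  gap <- (gene_spacing - width) %/% 2L
  if (gap < 0L)
    stop("gene_spacing ", gene_spacing, " cannot hold a ", width,
         "-base promoter window; genes would overlap")
  set.seed(seed)
  total_len <- (n_genes + 1L) * gene_spacing  # trailing block for gene bodies
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  codes <- utf8ToInt("ACGT")[sample.int(4L, total_len, replace = TRUE,
                                        prob = p)]
  genome <- Biostrings::DNAStringSet(intToUtf8(codes))
  names(genome) <- seq_id
  block <- (seq_len(n_genes) - 1L) * gene_spacing
  strand <- rep(c("+", "-"), length.out = n_genes)
  tss <- block + gap + ifelse(strand == "+", upstream, downstream)
  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    seq_id = seq_id, strand = strand, tss = as.integer(tss),
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

#' Plant zero-mismatch motif instances in promoter windows
#'
#' Overwrites `count_per_gene` non-overlapping positions inside the
#' promoter window of a seeded random subset of genes (`fraction_affected`
#' of them) with concrete zero-mismatch instances of `pattern`, on a
#' random strand. The window is partitioned into `count_per_gene` equal
#' blocks and one instance is placed at a random offset within each, so
#' instances never overlap. Background occurrences elsewhere are
#' untouched, so a re-scan recovers *at least* the planted count.
#'
#' @param genome `DNAStringSet`, e.g. from [gen_genome_and_genes()].
#' @param genes Gene data.frame (`gene_id`, `seq_id`, `strand`, `tss`).
#' @param pattern `tre_pattern` to plant (default the canonical halfsite).
#' @param fraction_affected Fraction of genes receiving instances
#'   (default 0.1).
#' @param count_per_gene Instances per affected gene (default 11).
#' @param seed Integer seed (required).
#' @param upstream,downstream Promoter window extents (defaults 500, 20).
#' @param strands Strands instances may be written on (default both).
#' @return List with `genome` (modified copy) and `truth` (data.frame
#'   `gene_id`, `pattern`, `planted_count`, `effect_class`).
#' @export
plant_tres <- function(genome, genes, pattern = tre_patterns()$halfsite,
                       fraction_affected = 0.1, count_per_gene = 11L,
                       seed, upstream = 500L, downstream = 20L,
                       strands = c("+", "-")) {
  stopifnot(inherits(pattern, "tre_pattern"),
            fraction_affected >= 0, fraction_affected <= 1,
            count_per_gene >= 1L, all(strands %in% c("+", "-")))
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  seq_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  windows <- promoter_windows(genes, seq_lengths, upstream, downstream)
  max_len <- if (inherits(pattern, "tre_halfsite")) length(pattern$sets)
             else pattern_width(pattern, pattern$spacer_max)
  block_size <- min(windows$end - windows$start) %/% count_per_gene
  if (block_size < max_len)
    stop("promoter window too small for ", count_per_gene,
         " non-overlapping instances of width ", max_len)
  n_aff <- round(fraction_affected * nrow(genes))
  affected <- sort(sample.int(nrow(genes), n_aff))
  ints <- lapply(as.character(genome), utf8ToInt)
  planted <- integer(nrow(genes))
  for (i in affected) {
    w0 <- windows$start[i]
    sid <- windows$seq_id[i]
    for (j in seq_len(count_per_gene)) {
      inst <- sample_instance(pattern)
      len <- nchar(inst$seq)
      off <- sample.int(block_size - len + 1L, 1L) - 1L
      s0 <- w0 + (j - 1L) * block_size + off
      strand <- if (length(strands) > 1L) sample(strands, 1L) else strands
      seq_out <- if (strand == "+") inst$seq else revcomp_chr(inst$seq)
      ints[[sid]][(s0 + 1L):(s0 + len)] <- utf8ToInt(seq_out)
    }
    planted[i] <- count_per_gene
  }
  out <- Biostrings::DNAStringSet(
    vapply(ints, intToUtf8, character(1)))
  names(out) <- names(genome)
  truth <- data.frame(
    gene_id = genes$gene_id, pattern = pattern$name,
    planted_count = planted,
    effect_class = ifelse(planted > 0L, "affected", "null"),
    stringsAsFactors = FALSE)
  list(genome = out, truth = truth)
}

#' Generate a differential-expression table with a motif-linked effect
#'
#' Genes classed `affected` in the truth table receive a log2 fold change
#' drawn from `Normal(+/-delta, sigma_lfc)` (sign random per gene); null
#' genes from `Normal(0, sigma_lfc)`. P values come from a two-sided
#' normal test of `log2fc / se_lfc` and are Benjamini-Hochberg adjusted.
#' Deterministic given `seed`.
#'
#' @param truth Truth data.frame from [plant_tres()].
#' @param delta Additive |log2FC| effect for affected genes (default 1).
#' @param sigma_lfc Between-gene log2FC standard deviation (default 0.5).
#' @param se_lfc Per-gene standard error used for the test (default 0.25).
#' @param seed Integer seed (required).
#' @param contrast Contrast label (default `"T4_27d"`).
#' @return List with `expression` (data.frame `gene_id`, `contrast`,
#'   `log2fc`, `pvalue`, `padj`) and `truth` (input plus `true_delta`).
#' @export
gen_expression <- function(truth, delta = 1, sigma_lfc = 0.5,
                           se_lfc = 0.25, seed, contrast = "T4_27d") {
  stopifnot(sigma_lfc > 0, se_lfc > 0,
            all(c("gene_id", "effect_class") %in% names(truth)))
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  n <- nrow(truth)
  affected <- truth$effect_class == "affected"
  sgn <- ifelse(affected, sample(c(-1, 1), n, replace = TRUE), 0)
  mu <- sgn * delta
  lfc <- stats::rnorm(n, mean = mu, sd = sigma_lfc)
  p <- 2 * stats::pnorm(-abs(lfc / se_lfc))
  truth$true_delta <- mu
  list(expression = data.frame(gene_id = truth$gene_id, contrast = contrast,
                               log2fc = lfc, pvalue = p,
                               padj = stats::p.adjust(p, method = "BH"),
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate noisy binding observations from a one-site model
#'
#' Evaluates [saturation_model()] or [competition_model()] over a
#' dilution series and adds Gaussian noise with standard deviation
#' `noise_frac` times the model's dynamic range, independently per
#' replicate and point. Deterministic given `seed`.
#'
#' @param params Named list of model parameters: for `"saturation"`,
#'   `kd`, `bmax` and optionally `ns_slope`, `background`; for
#'   `"competition"`, `ki`, `top`, `bottom`, `hot_conc`, `hot_kd`.
#' @param design A [make_dilution_series()] object (default: the 18-point
#'   3-fold series from 2.7e-4 M).
#' @param n_replicates Replicate series (default 3).
#' @param noise_frac Noise sd as a fraction of the model dynamic range
#'   (default 0.05).
#' @param seed Integer seed (required).
#' @param model `"competition"` (default) or `"saturation"`.
#' @return data.frame with `conc`, `signal`, `replicate`.
#' @export
gen_binding <- function(params, design = make_dilution_series(2.7e-4, 3, 18),
                        n_replicates = 3L, noise_frac = 0.05, seed,
                        model = c("competition", "saturation")) {
  stopifnot(inherits(design, "dilution_series"), noise_frac >= 0,
            n_replicates >= 1L)
  if (missing(seed)) stop("an explicit seed is required")
  model <- match.arg(model)
  set.seed(seed)
  conc <- design$concentrations
  mu <- if (model == "saturation") {
    saturation_model(conc, kd = params$kd, bmax = params$bmax,
                     ns_slope = params$ns_slope %||% 0,
                     background = params$background %||% 0)
  } else {
    competition_model(log10(conc), ki = params$ki, top = params$top,
                      bottom = params$bottom, hot_conc = params$hot_conc,
                      hot_kd = params$hot_kd)
  }
  sdev <- noise_frac * (max(mu) - min(mu))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(conc = conc,
               signal = mu + stats::rnorm(length(mu), 0, sdev),
               replicate = r)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ready-to-run synthetic dataset
#'
#' `"enrichment"` writes `genome.fa`, `genes.gff3`, `expression.tsv` and
#' `truth.tsv` for the motif-enrichment pipeline (random genome, planted
#' halfsites in 10% of promoters, expression table with a delta = 1
#' effect on the planted genes). `"binding"` writes `saturation.csv` and
#' `competition.csv` simulated from the one-site models under the
#' 18-point 3-fold dilution design with 3 replicates and 5% noise.
#'
#' @param preset `"enrichment"` or `"binding"`.
#' @param seed Integer seed (required).
#' @param out_dir Output directory (created if absent).
#' @param ... Overrides passed to the underlying generators
#'   ([gen_genome_and_genes()]/[plant_tres()]/[gen_expression()] or
#'   [gen_binding()]).
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_preset <- function(preset = c("enrichment", "binding"), seed,
                            out_dir, ...) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("an explicit seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dots <- list(...)
  arg <- function(name, default) dots[[name]] %||% default
  if (preset == "enrichment") {
    gg <- gen_genome_and_genes(n_genes = arg("n_genes", 2000L),
                               gene_spacing = arg("gene_spacing", 1000L),
                               gc_content = arg("gc_content", 0.5),
                               seed = seed)
    pl <- plant_tres(gg$genome, gg$genes,
                     pattern = arg("pattern", tre_patterns()$halfsite),
                     fraction_affected = arg("fraction_affected", 0.1),
                     count_per_gene = arg("count_per_gene", 11L),
                     seed = seed + 1L)
    ex <- gen_expression(pl$truth, delta = arg("delta", 1),
                         sigma_lfc = arg("sigma_lfc", 0.5),
                         se_lfc = arg("se_lfc", 0.25), seed = seed + 2L)
    files <- c(genome = file.path(out_dir, "genome.fa"),
               genes = file.path(out_dir, "genes.gff3"),
               expression = file.path(out_dir, "expression.tsv"),
               truth = file.path(out_dir, "truth.tsv"))
    Biostrings::writeXStringSet(pl$genome, files["genome"])
    write_gene_models(gg$genes, files["genes"])
    utils::write.table(ex$expression, files["expression"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(ex$truth, files["truth"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    design <- arg("design", make_dilution_series(2.7e-4, 3, 18))
    sat <- gen_binding(list(kd = arg("kd", 9.5e-8), bmax = arg("bmax", 100),
                            ns_slope = arg("ns_slope", 0),
                            background = arg("background", 0)),
                       design = design, seed = seed, model = "saturation",
                       noise_frac = arg("noise_frac", 0.05))
    cmp <- gen_binding(list(ki = arg("ki", 1e-9), top = arg("top", 100),
                            bottom = arg("bottom", 0),
                            hot_conc = arg("hot_conc", 1e-7),
                            hot_kd = arg("hot_kd", 9.5e-8)),
                       design = design, seed = seed + 1L,
                       model = "competition",
                       noise_frac = arg("noise_frac", 0.05))
    files <- c(saturation = file.path(out_dir, "saturation.csv"),
               competition = file.path(out_dir, "competition.csv"))
    utils::write.csv(sat, files["saturation"], row.names = FALSE)
    utils::write.csv(cmp, files["competition"], row.names = FALSE)
  }
  invisible(files)
}
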