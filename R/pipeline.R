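#' Read and write flat key=value run configuration files
#'
#' A run configuration is a named list; on disk it is a plain text file
#' with one `key = value` pair per line (`#` comments allowed).
#' Comma-separated values are split into vectors; numeric-looking values
#' are converted.
#'
#' @param path Config file path.
#' @return `read_config()` returns the named list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!anyNA(num)) num else val
  }
  cfg
}

#' @rdname read_config
#' @param config Named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

pipeline_defaults <- function() {
  list(patterns = c("halfsite", "dr4", "dr0_6"),
       feature_kind = "mRNA", upstream = 500, downstream = 20,
       alpha = 0.05, fold_cut = 2, min_degs = 50, both_strands = TRUE,
       adjust_p = FALSE)
}

require_fields <- function(config, fields) {
  missing_f <- setdiff(fields, names(config))
  if (length(missing_f))
    stop("config is missing required field(s): ",
         paste(missing_f, collapse = ", "))
}

#' Run the scan - associate - enrich pipeline
#'
#' Orchestrates the full motif-enrichment analysis from files to files:
#' reads the genome and gene models, scans the selected patterns on both
#' strands, tallies hits in promoter windows, and computes both
#' enrichment analyses (regulation strength of high-TRE vs zero-TRE
#' genes with a data-chosen threshold, and motif count/presence
#' enrichment near DEGs) for every requested contrast. All tables plus
#' the resolved configuration and a run log are written to
#' `config$out_dir`. Any stage failure is reported with its stage name.
#'
#' @param config Named list or path to a key=value config file. Required
#'   fields: `genome`, `gff`, `expression`, `out_dir`. Optional:
#'   `patterns` (default all three of [tre_patterns()]), `feature_kind`,
#'   `upstream`, `downstream`, `alpha`, `fold_cut`, `min_degs`,
#'   `contrasts` (default: all in the expression table), `both_strands`,
#'   and `adjust_p` (add Benjamini-Hochberg columns across the
#'   pattern x contrast families; off by default).
#' @return Invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  require_fields(cfg, c("genome", "gff", "expression", "out_dir"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("trescan ", as.character(utils::packageVersion("trescan")))
  stage <- function(name, expr) {
    logf("stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("read_genome", read_genome(cfg$genome))
  seq_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  genes <- stage("read_gene_models",
                 read_gene_models(cfg$gff, feature_kind = cfg$feature_kind,
                                  seq_lengths = seq_lengths))
  windows <- stage("promoter_windows",
                   promoter_windows(genes, seq_lengths,
                                    upstream = cfg$upstream,
                                    downstream = cfg$downstream))
  pats <- tre_patterns()[cfg$patterns]
  if (anyNA(names(pats)))
    stop("unknown pattern(s): ",
         paste(setdiff(cfg$patterns, names(tre_patterns())), collapse = ", "))
  hits <- stage("scan_sequence", do.call(rbind, lapply(pats, function(p)
    scan_sequence(genome, p, both_strands = isTRUE(cfg$both_strands)))))
  rownames(hits) <- NULL
  counts <- stage("associate",
                  associate(hits, windows, patterns = names(pats),
                            seq_ids = names(genome)))
  expression <- stage("read_expression", {
    ex <- utils::read.delim(cfg$expression, stringsAsFactors = FALSE)
    require_fields(ex, c("gene_id", "contrast", "log2fc", "padj"))
    ex
  })
  contrasts <- cfg$contrasts %||% unique(expression$contrast)
  enr <- stage("enrichment", do.call(rbind, lapply(contrasts, function(ct) {
    degs <- deg_set(expression, ct, alpha = cfg$alpha,
                    fold_cut = cfg$fold_cut)
    do.call(rbind, lapply(names(pats), function(pn) {
      K <- choose_threshold(counts, degs, pattern = pn,
                            min_degs = cfg$min_degs)
      lfc_by_tre_class(counts, expression, contrast = ct, pattern = pn,
                       K = K)
    }))
  })))
  deg_enr <- stage("deg_enrichment",
                   do.call(rbind, lapply(contrasts, function(ct)
    do.call(rbind, lapply(names(pats), function(pn)
      deg_tre_enrichment(counts, expression, contrast = ct, pattern = pn,
                         alpha = cfg$alpha, fold_cut = cfg$fold_cut))))))
  if (isTRUE(cfg$adjust_p)) {
    # optional BH correction across the pattern x contrast families
    enr$p_value_bh <- stats::p.adjust(enr$p_value, method = "BH")
    deg_enr$p_count_bh <- stats::p.adjust(deg_enr$p_count, method = "BH")
    deg_enr$p_prop_bh <- stats::p.adjust(deg_enr$p_prop, method = "BH")
  }
  files <- c(hits = file.path(cfg$out_dir, "hits.csv"),
             counts = file.path(cfg$out_dir, "counts.tsv"),
             enrichment_lfc = file.path(cfg$out_dir, "enrichment_lfc.tsv"),
             enrichment_deg = file.path(cfg$out_dir, "enrichment_deg.tsv"),
             config = file.path(cfg$out_dir, "run_config.txt"),
             log = log_path)
  stage("write_outputs", {
    write_hits(hits, files["hits"])
    write_counts(counts, files["counts"])
    utils::write.table(enr, files["enrichment_lfc"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(deg_enr, files["enrichment_deg"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_config(cfg[order(names(cfg))], files["config"])
  })
  logf("done")
  invisible(as.list(files))
}
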