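#' @title End-to-end pipeline driver
#' @description Runs simulate -> map -> annotate -> filter -> summarize ->
#'   select -> correlate with a single configuration object. Every stage
#'   writes its artifact under the configured output directory, thresholds
#'   are logged as applied, and an md5 checksum manifest makes reruns
#'   byte-comparable.
#' @name pipeline
NULL

.rp_version <- function() {
  tryCatch(as.character(utils::packageVersion("retroprobe")),
           error = function(e) "0.0.0")
}

#' Pipeline configuration
#'
#' Threshold values live only here (defaults are the published values) so
#' sensitivity re-runs need no code change.
#'
#' @param outdir output directory for all artifacts.
#' @param seed integer seed driving the synthetic inputs.
#' @param chemistry platform chemistry.
#' @param min_identity mapping identity threshold (default 0.95).
#' @param min_probeset_re_fraction strict probeset RE fraction (default 0.75).
#' @param min_gene_distance strict gene distance in bases (default 1000).
#' @param alpha ANOVA retention threshold on raw p (default 0.01).
#' @param tissue tissue level for the nearest-gene regression.
#' @param bgcorrect apply background correction (disable for matrices that
#'   are already corrected).
#' @param biweight_c,biweight_epsilon biweight constants.
#' @param simulate generate the inputs; when FALSE, \code{genome_path},
#'   \code{manifest_path}, \code{repeats_path}, \code{genes_path},
#'   \code{expression_path} and \code{factors_path} must name existing
#'   files.
#' @param ... input paths used when \code{simulate = FALSE}.
#' @return a \code{run_config} list.
#' @export
pipeline_config <- function(outdir, seed = 1L, chemistry = "antisense_crna",
                            min_identity = 0.95,
                            min_probeset_re_fraction = 0.75,
                            min_gene_distance = 1000L, alpha = 0.01,
                            tissue = "heart", bgcorrect = TRUE,
                            biweight_c = 5, biweight_epsilon = 1e-4,
                            simulate = TRUE, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    chemistry = match.arg(tolower(chemistry),
                          c("antisense_crna", "sense_cdna")),
    filter = filter_config(min_identity, min_probeset_re_fraction,
                           min_gene_distance),
    min_identity = min_identity, alpha = alpha, tissue = tissue,
    bgcorrect = isTRUE(bgcorrect), biweight_c = biweight_c,
    biweight_epsilon = biweight_epsilon, simulate = isTRUE(simulate),
    inputs = list(...)
  )
  class(cfg) <- "run_config"
  cfg
}

.validate_config <- function(cfg) {
  if (!cfg$simulate) {
    need <- c("genome_path", "manifest_path", "repeats_path", "genes_path",
              "expression_path", "factors_path")
    for (key in need) {
      p <- cfg$inputs[[key]]
      if (is.null(p) || !file.exists(p))
        stop("config validation: input '", key, "' missing or not a file: ",
             if (is.null(p)) "<unset>" else p)
    }
  }
  invisible(TRUE)
}

.stage_header <- function(cfg, stage) {
  c(sprintf("# retroprobe %s | stage=%s | seed=%d | chemistry=%s",
            .rp_version(), stage, cfg$seed, cfg$chemistry),
    sprintf("# min_identity=%g min_probeset_re_fraction=%g min_gene_distance=%d alpha=%g c=%g epsilon=%g",
            cfg$min_identity, cfg$filter$min_probeset_re_fraction,
            cfg$filter$min_gene_distance, cfg$alpha, cfg$biweight_c,
            cfg$biweight_epsilon))
}

#' Run the full pipeline
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with the stage results, artifact paths,
#'   checksums, and a summary comparing the retained probe set against the
#'   planted truth when the inputs were simulated.
#' @export
run_pipeline <- function(cfg) {
  .validate_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(.stage_header(cfg, "start"), sep = "\n", file = log_path)

  spec <- fixture_spec(seed = cfg$seed, chemistry = cfg$chemistry)
  truth <- NULL
  if (cfg$simulate) {
    gen <- generate_genome(spec, outdir = cfg$outdir)
    plat <- generate_platform(spec, gen, outdir = cfg$outdir)
    expr <- generate_expression(spec, gen, plat, outdir = cfg$outdir)
    truth <- plat$truth
    paths <- list(genome = gen$paths$genome, repeats = gen$paths$repeats,
                  genes = gen$paths$genes, manifest = plat$paths$manifest,
                  expression = expr$paths$linear,
                  factors = expr$paths$factors)
    logf("simulate: %d chromosomes, %d repeats, %d genes, %d probes",
         length(gen$genome), nrow(gen$repeats), nrow(gen$genes),
         nrow(plat$manifest$probes))
  } else {
    paths <- list(genome = cfg$inputs$genome_path,
                  repeats = cfg$inputs$repeats_path,
                  genes = cfg$inputs$genes_path,
                  manifest = cfg$inputs$manifest_path,
                  expression = cfg$inputs$expression_path,
                  factors = cfg$inputs$factors_path)
  }

  # everything downstream goes through the file formats
  genome <- Biostrings::readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  manifest <- read_platform_manifest(paths$manifest,
                                     chemistry = cfg$chemistry)
  repeats <- read_repeatmasker_out(paths$repeats)
  genes <- read_gene_annotation(paths$genes, format = "gtf")

  hits <- map_platform(manifest, genome, min_identity = cfg$min_identity)
  hits_path <- file.path(cfg$outdir, "hits.tsv")
  write_hits_tsv(hits, hits_path, header = .stage_header(cfg, "map"))
  logf("map: %d/%d probes placed", sum(hits$mapped), nrow(hits))

  annot <- build_annotation(manifest, hits, repeats, genes,
                            chemistry = cfg$chemistry)
  annot_path <- file.path(cfg$outdir, "annotation.csv")
  write_annotation_csv(annot, annot_path)
  logf("annotate: %d RE-reporting probes", nrow(annot))

  filtered <- enhanced_filter(annot, manifest, cfg$filter)
  filtered_path <- file.path(cfg$outdir, "filtered.csv")
  write_annotation_csv(filtered, filtered_path)
  coverage <- coverage_table(filtered, repeats)
  coverage_path <- file.path(cfg$outdir, "coverage.tsv")
  writeLines(.stage_header(cfg, "filter"), coverage_path)
  suppressWarnings(utils::write.table(coverage, coverage_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  logf("filter: %d probes retained (unique, intergenic >%d b, fraction >%g)",
       nrow(filtered), cfg$filter$min_gene_distance,
       cfg$filter$min_probeset_re_fraction)

  m_lin <- read_expression_matrix(paths$expression, paths$factors,
                                  scale = "linear")
  m <- if (cfg$bgcorrect) background_correct(m_lin) else m_lin
  m <- log2_transform(quantile_normalize(m))
  gene_sets <- grep("^ps_gene_", unique(manifest$probes$probeset),
                    value = TRUE)
  gene_summaries <- summarize_probeset(m, manifest, c = cfg$biweight_c,
                                       epsilon = cfg$biweight_epsilon,
                                       probesets = gene_sets)
  rownames(gene_summaries) <- sub("^ps_gene_", "", rownames(gene_summaries))
  summary_path <- file.path(cfg$outdir, "gene_summaries.tsv")
  con <- file(summary_path, "w")
  writeLines(.stage_header(cfg, "summarize"), con)
  utils::write.table(data.frame(gene = rownames(gene_summaries),
                                gene_summaries, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  selection <- anova_select(m, factor = "tissue", eliminate = "experiment",
                            alpha = cfg$alpha)
  selection_path <- file.path(cfg$outdir, "selection.tsv")
  con <- file(selection_path, "w")
  writeLines(.stage_header(cfg, "select"), con)
  utils::write.table(selection, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  logf("select: %d/%d probes at alpha=%g (tissue, eliminating experiment)",
       sum(selection$retained), nrow(selection), cfg$alpha)

  regression <- NULL
  if (nrow(filtered) > 0) {
    regression <- nearest_gene_regression(
      m$values[filtered$pid, , drop = FALSE], gene_summaries, filtered,
      m$sample_factors, tissue = cfg$tissue)
    regression_path <- file.path(cfg$outdir, "regression.tsv")
    con <- file(regression_path, "w")
    writeLines(.stage_header(cfg, "correlate"), con)
    utils::write.table(regression, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    logf("correlate: %s", paste(sprintf("%s r2=%.3f", regression$class,
                                        regression$r_squared),
                                collapse = ", "))
  }

  artifacts <- c(unlist(paths[c("genome", "repeats", "genes", "manifest",
                                "expression", "factors")]),
                 hits = hits_path, annotation = annot_path,
                 filtered = filtered_path, coverage = coverage_path,
                 summaries = summary_path, selection = selection_path,
                 regression = if (nrow(filtered) > 0)
                   file.path(cfg$outdir, "regression.tsv"))
  checksums <- tools::md5sum(artifacts)
  writeLines(sprintf("%s  %s", checksums, basename(names(checksums))),
             file.path(cfg$outdir, "checksums.txt"))

  summary <- NULL
  if (!is.null(truth)) {
    re_truth <- truth$pid[truth$expect_re]
    re_called <- annot$pid
    ret_truth <- truth$pid[truth$expect_retained]
    ret_called <- filtered$pid
    prf <- function(called, expected) {
      tp <- length(intersect(called, expected))
      c(precision = if (length(called)) tp / length(called) else NA,
        recall = if (length(expected)) tp / length(expected) else NA)
    }
    summary <- list(
      re = prf(re_called, re_truth),
      retained = prf(ret_called, ret_truth),
      n_re = nrow(annot), n_retained = nrow(filtered)
    )
    logf("truth: RE precision=%.3f recall=%.3f; retained precision=%.3f recall=%.3f",
         summary$re["precision"], summary$re["recall"],
         summary$retained["precision"], summary$retained["recall"])
  }

  invisible(list(
    config = cfg, truth = truth, hits = hits, annotation = annot,
    filtered = filtered, coverage = coverage, matrix = m,
    gene_summaries = gene_summaries, selection = selection,
    regression = regression, artifacts = artifacts, checksums = checksums,
    summary = summary
  ))
}
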