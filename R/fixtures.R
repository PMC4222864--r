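#' @title Deterministic synthetic-data generator
#' @description Produces toy-scale genomes, repeat and gene annotations,
#'   platform manifests and expression matrices with a recorded ground
#'   truth for every planted probe, standing in for full genome builds,
#'   repeat libraries and public expression accessions. A single integer
#'   seed drives one independent stream per sub-generator (genome,
#'   platform, expression) so extending one plan never perturbs the others.
#' @name fixtures
NULL

# one RNG stream per sub-generator, kept inside 32-bit integer range
.stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% 2147483647)
}

.rc <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Fixture specification
#'
#' Defaults describe the bundled demo fixture: a 3 x 60 kb genome carrying
#' 41 planted repeat instances (LTR, LINE and SINE families on both
#' strands, one family in 3 identical copies), 10 protein-coding genes and
#' one lincRNA, and a platform whose probesets straddle every filtering
#' boundary (9/11, 8/11 and 3/4 RE fractions; gene distances of exactly
#' 1000 and 1001 bases; multi-copy, wrong-orientation, boundary-overhang,
#' genic and unmappable probes).
#'
#' @param seed integer seed fixing all randomness.
#' @param chrom_length length of each chromosome in bases.
#' @param probe_length probe length in bases (default 25).
#' @param chemistry platform chemistry for probe orientation.
#' @param n_tissues,n_experiments expression design shape (samples are the
#'   tissue x experiment cells; experiments act as replicates-cum-batches).
#' @param tissue_effect planted tissue effect for tissue-specific genes,
#'   log2 units.
#' @param batch_effect planted experiment (batch) offset, log2 units.
#' @param shared_fraction fraction of RE probe variance shared with the
#'   nearest gene's expression (default 0.3).
#' @param noise_sd residual probe noise SD, log2 units.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed = 1L, chrom_length = 60000L,
                         probe_length = 25L,
                         chemistry = "antisense_crna",
                         n_tissues = 3L, n_experiments = 3L,
                         tissue_effect = 2.0, batch_effect = 0.5,
                         shared_fraction = 0.3, noise_sd = 0.5) {
  stopifnot(seed == floor(seed), chrom_length >= 40000, probe_length >= 10)
  structure(list(
    seed = as.integer(seed), chrom_length = as.integer(chrom_length),
    probe_length = as.integer(probe_length),
    chemistry = match.arg(tolower(chemistry),
                          c("antisense_crna", "sense_cdna")),
    n_tissues = n_tissues, n_experiments = n_experiments,
    tissue_effect = tissue_effect, batch_effect = batch_effect,
    shared_fraction = shared_fraction, noise_sd = noise_sd
  ), class = "fixture_spec")
}

# the demo layout: items placed left to right per chromosome with explicit
# gaps; repeats carry a key the probe plan refers back to
.demo_layout <- function() {
  rep_item <- function(key, name, class, strand, gap, len = 400L)
    list(kind = "repeat", key = key, name = name, class = class,
         strand = strand, gap = gap, len = len)
  gene_item <- function(key, biotype, strand, gap, len = 2000L)
    list(kind = "gene", key = key, biotype = biotype, strand = strand,
         gap = gap, len = len)
  list(
    chr1 = c(
      list(gene_item("G01", "protein_coding", "+", 1000L)),
      lapply(1:3, function(i) rep_item(paste0("r_ret_", i), "RLTR44-int",
        "LTR/ERVK", if (i == 2) "-" else "+", 2000L)),
      list(gene_item("G02", "protein_coding", "-", 2000L)),
      lapply(4:6, function(i) rep_item(paste0("r_ret_", i),
        c("L1Md_F", "L1Md_F", "B2_Mm1a")[i - 3],
        c("LINE/L1", "LINE/L1", "SINE/B2")[i - 3], "+", 2000L)),
      list(gene_item("NC01", "lincRNA", "+", 2000L)),
      lapply(7:9, function(i) rep_item(paste0("r_ret_", i),
        c("B2_Mm1a", "RLTR6-int", "RLTR6-int")[i - 6],
        c("SINE/B2", "LTR/ERVK", "LTR/ERVK")[i - 6],
        if (i == 8) "-" else "+", 2000L)),
      lapply(1:5, function(i) rep_item(paste0("r_pure_", i), "RLTR4_MM",
        "LTR/ERVK", if (i %in% c(2, 4)) "-" else "+", 2000L)),
      list(gene_item("G03", "protein_coding", "+", 2000L))
    ),
    chr2 = c(
      list(gene_item("G04", "protein_coding", "+", 1000L)),
      lapply(1:8, function(i) rep_item(paste0("r_ff_", i), "RLTR1B",
        "LTR/ERV1", if (i %% 2 == 0) "-" else "+", 1200L)),
      list(gene_item("G05", "protein_coding", "-", 1200L)),
      lapply(1:3, function(i) rep_item(paste0("r_ef_", i), "MT2B",
        "LTR/ERVL-MaLR", "+", 1200L))
    ),
    chr3 = c(
      list(
        gene_item("G06", "protein_coding", "+", 1000L),
        rep_item("r_near_1", "RLTR1B", "LTR/ERV1", "+", 300L),
        rep_item("r_near_2", "RLTR1B", "LTR/ERV1", "+", 200L),
        gene_item("G07", "protein_coding", "+", 3000L),
        rep_item("r_near_3", "RLTR1B", "LTR/ERV1", "-", 300L),
        rep_item("r_near_4", "RLTR1B", "LTR/ERV1", "+", 200L),
        gene_item("G08", "protein_coding", "+", 2500L),
        rep_item("r_d1000", "RLTR44-int", "LTR/ERVK", "+", 1000L),
        gene_item("G09", "protein_coding", "+", 2500L),
        rep_item("r_d1001", "RLTR44-int", "LTR/ERVK", "+", 1001L)
      ),
      lapply(1:4, function(i) rep_item(paste0("r_wo_", i), "L1Md_A",
        "LINE/L1", "+", 1500L)),
      lapply(1:3, function(i) rep_item(paste0("r_ov_", i), "B2_Mm1t",
        "SINE/B2", "+", 1500L)),
      lapply(1:3, function(i) rep_item(paste0("r_multi_", i), "MURVY-int",
        "LTR/ERVK", "+", 1500L)),
      list(rep_item("r_single", "RLTR1B", "LTR/ERV1", "+", 1500L),
           gene_item("G10", "protein_coding", "-", 2000L))
    )
  )
}

#' Generate the synthetic genome, repeat annotation and gene annotation
#'
#' Places the demo layout's repeats and genes without overlap on random
#' chromosome sequences; the multi-copy repeat family is planted as
#' identical copies. When \code{outdir} is given the genome FASTA,
#' RepeatMasker .out and GTF files are written and are guaranteed to parse
#' with the package's readers.
#'
#' @param spec a [fixture_spec()].
#' @param outdir optional output directory.
#' @return list with \code{genome} (DNAStringSet), \code{repeats} and
#'   \code{genes} data.frames (0-based half-open, with a \code{key}
#'   column), and \code{paths} when written.
#' @export
generate_genome <- function(spec, outdir = NULL) {
  set.seed(.stream_seed(spec$seed, 1))
  layout <- .demo_layout()
  seqs <- list(); reps <- list(); genes <- list()
  for (chrom in names(layout)) {
    seqs[[chrom]] <- .random_dna(spec$chrom_length)
    cursor <- 500L
    for (item in layout[[chrom]]) {
      start <- cursor + item$gap
      end <- start + item$len
      if (end > spec$chrom_length)
        stop("fixture plan exceeds chromosome capacity on ", chrom)
      if (item$kind == "repeat") {
        reps[[length(reps) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = end, strand = item$strand,
          repeat_name = item$name, repeat_class = item$class,
          key = item$key, stringsAsFactors = FALSE)
      } else {
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = end, strand = item$strand,
          gene_id = item$key, symbol = item$key, biotype = item$biotype,
          key = item$key, stringsAsFactors = FALSE)
      }
      cursor <- end
    }
  }
  reps <- do.call(rbind, reps); genes <- do.call(rbind, genes)
  # identical multi-family copies: copy the first instance's sequence
  multi <- reps[grepl("^r_multi_", reps$key), ]
  if (nrow(multi) > 1) {
    src <- multi[1, ]
    tmpl <- substr(seqs[[src$chrom]], src$start + 1L, src$end)
    for (i in 2:nrow(multi)) {
      tgt <- multi[i, ]
      substr(seqs[[tgt$chrom]], tgt$start + 1L, tgt$end) <- tmpl
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(seqs)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      repeats = file.path(outdir, "repeats.out"),
      genes = file.path(outdir, "genes.gtf")
    )
    Biostrings::writeXStringSet(genome, paths$genome)
    write_repeatmasker_out(reps[, names(reps) != "key"], paths$repeats)
    write_gene_gtf(genes[, names(genes) != "key"], paths$genes)
  }
  list(genome = genome, repeats = reps, genes = genes, paths = paths)
}

# sense-of-element probe sequence for a repeat substring, honoring chemistry
.probe_seq <- function(genome, rep_row, offset, plen, chemistry,
                       orientation = c("correct", "wrong")) {
  orientation <- match.arg(orientation)
  fwd <- substr(as.character(genome[[rep_row$chrom]]),
                rep_row$start + offset + 1L, rep_row$start + offset + plen)
  # probe strand that classifies as RE-reporting for this chemistry
  want <- if (chemistry == "antisense_crna") rep_row$strand else
    if (rep_row$strand == "+") "-" else "+"
  if (orientation == "wrong") want <- if (want == "+") "-" else "+"
  if (want == "+") fwd else .rc(fwd)
}

.mutate_base <- function(seq, pos) {
  b <- substr(seq, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), b)[1]
  substr(seq, pos, pos) <- repl
  seq
}

#' Generate the platform manifest with per-probe ground truth
#'
#' Samples probe sequences from the planted genome features. Probeset
#' composition is engineered to straddle the enhanced-filtering fraction
#' boundary (9/11, 8/11, 3/4 RE members), and the probe categories cover
#' every classification outcome: uniquely mapped intergenic RE probes
#' (including one carrying a single mismatch), near-gene RE probes within
#' 1 kb, RE probes at gene distances of exactly 1000 and 1001 bases,
#' multi-copy RE probes, wrong-orientation and boundary-overhang negatives,
#' genic probes, and unmappable probes.
#'
#' @param spec a [fixture_spec()].
#' @param gen result of [generate_genome()].
#' @param outdir optional output directory for the manifest TSV and truth
#'   table.
#' @return list with \code{manifest} (a [platform_manifest()]) and
#'   \code{truth} (data.frame: pid, probeset, category, source_key,
#'   expect_re, expect_retained, expect_numhits, nearest_gene).
#' @export
generate_platform <- function(spec, gen, outdir = NULL) {
  set.seed(.stream_seed(spec$seed, 2))
  plen <- spec$probe_length
  chem <- spec$chemistry
  reps <- gen$repeats; genes <- gen$genes
  rep_by_key <- function(k) reps[reps$key == k, , drop = FALSE]
  probes <- list(); truth <- list(); pid_n <- 0L
  add_probe <- function(probeset, sequence, category, source_key,
                        expect_re, expect_retained, expect_numhits) {
    pid_n <<- pid_n + 1L
    pid <- sprintf("p%03d", pid_n)
    probes[[pid_n]] <<- data.frame(pid = pid, probeset = probeset,
                                   sequence = sequence,
                                   stringsAsFactors = FALSE)
    truth[[pid_n]] <<- data.frame(
      pid = pid, probeset = probeset, category = category,
      source_key = source_key, expect_re = expect_re,
      expect_retained = expect_retained, expect_numhits = expect_numhits,
      stringsAsFactors = FALSE)
  }
  re_probe <- function(probeset, key, category, retained, offset = 50L,
                       orientation = "correct", mismatches = 0L,
                       numhits = 1L, expect_re = TRUE) {
    r <- rep_by_key(key)
    seq <- .probe_seq(gen$genome, r, offset, plen, chem, orientation)
    if (mismatches > 0L)
      for (p in seq_len(mismatches)) seq <- .mutate_base(seq, 3L + 5L * p)
    add_probe(probeset, seq, category, key, expect_re, retained, numhits)
  }
  gene_probe <- function(probeset, key, offset, category = "genic") {
    g <- genes[genes$key == key, ]
    seq <- substr(as.character(gen$genome[[g$chrom]]),
                  g$start + offset + 1L, g$start + offset + plen)
    add_probe(probeset, seq, category, key, FALSE, FALSE, 1L)
  }

  # probeset straddling the fraction boundary from above: 9/11 RE
  for (i in 1:9) re_probe("ps_frac_9of11", paste0("r_ret_", i),
                          "re_retained", TRUE)
  gene_probe("ps_frac_9of11", "G01", 200L)
  gene_probe("ps_frac_9of11", "G02", 200L)
  # 8/11 RE: fraction 0.727, below the strict 0.75 threshold
  for (i in 1:8) re_probe("ps_frac_8of11", paste0("r_ff_", i),
                          "re_frac_fail", FALSE)
  for (off in c(240L, 280L, 320L)) gene_probe("ps_frac_8of11", "G04", off)
  # 3/4 RE: exactly 0.75, rejected by the strict inequality
  for (i in 1:3) re_probe("ps_frac_3of4", paste0("r_ef_", i),
                          "re_exact_frac_fail", FALSE)
  gene_probe("ps_frac_3of4", "G05", 200L)
  # all-RE probeset; probe 5 carries one mismatch (still >= 95% identity)
  for (i in 1:5) re_probe("ps_pure", paste0("r_pure_", i), "re_retained",
                          TRUE, mismatches = if (i == 5) 1L else 0L)
  # within 1 kb of a gene: classified RE, removed by the distance filter
  for (i in 1:4) re_probe("ps_near_gene", paste0("r_near_", i),
                          "re_near_gene", FALSE, offset = 0L)
  # exact distance boundary: 1000 rejected, 1001 retained (strict >)
  re_probe("ps_d1000", "r_d1000", "re_dist_1000", FALSE, offset = 0L)
  re_probe("ps_d1001", "r_d1001", "re_dist_1001", TRUE, offset = 0L)
  # multi-copy family: probes hit all 3 identical copies
  for (off in c(30L, 90L, 150L, 210L))
    re_probe("ps_multi", "r_multi_1", "re_multi", FALSE, offset = off,
             numhits = 3L)
  # wrong-orientation negatives: antisense to what the chemistry requires
  for (i in 1:4) re_probe("ps_wrong_orient", paste0("r_wo_", i),
                          "wrong_orientation", FALSE,
                          orientation = "wrong", expect_re = FALSE)
  # boundary overhang: one base past the repeat end
  for (i in 1:3) {
    r <- rep_by_key(paste0("r_ov_", i))
    re_probe("ps_overhang", paste0("r_ov_", i), "boundary_overhang", FALSE,
             offset = r$end - r$start - plen + 1L, expect_re = FALSE)
  }
  # purely genic probeset
  for (off in c(400L, 500L, 600L, 700L)) gene_probe("ps_genic", "G03", off)
  # probeset with a single RE probe among genic peers, co-regulated with
  # them: exercises the probe-vs-probeset concordance test (1/4 RE, so the
  # fraction filter rejects it)
  re_probe("ps_single_re", "r_single", "re_single_concordant", FALSE)
  for (off in c(300L, 400L, 500L)) gene_probe("ps_single_re", "G10", off)
  # unmappable probes: random sequence absent from the genome
  for (i in 1:3)
    add_probe("ps_unmappable", .random_dna(plen), "unmappable", NA, FALSE,
              FALSE, 0L)
  # per-gene probesets used for nearest-gene summaries
  for (g in sprintf("G%02d", 1:10))
    for (off in c(800L, 900L, 1000L))
      gene_probe(paste0("ps_gene_", g), g, off, category = "gene_set")

  manifest <- platform_manifest("retroprobe-demo", chem,
                                do.call(rbind, probes))
  truth <- do.call(rbind, truth)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(manifest = file.path(outdir, "manifest.tsv"),
                  truth = file.path(outdir, "truth_probes.tsv"))
    write_platform_manifest(manifest, paths$manifest)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(manifest = manifest, truth = truth, paths = paths)
}

# nearest protein-coding gene symbol and gap for a planted repeat
# (generator-side ground truth, independent of the annotation code path)
.truth_nearest_gene <- function(rep_row, genes) {
  g <- genes[genes$biotype == "protein_coding" &
               genes$chrom == rep_row$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NA_character_)
  gaps <- ifelse(g$end <= rep_row$start, rep_row$start - g$end,
                 ifelse(g$start >= rep_row$end, g$start - rep_row$end, 0L))
  g$symbol[which.min(gaps)]
}

#' Generate the probe-level expression matrix with planted effects
#'
#' Samples are the tissue x experiment cells. Each gene receives a
#' tissue-specific signal (one preferred tissue, planted effect size) plus
#' an experiment (batch) offset; probes of its probeset follow that signal
#' with independent noise. Each RE-reporting probe shares a planted
#' fraction of its variance with the expression signal of its nearest
#' protein-coding gene; all other probes are pure noise around their
#' probeset baseline. One probe of the first gene probeset is shifted by
#' +4 log2 units as a planted outlier for the biweight summarization.
#'
#' @param spec a [fixture_spec()].
#' @param gen result of [generate_genome()].
#' @param plat result of [generate_platform()].
#' @param outdir optional output directory for the matrix and factor TSVs.
#' @return list with \code{matrix} (a log2-scale [expr_matrix()]),
#'   \code{linear} (same data on the linear scale), \code{gene_signal}
#'   (genes x samples), and \code{paths} when written.
#' @export
generate_expression <- function(spec, gen, plat, outdir = NULL) {
  set.seed(.stream_seed(spec$seed, 3))
  if (spec$n_experiments < 2)
    stop("need >= 2 replicates (experiments) per tissue for planted effects")
  tissues <- c("heart", "brain", "spleen")[seq_len(spec$n_tissues)]
  experiments <- sprintf("e%d", seq_len(spec$n_experiments))
  sf <- expand.grid(experiment = experiments, tissue = tissues,
                    stringsAsFactors = FALSE)[, c("tissue", "experiment")]
  rownames(sf) <- paste(sf$tissue, sf$experiment, sep = "_")
  n_s <- nrow(sf)
  batch <- stats::setNames(spec$batch_effect * (seq_along(experiments) - 1),
                           experiments)
  coding <- gen$genes[gen$genes$biotype == "protein_coding", ]
  pref <- stats::setNames(tissues[(seq_len(nrow(coding)) - 1) %% length(tissues) + 1],
                          coding$symbol)
  gene_signal <- t(vapply(coding$symbol, function(sym) {
    b <- stats::rnorm(1, 8, 1)
    b + spec$tissue_effect * (sf$tissue == pref[[sym]]) +
      batch[sf$experiment] + stats::rnorm(n_s, 0, 0.2)
  }, numeric(n_s)))
  colnames(gene_signal) <- rownames(sf)

  truth <- plat$truth
  probes <- plat$manifest$probes
  vals <- matrix(NA_real_, nrow(probes), n_s,
                 dimnames = list(probes$pid, rownames(sf)))
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  set_base <- stats::setNames(stats::rnorm(length(unique(probes$probeset)), 8, 1),
                              unique(probes$probeset))
  for (i in seq_len(nrow(probes))) {
    pid <- probes$pid[i]
    tr <- truth[truth$pid == pid, ]
    if (tr$probeset == "ps_single_re") {
      # whole probeset (RE probe included) tracks its gene's signal
      vals[pid, ] <- gene_signal["G10", ] + stats::rnorm(1, 0, 0.2) +
        stats::rnorm(n_s, 0, spec$noise_sd)
    } else if (tr$category == "gene_set" || tr$category == "genic") {
      sym <- if (tr$category == "gene_set") sub("^ps_gene_", "", tr$probeset)
             else tr$source_key
      sig <- if (sym %in% rownames(gene_signal)) gene_signal[sym, ]
             else set_base[[tr$probeset]] + numeric(n_s)
      vals[pid, ] <- sig + stats::rnorm(1, 0, 0.2) +
        stats::rnorm(n_s, 0, spec$noise_sd)
    } else if (isTRUE(tr$expect_re)) {
      rep_row <- gen$repeats[gen$repeats$key == tr$source_key, ][1, ]
      sym <- .truth_nearest_gene(rep_row, gen$genes)
      f <- spec$shared_fraction
      shared <- if (!is.na(sym)) std(gene_signal[sym, ]) else stats::rnorm(n_s)
      vals[pid, ] <- set_base[[tr$probeset]] +
        sqrt(f) * shared + sqrt(1 - f) * stats::rnorm(n_s)
    } else {
      vals[pid, ] <- set_base[[tr$probeset]] + stats::rnorm(n_s, 0, spec$noise_sd)
    }
  }
  # planted outlier probe within the first gene probeset
  out_pid <- probes$pid[probes$probeset == "ps_gene_G01"][1]
  vals[out_pid, ] <- vals[out_pid, ] + 4
  m_log <- expr_matrix(vals, scale = "log2", sample_factors = sf)
  m_lin <- expr_matrix(2^vals, scale = "linear", sample_factors = sf)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(matrix = file.path(outdir, "expression_log2.tsv"),
                  linear = file.path(outdir, "expression_linear.tsv"),
                  factors = file.path(outdir, "sample_factors.tsv"))
    write_expression_matrix(m_log, paths$matrix, paths$factors)
    write_expression_matrix(m_lin, paths$linear)
  }
  list(matrix = m_log, linear = m_lin, gene_signal = gene_signal,
       paths = paths)
}

#' Simulate probe values for ANOVA calibration
#'
#' Null probes carry no tissue effect; effect probes receive graded tissue
#' means (0, effect, 2*effect) in units of the residual SD.
#'
#' @param n_null,n_effect numbers of null and effect probes.
#' @param n_tissues,n_reps design shape.
#' @param effect between-tissue step in residual-SD units (default 3).
#' @param noise_sd residual SD.
#' @param seed integer seed.
#' @return log2-scale [expr_matrix()]; effect probe ids start with "eff".
#' @export
simulate_anova_matrix <- function(n_null = 1000L, n_effect = 0L,
                                  n_tissues = 3L, n_reps = 3L, effect = 3,
                                  noise_sd = 1, seed = 1L) {
  set.seed(seed)
  tissues <- sprintf("t%d", seq_len(n_tissues))
  sf <- expand.grid(rep = seq_len(n_reps), tissue = tissues,
                    stringsAsFactors = FALSE)[, c("tissue", "rep")]
  rownames(sf) <- paste(sf$tissue, sf$rep, sep = "_")
  sf$rep <- NULL
  n_s <- nrow(sf)
  shift <- effect * noise_sd * (match(sf$tissue, tissues) - 1)
  n <- n_null + n_effect
  vals <- matrix(stats::rnorm(n * n_s, 8, noise_sd), n, n_s,
                 dimnames = list(
                   c(sprintf("null%04d", seq_len(n_null)),
                     if (n_effect) sprintf("eff%04d", seq_len(n_effect))),
                   rownames(sf)))
  if (n_effect)
    vals[n_null + seq_len(n_effect), ] <-
      vals[n_null + seq_len(n_effect), ] + rep(shift, each = n_effect)
  expr_matrix(vals, scale = "log2", sample_factors = sf)
}

#' Simulate RE-gene probe pairs with a planted shared-variance fraction
#'
#' Each point pairs an RE probe value with its nearest gene's summary
#' value. The noise component is orthogonalized against the gene signal
#' and rescaled so the planted fraction is the sample r-squared exactly,
#' not merely in expectation: parameter-recovery checks then measure the
#' estimator, not Monte-Carlo noise in the truth.
#'
#' @param n_probes number of RE probe / gene pairs (one sample each).
#' @param shared_fraction planted r-squared in [0, 1].
#' @param seed integer seed.
#' @return list with \code{re_matrix} (probes x 1), \code{gene_summaries}
#'   (genes x 1), \code{annot} (minimal annotation rows linking each probe
#'   to its gene), \code{sample_factors}.
#' @export
simulate_coregulation <- function(n_probes = 500L, shared_fraction = 0.3,
                                  seed = 1L) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  set.seed(seed)
  g <- stats::rnorm(n_probes, 8, 1)
  shared <- g - 8
  noise <- stats::rnorm(n_probes)
  noise <- stats::residuals(stats::lm(noise ~ g))   # exactly uncorrelated
  noise <- noise / stats::sd(noise)
  re <- if (shared_fraction == 0) 6 + noise
        else 6 + shared +
          noise * stats::sd(shared) * sqrt((1 - shared_fraction) /
                                             shared_fraction)
  pids <- sprintf("re%04d", seq_len(n_probes))
  gids <- sprintf("G%04d", seq_len(n_probes))
  re_matrix <- matrix(re, ncol = 1, dimnames = list(pids, "heart_s1"))
  gene_summaries <- matrix(g, ncol = 1, dimnames = list(gids, "heart_s1"))
  annot <- data.frame(
    pid = pids, probeset = pids, plen = 25L, sid = "chr1",
    sstart = 5000L, send = 5025L, nident = 25L, numhits = 1L,
    repeat_name = "RLTR44-int", repclass = "LTR/ERVK",
    rstart = 4900L, rend = 5300L,
    fivep_id = gids, fivep_start = 1000L, fivep_end = 3000L,
    threep_id = NA_character_, threep_start = NA_integer_,
    threep_end = NA_integer_, stringsAsFactors = FALSE
  )
  sf <- data.frame(tissue = "heart", row.names = "heart_s1")
  list(re_matrix = re_matrix, gene_summaries = gene_summaries,
       annot = annot, sample_factors = sf)
}

#' Simulate one array from the signal-plus-noise convolution model
#'
#' Observed intensity = exponential signal + normal noise, the generative
#' model assumed by the background correction.
#'
#' @param n number of probes.
#' @param signal_mean mean of the exponential signal component.
#' @param noise_mean,noise_sd normal noise parameters.
#' @param seed integer seed.
#' @return list with \code{observed} and \code{signal} vectors.
#' @export
simulate_normexp_array <- function(n = 5000L, signal_mean = 200,
                                   noise_mean = 100, noise_sd = 20,
                                   seed = 1L) {
  set.seed(seed)
  signal <- stats::rexp(n, rate = 1 / signal_mean)
  observed <- signal + stats::rnorm(n, noise_mean, noise_sd)
  list(observed = pmax(observed, 1e-6), signal = signal)
}
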