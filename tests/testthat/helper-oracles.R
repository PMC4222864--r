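# Independent oracles, deliberately naive, used to cross-check the package
# implementations. They never call package code paths they verify.

# mismatch count of `probe` against `chrom` at every offset (0-based),
# by direct base comparison; 'N' never matches
oracle_mismatches <- function(probe, chrom) {
  L <- nchar(probe); G <- nchar(chrom)
  if (G < L) return(integer(0))
  g <- charToRaw(chrom); p <- charToRaw(probe)
  n_off <- G - L + 1L
  mm <- integer(n_off)
  for (j in seq_len(L)) mm <- mm + (g[j:(j + n_off - 1L)] != p[j])
  mm
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# all qualifying placements of a probe on a genome given as a named
# character vector; returns data.frame(sid, sstart, strand, nident)
oracle_map <- function(probe, genome_chr, min_identity = 0.95) {
  L <- nchar(probe)
  need <- as.integer(ceiling(min_identity * L))
  rows <- list()
  for (sid in names(genome_chr)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") probe else oracle_revcomp(probe)
      mm <- oracle_mismatches(q, genome_chr[[sid]])
      hit <- which(L - mm >= need)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          sid = sid, sstart = hit - 1L, strand = strand,
          nident = L - mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sid = character(), sstart = integer(),
                      strand = character(), nident = integer()))
  do.call(rbind, rows)
}

# straight-line transcription of the one-step biweight formula
oracle_biweight <- function(x, c = 5, epsilon = 1e-4) {
  M <- median(x)
  S <- median(abs(x - M))
  num <- 0; den <- 0
  for (xi in x) {
    u <- (xi - M) / (c * S + epsilon)
    w <- if (abs(u) < 1) (1 - u^2)^2 else 0
    num <- num + w * xi
    den <- den + w
  }
  num / den
}

# mean-of-order-statistics quantile normalization for tie-free columns
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) target[rank(col)])
}

# random genome with planted probes for mapper cross-checks
random_genome <- function(n_chroms, len) {
  g <- vapply(seq_len(n_chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  names(g) <- sprintf("chr%d", seq_len(n_chroms))
  g
}

mutate_at <- function(seq, pos) {
  b <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"), b)[1]
  seq
}

as_dss <- function(genome_chr) {
  Biostrings::DNAStringSet(genome_chr)
}

demo_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 101L)
      gen <- generate_genome(spec)
      plat <- generate_platform(spec, gen)
      expr <- generate_expression(spec, gen, plat)
      hits <- map_platform(plat$manifest, gen$genome)
      annot <- build_annotation(plat$manifest, hits,
                                gen$repeats, gen$genes)
      filtered <- enhanced_filter(annot, plat$manifest)
      cache <<- list(spec = spec, gen = gen, plat = plat, expr = expr,
                     hits = hits, annot = annot, filtered = filtered)
    }
    cache
  }
})
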