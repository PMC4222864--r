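#' @title Probe-to-genome mapping
#' @description Localizes each probe on the genome by full-length ungapped
#'   matching on both strands, counts placements meeting the identity
#'   threshold, and reports the highest-scoring hit. Identity is measured
#'   against the full probe length: a placement qualifies when it has at
#'   least \code{ceiling(min_identity * plen)} identical bases. Ambiguity
#'   bases (N) in the genome never match.
#' @name probe_mapper
NULL

# qualifying matches of `pattern` (a DNAString) on one chromosome sequence;
# returns data.frame(sstart, send, nident) in 0-based half-open coordinates
.scan_chrom <- function(pattern, chrom_seq, max_mm) {
  plen <- length(pattern)
  if (length(chrom_seq) < plen)
    return(data.frame(sstart = integer(), nident = integer()))
  m <- Biostrings::matchPattern(pattern, chrom_seq, max.mismatch = max_mm,
                                with.indels = FALSE, fixed = TRUE)
  if (length(m) == 0L)
    return(data.frame(sstart = integer(), nident = integer()))
  s <- BiocGenerics::start(m); e <- BiocGenerics::end(m)
  keep <- s >= 1L & e <= length(chrom_seq)
  s <- s[keep]
  if (length(s) == 0L)
    return(data.frame(sstart = integer(), nident = integer()))
  nedit <- Biostrings::neditStartingAt(pattern, chrom_seq, starting.at = s,
                                       with.indels = FALSE, fixed = TRUE)
  data.frame(sstart = s - 1L, nident = plen - nedit)
}

#' Map one probe onto a genome
#'
#' Scans both strands of every chromosome for full-length ungapped
#' placements of the probe with identity at or above \code{min_identity}.
#' \code{numhits} counts all qualifying placements (distinct
#' chromosome/offset/strand triples); the reported hit is the one with
#' maximal identical-base count, ties broken by lowest chromosome name, then
#' start, then strand ("+" before "-").
#'
#' @param probe one-row data.frame (or list) with \code{pid},
#'   \code{sequence}, \code{plen}.
#' @param genome named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param min_identity minimum identity fraction in (0, 1]; default 0.95.
#' @return one-row data.frame with \code{pid}, \code{sid}, \code{sstart},
#'   \code{send} (0-based half-open, forward strand), \code{strand},
#'   \code{nident}, \code{numhits}, \code{score}, or NULL when no placement
#'   qualifies.
#' @export
map_probe <- function(probe, genome, min_identity = 0.95) {
  stopifnot(min_identity > 0, min_identity <= 1)
  seq <- toupper(as.character(probe$sequence))
  if (grepl("[^ACGT]", seq))
    stop("probe ", probe$pid, " contains non-ACGT characters")
  plen <- nchar(seq)
  max_mm <- plen - as.integer(ceiling(min_identity * plen))
  pat_fwd <- Biostrings::DNAString(seq)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  hits <- list()
  for (sid in names(genome)) {
    chrom_seq <- genome[[sid]]
    fwd <- .scan_chrom(pat_fwd, chrom_seq, max_mm)
    if (nrow(fwd)) hits[[length(hits) + 1L]] <-
      data.frame(sid = sid, fwd, strand = "+", stringsAsFactors = FALSE)
    rev <- .scan_chrom(pat_rev, chrom_seq, max_mm)
    if (nrow(rev)) hits[[length(hits) + 1L]] <-
      data.frame(sid = sid, rev, strand = "-", stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(NULL)
  all_hits <- do.call(rbind, hits)
  all_hits <- all_hits[!duplicated(all_hits[, c("sid", "sstart", "strand")]), ]
  # best hit: max nident, then (sid, sstart, strand) lexicographic
  ord <- order(-all_hits$nident, all_hits$sid, all_hits$sstart,
               all_hits$strand)
  best <- all_hits[ord[1L], ]
  data.frame(
    pid = as.character(probe$pid), sid = best$sid, sstart = best$sstart,
    send = best$sstart + plen, strand = best$strand, nident = best$nident,
    numhits = nrow(all_hits), score = best$nident, stringsAsFactors = FALSE
  )
}

#' Map every probe of a platform
#'
#' Batch driver over [map_probe()] with deterministic output order by pid.
#' Probes with no qualifying placement are recorded with \code{mapped =
#' FALSE} and \code{numhits = 0}.
#'
#' @param manifest a [platform_manifest()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param min_identity identity threshold, default 0.95.
#' @param verbose log progress every 100 probes.
#' @return data.frame, one row per probe, columns of [map_probe()] plus
#'   \code{mapped}.
#' @export
map_platform <- function(manifest, genome, min_identity = 0.95,
                         verbose = FALSE) {
  probes <- manifest$probes
  probes <- probes[order(probes$pid), , drop = FALSE]
  n <- nrow(probes)
  if (n == 0L)
    return(data.frame(pid = character(), sid = character(),
                      sstart = integer(), send = integer(),
                      strand = character(), nident = integer(),
                      numhits = integer(), score = integer(),
                      mapped = logical(), stringsAsFactors = FALSE))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- probes[i, ]
    hit <- tryCatch(map_probe(p, genome, min_identity), error = function(e)
      stop("while mapping probe ", p$pid, ": ", conditionMessage(e)))
    if (is.null(hit)) {
      hit <- data.frame(
        pid = p$pid, sid = NA_character_, sstart = NA_integer_,
        send = NA_integer_, strand = NA_character_, nident = NA_integer_,
        numhits = 0L, score = NA_integer_, stringsAsFactors = FALSE
      )
    }
    out[[i]] <- hit
    if (verbose && i %% 100 == 0) message("mapped ", i, "/", n, " probes")
  }
  res <- do.call(rbind, out)
  res$mapped <- res$numhits > 0L
  rownames(res) <- NULL
  res
}

#' Write / read probe hits as TSV
#' @param hits data.frame from [map_platform()].
#' @param path TSV path.
#' @param header optional "#"-prefixed header lines.
#' @export
write_hits_tsv <- function(hits, path, header = NULL) {
  con <- file(path, "w")
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
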