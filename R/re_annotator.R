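#' @title Retroelement probe classification and annotation
#' @description Decides which mapped probes report retroelement expression
#'   and assembles annotation rows. A probe reports RE expression when its
#'   best placement lies entirely within a single repeat-masked interval in
#'   the orientation that reports sense transcription of the element, given
#'   the platform chemistry: on antisense-cRNA platforms (3' arrays) the
#'   probe must be sense to the element (probe strand equals repeat strand),
#'   on sense-cDNA platforms it must be antisense (strands differ).
#' @name re_annotator
NULL

#' LTR class from a repeat class string
#'
#' ERV1 families are class I, ERVK class II, ERVL together with the MaLRs
#' class III; non-LTR repeats and unrecognized LTR families get NA.
#'
#' @param repclass character vector of hierarchical class strings
#'   (e.g. "LTR/ERVK").
#' @return character vector of "I", "II", "III" or NA.
#' @export
ltr_class <- function(repclass) {
  root <- sub("/.*$", "", repclass)
  fam <- ifelse(grepl("/", repclass), sub("^[^/]*/", "", repclass), "")
  out <- rep(NA_character_, length(repclass))
  is_ltr <- !is.na(root) & root == "LTR"
  out[is_ltr & fam == "ERV1"] <- "I"
  out[is_ltr & fam == "ERVK"] <- "II"
  out[is_ltr & fam %in% c("ERVL", "ERVL-MaLR", "MaLR")] <- "III"
  out
}

#' Classify a mapped probe as RE-reporting
#'
#' @param hit one-row data.frame from [map_probe()] (the best hit).
#' @param repeats repeat features from [read_repeatmasker_out()].
#' @param chemistry "antisense_crna" or "sense_cdna".
#' @return the matching one-row repeat data.frame, or NULL when the probe is
#'   not contained in a repeat in the qualifying orientation. Containment is
#'   strict: a probe overhanging the repeat boundary by a single base does
#'   not match, and adjacent fragments of one element are not merged.
#' @export
classify_re_probe <- function(hit, repeats, chemistry) {
  chemistry <- match.arg(tolower(chemistry), c("antisense_crna", "sense_cdna"))
  cand <- repeats[repeats$chrom == hit$sid &
                    repeats$start <= hit$sstart &
                    repeats$end >= hit$send, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ok <- if (chemistry == "antisense_crna") cand$strand == hit$strand
        else cand$strand != hit$strand
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  # nested records: take the innermost (largest start), deterministically
  cand[order(-cand$start, cand$end), ][1L, , drop = FALSE]
}

#' Nearest genes chromosomally 5' and 3' of a probe placement
#'
#' Direction is chromosomal, irrespective of gene strand: the 5' gene is the
#' one with the greatest end at or before the probe start, the 3' gene the
#' one with the least start at or after the probe end. Distance is the gap
#' to the nearer of the two, and 0 when the probe overlaps any gene.
#'
#' @param hit one-row hit data.frame.
#' @param genes gene features from [read_gene_annotation()].
#' @param coding_only restrict to protein-coding genes (default TRUE).
#' @return list with \code{five_prime}, \code{three_prime} (one-row
#'   data.frames or NULL), \code{distance} (bases; NA when the chromosome
#'   carries no gene annotation) and \code{flagged} (TRUE when distance is
#'   undefined).
#' @export
nearest_genes <- function(hit, genes, coding_only = TRUE) {
  if (coding_only) genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  g <- genes[genes$chrom == hit$sid, , drop = FALSE]
  if (nrow(g) == 0L)
    return(list(five_prime = NULL, three_prime = NULL, distance = NA_integer_,
                flagged = TRUE))
  overlaps <- g$start < hit$send & g$end > hit$sstart
  five <- g[g$end <= hit$sstart, , drop = FALSE]
  five <- if (nrow(five)) five[which.max(five$end), , drop = FALSE] else NULL
  three <- g[g$start >= hit$send, , drop = FALSE]
  three <- if (nrow(three)) three[which.min(three$start), , drop = FALSE] else NULL
  if (any(overlaps)) {
    dist <- 0L
  } else {
    gaps <- c(
      if (!is.null(five)) hit$sstart - five$end,
      if (!is.null(three)) three$start - hit$send
    )
    dist <- if (length(gaps)) min(gaps) else NA_integer_
  }
  list(five_prime = five, three_prime = three, distance = as.integer(dist),
       flagged = is.na(dist))
}

.empty_annotation <- function() {
  data.frame(
    pid = character(), probeset = character(), plen = integer(),
    sid = character(), sstart = integer(), send = integer(),
    nident = integer(), numhits = integer(), repeat_name = character(),
    repclass = character(), rstart = integer(), rend = integer(),
    fivep_id = character(), fivep_start = integer(), fivep_end = integer(),
    threep_id = character(), threep_start = integer(),
    threep_end = integer(), is_unique = logical(),
    intergenic_distance = integer(), ltr_class = character(),
    intragenic = logical(), stringsAsFactors = FALSE
  )
}

#' Build annotation rows for RE-reporting probes
#'
#' One row per probe whose best hit classifies as RE-reporting. For probes
#' placed at multiple loci (\code{numhits > 1}) every field requiring a
#' specific genomic context is set NA; only pid, probeset, plen and numhits
#' survive serialization for those rows.
#'
#' @param manifest a [platform_manifest()].
#' @param hits data.frame from [map_platform()].
#' @param repeats repeat features.
#' @param genes gene features.
#' @param chemistry platform chemistry; defaults to the manifest's.
#' @return annotation data.frame (internal column names) with derived
#'   columns \code{is_unique}, \code{intergenic_distance}, \code{ltr_class},
#'   \code{intragenic} in addition to the 18 serialized fields.
#' @export
build_annotation <- function(manifest, hits, repeats, genes,
                             chemistry = manifest$chemistry) {
  probes <- manifest$probes
  rows <- list()
  mapped <- hits[hits$mapped %in% TRUE | (!("mapped" %in% names(hits)) &
                                            hits$numhits > 0), , drop = FALSE]
  for (i in seq_len(nrow(mapped))) {
    hit <- mapped[i, ]
    rep_match <- classify_re_probe(hit, repeats, chemistry)
    if (is.null(rep_match)) next
    p <- probes[probes$pid == hit$pid, ]
    if (nrow(p) != 1L) stop("hit for unknown probe ", hit$pid)
    unique_hit <- hit$numhits == 1L
    if (unique_hit) {
      ng <- nearest_genes(hit, genes, coding_only = TRUE)
      row <- data.frame(
        pid = hit$pid, probeset = p$probeset, plen = p$plen,
        sid = hit$sid, sstart = hit$sstart, send = hit$send,
        nident = hit$nident, numhits = hit$numhits,
        repeat_name = rep_match$repeat_name,
        repclass = rep_match$repeat_class,
        rstart = rep_match$start, rend = rep_match$end,
        fivep_id = if (is.null(ng$five_prime)) NA_character_ else ng$five_prime$symbol,
        fivep_start = if (is.null(ng$five_prime)) NA_integer_ else ng$five_prime$start,
        fivep_end = if (is.null(ng$five_prime)) NA_integer_ else ng$five_prime$end,
        threep_id = if (is.null(ng$three_prime)) NA_character_ else ng$three_prime$symbol,
        threep_start = if (is.null(ng$three_prime)) NA_integer_ else ng$three_prime$start,
        threep_end = if (is.null(ng$three_prime)) NA_integer_ else ng$three_prime$end,
        is_unique = TRUE, intergenic_distance = ng$distance,
        ltr_class = ltr_class(rep_match$repeat_class),
        intragenic = !is.na(ng$distance) && ng$distance == 0L,
        stringsAsFactors = FALSE
      )
    } else {
      row <- data.frame(
        pid = hit$pid, probeset = p$probeset, plen = p$plen,
        sid = NA_character_, sstart = NA_integer_, send = NA_integer_,
        nident = NA_integer_, numhits = hit$numhits,
        repeat_name = NA_character_, repclass = NA_character_,
        rstart = NA_integer_, rend = NA_integer_,
        fivep_id = NA_character_, fivep_start = NA_integer_,
        fivep_end = NA_integer_, threep_id = NA_character_,
        threep_start = NA_integer_, threep_end = NA_integer_,
        is_unique = FALSE, intergenic_distance = NA_integer_,
        ltr_class = NA_character_, intragenic = NA,
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) return(.empty_annotation())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of intragenic probe position within the identified gene
#'
#' For each RE-reporting probe overlapping or within 1 kb of a
#' protein-coding gene, the probe midpoint is expressed as a fraction of
#' gene length measured 5' to 3' along the gene's own strand, clamped to
#' [0, 1], and binned. A probe upstream of the gene therefore lands in the
#' first bin, downstream in the last; bins standardize for varying gene
#' size.
#'
#' @param rows annotation rows from [build_annotation()].
#' @param genes gene features.
#' @param bins number of bins (default 10).
#' @return integer vector of counts, one per bin, with the relative
#'   positions attached as attribute \code{"relpos"}.
#' @export
intragenic_position_bins <- function(rows, genes, bins = 10) {
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  rows <- rows[!is.na(rows$intergenic_distance) &
                 rows$intergenic_distance <= 1000L, , drop = FALSE]
  relpos <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    g <- coding[coding$chrom == r$sid, , drop = FALSE]
    ov <- g[g$start < r$send & g$end > r$sstart, , drop = FALSE]
    if (nrow(ov) > 0L) {
      gene <- ov[1L, ]
    } else {
      # nearest side within 1 kb; tie broken toward the 5' gene
      d5 <- if (!is.na(r$fivep_id)) r$sstart - r$fivep_end else NA_integer_
      d3 <- if (!is.na(r$threep_id)) r$threep_start - r$send else NA_integer_
      use5 <- !is.na(d5) && (is.na(d3) || d5 <= d3)
      gid <- if (use5) r$fivep_id else r$threep_id
      gene <- coding[coding$symbol == gid & coding$chrom == r$sid, , drop = FALSE]
      if (nrow(gene) == 0L) next
      gene <- gene[1L, ]
    }
    mid <- (r$sstart + r$send) / 2
    rel <- (mid - gene$start) / (gene$end - gene$start)
    if (gene$strand == "-") rel <- 1 - rel
    relpos <- c(relpos, min(max(rel, 0), 1))
  }
  idx <- pmin(floor(relpos * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  names(counts) <- sprintf("(%.2f,%.2f]", (seq_len(bins) - 1) / bins,
                           seq_len(bins) / bins)
  attr(counts, "relpos") <- relpos
  counts
}
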