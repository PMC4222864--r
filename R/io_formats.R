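#' @title File format readers and writers
#' @description Readers and writers for every external format the pipeline
#'   touches. All coordinate-convention conversion happens here: internally
#'   every interval is 0-based half-open; RepeatMasker .out and GTF are
#'   1-based inclusive on disk, BED is already half-open, and the emitted
#'   annotation CSV uses 1-based inclusive coordinates so it is directly
#'   comparable with published probe annotation files.
#' @name io_formats
NULL

#' Column order of the probe annotation CSV
#'
#' The 18 serialized fields, in order: probe and probeset identifiers, probe
#' length, best-hit placement (sid, sstart, send, nident), genome-wide hit
#' count, repeat identity and interval, and the nearest 5' and 3'
#' protein-coding gene blocks.
#' @export
ANNOTATION_COLUMNS <- c(
  "pid", "probeset", "plen", "sid", "sstart", "send", "nident", "numhits",
  "repeat", "repclass", "rstart", "rend",
  "5id", "5start", "5stop", "3id", "3start", "3stop"
)

.valid_repclass_roots <- c(
  "LTR", "LINE", "SINE", "DNA", "Simple_repeat", "Low_complexity", "Other"
)

#' Read a RepeatMasker .out file
#'
#' Parses the standard .out dialect: three header lines followed by
#' whitespace-delimited columns, 1-based inclusive coordinates, and "C" in
#' the strand column for minus-strand placements.
#'
#' @param path path to a RepeatMasker .out file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand} ("+"/"-"), \code{repeat_name},
#'   \code{repeat_class}.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("RepeatMasker .out file lacks the 3 header lines: ", path)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), repeat_name = character(),
    repeat_class = character(), stringsAsFactors = FALSE
  )
  if (length(body) == 0L) return(empty)
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(f) < 11)
      stop("malformed RepeatMasker line ", i + 3L, ": expected >= 11 fields, got ",
           length(f))
    b <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
    if (is.na(b) || is.na(e))
      stop("malformed RepeatMasker line ", i + 3L, ": non-numeric coordinates")
    strand <- switch(f[9], "+" = "+", "C" = "-",
      stop("unknown strand symbol '", f[9], "' on line ", i + 3L))
    data.frame(
      chrom = f[5], start = b - 1L, end = e, strand = strand,
      repeat_name = f[10], repeat_class = f[11], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  bad <- !(sub("/.*$", "", out$repeat_class) %in% .valid_repclass_roots)
  if (any(bad)) {
    warning("unrecognized repeat class root for: ",
            paste(unique(out$repeat_class[bad]), collapse = ", "),
            "; reassigned to 'Other'")
    out$repeat_class[bad] <- sub("^[^/]+", "Other", out$repeat_class[bad])
  }
  out
}

#' Write repeat features as a RepeatMasker .out file
#'
#' Inverse of [read_repeatmasker_out()]: 0-based half-open features are
#' written 1-based inclusive with "C" for the minus strand.
#'
#' @param features data.frame as returned by [read_repeatmasker_out()].
#' @param path output path.
#' @export
write_repeatmasker_out <- function(features, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query         matching repeat        position in repeat",
    "score  div. del. ins.  sequence  begin  end     (left)  repeat        class/family  begin  end (left)  ID",
    ""
  )
  lines <- hdr
  if (nrow(features) > 0) {
    lines <- c(lines, vapply(seq_len(nrow(features)), function(i) {
      f <- features[i, ]
      sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %d %d (0) %d",
              1000L, 0.0, 0.0, 0.0, f$chrom, f$start + 1L, f$end, 0L,
              if (f$strand == "-") "C" else "+",
              f$repeat_name, f$repeat_class, 1L, f$end - f$start, i)
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from GTF or BED
#'
#' GTF \code{gene} lines (1-based inclusive, converted here) must carry
#' \code{gene_id}; \code{gene_name} defaults to the id and a missing
#' \code{gene_biotype} yields a warning and biotype \code{"unknown"}. The BED
#' dialect is \code{chrom start end name score strand biotype} and is already
#' half-open.
#'
#' @param path annotation file path.
#' @param format "gtf" or "bed".
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand}, \code{gene_id}, \code{symbol},
#'   \code{biotype}.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), gene_id = character(), symbol = character(),
    biotype = character(), stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) return(empty)
  if (format == "gtf") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
    fields <- fields[keep]
    if (length(fields) == 0L) return(empty)
    attr1 <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    out <- do.call(rbind, lapply(fields, function(f) {
      gid <- attr1(f[9], "gene_id")
      if (is.na(gid)) stop("GTF gene line without gene_id attribute")
      sym <- attr1(f[9], "gene_name")
      bt <- attr1(f[9], "gene_biotype")
      data.frame(
        chrom = f[1], start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
        strand = f[7], gene_id = gid,
        symbol = if (is.na(sym)) gid else sym,
        biotype = bt, stringsAsFactors = FALSE
      )
    }))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- do.call(rbind, lapply(fields, function(f) {
      if (length(f) < 6) stop("BED gene line with fewer than 6 fields")
      data.frame(
        chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
        strand = f[6], gene_id = f[4], symbol = f[4],
        biotype = if (length(f) >= 7) f[7] else NA_character_,
        stringsAsFactors = FALSE
      )
    }))
  }
  if (anyNA(out$biotype)) {
    warning("gene record(s) without biotype attribute; set to 'unknown'")
    out$biotype[is.na(out$biotype)] <- "unknown"
  }
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  out
}

#' Write gene features as GTF
#' @param genes data.frame as from [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_gtf <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sprintf('%s\tretroprobe\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$symbol, g$biotype)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a platform manifest
#'
#' Tab-separated columns \code{pid}, \code{probeset}, \code{sequence}.
#' Chemistry (and optionally the platform name) can be declared in header
#' pragmas, e.g. \code{#%chemistry=antisense_crna}, or passed explicitly;
#' an explicit argument wins. Chemistry is never inferred from the platform
#' name.
#'
#' @param path manifest TSV.
#' @param chemistry "antisense_crna" or "sense_cdna"; overrides the pragma.
#' @return object of class \code{platform_manifest}: a list with
#'   \code{platform_name}, \code{chemistry} and \code{probes} (data.frame
#'   with \code{pid}, \code{probeset}, \code{sequence}, \code{plen}).
#' @export
read_platform_manifest <- function(path, chemistry = NULL) {
  lines <- readLines(path)
  pragmas <- lines[startsWith(lines, "#%")]
  get_pragma <- function(key) {
    hit <- grep(paste0("^#%", key, "="), pragmas, value = TRUE)
    if (length(hit)) sub(paste0("^#%", key, "="), "", hit[1]) else NULL
  }
  if (is.null(chemistry)) chemistry <- get_pragma("chemistry")
  if (is.null(chemistry))
    stop("chemistry not declared: add a '#%chemistry=' pragma or pass it explicitly")
  chemistry <- match.arg(tolower(chemistry), c("antisense_crna", "sense_cdna"))
  platform_name <- get_pragma("platform")
  if (is.null(platform_name)) platform_name <- basename(path)
  body <- lines[!startsWith(lines, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  probes <- utils::read.delim(con, stringsAsFactors = FALSE)
  if (!all(c("pid", "probeset", "sequence") %in% names(probes)))
    stop("manifest must have columns pid, probeset, sequence")
  probes$pid <- as.character(probes$pid)
  probes$probeset <- as.character(probes$probeset)
  probes$sequence <- toupper(as.character(probes$sequence))
  if (anyDuplicated(probes$pid))
    stop("duplicate pid in manifest: ",
         paste(unique(probes$pid[duplicated(probes$pid)]), collapse = ", "))
  bad <- grepl("[^ACGT]", probes$sequence)
  if (any(bad))
    stop("non-ACGT character in probe sequence: ",
         paste(probes$pid[bad], collapse = ", "))
  probes$plen <- nchar(probes$sequence)
  if (any(probes$plen < 10))
    stop("probe shorter than 10 bases: ",
         paste(probes$pid[probes$plen < 10], collapse = ", "))
  platform_manifest(platform_name, chemistry, probes)
}

#' Construct a platform manifest object
#' @param platform_name platform identifier.
#' @param chemistry "antisense_crna" (3' arrays, probes sense to the
#'   element) or "sense_cdna" (gene/ST arrays, probes antisense).
#' @param probes data.frame with pid, probeset, sequence (plen added).
#' @export
platform_manifest <- function(platform_name, chemistry, probes) {
  chemistry <- match.arg(tolower(chemistry), c("antisense_crna", "sense_cdna"))
  stopifnot(all(c("pid", "probeset", "sequence") %in% names(probes)))
  if (is.null(probes$plen)) probes$plen <- nchar(probes$sequence)
  structure(
    list(platform_name = platform_name, chemistry = chemistry,
         probes = probes),
    class = "platform_manifest"
  )
}

#' @export
print.platform_manifest <- function(x, ...) {
  cat("Platform manifest:", x$platform_name, "\n")
  cat("  chemistry:", x$chemistry, "\n")
  cat("  probes:", nrow(x$probes), "in",
      length(unique(x$probes$probeset)), "probesets\n")
  invisible(x)
}

#' Write a platform manifest TSV
#' @param manifest a \code{platform_manifest}.
#' @param path output path.
#' @export
write_platform_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#%platform=", manifest$platform_name),
               paste0("#%chemistry=", manifest$chemistry)), con)
  utils::write.table(manifest$probes[, c("pid", "probeset", "sequence")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write probe annotation rows as CSV
#'
#' Serializes the 18-column annotation schema. Genomic coordinates are
#' written 1-based inclusive. For probes mapping to multiple loci
#' (\code{numhits > 1}) every field tied to a specific placement is written
#' empty.
#'
#' @param rows annotation data.frame from [build_annotation()].
#' @param path output CSV path.
#' @export
write_annotation_csv <- function(rows, path) {
  out <- data.frame(row.names = seq_len(nrow(rows)))
  fmt <- function(v) ifelse(is.na(v), "", as.character(v))
  out[["pid"]] <- rows$pid
  out[["probeset"]] <- rows$probeset
  out[["plen"]] <- rows$plen
  out[["sid"]] <- fmt(rows$sid)
  out[["sstart"]] <- fmt(rows$sstart + 1L)
  out[["send"]] <- fmt(rows$send)
  out[["nident"]] <- fmt(rows$nident)
  out[["numhits"]] <- rows$numhits
  out[["repeat"]] <- fmt(rows$repeat_name)
  out[["repclass"]] <- fmt(rows$repclass)
  out[["rstart"]] <- fmt(rows$rstart + 1L)
  out[["rend"]] <- fmt(rows$rend)
  out[["5id"]] <- fmt(rows$fivep_id)
  out[["5start"]] <- fmt(rows$fivep_start + 1L)
  out[["5stop"]] <- fmt(rows$fivep_end)
  out[["3id"]] <- fmt(rows$threep_id)
  out[["3start"]] <- fmt(rows$threep_start + 1L)
  out[["3stop"]] <- fmt(rows$threep_end)
  names(out) <- ANNOTATION_COLUMNS
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe annotation CSV
#'
#' Inverse of [write_annotation_csv()]: 1-based inclusive file coordinates
#' come back 0-based half-open, and empty context fields (quoted or not)
#' become NA.
#'
#' @param path annotation CSV path.
#' @return internal annotation data.frame.
#' @export
read_annotation_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), ANNOTATION_COLUMNS))
    stop("annotation CSV does not have the expected 18 columns")
  num <- function(v) suppressWarnings(as.integer(ifelse(v == "", NA, v)))
  chr <- function(v) ifelse(v == "", NA_character_, v)
  data.frame(
    pid = raw$pid, probeset = raw$probeset, plen = as.integer(raw$plen),
    sid = chr(raw$sid), sstart = num(raw$sstart) - 1L, send = num(raw$send),
    nident = num(raw$nident), numhits = as.integer(raw$numhits),
    repeat_name = chr(raw[["repeat"]]), repclass = chr(raw$repclass),
    rstart = num(raw$rstart) - 1L, rend = num(raw$rend),
    fivep_id = chr(raw[["5id"]]), fivep_start = num(raw[["5start"]]) - 1L,
    fivep_end = num(raw[["5stop"]]),
    threep_id = chr(raw[["3id"]]), threep_start = num(raw[["3start"]]) - 1L,
    threep_end = num(raw[["3stop"]]),
    stringsAsFactors = FALSE
  )
}

#' Expression matrix container
#'
#' Probe-level intensities with sample factor metadata. \code{scale} records
#' whether values are linear intensities (all positive) or log2.
#'
#' @param values numeric matrix, probes x samples, with dimnames.
#' @param scale "linear" or "log2".
#' @param sample_factors data.frame of per-sample factors, rownames matching
#'   \code{colnames(values)}; may be NULL.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2"),
                        sample_factors = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale expression matrix must be strictly positive")
  if (!is.null(sample_factors)) {
    if (!all(colnames(values) %in% rownames(sample_factors)))
      stop("sample_factors must cover every sample in the matrix")
    sample_factors <- sample_factors[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, scale = scale,
                 sample_factors = sample_factors),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples (", x$scale, "scale )\n")
  if (!is.null(x$sample_factors))
    cat("  factors:", paste(names(x$sample_factors), collapse = ", "), "\n")
  invisible(x)
}

#' Read a probe-level expression matrix with optional sample factors
#'
#' @param path TSV, first column \code{probe_id}, remaining columns samples.
#' @param factors_path optional TSV with column \code{sample_id} plus factor
#'   columns.
#' @param scale scale of the stored values.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, factors_path = NULL,
                                   scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  sf <- NULL
  if (!is.null(factors_path)) {
    sf <- utils::read.delim(factors_path, comment.char = "#",
                            stringsAsFactors = FALSE)
    rownames(sf) <- sf$sample_id
    sf$sample_id <- NULL
  }
  expr_matrix(m, scale = scale, sample_factors = sf)
}

#' Write an expression matrix (and optionally its sample factors) as TSV
#' @param m an [expr_matrix()].
#' @param path output TSV for the matrix.
#' @param factors_path optional output TSV for the sample factors.
#' @param header optional character vector of "#"-prefixed header lines.
#' @export
write_expression_matrix <- function(m, path, factors_path = NULL,
                                    header = NULL) {
  con <- file(path, "w")
  if (!is.null(header)) writeLines(header, con)
  tab <- data.frame(probe_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(factors_path) && !is.null(m$sample_factors)) {
    sf <- data.frame(sample_id = rownames(m$sample_factors),
                     m$sample_factors, stringsAsFactors = FALSE)
    utils::write.table(sf, factors_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
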