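#' @title Enhanced probe filtering and platform coverage accounting
#' @description Isolates probes reporting single-integration, intergenic
#'   retroelements: a probe is retained when it maps uniquely, lies more
#'   than a configurable distance (default 1 kb, strict) from the nearest
#'   protein-coding gene, and belongs to a probeset in which strictly more
#'   than 75\% of all member probes report RE expression. The fraction is
#'   computed against every probe of the probeset in the manifest, including
#'   unmapped ones.
#' @name probe_filter
NULL

#' Filtering configuration
#'
#' @param min_identity mapping identity threshold, fraction in (0,1].
#' @param min_probeset_re_fraction probeset RE fraction that must be
#'   strictly exceeded (default 0.75).
#' @param min_gene_distance gene distance in bases that must be strictly
#'   exceeded (default 1000).
#' @param require_unique require a single genomic placement (default TRUE).
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(min_identity = 0.95,
                          min_probeset_re_fraction = 0.75,
                          min_gene_distance = 1000L,
                          require_unique = TRUE) {
  stopifnot(
    min_identity > 0, min_identity <= 1,
    min_probeset_re_fraction > 0, min_probeset_re_fraction <= 1,
    min_gene_distance >= 0
  )
  structure(list(
    min_identity = min_identity,
    min_probeset_re_fraction = min_probeset_re_fraction,
    min_gene_distance = as.integer(min_gene_distance),
    require_unique = isTRUE(require_unique)
  ), class = "filter_config")
}

#' Apply enhanced filtering to annotation rows
#'
#' @param rows annotation rows from [build_annotation()] (all RE-reporting
#'   probes of the platform; the probeset fraction is computed from this
#'   full set, before any removal).
#' @param manifest the [platform_manifest()] the rows were built from.
#' @param cfg a [filter_config()].
#' @return the retained subset of \code{rows}, invariant to input order.
#' @export
enhanced_filter <- function(rows, manifest, cfg = filter_config()) {
  if (nrow(rows) == 0L) return(rows)
  probes <- manifest$probes
  missing <- setdiff(rows$probeset, probes$probeset)
  if (length(missing))
    stop("probeset(s) absent from manifest: ", paste(missing, collapse = ", "))
  set_total <- table(probes$probeset)
  set_re <- table(rows$probeset)
  frac <- as.numeric(set_re[rows$probeset]) /
    as.numeric(set_total[rows$probeset])
  keep <- frac > cfg$min_probeset_re_fraction
  if (cfg$require_unique) keep <- keep & rows$numhits == 1L
  keep <- keep & !is.na(rows$intergenic_distance) &
    rows$intergenic_distance > cfg$min_gene_distance
  out <- rows[keep, , drop = FALSE]
  out[order(out$pid), , drop = FALSE]
}

#' Per-class probe counts and repeat coverage
#'
#' Counts retained probes per top-level repeat class (LTR, LINE, SINE) and
#' estimates the maximum coverage of individual elements: the percentage of
#' distinct repeat instances of each class carrying at least one retained
#' probe.
#'
#' @param rows retained annotation rows (from [enhanced_filter()]).
#' @param repeats the full repeat annotation the rows were classified
#'   against.
#' @return data.frame with columns \code{class}, \code{n_probes},
#'   \code{n_instances_hit}, \code{n_instances_total},
#'   \code{coverage_pct}; last row is the Total.
#' @export
coverage_table <- function(rows, repeats) {
  classes <- c("LTR", "LINE", "SINE")
  rep_root <- sub("/.*$", "", repeats$repeat_class)
  row_root <- sub("/.*$", "", rows$repclass)
  inst_key <- function(chrom, start, end, name) paste(chrom, start, end, name, sep = ":")
  rep_keys <- inst_key(repeats$chrom, repeats$start, repeats$end, repeats$repeat_name)
  hit_keys <- if (nrow(rows)) inst_key(rows$sid, rows$rstart, rows$rend, rows$repeat_name)
              else character(0)
  per_class <- lapply(classes, function(cl) {
    n_probes <- sum(row_root %in% cl, na.rm = TRUE)
    total <- length(unique(rep_keys[rep_root == cl]))
    hit <- length(unique(hit_keys[row_root %in% cl]))
    data.frame(class = cl, n_probes = n_probes, n_instances_hit = hit,
               n_instances_total = total,
               coverage_pct = if (total > 0) 100 * hit / total else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_class)
  total_row <- data.frame(
    class = "Total", n_probes = sum(out$n_probes),
    n_instances_hit = sum(out$n_instances_hit),
    n_instances_total = sum(out$n_instances_total),
    coverage_pct = if (sum(out$n_instances_total) > 0)
      100 * sum(out$n_instances_hit) / sum(out$n_instances_total) else 0,
    stringsAsFactors = FALSE
  )
  rbind(out, total_row)
}
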