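#' @title Expression preprocessing and selection statistics
#' @description Probe-level preprocessing (normal-exponential background
#'   correction, quantile normalization, log2) and the downstream
#'   statistics: one-step Tukey biweight probeset summarization, blocked
#'   ANOVA probe selection, probe-versus-probeset concordance testing,
#'   nearest-gene co-regulation regression, and hierarchical clustering.
#' @name expression_stats
NULL

#' Background-correct a linear-scale expression matrix
#'
#' Fits the signal-plus-noise convolution model (observed = exponential
#' signal + normal noise) per array and replaces each value with the
#' posterior expected signal. The transform is strictly positive and
#' monotone increasing within an array.
#'
#' @param m an [expr_matrix()] on the linear scale.
#' @return background-corrected [expr_matrix()], linear scale.
#' @export
background_correct <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear")
    stop("background correction expects linear-scale intensities")
  sds <- apply(m$values, 2, stats::sd)
  if (any(sds == 0))
    stop("array(s) with zero variance: ",
         paste(colnames(m$values)[sds == 0], collapse = ", "),
         "; model parameters are degenerate - rerun with --no-bgcorrect")
  corrected <- limma::backgroundCorrect.matrix(m$values, method = "normexp",
                                               normexp.method = "saddle",
                                               verbose = FALSE)
  dimnames(corrected) <- dimnames(m$values)
  expr_matrix(corrected, scale = "linear", sample_factors = m$sample_factors)
}

#' Quantile-normalize an expression matrix
#'
#' Forces identical value distributions across arrays: after normalization
#' every array's sorted vector equals the across-array mean of sorted
#' vectors; within-array ranks are preserved and ties receive the mean of
#' the quantile values they span. Idempotent.
#'
#' @param m an [expr_matrix()].
#' @return quantile-normalized [expr_matrix()] on the same scale.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) == 1L) return(m)
  normed <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(normed) <- dimnames(m$values)
  expr_matrix(normed, scale = m$scale, sample_factors = m$sample_factors)
}

#' Log2-transform a linear-scale matrix
#' @param m an [expr_matrix()] on the linear scale.
#' @return [expr_matrix()] on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear") stop("matrix is already on the log2 scale")
  expr_matrix(log2(m$values), scale = "log2",
              sample_factors = m$sample_factors)
}

#' One-step Tukey biweight location estimate
#'
#' Robust weighted mean of probe values: with M the median and S the
#' (unscaled) median absolute deviation of x, each value is scaled as
#' u_i = (x_i - M) / (c*S + epsilon) and weighted by (1 - u_i^2)^2 when
#' |u_i| < 1 and 0 otherwise; the estimate is sum(w*x) / sum(w). Values
#' with |u| >= 1 have exactly zero influence. The defaults c = 5 and
#' epsilon = 1e-4 follow the fixed constants of the Affymetrix probeset
#' summarization algorithm.
#'
#' @param x numeric vector of probe values (length >= 1).
#' @param c tuning constant (> 0), default 5.
#' @param epsilon small positive stabilizer, default 0.0001.
#' @return scalar location estimate.
#' @export
tukey_biweight <- function(x, c = 5, epsilon = 1e-4) {
  if (length(x) == 0L) stop("tukey_biweight of an empty vector")
  stopifnot(c > 0, epsilon > 0)
  M <- stats::median(x)
  S <- stats::median(abs(x - M))
  u <- (x - M) / (c * S + epsilon)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Collapse probes into probesets with the one-step biweight
#'
#' @param m log2-scale [expr_matrix()] of probe values.
#' @param manifest the [platform_manifest()] defining probeset membership.
#' @param c,epsilon biweight constants, see [tukey_biweight()].
#' @param probesets optional subset of probeset ids to summarize.
#' @return matrix, probesets x samples. Probesets without any probe present
#'   in the matrix are omitted with a warning.
#' @export
summarize_probeset <- function(m, manifest, c = 5, epsilon = 1e-4,
                               probesets = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  probes <- manifest$probes
  if (is.null(probesets)) probesets <- sort(unique(probes$probeset))
  present <- rownames(m$values)
  out <- matrix(NA_real_, nrow = length(probesets), ncol = ncol(m$values),
                dimnames = list(probesets, colnames(m$values)))
  empty <- character(0)
  for (ps in probesets) {
    members <- intersect(probes$pid[probes$probeset == ps], present)
    if (length(members) == 0L) { empty <- c(empty, ps); next }
    sub <- m$values[members, , drop = FALSE]
    out[ps, ] <- apply(sub, 2, tukey_biweight, c = c, epsilon = epsilon)
  }
  if (length(empty)) {
    warning("probeset(s) with no probes in the matrix omitted: ",
            paste(empty, collapse = ", "))
    out <- out[!(rownames(out) %in% empty), , drop = FALSE]
  }
  out
}

#' Per-probe ANOVA selection with blocking factors eliminated
#'
#' Fits, per probe, the fixed-effects model value ~ blocking factors +
#' factor-of-interest and tests the factor-of-interest term by its extra
#' sum of squares after the eliminated terms (sequential ANOVA). P values
#' are uncorrected by default, mirroring raw-p thresholds; set \code{fdr}
#' for Benjamini-Hochberg adjustment.
#'
#' @param m log2-scale [expr_matrix()] with \code{sample_factors} covering
#'   all named factors.
#' @param factor name of the factor of interest (>= 2 levels).
#' @param eliminate character vector of blocking factor names.
#' @param alpha retention threshold on the (possibly adjusted) p value.
#' @param fdr apply Benjamini-Hochberg correction before thresholding.
#' @return data.frame with \code{probe_id}, \code{F}, \code{p},
#'   \code{retained}, plus \code{p_adj} when \code{fdr}.
#' @export
anova_select <- function(m, factor, eliminate = character(0), alpha = 0.01,
                         fdr = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  sf <- m$sample_factors
  if (is.null(sf) || !all(c(factor, eliminate) %in% names(sf)))
    stop("sample_factors must contain: ",
         paste(c(factor, eliminate), collapse = ", "))
  f_int <- as.factor(sf[[factor]])
  if (nlevels(droplevels(f_int)) < 2)
    stop("factor of interest '", factor, "' has fewer than 2 levels")
  n <- ncol(m$values)
  X0 <- stats::model.matrix(
    if (length(eliminate))
      stats::reformulate(eliminate, intercept = TRUE) else ~1,
    data = as.data.frame(sf)
  )
  X1 <- stats::model.matrix(
    stats::reformulate(c(eliminate, factor), intercept = TRUE),
    data = as.data.frame(sf)
  )
  q0 <- qr(X0); q1 <- qr(X1)
  df_factor <- q1$rank - q0$rank
  if (df_factor <= 0)
    stop("factor '", factor, "' is aliased with eliminated factor(s): ",
         paste(eliminate, collapse = ", "))
  df_res <- n - q1$rank
  if (df_res <= 0) stop("no residual degrees of freedom")
  Y <- t(m$values)                      # samples x probes
  rss0 <- colSums(qr.resid(q0, Y)^2)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  Fstat <- ((rss0 - rss1) / df_factor) / (rss1 / df_res)
  p <- stats::pf(Fstat, df_factor, df_res, lower.tail = FALSE)
  out <- data.frame(probe_id = rownames(m$values), F = Fstat, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (fdr) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$retained <- out$p_adj < alpha
  } else {
    out$retained <- out$p < alpha
  }
  out
}

# Welch t test that tolerates degenerate (zero-variance) inputs
.safe_t_p <- function(x, y) {
  if (stats::var(x) + stats::var(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Concordance of a single RE-reporting probe with its probeset
#'
#' For every probeset containing exactly one RE-reporting probe and at
#' least two other probes, the RE probe's values are compared with the
#' biweight summary of the remaining probes, per level of the condition
#' factor (Welch t tests across replicate samples), with Holm-Bonferroni
#' correction across the levels of each probeset. A probeset is concordant
#' when every corrected p exceeds \code{alpha}.
#'
#' @param m log2-scale [expr_matrix()].
#' @param manifest the [platform_manifest()].
#' @param re_rows annotation rows identifying RE-reporting probes.
#' @param factor condition factor name in \code{sample_factors}.
#' @param alpha concordance threshold on the corrected p (default 0.05).
#' @param c,epsilon biweight constants.
#' @return data.frame with \code{probeset}, \code{re_pid}, \code{n_tests},
#'   \code{min_p_adj}, \code{concordant}; the fraction of concordant
#'   probesets is attached as attribute \code{"fraction_concordant"}.
#' @export
probe_vs_probeset_concordance <- function(m, manifest, re_rows, factor,
                                          alpha = 0.05, c = 5,
                                          epsilon = 1e-4) {
  stopifnot(inherits(m, "expr_matrix"))
  sf <- m$sample_factors
  if (is.null(sf) || !(factor %in% names(sf)))
    stop("sample_factors must contain factor '", factor, "'")
  lev <- split(colnames(m$values), sf[[factor]])
  lev <- lev[vapply(lev, length, integer(1)) >= 2]
  probes <- manifest$probes
  re_by_set <- split(re_rows$pid, re_rows$probeset)
  single <- names(re_by_set)[vapply(re_by_set, length, integer(1)) == 1L]
  out <- list(); skipped <- character(0)
  for (ps in single) {
    re_pid <- re_by_set[[ps]]
    others <- setdiff(probes$pid[probes$probeset == ps], re_pid)
    others <- intersect(others, rownames(m$values))
    if (length(others) < 2L || !(re_pid %in% rownames(m$values))) {
      skipped <- c(skipped, ps); next
    }
    summ <- apply(m$values[others, , drop = FALSE], 2, tukey_biweight,
                  c = c, epsilon = epsilon)
    pvals <- vapply(lev, function(samples)
      .safe_t_p(m$values[re_pid, samples], summ[samples]), numeric(1))
    p_adj <- stats::p.adjust(pvals, method = "holm")
    out[[length(out) + 1L]] <- data.frame(
      probeset = ps, re_pid = re_pid, n_tests = length(pvals),
      min_p_adj = min(p_adj), concordant = all(p_adj > alpha),
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped))
    warning("probeset(s) with fewer than 2 non-RE probes skipped: ",
            paste(skipped, collapse = ", "))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(probeset = character(), re_pid = character(),
               n_tests = integer(), min_p_adj = numeric(),
               concordant = logical(), stringsAsFactors = FALSE)
  attr(res, "fraction_concordant") <-
    if (nrow(res)) mean(res$concordant) else NA_real_
  res
}

#' Regression of RE probe expression on the nearest gene's summary
#'
#' One point per (RE probe, sample of the selected tissue): the probe's
#' value against the biweight summary of its nearest protein-coding gene
#' (the nearer of the 5' and 3' neighbors by distance; ties go 5').
#' Least-squares lines are fitted per top-level repeat class; points whose
#' nearest gene is absent from \code{gene_summaries} are omitted and
#' counted.
#'
#' @param re_matrix numeric matrix, RE probes x samples (log2).
#' @param gene_summaries numeric matrix, genes x samples, rownames = gene
#'   symbols.
#' @param annot annotation rows carrying the nearest-gene columns.
#' @param sample_factors per-sample factor data.frame.
#' @param tissue factor level selecting the samples (column \code{tissue}).
#' @return data.frame per repeat class with \code{class}, \code{slope},
#'   \code{intercept}, \code{r}, \code{r_squared}, \code{p}, \code{n_points};
#'   omitted-point count as attribute \code{"n_omitted"}.
#' @export
nearest_gene_regression <- function(re_matrix, gene_summaries, annot,
                                    sample_factors, tissue) {
  if (!("tissue" %in% names(sample_factors)))
    stop("sample_factors must contain a 'tissue' column")
  samples <- intersect(colnames(re_matrix),
                       rownames(sample_factors)[sample_factors$tissue == tissue])
  if (length(samples) == 0L) stop("no samples for tissue '", tissue, "'")
  pts <- list(); n_omitted <- 0L
  for (i in seq_len(nrow(annot))) {
    r <- annot[i, ]
    if (!(r$pid %in% rownames(re_matrix))) next
    d5 <- if (!is.na(r$fivep_id)) r$sstart - r$fivep_end else NA_integer_
    d3 <- if (!is.na(r$threep_id)) r$threep_start - r$send else NA_integer_
    if (is.na(d5) && is.na(d3)) { n_omitted <- n_omitted + length(samples); next }
    gid <- if (!is.na(d5) && (is.na(d3) || d5 <= d3)) r$fivep_id else r$threep_id
    if (!(gid %in% rownames(gene_summaries))) {
      n_omitted <- n_omitted + length(samples); next
    }
    pts[[length(pts) + 1L]] <- data.frame(
      class = sub("/.*$", "", r$repclass),
      re = as.numeric(re_matrix[r$pid, samples]),
      gene = as.numeric(gene_summaries[gid, samples]),
      stringsAsFactors = FALSE
    )
  }
  if (length(pts) == 0L)
    stop("no regression points: no annotated probe has its nearest gene on the platform")
  pts <- do.call(rbind, pts)
  res <- lapply(split(pts, pts$class), function(d) {
    fit <- stats::lm(re ~ gene, data = d)
    s <- summary(fit)
    data.frame(
      class = d$class[1L], slope = stats::coef(fit)[["gene"]],
      intercept = stats::coef(fit)[["(Intercept)"]],
      r = sign(stats::coef(fit)[["gene"]]) * sqrt(s$r.squared),
      r_squared = s$r.squared,
      p = if (nrow(d) > 2) stats::coef(s)["gene", "Pr(>|t|)"] else NA_real_,
      n_points = nrow(d), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_omitted") <- n_omitted
  out
}

#' Hierarchical clustering on correlation distance
#'
#' Average-linkage agglomeration on Pearson correlation distance (1 - r).
#' Items are sorted by identifier before clustering so the leaf order is
#' deterministic and invariant to input order. Constant items, whose
#' correlation is undefined, are placed at distance 1 from everything with
#' a warning.
#'
#' @param values numeric matrix with dimnames.
#' @param axis cluster "rows" or "cols".
#' @return an object of class \code{hclust}; leaf labels in dendrogram
#'   order are attached as attribute \code{"leaf_order"}.
#' @export
hierarchical_cluster <- function(values, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  x <- if (axis == "cols") t(values) else values
  x <- x[order(rownames(x)), , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 items to cluster")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    warning("constant item(s) with undefined correlation set to distance 1: ",
            paste(rownames(x)[sds == 0], collapse = ", "))
  cm <- suppressWarnings(stats::cor(t(x)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  attr(hc, "leaf_order") <- hc$labels[hc$order]
  hc
}
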