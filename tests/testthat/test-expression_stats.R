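mk_expr <- function(values, scale = "log2", sf = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values, scale = scale, sample_factors = sf)
}

test_that("background correction is positive, order-preserving and shrinks toward signal", {
  sim <- simulate_normexp_array(n = 4000, seed = 3)
  m <- mk_expr(cbind(a1 = sim$observed, a2 = sim$observed * 1.1),
               scale = "linear")
  out <- background_correct(m)
  expect_true(all(out$values > 0))
  ord <- order(m$values[, 1])
  expect_true(all(diff(out$values[ord, 1]) >= 0))
  # corrected values closer to the true signal than the raw observations
  expect_lt(mean(abs(out$values[, 1] - sim$signal)),
            mean(abs(m$values[, 1] - sim$signal)))
})

test_that("background correction rejects degenerate zero-variance arrays", {
  m <- mk_expr(cbind(a1 = rep(100, 10), a2 = 1:10 + 0.5), scale = "linear")
  expect_error(background_correct(m), "zero variance")
})

test_that("quantile normalization equalizes distributions", {
  m <- mk_expr(cbind(a = c(1, 2, 3), b = c(4, 5, 6)), scale = "log2")
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, "b"]), c(2.5, 3.5, 4.5))
  # single array and already-identical arrays are untouched
  single <- mk_expr(matrix(c(5, 1, 7), ncol = 1), scale = "log2")
  expect_equal(quantile_normalize(single)$values, single$values)
  same <- mk_expr(cbind(a = c(1, 5, 2), b = c(1, 5, 2)), scale = "log2")
  expect_equal(quantile_normalize(same)$values, same$values)
})

test_that("quantile normalization matches the order-statistics oracle and is idempotent", {
  set.seed(21)
  for (i in 1:5) {
    v <- matrix(rnorm(60), 12, 5)   # continuous, tie-free
    m <- mk_expr(v, scale = "log2")
    out <- quantile_normalize(m)
    expect_equal(unname(out$values), oracle_quantile_normalize(v),
                 tolerance = 1e-12)
    twice <- quantile_normalize(out)
    expect_equal(twice$values, out$values, tolerance = 1e-12)
    sorted <- apply(out$values, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
})

test_that("tukey_biweight matches its formula oracle and known values", {
  expect_equal(tukey_biweight(c(5, 5, 5)), 5)
  expect_equal(tukey_biweight(c(1, 2, 3)), 2)       # symmetric => median
  expect_equal(tukey_biweight(7.3), 7.3)            # single value
  x <- c(10, 10.2, 9.8, 10.1, 50)
  expect_equal(tukey_biweight(x), oracle_biweight(x), tolerance = 1e-12)
  expect_equal(tukey_biweight(x), 10.06, tolerance = 0.01)
  expect_error(tukey_biweight(numeric(0)), "empty")
  set.seed(22)
  for (i in 1:200) {
    v <- rnorm(sample(2:30, 1), sd = sample(c(0.01, 1, 100), 1))
    expect_equal(tukey_biweight(v), oracle_biweight(v), tolerance = 1e-12)
  }
})

test_that("points at |u| >= 1 have exactly zero influence and tight data give the mean", {
  x <- c(10, 10.2, 9.8, 10.1, 50)
  M <- median(x); S <- median(abs(x - M))
  expect_true(abs(50 - M) / (5 * S + 1e-4) >= 1)
  expect_identical(tukey_biweight(x), tukey_biweight(c(x[1:4], 1e6)))
  # tight cluster: all |u| << 1, estimate ~ arithmetic mean
  y <- 100 + c(-0.001, -0.0005, 0, 0.0005, 0.001)
  expect_equal(tukey_biweight(y), mean(y), tolerance = 1e-6)
})

test_that("probeset summarization collapses member probes robustly", {
  man <- platform_manifest("t", "antisense_crna", data.frame(
    pid = c("a1", "a2", "a3", "b1"),
    probeset = c("psA", "psA", "psA", "psB"),
    sequence = strrep("ACGTA", 5), stringsAsFactors = FALSE))
  v <- rbind(a1 = c(8, 9), a2 = c(8.1, 9.1), a3 = c(20, 25),
             b1 = c(5, 6))
  colnames(v) <- c("s1", "s2")
  m <- mk_expr(v, scale = "log2")
  s <- summarize_probeset(m, man)
  expect_equal(s["psB", ], v["b1", ])            # singleton passthrough
  # outlier probe a3 is downweighted to zero
  expect_equal(unname(s["psA", "s1"]), oracle_biweight(c(8, 8.1, 20)),
               tolerance = 1e-12)
  expect_lt(abs(s["psA", "s1"] - mean(c(8, 8.1))), 0.1)
  # probeset entirely absent from the matrix is omitted with a warning
  man2 <- platform_manifest("t", "antisense_crna", data.frame(
    pid = c("a1", "zz"), probeset = c("psA", "psZ"),
    sequence = strrep("ACGTA", 5), stringsAsFactors = FALSE))
  expect_warning(s2 <- summarize_probeset(m, man2), "psZ")
  expect_false("psZ" %in% rownames(s2))
})

test_that("anova_select retains planted effects and controls the null", {
  m <- simulate_anova_matrix(n_null = 200, n_effect = 30, effect = 3,
                             seed = 5)
  res <- anova_select(m, factor = "tissue", alpha = 0.01)
  eff <- grepl("^eff", res$probe_id)
  expect_gt(mean(res$retained[eff]), 0.8)
  expect_lt(mean(res$retained[!eff]), 0.05)
  # the F test agrees with lm/anova sequential sums of squares
  sf <- m$sample_factors
  for (pid in res$probe_id[c(1, 150, 210)]) {
    fit <- anova(lm(m$values[pid, ] ~ sf$tissue))
    i <- match(pid, res$probe_id)
    expect_equal(res$F[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("eliminating a batch factor restores selection under batch offsets", {
  set.seed(6)
  m <- simulate_anova_matrix(n_null = 0, n_effect = 40, effect = 1.2,
                             noise_sd = 1, seed = 6)
  sf <- m$sample_factors
  sf$experiment <- rep(c("e1", "e2", "e3"), 3)    # crossed with tissue
  batch <- c(e1 = 0, e2 = 4, e3 = 8)[sf$experiment]
  v <- m$values + rep(batch, each = nrow(m$values))
  m2 <- expr_matrix(v, scale = "log2", sample_factors = sf)
  with_elim <- anova_select(m2, "tissue", eliminate = "experiment",
                            alpha = 0.01)
  without <- anova_select(m2, "tissue", alpha = 0.01)
  expect_gt(sum(with_elim$retained), sum(without$retained))
  # sequential F for tissue after experiment matches lm/anova
  pid <- with_elim$probe_id[1]
  fit <- anova(lm(m2$values[pid, ] ~ sf$experiment + sf$tissue))
  expect_equal(with_elim$F[1], fit$`F value`[2], tolerance = 1e-10)
})

test_that("aliased designs are refused with a clear error", {
  m <- simulate_anova_matrix(n_null = 5, seed = 7)
  sf <- m$sample_factors
  sf$copy <- sf$tissue
  m2 <- expr_matrix(m$values, scale = "log2", sample_factors = sf)
  expect_error(anova_select(m2, "tissue", eliminate = "copy"), "aliased")
  expect_error(anova_select(m2, "missing_factor"), "sample_factors")
})

test_that("concordance testing separates duplicated from discordant RE probes", {
  sf <- data.frame(tissue = rep(c("heart", "brain", "spleen"), each = 3),
                   row.names = sprintf("s%d", 1:9))
  set.seed(8)
  base <- rnorm(9, 8, 0.1) + rep(c(0, 2, 0), each = 3)
  v <- rbind(
    re_dup = base,
    m1 = base, m2 = base + rnorm(9, 0, 0.05), m3 = base + rnorm(9, 0, 0.05),
    re_opp = 8 - rep(c(0, 2, 0), each = 3) + rnorm(9, 0, 0.1),
    n1 = base, n2 = base + rnorm(9, 0, 0.05), n3 = base + rnorm(9, 0, 0.05))
  colnames(v) <- rownames(sf)
  man <- platform_manifest("t", "antisense_crna", data.frame(
    pid = rownames(v), probeset = rep(c("psA", "psB"), each = 4),
    sequence = strrep("ACGTA", 5), stringsAsFactors = FALSE))
  re_rows <- data.frame(pid = c("re_dup", "re_opp"),
                        probeset = c("psA", "psB"),
                        stringsAsFactors = FALSE)
  m <- expr_matrix(v, scale = "log2", sample_factors = sf)
  res <- probe_vs_probeset_concordance(m, man, re_rows, "tissue")
  expect_true(res$concordant[res$probeset == "psA"])
  expect_false(res$concordant[res$probeset == "psB"])
  expect_equal(attr(res, "fraction_concordant"), 0.5)
  # probesets with too few non-RE members are skipped with a warning
  man2 <- platform_manifest("t", "antisense_crna", data.frame(
    pid = c("re_dup", "m1"), probeset = "psA",
    sequence = strrep("ACGTA", 5), stringsAsFactors = FALSE))
  expect_warning(
    probe_vs_probeset_concordance(m, man2,
                                  re_rows[re_rows$pid == "re_dup", ],
                                  "tissue"), "skipped")
})

test_that("nearest-gene regression recovers exact and null relationships", {
  sim <- simulate_coregulation(n_probes = 200, shared_fraction = 1,
                               seed = 9)
  # shared fraction 1 with the same scale: points fall on the identity
  # line (lm warns about the perfect fit)
  res <- suppressWarnings(
    nearest_gene_regression(sim$re_matrix, sim$gene_summaries,
                            sim$annot, sim$sample_factors, "heart"))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_equal(res$slope, 1, tolerance = 1e-10)

  null <- simulate_coregulation(n_probes = 400, shared_fraction = 0,
                                seed = 10)
  res0 <- nearest_gene_regression(null$re_matrix, null$gene_summaries,
                                  null$annot, null$sample_factors, "heart")
  expect_lt(res0$r_squared, 0.03)

  # points whose gene is off the platform are omitted and counted
  drop <- sim
  drop$gene_summaries <- drop$gene_summaries[-(1:20), , drop = FALSE]
  res_d <- suppressWarnings(
    nearest_gene_regression(drop$re_matrix, drop$gene_summaries,
                            drop$annot, drop$sample_factors, "heart"))
  expect_equal(attr(res_d, "n_omitted"), 20L)
  expect_equal(res_d$n_points, 180L)
})

test_that("hierarchical clustering groups duplicated samples and ignores column order", {
  set.seed(12)
  sig_a <- rnorm(30); sig_b <- rnorm(30)
  v <- cbind(a1 = sig_a, a2 = sig_a + rnorm(30, 0, 0.05),
             b1 = sig_b, b2 = sig_b + rnorm(30, 0, 0.05))
  rownames(v) <- sprintf("p%02d", 1:30)
  hc <- hierarchical_cluster(v, axis = "cols")
  ord <- attr(hc, "leaf_order")
  a_pos <- match(c("a1", "a2"), ord)
  expect_equal(abs(diff(a_pos)), 1)              # a's are adjacent
  groups <- cutree(hc, k = 2)
  expect_equal(groups[["a1"]], groups[["a2"]])
  expect_equal(groups[["b1"]], groups[["b2"]])
  expect_true(groups[["a1"]] != groups[["b1"]])
  # permuting input columns leaves memberships unchanged
  hc2 <- hierarchical_cluster(v[, c(3, 1, 4, 2)], axis = "cols")
  expect_equal(cutree(hc2, k = 2)[names(groups)], groups)
  # constant rows warn
  v2 <- rbind(const = rep(1, 4), x = rnorm(4), y = rnorm(4))
  colnames(v2) <- sprintf("s%d", 1:4)
  expect_warning(hierarchical_cluster(v2, axis = "rows"), "constant")
})
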