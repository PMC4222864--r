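mk_hit <- function(sid = "chr1", sstart = 5000L, send = 5025L,
                   strand = "+", pid = "p1", numhits = 1L, nident = 25L) {
  data.frame(pid = pid, sid = sid, sstart = sstart, send = send,
             strand = strand, nident = nident, numhits = numhits,
             score = nident, mapped = TRUE, stringsAsFactors = FALSE)
}

mk_repeat <- function(start = 4900L, end = 5300L, strand = "+",
                      name = "RLTR44-int", class = "LTR/ERVK",
                      chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             repeat_name = name, repeat_class = class,
             stringsAsFactors = FALSE)
}

mk_gene <- function(start, end, chrom = "chr1", strand = "+",
                    id = "G1", biotype = "protein_coding") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = id, symbol = id, biotype = biotype,
             stringsAsFactors = FALSE)
}

test_that("chemistry determines the qualifying probe orientation", {
  hit_plus <- mk_hit(strand = "+")
  hit_minus <- mk_hit(strand = "-")
  rep_plus <- mk_repeat(strand = "+")
  # antisense cRNA platforms: probe must be sense to the element
  expect_false(is.null(classify_re_probe(hit_plus, rep_plus,
                                         "antisense_crna")))
  expect_null(classify_re_probe(hit_minus, rep_plus, "antisense_crna"))
  # sense cDNA platforms: the reverse-orientation twin matches instead
  expect_null(classify_re_probe(hit_plus, rep_plus, "sense_cdna"))
  expect_false(is.null(classify_re_probe(hit_minus, rep_plus,
                                         "sense_cdna")))
})

test_that("containment is strict: a one-base overhang disqualifies", {
  reps <- mk_repeat(start = 4900L, end = 5300L)
  inside <- mk_hit(sstart = 5275L, send = 5300L)
  overhang <- mk_hit(sstart = 5276L, send = 5301L)
  at_start <- mk_hit(sstart = 4900L, send = 4925L)
  before <- mk_hit(sstart = 4899L, send = 4924L)
  expect_false(is.null(classify_re_probe(inside, reps, "antisense_crna")))
  expect_null(classify_re_probe(overhang, reps, "antisense_crna"))
  expect_false(is.null(classify_re_probe(at_start, reps, "antisense_crna")))
  expect_null(classify_re_probe(before, reps, "antisense_crna"))
})

test_that("nearest genes and distance follow chromosomal coordinates", {
  genes <- rbind(mk_gene(1000L, 2000L, id = "A"),
                 mk_gene(8000L, 9000L, id = "B"))
  ng <- nearest_genes(mk_hit(sstart = 5000L, send = 5025L), genes)
  expect_equal(ng$five_prime$symbol, "A")
  expect_equal(ng$three_prime$symbol, "B")
  # min of the two gaps: 5' gap 5000-2000=3000, 3' gap 8000-5025=2975
  expect_equal(ng$distance, 2975L)

  inside <- nearest_genes(mk_hit(sstart = 1500L, send = 1525L), genes)
  expect_equal(inside$distance, 0L)

  # boundary cases around the 1 kb filter
  g2 <- mk_gene(1000L, 4000L, id = "C")
  expect_equal(nearest_genes(mk_hit(sstart = 5000L), g2)$distance, 1000L)
  expect_equal(nearest_genes(mk_hit(sstart = 5001L), g2)$distance, 1001L)

  off <- nearest_genes(mk_hit(sid = "chrZ"), genes)
  expect_true(off$flagged)
  expect_true(is.na(off$distance))
  expect_null(off$five_prime)
})

test_that("non-coding genes are excluded from the nearest-gene search", {
  genes <- rbind(mk_gene(4500L, 4900L, id = "NC", biotype = "lincRNA"),
                 mk_gene(1000L, 2000L, id = "A"))
  ng <- nearest_genes(mk_hit(sstart = 5000L, send = 5025L), genes)
  expect_equal(ng$five_prime$symbol, "A")
  expect_equal(ng$distance, 3000L)
  ng_all <- nearest_genes(mk_hit(sstart = 5000L, send = 5025L), genes,
                          coding_only = FALSE)
  expect_equal(ng_all$five_prime$symbol, "NC")
  expect_equal(ng_all$distance, 100L)
})

test_that("ltr_class maps ERV families to classes I/II/III", {
  expect_equal(
    ltr_class(c("LTR/ERV1", "LTR/ERVK", "LTR/ERVL", "LTR/ERVL-MaLR",
                "LINE/L1", "SINE/B2", "LTR/Gypsy")),
    c("I", "II", "III", "III", NA, NA, NA))
})

test_that("annotation of the planted fixture recovers exactly the RE probes", {
  d <- demo_fixture()
  expect_setequal(d$annot$pid, d$plat$truth$pid[d$plat$truth$expect_re])
  # MaLR probes carry LTR class III
  malr <- d$annot[!is.na(d$annot$repclass) &
                    d$annot$repclass == "LTR/ERVL-MaLR", ]
  expect_true(nrow(malr) > 0)
  expect_true(all(malr$ltr_class == "III"))
  # multi-locus probes are present with empty context
  multi <- d$annot[d$annot$numhits > 1L, ]
  expect_true(nrow(multi) > 0)
  ctx <- c("sid", "sstart", "send", "nident", "repeat_name", "repclass",
           "rstart", "rend", "fivep_id", "threep_id")
  for (col in ctx) expect_true(all(is.na(multi[[col]])))
  # unique rows satisfy the containment invariant
  uniq <- d$annot[d$annot$numhits == 1L, ]
  expect_true(all(uniq$sstart >= uniq$rstart & uniq$send <= uniq$rend))
  # 5' gene before the probe, 3' gene after
  expect_true(all(is.na(uniq$fivep_end) | uniq$fivep_end <= uniq$sstart))
  expect_true(all(is.na(uniq$threep_start) |
                    uniq$threep_start >= uniq$send))
})

test_that("classification is invariant to flipping the whole genome fixture", {
  d <- demo_fixture()
  gen <- d$gen
  lens <- vapply(names(gen$genome), function(n) length(gen$genome[[n]]),
                 integer(1))
  flipped_genome <- Biostrings::reverseComplement(gen$genome)
  flip_feats <- function(df) {
    L <- lens[df$chrom]
    out <- df
    out$start <- as.integer(L - df$end)
    out$end <- as.integer(L - df$start)
    out$strand <- ifelse(df$strand == "+", "-", "+")
    out
  }
  hits2 <- map_platform(d$plat$manifest, flipped_genome)
  annot2 <- build_annotation(d$plat$manifest, hits2,
                             flip_feats(gen$repeats), flip_feats(gen$genes))
  expect_setequal(annot2$pid, d$annot$pid)
})

test_that("intragenic position bins clamp and localize correctly", {
  genes <- mk_gene(10000L, 20000L, id = "G")
  mk_row <- function(sstart, send, five = NA, fe = NA, three = NA,
                     ts = NA, dist) {
    data.frame(pid = "p", probeset = "ps", plen = 25L, sid = "chr1",
               sstart = sstart, send = send, nident = 25L, numhits = 1L,
               repeat_name = "r", repclass = "LTR/ERVK",
               rstart = sstart - 10L, rend = send + 10L,
               fivep_id = five, fivep_start = NA_integer_,
               fivep_end = fe, threep_id = three, threep_start = ts,
               threep_end = NA_integer_, is_unique = TRUE,
               intergenic_distance = dist, ltr_class = "II",
               intragenic = dist == 0, stringsAsFactors = FALSE)
  }
  # probe at the exact gene midpoint
  mid <- intragenic_position_bins(mk_row(14988L, 15013L, dist = 0L), genes)
  expect_equal(sum(mid), 1L)
  expect_equal(which(mid == 1L), 6L, ignore_attr = TRUE)
  # probe 500 bp upstream of a + strand gene clamps into the first bin
  up <- intragenic_position_bins(
    mk_row(9475L, 9500L, three = "G", ts = 10000L, dist = 500L), genes)
  expect_equal(which(up == 1L), 1L, ignore_attr = TRUE)
  # on a - strand gene the position is measured 5'->3' of the gene
  genes_m <- mk_gene(10000L, 20000L, id = "G", strand = "-")
  lowq <- intragenic_position_bins(mk_row(18000L, 18025L, dist = 0L),
                                   genes_m)
  expect_equal(which(lowq == 1L), 2L, ignore_attr = TRUE)
})

test_that("uniformly planted intragenic probes fill bins roughly evenly", {
  genes <- mk_gene(0L, 10000L, id = "G")
  rows <- do.call(rbind, lapply(seq(100L, 9900L, by = 200L), function(s) {
    data.frame(pid = paste0("p", s), probeset = "ps", plen = 25L,
               sid = "chr1", sstart = s, send = s + 25L, nident = 25L,
               numhits = 1L, repeat_name = "r", repclass = "LTR/ERVK",
               rstart = s - 10L, rend = s + 35L, fivep_id = NA_character_,
               fivep_start = NA_integer_, fivep_end = NA_integer_,
               threep_id = NA_character_, threep_start = NA_integer_,
               threep_end = NA_integer_, is_unique = TRUE,
               intergenic_distance = 0L, ltr_class = "II",
               intragenic = TRUE, stringsAsFactors = FALSE)
  }))
  counts <- intragenic_position_bins(rows, genes)
  expect_equal(sum(counts), 50L)
  expect_true(all(counts == 5L))
})
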