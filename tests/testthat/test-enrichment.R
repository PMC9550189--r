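test_that("window tiling, gap filter and centromere boundary semantics", {
  cl <- c(chr1 = 1e6)
  w <- make_windows(cl, 1e4)
  expect_equal(nrow(w), 100L)
  expect_true(all(w$kept))
  expect_false(any(w$partial))
  # a window with 6 kbp of gap (60% > 50%) is removed
  gaps <- data.frame(chrom = "chr1", start = 12e3, end = 18e3)
  w2 <- make_windows(cl, 1e4, gaps = gaps)
  expect_false(w2$kept[w2$start == 10e3])
  expect_true(w2$kept[w2$start == 20e3])
  # half-open: a window abutting the centromere end keeps zero overlap
  cen <- data.frame(chrom = "chr1", start = 40e3, end = 50e3)
  w3 <- make_windows(cl, 1e4, centromeres = cen)
  expect_false(w3$kept[w3$start == 40e3])
  expect_true(w3$kept[w3$start == 50e3])
  # the trailing partial window is kept but flagged
  w4 <- make_windows(c(chr1 = 95e3), 1e4)
  expect_equal(nrow(w4), 10L)
  expect_true(w4$partial[10L])
  expect_equal(w4$end[10L], 95e3)
})

test_that("window classification requires full containment", {
  cl <- c(chr1 = 100e3)
  w <- make_windows(cl, 1e4)
  mshsbs <- data.frame(chrom = "chr1", start = 0, end = 35e3)
  ebrs <- data.frame(chrom = "chr1", start = 50e3, end = 80e3,
                     reuse = TRUE, tip_specific = FALSE)
  wc <- classify_windows(w, mshsbs, ebrs)
  expect_equal(wc$class[wc$start == 0], "msHSB")
  expect_equal(wc$class[wc$start == 30e3], "other")   # straddles the boundary
  expect_equal(wc$class[wc$start == 50e3], "EBR")
  expect_true(wc$ebr_reuse[wc$start == 50e3])
  # per-bp brute force of class counts
  counts <- table(wc$class)
  oracle <- vapply(seq_len(nrow(w)), function(i) {
    s <- w$start[i]; e <- w$end[i]
    if (s >= 0 && e <= 35e3) "msHSB"
    else if (s >= 50e3 && e <= 80e3) "EBR"
    else "other"
  }, "")
  expect_equal(as.vector(counts[names(table(oracle))]),
               as.vector(table(oracle)))
  expect_error(classify_windows(w, mshsbs,
                                data.frame(chrom = "chr1", start = 30e3,
                                           end = 60e3)),
               "overlapping region sets")
})

test_that("feature tallies follow the gene-start rule and a per-bp oracle", {
  cl <- c(chr1 = 50e3)
  w <- make_windows(cl, 1e4)
  tracks <- list(
    genes = data.frame(chrom = "chr1", start = c(5e3, 18e3), end = c(25e3, 21e3)),
    SINE_Alu = data.frame(chrom = "chr1", start = c(1e3, 9.8e3, 30e3),
                          end = c(1.3e3, 10.1e3, 30.3e3)),
    TAD = data.frame(chrom = "chr1", start = 15e3, end = 42e3),
    compartments = data.frame(chrom = "chr1", start = c(0, 25e3),
                              end = c(25e3, 50e3), label = c("A", "B")))
  t <- tally_features(w, tracks)
  # gene spanning windows: counted once at its start window, bases split
  expect_equal(t$n_genes, c(1L, 1L, 0L, 0L, 0L))
  for (i in 1:5) {
    expect_equal(t$gene_bases[i],
                 oracle_overlap_bases(t$start[i], t$end[i],
                                      tracks$genes$chrom, tracks$genes, "chr1"))
    expect_equal(t$SINE_Alu_bases[i],
                 oracle_overlap_bases(t$start[i], t$end[i],
                                      tracks$SINE_Alu$chrom, tracks$SINE_Alu, "chr1"))
  }
  # tally conservation: summed window bases equal total track bases
  expect_equal(sum(t$SINE_Alu_bases), sum(tracks$SINE_Alu$end - tracks$SINE_Alu$start))
  expect_equal(t$tad_present, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(t$compartment, c("A", "A", "A/B", "B", "B"))
  # empty tracks give zeros and compartment none
  t0 <- tally_features(w, list(genes = NULL))
  expect_true(all(t0$n_genes == 0L) && all(t0$compartment == "none"))
})

test_that("Wilcoxon machinery matches a brute-force rank sum", {
  set.seed(14)
  for (rep in 1:10) {
    x <- sample(1:50, sample(3:8, 1))
    y <- sample(1:50, sample(3:8, 1))
    res <- pairwise_wilcoxon(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
    expect_equal(res$W, oracle_rank_sum_W(x, y))
  }
  # identical groups: p near 1, equal medians
  v <- rep(1:20, 2)
  res <- pairwise_wilcoxon(v, rep(c("a", "b"), each = 20))
  expect_gt(res$p, 0.9)
  expect_equal(res$median1, res$median2)
  # a single-observation group is skipped and flagged
  res2 <- pairwise_wilcoxon(c(1, 2, 3, 9), rep(c("a", "b"), c(3, 1)))
  expect_true(res2$skipped)
})

test_that("chi-square association and odds ratios match hand arithmetic", {
  f <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  g <- rep(c("x", "y"), each = 100)
  res <- association_test(f, g)
  expect_equal(res$odds_ratio, 27 / 7, tolerance = 1e-12)
  # textbook Pearson statistic
  tab <- rbind(c(30, 70), c(10, 90))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chisq, sum((tab - E)^2 / E), tolerance = 1e-12)
  # equal proportions: OR = 1
  f2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 30, 40, 60))
  g2 <- rep(c("x", "y"), c(50, 100))
  expect_equal(association_test(f2, g2)$odds_ratio, 1)
  # zero cell triggers the flagged Haldane correction
  f3 <- c(rep(TRUE, 5), rep(FALSE, 5), rep(FALSE, 10))
  g3 <- rep(c("x", "y"), each = 10)
  res3 <- association_test(f3, g3)
  expect_true(res3$haldane)
  expect_true(is.finite(res3$odds_ratio))
})

test_that("repeat subclasses below the density floor are suppressed", {
  w <- data.frame(chrom = "chr1", start = 0:99 * 1e4, end = 1:100 * 1e4,
                  kept = TRUE, class = rep(c("EBR", "msHSB"), 50))
  w$SINE_Alu_bases <- rep(c(900, 950), 50)
  w$LINE_L2_bases <- rep(c(20, 30), 50)   # mean < 100 bp everywhere
  rep_rep <- repeat_density_report(w, subclasses = c("SINE_Alu", "LINE_L2"))
  expect_equal(rep_rep$suppressed, "LINE_L2")
  expect_true("SINE_Alu" %in% names(rep_rep$comparisons))
})
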