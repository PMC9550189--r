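# helper: maps for a set of constructed genomes with a given reference
maps_for <- function(genomes, reference) {
  make_orthology_maps(genomes, reference)
}

test_that("identical genomes give one SF per chromosome", {
  a <- mk_genome(list(1:4), len = 250e3, name = "a")  # 1-Mbp chromosome
  b <- mk_genome(list(1:4), len = 250e3, name = "b")
  sfs <- detect_sfs(maps_for(list(a = a, b = b), "a"), resolution = 300e3)
  expect_equal(nrow(sfs$table), 1L)
  expect_equal(sfs$table$length, 1e6)
  expect_equal(nrow(sfs$unplaced), 0L)
})

test_that("an interior inversion above resolution yields 3 SFs, flipped in the carrier", {
  # blocks of 200 kbp; blocks 3-4 (400 kbp) inverted in genome b
  a <- mk_genome(list(1:6), len = 200e3, name = "a")
  b <- mk_genome(list(c(1L, 2L, -4L, -3L, 5L, 6L)), len = 200e3, name = "b")
  sfs <- detect_sfs(maps_for(list(a = a, b = b), "a"), resolution = 300e3)
  expect_equal(nrow(sfs$table), 3L)
  mid <- sfs$table$sf[sfs$table$start == 400e3]
  pl <- sfs$placements
  expect_equal(pl$orient[pl$sf == mid & pl$genome == "b"], -1L)
  expect_equal(pl$orient[pl$sf == mid & pl$genome == "a"], 1L)
})

test_that("a sub-resolution inverted segment is dropped and reported unplaced", {
  # blocks of 100 kbp; blocks 5-6 (200 kbp < 300 kbp) inverted in b, flanked
  # by 400-kbp colinear runs
  a <- mk_genome(list(1:10), len = 100e3, name = "a")
  b <- mk_genome(list(c(1L, 2L, 3L, 4L, -6L, -5L, 7L, 8L, 9L, 10L)),
                 len = 100e3, name = "b")
  sfs <- detect_sfs(maps_for(list(a = a, b = b), "a"), resolution = 300e3)
  expect_equal(nrow(sfs$table), 2L)
  expect_equal(nrow(sfs$unplaced), 1L)
  expect_equal(sfs$unplaced$length, 200e3)
})

test_that("adjacency scores follow the inverse-distance formula", {
  # 4-tip balanced tree: ingroup tips at distance 10 from the target node,
  # outgroup tips at 30; support by one ingroup + one outgroup tip gives
  # (1/10 + 1/30) / (2/10 + 2/30) = 0.5, two-sided
  tr <- dated_tree(ape::read.tree(text = "((A:10,B:10)ab:10,(C:10,D:10)cd:10)r;"))
  a <- mk_genome(list(c(1L, 2L)), len = 400e3, name = "A")     # carries 1h|2t
  b <- mk_genome(list(1L, 2L), len = 400e3, name = "B")
  c3 <- mk_genome(list(c(1L, 2L)), len = 400e3, name = "C")
  d <- mk_genome(list(1L, 2L), len = 400e3, name = "D")
  maps <- maps_for(list(A = a, B = b, C = c3, D = d), "A")
  sfs <- detect_sfs(maps, resolution = 300e3)
  sc <- score_adjacencies(sfs, tr, "ab")
  row <- sc[sc$adj == "1h|2t", ]
  expect_equal(row$score, 0.5)
  expect_true(row$sided)
  expect_setequal(strsplit(row$support, ",")[[1L]], c("A", "C"))
  # an adjacency present in all genomes scores 1 with two-sided support
  # (placements constructed directly: two SFs adjacent in every genome)
  pl <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(g)
    data.frame(sf = 1:2, genome = g, chrom = "chr1",
               start = c(0, 4e5), end = c(4e5, 8e5), orient = 1L)))
  sfs2 <- structure(list(
    table = data.frame(sf = 1:2, chrom = "chr1", start = c(0, 4e5),
                       end = c(4e5, 8e5), length = 4e5),
    placements = pl, resolution = 3e5), class = "sf_set")
  sc2 <- score_adjacencies(sfs2, tr, "ab")
  expect_equal(sc2$score[sc2$adj == "1h|2t"], 1)
  expect_true(sc2$sided[sc2$adj == "1h|2t"])
  expect_error(score_adjacencies(sfs2, tr, "A"), "internal node")
})

test_that("greedy assembly resolves conflicts by score and is deterministic", {
  sfs <- list(table = data.frame(sf = 1:3, chrom = "chr1",
                                 start = c(0, 1e6, 2e6),
                                 end = c(1e6, 2e6, 3e6),
                                 length = rep(1e6, 3)))
  # two mutually exclusive adjacencies competing for 1h
  scores <- data.frame(
    adj = c("1h|2t", "1h|3t"),
    id1 = c(1L, 1L), ext1 = c("h", "h"), id2 = c(2L, 3L), ext2 = c("t", "t"),
    score = c(0.8, 0.6), sided = c(TRUE, TRUE),
    support = "", target = "anc")
  racfs <- assemble_racfs(scores, sfs)
  expect_identical(attr(racfs, "accepted"), "1h|2t")
  # tie: the lexicographically smaller adjacency id wins, reproducibly
  scores$score <- c(0.8, 0.8)
  r1 <- assemble_racfs(scores[order(-scores$score, !scores$sided, scores$adj), ], sfs)
  r2 <- assemble_racfs(scores[order(-scores$score, !scores$sided, scores$adj), ], sfs)
  expect_identical(attr(r1, "accepted"), "1h|2t")
  expect_identical(r1$chromosomes, r2$chromosomes)
  # every SF appears exactly once
  expect_setequal(abs(unlist(r1$chromosomes)), 1:3)
})

test_that("RACF ordering merges on majority and refuses ties", {
  tr <- dated_tree(ape::read.tree(
    text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;"))
  base <- list(c(1L, 2L), c(3L, 4L))  # two racfs over blocks of 400 kbp
  mk <- function(chroms, nm) mk_genome(chroms, len = 400e3, name = nm)
  # 3 of 4 tips place the racfs adjacent (2h|3t), one differs
  tips_maj <- list(A = mk(list(c(1L, 2L, 3L, 4L)), "A"),
                   B = mk(list(c(1L, 2L, 3L, 4L)), "B"),
                   C = mk(list(c(1L, 2L, 3L, 4L)), "C"),
                   D = mk(list(c(3L, 4L), c(1L, 2L)), "D"))
  sfs <- detect_sfs(maps_for(tips_maj, "D"), resolution = 300e3)
  racfs <- assemble_racfs(score_adjacencies(sfs, tr, "ab"), sfs)
  ord <- order_racfs(racfs, sfs, tr, genomes = names(tips_maj))
  expect_equal(length(ord$genome$chromosomes), 1L)
  # 2 vs 2 conflicting orders: tie means no join
  tips_tie <- list(A = mk(list(c(1L, 2L, 3L, 4L)), "A"),
                   B = mk(list(c(1L, 2L, 3L, 4L)), "B"),
                   C = mk(list(c(1L, 2L, -4L, -3L)), "C"),
                   D = mk(list(c(1L, 2L, -4L, -3L)), "D"))
  sfs2 <- detect_sfs(maps_for(tips_tie, "A"), resolution = 300e3)
  sc2 <- score_adjacencies(sfs2, tr, "ab")
  racfs2 <- assemble_racfs(sc2, sfs2,
                           rule = function(score, sided) score >= 0.99)
  expect_gte(length(racfs2$chromosomes), 2L)
  ord2 <- order_racfs(racfs2, sfs2, tr, genomes = names(tips_tie),
                      majority = 0.5)
  expect_true(any(ord2$log$decision == "tied conflict"))
  expect_equal(length(ord2$genome$chromosomes), length(racfs2$chromosomes))
})

test_that("reconstruction comparison classifies maintained/extra/inconsistent", {
  sfs <- list(table = data.frame(sf = 1:4, chrom = "chr1",
                                 start = c(0, 1, 2, 3) * 1e6,
                                 end = c(1, 2, 3, 4) * 1e6,
                                 length = rep(1e6, 4)))
  lens <- stats::setNames(rep(1e6, 4), 1:4)
  ra <- block_genome(list(c(1L, 2L, 3L), 4L), lens, name = "A")
  # identical reconstructions: all maintained, fraction 0
  cmp0 <- compare_reconstructions(ra, ra, sfs)
  expect_true(all(cmp0$classes$class == "maintained"))
  expect_equal(cmp0$inconsistent_fraction, 0)
  # B splits the RACF at a junction: that adjacency is extra, not inconsistent
  rb <- block_genome(list(c(1L, 2L), 3L, 4L), lens, name = "B")
  cmp1 <- compare_reconstructions(ra, rb, sfs)
  expect_equal(cmp1$classes$class[cmp1$classes$adj == "2h|3t"], "extra")
  expect_equal(cmp1$inconsistent_fraction, 0)
  # B joins 2h to 4t instead: contradiction
  rc <- block_genome(list(c(1L, 2L, 4L), 3L), lens, name = "C")
  cmp2 <- compare_reconstructions(ra, rc, sfs)
  expect_equal(cmp2$classes$class[cmp2$classes$adj == "2h|3t"], "inconsistent")
  expect_equal(cmp2$inconsistent_fraction, 0.5)  # SFs 2 and 3 of 4 Mbp total
  expect_error(compare_reconstructions(ra, block_genome(list(1:3), lens[1:3]), sfs),
               "different SF universes")
})

test_that("SF reference intervals are disjoint and sorted", {
  h <- simulate_history(toy_tree6(), simulation_config(n_blocks = 30, rate = 2, seed = 6))
  maps <- make_orthology_maps(h$genomes[toy_tree6()$tip.label], "A")
  sfs <- detect_sfs(maps, resolution = 300e3)
  tab <- sfs$table
  for (cn in unique(tab$chrom)) {
    tc <- tab[tab$chrom == cn, ]
    tc <- tc[order(tc$start), ]
    expect_true(all(tc$start[-1L] >= tc$end[-nrow(tc)] - 1e-9))
  }
})
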