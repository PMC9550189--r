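test_that("reversal distance matches hand-checkable cases", {
  expect_equal(reversal_distance(c(1L, 2L, 3L)), 0L)
  expect_equal(reversal_distance(c(-3L, -2L, -1L)), 1L)
  expect_equal(reversal_distance(c(2L, 1L)), 3L)
  expect_equal(reversal_distance(integer(0)), 0L)
})

test_that("reversal distance agrees with BFS exhaustively for small n", {
  for (n in 1:3) {
    dist <- bfs_all_reversal_distances(n)
    for (k in ls(dist)) {
      p <- as.integer(strsplit(k, ",")[[1L]])
      expect_identical(reversal_distance(p), dist[[k]])
    }
  }
})

test_that("sorting by reversals realises the exact distance", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    p <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    d <- reversal_distance(p)
    moves <- karyevol:::sort_by_reversals(p)
    expect_length(moves, d)
    q <- karyevol:::normalize_signed(p)
    for (mv in moves) q <- karyevol:::apply_reversal(q, mv[1L], mv[2L])
    expect_identical(q, seq_len(n))
  }
})

test_that("signed-permutation relabelling round-trips", {
  a <- mk_genome(list(c(3L, -1L), c(2L)))
  b <- mk_genome(list(c(-2L, 1L), c(3L)))
  p <- to_signed_permutation(a, b)
  expect_identical(to_signed_permutation(a, a)$chromosomes,
                   list(c(1L, 2L), 3L))
  # relabelling a through b and back through a is the identity transform
  back <- to_signed_permutation(b, b)
  expect_identical(back$chromosomes, list(c(1L, 2L), 3L))
  expect_error(to_signed_permutation(a, mk_genome(list(c(1L, 2L)))),
               "block sets differ")
})

test_that("scenarios type fusions and fissions correctly", {
  a <- mk_genome(list(c(1L, 2L), 3L))
  b <- mk_genome(list(c(1L, 2L, 3L)))
  sc <- multichromosomal_scenario(a, b)
  expect_equal(sc$counts$n_fusions, 1L)
  expect_equal(sc$counts$n_events, 1L)
  expect_equal(sc$counts$n_breakpoints, 0L)
  sc2 <- multichromosomal_scenario(b, a)
  expect_equal(sc2$counts$n_fissions, 1L)
  expect_equal(sc2$counts$n_breakpoints, 1L)
  # identical genomes: empty scenario
  expect_equal(multichromosomal_scenario(a, a)$counts$n_events, 0L)
})

test_that("exact scenarios equal the BFS oracle and replay correctly", {
  set.seed(3)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    a <- rand_genome(n)
    b <- rand_genome(n)
    sc <- multichromosomal_scenario(a, b)
    start <- to_signed_permutation(a, b)$chromosomes
    d <- oracle_genome_distance(start, sc$target_state)
    expect_lte(sc$counts$n_events, d + 1L)
    expect_equal(sc$counts$n_events, d)
    # replay reproduces the target exactly (up to chromosome order/flips)
    expect_identical(oracle_genome_key(sc$replay(a)),
                     oracle_genome_key(sc$target_state))
  }
})

test_that("scenario length obeys metric axioms on small random genomes", {
  set.seed(19)
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    a <- rand_genome(n); b <- rand_genome(n); c3 <- rand_genome(n)
    dab <- multichromosomal_scenario(a, b)$counts$n_events
    dba <- multichromosomal_scenario(b, a)$counts$n_events
    dac <- multichromosomal_scenario(a, c3)$counts$n_events
    dcb <- multichromosomal_scenario(c3, b)$counts$n_events
    expect_equal(multichromosomal_scenario(a, a)$counts$n_events, 0L)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb)
  }
})

test_that("branch events are inferred along a constructed lineage", {
  root <- mk_genome(list(c(1L, 2L, 3L, 4L), c(5L, 6L)), name = "root")
  mid <- mk_genome(list(c(1L, -3L, -2L, 4L), c(5L, 6L)), name = "mid")   # 1 inversion
  tip <- mk_genome(list(c(1L, -3L, -2L, 4L), c(5L), c(6L)), name = "tip") # 1 fission
  ev <- infer_branch_events(list(root = root, mid = mid, tip = tip))
  expect_equal(ev$branch, c("mid", "tip"))
  expect_equal(ev$n_inversions, c(1L, 0L))
  expect_equal(ev$n_fissions, c(0L, 1L))
  expect_equal(ev$n_breakpoints, c(2L, 1L))
  ev0 <- infer_branch_events(list(a = root, b = root, c = root))
  expect_true(all(ev0$n_events == 0L))
})

test_that("rearrangement fractions follow the majority-chromosome rules", {
  anc <- mk_genome(list(chrA = c(1L, 2L, 3L, 4L, 5L)))
  expect_equal(fraction_rearranged(anc, "chrA", anc), c(inter = 0, intra = 0))
  anc4 <- mk_genome(list(chrA = c(1L, 2L, 3L, 4L)))
  moved <- mk_genome(list(c(1L, 2L, 3L), c(4L)))
  expect_equal(fraction_rearranged(anc4, "chrA", moved)[["inter"]], 0.25)
  inv <- mk_genome(list(c(1L, 2L, -3L, 4L, 5L)))
  fr <- fraction_rearranged(anc, "chrA", inv)
  expect_equal(fr[["inter"]], 0)
  expect_equal(fr[["intra"]], 0.2)
  # fully reversed chromosome is colinear: no intra signal
  rev5 <- mk_genome(list(c(-5L, -4L, -3L, -2L, -1L)))
  expect_equal(fraction_rearranged(anc, "chrA", rev5)[["intra"]], 0)
})

test_that("orthology classification reproduces the printed karyotype calls", {
  map <- mam_gga_map()
  cls <- classify_orthology(map)
  expect_equal(cls$class[cls$chrom_a == "MAM7"], "1:1")
  expect_equal(cls$partners[cls$chrom_a == "MAM7"], "GGA6")
  expect_equal(cls$class[cls$chrom_a == "MAM10"], "1:n complete")
  expect_equal(cls$partners[cls$chrom_a == "MAM10"], "GGA18,GGA27")
  expect_equal(cls$class[cls$chrom_a == "MAM18"], "1:n complete")
  expect_equal(cls$class[cls$chrom_a == "MAM8"], "partial")
  expect_equal(cls$class[cls$chrom_a == "MAM13"], "partial")
  expect_equal(cls$class[cls$chrom_a == "MAMX"], "partial")
  expect_error(classify_orthology(map[0, ]), "empty")
})
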