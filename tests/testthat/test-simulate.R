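test_that("rate zero propagates the root genome unchanged", {
  h <- simulate_history(toy_tree6(), simulation_config(n_blocks = 12, rate = 0, seed = 1))
  for (g in h$genomes) {
    expect_identical(unname(lapply(g$chromosomes, as.integer)),
                     unname(lapply(h$genomes$root$chromosomes, as.integer)))
  }
  expect_equal(nrow(h$events), 0L)
})

test_that("simulation conserves genome content and validity", {
  h <- simulate_history(toy_tree6(), simulation_config(n_blocks = 30, rate = 2, seed = 4))
  L <- genome_length(h$genomes$root)
  for (g in h$genomes) {
    validate_block_genome(g)
    expect_equal(genome_length(g), L)
    expect_equal(n_blocks(g), 30L)
  }
})

test_that("a branch with a single inversion yields one reversed run", {
  h <- simulate_history(toy_tree6(), simulation_config(n_blocks = 30, rate = 2, seed = 4))
  tab <- table(h$events$branch, h$events$type)
  one_inv <- rownames(tab)[tab[, "inversion"] == 1 &
                             rowSums(tab) == 1]
  expect_gt(length(one_inv), 0)
  bt <- karyevol:::branch_table(toy_tree6())
  for (br in one_inv) {
    parent <- h$genomes[[bt$parent[bt$branch == br]]]
    child <- h$genomes[[br]]
    sc <- multichromosomal_scenario(parent, child, exact_limit = 40L)
    expect_equal(sc$counts$n_inversions, 1L)
    expect_equal(sc$counts$n_events, 1L)
  }
})

test_that("event counts are Poisson with mean rate x total branch length", {
  tr <- dated_tree(ape::read.tree(text = "((A:2,B:2)ab:2,C:4)r;"))
  # total branch length 10 My at rate 2/My: Poisson(20)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_history(tr, simulation_config(n_blocks = 60, rate = 2,
                                                seed = s))$events)
  }, 1L)
  lo <- qpois(0.005, 20); hi <- qpois(0.995, 20)
  expect_gte(mean(counts >= lo & counts <= hi), 0.95)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 200))
})

test_that("true breakpoints count 2 per inversion, 1 per fission, 0 per fusion", {
  h <- simulate_history(toy_tree6(),
                        simulation_config(n_blocks = 30, rate = 3, seed = 9,
                                          mix = c(inversion = 0.5, fusion = 0.25,
                                                  fission = 0.25)))
  for (br in h$branches) {
    ev <- h$events[h$events$branch == br, ]
    expect_equal(nrow(true_breakpoints(h, br)),
                 2L * sum(ev$type == "inversion") + sum(ev$type == "fission"))
  }
  expect_error(true_breakpoints(h, "nosuch"), "unknown branch")
})

test_that("orthology maps encode identity, inversions and compose", {
  h <- simulate_history(toy_tree6(), simulation_config(n_blocks = 20, rate = 1, seed = 2))
  maps <- make_orthology_maps(h$genomes[toy_tree6()$tip.label], "A")
  self <- maps$A
  expect_true(all(self$orient == 1L))
  expect_identical(self[, c("ref_chrom", "ref_start", "ref_end")],
                   self[, c("tgt_chrom", "tgt_start", "tgt_end")],
                   ignore_attr = TRUE)
  # a constructed single inversion flips orientation exactly for its blocks
  a <- mk_genome(list(c(1L, 2L, 3L, 4L)), len = 1000, name = "a")
  b <- mk_genome(list(c(1L, -3L, -2L, 4L)), len = 1000, name = "b")
  m <- make_orthology_maps(list(a = a, b = b), "a")$b
  expect_equal(m$orient[m$block %in% c(2, 3)], c(-1L, -1L))
  expect_equal(m$orient[m$block %in% c(1, 4)], c(1L, 1L))
  # composition: map A->ref composed with ref->B matches direct block
  # correspondence A->B (same block, consistent relative orientation)
  ma <- maps$B; mb <- maps$C
  rel_direct <- make_orthology_maps(h$genomes[c("B", "C")], "B")$C
  ab <- merge(ma, mb, by = "block")
  comp_orient <- ab$orient.x * ab$orient.y
  expect_equal(comp_orient[order(ab$block)],
               rel_direct$orient[order(rel_direct$block)])
})

test_that("simulation is reproducible and configs validate", {
  tr <- toy_tree6()
  cfg <- simulation_config(n_blocks = 25, rate = 1.5, seed = 77)
  h1 <- simulate_history(tr, cfg)
  h2 <- simulate_history(tr, cfg)
  expect_identical(h1$events, h2$events)
  expect_identical(lapply(h1$genomes, `[[`, "chromosomes"),
                   lapply(h2$genomes, `[[`, "chromosomes"))
  expect_error(simulation_config(rate = -1), "rate")
  expect_error(simulation_config(mix = c(inversion = 0.5, fusion = 0.5,
                                         fission = 0.5)), "sum to 1")
})
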