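# Forward simulation of block-level karyotype evolution on a dated tree,
# with full ground truth: every internal-node genome, a typed event log and
# the reference-frame coordinates of every breakpoint.

#' Simulation configuration
#'
#' Parameters of the karyotype-evolution simulator. Defaults describe a
#' mammal-like regime: blocks averaging 880 kbp (the mean size of the
#' syntenic building blocks of mammalian genomes), an event rate of 1.2
#' events/My — about 2 breakpoints/My under the default event mix, the
#' long-term lineage average observed in mammals — and an inversion-heavy
#' mix (inversions are reported to account for roughly 76-85% of mammalian
#' rearrangements).
#'
#' @param n_blocks number of blocks in the root genome.
#' @param n_chromosomes number of root chromosomes.
#' @param block_length_mean mean block length (bp), gamma-distributed.
#' @param block_length_shape gamma shape; larger = more uniform lengths.
#' @param block_length_floor minimum block length (bp).
#' @param rate rearrangement events per My per lineage.
#' @param mix named probabilities for `inversion`, `fusion`, `fission`
#'   (must sum to 1).
#' @param seed integer seed; a single global RNG stream is used per run.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_blocks = 100L, n_chromosomes = 3L,
                              block_length_mean = 880e3,
                              block_length_shape = 2,
                              block_length_floor = 10e3,
                              rate = 1.2,
                              mix = c(inversion = 0.8, fusion = 0.1, fission = 0.1),
                              seed = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  if (abs(sum(mix) - 1) > 1e-8) stop("event mix must sum to 1")
  if (any(mix < 0)) stop("event mix must be non-negative")
  if (n_blocks < 1L || n_chromosomes < 1L || n_chromosomes > n_blocks) {
    stop("need 1 <= n_chromosomes <= n_blocks")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 n_chromosomes = as.integer(n_chromosomes),
                 block_length_mean = block_length_mean,
                 block_length_shape = block_length_shape,
                 block_length_floor = block_length_floor,
                 rate = rate, mix = mix, seed = as.integer(seed)),
            class = "simulation_config")
}

# draw the root genome
draw_root_genome <- function(config) {
  n <- config$n_blocks
  len <- pmax(config$block_length_floor,
              round(stats::rgamma(n, shape = config$block_length_shape,
                                  scale = config$block_length_mean /
                                    config$block_length_shape)))
  names(len) <- as.character(seq_len(n))
  nc <- config$n_chromosomes
  sizes <- rep(n %/% nc, nc)
  extra <- n %% nc
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chroms <- split(seq_len(n), rep(seq_len(nc), sizes))
  block_genome(lapply(chroms, as.integer), len, name = "root")
}

# draw one feasible event on `state` (list of signed int vectors); returns
# NULL if nothing is feasible (fully fragmented single-block genome)
draw_event <- function(state, mix) {
  for (attempt in 1:50) {
    type <- sample(names(mix), 1L, prob = mix)
    nc <- length(state)
    L <- lengths(state)
    if (type == "inversion") {
      # two distinct internal cut sites on one chromosome (needs >= 3 blocks)
      elig <- which(L >= 3L)
      if (!length(elig)) next
      w <- choose(L[elig] - 1L, 2L)
      ci <- elig[sample.int(length(elig), 1L, prob = w)]
      cuts <- sort(sample.int(L[ci] - 1L, 2L))
      return(list(type = "inversion", chrom = ci, i = cuts[1L] + 1L, j = cuts[2L]))
    } else if (type == "fission") {
      elig <- which(L >= 2L)
      if (!length(elig)) next
      w <- L[elig] - 1L
      ci <- elig[sample.int(length(elig), 1L, prob = w)]
      pos <- sample.int(L[ci] - 1L, 1L)
      return(list(type = "fission", chrom = ci, pos = pos))
    } else {
      if (nc < 2L) next
      pr <- sample.int(nc, 2L)
      return(list(type = "fusion", chrom = min(pr), chrom2 = max(pr),
                  orient1 = sample(c(1L, -1L), 1L), orient2 = sample(c(1L, -1L), 1L)))
    }
  }
  NULL
}

# reference(root)-frame coordinates of the parent junctions broken by an
# event; one row per broken junction
broken_junctions <- function(state, ev, root_layout) {
  junctions <- switch(ev$type,
    inversion = list(c(ev$chrom, ev$i - 1L), c(ev$chrom, ev$j)),
    fission = list(c(ev$chrom, ev$pos)),
    fusion = list())
  if (!length(junctions)) return(NULL)
  out <- lapply(junctions, function(jn) {
    ch <- state[[jn[1L]]]
    x <- ch[jn[2L]]; y <- ch[jn[2L] + 1L]
    # reference coordinate of the extremity each block presents at the junction
    rx <- root_layout[root_layout$block == abs(x), ]
    ry <- root_layout[root_layout$block == abs(y), ]
    px <- if (right_extremity(x) == "h") rx$end else rx$start
    py <- if (left_extremity(y) == "t") ry$start else ry$end
    ancestral <- rx$chrom == ry$chrom && abs(px - py) < 0.5
    data.frame(block1 = abs(x), bext1 = right_extremity(x),
               block2 = abs(y), bext2 = left_extremity(y),
               chrom1 = rx$chrom, pos1 = px, chrom2 = ry$chrom, pos2 = py,
               ancestral = ancestral)
  })
  do.call(rbind, out)
}

#' Simulate karyotype evolution along a dated tree
#'
#' Starting from a root genome drawn from `config`, applies inversions,
#' fusions and fissions along every branch: the event count per branch is
#' Poisson with mean `rate * dt`, event types follow the configured mix, and
#' breakpoints fall uniformly between blocks (inversion cut sites are
#' restricted to internal junctions so that every inversion breaks exactly
#' two ancestral junctions). Events that are infeasible in the current state
#' (e.g. a fission on a single-block chromosome) are resampled and logged.
#' All internal-node genomes are retained and a complete event log with
#' reference(root)-frame breakpoint coordinates is returned. Identical seeds
#' give identical output.
#'
#' @param tree a validated dated tree (see [dated_tree()]).
#' @param config a [simulation_config()].
#' @return list with `genomes` (named list of `block_genome`, one per node,
#'   root first in preorder), `events` (data.frame: branch, event_id, type,
#'   detail), `breakpoints` (data.frame: branch, event_id, chrom1, pos1,
#'   chrom2, pos2, ancestral), `root_layout`, `branches` and `n_resampled`.
#' @export
simulate_history <- function(tree, config) {
  tree <- dated_tree(tree)
  tree <- stats::reorder(tree, "cladewise")  # edges in preorder
  set.seed(config$seed)
  root <- draw_root_genome(config)
  root_layout <- block_layout(root)
  bt <- branch_table(tree)
  states <- list()
  states[[root_label(tree)]] <- unname(root$chromosomes)
  events <- list(); breakpoints <- list(); n_resampled <- 0L
  eid <- 0L
  for (r in seq_len(nrow(bt))) {
    st <- states[[bt$parent[r]]]
    k <- stats::rpois(1L, config$rate * bt$dt[r])
    if (k > 0L) for (e in seq_len(k)) {
      repeat {
        ev <- draw_event(st, config$mix)
        if (!is.null(ev)) break
        n_resampled <- n_resampled + 1L
      }
      eid <- eid + 1L
      bj <- broken_junctions(st, ev, root_layout)
      if (!is.null(bj)) {
        breakpoints[[length(breakpoints) + 1L]] <-
          cbind(data.frame(branch = bt$branch[r], event_id = eid), bj)
      }
      events[[length(events) + 1L]] <- data.frame(
        branch = bt$branch[r], event_id = eid, type = ev$type,
        detail = switch(ev$type,
          inversion = sprintf("chrom %d blocks %d..%d", ev$chrom, ev$i, ev$j),
          fission = sprintf("chrom %d after block %d", ev$chrom, ev$pos),
          fusion = sprintf("chrom %d (%+d) + chrom %d (%+d)",
                           ev$chrom, ev$orient1, ev$chrom2, ev$orient2)))
      st <- apply_event(st, ev)
    }
    states[[bt$branch[r]]] <- st
  }
  genomes <- lapply(names(states), function(nm) {
    g <- block_genome(states[[nm]], root$block_lengths, name = nm)
    g
  })
  names(genomes) <- names(states)
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), event_id = integer(), type = character(),
               detail = character())
  bp_df <- if (length(breakpoints)) do.call(rbind, breakpoints) else
    data.frame(branch = character(), event_id = integer(),
               block1 = integer(), bext1 = character(),
               block2 = integer(), bext2 = character(),
               chrom1 = character(), pos1 = numeric(), chrom2 = character(),
               pos2 = numeric(), ancestral = logical())
  list(genomes = genomes, events = ev_df, breakpoints = bp_df,
       root_layout = root_layout, branches = bt$branch,
       n_resampled = n_resampled)
}

#' Ground-truth breakpoints of a branch
#'
#' Reference(root)-frame breakpoints created by the events of one branch:
#' an inversion contributes 2, a fission 1 and a fusion 0. Each row carries
#' the reference coordinates of the two block extremities that met at the
#' broken junction.
#'
#' @param history result of [simulate_history()].
#' @param branch child-node label of the branch.
#' @return data.frame of breakpoints (possibly 0 rows).
#' @export
true_breakpoints <- function(history, branch) {
  if (!branch %in% history$branches) stop("unknown branch: ", branch)
  history$breakpoints[history$breakpoints$branch == branch, , drop = FALSE]
}

#' Build per-species orthology maps against a reference node
#'
#' For each genome, one row per block giving its interval on the reference
#' genome, its interval on the target genome, and the relative orientation.
#' This is the simulator's stand-in for pairwise whole-genome alignment.
#'
#' @param genomes named list of `block_genome` over a shared block universe.
#' @param reference name of the reference genome in `genomes`.
#' @return named list of data.frames (one per non-reference genome) with
#'   columns `ref_chrom`, `ref_start`, `ref_end`, `tgt_chrom`, `tgt_start`,
#'   `tgt_end`, `orient`, `block`, sorted by reference position.
#' @export
make_orthology_maps <- function(genomes, reference) {
  if (!reference %in% names(genomes)) stop("reference node absent: ", reference)
  ref <- genomes[[reference]]
  rl <- block_layout(ref)
  rl <- rl[order(rl$block), ]
  out <- lapply(genomes, function(g) {
    tl <- block_layout(g)
    tl <- tl[order(tl$block), ]
    if (!identical(tl$block, rl$block)) {
      stop("genome '", g$name, "' does not share the reference block universe")
    }
    m <- data.frame(ref_chrom = rl$chrom, ref_start = rl$start, ref_end = rl$end,
                    tgt_chrom = tl$chrom, tgt_start = tl$start, tgt_end = tl$end,
                    orient = tl$sign * rl$sign, block = rl$block)
    m[order(m$ref_chrom, m$ref_start), ]
  })
  out  # includes the reference itself (an identity map, all orientations +)
}
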