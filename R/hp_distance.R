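# Hannenhalli-Pevzner theory for sorting signed permutations by reversals.
#
# d(pi) = (n + 1) - c + h + f, with c the number of cycles of the breakpoint
# graph, h the number of hurdles (unoriented components that appear as a
# single run on the circle of positions) and f = 1 for a fortress (an odd
# number of hurdles, all of which are superhurdles). The implementation below
# does the full hurdle/fortress accounting; it is validated against a
# breadth-first-search oracle in the test suite.

# unsigned extension: signed element x -> (2x-1, 2x) if x > 0, (2|x|, 2|x|-1)
# otherwise, framed by 0 and 2n+1
hp_extend <- function(p) {
  n <- length(p)
  ext <- integer(2L * n + 2L)
  idx <- 2L * seq_len(n)
  pos_mask <- p > 0L
  ext[idx[pos_mask]] <- 2L * p[pos_mask] - 1L
  ext[idx[pos_mask] + 1L] <- 2L * p[pos_mask]
  ext[idx[!pos_mask]] <- -2L * p[!pos_mask]
  ext[idx[!pos_mask] + 1L] <- -2L * p[!pos_mask] - 1L
  ext[2L * n + 2L] <- 2L * n + 1L
  ext
}

# breakpoint-graph analysis of a signed permutation.
# Returns cycles, per-gray-edge data and the unoriented-component structure.
hp_graph <- function(p) {
  p <- as.integer(p)
  n <- length(p)
  ext <- hp_extend(p)               # values at positions 0..2n+1 (1-indexed)
  pos <- integer(2L * n + 2L)
  pos[ext + 1L] <- 0:(2L * n + 1L)  # pos[v+1] = 0-based position of value v

  # gray edge i joins values 2i and 2i+1 (i = 0..n)
  gi <- 0:n
  pa <- pos[2L * gi + 1L]
  pb <- pos[2L * gi + 2L]
  gmin <- pmin(pa, pb)
  gmax <- pmax(pa, pb)
  oriented <- (pa %% 2L) == (pb %% 2L)

  # walk cycles: each value has one gray edge (v xor 1) and one black edge
  # (value at the neighbouring position of the same black pair)
  cyc_of_gray <- integer(n + 1L)
  n_cycles <- 0L
  seen <- logical(n + 1L)
  for (i in gi) {
    if (seen[i + 1L]) next
    n_cycles <- n_cycles + 1L
    v <- 2L * i
    repeat {
      g <- v %/% 2L
      if (seen[g + 1L]) break
      seen[g + 1L] <- TRUE
      cyc_of_gray[g + 1L] <- n_cycles
      v <- bitwXor(v, 1L)                       # gray step
      v <- ext[bitwXor(pos[v + 1L], 1L) + 1L]   # black step
    }
  }
  gray_per_cycle <- tabulate(cyc_of_gray, n_cycles)
  trivial <- gray_per_cycle == 1L

  list(n = n, n_cycles = n_cycles, cyc_of_gray = cyc_of_gray,
       gmin = gmin, gmax = gmax, oriented = oriented,
       trivial_cycle = trivial)
}

# connected components of the cycle-interleaving graph (nontrivial cycles
# only); returns for each gray edge the component id or NA
hp_components <- function(gr) {
  keep <- which(!gr$trivial_cycle[gr$cyc_of_gray])   # gray edges of nontrivial cycles
  comp <- rep(NA_integer_, length(gr$cyc_of_gray))
  if (!length(keep)) return(list(comp_of_gray = comp, comp_oriented = logical()))
  # union-find over cycles
  parent <- seq_len(gr$n_cycles)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  m <- length(keep)
  if (m > 1L) {
    a1 <- gr$gmin[keep]; b1 <- gr$gmax[keep]; cy <- gr$cyc_of_gray[keep]
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (cy[i] == cy[j]) next
      # strict interleaving of the two position intervals
      if ((a1[i] < a1[j] & a1[j] < b1[i] & b1[i] < b1[j]) ||
          (a1[j] < a1[i] & a1[i] < b1[j] & b1[j] < b1[i])) union(cy[i], cy[j])
    }
  }
  roots <- vapply(gr$cyc_of_gray[keep], find, 1L)
  ids <- match(roots, unique(roots))
  comp[keep] <- ids
  n_comp <- max(ids)
  comp_oriented <- vapply(seq_len(n_comp),
                          function(k) any(gr$oriented[keep][ids == k]), TRUE)
  list(comp_of_gray = comp, comp_oriented = comp_oriented)
}

# compress a circular sequence of labels into runs
circular_runs <- function(x) {
  if (!length(x)) return(x)
  r <- rle(x)$values
  if (length(r) > 1L && r[1L] == r[length(r)]) r <- r[-length(r)]
  r
}

# hurdle / fortress accounting from the unoriented components
hp_hurdles <- function(gr, comps) {
  unor <- which(!comps$comp_oriented)
  if (!length(unor)) return(list(h = 0L, f = 0L))
  # positions 0..2n+1 in order; label = unoriented component of the gray edge
  # at that position (others transparent)
  lab <- integer(0)
  gray_at_pos <- integer(2L * gr$n + 2L)
  for (g in seq_along(comps$comp_of_gray)) {
    gray_at_pos[gr$gmin[g] + 1L] <- g
    gray_at_pos[gr$gmax[g] + 1L] <- g
  }
  seqlab <- comps$comp_of_gray[gray_at_pos]
  seqlab <- seqlab[!is.na(seqlab) & seqlab %in% unor]
  runs <- circular_runs(seqlab)
  counts <- table(runs)
  hurdles <- as.integer(names(counts)[counts == 1L])
  h <- length(hurdles)
  f <- 0L
  if (h >= 3L && h %% 2L == 1L) {
    is_super <- vapply(hurdles, function(hh) {
      rem <- circular_runs(runs[runs != hh])
      cnt <- table(rem)
      newh <- as.integer(names(cnt)[cnt == 1L])
      length(setdiff(newh, hurdles)) > 0L
    }, TRUE)
    if (all(is_super)) f <- 1L
  }
  list(h = h, f = f)
}

# exact reversal distance of a signed permutation given as an integer vector
# whose magnitudes are 1..n in some order
hp_reversal_distance <- function(p) {
  p <- as.integer(p)
  n <- length(p)
  if (n == 0L) return(0L)
  gr <- hp_graph(p)
  comps <- hp_components(gr)
  hf <- hp_hurdles(gr, comps)
  (n + 1L) - gr$n_cycles + hf$h + hf$f
}

# relabel a signed vector with distinct magnitudes to magnitudes 1..n,
# preserving order-isomorphism and signs
normalize_signed <- function(p) {
  r <- rank(abs(p))
  as.integer(sign(p) * r)
}

#' Exact reversal distance between signed block orders
#'
#' Minimum number of reversals (inversions) transforming one signed block
#' order into the identity, computed with the Hannenhalli-Pevzner formula
#' d = (n + 1) - c + h + f, including the full hurdle and fortress
#' accounting on the breakpoint graph.
#'
#' @param p a single-chromosome [signed_permutation()] or an integer vector
#'   of signed values with distinct magnitudes (relabelled internally to
#'   1..n).
#' @return the exact reversal distance (non-negative integer).
#' @examples
#' reversal_distance(c(-3L, -2L, -1L))  # one whole-segment reversal
#' reversal_distance(c(2L, 1L))         # the classic 3-reversal pair
#' @export
reversal_distance <- function(p) {
  if (inherits(p, "signed_permutation")) {
    if (length(p$chromosomes) != 1L) {
      stop("reversal_distance() needs a single-chromosome permutation; ",
           "use multichromosomal_scenario() for whole genomes")
    }
    p <- p$chromosomes[[1L]]
  }
  if (!length(p)) return(0L)
  if (anyDuplicated(abs(p))) stop("magnitudes must be distinct")
  hp_reversal_distance(normalize_signed(p))
}

# apply reversal of positions i..j (1-based, inclusive) to a signed vector
apply_reversal <- function(p, i, j) {
  p[i:j] <- -rev(p[i:j])
  p
}

# an optimal sorting scenario for a single chromosome: repeatedly take the
# leftmost reversal that decreases the exact distance (one always exists).
# Returns a list of c(i, j) position pairs.
sort_by_reversals <- function(p) {
  p <- normalize_signed(as.integer(p))
  n <- length(p)
  moves <- list()
  d <- hp_reversal_distance(p)
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        q <- apply_reversal(p, i, j)
        if (hp_reversal_distance(q) == d - 1L) {
          moves[[length(moves) + 1L]] <- c(i, j)
          p <- q
          d <- d - 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-decreasing reversal found")
  }
  moves
}
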