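# Signed-permutation rearrangement algebra: distances and typed scenarios
# between karyotypes, per-branch event inference, per-chromosome
# rearrangement fractions and chromosome-level orthology classification.

#' Express one genome as a signed permutation of another
#'
#' Relabels the shared block universe so that genome `b` reads as identity
#' chromosomes (1..n in order, all positive); genome `a` is then expressed in
#' that labelling. This is the canonical input preparation for rearrangement
#' distance computations.
#'
#' @param a,b `block_genome` objects over the same block set.
#' @return an object of class `signed_permutation`: a list with
#'   `chromosomes` (list of signed integer vectors) and `n`.
#' @export
to_signed_permutation <- function(a, b) {
  validate_block_genome(a); validate_block_genome(b)
  ba <- unlist(a$chromosomes, use.names = FALSE)
  bb <- unlist(b$chromosomes, use.names = FALSE)
  if (!setequal(abs(ba), abs(bb))) {
    only_a <- setdiff(abs(ba), abs(bb))
    only_b <- setdiff(abs(bb), abs(ba))
    stop("block sets differ; only in '", a$name, "': {",
         paste(only_a, collapse = ","), "}, only in '", b$name, "': {",
         paste(only_b, collapse = ","), "}")
  }
  relab <- integer(max(abs(bb)))
  bsign <- integer(max(abs(bb)))
  relab[abs(bb)] <- seq_along(bb)
  bsign[abs(bb)] <- sign(bb)
  chroms <- lapply(a$chromosomes, function(x) {
    as.integer(relab[abs(x)] * sign(x) * bsign[abs(x)])
  })
  structure(list(chromosomes = unname(chroms), n = length(bb)),
            class = "signed_permutation")
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat("<signed_permutation> n =", x$n, "\n")
  for (ch in x$chromosomes) cat(" ", paste(ch, collapse = " "), "\n")
  invisible(x)
}

## ---- genome states for scenario search -----------------------------------
## a state is a plain list of signed integer vectors (chromosomes)

canonical_chrom <- function(x) {
  y <- -rev(x)
  kx <- paste(x, collapse = ",")
  ky <- paste(y, collapse = ",")
  if (ky < kx) y else x
}

state_key <- function(state) {
  keys <- vapply(state, function(ch) paste(canonical_chrom(ch), collapse = ","),
                 "")
  paste(sort(keys), collapse = ";")
}

state_adjacencies <- function(state) {
  unlist(lapply(state, function(blocks) {
    if (length(blocks) < 2L) return(character())
    a <- blocks[-length(blocks)]
    b <- blocks[-1L]
    adjacency_id(abs(a), right_extremity(a), abs(b), left_extremity(b))
  }))
}

# apply a typed event to a state; events are lists with fields
# type ("inversion"|"fusion"|"fission"), chrom (index), and
#  inversion: i, j (block positions, inclusive)
#  fission:   pos (split after this block position)
#  fusion:    chrom2, orient1, orient2 (+1 keep, -1 reverse before joining)
apply_event <- function(state, ev) {
  switch(ev$type,
    inversion = {
      ch <- state[[ev$chrom]]
      ch[ev$i:ev$j] <- -rev(ch[ev$i:ev$j])
      state[[ev$chrom]] <- ch
      state
    },
    fission = {
      ch <- state[[ev$chrom]]
      left <- ch[seq_len(ev$pos)]
      right <- ch[(ev$pos + 1L):length(ch)]
      append(state[-ev$chrom], list(left, right), after = ev$chrom - 1L)
    },
    fusion = {
      c1 <- state[[ev$chrom]]
      c2 <- state[[ev$chrom2]]
      if (ev$orient1 < 0) c1 <- -rev(c1)
      if (ev$orient2 < 0) c2 <- -rev(c2)
      keep <- min(ev$chrom, ev$chrom2)
      drop <- max(ev$chrom, ev$chrom2)
      state[[keep]] <- c(c1, c2)
      state[-drop]
    },
    stop("unknown event type: ", ev$type))
}

# deterministic enumeration of all candidate events from a state
enumerate_events <- function(state) {
  evs <- list()
  nc <- length(state)
  for (ci in seq_len(nc)) {
    L <- length(state[[ci]])
    if (L >= 2L) for (pos in seq_len(L - 1L)) {
      evs[[length(evs) + 1L]] <- list(type = "fission", chrom = ci, pos = pos)
    }
  }
  if (nc >= 2L) for (ci in seq_len(nc - 1L)) for (cj in (ci + 1L):nc) {
    for (o1 in c(1L, -1L)) for (o2 in c(1L, -1L)) {
      evs[[length(evs) + 1L]] <- list(type = "fusion", chrom = ci,
                                      chrom2 = cj, orient1 = o1, orient2 = o2)
    }
  }
  for (ci in seq_len(nc)) {
    L <- length(state[[ci]])
    for (i in seq_len(L)) for (j in i:L) {
      if (i == 1L && j == L) next  # whole-chromosome flip is a no-op
      evs[[length(evs) + 1L]] <- list(type = "inversion", chrom = ci, i = i, j = j)
    }
  }
  evs
}

# extremity pairing of a state: extremities are encoded tail(g) = 2g-1,
# head(g) = 2g; pairing[e] = extremity adjacent to e, or 0 at a telomere
extremity_pairing <- function(state, n) {
  pairing <- integer(2L * n)
  for (ch in state) {
    if (length(ch) < 2L) next
    a <- ch[-length(ch)]
    b <- ch[-1L]
    ea <- ifelse(a > 0L, 2L * a, -2L * a - 1L)        # right extremity of a
    eb <- ifelse(b > 0L, 2L * b - 1L, -2L * b)        # left extremity of b
    pairing[ea] <- eb
    pairing[eb] <- ea
  }
  pairing
}

# double-cut-and-join distance between two extremity pairings; every
# inversion, fusion or fission is a single DCJ operation, so this is an
# admissible lower bound for the typed scenario length
dcj_bound <- function(pairA, pairB, n) {
  visited <- logical(2L * n)
  cycles <- 0L; odd_paths <- 0L
  for (e0 in seq_len(2L * n)) {
    if (visited[e0]) next
    # walk the component containing e0
    size <- 0L; is_path <- FALSE
    stack <- e0
    while (length(stack)) {
      e <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (visited[e]) next
      visited[e] <- TRUE
      size <- size + 1L
      na <- pairA[e]; nb <- pairB[e]
      if (na == 0L || nb == 0L) is_path <- TRUE
      if (na > 0L && !visited[na]) stack <- c(stack, na)
      if (nb > 0L && !visited[nb]) stack <- c(stack, nb)
    }
    if (is_path) {
      if (size %% 2L == 1L) odd_paths <- odd_paths + 1L
    } else cycles <- cycles + 1L
  }
  n - cycles - odd_paths %/% 2L
}

# exact minimal scenario via iterative-deepening A* over typed events with
# the DCJ bound (plus the chromosome-count difference) as heuristic
scenario_exact <- function(start, target) {
  n <- length(unlist(target))
  pairB <- extremity_pairing(target, n)
  target_key <- state_key(target)
  n_chrom_target <- length(target)
  h_of <- function(state) {
    max(dcj_bound(extremity_pairing(state, n), pairB, n),
        abs(length(state) - n_chrom_target))
  }
  # DCJ distance 0 together with matching chromosome count means the states
  # carry identical adjacency and telomere sets, i.e. the same genome
  if (h_of(start) == 0L && state_key(start) == target_key) return(list())
  path <- NULL
  dfs <- function(state, g, bound, trail) {
    h <- h_of(state)
    if (g + h > bound) return(FALSE)
    if (h == 0L && length(state) == n_chrom_target) { path <<- trail; return(TRUE) }
    if (g == bound) return(FALSE)
    for (ev in enumerate_events(state)) {
      child <- apply_event(state, ev)
      if (dfs(child, g + 1L, bound, c(trail, list(ev)))) return(TRUE)
    }
    FALSE
  }
  bound <- h_of(start)
  repeat {
    if (dfs(start, 0L, bound, list())) return(path)
    bound <- bound + 1L
  }
}

# deterministic heuristic scenario for larger genomes: fissions at junctions
# joining blocks of different target chromosomes, fusions assembling each
# target chromosome in target order, then optimal per-chromosome reversal
# sorting
scenario_heuristic <- function(start, target) {
  # membership and position of each block in the target
  maxid <- max(abs(unlist(target)))
  t_chrom <- integer(maxid); t_pos <- integer(maxid); t_sign <- integer(maxid)
  for (k in seq_along(target)) {
    ch <- target[[k]]
    t_chrom[abs(ch)] <- k
    t_pos[abs(ch)] <- seq_along(ch)
    t_sign[abs(ch)] <- sign(ch)
  }
  state <- start
  events <- list()
  push <- function(ev) { events[[length(events) + 1L]] <<- ev; state <<- apply_event(state, ev) }
  # phase 1: fission until every chromosome is pure w.r.t. target membership
  repeat {
    done <- TRUE
    for (ci in seq_along(state)) {
      ch <- state[[ci]]
      memb <- t_chrom[abs(ch)]
      cut <- which(memb[-length(memb)] != memb[-1L])
      if (length(cut)) {
        push(list(type = "fission", chrom = ci, pos = cut[1L]))
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  # phase 2: fuse fragments of the same target chromosome, ordered by the
  # smallest target position they contain
  repeat {
    memb <- vapply(state, function(ch) t_chrom[abs(ch[1L])], 1L)
    k <- which(duplicated(memb))
    if (!length(k)) break
    tk <- memb[k[1L]]
    frags <- which(memb == tk)
    minpos <- vapply(state[frags], function(ch) min(t_pos[abs(ch)]), 1L)
    ord <- frags[order(minpos)]
    push(list(type = "fusion", chrom = ord[1L], chrom2 = ord[2L],
              orient1 = 1L, orient2 = 1L))
  }
  # phase 3: sort each chromosome by reversals
  for (ci in seq_along(state)) {
    ch <- state[[ci]]
    tk <- t_chrom[abs(ch[1L])]
    rel <- t_pos[abs(ch)] * sign(ch) * t_sign[abs(ch)]
    for (mv in sort_by_reversals(rel)) {
      push(list(type = "inversion", chrom = ci, i = mv[1L], j = mv[2L]))
    }
  }
  list(events = events, state = state)
}

#' Parsimonious typed rearrangement scenario between two genomes
#'
#' Finds a scenario of inversions, fusions and fissions transforming genome
#' `a` into genome `b`. For genomes up to `exact_limit` blocks the scenario
#' is provably minimal (iterative-deepening search with admissible
#' adjacency-count bounds); larger genomes use a deterministic
#' fission/fusion/reversal-sorting construction. Translocations never occur
#' as primitives: where a minimal solution would use one, it appears as a
#' fission followed by a fusion, and fusions that consume a fission product
#' are flagged in the event list.
#'
#' @param a,b `block_genome` objects over the same block universe.
#' @param exact_limit maximum number of blocks for which the exact search is
#'   used (default 10).
#' @return list with `events` (data.frame: step, type, detail,
#'   translocation_part), `counts` (an event-count row, see
#'   [infer_branch_events()]), and `replay` — a function of a `block_genome`
#'   that applies the scenario (so `replay(a)` reproduces `b` exactly).
#' @export
multichromosomal_scenario <- function(a, b, exact_limit = 10L) {
  p <- to_signed_permutation(a, b)   # validates shared block universe
  start <- p$chromosomes
  target <- lapply(seq_along(b$chromosomes),
                   function(k) seq_len(length(b$chromosomes[[k]])) +
                     if (k > 1L) sum(lengths(b$chromosomes[1:(k - 1L)])) else 0L)
  target <- lapply(target, as.integer)
  if (p$n <= exact_limit) {
    events <- scenario_exact(start, target)
  } else {
    events <- scenario_heuristic(start, target)$events
  }
  # verify and annotate: replay on the permutation, flag fission products
  state <- start
  n0 <- length(state)
  birth <- as.list(seq_len(n0))              # provenance tags per chromosome
  next_tag <- n0
  fission_tags <- integer()
  transloc <- logical(length(events))
  for (k in seq_along(events)) {
    ev <- events[[k]]
    if (ev$type == "fission") {
      tags <- c(next_tag + 1L, next_tag + 2L)
      next_tag <- next_tag + 2L
      fission_tags <- c(fission_tags, tags)
      birth <- append(birth[-ev$chrom], as.list(tags), after = ev$chrom - 1L)
    } else if (ev$type == "fusion") {
      t1 <- birth[[ev$chrom]]; t2 <- birth[[ev$chrom2]]
      if (xor(t1 %in% fission_tags, t2 %in% fission_tags)) transloc[k] <- TRUE
      keep <- min(ev$chrom, ev$chrom2); drop <- max(ev$chrom, ev$chrom2)
      next_tag <- next_tag + 1L
      birth[[keep]] <- next_tag
      birth <- birth[-drop]
    }
    state <- apply_event(state, ev)
  }
  if (state_key(state) != state_key(target)) {
    stop("internal error: scenario replay does not reproduce the target")
  }
  types <- vapply(events, `[[`, "", "type")
  detail <- vapply(events, function(ev) {
    switch(ev$type,
      inversion = sprintf("chrom %d, blocks %d..%d", ev$chrom, ev$i, ev$j),
      fission = sprintf("chrom %d after block %d", ev$chrom, ev$pos),
      fusion = sprintf("chrom %d (%+d) + chrom %d (%+d)", ev$chrom,
                       ev$orient1, ev$chrom2, ev$orient2))
  }, "")
  counts <- data.frame(
    n_inversions = sum(types == "inversion"),
    n_fusions = sum(types == "fusion"),
    n_fissions = sum(types == "fission"),
    n_events = length(types)
  )
  counts$n_breakpoints <- 2L * counts$n_inversions + counts$n_fissions
  replay <- function(g) {
    pg <- to_signed_permutation(g, b)
    st <- pg$chromosomes
    for (ev in events) st <- apply_event(st, ev)
    st
  }
  list(events = data.frame(step = seq_along(types), type = types,
                           detail = detail, translocation_part = transloc),
       event_list = events, counts = counts, replay = replay,
       target_state = target)
}

#' Infer typed rearrangement events along an ancestral lineage
#'
#' Runs [multichromosomal_scenario()] between each consecutive pair of a
#' root-to-tip ordered series of karyotypes and returns one event-count row
#' per branch.
#'
#' @param lineage named list of `block_genome` objects ordered root to tip;
#'   consecutive genomes must share their block universe.
#' @param exact_limit passed to [multichromosomal_scenario()].
#' @return data.frame with columns `branch` (child node label),
#'   `n_inversions`, `n_fusions`, `n_fissions`, `n_events`, `n_breakpoints`.
#' @export
infer_branch_events <- function(lineage, exact_limit = 10L) {
  if (length(lineage) < 2L) stop("need at least two genomes (root and one descendant)")
  labs <- names(lineage)
  if (is.null(labs)) labs <- vapply(lineage, function(g) g$name, "")
  out <- vector("list", length(lineage) - 1L)
  for (k in 2:length(lineage)) {
    sc <- multichromosomal_scenario(lineage[[k - 1L]], lineage[[k]],
                                    exact_limit = exact_limit)
    out[[k - 1L]] <- cbind(data.frame(branch = labs[k]), sc$counts)
  }
  do.call(rbind, out)
}

#' Fraction of an ancestral chromosome affected by rearrangements
#'
#' For one chromosome of an ancestral karyotype, measures how much of it was
#' moved to other chromosomes (interchromosomal fraction) and how much of the
#' remainder was internally reshuffled (intrachromosomal fraction) in a
#' descendant or outgroup genome. The interchromosomal fraction is 1 minus
#' the share of the chromosome's mapped length found on the single descendant
#' chromosome that carries the largest share; the intrachromosomal fraction
#' is computed on that majority chromosome as 1 minus the share of its length
#' lying in the longest signed-colinear subsequence.
#'
#' @param ancestor a `block_genome`; `chrom` names one of its chromosomes.
#' @param chrom chromosome label in `ancestor`.
#' @param other a `block_genome` containing (a subset of) the same blocks.
#' @return named numeric vector `c(inter, intra)`.
#' @export
fraction_rearranged <- function(ancestor, chrom, other) {
  validate_block_genome(ancestor); validate_block_genome(other)
  mam <- ancestor$chromosomes[[chrom]]
  if (is.null(mam)) stop("no chromosome '", chrom, "' in ", ancestor$name)
  ids <- abs(mam)
  # locate blocks in `other`
  loc <- do.call(rbind, lapply(names(other$chromosomes), function(cn) {
    ch <- other$chromosomes[[cn]]
    hit <- abs(ch) %in% ids
    if (!any(hit)) return(NULL)
    data.frame(block = abs(ch)[hit], chrom = cn, pos = which(hit),
               sign = sign(ch)[hit])
  }))
  if (is.null(loc) || !nrow(loc)) stop("no blocks of '", chrom, "' mapped in ", other$name)
  loc$len <- other$block_lengths[as.character(loc$block)]
  total <- sum(loc$len)
  share <- tapply(loc$len, loc$chrom, sum)
  major <- names(share)[which.max(share)]
  inter <- 1 - max(share) / total
  # intra: majority chromosome, blocks in positional order
  mj <- loc[loc$chrom == major, ]
  mj <- mj[order(mj$pos), ]
  anc_idx <- match(mj$block, ids)            # order within the ancestor chromosome
  rel_sign <- mj$sign * sign(mam)[anc_idx]
  w <- mj$len
  best <- max(colinear_weight(anc_idx, rel_sign, w),
              colinear_weight(-anc_idx, -rel_sign, w))
  intra <- 1 - best / sum(w)
  c(inter = unname(inter), intra = unname(intra))
}

# maximum-weight strictly-increasing subsequence restricted to elements with
# positive relative sign (O(k^2), k small)
colinear_weight <- function(idx, rel_sign, w) {
  keep <- rel_sign > 0
  idx <- idx[keep]; w <- w[keep]
  k <- length(idx)
  if (!k) return(0)
  best <- numeric(k)
  for (i in seq_len(k)) {
    prev <- which(idx[seq_len(i - 1L)] < idx[i])
    best[i] <- w[i] + if (length(prev)) max(best[prev]) else 0
  }
  max(best)
}

#' Classify chromosome-level orthology between two karyotypes
#'
#' Given a table of orthologous segments between the chromosomes of karyotype
#' A and karyotype B with fractional coverages, labels each A chromosome as
#' `"1:1"` (it maps to a single B chromosome, covering both essentially
#' completely), `"1:n complete"` (it maps to n > 1 B chromosomes, each of
#' which maps entirely back to it), or `"partial"` otherwise.
#'
#' @param map data.frame with columns `chrom_a`, `chrom_b`, `frac_a`
#'   (fraction of the A chromosome covered by the segment) and `frac_b`
#'   (fraction of the B chromosome covered).
#' @param tol completeness tolerance: a coverage fraction >= `tol` counts as
#'   complete (default 0.95).
#' @return data.frame with columns `chrom_a`, `class`, `n_partners`,
#'   `partners`.
#' @export
classify_orthology <- function(map, tol = 0.95) {
  need <- c("chrom_a", "chrom_b", "frac_a", "frac_b")
  if (!all(need %in% names(map))) {
    stop("map needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(map)) stop("empty orthology map")
  out <- lapply(split(map, map$chrom_a), function(rows) {
    a_complete <- sum(rows$frac_a) >= tol
    back_complete <- rows$frac_b >= tol
    cls <- if (nrow(rows) == 1L && a_complete && back_complete[1L]) {
      "1:1"
    } else if (nrow(rows) > 1L && a_complete && all(back_complete)) {
      "1:n complete"
    } else {
      "partial"
    }
    data.frame(chrom_a = rows$chrom_a[1L], class = cls,
               n_partners = nrow(rows),
               partners = paste(rows$chrom_b, collapse = ","))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
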