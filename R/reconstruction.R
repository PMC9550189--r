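# Ancestral-karyotype reconstruction: detect syntenic fragments (SFs) at a
# resolution threshold, score SF adjacencies at a target ancestral node by
# phylogeny-weighted presence, chain accepted adjacencies into reconstructed
# ancestral chromosome fragments (RACFs), order RACFs into chromosomes by
# descendant majority vote, and compare reconstructions.

#' Detect syntenic fragments across a genome set
#'
#' The reference axis is cut at every junction where any genome interrupts
#' colinearity (change of target chromosome, order or orientation); maximal
#' uncut runs of at least `resolution` bp become syntenic fragments, with one
#' placement per genome. Runs below the resolution are discarded and their
#' reference spans reported as unplaced.
#'
#' @param maps named list of per-species orthology tables (see
#'   [make_orthology_maps()] / [read_orthology_table()]); all tables must
#'   share the reference segmentation.
#' @param resolution minimum SF length in bp (default 300 kbp, the standard
#'   SF resolution for mammal-scale reconstructions).
#' @return an object of class `sf_set`: list with `table` (sf, chrom, start,
#'   end, length on the reference), `blocks` (reference blocks per SF),
#'   `placements` (per-genome intervals and orientation), `unplaced` and
#'   `resolution`.
#' @export
detect_sfs <- function(maps, resolution = 300e3) {
  if (resolution <= 0) stop("resolution must be > 0")
  if (!length(maps)) stop("no orthology maps supplied")
  maps <- lapply(maps, function(m) {
    m <- m[order(m$ref_chrom, m$ref_start), , drop = FALSE]
    if (any(m$ref_start[-1L] < m$ref_end[-nrow(m)] &
            m$ref_chrom[-1L] == m$ref_chrom[-nrow(m)])) {
      stop("overlapping reference rows in an orthology table")
    }
    rownames(m) <- NULL
    m
  })
  ref <- maps[[1L]][, c("ref_chrom", "ref_start", "ref_end")]
  for (m in maps) {
    if (!identical(m[, c("ref_chrom", "ref_start", "ref_end")], ref)) {
      stop("orthology tables do not share the reference segmentation")
    }
  }
  n <- nrow(ref)
  # per genome: global target rank and per-junction colinearity
  cut_after <- logical(n)  # cut between row i and i+1
  new_chrom <- c(ref$ref_chrom[-1L] != ref$ref_chrom[-n], TRUE)
  cut_after <- cut_after | new_chrom
  for (m in maps) {
    rk <- order(order(m$tgt_chrom, m$tgt_start))
    o <- m$orient
    same <- m$tgt_chrom[-n] == m$tgt_chrom[-1L] &
      o[-n] == o[-1L] &
      rk[-1L] == rk[-n] + o[-n]
    cut_after <- cut_after | c(!same, TRUE)
  }
  seg <- cumsum(c(TRUE, cut_after[-n]))
  seg_len <- tapply(ref$ref_end - ref$ref_start, seg, sum)
  keep <- as.integer(names(seg_len)[seg_len >= resolution])
  sf_of_seg <- integer(max(seg)); sf_of_seg[keep] <- seq_along(keep)
  rows_of <- split(seq_len(n), seg)
  table_rows <- lapply(keep, function(s) {
    rows <- rows_of[[as.character(s)]]
    data.frame(sf = sf_of_seg[s], chrom = ref$ref_chrom[rows[1L]],
               start = ref$ref_start[rows[1L]],
               end = ref$ref_end[rows[length(rows)]])
  })
  tab <- do.call(rbind, table_rows)
  tab$length <- tab$end - tab$start
  blocks <- lapply(keep, function(s) {
    rows <- rows_of[[as.character(s)]]
    if ("block" %in% names(maps[[1L]])) maps[[1L]]$block[rows] else rows
  })
  unplaced <- do.call(rbind, lapply(setdiff(seq_len(max(seg)), keep), function(s) {
    rows <- rows_of[[as.character(s)]]
    data.frame(chrom = ref$ref_chrom[rows[1L]], start = ref$ref_start[rows[1L]],
               end = ref$ref_end[rows[length(rows)]])
  }))
  if (is.null(unplaced)) {
    unplaced <- data.frame(chrom = character(), start = numeric(), end = numeric())
  } else unplaced$length <- unplaced$end - unplaced$start
  placements <- do.call(rbind, lapply(names(maps), function(g) {
    m <- maps[[g]]
    do.call(rbind, lapply(keep, function(s) {
      rows <- rows_of[[as.character(s)]]
      data.frame(sf = sf_of_seg[s], genome = g, chrom = m$tgt_chrom[rows[1L]],
                 start = min(m$tgt_start[rows]), end = max(m$tgt_end[rows]),
                 orient = m$orient[rows[1L]])
    }))
  }))
  structure(list(table = tab, blocks = blocks, placements = placements,
                 unplaced = unplaced, resolution = resolution),
            class = "sf_set")
}

#' @export
print.sf_set <- function(x, ...) {
  cat("<sf_set> ", nrow(x$table), " syntenic fragments at ",
      format(x$resolution, big.mark = ","), " bp resolution; ",
      nrow(x$unplaced), " unplaced span(s), ",
      format(sum(x$unplaced$length), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Per-genome chains of signed SF ids
#'
#' Orders each genome's SF placements along its own chromosomes, giving the
#' genome's karyotype in SF space (one signed vector per target chromosome).
#'
#' @param sfs an `sf_set`.
#' @return named list (per genome) of lists of signed integer SF vectors.
#' @export
genome_sf_chains <- function(sfs) {
  pl <- sfs$placements
  out <- lapply(split(pl, pl$genome), function(p) {
    p <- p[order(p$chrom, p$start), ]
    unname(lapply(split(seq_len(nrow(p)), p$chrom),
                  function(i) as.integer(p$sf[i] * p$orient[i])))
  })
  out[unique(pl$genome)]
}

#' Adjacency table of a list of signed chains
#'
#' One row per junction between consecutive signed elements, in canonical
#' unordered form.
#'
#' @param chains list of signed integer vectors.
#' @return data.frame with `id1`, `ext1`, `id2`, `ext2`, `adj`.
#' @export
chain_adjacency_table <- function(chains) {
  out <- lapply(chains, function(blocks) {
    if (length(blocks) < 2L) return(NULL)
    a <- blocks[-length(blocks)]
    b <- blocks[-1L]
    data.frame(id1 = abs(a), ext1 = right_extremity(a),
               id2 = abs(b), ext2 = left_extremity(b))
  })
  tab <- do.call(rbind, out)
  if (is.null(tab)) {
    return(data.frame(id1 = integer(), ext1 = character(), id2 = integer(),
                      ext2 = character(), adj = character()))
  }
  # canonical column order so the same unordered adjacency always yields the
  # same row regardless of traversal direction
  swap <- (tab$id2 < tab$id1) | (tab$id2 == tab$id1 & tab$ext2 < tab$ext1)
  if (any(swap)) {
    tmp <- tab[swap, ]
    tab[swap, c("id1", "ext1", "id2", "ext2")] <-
      tmp[, c("id2", "ext2", "id1", "ext1")]
  }
  tab$adj <- adjacency_id(tab$id1, tab$ext1, tab$id2, tab$ext2)
  tab
}

#' Score SF adjacencies at a target ancestral node
#'
#' Every SF adjacency observed in at least one genome is scored by
#' phylogeny-weighted presence: each genome carrying the adjacency
#' contributes weight 1/(patristic distance in My from its tip to the target
#' node), normalised by the total weight of all genomes. An adjacency has
#' two-sided support (`sided`) iff it is carried by at least one descendant
#' of the target node and either an outgroup genome or descendants of both
#' children of the target node.
#'
#' @param sfs an `sf_set` whose placements cover tips of `tree`.
#' @param tree dated tree; tip labels must match the placement genomes.
#' @param target label of an internal node of `tree`.
#' @return data.frame with columns `adj`, `id1`, `ext1`, `id2`, `ext2`,
#'   `score`, `sided`, `support` (comma-separated genome list), sorted for
#'   deterministic downstream assembly (score desc, sided first, adjacency
#'   id).
#' @export
score_adjacencies <- function(sfs, tree, target) {
  tree <- dated_tree(tree)
  if (target %in% tree$tip.label) stop("target must be an internal node")
  node_number(tree, target)  # errors on unknown label
  chains <- genome_sf_chains(sfs)
  genomes <- names(chains)
  missing_tips <- setdiff(genomes, tree$tip.label)
  if (length(missing_tips)) {
    stop("genomes not on the tree: ", paste(missing_tips, collapse = ", "))
  }
  dmat <- ape::dist.nodes(tree)
  w <- vapply(genomes, function(g) 1 / patristic_distance(tree, g, target, dmat), 1)
  wtot <- sum(w)
  desc <- descendant_tips(tree, target)
  kids <- child_labels(tree, target)
  side1 <- descendant_tips(tree, kids[1L])
  side2 <- descendant_tips(tree, kids[2L])
  per_g <- lapply(chains, chain_adjacency_table)
  all_adj <- unique(do.call(rbind, lapply(per_g, function(x)
    x[, c("adj", "id1", "ext1", "id2", "ext2")])))
  if (!nrow(all_adj)) {
    return(data.frame(adj = character(), id1 = integer(), ext1 = character(),
                      id2 = integer(), ext2 = character(), score = numeric(),
                      sided = logical(), support = character(),
                      target = character()))
  }
  support <- lapply(all_adj$adj, function(a) {
    genomes[vapply(per_g, function(x) a %in% x$adj, TRUE)]
  })
  score <- vapply(support, function(s) sum(w[s]) / wtot, 1)
  sided <- vapply(support, function(s) {
    in_desc <- intersect(s, desc)
    length(in_desc) > 0 &&
      (length(setdiff(s, desc)) > 0 ||
         (length(intersect(s, side1)) > 0 && length(intersect(s, side2)) > 0))
  }, TRUE)
  out <- cbind(all_adj,
               data.frame(score = score, sided = sided,
                          support = vapply(support, paste, "", collapse = ",")))
  out <- out[order(-out$score, !out$sided, out$adj), ]
  rownames(out) <- NULL
  out$target <- target
  out
}

# default adjacency acceptance rule: at least half of the phylogeny-weighted
# evidence, and support on both sides of the target node. The threshold is
# inclusive: on balanced trees common weight structures place well-supported
# two-sided adjacencies exactly at 0.5, and the sidedness requirement already
# guards against one-sided ties.
default_acceptance <- function(score, sided) score >= 0.5 & sided

# assemble vertex-disjoint chains from an adjacency table over `ids`
build_chains <- function(ids, adj_tab) {
  link <- new.env(hash = TRUE)
  for (r in seq_len(nrow(adj_tab))) {
    assign(paste0(adj_tab$id1[r], adj_tab$ext1[r]),
           c(adj_tab$id2[r], adj_tab$ext2[r]), envir = link)
    assign(paste0(adj_tab$id2[r], adj_tab$ext2[r]),
           c(adj_tab$id1[r], adj_tab$ext1[r]), envir = link)
  }
  used <- logical(max(ids))
  chains <- list()
  for (s in sort(ids)) {
    if (used[s]) next
    # walk left from s, then right, starting in + orientation
    chain <- s; used[s] <- TRUE
    # extend to the right: exit through head of last element
    repeat {
      last <- chain[length(chain)]
      ex <- paste0(abs(last), right_extremity(last))
      nxt <- link[[ex]]
      if (is.null(nxt)) break
      nid <- as.integer(nxt[1L])
      if (used[nid]) break  # would close a cycle
      sgn <- if (nxt[2L] == "t") 1L else -1L
      chain <- c(chain, sgn * nid); used[nid] <- TRUE
    }
    # extend to the left: enter through tail of first element
    repeat {
      first <- chain[1L]
      ex <- paste0(abs(first), left_extremity(first))
      prv <- link[[ex]]
      if (is.null(prv)) break
      pid <- as.integer(prv[1L])
      if (used[pid]) break
      sgn <- if (prv[2L] == "h") 1L else -1L
      chain <- c(sgn * pid, chain); used[pid] <- TRUE
    }
    chains[[length(chains) + 1L]] <- canonical_chrom(chain)
  }
  chains[order(vapply(chains, function(x) abs(x[1L]), 1L))]
}

#' Assemble RACFs from scored adjacencies
#'
#' Greedy path growing: adjacencies are visited in order (score descending,
#' two-sided support first, then lexicographic adjacency id) and accepted iff
#' both extremities are still free, acceptance would not close a circular
#' chromosome, and the acceptance rule passes (default: score > 0.5 with
#' two-sided support). Accepted adjacencies form vertex-disjoint paths — the
#' reconstructed ancestral chromosome fragments. Every SF ends up in exactly
#' one RACF (singletons allowed). The procedure is fully deterministic.
#'
#' @param scores output of [score_adjacencies()].
#' @param sfs the `sf_set` the scores were computed from.
#' @param rule function(score, sided) -> logical acceptance.
#' @return a `block_genome` whose "blocks" are SF ids (one chromosome per
#'   RACF), with attributes `accepted` (adjacency ids) and `target`.
#' @export
assemble_racfs <- function(scores, sfs, rule = default_acceptance) {
  ids <- sfs$table$sf
  free <- new.env(hash = TRUE)
  parent <- seq_len(max(ids))  # union-find to refuse circular chromosomes
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  accepted <- logical(nrow(scores))
  for (r in seq_len(nrow(scores))) {
    if (!rule(scores$score[r], scores$sided[r])) next
    e1 <- paste0(scores$id1[r], scores$ext1[r])
    e2 <- paste0(scores$id2[r], scores$ext2[r])
    if (!is.null(free[[e1]]) || !is.null(free[[e2]])) next
    r1 <- find(scores$id1[r]); r2 <- find(scores$id2[r])
    if (r1 == r2) next  # would close a cycle
    parent[r1] <- r2
    free[[e1]] <- TRUE; free[[e2]] <- TRUE
    accepted[r] <- TRUE
  }
  chains <- build_chains(ids, scores[accepted, , drop = FALSE])
  lens <- stats::setNames(sfs$table$length, as.character(sfs$table$sf))
  g <- block_genome(chains, lens,
                    name = if (!is.null(scores$target)) scores$target[1L] else "ancestor")
  names(g$chromosomes) <- sprintf("racf%03d", seq_along(g$chromosomes))
  attr(g, "accepted") <- scores$adj[accepted]
  attr(g, "target") <- if (!is.null(scores$target)) scores$target[1L] else NA_character_
  g
}

#' Order RACFs into ancestral chromosomes by descendant majority
#'
#' Two RACFs are concatenated when a configured majority of informative
#' descendant genomes place their terminal SFs adjacent, in a consistent
#' orientation. Tied conflicting joins are refused (tie means no join). All
#' decisions are returned in a log.
#'
#' @param racfs RACF genome from [assemble_racfs()].
#' @param sfs the underlying `sf_set`.
#' @param tree dated tree.
#' @param genomes genome names to use as evidence; defaults to the
#'   descendants of the reconstruction target among placed genomes.
#' @param majority minimum fraction of informative genomes supporting a join
#'   (default 2/3).
#' @return list with `genome` (a `block_genome` of ordered chromosomes) and
#'   `log` (data.frame of candidate joins and decisions).
#' @export
order_racfs <- function(racfs, sfs, tree, genomes = NULL, majority = 2 / 3) {
  chains_all <- genome_sf_chains(sfs)
  if (is.null(genomes)) {
    tgt <- attr(racfs, "target")
    genomes <- if (!is.na(tgt) && !is.null(tgt)) {
      intersect(descendant_tips(dated_tree(tree), tgt), names(chains_all))
    } else names(chains_all)
  }
  chains <- chains_all[genomes]
  racf_adj <- chain_adjacency_table(racfs$chromosomes)
  used_ext <- c(paste0(racf_adj$id1, racf_adj$ext1), paste0(racf_adj$id2, racf_adj$ext2))
  racf_of <- integer(max(sfs$table$sf))
  for (k in seq_along(racfs$chromosomes)) racf_of[abs(racfs$chromosomes[[k]])] <- k
  # candidate joins: genome adjacencies between free terminal extremities of
  # different RACFs
  votes <- list()
  for (g in names(chains)) {
    tab <- chain_adjacency_table(chains[[g]])
    for (r in seq_len(nrow(tab))) {
      if (racf_of[tab$id1[r]] == racf_of[tab$id2[r]]) next
      e1 <- paste0(tab$id1[r], tab$ext1[r]); e2 <- paste0(tab$id2[r], tab$ext2[r])
      if (e1 %in% used_ext || e2 %in% used_ext) next
      key <- tab$adj[r]
      votes[[key]] <- c(votes[[key]], g)
    }
  }
  if (!length(votes)) {
    return(list(genome = racfs,
                log = data.frame(adj = character(), votes = integer(),
                                 frac = numeric(), decision = character())))
  }
  n_inf <- length(chains)
  cand <- data.frame(adj = names(votes),
                     votes = vapply(votes, length, 1L),
                     frac = vapply(votes, length, 1L) / n_inf)
  cand <- cand[order(-cand$votes, cand$adj), ]
  # parse extremities back out of the adjacency ids
  parse_ext <- function(a) {
    parts <- strsplit(a, "|", fixed = TRUE)[[1L]]
    t(vapply(parts, function(p) {
      nc <- nchar(p)
      c(substr(p, 1L, nc - 1L), substr(p, nc, nc))
    }, c("", "")))
  }
  taken <- character(0)
  parent <- seq_along(racfs$chromosomes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  decision <- character(nrow(cand))
  accepted_rows <- list()
  for (r in seq_len(nrow(cand))) {
    pe <- parse_ext(cand$adj[r])
    e1 <- paste0(pe[1L, 1L], pe[1L, 2L]); e2 <- paste0(pe[2L, 1L], pe[2L, 2L])
    if (cand$frac[r] < majority) { decision[r] <- "below majority"; next }
    # tie with a conflicting candidate of equal votes (itself above majority)?
    conflict <- cand$votes == cand$votes[r] & cand$frac >= majority &
      cand$adj != cand$adj[r] &
      vapply(cand$adj, function(a) {
        q <- parse_ext(a)
        any(c(paste0(q[1L, 1L], q[1L, 2L]), paste0(q[2L, 1L], q[2L, 2L])) %in% c(e1, e2))
      }, TRUE)
    if (any(conflict)) { decision[r] <- "tied conflict"; next }
    if (e1 %in% taken || e2 %in% taken) { decision[r] <- "extremity taken"; next }
    r1 <- find(racf_of[as.integer(pe[1L, 1L])])
    r2 <- find(racf_of[as.integer(pe[2L, 1L])])
    if (r1 == r2) { decision[r] <- "would close cycle"; next }
    parent[r1] <- r2
    taken <- c(taken, e1, e2)
    decision[r] <- "joined"
    accepted_rows[[length(accepted_rows) + 1L]] <-
      data.frame(id1 = as.integer(pe[1L, 1L]), ext1 = pe[1L, 2L],
                 id2 = as.integer(pe[2L, 1L]), ext2 = pe[2L, 2L])
  }
  cand$decision <- decision
  full_adj <- rbind(racf_adj[, c("id1", "ext1", "id2", "ext2")],
                    do.call(rbind, accepted_rows))
  chains_new <- build_chains(sfs$table$sf, full_adj)
  lens <- stats::setNames(sfs$table$length, as.character(sfs$table$sf))
  g <- block_genome(chains_new, lens, name = racfs$name)
  names(g$chromosomes) <- sprintf("anc_chr%02d", seq_along(g$chromosomes))
  attr(g, "target") <- attr(racfs, "target")
  list(genome = g, log = cand)
}

#' Compare two reconstructions on a shared SF universe
#'
#' Each SF adjacency of reconstruction A is classified as `maintained` (also
#' present in B), `extra` (absent from B with both flanking extremities free,
#' i.e. terminal or unjoined in B) or `inconsistent` (contradicted by a
#' different adjacency in B). The inconsistent length fraction is the
#' cumulative reference length of SFs flanking inconsistent adjacencies
#' divided by the total reconstruction length.
#'
#' @param recon_a,recon_b RACF genomes (from [assemble_racfs()] or
#'   [order_racfs()]) over the same SF universe.
#' @param sfs the shared `sf_set`.
#' @return list with `classes` (data.frame: adj, class) and
#'   `inconsistent_fraction`.
#' @export
compare_reconstructions <- function(recon_a, recon_b, sfs) {
  ua <- sort(abs(unlist(recon_a$chromosomes, use.names = FALSE)))
  ub <- sort(abs(unlist(recon_b$chromosomes, use.names = FALSE)))
  if (!identical(ua, ub)) stop("reconstructions use different SF universes")
  ta <- chain_adjacency_table(recon_a$chromosomes)
  tb <- chain_adjacency_table(recon_b$chromosomes)
  used_b <- c(paste0(tb$id1, tb$ext1), paste0(tb$id2, tb$ext2))
  cls <- vapply(seq_len(nrow(ta)), function(r) {
    if (ta$adj[r] %in% tb$adj) return("maintained")
    e1 <- paste0(ta$id1[r], ta$ext1[r]); e2 <- paste0(ta$id2[r], ta$ext2[r])
    if (!(e1 %in% used_b) && !(e2 %in% used_b)) "extra" else "inconsistent"
  }, "")
  lens <- stats::setNames(sfs$table$length, as.character(sfs$table$sf))
  bad <- unique(c(ta$id1[cls == "inconsistent"], ta$id2[cls == "inconsistent"]))
  frac <- sum(lens[as.character(bad)]) / sum(lens[as.character(ua)])
  list(classes = data.frame(adj = ta$adj, class = cls),
       inconsistent_fraction = unname(frac))
}

#' Express a block genome as chains of signed SF ids
#'
#' Converts a (typically true ancestral) block genome into SF space for
#' comparison with reconstructions: blocks belonging to no SF
#' (sub-resolution spans) are transparent, and a chain break is emitted
#' wherever an SF's blocks are not traversed contiguously and colinearly.
#' SF orientation is defined on the reference frame, so block signs are
#' compared against the reference genome's.
#'
#' @param genome a `block_genome` sharing the block universe.
#' @param sfs the `sf_set`.
#' @param reference the reference `block_genome` of the SF detection.
#' @return list of signed integer SF vectors.
#' @export
as_sf_genome <- function(genome, sfs, reference) {
  maxb <- max(unlist(sfs$blocks))
  sf_of_block <- integer(maxb)
  pos_in_sf <- integer(maxb)
  for (k in seq_along(sfs$blocks)) {
    b <- sfs$blocks[[k]]
    sf_of_block[b] <- sfs$table$sf[k]
    pos_in_sf[b] <- seq_along(b)
  }
  rl <- block_layout(reference)
  ref_sign <- integer(max(rl$block))
  ref_sign[rl$block] <- rl$sign
  sf_len <- lengths(sfs$blocks)
  chains <- list()
  for (ch in genome$chromosomes) {
    rel <- sign(ch) * ref_sign[abs(ch)]   # orientation relative to reference
    chain <- integer(0)
    i <- 1L
    while (i <= length(ch)) {
      b <- abs(ch[i])
      s <- if (b <= maxb) sf_of_block[b] else 0L
      if (s == 0L) { i <- i + 1L; next }  # unplaced block: transparent
      k <- match(s, sfs$table$sf)
      L <- sf_len[k]
      dir <- rel[i]
      ok <- pos_in_sf[b] == (if (dir > 0L) 1L else L)
      j <- i
      if (ok && L > 1L) {
        while (j - i + 1L < L) {
          jj <- j + 1L
          if (jj > length(ch)) { ok <- FALSE; break }
          nb <- abs(ch[jj])
          if (nb > maxb || sf_of_block[nb] != s || rel[jj] != dir ||
              pos_in_sf[nb] != pos_in_sf[abs(ch[j])] + dir) { ok <- FALSE; break }
          j <- jj
        }
      }
      if (ok) {
        chain <- c(chain, dir * s)
        i <- j + 1L
      } else {
        # broken SF occurrence: break the chain and skip this block
        if (length(chain)) { chains[[length(chains) + 1L]] <- chain; chain <- integer(0) }
        i <- i + 1L
      }
    }
    if (length(chain)) chains[[length(chains) + 1L]] <- chain
  }
  chains
}
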