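# Independent oracles, implemented from first principles (no calls into the
# package's distance/scenario machinery).

# all-pairs reversal distances from the identity by breadth-first search
# over the reversal graph of signed permutations of size n
bfs_all_reversal_distances <- function(n) {
  key <- function(p) paste(p, collapse = ",")
  dist <- new.env(hash = TRUE)
  id <- seq_len(n)
  assign(key(id), 0L, envir = dist)
  frontier <- list(id)
  d <- 0L
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (i in seq_len(n)) for (j in i:n) {
        q <- p
        q[i:j] <- -rev(q[i:j])
        k <- key(q)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d + 1L
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    d <- d + 1L
    frontier <- nxt
  }
  dist
}

# exact reversal distance by iterative-deepening search pruned with the
# breakpoint-graph cycle lower bound only (a provable lower bound that does
# not involve any hurdle/fortress accounting)
oracle_cycle_bound <- function(p) {
  n <- length(p)
  ext <- integer(2L * n + 2L)
  for (k in seq_len(n)) {
    x <- p[k]
    if (x > 0L) ext[c(2L * k, 2L * k + 1L)] <- c(2L * x - 1L, 2L * x)
    else ext[c(2L * k, 2L * k + 1L)] <- c(-2L * x, -2L * x - 1L)
  }
  ext[1L] <- 0L
  ext[2L * n + 2L] <- 2L * n + 1L
  pos <- integer(2L * n + 2L)
  pos[ext + 1L] <- 0:(2L * n + 1L)
  seen <- logical(n + 1L)
  cycles <- 0L
  for (i in 0:n) {
    if (seen[i + 1L]) next
    cycles <- cycles + 1L
    v <- 2L * i
    repeat {
      g <- v %/% 2L
      if (seen[g + 1L]) break
      seen[g + 1L] <- TRUE
      v <- bitwXor(v, 1L)
      v <- ext[bitwXor(pos[v + 1L], 1L) + 1L]
    }
  }
  (n + 1L) - cycles
}

oracle_reversal_distance <- function(p) {
  p <- as.integer(sign(p) * rank(abs(p)))
  n <- length(p)
  dfs <- function(p, g, bound) {
    lb <- oracle_cycle_bound(p)
    if (g + lb > bound) return(FALSE)
    if (lb == 0L && all(p == seq_len(n))) return(TRUE)
    if (g == bound) return(FALSE)
    for (i in seq_len(n)) for (j in i:n) {
      q <- p
      q[i:j] <- -rev(q[i:j])
      if (dfs(q, g + 1L, bound)) return(TRUE)
    }
    FALSE
  }
  bound <- oracle_cycle_bound(p)
  repeat {
    if (dfs(p, 0L, bound)) return(bound)
    bound <- bound + 1L
  }
}

# breadth-first search distance between two genomes (lists of signed
# chromosome vectors) under inversions, fusions and fissions; genomes are
# compared up to chromosome order and whole-chromosome flips
oracle_genome_key <- function(state) {
  canon <- vapply(state, function(ch) {
    a <- paste(ch, collapse = ",")
    b <- paste(-rev(ch), collapse = ",")
    if (b < a) b else a
  }, "")
  paste(sort(canon), collapse = ";")
}

oracle_genome_moves <- function(state) {
  out <- list()
  nc <- length(state)
  for (ci in seq_len(nc)) {
    ch <- state[[ci]]
    L <- length(ch)
    for (i in seq_len(L)) for (j in i:L) {
      if (i == 1L && j == L) next
      q <- ch
      q[i:j] <- -rev(q[i:j])
      s <- state
      s[[ci]] <- q
      out[[length(out) + 1L]] <- s
    }
    if (L >= 2L) for (pos in seq_len(L - 1L)) {
      s <- c(state[-ci], list(ch[seq_len(pos)], ch[(pos + 1L):L]))
      out[[length(out) + 1L]] <- s
    }
  }
  if (nc >= 2L) for (ci in seq_len(nc - 1L)) for (cj in (ci + 1L):nc) {
    for (o1 in c(1L, -1L)) for (o2 in c(1L, -1L)) {
      c1 <- if (o1 > 0) state[[ci]] else -rev(state[[ci]])
      c2 <- if (o2 > 0) state[[cj]] else -rev(state[[cj]])
      s <- c(state[-c(ci, cj)], list(c(c1, c2)))
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

oracle_genome_distance <- function(a, b, cap = 12L) {
  sk <- oracle_genome_key(a)
  tk <- oracle_genome_key(b)
  if (sk == tk) return(0L)
  seen <- new.env(hash = TRUE)
  assign(sk, TRUE, envir = seen)
  frontier <- list(a)
  d <- 0L
  repeat {
    d <- d + 1L
    if (d > cap) stop("oracle BFS cap exceeded")
    nxt <- list()
    for (st in frontier) for (ch in oracle_genome_moves(st)) {
      k <- oracle_genome_key(ch)
      if (k == tk) return(d)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        nxt[[length(nxt) + 1L]] <- ch
      }
    }
    frontier <- nxt
  }
}

# per-bp brute force: bases of `track` inside [start, end) on one chromosome
oracle_overlap_bases <- function(start, end, track_chrom, track, chrom) {
  if (end - start > 1e6) stop("oracle is per-bp; keep toys small")
  covered <- logical(end - start)
  tr <- track[track_chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(tr))) {
    s <- max(start, tr$start[r])
    e <- min(end, tr$end[r])
    if (e > s) covered[(s - start + 1L):(e - start)] <- TRUE
  }
  sum(covered)
}

# rank-sum statistic (sum of ranks of x within c(x, y)), brute force
oracle_rank_sum_W <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}
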