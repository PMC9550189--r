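# Evolutionary breakpoint regions (EBRs) within RACFs, breakpoint-reuse
# classification across lineages, multispecies homologous synteny blocks
# (msHSBs) and the exponential maximum-size test.

#' Detect EBRs along a lineage of reconstructions
#'
#' Walks a root-to-tip series of SF arrangements (reconstructed RACF sets
#' and/or genomes expressed in SF space) relative to the first element — the
#' baseline ancestor. Every baseline SF junction that is intact in a parent
#' but broken in its child, and stays broken in all nodes below (a transient
#' absence at a single intermediate reconstruction is treated as
#' reconstruction noise, not a break), yields one EBR assigned to the first
#' branch on which the break appears. The EBR is located on the reference
#' genome at the gap delimited by the two SF extremities that met at the
#' broken junction; when those extremities map to distant reference loci the
#' EBR is flagged `diffuse` and both point coordinates are retained.
#' Junctions between RACFs joined at the chromosome-ordering stage are not
#' considered (EBRs are called within RACFs only: pass RACF chains, not
#' ordered chromosomes).
#'
#' @param lineage named list, ordered root to tip, of SF chain lists (each a
#'   list of signed SF-id vectors, e.g. `$chromosomes` of an
#'   [assemble_racfs()] result or the output of the SF conversion of a true
#'   genome); names are node labels, the first being the baseline ancestor.
#' @param sfs the shared `sf_set` (for reference coordinates).
#' @param max_gap EBR intervals wider than this are flagged diffuse
#'   (default 10x the SF resolution).
#' @return data.frame with columns `branch`, `adj`, `chrom`, `start`, `end`,
#'   `length`, `diffuse`, `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
detect_ebrs <- function(lineage, sfs, max_gap = 10 * sfs$resolution) {
  if (length(lineage) < 2L) stop("lineage needs a baseline and at least one descendant")
  labs <- names(lineage)
  if (is.null(labs) || any(labs == "")) stop("lineage must be named root to tip")
  tabs <- lapply(lineage, chain_adjacency_table)
  base <- tabs[[1L]]
  K <- length(lineage)
  coord <- function(id, ext) {
    row <- sfs$table[match(id, sfs$table$sf), ]
    list(chrom = row$chrom, pos = if (ext == "h") row$end else row$start)
  }
  # reference gap flanking an SF extremity: the SF-free span between the SF
  # and its reference neighbour on that side (1-bp placeholder when they
  # abut)
  side_gap <- function(id, ext) {
    row <- sfs$table[match(id, sfs$table$sf), ]
    tc <- sfs$table[sfs$table$chrom == row$chrom, ]
    if (ext == "h") {
      nxt <- tc$start[tc$start >= row$end]
      s <- row$end
      e <- if (length(nxt)) min(nxt) else row$end
    } else {
      prv <- tc$end[tc$end <= row$start]
      e <- row$start
      s <- if (length(prv)) max(prv) else row$start
    }
    ph <- e <= s
    if (ph) { s <- if (ext == "h") row$end else max(0, row$start - 1); e <- s + 1 }
    list(chrom = row$chrom, start = s, end = e, placeholder = ph)
  }
  ebrs <- list()
  for (r in seq_len(nrow(base))) {
    present <- vapply(tabs, function(tb) base$adj[r] %in% tb$adj, TRUE)
    # first branch after which the junction is gone for good
    broken_at <- NA_integer_
    for (k in 2:K) {
      if (!any(present[k:K])) { broken_at <- k; break }
    }
    if (is.na(broken_at)) next
    c1 <- coord(base$id1[r], base$ext1[r])
    c2 <- coord(base$id2[r], base$ext2[r])
    g <- side_gap(base$id1[r], base$ext1[r])
    # the junction persisted to the reference iff the partner extremity sits
    # at the far edge of the same gap; otherwise the break is diffuse (its
    # two extremities ended up at distant reference loci)
    diffuse <- !(c2$chrom == g$chrom && c2$pos >= g$start - 1 &&
                   c2$pos <= g$end + 1) || (g$end - g$start) > max_gap
    ebrs[[length(ebrs) + 1L]] <- data.frame(
      branch = labs[broken_at], adj = base$adj[r],
      chrom = g$chrom, start = g$start, end = g$end,
      length = g$end - g$start, diffuse = diffuse, placeholder = g$placeholder,
      chrom1 = c1$chrom, pos1 = c1$pos, chrom2 = c2$chrom, pos2 = c2$pos)
  }
  if (!length(ebrs)) {
    return(data.frame(branch = character(), adj = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      length = numeric(), diffuse = logical(),
                      placeholder = logical(),
                      chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric()))
  }
  out <- do.call(rbind, ebrs)
  rownames(out) <- NULL
  out
}

#' Flag centromere-associated EBRs
#'
#' An EBR overlapping the centromere track (by at least 1 bp) is flagged;
#' such EBRs are conventionally retained in tables but masked from
#' enrichment analyses.
#'
#' @param ebrs EBR data.frame from [detect_ebrs()].
#' @param centromeres data.frame with `chrom`, `start`, `end`.
#' @return `ebrs` with a logical `centromeric` column.
#' @export
flag_centromeric_ebrs <- function(ebrs, centromeres) {
  ebrs$centromeric <- vapply(seq_len(nrow(ebrs)), function(r) {
    any(centromeres$chrom == ebrs$chrom[r] &
          centromeres$start < ebrs$end[r] & ebrs$start[r] < centromeres$end)
  }, TRUE)
  ebrs
}

#' Classify breakpoint reuse across lineages
#'
#' An EBR shorter than `max_len` is classified as reused iff its reference
#' interval overlaps an EBR (also shorter than `max_len`) detected on an
#' independent lineage — a branch that shares no root-to-tip path with its
#' own (neither branch is ancestral to the other). The size gate avoids
#' erroneous reuse calls caused by EBR chaining; EBRs at or above the gate
#' are never classified as reuse.
#'
#' @param ebrs data.frame of EBRs pooled across lineages (must carry
#'   `branch` plus the coordinate columns of [detect_ebrs()]).
#' @param tree dated tree on which branches are identified by child label.
#' @param max_len size gate in bp (default 300 kbp).
#' @return `ebrs` with logical `reuse` and character `reuse_branches`
#'   columns.
#' @export
classify_reuse <- function(ebrs, tree, max_len = 300e3) {
  tree <- dated_tree(tree)
  n <- nrow(ebrs)
  reuse <- logical(n)
  partners <- character(n)
  small <- ebrs$length < max_len
  for (i in seq_len(n)) {
    if (!small[i]) next
    hits <- which(small & ebrs$chrom == ebrs$chrom[i] &
                    ebrs$start < ebrs$end[i] & ebrs$start[i] < ebrs$end)
    hits <- hits[hits != i]
    indep <- hits[vapply(hits, function(j)
      independent_branches(tree, ebrs$branch[i], ebrs$branch[j]), TRUE)]
    if (length(indep)) {
      reuse[i] <- TRUE
      partners[i] <- paste(sort(unique(ebrs$branch[indep])), collapse = ",")
    }
  }
  ebrs$reuse <- reuse
  ebrs$reuse_branches <- partners
  ebrs
}

#' Detect multispecies homologous synteny blocks
#'
#' msHSBs are the maximal reference intervals covered colinearly in every
#' genome of the analysis set: the intersection of the per-species covered
#' interval sets (typically the reference spans of pairwise syntenic
#' fragments), filtered to a minimum length.
#'
#' @param coverages named list (one entry per species) of data.frames with
#'   `chrom`, `start`, `end` giving the reference intervals that species
#'   covers colinearly.
#' @param min_len minimum msHSB length in bp (default 300 kbp, shared with
#'   the SF resolution).
#' @param maps optional named list of orthology tables used to compute
#'   per-species placement lengths.
#' @return data.frame with `chrom`, `start`, `end`, `length`, plus one
#'   `len_<species>` column per species when `maps` is given.
#' @export
detect_mshsbs <- function(coverages, min_len = 300e3, maps = NULL) {
  if (!length(coverages)) stop("no coverages supplied")
  empty <- names(coverages)[vapply(coverages, nrow, 1L) == 0L]
  if (length(empty)) stop("species with empty coverage: ", paste(empty, collapse = ", "))
  as_grl <- function(df) {
    split(IRanges::IRanges(start = df$start + 1L, end = df$end), df$chrom)
  }
  cur <- lapply(as_grl(coverages[[1L]]), IRanges::reduce)
  for (k in seq_along(coverages)[-1L]) {
    nxt <- lapply(as_grl(coverages[[k]]), IRanges::reduce)
    chroms <- intersect(names(cur), names(nxt))
    cur <- lapply(stats::setNames(chroms, chroms), function(cn)
      IRanges::intersect(cur[[cn]], nxt[[cn]]))
  }
  out <- do.call(rbind, lapply(names(cur), function(cn) {
    ir <- cur[[cn]]
    if (!length(ir)) return(NULL)
    data.frame(chrom = cn, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  }))
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  out$length <- out$end - out$start
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(maps) && nrow(out)) {
    for (sp in names(maps)) {
      m <- maps[[sp]]
      out[[paste0("len_", sp)]] <- vapply(seq_len(nrow(out)), function(r) {
        ov <- pmax(0, pmin(m$ref_end, out$end[r]) - pmax(m$ref_start, out$start[r]))
        ov[m$ref_chrom != out$chrom[r]] <- 0
        sum(ov)
      }, 1)
    }
  }
  out
}

#' Match called EBRs against ground-truth breakpoints
#'
#' For simulation benchmarking: a breakpoint of the EBR's assigned branch is
#' mapped into the frame of the genome the EBRs are reported on (via the
#' recorded broken block extremities), and the EBR matches when either
#' mapped coordinate falls inside its reference interval (within `tol` bp).
#' Diffuse EBRs are matched on their two point coordinates.
#'
#' @param ebrs EBR data.frame from [detect_ebrs()].
#' @param history result of [simulate_history()].
#' @param reference the `block_genome` whose frame the EBR coordinates use
#'   (the reference genome of the SF detection).
#' @param tol boundary tolerance in bp (default 1).
#' @return logical vector, one element per EBR row.
#' @export
ebr_truth_overlap <- function(ebrs, history, reference, tol = 1) {
  rl <- block_layout(reference)
  rl <- rl[order(rl$block), ]
  pt <- function(block, ext) {
    row <- rl[match(block, rl$block), ]
    at_end <- (ext == "h") == (row$sign > 0)
    list(chrom = row$chrom, pos = ifelse(at_end, row$end, row$start))
  }
  vapply(seq_len(nrow(ebrs)), function(r) {
    bp <- history$breakpoints[history$breakpoints$branch == ebrs$branch[r], ]
    if (!nrow(bp)) return(FALSE)
    p1 <- pt(bp$block1, bp$bext1)
    p2 <- pt(bp$block2, bp$bext2)
    pts <- data.frame(chrom = c(p1$chrom, p2$chrom), pos = c(p1$pos, p2$pos))
    any(pts$chrom == ebrs$chrom[r] &
          pts$pos >= ebrs$start[r] - tol & pts$pos <= ebrs$end[r] + tol) ||
      any((pts$chrom == ebrs$chrom1[r] & abs(pts$pos - ebrs$pos1[r]) <= tol) |
            (pts$chrom == ebrs$chrom2[r] & abs(pts$pos - ebrs$pos2[r]) <= tol))
  }, TRUE)
}

#' Exponential maximum-size test for msHSB lengths
#'
#' Under an exponential length model with mean `mu` (estimated as the sample
#' mean), the expected maximum of `n` draws is `mu * H_n` (the harmonic
#' number), and the probability of observing a maximum at least as large as
#' `x` is `1 - (1 - exp(-x/mu))^n`.
#'
#' @param lengths positive numeric vector of block lengths (bp).
#' @return list with `n`, `mu`, `expected_max`, `observed_max`, `p_value`.
#' @export
max_mshsb_test <- function(lengths) {
  if (!length(lengths)) stop("need at least one length")
  if (any(lengths <= 0)) stop("lengths must be positive")
  n <- length(lengths)
  mu <- mean(lengths)
  hn <- sum(1 / seq_len(n))
  xmax <- max(lengths)
  list(n = n, mu = mu, expected_max = mu * hn, observed_max = xmax,
       p_value = 1 - (1 - exp(-xmax / mu))^n)
}
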