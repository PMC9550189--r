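# Window-based enrichment statistics: fixed-width genome windows classified
# by region (msHSB / EBR subclasses / other), per-window feature tallies,
# and the comparison tests (pairwise Wilcoxon, Pearson chi-square with odds
# ratios, leave-one-out density tests).

ir_of <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

#' Tile chromosomes into fixed-width windows
#'
#' The last, partial window of each chromosome is kept but flagged. Windows
#' with more than 50% of their length in assembly gaps, or overlapping a
#' centromere by at least 1 bp, are flagged as removed (`kept = FALSE`) and
#' excluded from all statistics.
#'
#' @param chrom_lengths named numeric vector (bp).
#' @param width window width (bp), e.g. 1e4 or 1e5.
#' @param gaps,centromeres optional data.frames with `chrom`, `start`,
#'   `end`.
#' @return data.frame with `chrom`, `start`, `end`, `partial`, `gap_bases`,
#'   `centromere_bases`, `kept`.
#' @export
make_windows <- function(chrom_lengths, width, gaps = NULL, centromeres = NULL) {
  if (width <= 0) stop("width must be > 0")
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    s <- seq(0, L - 1, by = width)
    e <- pmin(s + width, L)
    data.frame(chrom = cn, start = s, end = e, partial = (e - s) < width)
  })
  w <- do.call(rbind, out)
  w$gap_bases <- overlap_bases(w, gaps)
  w$centromere_bases <- overlap_bases(w, centromeres)
  w$kept <- !(w$gap_bases > 0.5 * (w$end - w$start)) & w$centromere_bases == 0
  w
}

# total bases of `track` overlapping each window (0-based half-open both)
overlap_bases <- function(windows, track) {
  res <- numeric(nrow(windows))
  if (is.null(track) || !nrow(track)) return(res)
  for (cn in unique(windows$chrom)) {
    wi <- which(windows$chrom == cn)
    ti <- track[track$chrom == cn, , drop = FALSE]
    if (!nrow(ti)) next
    hits <- IRanges::findOverlaps(ir_of(windows[wi, ]), IRanges::reduce(ir_of(ti)))
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      ir_of(windows[wi, ])[S4Vectors::queryHits(hits)],
      IRanges::reduce(ir_of(ti))[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    res[wi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  res
}

# number of track intervals overlapping each window by >= 1 bp
overlap_counts <- function(windows, track) {
  res <- integer(nrow(windows))
  if (is.null(track) || !nrow(track)) return(res)
  for (cn in unique(windows$chrom)) {
    wi <- which(windows$chrom == cn)
    ti <- track[track$chrom == cn, , drop = FALSE]
    if (!nrow(ti)) next
    cnt <- IRanges::countOverlaps(ir_of(windows[wi, ]), ir_of(ti))
    res[wi] <- cnt
  }
  res
}

#' Region class of point positions
#'
#' Assigns features (by a representative point, conventionally the start
#' coordinate) to the region containing the point. Used to group complete
#' genes by region class.
#'
#' @param chrom,pos vectors of chromosome labels and 0-based positions.
#' @param regions named list of interval data.frames (`chrom`, `start`,
#'   `end`); later entries take precedence.
#' @return character vector of region names, `"other"` when no region
#'   contains the point.
#' @export
point_class <- function(chrom, pos, regions) {
  cls <- rep("other", length(chrom))
  for (nm in names(regions)) {
    reg <- regions[[nm]]
    if (!nrow(reg)) next
    for (cn in unique(reg$chrom)) {
      ri <- reg[reg$chrom == cn, , drop = FALSE]
      sel <- which(chrom == cn)
      if (!length(sel)) next
      hit <- vapply(pos[sel], function(p) any(ri$start <= p & p < ri$end), TRUE)
      cls[sel[hit]] <- nm
    }
  }
  cls
}

#' Classify windows by genomic region
#'
#' A window is assigned to a region class only when it is fully contained in
#' one region interval; windows straddling a boundary stay `other`. EBR
#' windows additionally carry reuse/nonreuse and tip-specific/ancient
#' subclass labels taken from the EBR table.
#'
#' @param windows output of [make_windows()].
#' @param mshsbs data.frame `chrom`, `start`, `end`.
#' @param ebrs data.frame `chrom`, `start`, `end` plus optional logical
#'   `reuse` and `tip_specific` columns.
#' @return `windows` with columns `class` (`"msHSB"`, `"EBR"`, `"other"`),
#'   `ebr_reuse`, `ebr_tip` (logical, NA outside EBRs).
#' @export
classify_windows <- function(windows, mshsbs, ebrs) {
  # region sets must be disjoint
  both <- rbind(mshsbs[, c("chrom", "start", "end")],
                ebrs[, c("chrom", "start", "end")])
  for (cn in unique(both$chrom)) {
    ir <- ir_of(both[both$chrom == cn, , drop = FALSE])
    if (length(ir) > 1L && any(IRanges::countOverlaps(ir, ir) > 1L)) {
      stop("overlapping region sets on ", cn)
    }
  }
  windows$class <- "other"
  windows$ebr_reuse <- NA
  windows$ebr_tip <- NA
  assign_within <- function(windows, reg, label) {
    for (cn in unique(reg$chrom)) {
      wi <- which(windows$chrom == cn)
      ri <- reg[reg$chrom == cn, , drop = FALSE]
      if (!length(wi) || !nrow(ri)) next
      hits <- IRanges::findOverlaps(ir_of(windows[wi, ]), ir_of(ri),
                                    type = "within")
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      windows$class[wi[qh]] <- label
      if (label == "EBR") {
        if (!is.null(ri$reuse)) windows$ebr_reuse[wi[qh]] <- ri$reuse[sh]
        if (!is.null(ri$tip_specific)) windows$ebr_tip[wi[qh]] <- ri$tip_specific[sh]
      }
    }
    windows
  }
  windows <- assign_within(windows, mshsbs, "msHSB")
  windows <- assign_within(windows, ebrs, "EBR")
  windows
}

#' Tally annotation features per window
#'
#' Gene counts use the gene-start rule (a gene is counted once, in the
#' window containing its start) while gene bases are split across windows;
#' repeat subclasses and TADs contribute overlapped bases; TAD presence
#' means >= 1 bp of a TAD body; the compartment label is `A`, `B`, `A/B`
#' (both compartments intersect the window) or `none`.
#'
#' @param windows (classified) window table.
#' @param bundle an `annotation_bundle` or a named list of tracks.
#' @return `windows` with tally columns (`n_genes`, `gene_bases`,
#'   `<subclass>_bases`, `n_tads`, `tad_bases`, `tad_present`,
#'   `compartment`).
#' @export
tally_features <- function(windows, bundle) {
  tracks <- if (inherits(bundle, "annotation_bundle")) bundle$tracks else bundle
  genes <- tracks$genes
  windows$n_genes <- 0L
  if (!is.null(genes) && nrow(genes)) {
    starts <- data.frame(chrom = genes$chrom, start = genes$start,
                         end = genes$start + 1)
    windows$n_genes <- overlap_counts(windows, starts)
    windows$gene_bases <- overlap_bases(windows, genes)
  } else windows$gene_bases <- 0
  rep_names <- setdiff(names(tracks),
                       c("genes", "TAD", "compartments", "gaps", "centromeres"))
  for (tk in rep_names) {
    windows[[paste0(tk, "_bases")]] <- overlap_bases(windows, tracks[[tk]])
  }
  windows$n_tads <- overlap_counts(windows, tracks$TAD)
  windows$tad_bases <- overlap_bases(windows, tracks$TAD)
  windows$tad_present <- windows$n_tads >= 1L
  comp <- tracks$compartments
  windows$compartment <- "none"
  if (!is.null(comp) && nrow(comp)) {
    a_b <- overlap_counts(windows, comp[comp$label == "A", , drop = FALSE]) > 0L
    b_b <- overlap_counts(windows, comp[comp$label == "B", , drop = FALSE]) > 0L
    windows$compartment <- ifelse(a_b & b_b, "A/B",
                                  ifelse(a_b, "A", ifelse(b_b, "B", "none")))
  }
  windows
}

#' Pairwise Wilcoxon comparisons with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of groups, with
#' Bonferroni correction over the number of pairs and group medians
#' reported. Pairs involving a group with fewer than 2 observations are
#' skipped and flagged.
#'
#' @param values numeric vector (e.g. complete gene lengths, window gene
#'   counts or repeat bases).
#' @param groups group label per value.
#' @return data.frame with `group1`, `group2`, `W`, `p`, `p_bonf`,
#'   `median1`, `median2`, `n1`, `n2`, `skipped`.
#' @export
pairwise_wilcoxon <- function(values, groups) {
  gs <- sort(unique(groups))
  pairs <- utils::combn(gs, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(group1 = pr[1L], group2 = pr[2L], W = NA_real_,
                        p = NA_real_, p_bonf = NA_real_,
                        median1 = stats::median(x), median2 = stats::median(y),
                        n1 = length(x), n2 = length(y), skipped = TRUE))
    }
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    data.frame(group1 = pr[1L], group2 = pr[2L], W = unname(wt$statistic),
               p = wt$p.value, p_bonf = NA_real_,
               median1 = stats::median(x), median2 = stats::median(y),
               n1 = length(x), n2 = length(y), skipped = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_bonf <- pmin(1, res$p * sum(!res$skipped))
  res
}

#' Compare complete gene lengths between region classes
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on complete gene lengths
#' grouped by region class, Bonferroni-corrected over the pairs, with group
#' medians.
#'
#' @param genes data.frame with `start`, `end` (or `length`) and `class`.
#' @return see [pairwise_wilcoxon()].
#' @export
compare_gene_lengths <- function(genes) {
  len <- if (!is.null(genes$length)) genes$length else genes$end - genes$start
  pairwise_wilcoxon(len, genes$class)
}

#' Association between a binary feature and region classes
#'
#' For each pair of classes, a 2x2 contingency table of class x feature
#' presence is tested with a Pearson chi-square test of independence
#' (no continuity correction) and summarised by the odds ratio
#' (a*d)/(b*c), with the Haldane-Anscombe 0.5 correction (flagged) when a
#' cell is empty. P-values are Bonferroni-corrected over the pairs.
#'
#' @param feature logical vector per window (e.g. TAD absence).
#' @param groups class label per window.
#' @return data.frame with `group1`, `group2`, `chisq`, `p`, `p_bonf`,
#'   `odds_ratio`, `haldane`, `n1`, `n2`, `skipped`.
#' @export
association_test <- function(feature, groups) {
  gs <- sort(unique(groups))
  pairs <- utils::combn(gs, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    f1 <- feature[groups == pr[1L]]
    f2 <- feature[groups == pr[2L]]
    if (!length(f1) || !length(f2)) {
      return(data.frame(group1 = pr[1L], group2 = pr[2L], chisq = NA_real_,
                        p = NA_real_, p_bonf = NA_real_, odds_ratio = NA_real_,
                        haldane = NA, n1 = length(f1), n2 = length(f2),
                        skipped = TRUE))
    }
    a <- sum(f1); b <- sum(!f1); c_ <- sum(f2); d <- sum(!f2)
    hald <- any(c(a, b, c_, d) == 0)
    if (hald) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c_)
    tab <- rbind(c(sum(f1), sum(!f1)), c(sum(f2), sum(!f2)))
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(group1 = pr[1L], group2 = pr[2L], chisq = unname(ch$statistic),
               p = ch$p.value, p_bonf = NA_real_, odds_ratio = or,
               haldane = hald, n1 = length(f1), n2 = length(f2),
               skipped = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_bonf <- pmin(1, res$p * sum(!res$skipped))
  res
}

#' Repeat-subclass density comparisons with the reporting rule
#'
#' Runs [pairwise_wilcoxon()] on per-window repeat bases for each subclass,
#' but only reports subclasses whose mean base count per window reaches
#' `min_mean` (default 100 bp per 10-kbp window) in at least one region
#' class; the others are suppressed.
#'
#' @param windows tallied, classified window table (kept windows only are
#'   used).
#' @param subclasses character vector of track names (default: every
#'   `*_bases` tally except genes/TAD).
#' @param min_mean reporting threshold (bp per window).
#' @return list with `comparisons` (named list of comparison tables) and
#'   `suppressed` (character vector).
#' @export
repeat_density_report <- function(windows, subclasses = NULL, min_mean = 100) {
  w <- windows[windows$kept, , drop = FALSE]
  if (is.null(subclasses)) {
    subclasses <- sub("_bases$", "",
                      grep("_bases$", names(w), value = TRUE))
    subclasses <- setdiff(subclasses, c("gene", "tad"))
  }
  comparisons <- list(); suppressed <- character(0)
  for (tk in subclasses) {
    col <- paste0(tk, "_bases")
    means <- tapply(w[[col]], w$class, mean)
    if (all(means < min_mean, na.rm = TRUE)) {
      suppressed <- c(suppressed, tk)
      next
    }
    comparisons[[tk]] <- pairwise_wilcoxon(w[[col]], w$class)
  }
  list(comparisons = comparisons, suppressed = suppressed)
}
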