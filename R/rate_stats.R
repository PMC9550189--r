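# Per-branch breakpoint and rearrangement rates, with significance testing
# against the lineage average and FDR correction.

# leave-one-out t-test: each observation against the mean and sd of the
# remaining ones, df = m - 2. The standard error term sd * sqrt(1 + 1/(m-1))
# accounts for the tested observation's own sampling variance (the
# single-outlier t), so the test is calibrated under a constant-rate null.
loo_t_test <- function(x) {
  m <- length(x)
  if (m < 3L) stop("need at least 3 observations")
  t_stat <- rep(NA_real_, m)
  p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    rest <- x[-i]
    s <- stats::sd(rest)
    if (is.na(s) || s == 0) next  # p undefined under zero variance
    t_stat[i] <- (x[i] - mean(rest)) / (s * sqrt(1 + 1 / (m - 1L)))
    p[i] <- 2 * stats::pt(-abs(t_stat[i]), df = m - 2L)
  }
  data.frame(t = t_stat, p = p)
}

#' Per-branch breakpoint and rearrangement rates
#'
#' Rates are the per-branch counts divided by the branch length in My.
#'
#' @param events data.frame with columns `branch`, `n_breakpoints` and
#'   (optionally) `n_events` or `n_rearrangements`.
#' @param tree dated tree supplying branch lengths, or `NULL` if `events`
#'   already has a `dt` column.
#' @return data.frame with `branch`, counts, `dt`, `bp_rate`, `re_rate`.
#' @export
compute_rates <- function(events, tree = NULL) {
  if (is.null(events$dt)) {
    if (is.null(tree)) stop("need a tree or a dt column")
    bt <- branch_table(dated_tree(tree))
    events$dt <- bt$dt[match(events$branch, bt$branch)]
  }
  if (anyNA(events$dt) || any(events$dt <= 0)) {
    stop("every branch needs a positive length (My)")
  }
  n_re <- if (!is.null(events$n_rearrangements)) events$n_rearrangements
          else if (!is.null(events$n_events)) events$n_events
          else NA_real_
  data.frame(branch = events$branch,
             n_breakpoints = events$n_breakpoints,
             n_rearrangements = n_re,
             dt = events$dt,
             bp_rate = events$n_breakpoints / events$dt,
             re_rate = n_re / events$dt)
}

#' Test branch rates against the lineage average
#'
#' Each branch's rate is compared with the mean and standard deviation of
#' the remaining branches' rates (leave-one-out one-sample t, df = m - 2,
#' two-sided); p-values are Benjamini-Hochberg corrected across branches and
#' flagged at FDR q < `alpha`. Branches whose leave-one-out complement has
#' zero variance get an undefined (NA) p.
#'
#' @param rates output of [compute_rates()].
#' @param rate_col which rate to test (default `"bp_rate"`).
#' @param alpha significance level on the FDR-corrected scale (default 0.05).
#' @return `rates` with columns `t`, `p`, `q`, `significant`.
#' @export
test_rates <- function(rates, rate_col = "bp_rate", alpha = 0.05) {
  tt <- loo_t_test(rates[[rate_col]])
  rates$t <- tt$t
  rates$p <- tt$p
  rates$q <- stats::p.adjust(tt$p, method = "BH")
  rates$significant <- !is.na(rates$q) & rates$q < alpha
  rates
}

#' Gene density per ancestral chromosome, with significance
#'
#' Density (complete genes per Mbp) per chromosome of an ancestral
#' karyotype, each tested against the average of the remaining chromosomes
#' with the same leave-one-out t procedure used for branch rates, with BH
#' FDR correction.
#'
#' @param gene_counts named integer vector: complete genes per chromosome.
#' @param lengths named numeric vector: chromosome lengths in bp (same
#'   names).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with `chrom`, `n_genes`, `length_mbp`, `density`
#'   (genes/Mbp), `t`, `p`, `q`, `significant`.
#' @export
gene_density_per_mam <- function(gene_counts, lengths, alpha = 0.05) {
  if (length(gene_counts) < 3L) stop("need at least 3 chromosomes")
  if (any(lengths <= 0)) stop("chromosome with zero length")
  chroms <- names(gene_counts)
  if (!identical(sort(chroms), sort(names(lengths)))) {
    stop("gene_counts and lengths must be named consistently")
  }
  lengths <- lengths[chroms]
  dens <- gene_counts / (lengths / 1e6)
  tt <- loo_t_test(as.numeric(dens))
  q <- stats::p.adjust(tt$p, method = "BH")
  data.frame(chrom = chroms, n_genes = as.integer(gene_counts),
             length_mbp = lengths / 1e6, density = as.numeric(dens),
             t = tt$t, p = tt$p, q = q,
             significant = !is.na(q) & q < alpha)
}
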