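# Shared fixtures: tiny genomes, a 6-tip dated tree, random genome draws.

mk_genome <- function(chroms, len = 100, name = "g") {
  ids <- abs(unlist(chroms))
  lens <- if (length(len) == 1L) stats::setNames(rep(len, length(ids)), ids)
          else stats::setNames(len[as.character(ids)], ids)
  block_genome(chroms, lens, name = name)
}

toy_tree6 <- function() {
  dated_tree(ape::read.tree(
    text = "(((A:1,B:1)ab:1,(C:1,D:1)cd:1)in:1,(E:2,F:2)ef:1)root;"))
}

# random multichromosomal genome over blocks 1..n
rand_genome <- function(n, maxc = 3, name = "g") {
  ids <- sample(n)
  signs <- sample(c(-1L, 1L), n, replace = TRUE)
  nc <- sample(seq_len(min(maxc, n)), 1L)
  cuts <- if (nc > 1L) sort(sample(seq_len(n - 1L), nc - 1L)) else integer(0)
  parts <- split(ids * signs, cut(seq_len(n), c(0, cuts, n)))
  mk_genome(unname(lapply(parts, as.integer)), name = name)
}

# orthology map of a genome against itself (identity reference map)
identity_map <- function(g) {
  l <- block_layout(g)
  l <- l[order(l$block), ]
  m <- data.frame(ref_chrom = l$chrom, ref_start = l$start, ref_end = l$end,
                  tgt_chrom = l$chrom, tgt_start = l$start, tgt_end = l$end,
                  orient = 1L, block = l$block)
  m[order(m$ref_chrom, m$ref_start), ]
}
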