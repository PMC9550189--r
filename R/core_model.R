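#' Construct a block genome
#'
#' A `block_genome` is a karyotype represented as ordered, signed synteny
#' blocks: each chromosome is an ordered vector of signed integer block ids,
#' and every block has a length in bp. The sign encodes block orientation
#' (a block with sign -1 is read right-to-left, i.e. it presents its head
#' extremity first). This is the universal currency of the pipeline: extant
#' species, simulated ancestors and reconstructed ancestors are all
#' `block_genome` objects (reconstructions use syntenic-fragment ids as
#' blocks).
#'
#' @param chromosomes list of integer vectors of signed block ids; names, if
#'   any, are display labels only (chromosome order carries no meaning).
#' @param block_lengths numeric vector of block lengths in bp, named by
#'   (unsigned) block id.
#' @param name genome label (species or ancestral-node name).
#' @return an object of class `block_genome`.
#' @examples
#' g <- block_genome(list(c(1L, 2L, -3L), 4L), c(`1` = 100, `2` = 50, `3` = 80, `4` = 30))
#' adjacencies_of(g)
#' @export
block_genome <- function(chromosomes, block_lengths, name = "genome") {
  if (!is.list(chromosomes)) chromosomes <- list(chromosomes)
  chromosomes <- lapply(chromosomes, function(x) as.integer(x))
  if (is.null(names(chromosomes))) {
    names(chromosomes) <- paste0("chr", seq_along(chromosomes))
  }
  g <- structure(list(
    name = name,
    chromosomes = chromosomes,
    block_lengths = block_lengths
  ), class = "block_genome")
  validate_block_genome(g)
  g
}

#' Validate a block genome
#'
#' Checks the structural invariants: every block id appears at most once
#' across the whole genome, every block length is positive, and every
#' chromosome is non-empty.
#'
#' @param g a `block_genome`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_block_genome <- function(g) {
  stopifnot(inherits(g, "block_genome"))
  if (length(g$chromosomes) == 0L) stop("genome has no chromosomes")
  if (any(vapply(g$chromosomes, length, 1L) == 0L)) {
    stop("empty chromosome in genome '", g$name, "'")
  }
  ids <- abs(unlist(g$chromosomes, use.names = FALSE))
  if (any(ids == 0L)) stop("block id 0 is not allowed")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate block id(s) in genome '", g$name, "': ",
         paste(unique(dup), collapse = ", "))
  }
  len <- g$block_lengths[as.character(ids)]
  if (anyNA(len)) {
    stop("missing block length(s) for block(s): ",
         paste(ids[is.na(len)], collapse = ", "))
  }
  if (any(len <= 0)) stop("block lengths must be > 0")
  invisible(g)
}

#' @export
print.block_genome <- function(x, ...) {
  cat("<block_genome> ", x$name, ": ", length(x$chromosomes), " chromosome(s), ",
      n_blocks(x), " blocks, ", format(genome_length(x), big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Number of blocks in a genome
#' @param g a `block_genome`.
#' @return integer count of blocks.
#' @export
n_blocks <- function(g) length(unlist(g$chromosomes, use.names = FALSE))

#' Total genome length
#' @param g a `block_genome`.
#' @return sum of the lengths of all blocks present, in bp.
#' @export
genome_length <- function(g) {
  ids <- abs(unlist(g$chromosomes, use.names = FALSE))
  sum(g$block_lengths[as.character(ids)])
}

#' Lay out a genome on its own coordinate axis
#'
#' Assigns each block a 0-based half-open interval on its chromosome by
#' cumulating block lengths in chromosome order.
#'
#' @param g a `block_genome`.
#' @return data.frame with columns `block` (unsigned id), `chrom`, `start`,
#'   `end`, `sign`.
#' @export
block_layout <- function(g) {
  out <- lapply(names(g$chromosomes), function(cn) {
    blocks <- g$chromosomes[[cn]]
    len <- g$block_lengths[as.character(abs(blocks))]
    end <- cumsum(len)
    data.frame(block = abs(blocks), chrom = cn,
               start = end - len, end = end,
               sign = sign(blocks), row.names = NULL)
  })
  do.call(rbind, out)
}

# canonical unordered adjacency id, e.g. "3h|12t": block extremities sorted
# numerically then by extremity letter so that (a,b) == (b,a)
adjacency_id <- function(id1, ext1, id2, ext2) {
  a <- paste0(id1, ext1)
  b <- paste0(id2, ext2)
  swap <- (id2 < id1) | (id2 == id1 & ext2 < ext1)
  ifelse(swap, paste0(b, "|", a), paste0(a, "|", b))
}

# extremity presented at the right end of a signed block (+b runs tail->head)
right_extremity <- function(signed_block) ifelse(signed_block > 0, "h", "t")
# extremity presented at the left end
left_extremity <- function(signed_block) ifelse(signed_block > 0, "t", "h")

#' Extract the adjacency set of a genome
#'
#' One adjacency per pair of consecutive blocks on each chromosome, as an
#' unordered pair of block extremities. A block with positive sign presents
#' its tail first and exits through its head; a negative sign flips the
#' presented extremities. Chromosome ends contribute no telomeric adjacency,
#' so a genome with B blocks and C chromosomes has exactly B - C adjacencies.
#'
#' @param g a `block_genome`.
#' @return character vector of canonical adjacency ids of the form
#'   `"<id><h|t>|<id><h|t>"`; empty when every chromosome is a single block.
#' @export
adjacencies_of <- function(g) {
  validate_block_genome(g)
  out <- lapply(g$chromosomes, function(blocks) {
    if (length(blocks) < 2L) return(character())
    a <- blocks[-length(blocks)]
    b <- blocks[-1L]
    adjacency_id(abs(a), right_extremity(a), abs(b), left_extremity(b))
  })
  unname(unlist(out))
}

#' Overlap length between two genomic intervals
#'
#' Intervals are 0-based half-open; intervals on different chromosomes have
#' zero overlap, and abutting intervals ([0,100) vs [100,200)) as well.
#'
#' @param a,b lists or one-row data.frames with fields `chrom`, `start`, `end`.
#' @return overlap length in bp (>= 0).
#' @export
interval_overlap <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# vectorised interval validation used by the readers
check_intervals <- function(start, end, where = "interval") {
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(where, ": invalid interval(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (need 0 <= start < end)")
  }
  invisible(TRUE)
}
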