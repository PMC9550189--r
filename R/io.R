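# Readers and writers for the package's tabular formats: block-table TSV,
# orthology-map TSV, BED3+ tracks, plus the packaged orthology fixture for
# the mammalian-ancestor versus chicken karyotype comparison.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write block genomes to a block-table TSV
#'
#' @param genomes a `block_genome` or a (named) list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_block_table <- function(genomes, path) {
  if (inherits(genomes, "block_genome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    do.call(rbind, lapply(names(g$chromosomes), function(cn) {
      blocks <- g$chromosomes[[cn]]
      data.frame(genome = g$name, chromosome = cn,
                 position = seq_along(blocks), block = abs(blocks),
                 sign = sign(blocks),
                 length = unname(g$block_lengths[as.character(abs(blocks))]))
    }))
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read block genomes from a block-table TSV
#'
#' Expects a header with columns `genome`, `chromosome`, `position`,
#' `block`, `sign`, `length`; rows are validated and offending line numbers
#' reported.
#'
#' @param path input file.
#' @return named list of `block_genome` objects (one per genome label).
#' @export
read_block_table <- function(path) {
  df <- read_tsv(path)
  need <- c("genome", "chromosome", "position", "block", "sign", "length")
  if (!all(need %in% names(df))) {
    stop("block table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$length <= 0)) {
    stop("non-positive block length at line(s) ",
         paste(which(df$length <= 0) + 1L, collapse = ", "))
  }
  if (any(df$sign != 1 & df$sign != -1)) {
    stop("sign must be +1 or -1 at line(s) ",
         paste(which(df$sign != 1 & df$sign != -1) + 1L, collapse = ", "))
  }
  out <- lapply(split(df, df$genome), function(d) {
    dup <- d$block[duplicated(d$block)]
    if (length(dup)) {
      lines <- which(df$genome == d$genome[1L] & df$block %in% dup) + 1L
      stop("duplicate block id ", paste(unique(dup), collapse = ","),
           " in genome '", d$genome[1L], "' (line(s) ",
           paste(lines, collapse = ","), ")")
    }
    chroms <- lapply(split(d, d$chromosome), function(ch) {
      if (is.unsorted(ch$position, strictly = TRUE)) {
        stop("unsorted order-index in genome '", d$genome[1L],
             "', chromosome '", ch$chromosome[1L], "'")
      }
      as.integer(ch$block * ch$sign)
    })
    lens <- stats::setNames(d$length, as.character(d$block))
    block_genome(chroms, lens, name = d$genome[1L])
  })
  out[unique(df$genome)]
}

#' Write an orthology map to TSV
#' @param map orthology data.frame (see [make_orthology_maps()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_orthology_table <- function(map, path) write_tsv(map, path)

#' Read an orthology map from TSV
#'
#' Columns: `ref_chrom`, `ref_start`, `ref_end`, `tgt_chrom`, `tgt_start`,
#' `tgt_end`, `orient` (+1/-1), optional `block`. Coordinates are 0-based
#' half-open; pass `one_based = TRUE` to convert inclusive 1-based input at
#' the boundary.
#'
#' @param path input file.
#' @param one_based convert 1-based inclusive coordinates.
#' @return validated orthology data.frame sorted by reference position.
#' @export
read_orthology_table <- function(path, one_based = FALSE) {
  df <- read_tsv(path)
  need <- c("ref_chrom", "ref_start", "ref_end", "tgt_chrom", "tgt_start",
            "tgt_end", "orient")
  if (!all(need %in% names(df))) {
    stop("orthology table needs columns: ", paste(need, collapse = ", "))
  }
  if (one_based) {
    df$ref_start <- df$ref_start - 1L
    df$tgt_start <- df$tgt_start - 1L
  }
  check_intervals(df$ref_start, df$ref_end, "reference interval")
  check_intervals(df$tgt_start, df$tgt_end, "target interval")
  if (any(!df$orient %in% c(-1L, 1L))) stop("orient must be +1 or -1")
  df[order(df$ref_chrom, df$ref_start), ]
}

#' Read a BED3+ track
#'
#' 0-based half-open intervals; optional 4th (name) and 5th (score) columns
#' are kept; strand is ignored.
#'
#' @param path BED file (no header).
#' @param track optional track name stored as an attribute.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`, `score`).
#' @export
read_bed <- function(path, track = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("non-numeric coordinates in ", path)
  }
  check_intervals(df$start, df$end, basename(path))
  attr(df, "track") <- track
  df
}

#' Write intervals as BED
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Packaged orthology of mammalian-ancestor chromosomes to chicken
#'
#' Transcription of the published karyotype-orthology table relating the 20
#' reconstructed mammalian-ancestor chromosomes (MAM1-MAM19 plus MAMX, 19
#' autosomes and X) to chicken chromosomes (GGA), with the qualitative
#' complete/partial calls encoded as fractional coverages: a chicken
#' chromosome wholly orthologous to one MAM carries `frac_gga = 1`, "part
#' of" assignments carry fractions below the completeness tolerance. The
#' fractional magnitudes are stylised; the complete/partial calls follow
#' the printed table. The file is frozen; its md5 checksum is verified on
#' load.
#'
#' @return data.frame with columns `mam`, `mam_length_mbp`, `hsa`, `gga`,
#'   `frac_mam`, `frac_gga`.
#' @export
load_mam_gga_orthology <- function() {
  path <- system.file("extdata", "mam_gga_orthology.tsv", package = "karyevol")
  if (path == "") stop("fixture not found; is the package installed?")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "ae62d3f7458a088dbd73823cc55c3d84")) {
    warning("mam_gga_orthology.tsv checksum mismatch; fixture may have been edited")
  }
  read_tsv(path)
}

#' Orthology map of the packaged fixture in classifier form
#'
#' @param small_only keep only small MAMs (< 100 Mbp).
#' @return data.frame with `chrom_a`, `chrom_b`, `frac_a`, `frac_b` suitable
#'   for [classify_orthology()].
#' @export
mam_gga_map <- function(small_only = FALSE) {
  df <- load_mam_gga_orthology()
  if (small_only) df <- df[df$mam_length_mbp < 100, ]
  data.frame(chrom_a = df$mam, chrom_b = df$gga,
             frac_a = df$frac_mam, frac_b = df$frac_gga)
}
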