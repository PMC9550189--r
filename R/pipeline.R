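# End-to-end synthetic-mode pipeline: simulate genomes on a dated tree,
# reconstruct ancestors along the lineage to a reference tip, call EBRs and
# msHSBs, compute branch rates, generate annotation tracks anchored on the
# called breakpoints, and run the window-based enrichment statistics. Every
# stage writes its standard tabular output plus a run manifest.

#' Run the full synthetic-mode pipeline
#'
#' A single seeded, deterministic run: identical seeds give byte-identical
#' output trees. Stochastic stages draw from one RNG stream in a documented
#' order (simulation first, annotation generation second with seed + 1).
#'
#' @param tree a dated `phylo` tree (or newick string).
#' @param config a [simulation_config()]; its seed keys the whole run.
#' @param reference tip label used as reference genome (default: first tip).
#' @param out_dir output directory (created if needed).
#' @param resolution SF resolution and msHSB minimum length (bp).
#' @param ann_params an [annotation_params()] object.
#' @return invisibly, a list with the main in-memory objects (`history`,
#'   `sfs`, `reconstructions`, `ebrs`, `mshsbs`, `rates`, `windows`,
#'   `reports`).
#' @export
run_pipeline <- function(tree, config = simulation_config(), reference = NULL,
                         out_dir, resolution = 300e3,
                         ann_params = annotation_params()) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- dated_tree(tree)
  if (is.null(reference)) reference <- tree$tip.label[1L]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  history <- simulate_history(tree, config)
  write_block_table(history$genomes, file.path(out_dir, "genomes.tsv"))
  write_tsv(history$events, file.path(out_dir, "event_log.tsv"))
  write_tsv(history$breakpoints, file.path(out_dir, "breakpoints.tsv"))
  maps <- make_orthology_maps(history$genomes[tree$tip.label], reference)
  map_df <- do.call(rbind, lapply(names(maps), function(g)
    cbind(data.frame(genome = g), maps[[g]])))
  write_tsv(map_df, file.path(out_dir, "orthology_maps.tsv"))
  sfs <- detect_sfs(maps, resolution = resolution)
  write_tsv(sfs$table, file.path(out_dir, "sfs.tsv"))
  write_tsv(sfs$unplaced, file.path(out_dir, "sfs_unplaced.tsv"))
  # reconstructions at every internal node
  internal <- tree$node.label
  recons <- lapply(internal, function(nd)
    assemble_racfs(score_adjacencies(sfs, tree, nd), sfs))
  names(recons) <- internal
  for (nd in internal) {
    write_block_table(recons[[nd]], file.path(out_dir, paste0("racf_", nd, ".tsv")))
  }
  # EBRs along the root-to-tip lineage of every tip, pooled
  chains <- genome_sf_chains(sfs)
  ebr_list <- lapply(tree$tip.label, function(tip) {
    path <- root_path(tree, tip)
    lineage <- c(lapply(recons[path[-length(path)]], `[[`, "chromosomes"),
                 stats::setNames(list(chains[[tip]]), tip))
    names(lineage) <- path
    e <- detect_ebrs(lineage, sfs)
    if (nrow(e)) e$lineage <- tip
    e
  })
  ebrs <- do.call(rbind, ebr_list[vapply(ebr_list, nrow, 1L) > 0])
  if (is.null(ebrs)) ebrs <- detect_ebrs(list(a = list(), b = list())[0], sfs)
  ebrs <- classify_reuse(ebrs, tree)
  write_tsv(ebrs, file.path(out_dir, "ebrs.tsv"))
  ebr_ref <- unique(ebrs[!ebrs$diffuse & ebrs$lineage == reference,
                         c("chrom", "start", "end", "branch", "reuse")])
  if (nrow(ebr_ref)) {
    bed <- data.frame(chrom = ebr_ref$chrom, start = ebr_ref$start,
                      end = ebr_ref$end,
                      name = paste0(ebr_ref$branch,
                                    ifelse(ebr_ref$reuse, ";reuse", "")))
    write_bed(bed, file.path(out_dir, "ebrs.bed"))
  }
  # branch rates from unique (branch, junction) EBR counts
  uniq <- unique(ebrs[, c("branch", "adj")])
  bt <- branch_table(tree)
  counts <- data.frame(branch = bt$branch,
                       n_breakpoints = as.integer(table(factor(uniq$branch,
                                                               levels = bt$branch))))
  rates <- test_rates(compute_rates(counts, tree))
  write_tsv(rates, file.path(out_dir, "branch_rates.tsv"))
  # msHSBs from pairwise coverage against the reference
  coverages <- lapply(setdiff(tree$tip.label, reference), function(sp) {
    pw <- detect_sfs(maps[c(reference, sp)], resolution = resolution)
    pw$table[, c("chrom", "start", "end")]
  })
  names(coverages) <- setdiff(tree$tip.label, reference)
  mshsbs <- detect_mshsbs(coverages, min_len = resolution, maps = maps)
  write_tsv(mshsbs, file.path(out_dir, "mshsbs.tsv"))
  if (nrow(mshsbs)) {
    write_bed(mshsbs[, c("chrom", "start", "end")],
              file.path(out_dir, "mshsbs.bed"))
  }
  # annotation tracks anchored on the reference-lineage EBR coordinates
  ref_layout <- block_layout(history$genomes[[reference]])
  chrom_lengths <- tapply(ref_layout$end, ref_layout$chrom, max)
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  bps <- if (nrow(ebr_ref)) {
    data.frame(chrom = ebr_ref$chrom,
               pos = round((ebr_ref$start + ebr_ref$end) / 2))
  } else NULL
  bundle <- generate_annotations(chrom_lengths, bps, ann_params,
                                 seed = config$seed + 1L)
  for (tk in names(bundle$tracks)) {
    tr <- bundle$tracks[[tk]]
    if (nrow(tr)) write_bed(tr, file.path(out_dir, paste0("track_", tk, ".bed")))
  }
  # window statistics
  reports <- list()
  w10 <- make_windows(chrom_lengths, 1e4, bundle$tracks$gaps,
                      bundle$tracks$centromeres)
  w10 <- tally_features(classify_windows(w10, bundle$regions$mshsb,
                                         bundle$regions$ebr), bundle)
  write_tsv(w10, file.path(out_dir, "windows_10kbp.tsv"))
  w100 <- make_windows(chrom_lengths, 1e5, bundle$tracks$gaps,
                       bundle$tracks$centromeres)
  w100 <- tally_features(classify_windows(w100, bundle$regions$mshsb,
                                          bundle$regions$ebr), bundle)
  write_tsv(w100, file.path(out_dir, "windows_100kbp.tsv"))
  k10 <- w10[w10$kept & w10$class != "other", ]
  k100 <- w100[w100$kept & w100$class != "other", ]
  if (length(unique(k100$class)) >= 2L) {
    reports$gene_density <- pairwise_wilcoxon(k100$n_genes, k100$class)
    write_tsv(reports$gene_density, file.path(out_dir, "gene_density_tests.tsv"))
  }
  genes <- bundle$tracks$genes
  if (nrow(genes)) {
    genes$class <- point_class(genes$chrom, genes$start,
                               list(msHSB = bundle$regions$mshsb,
                                    EBR = bundle$regions$ebr))
    gsub_ <- genes[genes$class != "other", ]
    if (length(unique(gsub_$class)) >= 2L) {
      reports$gene_lengths <- compare_gene_lengths(gsub_)
      write_tsv(reports$gene_lengths, file.path(out_dir, "gene_length_tests.tsv"))
    }
  }
  if (length(unique(k10$class)) >= 2L) {
    reports$tad <- association_test(!k10$tad_present, k10$class)
    write_tsv(reports$tad, file.path(out_dir, "tad_association.tsv"))
    rep_rep <- repeat_density_report(w10)
    reports$repeats <- rep_rep
    if (length(rep_rep$comparisons)) {
      tabs <- do.call(rbind, lapply(names(rep_rep$comparisons), function(nm)
        cbind(data.frame(subclass = nm), rep_rep$comparisons[[nm]])))
      write_tsv(tabs, file.path(out_dir, "repeat_density_tests.tsv"))
    }
  }
  # manifest: configuration, seed and output checksums
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    key = c("package_version", "seed", "reference", "resolution",
            "rate", "n_blocks", "tree",
            paste0("md5:", files)),
    value = c(as.character(utils::packageVersion("karyevol")),
              config$seed, reference, resolution, config$rate,
              config$n_blocks, ape::write.tree(tree),
              unname(tools::md5sum(file.path(out_dir, files)))))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(history = history, sfs = sfs, reconstructions = recons,
                 ebrs = ebrs, mshsbs = mshsbs, rates = rates,
                 windows = list(w10 = w10, w100 = w100), reports = reports,
                 bundle = bundle))
}
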