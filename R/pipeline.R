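## End-to-end pipeline on a synthetic bundle: partition -> RPKM -> two SOMs
## -> metaclustering -> linking -> motif scan + density enrichment ->
## filter cascade -> network, with planted-truth evaluation.

#' Run the full linked-SOM inference pipeline on a synthetic bundle
#'
#' Executes partitioning of the bundle's peak calls, RPKM quantification,
#' DNA- and RNA-SOM training with AIC metacluster selection, nearest-TSS
#' linking, PWM scanning of partition sequences with exact p-values
#' (q < `q_motif` hits), per-LM motif-density enrichment, the ChIP
#' percentile / expression / Ep300 / gene-list cascade, and network
#' assembly.
#'
#' @param bundle A `synthetic_bundle` from [generate_bundle()].
#' @param som_rows,som_cols Lattice size for both SOMs (default 12 x 18).
#' @param epochs,trials SOM training schedule (default 30 epochs, 5 trials).
#' @param k_range Candidate metacluster counts (default `seq(3, 15, 2)`).
#' @param mc_trials Restarts per k in the constrained k-means (default 3).
#' @param q_motif Motif hit q-value threshold (default 0.1).
#' @param alpha_enrich LM density-enrichment retention threshold (0.05).
#' @param chip_percentile ChIP / Ep300 percentile rule (default 75).
#' @param min_tpm Expression floor for RNA metaclusters (default 1).
#' @param seed Pipeline seed (SOM and metaclustering restarts).
#' @return A list with the network, evaluation against the planted truth,
#'   and all intermediates (`partitions`, `rpkm`, `dna_som`, `rna_som`,
#'   `dna_mc`, `rna_mc`, `lm_map`, `hits`, `enrichment`, `cascade`).
#' @export
run_pipeline <- function(bundle,
                         som_rows = 12L, som_cols = 18L,
                         epochs = 30L, trials = 5L,
                         k_range = seq(3L, 15L, 2L),
                         mc_trials = 3L,
                         q_motif = 0.1,
                         alpha_enrich = 0.05,
                         chip_percentile = 75,
                         min_tpm = 1,
                         seed = 1L) {
  config <- bundle$config
  seqlen <- setNames(Biostrings::width(bundle$genome), names(bundle$genome))

  ## 1. genome partition + RPKM
  partitions <- partition_genome(bundle$chromatin$peaks, min_size = 200L,
                                 seqlengths = seqlen)
  rpkm <- quantify_rpkm(bundle$chromatin$reads, partitions,
                        bundle$chromatin$total_mapped)

  ## 2. DNA SOM over chromatin signal
  dna_mat <- preprocess_matrix(rpkm, "log2p1")
  dna_som <- train_som(dna_mat, som_config(som_rows, som_cols, epochs = epochs,
                                           trials = trials,
                                           seed = derive_seed(seed, 11L)))
  dna_assign <- assign_items(dna_som, dna_mat)
  dna_mc <- select_k(dna_som, k_range, criterion = "AIC", trials = mc_trials,
                     seed = derive_seed(seed, 12L))
  region_mc <- assign_items_to_metaclusters(dna_assign, dna_mc)

  ## 3. RNA SOM over expression
  rna_mat <- preprocess_matrix(bundle$expression$tpm, "log2p1")
  rna_som <- train_som(rna_mat, som_config(som_rows, som_cols, epochs = epochs,
                                           trials = trials,
                                           seed = derive_seed(seed, 13L)))
  rna_assign <- assign_items(rna_som, rna_mat)
  rna_mc <- select_k(rna_som, k_range, criterion = "AIC", trials = mc_trials,
                     seed = derive_seed(seed, 14L))
  gene_mc <- assign_items_to_metaclusters(rna_assign, rna_mc)

  ## 4. link the two SOMs
  lm_map <- link_soms(region_mc, gene_mc, partitions, bundle$genes,
                      k_rna = rna_mc$k, k_dna = dna_mc$k)

  ## 5. motif scan of partition sequences (exact DP p-values, BH per motif)
  seqs <- region_sequences(bundle$genome, partitions)
  hits <- list()
  enr_hits <- list()
  for (t in seq_len(nrow(bundle$grn$tfs))) {
    tf <- bundle$grn$tfs$tf[t]
    pwm <- iupac_to_pwm(bundle$grn$tfs$consensus[t], id = tf)
    h <- scan_regions(seqs, pwm)
    hits[[tf]] <- filter_hits(h, q_motif)
  }
  enrichment <- lm_density_enrichment(hits, lm_map, alpha = alpha_enrich)
  for (tf in names(hits)) {
    keep_bins <- enrichment[enrichment$motif == tf & enrichment$retained,
                            c("rna_mc", "dna_mc")]
    h <- hits[[tf]]
    bin_of <- lm_map$pairs
    reg_bins <- bin_of[match(h$region_id, bin_of$region_id),
                       c("rna_mc", "dna_mc")]
    ok <- paste(reg_bins$rna_mc, reg_bins$dna_mc) %in%
      paste(keep_bins$rna_mc, keep_bins$dna_mc)
    enr_hits[[tf]] <- h[ok & !is.na(reg_bins$rna_mc), , drop = FALSE]
  }

  ## 6. filter cascade
  dna_ret <- lapply(setNames(bundle$grn$tfs$tf, bundle$grn$tfs$tf),
                    function(tf) chip_percentile_filter(
                      region_mc, rpkm, paste0("chip_", tf), chip_percentile))
  ep_ret <- ep300_filter(region_mc, rpkm, "ep300", chip_percentile)
  stage_cols <- paste0("wt_", config$stages[1:min(4, length(config$stages))])
  rna_ret <- expression_filter(gene_mc, bundle$expression$tpm, stage_cols,
                               min_tpm)
  network <- assemble_network(enr_hits, lm_map, dna_ret, ep_ret, rna_ret,
                              bundle$gastrulation_genes, bundle$tf_genes)
  evaluation <- evaluate_network(network, bundle$grn)

  list(network = network, evaluation = evaluation, partitions = partitions,
       rpkm = rpkm, dna_som = dna_som, rna_som = rna_som, dna_mc = dna_mc,
       rna_mc = rna_mc, region_mc = region_mc, gene_mc = gene_mc,
       lm_map = lm_map, hits = hits, enrichment = enrichment,
       cascade = network$cascade)
}

#' Extract partition sequences from a genome
#'
#' @param genome `DNAStringSet`.
#' @param partitions `GRanges` with `region_id`.
#' @return Named character vector of region sequences.
#' @export
region_sequences <- function(genome, partitions) {
  out <- vapply(seq_along(partitions), function(i) {
    ch <- as.character(GenomicRanges::seqnames(partitions)[i])
    as.character(Biostrings::subseq(
      genome[[ch]], GenomicRanges::start(partitions)[i],
      GenomicRanges::end(partitions)[i]))
  }, "")
  names(out) <- S4Vectors::mcols(partitions)$region_id
  out
}
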