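test_that("the full bundle is byte-identical across runs at a fixed seed", {
  b1 <- generate_bundle(tiny_config(seed = 5))
  b2 <- generate_bundle(tiny_config(seed = 5))
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$grn$edges, b2$grn$edges)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$expression$tpm, b2$expression$tpm)
  for (e in names(b1$chromatin$peaks))
    expect_identical(as.data.frame(b1$chromatin$peaks[[e]]),
                     as.data.frame(b2$chromatin$peaks[[e]]))
  b3 <- generate_bundle(tiny_config(seed = 6))
  expect_false(identical(as.character(b1$genome), as.character(b3$genome)))
})

test_that("gene models are in bounds, non-overlapping, with 5' TSS", {
  cfg <- tiny_config(seed = 2)
  gen <- generate_genome(cfg)
  g <- gen$genes
  expect_equal(nrow(g), cfg$n_genes)
  expect_equal(anyDuplicated(g$gene_id), 0L)
  expect_true(all(g$start >= 1 & g$end <= cfg$chromosome_length))
  expect_true(all(g$tss == ifelse(g$strand == "+", g$start, g$end)))
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
  }
  ## minimal two-gene genome fits in 10 kb
  cfg2 <- synthetic_config(seed = 1, n_chromosomes = 1,
                           chromosome_length = 10000L, n_genes = 2L,
                           n_tfs = 1L, targets_per_tf = 1L,
                           n_expression_modules = 2L, gene_length = 1000L,
                           min_gene_gap = 500L)
  g2 <- generate_genome(cfg2)$genes
  expect_equal(nrow(g2), 2L)
  expect_true(all(g2$tss >= 1 & g2$tss <= 10000))
  ## impossible packing raises a placement error
  cfg3 <- synthetic_config(seed = 1, n_chromosomes = 1,
                           chromosome_length = 10000L, n_genes = 50L,
                           n_tfs = 1L, targets_per_tf = 1L,
                           n_expression_modules = 2L)
  expect_error(generate_genome(cfg3), "without overlap")
})

test_that("background sequence is uniform over ACGT within 3 binomial SD", {
  gen <- generate_genome(tiny_config(seed = 3))
  counts <- Biostrings::alphabetFrequency(gen$genome[[1]])[c("A", "C", "G", "T")]
  n <- sum(counts)
  sd3 <- 3 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n * 0.25) < sd3))
})

test_that("the planted network satisfies its cardinality and distance invariants", {
  cfg <- tiny_config(seed = 7)
  gen <- generate_genome(cfg)
  grn <- generate_planted_grn(cfg, gen$genes)
  expect_equal(nrow(grn$edges), cfg$n_tfs * cfg$targets_per_tf)
  expect_equal(anyDuplicated(grn$edges$crm_id), 0L)
  tss <- setNames(gen$genes$tss, gen$genes$gene_id)
  for (i in seq_len(nrow(grn$edges))) {
    r <- grn$regions[grn$regions$crm_id == grn$edges$crm_id[i], ]
    mid <- floor((r$start + r$end) / 2)
    expect_lte(abs(mid - tss[[grn$edges$target[i]]]), 1e6)
  }
  ## region intervals inside chromosome bounds
  expect_true(all(grn$regions$start >= 1 &
                    grn$regions$end <= cfg$chromosome_length))
  ## oversubscription raises a sizing error
  cfg_big <- tiny_config(seed = 7, targets_per_tf = 100L)
  expect_error(generate_planted_grn(cfg_big, gen$genes), "more targets")
})

test_that("planted sites realize their consensus and decoys carry the knockout", {
  cfg <- tiny_config(seed = 11)
  b <- generate_bundle(cfg)
  cons_of <- setNames(b$grn$tfs$consensus, b$grn$tfs$tf)
  ko_of <- setNames(b$grn$tfs$consensus_knockout, b$grn$tfs$tf)
  ## every truth-table site rescans exactly at its recorded position
  for (i in seq_len(nrow(b$sites))) {
    s <- b$sites[i, ]
    pat <- if (s$kind == "true") cons_of[[s$tf]] else ko_of[[s$tf]]
    expect_true(s$seq %in% iupac_expand(pat))
    w <- nchar(s$seq)
    genome_seq <- as.character(Biostrings::subseq(b$genome[[s$chrom]],
                                                  s$start, s$start + w - 1))
    want <- if (s$strand == "+") s$seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s$seq)))
    expect_identical(genome_seq, want)
  }
  ## the published substitution rules hold for the built-in cores
  tfs <- tf_motif_table(2)
  expect_equal(tfs$core_knockout[tfs$tf == "foxh1"], "AAGMHAAA")
  expect_equal(tfs$core_knockout[tfs$tf == "sox17"], "ATAGWRG")
  ## decoy CRMs contain a knockout realization and no intact core match
  decoys <- b$grn$regions[b$grn$regions$kind == "decoy", ]
  core_of <- setNames(b$grn$tfs$core, b$grn$tfs$tf)
  n_intact <- 0L
  for (i in seq_len(nrow(decoys))) {
    d <- decoys[i, ]
    seq <- Biostrings::DNAString(as.character(
      Biostrings::subseq(b$genome[[d$chrom]], d$start, d$end)))
    ko_hits <- length(Biostrings::matchPattern(ko_of[[d$tf]], seq,
                                               fixed = FALSE)) +
      length(Biostrings::matchPattern(ko_of[[d$tf]],
                                      Biostrings::reverseComplement(seq),
                                      fixed = FALSE))
    expect_gte(ko_hits, 1L)
    core <- core_of[[d$tf]]
    fwd <- Biostrings::matchPattern(core, seq, fixed = FALSE)
    rev <- Biostrings::matchPattern(core,
                                    Biostrings::reverseComplement(seq),
                                    fixed = FALSE)
    n_intact <- n_intact + (length(fwd) + length(rev) > 0)
  }
  ## intact cores appear in decoys only at the background chance rate
  expect_lte(n_intact, max(2L, ceiling(0.3 * nrow(decoys))))
})

test_that("noise-free expression equals the planted means", {
  cfg <- tiny_config(seed = 4, noise_sd = 0)
  gen <- generate_genome(cfg)
  grn <- generate_planted_grn(cfg, gen$genes)
  ex <- generate_expression_matrix(cfg, grn)
  expect_identical(ex$tpm, ex$mean_tpm)
  expect_true(all(ex$tpm >= 0))
  expect_equal(nrow(ex$metadata), ncol(ex$tpm))
  ## unknown TF in a perturbation is a config error
  cfg_bad <- tiny_config(seed = 4)
  cfg_bad$perturbations <- data.frame(tf = "nosuchtf", stage = "st9")
  expect_error(generate_expression_matrix(cfg_bad, grn), "unknown TF")
})

test_that("knockdown targets show the planted MO/control ratio", {
  cfg <- synthetic_config(seed = 8, n_chromosomes = 2,
                          chromosome_length = 750000L, n_genes = 250L,
                          n_tfs = 1L, targets_per_tf = 200L,
                          n_expression_modules = 3L,
                          n_decoys_per_tf = 2L, n_background_regions = 5L)
  gen <- generate_genome(cfg)
  grn <- generate_planted_grn(cfg, gen$genes)
  ex <- generate_expression_matrix(cfg, grn)
  tf <- grn$tfs$tf[1]
  mo <- ex$metadata$experiment[ex$metadata$type == "mo"][1]
  ctrl <- ex$metadata$pair[ex$metadata$experiment == mo]
  targets <- grn$edges$target
  others <- setdiff(rownames(ex$tpm), c(targets, grn$tfs$gene_id))
  ratio <- ex$tpm[, mo] / ex$tpm[, ctrl]
  ## log-normal noise: per-gene log2 ratio has SD sqrt(2)*noise_sd
  se_t <- sqrt(2) * cfg$noise_sd / sqrt(length(targets))
  expect_lt(abs(mean(log2(ratio[targets])) - log2(0.25)), 2 * se_t)
  se_o <- sqrt(2) * cfg$noise_sd / sqrt(length(others))
  expect_lt(abs(mean(log2(ratio[others]))), 2 * se_o)
})

test_that("module means separate by more than 4 SE at the default noise", {
  cfg <- synthetic_config(seed = 9, n_chromosomes = 2,
                          chromosome_length = 750000L, n_genes = 200L,
                          n_tfs = 3L, targets_per_tf = 50L,
                          n_expression_modules = 4L,
                          n_decoys_per_tf = 2L, n_background_regions = 5L)
  gen <- generate_genome(cfg)
  grn <- generate_planted_grn(cfg, gen$genes)
  ex <- generate_expression_matrix(cfg, grn)
  lx <- log2(ex$tpm + 1)
  stage_cols <- ex$metadata$experiment[ex$metadata$type == "stage"]
  mods <- grn$modules[rownames(lx)]
  for (m1 in 1:3) for (m2 in seq_len(m1 - 1)) {
    g1 <- names(mods)[mods == m1]; g2 <- names(mods)[mods == m2]
    p1 <- colMeans(lx[g1, stage_cols]); p2 <- colMeans(lx[g2, stage_cols])
    se <- sqrt(mean(apply(lx[c(g1, g2), stage_cols], 2, var)) *
                 (1 / length(g1) + 1 / length(g2)))
    expect_gt(sqrt(sum((p1 - p2)^2)), 4 * se)
  }
})

test_that("chromatin reads reproduce the planted state signatures", {
  cfg <- tiny_config(seed = 10)
  b <- generate_bundle(cfg)
  regions <- b$chromatin$regions
  rpkm <- quantify_rpkm(b$chromatin$reads, {
    g <- regions
    S4Vectors::mcols(g)$region_id <- S4Vectors::mcols(g)$crm_id
    g
  }, b$chromatin$total_mapped)
  states <- b$grn$regions$state
  active <- states == "active_enhancer"
  het <- states == "heterochromatin"
  a_mean <- mean(rpkm[active, "ep300"]); h_mean <- mean(rpkm[het, "ep300"])
  ## planted separation: ep300 10 RPKM vs the 0.2 baseline
  expect_gt(a_mean, h_mean)
  se_a <- sd(rpkm[active, "ep300"]) / sqrt(sum(active))
  expect_lt(abs(a_mean - 10), 3 * se_a + 0.5)
  expect_lt(h_mean, 1)
  ## every GRN edge has at least one planted site and a peak-covered CRM
  tfpk <- b$chromatin$peaks[[paste0("chip_", b$grn$tfs$tf[1])]]
  for (i in seq_len(nrow(b$grn$edges))) {
    e <- b$grn$edges[i, ]
    expect_gte(sum(b$sites$crm_id == e$crm_id), 1L)
    r <- b$grn$regions[b$grn$regions$crm_id == e$crm_id, ]
    covered <- any(vapply(b$chromatin$peaks, function(pk)
      length(GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end)),
        pk)) > 0, TRUE))
    expect_true(covered)
  }
})

test_that("an all-zero state signature emits no peaks and no reads", {
  cfg <- tiny_config(seed = 12)
  null_sig <- setNames(rep(0, 9),
                       c("tf_chip", "h3k4me1", "h3k4me3", "h3k27ac",
                         "h3k27me3", "h3k36me3", "h3k9me3", "ep300", "atac"))
  cfg$chromatin_states <- c(default_chromatin_states()[c("active_enhancer",
                                                         "poised_enhancer")],
                            list(dead = null_sig))
  gen <- generate_genome(cfg)
  grn <- generate_planted_grn(cfg, gen$genes)
  chrom <- generate_chromatin_data(cfg, grn)
  dead <- grn$regions$crm_id[grn$regions$state == "dead"]
  expect_gt(length(dead), 0L)
  expect_true(all(chrom$expected_rpkm[dead, ] == 0))
  dead_gr <- GenomicRanges::GRanges(
    grn$regions$chrom[grn$regions$state == "dead"],
    IRanges::IRanges(grn$regions$start[grn$regions$state == "dead"],
                     grn$regions$end[grn$regions$state == "dead"]))
  for (e in names(chrom$reads)) {
    expect_equal(sum(GenomicRanges::countOverlaps(dead_gr, chrom$reads[[e]])), 0L)
    expect_equal(sum(GenomicRanges::countOverlaps(dead_gr, chrom$peaks[[e]])), 0L)
  }
  ## a signature naming an unknown experiment is a config error
  cfg$chromatin_states$dead <- c(nosuch = 1)
  expect_error(generate_chromatin_data(cfg, grn), "unknown experiment")
})

test_that("bundles round-trip to plain-text files", {
  b <- generate_bundle(tiny_config(seed = 13))
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(fa), as.character(b$genome))
  genes <- read.table(file.path(dir, "genes.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  expect_identical(genes$gene_id, b$genes$gene_id)
  truth <- jsonlite::read_json(file.path(dir, "planted_grn.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$edges), nrow(b$grn$edges))
  pk <- read_peaks(file.path(dir, "peaks", "ep300.bed"))
  expect_equal(length(pk), length(b$chromatin$peaks$ep300))
})
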