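test_that("the ChIP percentile filter uses linear-interpolation percentiles", {
  region_mc <- data.frame(item = paste0("P", 1:8),
                          metacluster = rep(1:4, each = 2))
  sig <- matrix(rep(c(1, 2, 3, 4), each = 2), ncol = 1,
                dimnames = list(paste0("P", 1:8), "chip"))
  ## metacluster means {1,2,3,4}: 75th percentile = 3.25 -> only {4}
  expect_equal(chip_percentile_filter(region_mc, sig, "chip", 75), 4L)
  expect_equal(chip_percentile_filter(region_mc, sig, "chip", 0), 1:4)
  sig_eq <- matrix(2, 8, 1, dimnames = list(paste0("P", 1:8), "chip"))
  expect_equal(chip_percentile_filter(region_mc, sig_eq, "chip", 75), 1:4)
  expect_error(chip_percentile_filter(region_mc, sig, "nope"), "not in signal")
  ## metaclusters without regions in the matrix are excluded with a warning
  region_mc2 <- rbind(region_mc, data.frame(item = "P99", metacluster = 5L))
  expect_warning(r <- chip_percentile_filter(region_mc2, sig, "chip", 75),
                 "excluded")
  expect_equal(r, 4L)
  ## ep300_filter shares the same contract
  expect_equal(ep300_filter(region_mc, sig, "chip", 75), 4L)
  expect_true(all(ep300_filter(region_mc, sig, "chip", 75) %in%
                    ep300_filter(region_mc, sig, "chip", 0)))
})

test_that("the expression filter keeps metaclusters above the TPM floor", {
  gene_mc <- data.frame(item = paste0("g", 1:4),
                        metacluster = c(1L, 1L, 2L, 2L))
  tpm <- matrix(c(0, 0, 0,      0, 0, 0,     # mc 1: all zero -> dropped
                  0.5, 1.2, 0.8, 0.5, 1.2, 0.8),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), c("s8", "s9", "s10")))
  expect_equal(expression_filter(gene_mc, tpm, c("s8", "s9", "s10")), 2L)
  expect_equal(expression_filter(gene_mc, tpm, c("s8", "s9", "s10"),
                                 min_tpm = 0), 2L)  # strict >0 drops all-zero
})

test_that("network assembly applies the cascade with monotone counts", {
  ## two regions linked to two genes; only region P1's metacluster passes
  pairs <- data.frame(rna_mc = c(1L, 2L), dna_mc = c(1L, 2L),
                      region_id = c("P1", "P2"), gene_id = c("g1", "g2"),
                      distance = 0)
  lm <- structure(list(pairs = pairs, k_rna = 2L, k_dna = 2L, n_bins = 4L),
                  class = "lm_map")
  hits <- list(tfA = data.frame(region_id = c("P1", "P2")))
  net <- assemble_network(hits, lm,
                         dna_mc_retained = list(tfA = 1L),
                         ep300_retained = 1:2,
                         rna_mc_retained = 1:2,
                         gastrulation_genes = c("g1", "g2"),
                         tf_genes = c("g1", "g2"))
  expect_equal(net$edges$tf, "tfA")
  expect_equal(net$edges$target, "g1")
  expect_equal(net$edges$n_crms, 1L)
  expect_true(all(diff(net$cascade$n_instances) <= 0))
  ## gene-list restriction drops the remaining edge
  net2 <- assemble_network(hits, lm, list(tfA = 1:2), 1:2, 1:2,
                           gastrulation_genes = "g2", tf_genes = "g1")
  expect_equal(nrow(net2$edges), 0L)
  ## empty motif set -> empty network, zero cascade counts
  net3 <- assemble_network(list(tfA = data.frame(region_id = character())),
                           lm, list(tfA = 1L), 1L, 1L, "g1", "g1")
  expect_equal(nrow(net3$edges), 0L)
  expect_true(all(net3$cascade$n_instances == 0))
  ## regions missing from the LM map are an integrity error
  bad <- list(tfA = data.frame(region_id = "P99"))
  expect_error(assemble_network(bad, lm, list(tfA = 1L), 1L, 1L, "g1", "g1"),
               "integrity")
})

test_that("the equivalence test calls unchanging genes correctly", {
  set.seed(41)
  n <- 400
  ## half the genes truly unchanged, half with |log2 FC| = 2; replicate
  ## noise is multiplicative log-normal around a per-gene baseline (0.15
  ## log2 SD, typical for biological replicates of well-expressed genes;
  ## at larger replicate noise the +/-0.5 equivalence bound is not
  ## certifiable from 3 replicates by any test)
  base <- rexp(n, 1 / 50) + 5
  noise <- function() matrix(2^rnorm(n * 3, 0, 0.15), n, 3)
  fc <- c(rep(1, n / 2), rep(4, n / 2))
  mo <- base * fc * noise()
  ctrl <- base * noise()
  rownames(mo) <- rownames(ctrl) <- paste0("g", 1:n)
  r <- unchanging_test(mo, ctrl)
  changed <- r$unchanging[(n / 2 + 1):n]
  expect_lt(mean(changed), 0.01)
  unchanged <- r$unchanging[1:(n / 2)]
  expect_gte(mean(unchanged), 0.6)
  ## identical MO and control arms -> unchanging, zero-variance flagged
  x <- matrix(rep(rexp(10, 1 / 20) + 5, 3), 10, 3,
              dimnames = list(paste0("g", 1:10), NULL))
  r2 <- unchanging_test(x, x)
  expect_true(all(r2$unchanging))
  expect_true(all(r2$degenerate))
  expect_error(unchanging_test(x[, 1, drop = FALSE], x), "replicates")
})

test_that("equivalence calls agree with DESeq2 lessAbs on extreme genes", {
  set.seed(77)
  n <- 150
  mu <- rexp(n, 1 / 500) + 200
  ## 100 null genes; 50 changed genes balanced up/down so size factors
  ## stay near 1
  fc <- c(rep(1, 100), rep(6, 25), rep(1 / 6, 25))
  counts <- cbind(
    matrix(rnbinom(n * 3, mu = mu, size = 80), n, 3),
    matrix(rnbinom(n * 3, mu = mu * fc, size = 80), n, 3))
  rownames(counts) <- paste0("g", 1:n)
  colnames(counts) <- paste0("s", 1:6)
  cond <- factor(rep(c("ctrl", "mo"), each = 3))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, S4Vectors::DataFrame(condition = cond),
                                        ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, fitType = "local")
  res <- DESeq2::results(dds, lfcThreshold = 0.5, altHypothesis = "lessAbs")
  ds_unchanging <- !is.na(res$padj) & res$padj < 0.05
  ours <- unchanging_test(counts[, 4:6], counts[, 1:3])
  ## strong-change genes: neither method calls them unchanging
  expect_equal(sum(ds_unchanging[101:n]), 0)
  expect_equal(sum(ours$unchanging[101:n]), 0)
  ## null genes: both methods call a clear majority unchanging
  expect_gt(mean(ds_unchanging[1:100]), 0.5)
  expect_gt(mean(ours$unchanging[1:100]), 0.5)
})

test_that("true-negative intersection and FPR/FDR follow their definitions", {
  calls <- list(c("a", "b", "c"), c("b", "c", "d"), c("c", "b"))
  expect_equal(true_negative_set(calls), c("b", "c"))
  expect_equal(true_negative_set(calls[1]), c("a", "b", "c"))
  expect_equal(true_negative_set(list(c("a"), c("b"))), character(0))
  set.seed(1)
  r1 <- sample(letters, 10); r2 <- sample(letters, 12)
  expect_equal(true_negative_set(list(r1, r2)), sort(intersect(r1, r2)))

  tn <- paste0("t", 1:50)
  pred <- c(paste0("t", 1:10), paste0("p", 1:40))
  f <- fpr_fdr(pred, tn)
  expect_equal(f$fpr_percent, 100 * 10 / 50)
  expect_equal(f$fdr_percent, 100 * 10 / 50)
  f0 <- fpr_fdr(paste0("x", 1:5), tn)
  expect_equal(f0$fpr_percent, 0)
  expect_equal(f0$fdr_percent, 0)
  expect_error(fpr_fdr(pred, character(0)), "undefined")
})

test_that("CRM scorecards average group signals with a combined mean", {
  sig <- matrix(c(1, 2, 3, 4, 5,
                  0, 0, 0, 0, 0), 2, 5, byrow = TRUE,
                dimnames = list(c("P1", "P2"),
                                c("k4", "k27", "ep", "tf", "at")))
  groups <- list(h3k4me1 = "k4", h3k27ac = "k27", ep300 = "ep",
                 tf_signal_density = "tf", chromatin_accessibility = "at")
  sc <- crm_effect_scores(list(crmA = "P1", crmB = "P2"), sig, groups)
  expect_equal(sc$combined[sc$crm_id == "crmA"], 3)
  expect_equal(unname(unlist(sc[sc$crm_id == "crmA", 2:6])), c(1, 2, 3, 4, 5))
  expect_true(all(sc[sc$crm_id == "crmB", 2:7] == 0))
  ## multi-partition CRM: mean over partitions (direct averaging oracle)
  sc2 <- crm_effect_scores(list(crmC = c("P1", "P2")), sig, groups)
  expect_equal(sc2$h3k4me1, mean(sig[, "k4"]))
  expect_error(crm_effect_scores(list(a = "P1"), sig, groups[-1]), "groups")
})

test_that("score-method validation ranks by Spearman agreement", {
  sc <- data.frame(crm_id = paste0("c", 1:6),
                   h3k4me1 = c(1, 2, 3, 4, 5, 6),
                   h3k27ac = c(6, 5, 4, 3, 2, 1),
                   ep300 = c(2, 1, 4, 3, 6, 5))
  obs <- setNames(c(10, 20, 30, 40, 50, 60), paste0("c", 1:6))
  r <- score_validation_agreement(sc, obs)
  expect_equal(r$method[1], "h3k4me1")
  expect_equal(r$rho[r$method == "h3k4me1"], 1)
  expect_equal(r$rho[r$method == "h3k27ac"], -1)
  expect_equal(r$rho[r$method == "ep300"],
               cor(c(2, 1, 4, 3, 6, 5), 1:6, method = "spearman"))
  ## constant score columns are flagged undefined
  sc$flat <- 1
  r2 <- score_validation_agreement(sc, obs)
  expect_true(is.na(r2$rho[r2$method == "flat"]))
  expect_error(score_validation_agreement(sc[1:2, ], obs), ">= 3")
})

test_that("spatial regulator classification labels by profile correlation", {
  tf <- c(1, 3, 2, 5)
  targets <- rbind(tf + 0.1, tf - 0.1)
  r <- spatial_regulator_classification(tf, targets)
  expect_equal(r$correlation, 1, tolerance = 1e-9)
  expect_equal(r$label, "activator")
  r2 <- spatial_regulator_classification(tf, rbind(-tf, -tf))
  expect_equal(r2$correlation, -1, tolerance = 1e-9)
  expect_equal(r2$label, "repressor")
  r3 <- spatial_regulator_classification(tf, targets, significant_q = 0.5)
  expect_equal(r3$label, "not_significant")
  r4 <- spatial_regulator_classification(c(1, 1, 1), targets[, 1:3])
  expect_equal(r4$label, "undefined")
})

test_that("the overlap permutation test behaves at its extremes", {
  set.seed(3)
  st <- sample(1:90000, 30)
  pred <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 199))
  p_same <- region_overlap_permutation(pred, pred, c(chr1 = 100000),
                                       n_perm = 99, seed = 1)
  expect_equal(p_same$observed, 30)
  expect_equal(p_same$p, 1 / 100)
  other <- GenomicRanges::GRanges("chr2", IRanges::IRanges(st, st + 199))
  p_none <- suppressWarnings(
    region_overlap_permutation(pred, other, c(chr1 = 100000),
                               n_perm = 99, seed = 1))
  expect_equal(p_none$observed, 0)
  expect_equal(p_none$p, 1)
  expect_error(region_overlap_permutation(pred, pred, c(chr1 = 1e5), 0),
               "n_perm")
})

test_that("networks export as TSV edge lists and GraphML", {
  net <- structure(list(
    edges = data.frame(tf = c("a", "a"), target = c("x", "y"),
                       n_crms = c(1L, 2L), crm_ids = c("P1", "P2,P3")),
    cascade = data.frame(stage = "enriched_motifs", n_instances = 3L,
                         n_genes = 2L)), class = "regulatory_network")
  tsv <- tempfile(fileext = ".tsv")
  write_network(net, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$target, c("x", "y"))
  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
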