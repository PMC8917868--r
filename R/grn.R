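## The target-filtering cascade: percentile filters on chromatin signal,
## expression filters on RNA metaclusters, network assembly from enriched
## motif instances, unchanging-gene equivalence testing, FPR/FDR estimation,
## CRM effect scoring, spatial regulator classification, and a circular-
## shift permutation test for region-set overlap.

#' Retain DNA metaclusters by a ChIP-signal percentile rule
#'
#' The mean RPKM of `experiment` is computed per DNA metacluster over its
#' member regions; metaclusters whose mean is at or above the requested
#' percentile (linear-interpolation definition) of the per-metacluster
#' means are retained.
#'
#' @param region_mc Data.frame `item` (region id) -> `metacluster`.
#' @param signal Regions x experiments RPKM matrix (row names = region ids).
#' @param experiment Column name or index.
#' @param percentile Percentile in `[0, 100)` (default 75).
#' @return Integer vector of retained metacluster labels.  Metaclusters
#'   with no regions present in the matrix are excluded with a warning.
#' @export
chip_percentile_filter <- function(region_mc, signal, experiment,
                                   percentile = 75) {
  if (is.character(experiment) && !(experiment %in% colnames(signal)))
    stopf("experiment '%s' not in signal matrix", experiment)
  vals <- signal[, experiment]
  names(vals) <- rownames(signal)
  mcs <- sort(unique(region_mc$metacluster))
  means <- vapply(mcs, function(g) {
    items <- intersect(region_mc$item[region_mc$metacluster == g],
                       rownames(signal))
    if (!length(items)) return(NA_real_)
    mean(vals[items])
  }, 0)
  if (anyNA(means)) {
    warnf("%d metacluster(s) had no regions in the signal matrix; excluded",
          sum(is.na(means)))
    mcs <- mcs[!is.na(means)]
    means <- means[!is.na(means)]
  }
  cut <- quantile(means, percentile / 100, type = 7, names = FALSE)
  mcs[means >= cut]
}

#' Retain RNA metaclusters expressed above a TPM floor
#'
#' A metacluster is retained when its mean member TPM exceeds `min_tpm` in
#' at least one of the listed stage columns.
#'
#' @param gene_mc Data.frame `item` (gene id) -> `metacluster`.
#' @param tpm Genes x experiments TPM matrix.
#' @param stage_columns Column names (or indices) of the stages to test.
#' @param min_tpm Strict lower bound (default 1).
#' @return Integer vector of retained metacluster labels.
#' @export
expression_filter <- function(gene_mc, tpm, stage_columns, min_tpm = 1) {
  mcs <- sort(unique(gene_mc$metacluster))
  keep <- vapply(mcs, function(g) {
    items <- intersect(gene_mc$item[gene_mc$metacluster == g], rownames(tpm))
    if (!length(items)) return(FALSE)
    prof <- colMeans(tpm[items, stage_columns, drop = FALSE])
    any(prof > min_tpm)
  }, TRUE)
  mcs[keep]
}

#' Retain DNA metaclusters with enriched Ep300 signal
#'
#' Identical percentile rule to [chip_percentile_filter()], applied to the
#' Ep300 experiment column.
#'
#' @inheritParams chip_percentile_filter
#' @param ep300_experiment Column of the Ep300 experiment.
#' @export
ep300_filter <- function(region_mc, signal, ep300_experiment, percentile = 75) {
  chip_percentile_filter(region_mc, signal, ep300_experiment, percentile)
}

#' Assemble the TF -> target network from enriched motif instances
#'
#' Implements the filtering cascade: a motif instance survives when its
#' region's DNA metacluster passed both the TF-ChIP percentile filter (for
#' that motif's TF) and the Ep300 filter, and its region's nearest gene
#' lies in an RNA metacluster passing the expression filter; surviving
#' instances are then restricted to genes on the gastrulation list and
#' finally to the TF/growth-factor list.  One edge is emitted per
#' (TF, target) with its supporting CRMs; counts are reported at every
#' cascade stage.
#'
#' @param enriched_hits Named list (motif/TF id -> hits data.frame with a
#'   `region_id` column; typically q-filtered, density-enriched instances).
#' @param lm_map An `lm_map` (provides region -> gene and metacluster bins).
#' @param dna_mc_retained Named list (TF id -> integer labels from
#'   [chip_percentile_filter()]).
#' @param ep300_retained Integer labels from [ep300_filter()].
#' @param rna_mc_retained Integer labels from [expression_filter()].
#' @param gastrulation_genes,tf_genes Character vectors of gene ids.
#' @return A `regulatory_network`: `edges` (data.frame `tf`, `target`,
#'   `n_crms`, `crm_ids`), `instances` (surviving motif instances with
#'   provenance flags), `cascade` (data.frame of per-stage motif and gene
#'   counts).
#' @export
assemble_network <- function(enriched_hits, lm_map, dna_mc_retained,
                             ep300_retained, rna_mc_retained,
                             gastrulation_genes, tf_genes) {
  pairs <- lm_map$pairs
  gene_of <- setNames(pairs$gene_id, pairs$region_id)
  rna_of <- setNames(pairs$rna_mc, pairs$region_id)
  dna_of <- setNames(pairs$dna_mc, pairs$region_id)

  inst <- list()
  for (tf in names(enriched_hits)) {
    h <- enriched_hits[[tf]]
    if (!nrow(h)) next
    inst[[tf]] <- data.frame(tf = tf, region_id = h$region_id,
                             stringsAsFactors = FALSE)
  }
  inst <- if (length(inst)) do.call(rbind, inst) else
    data.frame(tf = character(), region_id = character())
  unknown <- setdiff(unique(inst$region_id), names(gene_of))
  if (length(unknown))
    stopf("integrity error at network assembly: %d motif region(s) missing from the LM map",
          length(unknown))
  inst$gene_id <- gene_of[inst$region_id]

  cascade <- list()
  note <- function(stage, d) {
    cascade[[length(cascade) + 1L]] <<- data.frame(
      stage = stage, n_instances = nrow(d),
      n_genes = length(unique(d$gene_id)), stringsAsFactors = FALSE)
  }
  note("enriched_motifs", inst)

  keep_chip <- vapply(seq_len(nrow(inst)), function(i) {
    ret <- dna_mc_retained[[inst$tf[i]]]
    !is.null(ret) && dna_of[[inst$region_id[i]]] %in% ret
  }, TRUE)
  keep_expr <- rna_of[inst$region_id] %in% rna_mc_retained
  inst1 <- inst[keep_chip & keep_expr, , drop = FALSE]
  note("chip_and_expression", inst1)

  keep_ep <- dna_of[inst1$region_id] %in% ep300_retained
  inst2 <- inst1[keep_ep, , drop = FALSE]
  note("ep300", inst2)

  inst3 <- inst2[inst2$gene_id %in% gastrulation_genes, , drop = FALSE]
  note("gastrulation_list", inst3)

  inst4 <- inst3[inst3$gene_id %in% tf_genes, , drop = FALSE]
  note("tf_growthfactor_list", inst4)

  edges <- if (nrow(inst4)) {
    agg <- aggregate(region_id ~ tf + gene_id, data = inst4,
                     FUN = function(x) length(unique(x)))
    crms <- aggregate(region_id ~ tf + gene_id, data = inst4,
                      FUN = function(x) paste(sort(unique(x)), collapse = ","))
    data.frame(tf = agg$tf, target = agg$gene_id, n_crms = agg$region_id,
               crm_ids = crms$region_id, stringsAsFactors = FALSE)
  } else {
    data.frame(tf = character(), target = character(),
               n_crms = integer(), crm_ids = character())
  }
  structure(list(edges = edges, instances = inst4,
                 cascade = do.call(rbind, cascade)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d edges, %d TFs, %d targets\n",
              nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$target))))
  print(x$cascade, row.names = FALSE)
  invisible(x)
}

#' Compare a network against planted truth
#'
#' @param network A `regulatory_network`.
#' @param grn A `planted_grn`.
#' @return List with `recall`, `precision`, `n_true`, `n_predicted`,
#'   `n_correct`.
#' @export
evaluate_network <- function(network, grn) {
  truth <- paste(grn$edges$tf, grn$edges$target)
  pred <- paste(network$edges$tf, network$edges$target)
  n_correct <- length(intersect(truth, pred))
  list(recall = if (length(truth)) n_correct / length(truth) else NA,
       precision = if (length(pred)) n_correct / length(pred) else NA,
       n_true = length(truth), n_predicted = length(pred),
       n_correct = n_correct)
}

#' Equivalence test for unchanging genes (TOST)
#'
#' Tests, per gene, that `|log2 fold change|` between MO and control
#' replicates is below `lfc_threshold`, using two one-sided normal tests.
#' The SE combines an empirical-Bayes moderated replicate variance
#' ([limma::squeezeVar] pooling information across genes, essential at 2-3
#' replicates) with a small-count stabilizer added in quadrature; the TOST
#' p-value is the larger of the two one-sided p-values, BH-corrected across
#' genes.  A gene is called unchanging when `q < 0.05`.
#'
#' @param mo,control Genes x replicates matrices (TPM scale, same genes).
#' @param lfc_threshold Equivalence bound on the log2 scale (default 0.5).
#' @param stabilizer Added in quadrature to the SE (default 0.05), keeping
#'   zero-variance genes testable.
#' @return Data.frame: `gene_id`, `lfc`, `se`, `p`, `q`, `unchanging`,
#'   `degenerate` (zero observed variance).
#' @export
unchanging_test <- function(mo, control, lfc_threshold = 0.5,
                            stabilizer = 0.05) {
  if (ncol(mo) < 2 || ncol(control) < 2)
    stopf("need >= 2 replicates per arm")
  lmo <- log2(as.matrix(mo) + 1)
  lct <- log2(as.matrix(control) + 1)
  n1 <- ncol(lmo); n2 <- ncol(lct)
  lfc <- rowMeans(lmo) - rowMeans(lct)
  df <- n1 + n2 - 2
  s2 <- (apply(lmo, 1, stats::var) * (n1 - 1) +
           apply(lct, 1, stats::var) * (n2 - 1)) / df
  degenerate <- s2 == 0
  s2_mod <- if (length(s2) >= 3 && any(s2 > 0)) {
    limma::squeezeVar(s2, df)$var.post
  } else {
    s2
  }
  v <- s2_mod * (1 / n1 + 1 / n2)
  se <- sqrt(v + stabilizer^2)
  p_upper <- pnorm((lfc - lfc_threshold) / se)           # H0: lfc >= thr
  p_lower <- pnorm(-(lfc + lfc_threshold) / se)          # H0: lfc <= -thr
  p <- pmax(p_upper, p_lower)
  q <- bh_qvalues(p)
  data.frame(gene_id = rownames(lmo) %||% as.character(seq_along(lfc)),
             lfc = lfc, se = se, p = p, q = q,
             unchanging = q < 0.05, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect unchanging-gene calls across conditions
#'
#' A gene enters the true-negative set only if it was called unchanging in
#' every condition.
#'
#' @param calls List of character vectors (or of [unchanging_test()]
#'   results) of unchanging gene ids, one per condition.
#' @return Sorted character vector of gene ids.
#' @export
true_negative_set <- function(calls) {
  if (!length(calls)) stopf("need at least one condition")
  sets <- lapply(calls, function(x) {
    if (is.data.frame(x)) x$gene_id[x$unchanging] else as.character(x)
  })
  sort(Reduce(intersect, sets))
}

#' False positive and false discovery rates against a true-negative set
#'
#' `FPR = 100 * |TN intersect P| / |TN|`;
#' `FDR = 100 * |TN intersect P| / |P|` (both in percent).
#'
#' @param predicted Character vector of predicted target gene ids.
#' @param true_negatives Character vector of likely-true-negative gene ids.
#' @return List with `fpr_percent`, `fdr_percent`, `n_overlap`,
#'   `n_true_negatives`, `n_predicted`.
#' @export
fpr_fdr <- function(predicted, true_negatives) {
  if (!length(true_negatives)) stopf("true-negative set is empty: FPR undefined")
  ov <- length(intersect(unique(predicted), unique(true_negatives)))
  list(fpr_percent = 100 * ov / length(unique(true_negatives)),
       fdr_percent = if (length(predicted))
         100 * ov / length(unique(predicted)) else NA_real_,
       n_overlap = ov,
       n_true_negatives = length(unique(true_negatives)),
       n_predicted = length(unique(predicted)))
}

#' Six-method CRM effect scorecard
#'
#' Per CRM, each component score is the mean RPKM over the experiment
#' columns of its group over the CRM's partitions; the combined score is
#' the arithmetic mean of the five component scores.
#'
#' @param crm_regions Named list (CRM id -> character vector of partition
#'   region ids).
#' @param signal Regions x experiments RPKM matrix.
#' @param groups Named list with elements `h3k4me1`, `h3k27ac`, `ep300`,
#'   `tf_signal_density`, `chromatin_accessibility`, each a non-empty
#'   vector of experiment columns.
#' @return Data.frame: `crm_id`, the five component scores, `combined`.
#' @export
crm_effect_scores <- function(crm_regions, signal, groups) {
  need <- c("h3k4me1", "h3k27ac", "ep300", "tf_signal_density",
            "chromatin_accessibility")
  if (!all(need %in% names(groups)))
    stopf("groups must name: %s", paste(need, collapse = ", "))
  if (any(!lengths(groups[need]))) stopf("empty experiment group")
  rows <- lapply(names(crm_regions), function(crm) {
    regs <- intersect(crm_regions[[crm]], rownames(signal))
    comp <- vapply(need, function(g) {
      if (!length(regs)) return(0)
      mean(signal[regs, groups[[g]], drop = FALSE])
    }, 0)
    data.frame(crm_id = crm, t(comp), combined = mean(comp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank agreement of CRM scoring methods with observed effects
#'
#' Spearman correlation of each score column with the observed effect
#' magnitudes; methods ranked by correlation.
#'
#' @param scorecard Data.frame from [crm_effect_scores()].
#' @param observed Named numeric vector of observed effects per `crm_id`
#'   (magnitudes are taken internally).
#' @return Data.frame `method`, `rho`, `rank` (NA correlation for constant
#'   scores, flagged), ordered best-first.
#' @export
score_validation_agreement <- function(scorecard, observed) {
  shared <- intersect(scorecard$crm_id, names(observed))
  if (length(shared) < 3) stopf("need >= 3 CRMs with observed effects")
  obs <- abs(observed[shared])
  sc <- scorecard[match(shared, scorecard$crm_id), , drop = FALSE]
  methods <- setdiff(names(sc), "crm_id")
  rho <- vapply(methods, function(m) {
    x <- sc[[m]]
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(cor(x, obs, method = "spearman"))
  }, 0)
  out <- data.frame(method = methods, rho = rho, row.names = NULL)
  out$rank <- rank(-out$rho, ties.method = "min", na.last = "keep")
  out[order(out$rank), ]
}

#' Classify a TF as spatial activator or repressor
#'
#' Pearson correlation of the TF's spatial expression profile with the mean
#' spatial profile of its predicted targets; positive correlation labels an
#' activator, negative a repressor.  The label is only reported when the
#' TF's own spatial differential test is significant (`significant_q`
#' below `q_threshold`); otherwise the label is `"not_significant"`.
#'
#' @param tf_profile Numeric vector over ordered tissue columns (length
#'   >= 3).
#' @param target_profiles Matrix (targets x tissues) of predicted-target
#'   spatial profiles.
#' @param significant_q The TF's spatial differential q-value (default 0,
#'   i.e. significant).
#' @param q_threshold Significance threshold (default 0.05).
#' @return List with `correlation` and `label` ("activator", "repressor",
#'   "not_significant", or "undefined" for zero-variance profiles).
#' @export
spatial_regulator_classification <- function(tf_profile, target_profiles,
                                             significant_q = 0,
                                             q_threshold = 0.05) {
  if (length(tf_profile) < 3) stopf("profiles must cover >= 3 tissues")
  target_mean <- colMeans(rbind(target_profiles))
  if (length(target_mean) != length(tf_profile))
    stopf("profiles must cover the same ordered tissue columns")
  if (sd(tf_profile) == 0 || sd(target_mean) == 0)
    return(list(correlation = NA_real_, label = "undefined"))
  r <- cor(tf_profile, target_mean)
  label <- if (significant_q >= q_threshold) "not_significant"
    else if (r > 0) "activator" else if (r < 0) "repressor" else "undefined"
  list(correlation = r, label = label)
}

#' Permutation test for region-set overlap by circular shifts
#'
#' The observed statistic is the number of predicted regions overlapping at
#' least one holdout peak.  Under the null, predicted regions are circularly
#' shifted per chromosome by a uniform offset (with wrap-around past the
#' chromosome end) and the statistic recomputed;
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param predicted,holdout `GRanges`.
#' @param seqlengths Named chromosome lengths (required for wrapping).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `observed`, `p`, `null` (the permuted statistics).
#' @export
region_overlap_permutation <- function(predicted, holdout, seqlengths,
                                       n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  observed <- sum(GenomicRanges::countOverlaps(predicted, holdout) > 0)
  chrom <- as.character(GenomicRanges::seqnames(predicted))
  st <- GenomicRanges::start(predicted)
  en <- GenomicRanges::end(predicted)
  null <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pieces <- list()
      for (ch in unique(chrom)) {
        L <- seqlengths[[ch]]
        idx <- chrom == ch
        off <- floor(runif(1, 0, L))
        s2 <- (st[idx] - 1 + off) %% L + 1
        e2 <- s2 + (en[idx] - st[idx])
        wrap <- e2 > L
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = ch,
          start = c(s2, rep(1, sum(wrap))),
          end = c(pmin(e2, L), (e2 - L)[wrap]),
          piece = paste0(ch, "_", c(seq_len(sum(idx)), which(wrap))))
      }
      df <- do.call(rbind, pieces)
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start, df$end))
      hit <- GenomicRanges::countOverlaps(gr, holdout) > 0
      length(unique(df$piece[hit]))
    }, 0)
  })
  list(observed = observed, p = (1 + sum(null >= observed)) / (n_perm + 1),
       null = null)
}

#' Export a regulatory network
#'
#' @param network A `regulatory_network`.
#' @param path Output path; format by extension: `.tsv` (edge list) or
#'   `.graphml`.
#' @export
write_network <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("tf", "target", "n_crms")], directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write.table(network$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
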