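## Synthetic multi-omic bundle with a planted gene regulatory network:
## a small random genome with non-overlapping gene models, planted TF
## binding sites inside cis-regulatory modules (CRMs), decoy CRMs carrying
## motif-knockout substitutions, chromatin peaks/reads drawn from discrete
## chromatin-state signatures, and a TPM expression matrix with temporal
## modules, tissue offsets and morpholino knockdown pairs.

#' Built-in transcription-factor motif models
#'
#' Each planted TF carries a full-length IUPAC binding-site consensus whose
#' core is a published reporter-mutagenesis motif, together with the
#' knockout substitution of that core used for decoy CRMs
#' (AATMHACA -> AAGMHAAA for the forkhead core, ACAAWRG -> ATAGWRG for the
#' Sox core; additional TFs use a transition substitution at core positions
#' 2 and 4).
#'
#' @param n Number of TFs requested.
#' @param seed Seed for consensi beyond the built-in three.
#' @return Data.frame: `tf`, `consensus`, `core`, `core_knockout`,
#'   `consensus_knockout`.
#' @export
tf_motif_table <- function(n, seed = 1L) {
  builtin <- data.frame(
    tf = c("foxh1", "sox17", "vegt"),
    consensus = c("GTAATMHACAG", "TACAAWRGAC", "CAGGTGTGAA"),
    core = c("AATMHACA", "ACAAWRG", "AGGTGTGA"),
    core_knockout = c("AAGMHAAA", "ATAGWRG", "AAGCGTGA"),
    stringsAsFactors = FALSE)
  if (n > nrow(builtin)) {
    extra <- local_seed(derive_seed(seed, 991L), {
      lapply(seq_len(n - nrow(builtin)), function(i) {
        core <- paste(sample(DNA_BASES, 8, replace = TRUE), collapse = "")
        data.frame(tf = sprintf("tf%02d", i + nrow(builtin)),
                   consensus = paste0("G", core, "C"),
                   core = core,
                   core_knockout = transition_knockout(core),
                   stringsAsFactors = FALSE)
      })
    })
    builtin <- rbind(builtin, do.call(rbind, extra))
  }
  out <- builtin[seq_len(n), , drop = FALSE]
  out$consensus_knockout <- mapply(function(cons, core, ko)
    sub(core, ko, cons, fixed = TRUE), out$consensus, out$core,
    out$core_knockout, USE.NAMES = FALSE)
  out
}

## transition substitution (A<->G, C<->T) at positions 2 and 4, mirroring
## the two-point published knockouts
transition_knockout <- function(core) {
  map <- c(A = "G", G = "A", C = "T", T = "C")
  ch <- strsplit(core, "")[[1]]
  for (pos in c(2L, 4L)) if (pos <= length(ch) && ch[pos] %in% names(map))
    ch[pos] <- map[[ch[pos]]]
  paste(ch, collapse = "")
}

#' Default chromatin-state signatures
#'
#' Mean RPKM per chromatin experiment for each simulated state.  The key
#' `tf_chip` stands for the ChIP experiment of the region's owning TF (other
#' TFs' ChIP columns get the `baseline` level).
#'
#' @param baseline Background RPKM for unmarked experiments.
#' @return Named list of named numeric signature vectors.
#' @export
default_chromatin_states <- function(baseline = 0.2) {
  base <- c(tf_chip = baseline, h3k4me1 = baseline, h3k4me3 = baseline,
            h3k27ac = baseline, h3k27me3 = baseline, h3k36me3 = baseline,
            h3k9me3 = baseline, ep300 = baseline, atac = baseline)
  upd <- function(...) { v <- base; a <- c(...); v[names(a)] <- a; v }
  list(
    active_enhancer = upd(tf_chip = 12, h3k4me1 = 8, h3k27ac = 10,
                          ep300 = 10, atac = 8),
    poised_enhancer = upd(tf_chip = 3, h3k4me1 = 8, h3k27me3 = 6,
                          ep300 = 0.5, atac = 1),
    promoter = upd(h3k4me3 = 10, h3k27ac = 6, ep300 = 2, atac = 10),
    transcribed = upd(h3k36me3 = 8),
    polycomb = upd(h3k27me3 = 8),
    primed = upd(h3k4me1 = 6, atac = 2),
    heterochromatin = upd(h3k9me3 = 8))
}

#' Configuration of the synthetic bundle
#'
#' Defaults define the study conditions of the simulated experiment: a
#' two-chromosome 1.5 Mb genome with 100 genes, a planted network of 3 TFs
#' with 20 targets each, five temporal expression modules, six stages, four
#' dissected tissues, one morpholino knockdown per TF, log-normal
#' multiplicative noise with log2-scale SD 0.25, and the chromatin states of
#' [default_chromatin_states()].
#'
#' @param seed Master seed; every generated artifact is a deterministic
#'   function of it.
#' @param n_chromosomes,chromosome_length Genome shape.
#' @param n_genes Total genes (non-overlapping).
#' @param n_tfs,targets_per_tf Planted network size.
#' @param n_expression_modules Temporal modules; must exceed `n_tfs` (each
#'   TF's targets share one module; the last module is a low-expression
#'   module below the 1 TPM filter).
#' @param stages,tissues Column labels of the temporal / spatial design.
#' @param perturbations Data.frame (`tf`, `stage`) of MO designs; default
#'   one knockdown per TF at the fourth stage.
#' @param knockdown_factor Multiplier applied to target means in MO columns.
#' @param noise_sd Log2-scale SD of the multiplicative log-normal noise.
#' @param chromatin_states Named list of signature vectors.
#' @param gene_length,min_gene_gap Gene placement geometry (bp).
#' @param crm_length CRM width in bp.
#' @param crm_min_dist,crm_max_dist CRM-to-TSS distance window (bp); actual
#'   placement also stays within 45% of the gap to the neighbouring TSS so
#'   that nearest-TSS linking is well defined for the planted truth.
#' @param n_decoys_per_tf Decoy CRMs per TF (knockout motif, active state).
#' @param n_background_regions Peak regions without planted motifs.
#' @param motif_instances_per_crm Planted sites per true CRM.
#' @param active_state_fraction Fraction of true CRMs in the active-enhancer
#'   state (the rest are poised and invisible to the Ep300 filter).
#' @param total_mapped Nominal mapped reads per chromatin experiment.
#' @param peak_min_rpkm Expected RPKM at or above which a region emits a
#'   peak call in an experiment.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chromosome_length = 750000L,
                             n_genes = 100L,
                             n_tfs = 3L,
                             targets_per_tf = 20L,
                             n_expression_modules = 5L,
                             stages = c("st8", "st9", "st10", "st10.5", "st11", "st12"),
                             tissues = c("whole_embryo", "animal_cap",
                                         "marginal_zone", "vegetal_pole"),
                             perturbations = NULL,
                             knockdown_factor = 0.25,
                             noise_sd = 0.25,
                             chromatin_states = default_chromatin_states(),
                             gene_length = 2000L,
                             min_gene_gap = 4000L,
                             crm_length = 240L,
                             crm_min_dist = 1000L,
                             crm_max_dist = 50000L,
                             n_decoys_per_tf = 5L,
                             n_background_regions = 200L,
                             motif_instances_per_crm = 2L,
                             active_state_fraction = 0.85,
                             total_mapped = 2e7,
                             peak_min_rpkm = 1) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (n_tfs > n_genes) stopf("n_tfs must not exceed n_genes")
  if (length(stages) < 2) stopf("need at least two stages")
  if (n_expression_modules <= n_tfs)
    stopf("n_expression_modules must exceed n_tfs")
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  if (is.null(cfg$perturbations)) {
    tfs <- tf_motif_table(n_tfs, seed)$tf
    cfg$perturbations <- data.frame(tf = tfs,
                                    stage = stages[min(4L, length(stages))],
                                    stringsAsFactors = FALSE)
  }
  cfg
}

#' Generate a random genome with non-overlapping gene models
#'
#' Sequence is i.i.d. uniform over ACGT (before motif planting).  Genes of
#' `gene_length` bp are placed in equal slots per chromosome with seeded
#' jitter, guaranteeing non-overlap and a minimum gap; TSS is the 5' gene
#' end by strand.
#'
#' @param config A [synthetic_config()].
#' @return List: `genome` ([Biostrings::DNAStringSet]) and `genes`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`, `tss`, `strand`).
#' @export
generate_genome <- function(config) {
  if (config$chromosome_length < 10000) stopf("chromosome_length must be >= 10,000")
  if (config$n_genes < 2) stopf("n_genes must be >= 2")
  local_seed(derive_seed(config$seed, 1L), {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    seqs <- vapply(chroms, function(ch)
      paste(sample(DNA_BASES, config$chromosome_length, replace = TRUE),
            collapse = ""), "")
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms

    per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
    rows <- list()
    gi <- 0L
    for (ci in seq_along(chroms)) {
      n_c <- per[ci]
      if (!n_c) next
      slot <- config$chromosome_length / n_c
      if (slot < config$gene_length + config$min_gene_gap)
        stopf("genes cannot be placed without overlap: %d genes of %d bp (+%d bp gap) exceed chromosome length %d",
              n_c, config$gene_length, config$min_gene_gap,
              config$chromosome_length)
      jitter_max <- slot - config$gene_length - config$min_gene_gap
      for (j in seq_len(n_c)) {
        gi <- gi + 1L
        start <- floor((j - 1) * slot) + 1L +
          floor(runif(1, 0, max(jitter_max, 1)))
        end <- start + config$gene_length - 1L
        strand <- sample(c("+", "-"), 1)
        rows[[gi]] <- data.frame(
          gene_id = sprintf("gene%03d", gi), chrom = chroms[ci],
          start = start, end = end,
          tss = if (strand == "+") start else end,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    list(genome = genome, genes = do.call(rbind, rows))
  })
}

#' Plant a ground-truth regulatory network over gene models
#'
#' Assigns each TF a binding-site consensus ([tf_motif_table()]), draws
#' disjoint target sets, places one CRM per target 1-50 kb from its TSS
#' (bounded by 45% of the gap to the neighbouring TSS so the target is the
#' CRM's nearest gene), assigns chromatin states (active enhancer with
#' probability `active_state_fraction`, otherwise poised), and adds decoy
#' CRMs (knockout consensus, active state) near non-target genes plus
#' unowned background regions in primed / heterochromatic states.
#'
#' @param config A [synthetic_config()].
#' @param genes Gene models from [generate_genome()].
#' @return A `planted_grn` list: `tfs`, `edges`, `regions` (all CRMs,
#'   decoys, background with intervals and states), `modules` (gene ->
#'   expression module).
#' @export
generate_planted_grn <- function(config, genes) {
  if (config$n_tfs < 1) stopf("n_tfs must be >= 1")
  if (config$targets_per_tf < 1) stopf("targets_per_tf must be >= 1")
  n_targets <- config$n_tfs * config$targets_per_tf
  if (n_targets + config$n_tfs > nrow(genes))
    stopf("more targets requested (%d) than genes available (%d)",
          n_targets + config$n_tfs, nrow(genes))
  tfs <- tf_motif_table(config$n_tfs, config$seed)
  local_seed(derive_seed(config$seed, 2L), {
    ids <- genes$gene_id
    tf_gene_ids <- sample(ids, config$n_tfs)
    tfs$gene_id <- tf_gene_ids
    tfs$chip_experiment <- paste0("chip_", tfs$tf)
    remaining <- setdiff(ids, tf_gene_ids)
    target_ids <- sample(remaining, n_targets)
    remaining <- setdiff(remaining, target_ids)

    region_rows <- list()
    edge_rows <- list()
    rid <- 0L
    used <- GenomicRanges::GRanges()
    place <- function(gene_id, kind, tf, state) {
      g <- genes[genes$gene_id == gene_id, ]
      iv <- place_crm(config, genes, g)
      rid <<- rid + 1L
      crm_id <- sprintf("crm%03d", rid)
      region_rows[[rid]] <<- data.frame(
        crm_id = crm_id, chrom = g$chrom, start = iv[1], end = iv[2],
        kind = kind, tf = tf, gene_id = gene_id, state = state,
        stringsAsFactors = FALSE)
      crm_id
    }
    for (t in seq_len(config$n_tfs)) {
      tg <- target_ids[((t - 1) * config$targets_per_tf + 1):(t * config$targets_per_tf)]
      for (g in tg) {
        state <- if (runif(1) < config$active_state_fraction)
          "active_enhancer" else "poised_enhancer"
        crm_id <- place(g, "crm", tfs$tf[t], state)
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          tf = tfs$tf[t], tf_gene_id = tfs$gene_id[t], target = g,
          crm_id = crm_id, consensus = tfs$consensus[t], state = state,
          stringsAsFactors = FALSE)
      }
    }
    decoy_genes <- sample(remaining,
                          min(config$n_tfs * config$n_decoys_per_tf,
                              length(remaining)))
    di <- 0L
    for (t in seq_len(config$n_tfs)) {
      for (j in seq_len(config$n_decoys_per_tf)) {
        di <- di + 1L
        if (di > length(decoy_genes)) break
        place(decoy_genes[di], "decoy", tfs$tf[t], "active_enhancer")
      }
    }
    ## background regions: random peak-like intervals away from planted
    ## CRMs, cycling through the non-enhancer chromatin states
    bg_states <- setdiff(names(config$chromatin_states),
                         c("active_enhancer", "poised_enhancer"))
    if (!length(bg_states)) bg_states <- names(config$chromatin_states)
    existing <- do.call(rbind, region_rows)
    for (b in seq_len(config$n_background_regions)) {
      repeat {
        ch <- sample(names_chroms(config), 1)
        st <- floor(runif(1, 1, config$chromosome_length - config$crm_length))
        en <- st + config$crm_length - 1L
        clash <- any(existing$chrom == ch & existing$start <= en &
                       existing$end >= st)
        if (!clash) break
      }
      rid <- rid + 1L
      state <- bg_states[1L + (b - 1L) %% length(bg_states)]
      region_rows[[rid]] <- data.frame(
        crm_id = sprintf("crm%03d", rid), chrom = ch, start = st, end = en,
        kind = "background", tf = NA_character_, gene_id = NA_character_,
        state = state, stringsAsFactors = FALSE)
      existing <- rbind(existing, region_rows[[rid]])
    }
    regions <- do.call(rbind, region_rows)
    bad_state <- setdiff(unique(regions$state), names(config$chromatin_states))
    if (length(bad_state))
      stopf("state signature missing for: %s", paste(bad_state, collapse = ", "))

    ## expression modules: TF t's targets -> module t; the last module is a
    ## low-expression module; everything else spread over the rest
    n_mod <- config$n_expression_modules
    modules <- setNames(integer(nrow(genes)), genes$gene_id)
    for (t in seq_len(config$n_tfs)) {
      tg <- target_ids[((t - 1) * config$targets_per_tf + 1):(t * config$targets_per_tf)]
      modules[tg] <- t
    }
    modules[tf_gene_ids] <- min(config$n_tfs + 1L, n_mod - 1L)
    rest <- names(modules)[modules == 0L]
    modules[rest] <- sample(seq(config$n_tfs + 1L, n_mod), length(rest),
                            replace = TRUE)
    edges <- do.call(rbind, edge_rows)
    check_crm_distance(edges, regions, genes)
    structure(list(tfs = tfs, edges = edges, regions = regions,
                   modules = modules),
              class = "planted_grn")
  })
}

names_chroms <- function(config) sprintf("chr%d", seq_len(config$n_chromosomes))

## CRM interval near a gene's TSS, bounded so the target stays the nearest
## TSS; returns c(start, end), 1-based closed
place_crm <- function(config, genes, g) {
  same <- genes[genes$chrom == g$chrom, ]
  left_gap <- g$tss - max(c(0, same$tss[same$tss < g$tss]))
  right_gap <- min(c(config$chromosome_length + 1, same$tss[same$tss > g$tss])) - g$tss
  side <- if (left_gap > right_gap) -1 else 1
  room <- max(left_gap, right_gap)
  d_hi <- min(config$crm_max_dist, floor(0.45 * room))
  d_lo <- min(config$crm_min_dist, max(d_hi - 1, 1))
  d <- floor(runif(1, d_lo, max(d_hi, d_lo + 1)))
  center <- g$tss + side * d
  half <- config$crm_length %/% 2L
  st <- max(1L, center - half)
  en <- st + config$crm_length - 1L
  if (en > config$chromosome_length) {
    en <- config$chromosome_length
    st <- en - config$crm_length + 1L
  }
  c(st, en)
}

check_crm_distance <- function(edges, regions, genes) {
  for (i in seq_len(nrow(edges))) {
    r <- regions[regions$crm_id == edges$crm_id[i], ]
    tss <- genes$tss[genes$gene_id == edges$target[i]]
    mid <- floor((r$start + r$end) / 2)
    if (abs(mid - tss) > 1e6)
      stopf("internal error: CRM %s is > 1 Mb from its target TSS", r$crm_id)
  }
  invisible(TRUE)
}

#' Plant motif instances into the genome sequence
#'
#' Each true CRM receives `motif_instances_per_crm` exact realizations of
#' its TF's IUPAC consensus at non-overlapping offsets and random strands;
#' a `negative_fraction` of decoy CRMs receive the knockout-substituted
#' variant instead (remaining decoys are left unplanted).  The truth table
#' records every planted offset, strand and realized sequence.
#'
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param grn A `planted_grn`.
#' @param config A [synthetic_config()].
#' @param negative_fraction Fraction of decoy CRMs that carry the knockout
#'   variant (default 1).
#' @return List: `genome` (modified sequence) and `sites` (truth table:
#'   `crm_id`, `tf`, `kind`, `chrom`, `start`, `offset`, `strand`, `seq`).
#' @export
plant_motif_instances <- function(genome, grn, config, negative_fraction = 1) {
  seqs <- as.character(genome)
  local_seed(derive_seed(config$seed, 3L), {
    sites <- list()
    plant_one <- function(region, consensus, kind, n_inst) {
      L <- region$end - region$start + 1L
      w <- nchar(consensus)
      if (w > L) stopf("consensus %s (%d bp) longer than CRM %s (%d bp)",
                       consensus, w, region$crm_id, L)
      taken <- integer(0)
      for (inst in seq_len(n_inst)) {
        for (try in 1:50) {
          off <- floor(runif(1, 0, L - w + 1))
          if (!any(abs(taken - off) < w)) break
        }
        taken <- c(taken, off)
        realization <- paste(vapply(strsplit(consensus, "")[[1]], function(cd)
          sample(IUPAC_SETS[[cd]], 1), ""), collapse = "")
        strand <- sample(c("+", "-"), 1)
        inserted <- if (strand == "+") realization else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(realization)))
        pos <- region$start + off
        substr(seqs[[region$chrom]], pos, pos + w - 1L) <<- inserted
        sites[[length(sites) + 1L]] <<- data.frame(
          crm_id = region$crm_id, tf = region$tf, kind = kind,
          chrom = region$chrom, start = pos, offset = off, strand = strand,
          seq = realization, stringsAsFactors = FALSE)
      }
    }
    cons_of <- setNames(grn$tfs$consensus, grn$tfs$tf)
    ko_of <- setNames(grn$tfs$consensus_knockout, grn$tfs$tf)
    for (i in which(grn$regions$kind == "crm")) {
      r <- grn$regions[i, ]
      plant_one(r, cons_of[[r$tf]], "true", config$motif_instances_per_crm)
    }
    decoys <- which(grn$regions$kind == "decoy")
    n_neg <- round(negative_fraction * length(decoys))
    for (i in head(decoys, n_neg)) {
      r <- grn$regions[i, ]
      plant_one(r, ko_of[[r$tf]], "decoy", config$motif_instances_per_crm)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(genome)
    list(genome = out,
         sites = if (length(sites)) do.call(rbind, sites) else
           data.frame(crm_id = character(), tf = character(),
                      kind = character(), chrom = character(),
                      start = integer(), offset = integer(),
                      strand = character(), seq = character()))
  })
}

#' Generate the TPM expression matrix
#'
#' Each expression module has a smooth temporal mean profile (a Gaussian
#' bump over stage order; the last module is flat at 0.3 TPM); tissue
#' columns multiply the stage-10.5 mean by planted module-specific spatial
#' offsets; each MO column multiplies the means of the perturbed TF's
#' targets by `knockdown_factor`, with a paired control column.  Observed
#' TPM = mean * 2^Normal(0, noise_sd).
#'
#' @param config A [synthetic_config()].
#' @param grn A `planted_grn` (target/module structure, perturbation truth).
#' @return List: `tpm` (genes x experiments matrix), `metadata` (data.frame
#'   per experiment: `experiment`, `type`, `stage`, `tissue`,
#'   `perturbed_tf`, `pair`), `mean_tpm` (noise-free truth).
#' @export
generate_expression_matrix <- function(config, grn) {
  bad <- setdiff(config$perturbations$tf, grn$tfs$tf)
  if (length(bad)) stopf("perturbation names unknown TF(s): %s",
                         paste(bad, collapse = ", "))
  genes <- names(grn$modules)
  n_mod <- config$n_expression_modules
  n_stage <- length(config$stages)

  ## module temporal profiles: bump of amplitude 30 on a baseline of 2;
  ## the last module is constitutively low (0.3 TPM)
  stage_pos <- seq_len(n_stage)
  prof <- t(vapply(seq_len(n_mod), function(m) {
    if (m == n_mod) return(rep(0.3, n_stage))
    center <- 1 + (m - 1) * (n_stage - 1) / max(n_mod - 2, 1)
    2 + 30 * exp(-(stage_pos - center)^2 / (2 * 1.5^2))
  }, numeric(n_stage)))

  ## module spatial multipliers (whole embryo is 1 by construction)
  n_tis <- length(config$tissues)
  spat <- t(vapply(seq_len(n_mod), function(m) {
    v <- rep(1, n_tis)
    if (n_tis > 1) {
      hot <- 1 + (m %% (n_tis - 1)) + 1  # rotate enrichment among tissues
      hot <- min(hot, n_tis)
      v[-1] <- 0.3
      v[hot] <- 4
    }
    v
  }, numeric(n_tis)))

  mod <- grn$modules[genes]
  ref_stage_idx <- min(4L, n_stage)
  mean_cols <- list()
  meta <- list()
  for (s in seq_len(n_stage)) {
    nm <- paste0("wt_", config$stages[s])
    mean_cols[[nm]] <- prof[mod, s]
    meta[[nm]] <- data.frame(experiment = nm, type = "stage",
                             stage = config$stages[s], tissue = NA,
                             perturbed_tf = NA, pair = NA)
  }
  for (ti in seq_len(n_tis)) {
    nm <- paste0("tissue_", config$tissues[ti])
    mean_cols[[nm]] <- prof[mod, ref_stage_idx] * spat[mod, ti]
    meta[[nm]] <- data.frame(experiment = nm, type = "tissue",
                             stage = config$stages[ref_stage_idx],
                             tissue = config$tissues[ti],
                             perturbed_tf = NA, pair = NA)
  }
  targets_of <- split(grn$edges$target, grn$edges$tf)
  for (p in seq_len(nrow(config$perturbations))) {
    tf <- config$perturbations$tf[p]
    stage <- config$perturbations$stage[p]
    s <- match(stage, config$stages)
    if (is.na(s)) stopf("perturbation stage %s not in stages", stage)
    base <- prof[mod, s]
    kd <- base
    kd[genes %in% targets_of[[tf]]] <-
      kd[genes %in% targets_of[[tf]]] * config$knockdown_factor
    nm_mo <- paste0("mo_", tf, "_", stage)
    nm_ct <- paste0("ctrl_", tf, "_", stage)
    mean_cols[[nm_mo]] <- kd
    mean_cols[[nm_ct]] <- base
    meta[[nm_mo]] <- data.frame(experiment = nm_mo, type = "mo", stage = stage,
                                tissue = NA, perturbed_tf = tf, pair = nm_ct)
    meta[[nm_ct]] <- data.frame(experiment = nm_ct, type = "control",
                                stage = stage, tissue = NA, perturbed_tf = tf,
                                pair = nm_mo)
  }
  mean_tpm <- do.call(cbind, mean_cols)
  rownames(mean_tpm) <- genes
  tpm <- local_seed(derive_seed(config$seed, 4L), {
    noise <- matrix(2^rnorm(length(mean_tpm), 0, config$noise_sd),
                    nrow(mean_tpm), ncol(mean_tpm))
    mean_tpm * noise
  })
  list(tpm = tpm, metadata = do.call(rbind, meta), mean_tpm = mean_tpm)
}

#' Generate chromatin peak calls and read placements
#'
#' Every planted region emits, for each chromatin experiment where its
#' state signature is at least `peak_min_rpkm`, a peak call (the region
#' interval with small seeded boundary jitter per experiment) and a
#' Poisson-distributed number of 50 bp read placements whose expectation
#' makes the region's expected RPKM equal the signature level at the
#' nominal `total_mapped` library size.
#'
#' @param config A [synthetic_config()].
#' @param grn A `planted_grn`.
#' @return List: `experiments` (metadata data.frame), `peaks` (named list of
#'   `GRanges`), `reads` (named list of `GRanges`), `total_mapped` (named
#'   vector), `expected_rpkm` (regions x experiments truth matrix),
#'   `regions` (`GRanges` of planted regions with `crm_id`).
#' @export
generate_chromatin_data <- function(config, grn) {
  if (!length(config$chromatin_states)) stopf("chromatin_states is empty")
  tf_chips <- paste0("chip_", grn$tfs$tf)
  marks <- c("h3k4me1", "h3k4me3", "h3k27ac", "h3k27me3", "h3k36me3",
             "h3k9me3", "ep300", "atac")
  experiments <- c(tf_chips, marks)
  for (sig in config$chromatin_states) {
    bad <- setdiff(names(sig), c("tf_chip", marks, tf_chips))
    if (length(bad))
      stopf("state signature references unknown experiment(s): %s",
            paste(bad, collapse = ", "))
  }
  regions <- grn$regions
  n_r <- nrow(regions)
  expected <- matrix(0, n_r, length(experiments),
                     dimnames = list(regions$crm_id, experiments))
  sig_get <- function(sig, key, default = 0) {
    if (key %in% names(sig)) unname(sig[[key]]) else default
  }
  for (i in seq_len(n_r)) {
    sig <- config$chromatin_states[[regions$state[i]]]
    floor_level <- if (length(sig)) min(sig) else 0
    for (e in experiments) {
      expected[i, e] <- if (e %in% tf_chips) {
        own <- !is.na(regions$tf[i]) && e == paste0("chip_", regions$tf[i])
        if (own) sig_get(sig, "tf_chip") else sig_get(sig, e, floor_level)
      } else {
        sig_get(sig, e)
      }
    }
  }
  widths <- regions$end - regions$start + 1L
  local_seed(derive_seed(config$seed, 5L), {
    peaks <- list(); reads <- list()
    for (e in experiments) {
      lambda <- expected[, e] * widths * config$total_mapped / 1e9
      n_reads <- stats::rpois(n_r, lambda)
      idx <- rep.int(seq_len(n_r), n_reads)
      if (length(idx)) {
        pos <- floor(runif(length(idx), regions$start[idx],
                           regions$end[idx] - 49))
        reads[[e]] <- GenomicRanges::GRanges(
          regions$chrom[idx], IRanges::IRanges(pos, width = 50),
          strand = sample(c("+", "-"), length(idx), replace = TRUE))
      } else {
        reads[[e]] <- GenomicRanges::GRanges()
      }
      has_peak <- expected[, e] >= config$peak_min_rpkm
      if (any(has_peak)) {
        jit <- floor(runif(sum(has_peak), -20, 21))
        peaks[[e]] <- GenomicRanges::GRanges(
          regions$chrom[has_peak],
          IRanges::IRanges(pmax(1L, regions$start[has_peak] + jit),
                           regions$end[has_peak] + jit))
      } else {
        peaks[[e]] <- GenomicRanges::GRanges()
      }
    }
    region_gr <- GenomicRanges::GRanges(regions$chrom,
                                        IRanges::IRanges(regions$start,
                                                         regions$end))
    S4Vectors::mcols(region_gr)$crm_id <- regions$crm_id
    meta <- data.frame(
      experiment = experiments,
      assay = ifelse(experiments == "atac", "atac", "chip"),
      factor = c(grn$tfs$tf, marks),
      stage = ifelse(experiments == "ep300", "st9", "st10.5"),
      stringsAsFactors = FALSE)
    list(experiments = meta, peaks = peaks, reads = reads,
         total_mapped = setNames(rep(config$total_mapped, length(experiments)),
                                 experiments),
         expected_rpkm = expected, regions = region_gr)
  })
}

#' Generate the full synthetic bundle
#'
#' Runs the whole generator chain (genome, planted network, motif planting,
#' expression, chromatin) and derives the curated gene lists that the
#' filtering cascade requires: the gastrulation list (all planted targets
#' and TFs plus a seeded 10% of other genes) and the TF/growth-factor list
#' (targets and TFs plus a seeded 5% of other genes).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bundle` list: `config`, `genome`, `genes`, `grn`,
#'   `sites`, `expression`, `chromatin`, `gastrulation_genes`, `tf_genes`.
#' @export
generate_bundle <- function(config) {
  gen <- generate_genome(config)
  grn <- generate_planted_grn(config, gen$genes)
  planted <- plant_motif_instances(gen$genome, grn, config)
  expr <- generate_expression_matrix(config, grn)
  chrom <- generate_chromatin_data(config, grn)
  lists <- local_seed(derive_seed(config$seed, 6L), {
    core <- unique(c(grn$edges$target, grn$tfs$gene_id))
    others <- setdiff(gen$genes$gene_id, core)
    list(gast = sort(c(core, sample(others, round(0.10 * length(others))))),
         tf = sort(c(core, sample(others, round(0.05 * length(others))))))
  })
  structure(list(config = config, genome = planted$genome, genes = gen$genes,
                 grn = grn, sites = planted$sites, expression = expr,
                 chromatin = chrom,
                 gastrulation_genes = lists$gast, tf_genes = lists$tf),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to plain-text files
#'
#' FASTA genome, TSV gene models, BED peak and read placements per
#' experiment, TSV expression and expected-RPKM matrices, JSON planted-GRN
#' truth, and plain-text gene lists.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  write.table(bundle$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pk <- file.path(dir, "peaks"); dir.create(pk, showWarnings = FALSE)
  for (e in names(bundle$chromatin$peaks)) {
    rtracklayer::export(bundle$chromatin$peaks[[e]],
                        file.path(pk, paste0(e, ".bed")), format = "BED")
    rtracklayer::export(bundle$chromatin$reads[[e]],
                        file.path(pk, paste0(e, ".reads.bed")), format = "BED")
  }
  write.table(bundle$expression$tpm, file.path(dir, "expression_tpm.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(bundle$chromatin$expected_rpkm,
              file.path(dir, "expected_rpkm.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(list(tfs = bundle$grn$tfs, edges = bundle$grn$edges,
                            regions = bundle$grn$regions,
                            sites = bundle$sites),
                       file.path(dir, "planted_grn.json"), dataframe = "rows")
  writeLines(bundle$gastrulation_genes, file.path(dir, "gastrulation_genes.txt"))
  writeLines(bundle$tf_genes, file.path(dir, "tf_growthfactor_genes.txt"))
  invisible(dir)
}
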