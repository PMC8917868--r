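## PWM construction (from sites or IUPAC consensi), log-likelihood-ratio
## scanning of region sequences on both strands, exact dynamic-programming
## score p-values, BH q-values, and per-LM motif-density enrichment.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Position weight matrix from aligned binding sites
#'
#' Probabilities are `(count + pseudocount) / (n_sites + 4 * pseudocount)`
#' per position.
#'
#' @param sites Character vector of equal-length sequences over ACGT.
#' @param pseudocount Added to each base count (default 0.25).
#' @param id Motif identifier.
#' @param background Named background distribution over ACGT (default
#'   uniform).
#' @return A `pwm` object: `id`, `prob` (4 x w matrix, rows ACGT), `width`,
#'   `pseudocount`, `background`.
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.25, id = "motif",
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(sites) < 2) stopf("need at least two sites")
  w <- unique(nchar(sites))
  if (length(w) != 1) stopf("sites must have equal length")
  chars <- do.call(rbind, strsplit(toupper(sites), ""))
  if (!all(chars %in% DNA_BASES)) stopf("sites must use only A/C/G/T")
  prob <- sapply(seq_len(w), function(j) {
    cnt <- table(factor(chars[, j], levels = DNA_BASES))
    (as.numeric(cnt) + pseudocount) / (length(sites) + 4 * pseudocount)
  })
  prob <- matrix(prob, nrow = 4, dimnames = list(DNA_BASES, NULL))
  new_pwm(id, prob, pseudocount, background)
}

#' Position weight matrix from an IUPAC consensus
#'
#' Each position is uniform over the IUPAC code's base set (zero elsewhere),
#' then regularized with a pseudocount.
#'
#' @param pattern IUPAC string (e.g. `"AATMHACA"`).
#' @param pseudocount Pseudocount weight mixed in as
#'   `(p + pc) / (1 + 4 * pc)` (default 0.01, keeping all probabilities
#'   positive so mismatch scores stay finite).
#' @inheritParams pwm_from_sites
#' @return A `pwm` object.
#' @export
iupac_to_pwm <- function(pattern, pseudocount = 0.01, id = pattern,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (length(bad)) stopf("invalid IUPAC code(s): %s", paste(bad, collapse = ", "))
  prob <- vapply(codes, function(cd) {
    p <- setNames(numeric(4), DNA_BASES)
    p[IUPAC_SETS[[cd]]] <- 1 / length(IUPAC_SETS[[cd]])
    (p + pseudocount) / (1 + 4 * pseudocount)
  }, numeric(4))
  new_pwm(id, prob, pseudocount, background)
}

new_pwm <- function(id, prob, pseudocount, background) {
  dimnames(prob) <- list(DNA_BASES, NULL)
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-9) stopf("background must sum to 1")
  if (any(abs(colSums(prob) - 1) > 1e-9)) stopf("PWM columns must sum to 1")
  structure(list(id = id, prob = prob, width = ncol(prob),
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' Enumerate the consensus k-mers of an IUPAC pattern
#'
#' @param pattern IUPAC string.
#' @return Character vector of all exact-match realizations.
#' @export
iupac_expand <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (length(bad)) stopf("invalid IUPAC code(s): %s", paste(bad, collapse = ", "))
  out <- ""
  for (cd in codes) out <- as.vector(outer(out, IUPAC_SETS[[cd]], paste0))
  out
}

#' Reverse complement of a pwm (for minus-strand scanning)
#' @noRd
pwm_revcomp <- function(pwm) {
  prob <- pwm$prob[rev(DNA_BASES), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(prob) <- DNA_BASES
  pwm$prob <- prob
  pwm
}

## log2 likelihood-ratio score matrix (bits), 4 x w
pwm_score_matrix <- function(pwm) {
  log2(pwm$prob / pwm$background)
}

#' Exact null distribution of PWM scores and p-value lookup
#'
#' Discretizes the per-position log-likelihood-ratio scores to multiples of
#' `granularity` (bits) and convolves the per-position score distributions
#' under the background model, giving the exact distribution of the
#' discretized score at a single position/strand.  `p(s) = P(score >= s)`.
#'
#' @param pwm A `pwm`.
#' @param granularity Discretization step in bits (default 1e-3).
#' @return A `pwm_null` object with integer score support, tail
#'   probabilities, and the rounded integer score matrix used for lookup.
#' @export
score_pvalues <- function(pwm, granularity = 1e-3) {
  if (granularity <= 0) stopf("granularity must be positive")
  if (pwm$width > 30) stopf("PWM width > 30 not supported by the exact DP")
  S <- pwm_score_matrix(pwm)
  ## zero-probability bases (pseudocount 0) get a finite floor of -30 bits
  ## per position so the discretized null stays well defined
  S[!is.finite(S)] <- -30
  K <- matrix(as.integer(round(S / granularity)), nrow = 4,
              dimnames = dimnames(S))
  ## DP over positions: dp[i] = P(sum of discretized scores = dp_lo + i - 1)
  dp <- 1
  dp_lo <- 0L
  for (j in seq_len(pwm$width)) {
    new_lo <- dp_lo + min(K[, j])
    new_hi <- dp_lo + length(dp) - 1L + max(K[, j])
    nd <- numeric(new_hi - new_lo + 1L)
    for (b in seq_len(4)) {
      shift <- dp_lo + K[b, j] - new_lo
      idx <- seq_along(dp) + shift
      nd[idx] <- nd[idx] + dp * pwm$background[b]
    }
    dp <- nd
    dp_lo <- new_lo
  }
  tail <- rev(cumsum(rev(dp)))
  tail <- pmin(tail, 1)
  structure(list(pwm_id = pwm$id, granularity = granularity,
                 support_lo = dp_lo, probs = dp, tail = tail,
                 score_int = K),
            class = "pwm_null")
}

#' P-values for integer (discretized) scores under a pwm_null
#'
#' @param null A `pwm_null` from [score_pvalues()].
#' @param score_int Integer score(s) on the null's granularity grid.
#' @return `P(score >= score_int)`, in `(0, 1]`.
#' @export
null_pvalue <- function(null, score_int) {
  idx <- score_int - null$support_lo + 1L
  idx <- pmax(pmin(idx, length(null$tail)), 1L)
  p <- null$tail[idx]
  p[score_int > null$support_lo + length(null$tail) - 1L] <- 0
  p[score_int < null$support_lo] <- 1
  pmax(p, .Machine$double.xmin)
}

#' Scan region sequences with a PWM on both strands
#'
#' At every offset and strand the log2 likelihood-ratio score
#' `sum(log2(P_pwm(base) / P_bg(base)))` is computed; windows containing N
#' are skipped.  P-values come from the exact discretized null
#' ([score_pvalues()]); q-values are BH-adjusted across all scanned
#' positions of this motif over the whole region set (one family per motif).
#'
#' @param sequences Named character vector or `DNAStringSet` of region
#'   sequences (names = region ids).
#' @param pwm A `pwm`.
#' @param null Optional precomputed `pwm_null` (built on the fly otherwise).
#' @return Data.frame: `region_id`, `offset` (0-based), `strand`, `score`
#'   (bits), `p`, `q`, sorted by p.  Regions shorter than the motif width
#'   contribute no positions.
#' @export
scan_regions <- function(sequences, pwm, null = NULL) {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("region", seq_along(sequences))
  null <- null %||% score_pvalues(pwm)
  Kf <- null$score_int
  Kr <- Kf[rev(DNA_BASES), rev(seq_len(ncol(Kf))), drop = FALSE]
  rownames(Kr) <- DNA_BASES
  gran <- null$granularity
  w <- pwm$width
  res <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- toupper(sequences[[i]])
    L <- nchar(s)
    if (L < w) next
    code <- match(strsplit(s, "")[[1]], DNA_BASES)   # NA for N
    n_pos <- L - w + 1L
    fwd <- integer(n_pos); rev_ <- integer(n_pos); ok <- rep(TRUE, n_pos)
    for (j in seq_len(w)) {
      b <- code[j:(j + n_pos - 1L)]
      miss <- is.na(b)
      ok <- ok & !miss
      b[miss] <- 1L
      fwd <- fwd + Kf[cbind(b, j)]
      rev_ <- rev_ + Kr[cbind(b, j)]
    }
    if (!any(ok)) next
    off <- which(ok) - 1L
    res[[i]] <- data.frame(
      region_id = names(sequences)[i],
      offset = c(off, off),
      strand = rep(c("+", "-"), each = length(off)),
      score_int = c(fwd[ok], rev_[ok]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(region_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p = numeric(), q = numeric()))
  out$score <- out$score_int * gran
  out$p <- null_pvalue(null, out$score_int)
  out$q <- bh_qvalues(out$p)
  out$score_int <- NULL
  out[order(out$p, out$region_id, out$offset), ]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment with monotonicity enforcement (identical to
#' `p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Filter scan hits at a q-value threshold
#'
#' @param hits Data.frame from [scan_regions()].
#' @param q_threshold Keep hits with `q < q_threshold` (default 0.1).
#' @return The filtered data.frame.
#' @export
filter_hits <- function(hits, q_threshold = 0.1) {
  hits[hits$q < q_threshold, , drop = FALSE]
}

#' Motif-density enrichment per linked metacluster
#'
#' For each LM bin and motif, the proportion of the bin's regions carrying
#' at least one (q-filtered) hit is compared with the global proportion over
#' all linked regions by a one-tailed z-test
#' `z = (p_lm - p_global) / sqrt(p_global (1 - p_global) / n_lm)`,
#' BH-corrected across all (LM, motif) pairs; pairs with `q < alpha` (or
#' `p < alpha` in p-mode) are retained.
#'
#' @param hits_by_motif Named list (motif id -> q-filtered hits data.frame
#'   from [scan_regions()]).
#' @param lm_map An `lm_map` from [link_soms()].
#' @param alpha Retention threshold (default 0.05).
#' @param mode `"q"` (default) or `"p"`: which value `alpha` thresholds.
#' @return Data.frame: `rna_mc`, `dna_mc`, `motif`, `n_regions`,
#'   `n_with_hit`, `proportion`, `global_proportion`, `z`, `p`, `q`,
#'   `retained`, `flagged` (degenerate global proportion).  Empty bins are
#'   skipped.
#' @export
lm_density_enrichment <- function(hits_by_motif, lm_map, alpha = 0.05,
                                  mode = c("q", "p")) {
  mode <- match.arg(mode)
  pairs <- lm_map$pairs
  all_regions <- unique(pairs$region_id)
  n_all <- length(all_regions)
  bins <- unique(pairs[, c("rna_mc", "dna_mc")])
  rows <- list()
  for (motif in names(hits_by_motif)) {
    hit_regions <- unique(hits_by_motif[[motif]]$region_id)
    p_global <- sum(all_regions %in% hit_regions) / n_all
    for (b in seq_len(nrow(bins))) {
      sel <- pairs$rna_mc == bins$rna_mc[b] & pairs$dna_mc == bins$dna_mc[b]
      regs <- unique(pairs$region_id[sel])
      n_lm <- length(regs)
      if (!n_lm) next
      n_hit <- sum(regs %in% hit_regions)
      flagged <- p_global %in% c(0, 1)
      z <- if (flagged) NA_real_ else
        (n_hit / n_lm - p_global) / sqrt(p_global * (1 - p_global) / n_lm)
      rows[[length(rows) + 1L]] <- data.frame(
        rna_mc = bins$rna_mc[b], dna_mc = bins$dna_mc[b], motif = motif,
        n_regions = n_lm, n_with_hit = n_hit, proportion = n_hit / n_lm,
        global_proportion = p_global, z = z,
        p = if (flagged) NA_real_ else pnorm(z, lower.tail = FALSE),
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_qvalues(out$p[ok])
  out$retained <- !is.na(out$p) &
    (if (mode == "q") out$q < alpha else out$p < alpha)
  out
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  if (is(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
             "")
  for (p in pwms) {
    lines <- c(lines,
               sprintf("MOTIF %s", p$id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width),
               apply(p$prob, 2, function(col)
                 sprintf(" %.6f  %.6f  %.6f  %.6f", col[1], col[2], col[3], col[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#'
#' @param path Path to a MEME text file.
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx)) {
    toks <- strsplit(trimws(lines[bg_idx[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])[DNA_BASES]
  }
  out <- list()
  motif_idx <- grep("^MOTIF ", lines)
  for (mi in motif_idx) {
    id <- strsplit(lines[mi], "\\s+")[[1]][2]
    hdr <- lines[mi + 1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    rowsm <- lines[(mi + 2):(mi + 1 + w)]
    prob <- vapply(rowsm, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4))
    prob <- matrix(prob, nrow = 4, dimnames = list(DNA_BASES, NULL))
    prob <- sweep(prob, 2, colSums(prob), "/")   # undo fixed-precision rounding
    out[[id]] <- new_pwm(id, prob, pseudocount = NA, background = bg)
  }
  out
}
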