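## Independent brute-force oracles used to cross-check the implementation.
## These deliberately avoid the package's own code paths.

## Per-base coverage-run-length partitioner on a single toy chromosome.
## peaks: data.frame(start, end), 1-based closed coordinates.
## Returns data.frame(start, end) of partitions under the same merge rule:
## cut the covered runs at every peak boundary; within each run, a segment
## shorter than min_size merges into the preceding kept segment, else into
## the following one; a whole-run shorter than min_size is padded
## symmetrically and clipped to [1, chrom_len].
oracle_partition <- function(peaks, min_size, chrom_len) {
  cov <- logical(chrom_len)
  is_bnd <- logical(chrom_len + 1L)
  for (i in seq_len(nrow(peaks))) {
    cov[peaks$start[i]:peaks$end[i]] <- TRUE
    is_bnd[peaks$start[i]] <- TRUE
    is_bnd[peaks$end[i] + 1L] <- TRUE
  }
  out <- list()
  pos <- 1L
  while (pos <= chrom_len) {
    if (!cov[pos]) { pos <- pos + 1L; next }
    run_end <- pos
    while (run_end < chrom_len && cov[run_end + 1L]) run_end <- run_end + 1L
    ## cut the run at interior boundaries
    cuts <- which(is_bnd[(pos + 1L):run_end]) + pos
    st <- c(pos, cuts); en <- c(cuts - 1L, run_end)
    keep_st <- integer(0); keep_en <- integer(0)
    for (i in seq_along(st)) {
      w <- en[i] - st[i] + 1L
      if (w >= min_size || length(st) == 1L) {
        keep_st <- c(keep_st, st[i]); keep_en <- c(keep_en, en[i])
      } else if (length(keep_st)) {
        keep_en[length(keep_en)] <- en[i]
      } else if (i < length(st)) {
        st[i + 1L] <- st[i]
      } else {
        keep_st <- c(keep_st, st[i]); keep_en <- c(keep_en, en[i])
      }
    }
    for (i in seq_along(keep_st)) {
      w <- keep_en[i] - keep_st[i] + 1L
      if (w < min_size && length(keep_st) == 1L) {
        pad <- min_size - w
        left <- pad %/% 2L
        keep_st[i] <- max(1L, keep_st[i] - left)
        keep_en[i] <- min(chrom_len, keep_en[i] + (pad - left))
      }
      out[[length(out) + 1L]] <- c(keep_st[i], keep_en[i])
    }
    pos <- run_end + 1L
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

## Exhaustive nearest-unit search.
oracle_bmu <- function(data, weights) {
  t(apply(data, 1, function(row) {
    d <- sqrt(colSums((t(weights) - row)^2))
    c(unit = which.min(d), dist = min(d))
  }))
}

## Exact two-sided signed-rank p-value by enumerating all sign flips of the
## non-zero differences (tie-free input assumed).
oracle_signflip_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

## Exhaustive best lattice-contiguous 2-partition RSS over <= 16 units.
oracle_best_2partition_rss <- function(weights, lattice) {
  n <- nrow(weights)
  stopifnot(n <= 16)
  connected <- function(members) {
    if (!length(members)) return(FALSE)
    seen <- members[1]; frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(intersect(unique(unlist(lattice$adjacency[frontier])),
                               members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(members)
  }
  rss_of <- function(members) {
    rows <- weights[members, , drop = FALSE]
    sum(sweep(rows, 2, colMeans(rows))^2)
  }
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    a <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    b <- setdiff(seq_len(n), a)
    if (!connected(a) || !connected(b)) next
    best <- min(best, rss_of(a) + rss_of(b))
  }
  best
}

## Exact discretized-score distribution by enumerating all 4^w sequences.
## K: integer score matrix (4 x w); bg: background probabilities (length 4).
## Returns function(score_int) -> P(score >= score_int).
oracle_pwm_tail <- function(K, bg) {
  w <- ncol(K)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- vapply(seq_len(nrow(grid)), function(i)
    sum(K[cbind(grid[i, ], seq_len(w))]), 0L)
  probs <- apply(grid, 1, function(b) prod(bg[b]))
  function(s) sum(probs[scores >= s])
}

## Linear-scan nearest gene (same tie rule: smaller gene_id).
oracle_nearest_gene <- function(mid, chrom, genes, max_distance) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene = NA_character_, dist = NA_real_))
  dd <- abs(g$tss - mid)
  best <- which(dd == min(dd))
  if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
  if (dd[best] > max_distance) return(list(gene = NA_character_, dist = NA_real_))
  list(gene = g$gene_id[best], dist = dd[best])
}

## Build a som_model directly from a weight matrix (no training).
make_model <- function(weights, rows, cols) {
  structure(list(lattice = hex_lattice(rows, cols),
                 weights = as.matrix(weights),
                 config = NULL, final_score = NA_real_),
            class = "som_model")
}

## Small synthetic config used across tests (fast to generate).
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chromosomes = 1L, chromosome_length = 300000L,
               n_genes = 30L, n_tfs = 2L, targets_per_tf = 5L,
               n_expression_modules = 4L, n_decoys_per_tf = 3L,
               n_background_regions = 30L)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}

## GRanges helper for toy peak sets on one chromosome.
gr <- function(start, end, chrom = "chr1", strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}
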