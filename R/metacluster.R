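## Lattice-constrained metaclustering of SOM units, model selection by
## AIC/BIC, metacluster eigen-profiles, per-metacluster hypothesis tests,
## fold changes and experiment hierarchies.

#' Lattice-constrained k-means on SOM units
#'
#' Groups SOM units into `k` metaclusters that are each connected under the
#' hexagonal lattice adjacency.  Each restart seeds `k` distinct units, then
#' greedily grows regions: the unassigned unit adjacent to some cluster with
#' the smallest weight-space distance to that cluster's centroid is attached
#' (globally greedy), centroids updated incrementally.  A refinement pass
#' then reassigns boundary units between adjacent clusters whenever the move
#' lowers the residual sum of squares and keeps the donor cluster connected
#' and non-empty, until no move helps (at most 100 sweeps).  The restart with
#' the lowest RSS wins.
#'
#' @param model A `som_model` from [train_som()].
#' @param k Number of metaclusters, `1 <= k <= n_units`.
#' @param trials Number of random restarts.
#' @param seed Integer seed (restart seeds derived from it).
#' @return A `metaclustering` object: `labels` (one per unit), `k`, `rss`,
#'   `aic`, `bic`, `trial_rss`.
#' @export
constrained_kmeans <- function(model, k, trials = 10L, seed = 1L) {
  w <- model$weights
  lat <- model$lattice
  n <- nrow(w)
  k <- as.integer(k)
  if (k < 1 || k > n) stopf("k must be between 1 and the number of units (%d)", n)
  best_lab <- NULL
  best_rss <- Inf
  trial_rss <- numeric(trials)
  for (tr in seq_len(trials)) {
    lab <- local_seed(derive_seed(seed, 7000L + tr), {
      grow_contiguous(w, lat, k)
    })
    lab <- refine_boundaries(w, lat, lab, k)
    rss <- partition_rss(w, lab)
    trial_rss[tr] <- rss
    if (rss < best_rss) { best_rss <- rss; best_lab <- lab }
  }
  mc_object(model, best_lab, k, best_rss, trial_rss)
}

mc_object <- function(model, labels, k, rss, trial_rss = NULL) {
  d <- ncol(model$weights)
  n <- nrow(model$weights)
  ll <- spherical_loglik(rss, n, d)
  p <- k * (d + 1)
  structure(list(labels = labels, k = k, rss = rss,
                 aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(n),
                 trial_rss = trial_rss,
                 lattice = model$lattice),
            class = "metaclustering")
}

## log-likelihood of unit weights under a spherical Gaussian per cluster with
## pooled variance RSS/(n*d)
spherical_loglik <- function(rss, n, d) {
  sigma2 <- max(rss / (n * d), 1e-12)
  -(n * d) / 2 * (log(2 * pi * sigma2) + 1)
}

partition_rss <- function(w, lab) {
  rss <- 0
  for (g in unique(lab)) {
    rows <- w[lab == g, , drop = FALSE]
    ctr <- colMeans(rows)
    rss <- rss + sum(sweep(rows, 2, ctr)^2)
  }
  rss
}

## greedy contiguous region growing from k random distinct seed units;
## per-cluster frontiers (unassigned units adjacent to the cluster) are
## maintained incrementally
grow_contiguous <- function(w, lat, k) {
  n <- nrow(w)
  lab <- integer(n)
  seeds <- sample.int(n, k)
  lab[seeds] <- seq_len(k)
  sums <- w[seeds, , drop = FALSE]
  sizes <- rep(1L, k)
  frontier <- lapply(seq_len(k), function(g) {
    nb <- lat$adjacency[[seeds[g]]]
    nb[lab[nb] == 0L]
  })
  n_left <- n - k
  while (n_left > 0L) {
    best_d <- Inf; best_u <- 0L; best_g <- 0L
    for (g in seq_len(k)) {
      fr <- frontier[[g]]
      if (!length(fr)) next
      ctr <- sums[g, ] / sizes[g]
      dd <- colSums((t(w[fr, , drop = FALSE]) - ctr)^2)
      j <- which.min(dd)
      if (dd[j] < best_d) { best_d <- dd[j]; best_u <- fr[j]; best_g <- g }
    }
    if (!best_u) stopf("lattice not connected; cannot grow clusters")
    lab[best_u] <- best_g
    sums[best_g, ] <- sums[best_g, ] + w[best_u, ]
    sizes[best_g] <- sizes[best_g] + 1L
    for (g in seq_len(k))
      frontier[[g]] <- frontier[[g]][frontier[[g]] != best_u]
    nb <- lat$adjacency[[best_u]]
    frontier[[best_g]] <- unique(c(frontier[[best_g]], nb[lab[nb] == 0L]))
    n_left <- n_left - 1L
  }
  lab
}

## first-improvement boundary reassignment preserving connectivity; sweeps
## until a full sweep applies no move (RSS strictly decreases per move)
refine_boundaries <- function(w, lat, lab, k, max_iter = 100L) {
  sums <- rowsum(w, lab)
  sizes <- tabulate(lab, k)
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (u in seq_along(lab)) {
      g <- lab[u]
      if (sizes[g] <= 1L) next
      neigh_lab <- unique(lab[lat$adjacency[[u]]])
      neigh_lab <- neigh_lab[neigh_lab != g]
      if (!length(neigh_lab)) next
      ng <- sizes[g]
      cg <- sums[g, ] / ng
      dg <- sum((w[u, ] - cg)^2) * ng / (ng - 1)
      best_gain <- 1e-12; best_h <- 0L
      for (h in neigh_lab) {
        nh <- sizes[h]
        ch <- sums[h, ] / nh
        dh <- sum((w[u, ] - ch)^2) * nh / (nh + 1)
        if (dg - dh > best_gain) { best_gain <- dg - dh; best_h <- h }
      }
      if (best_h && stays_connected(lat, lab, u)) {
        lab[u] <- best_h
        sums[g, ] <- sums[g, ] - w[u, ]; sizes[g] <- sizes[g] - 1L
        sums[best_h, ] <- sums[best_h, ] + w[u, ]; sizes[best_h] <- sizes[best_h] + 1L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  lab
}

cluster_centroids <- function(w, lab, k) {
  ctr <- matrix(NA_real_, k, ncol(w))
  for (g in seq_len(k)) {
    rows <- which(lab == g)
    if (length(rows)) ctr[g, ] <- colMeans(w[rows, , drop = FALSE])
  }
  ctr
}

## would cluster lab[u] remain connected if u left?  (integer BFS)
stays_connected <- function(lat, lab, u) {
  g <- lab[u]
  members <- which(lab == g)
  members <- members[members != u]
  n_m <- length(members)
  if (n_m <= 1L) return(TRUE)
  in_set <- logical(length(lab))
  in_set[members] <- TRUE
  visited <- logical(length(lab))
  queue <- members[1]
  visited[queue] <- TRUE
  n_seen <- 1L
  while (length(queue)) {
    nb <- unlist(lat$adjacency[queue], use.names = FALSE)
    nb <- nb[in_set[nb] & !visited[nb]]
    nb <- unique(nb)
    visited[nb] <- TRUE
    n_seen <- n_seen + length(nb)
    queue <- nb
  }
  n_seen == n_m
}

#' Check the lattice-connectivity invariant of a metaclustering
#'
#' @param mc A `metaclustering`.
#' @return `TRUE` if every metacluster's unit set is connected under the
#'   lattice adjacency and all labels `1..k` are non-empty.
#' @export
is_contiguous <- function(mc) {
  lab <- mc$labels; lat <- mc$lattice
  if (!setequal(unique(lab), seq_len(mc$k))) return(FALSE)
  for (g in seq_len(mc$k)) {
    members <- which(lab == g)
    seen <- members[1]; frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(intersect(unique(unlist(lat$adjacency[frontier])), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) != length(members)) return(FALSE)
  }
  TRUE
}

#' Select the number of metaclusters by AIC or BIC
#'
#' Runs [constrained_kmeans()] for every `k` in `k_range` and scores each
#' clustering with a spherical-Gaussian likelihood over the unit weights
#' (pooled variance `RSS/(n*d)`, parameter count `k*(d+1)`).
#'
#' @param model A `som_model`.
#' @param k_range Integer vector of candidate `k`.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param trials Restarts per `k`.
#' @param seed Integer seed.
#' @return The `metaclustering` minimizing the chosen criterion, with an
#'   added `selection` data.frame (k, rss, aic, bic).
#' @export
select_k <- function(model, k_range, criterion = c("AIC", "BIC"),
                     trials = 10L, seed = 1L) {
  criterion <- match.arg(criterion)
  if (!length(k_range)) stopf("k_range is empty")
  fits <- lapply(k_range, function(k)
    constrained_kmeans(model, k, trials = trials, seed = derive_seed(seed, k)))
  tab <- data.frame(k = as.integer(k_range),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    bic = vapply(fits, `[[`, 0, "bic"))
  crit <- if (criterion == "AIC") tab$aic else tab$bic
  best <- fits[[which.min(crit)]]
  best$selection <- tab
  best$criterion <- criterion
  best
}

#' Metacluster eigen-profiles
#'
#' The eigen-profile of a metacluster is the mean weight vector of its member
#' units, one value per experiment.
#'
#' @param model A `som_model`.
#' @param mc A `metaclustering` of its units.
#' @param normalize If `TRUE`, each profile is divided by its maximum
#'   (all-zero profiles kept at zero).
#' @return A `k x experiments` matrix.
#' @export
metacluster_profiles <- function(model, mc, normalize = FALSE) {
  prof <- rowsum(model$weights, mc$labels) / as.vector(table(mc$labels))
  rownames(prof) <- paste0("MC", sort(unique(mc$labels)))
  if (normalize) {
    mx <- apply(prof, 1, max)
    mx[mx == 0] <- 1
    prof <- prof / mx
  }
  prof
}

#' Map items to metaclusters through their best-matching units
#'
#' @param assignment Item assignment from [assign_items()].
#' @param mc A `metaclustering` of the same SOM's units.
#' @return A data.frame with `item` and `metacluster` columns.
#' @export
assign_items_to_metaclusters <- function(assignment, mc) {
  if (any(assignment$unit < 1 | assignment$unit > length(mc$labels)))
    stopf("assignment refers to units missing from the metaclustering")
  data.frame(item = assignment$item,
             metacluster = mc$labels[assignment$unit],
             stringsAsFactors = FALSE)
}

#' Per-metacluster paired Wilcoxon test between two experiments
#'
#' For each metacluster with at least `min_members` member items, performs a
#' two-sided paired Wilcoxon signed-rank test of the members' values in
#' experiment `contrast[1]` against `contrast[2]` (zero differences dropped;
#' exact null for n <= 25, normal approximation with continuity correction
#' above), followed by Benjamini-Hochberg correction across metaclusters.
#'
#' @param membership Data.frame from [assign_items_to_metaclusters()].
#' @param x Items x experiments matrix (row names = item ids).
#' @param contrast Length-2 vector of experiment column names or indices.
#' @param min_members Minimum member count for testing (default 5).
#' @return Data.frame: `metacluster`, `n`, `statistic`, `p`, `q`,
#'   `direction` (+1/-1/0 by median difference), `degenerate`.
#' @export
hypothesis_test <- function(membership, x, contrast, min_members = 5L) {
  m <- as_data_matrix(x)
  if (length(contrast) != 2) stopf("contrast must name two experiments")
  a <- m[, contrast[1]]; b <- m[, contrast[2]]
  names(a) <- names(b) <- rownames(m)
  mcs <- sort(unique(membership$metacluster))
  rows <- lapply(mcs, function(g) {
    items <- membership$item[membership$metacluster == g]
    items <- intersect(items, rownames(m))
    if (length(items) < min_members) return(NULL)
    d <- a[items] - b[items]
    nz <- d != 0
    if (!any(nz)) {
      return(data.frame(metacluster = g, n = length(items),
                        statistic = NA_real_, p = 1, direction = 0L,
                        degenerate = TRUE))
    }
    wt <- suppressWarnings(
      wilcox.test(a[items][nz], b[items][nz], paired = TRUE,
                  exact = sum(nz) <= 25, correct = TRUE))
    data.frame(metacluster = g, n = length(items),
               statistic = unname(wt$statistic), p = wt$p.value,
               direction = as.integer(sign(stats::median(d))),
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- p.adjust(out$p, "BH")
  out[, c("metacluster", "n", "statistic", "p", "q", "direction", "degenerate")]
}

#' Mean log2 fold change of metacluster members between two experiments
#'
#' `mean(log2((tissue + c) / (reference + c)))` over member items, with
#' pseudocount `c = 1`.
#'
#' @param membership Data.frame from [assign_items_to_metaclusters()].
#' @param x Items x experiments matrix.
#' @param tissue,reference Experiment column names or indices.
#' @param pseudocount Added to both numerator and denominator (default 1).
#' @return Named numeric vector, one value per metacluster (`NA` for empty
#'   metaclusters).
#' @export
metacluster_foldchange <- function(membership, x, tissue, reference,
                                   pseudocount = 1) {
  m <- as_data_matrix(x)
  lfc <- log2((m[, tissue] + pseudocount) / (m[, reference] + pseudocount))
  names(lfc) <- rownames(m)
  mcs <- sort(unique(membership$metacluster))
  out <- vapply(mcs, function(g) {
    items <- intersect(membership$item[membership$metacluster == g], rownames(m))
    if (!length(items)) return(NA_real_)
    mean(lfc[items])
  }, 0)
  names(out) <- paste0("MC", mcs)
  out
}

#' Hierarchical clustering of experiments from metacluster profiles
#'
#' Average-linkage agglomerative clustering with distance
#' `1 - Pearson correlation` between the experiment columns of the
#' eigen-profile matrix.
#'
#' @param profiles Metaclusters x experiments matrix from
#'   [metacluster_profiles()].
#' @return An [stats::hclust] object (merge tree plus leaf order).
#' @export
experiment_hierarchy <- function(profiles) {
  if (ncol(profiles) < 2) stopf("need at least two experiments")
  sds <- apply(profiles, 2, sd)
  cc <- suppressWarnings(cor(profiles))
  if (any(sds == 0)) {
    warnf("zero-variance experiment(s): correlation undefined, distance set to 1")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  hclust(as.dist(1 - cc), method = "average")
}
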