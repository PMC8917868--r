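## Self-organizing map on a hexagonal lattice: best-of-trials training,
## quantization scoring, item assignment and per-experiment slice views.

#' Hexagonal SOM lattice
#'
#' Builds an "odd-r" offset hexagonal lattice of `rows` x `cols` units.
#' Units are indexed row-major (unit 1 = top-left).  Lattice distance is the
#' hexagonal (cube-coordinate) distance; interior units have six neighbours.
#'
#' @param rows,cols Lattice dimensions (positive integers).
#' @return An object of class `hex_lattice` with elements `rows`, `cols`,
#'   `n_units`, cube coordinates `hx`/`hy`, and `adjacency` (a list mapping
#'   each unit to its neighbouring unit indices).
#' @examples
#' lat <- hex_lattice(3, 4)
#' lengths(lat$adjacency)  # corner units have 2-3 neighbours
#' @export
hex_lattice <- function(rows, cols) {
  if (rows < 1 || cols < 1) stopf("lattice dimensions must be positive")
  rows <- as.integer(rows); cols <- as.integer(cols)
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  ## odd-r offset -> cube coordinates
  hx <- c - (r - (r %% 2L)) / 2
  hy <- r
  n <- rows * cols
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    d <- hex_dist(hx[i], hy[i], hx, hy)
    adj[[i]] <- which(d == 1)
  }
  structure(list(rows = rows, cols = cols, n_units = n,
                 hx = hx, hy = hy, adjacency = adj),
            class = "hex_lattice")
}

## hexagonal distance between (x1,y1) and vectors (x2,y2) in axial coords
## (cube z = -x-y)
hex_dist <- function(x1, y1, x2, y2) {
  (abs(x1 - x2) + abs(y1 - y2) + abs((-x1 - y1) - (-x2 - y2))) / 2
}

#' SOM training configuration
#'
#' @param rows,cols Lattice dimensions.
#' @param epochs Number of passes over the training split; every training row
#'   is presented once per epoch in random order.
#' @param trials Independent trainings; the trial with the lowest mean
#'   quantization error on the full matrix is kept.
#' @param alpha0 Initial learning rate.
#' @param sigma0 Initial neighbourhood radius in lattice units; defaults to
#'   `max(rows, cols) / 2`.
#' @param sigma_min Floor of the neighbourhood radius (default 0.25); as the
#'   radius decays below ~0.3 the update becomes effectively winner-only,
#'   letting units localize on their data.
#' @param decay_constant Time constant of the exponential decay of both the
#'   learning rate and the neighbourhood radius, in presentations; defaults
#'   to `total_presentations / log(sigma0 / sigma_min)` so the radius
#'   anneals to its floor exactly at the end of training.
#' @param train_fraction Fraction of matrix rows used for training (the
#'   quantization score always uses the full matrix).
#' @param seed Integer seed; per-trial seeds are derived from it.
#' @return A `som_config` list.
#' @export
som_config <- function(rows, cols, epochs = 100L, trials = 100L,
                       alpha0 = 0.1, sigma0 = max(rows, cols) / 2,
                       sigma_min = 0.25, decay_constant = NULL,
                       train_fraction = 0.5, seed = 1L) {
  if (alpha0 <= 0 || alpha0 > 1) stopf("alpha0 must be in (0, 1]")
  if (sigma0 < 1) stopf("sigma0 must be >= 1")
  if (sigma_min <= 0) stopf("sigma_min must be positive")
  if (train_fraction <= 0 || train_fraction > 1)
    stopf("train_fraction must be in (0, 1]")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs), trials = as.integer(trials),
                 alpha0 = alpha0, sigma0 = sigma0, sigma_min = sigma_min,
                 decay_constant = decay_constant,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "som_config")
}

#' Preprocess a non-negative data matrix for SOM training
#'
#' @param x Non-negative numeric matrix (items x experiments).
#' @param transform `"log2p1"` (default, `log2(x + 1)`), `"identity"`, or
#'   `"maxnorm"` (each row divided by its maximum; all-zero rows kept at 0).
#' @return Transformed matrix of the same shape.
#' @export
preprocess_matrix <- function(x, transform = c("log2p1", "identity", "maxnorm")) {
  transform <- match.arg(transform)
  m <- as_data_matrix(x, "input matrix")
  if (any(m < 0)) stopf("preprocess_matrix: negative values in input")
  switch(transform,
    log2p1 = log2(m + 1),
    identity = m,
    maxnorm = {
      mx <- apply(m, 1, max)
      mx[mx == 0] <- 1
      m / mx
    })
}

#' Train a self-organizing map
#'
#' Runs `config$trials` independent trainings.  Each trial samples a training
#' split (a seeded uniform `train_fraction` row subset), initializes unit
#' weights by sampling data rows with replacement, and performs sequential
#' Kohonen updates: per epoch every training row is presented once in random
#' order; the winning unit is the Euclidean-nearest unit and every unit `u`
#' moves toward the presented point by
#' `alpha(t) * exp(-lattice_dist(u, winner)^2 / (2 sigma(t)^2))`,
#' with `alpha` and `sigma` decaying as negative exponentials of the
#' presentation counter.  The returned model is the trial whose mean
#' quantization error on the full matrix is lowest.
#'
#' @param x Numeric matrix (items x experiments), already preprocessed.
#' @param config A [som_config()].
#' @return A `som_model` with elements `lattice`, `weights`
#'   (units x experiments), `config`, `final_score` and `trial_scores`.
#' @export
train_som <- function(x, config) {
  m <- as_data_matrix(x, "training matrix")
  if (nrow(m) < 1) stopf("training matrix has no rows")
  if (!all(is.finite(m))) stopf("training matrix contains non-finite values")
  lat <- hex_lattice(config$rows, config$cols)
  n <- nrow(m)
  n_train <- max(1L, as.integer(round(n * config$train_fraction)))
  total <- n_train * config$epochs
  sigma_min <- config$sigma_min %||% 0.25
  ratio <- config$sigma0 / sigma_min
  lambda <- config$decay_constant %||%
    (if (ratio > 1) total / log(ratio) else total)

  best <- NULL
  scores <- numeric(config$trials)
  for (trial in seq_len(config$trials)) {
    w <- local_seed(derive_seed(config$seed, trial), {
      train_rows <- sample.int(n, n_train)
      init <- m[sample.int(n, lat$n_units, replace = TRUE), , drop = FALSE]
      order0 <- as.integer(unlist(lapply(seq_len(config$epochs), function(e) {
        train_rows[sample.int(n_train)]
      }))) - 1L
      .som_train_cpp(m, init, order0, lat$hx, lat$hy,
                     config$alpha0, config$sigma0, lambda, sigma_min)
    })
    model_t <- structure(list(lattice = lat, weights = w, config = config,
                              final_score = NA_real_),
                         class = "som_model")
    scores[trial] <- score_som(model_t, m)
    if (is.null(best) || scores[trial] < best$final_score) {
      model_t$final_score <- scores[trial]
      best <- model_t
    }
  }
  best$trial_scores <- scores
  best
}

#' Mean quantization error of a SOM on a data matrix
#'
#' Mean over rows of the Euclidean distance to the closest unit.
#'
#' @param model A `som_model`.
#' @param x Data matrix with the model's experiment dimension.
#' @return A single number, `>= 0`.
#' @export
score_som <- function(model, x) {
  m <- as_data_matrix(x)
  if (ncol(m) != ncol(model$weights))
    stopf("dimension mismatch: matrix has %d columns, model %d",
          ncol(m), ncol(model$weights))
  mean(.som_bmu_cpp(m, model$weights)$dist)
}

#' Assign items to best-matching units
#'
#' @inheritParams score_som
#' @return A data.frame with columns `item`, `unit` (1-based, row-major) and
#'   `distance`; ties go to the lowest unit index.
#' @export
assign_items <- function(model, x) {
  m <- as_data_matrix(x)
  if (ncol(m) != ncol(model$weights))
    stopf("dimension mismatch: matrix has %d columns, model %d",
          ncol(m), ncol(model$weights))
  res <- .som_bmu_cpp(m, model$weights)
  data.frame(item = rownames(m), unit = res$bmu + 1L, distance = res$dist,
             stringsAsFactors = FALSE)
}

#' Per-experiment slice of the SOM weights
#'
#' @param model A `som_model`.
#' @param experiment Column index (or name) of the experiment dimension.
#' @return A `rows x cols` matrix of the chosen weight component, addressed
#'   by lattice row/column, suitable for heat-map rendering.
#' @export
slice_view <- function(model, experiment) {
  w <- model$weights
  if (is.character(experiment)) {
    experiment <- match(experiment, colnames(w))
    if (is.na(experiment)) stopf("unknown experiment name")
  }
  if (experiment < 1 || experiment > ncol(w)) stopf("experiment index out of range")
  matrix(w[, experiment], nrow = model$lattice$rows,
         ncol = model$lattice$cols, byrow = TRUE)
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("SOM model: %d x %d hexagonal lattice, %d experiments\n",
              x$lattice$rows, x$lattice$cols, ncol(x$weights)))
  cat(sprintf("  mean quantization error: %.4f (best of %d trials)\n",
              x$final_score, length(x$trial_scores %||% NA)))
  invisible(x)
}
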