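# Binary grey wolf channel selection.
#
# A pack of wolves explores channel subsets; each wolf carries a
# continuous position in [0,1]^d updated toward the three fittest wolves
# (alpha, beta, delta) by the canonical GWO rules, then mapped to a binary
# channel mask through a steep sigmoid transfer against per-dimension
# uniform draws. Fitness is the cross-validated accuracy of a KNN
# classifier on the masked channels, lightly penalised by subset size.

#' Sigmoid transfer function of the binary grey wolf optimizer
#'
#' `S(x) = 1 / (1 + exp(-10 * (x - 0.5)))`: a logistic centred at 0.5 with
#' slope 10, steep enough that positions near 0 or 1 map to near-certain
#' bits.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
#' @examples
#' sigmoid_transfer(c(0, 0.5, 1))
sigmoid_transfer <- function(x) 1 / (1 + exp(-10 * (x - 0.5)))

#' Binarize averaged leader candidates into a channel mask
#'
#' Per dimension, the bit is 1 iff `S((I1 + I2 + I3) / 3) > r3` with
#' `r3 ~ Uniform[0, 1]` drawn from the current RNG stream.
#'
#' @param i1,i2,i3 numeric vectors of equal length (leader-guided
#'   candidate positions).
#' @return integer mask of the same length.
#' @export
binarize <- function(i1, i2, i3) {
  d <- length(i1)
  if (length(i2) != d || length(i3) != d)
    stop("I1, I2, I3 must have the same length", call. = FALSE)
  as.integer(sigmoid_transfer((i1 + i2 + i3) / 3) > stats::runif(d))
}

#' BGWO configuration
#'
#' @param pack_size number of wolves (>= 3: alpha, beta, delta leaders).
#' @param n_iter iterations.
#' @param knn_k neighbours of the KNN wrapper fitness.
#' @param fitness_folds stratified CV folds used by the fitness.
#' @param cardinality_weight penalty weight on `|mask| / d`.
#' @param target_channels final subset size (the pipeline selects 5).
#' @param seed integer seed; the whole search is deterministic given it.
#' @return a `bgwo_config` list.
#' @export
bgwo_config <- function(pack_size = 10L, n_iter = 30L, knn_k = 5L,
                        fitness_folds = 5L, cardinality_weight = 0.01,
                        target_channels = 5L, seed = 1L) {
  stopifnot(pack_size >= 3, n_iter >= 1, target_channels >= 1)
  structure(list(pack_size = as.integer(pack_size), n_iter = as.integer(n_iter),
                 knn_k = as.integer(knn_k), fitness_folds = as.integer(fitness_folds),
                 cardinality_weight = cardinality_weight,
                 target_channels = as.integer(target_channels),
                 seed = as.integer(seed)),
            class = "bgwo_config")
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' KNN wrapper fitness of a channel mask
#'
#' Stratified `fitness_folds`-fold cross-validated accuracy of a
#' `knn_k`-nearest-neighbour classifier on the masked channels (features
#' z-scored on each training fold only), minus
#' `cardinality_weight * |mask| / d`. The empty mask scores 0 by
#' convention. The fold assignment depends only on `cfg$seed`, so fitness
#' values of different masks are comparable.
#'
#' @param features a `feature_matrix`.
#' @param mask binary vector over channels.
#' @param cfg a [bgwo_config()].
#' @return scalar fitness.
#' @export
knn_fitness <- function(features, mask, cfg = bgwo_config()) {
  d <- length(features$channel_groups)
  if (length(mask) != d)
    stop("mask length must equal the channel count", call. = FALSE)
  if (sum(mask) == 0) return(0)
  x <- mask_columns(features, mask)
  y <- factor(features$labels)
  folds <- stratified_folds(features$labels, cfg$fitness_folds, cfg$seed)
  correct <- 0L
  for (f in seq_len(cfg$fitness_folds)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sig <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sig[sig < .Machine$double.eps] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sig, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sig, "/")
    pred <- FNN::knn(xtr, xte, y[tr], k = cfg$knn_k)
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  correct / length(y) - cfg$cardinality_weight * sum(mask) / d
}

# canonical GWO candidate: X_leader - A * |C * X_leader - X|
gwo_candidate <- function(x, leader, a) {
  d <- length(x)
  aa <- 2 * a * stats::runif(d) - a
  cc <- 2 * stats::runif(d)
  leader - aa * abs(cc * leader - x)
}

#' Select channels by binary grey wolf optimization
#'
#' Wolves are initialised with random binary positions; each iteration
#' evaluates the KNN fitness of every wolf's mask, ranks the pack
#' (alpha >= beta >= delta), moves every wolf toward the three leaders via
#' the canonical GWO updates with exploration coefficient decaying
#' linearly 2 -> 0, and re-binarizes through [sigmoid_transfer()]. The
#' best mask ever seen is tracked elitistically and finally coerced to
#' exactly `target_channels` channels: backward elimination of the channel
#' whose removal costs the least fitness when the mask is too large,
#' greedy addition of the best channel when too small.
#'
#' @param features a `feature_matrix` with both classes present.
#' @param cfg a [bgwo_config()].
#' @return a `selection_result`: `mask` (exactly `target_channels` ones),
#'   `channels` (selected indices), `history` (best-so-far fitness per
#'   iteration, non-decreasing), `leader_fitness`, `evaluations`.
#' @export
bgwo_select <- function(features, cfg = bgwo_config()) {
  d <- length(features$channel_groups)
  if (length(unique(features$labels)) < 2)
    stop("channel selection needs both classes present", call. = FALSE)
  if (d < cfg$target_channels)
    stop("fewer channels than target_channels", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_of <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    val <- knn_fitness(features, mask, cfg)
    cache[[key]] <- val
    val
  }

  if (d == cfg$target_channels) {
    mask <- rep(1L, d)
    fit <- fit_of(mask)
    return(structure(list(mask = mask, channels = seq_len(d),
                          history = fit, leader_fitness = fit,
                          evaluations = n_eval),
                     class = "selection_result"))
  }

  with_seed(cfg$seed, {
    pos <- matrix(as.numeric(stats::runif(cfg$pack_size * d) > 0.5),
                  nrow = cfg$pack_size)
    masks <- matrix(as.integer(pos), nrow = cfg$pack_size)
    best_mask <- NULL; best_fit <- -Inf
    history <- numeric(cfg$n_iter)

    for (it in seq_len(cfg$n_iter)) {
      fits <- apply(masks, 1, fit_of)
      ord <- order(fits, decreasing = TRUE)
      leaders <- pos[ord[1:3], , drop = FALSE]
      if (fits[ord[1]] > best_fit) {
        best_fit <- fits[ord[1]]
        best_mask <- masks[ord[1], ]
      }
      history[it] <- best_fit

      a <- 2 - 2 * (it - 1) / max(1L, cfg$n_iter - 1L)
      for (w in seq_len(cfg$pack_size)) {
        i1 <- gwo_candidate(pos[w, ], leaders[1, ], a)
        i2 <- gwo_candidate(pos[w, ], leaders[2, ], a)
        i3 <- gwo_candidate(pos[w, ], leaders[3, ], a)
        masks[w, ] <- binarize(i1, i2, i3)
        pos[w, ] <- clamp((i1 + i2 + i3) / 3, 0, 1)
      }
    }

    # coerce the elitist mask to exactly target_channels channels
    mask <- best_mask
    while (sum(mask) > cfg$target_channels) {
      on <- which(mask == 1)
      drop_fit <- vapply(on, function(ch) {
        m <- mask; m[ch] <- 0L; fit_of(m)
      }, numeric(1))
      mask[on[which.max(drop_fit)]] <- 0L
    }
    while (sum(mask) < cfg$target_channels) {
      off <- which(mask == 0)
      add_fit <- vapply(off, function(ch) {
        m <- mask; m[ch] <- 1L; fit_of(m)
      }, numeric(1))
      mask[off[which.max(add_fit)]] <- 1L
    }

    structure(list(mask = mask, channels = which(mask == 1),
                   history = history, leader_fitness = fit_of(mask),
                   evaluations = n_eval),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> channels {%s}, fitness %.4f (%d evaluations)\n",
              paste(x$channels, collapse = ", "), x$leader_fitness, x$evaluations))
  invisible(x)
}
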