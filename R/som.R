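#' @useDynLib somportraits, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct an empty SOM grid
#'
#' @param kx,ky grid dimensions (tiles). Tiles are indexed row-major:
#'   linear index `k = (y - 1) * kx + x` with 1-based coordinates.
#' @param weights optional K x M weight matrix.
#' @return object of class `som_grid` with fields `kx`, `ky`, `k`,
#'   `coords` (K x 2 matrix of x, y) and `weights`.
#' @keywords internal
som_grid <- function(kx, ky, weights = NULL) {
  kx <- as.integer(kx); ky <- as.integer(ky)
  stopifnot(kx >= 1L, ky >= 1L)
  coords <- cbind(x = rep(seq_len(kx), times = ky),
                  y = rep(seq_len(ky), each = kx))
  structure(list(kx = kx, ky = ky, k = kx * ky, coords = coords,
                 weights = weights),
            class = "som_grid")
}

#' Linear (PCA-based) SOM initialization
#'
#' Places metagene profiles on the plane spanned by the two leading
#' eigenvectors of the gene-profile covariance: the tile at grid position
#' (x, y) gets `coeff_x * v1 + coeff_y * v2` with
#' `coeff = 2 * (pos - 1) / (dim - 1) - 1`, so coefficients span -1..1.
#' Eigenvectors are scaled by the standard deviation along each component
#' and sign-fixed (largest-magnitude element positive), making the
#' initialization deterministic and platform-reproducible.
#'
#' @param delta genes x samples matrix of gene-centered differential
#'   expression (rows are the training profiles).
#' @param dims integer vector `c(kx, ky)`.
#' @return a `som_grid` with initialized `weights` (K x M).
#' @export
som_linear_init <- function(delta, dims = c(60L, 60L)) {
  delta <- as.matrix(delta)
  if (ncol(delta) < 2L)
    stop("need at least 2 samples for linear initialization")
  if (nrow(delta) < 2L)
    stop("need at least 2 gene profiles")
  grid <- som_grid(dims[1L], dims[2L])
  cv <- crossprod(delta) / max(1L, nrow(delta) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] <= max(eg$values[1L], 0) * 1e-12 || eg$values[2L] <= 0)
    stop("gene-profile covariance has rank < 2; add samples or jitter the data")
  vs <- lapply(1:2, function(i) {
    v <- eg$vectors[, i] * sqrt(eg$values[i])
    if (v[which.max(abs(v))] < 0) v <- -v
    v
  })
  cx <- if (grid$kx == 1L) rep(0, grid$k) else
    2 * (grid$coords[, "x"] - 1) / (grid$kx - 1) - 1
  cy <- if (grid$ky == 1L) rep(0, grid$k) else
    2 * (grid$coords[, "y"] - 1) / (grid$ky - 1) - 1
  grid$weights <- outer(cx, vs[[1L]]) + outer(cy, vs[[2L]])
  colnames(grid$weights) <- colnames(delta)
  grid
}

#' Best-matching unit of a single profile
#'
#' @param profile numeric vector of length M.
#' @param grid a `som_grid` with weights.
#' @return 1-based linear tile index (row-major); ties go to the lowest
#'   index.
#' @export
best_matching_unit <- function(profile, grid) {
  stopifnot(inherits(grid, "som_grid"), length(profile) == ncol(grid$weights))
  d2 <- rowSums(sweep(grid$weights, 2L, profile)^2)
  which.min(d2)  # which.min takes the first (lowest index) on ties
}

#' Training schedule for the SOM
#'
#' The learning rate decays linearly from `rate_max` to `rate_min`; the
#' Gaussian neighborhood radius decays exponentially from `radius_init`
#' (default `kx / 2`, resolved at training time) to `radius_min` over the
#' presentation budget. The default final radius of 1.5 tiles keeps
#' neighboring prototypes weakly coupled at convergence, which keeps
#' co-expression clusters spatially compact instead of fragmenting them
#' over many tiles (the usual Kohonen recommendation of ending with a
#' non-vanishing neighborhood). Gene presentation order is a seeded
#' shuffled cyclic sweep so every gene is presented equally often.
#'
#' @param presentations total number of single-gene presentations.
#' @param rate_max,rate_min learning-rate bounds, in (0, 1].
#' @param radius_init initial neighborhood sigma (`NULL` = `kx / 2`).
#' @param radius_min final sigma (>= 0; 0 restricts updates to the BMU).
#' @param seed RNG seed for the presentation order.
#' @return object of class `som_schedule`.
#' @export
som_schedule <- function(presentations = 250000L, rate_max = 0.05,
                         rate_min = 0.01, radius_init = NULL,
                         radius_min = 1.5, seed = 42L) {
  presentations <- as.integer(presentations)
  stopifnot(presentations >= 1L,
            rate_max > 0, rate_max <= 1, rate_min >= 0, rate_min <= rate_max,
            is.null(radius_init) || radius_init >= 0, radius_min >= 0)
  structure(list(presentations = presentations, rate_max = rate_max,
                 rate_min = rate_min, radius_init = radius_init,
                 radius_min = radius_min, seed = as.integer(seed)),
            class = "som_schedule")
}

schedule_vectors <- function(schedule, grid, n_genes) {
  P <- schedule$presentations
  r0 <- schedule$radius_init %||% (grid$kx / 2)
  if (schedule$radius_min > r0)
    stop("radius must decrease: radius_min > initial radius")
  rate <- if (P == 1L) schedule$rate_max else
    seq(schedule$rate_max, schedule$rate_min, length.out = P)
  radius <- if (r0 == 0) {
    rep(0, P)
  } else if (schedule$radius_min > 0) {
    r0 * (schedule$radius_min / r0)^((seq_len(P) - 1L) / max(1L, P - 1L))
  } else if (P == 1L) {
    0
  } else {
    # decay toward a vanishing radius, exactly zero on the last presentation
    c(r0 * (min(r0, 1e-3) / r0)^((0:(P - 2L)) / (P - 1L)), 0)
  }
  ord <- with_seed(schedule$seed, {
    n_epochs <- ceiling(P / n_genes)
    idx <- unlist(lapply(seq_len(n_epochs), function(i) sample.int(n_genes)))
    idx[seq_len(P)]
  })
  list(rate = rate, radius = radius, order = ord)
}

#' Train a SOM on gene profiles
#'
#' Iteratively presents single gene profiles, finds the best-matching
#' metagene and moves it (and, Gaussian-weighted, its grid neighbors)
#' toward the profile. Fully deterministic for a fixed seed.
#'
#' @param delta genes x samples training matrix.
#' @param grid initialized `som_grid`.
#' @param schedule a [som_schedule()].
#' @return the `som_grid` with trained weights; the schedule is attached
#'   as attribute `"schedule"`.
#' @export
som_train <- function(delta, grid, schedule = som_schedule()) {
  delta <- as.matrix(delta)
  stopifnot(inherits(grid, "som_grid"), !is.null(grid$weights),
            ncol(delta) == ncol(grid$weights),
            inherits(schedule, "som_schedule"))
  sv <- schedule_vectors(schedule, grid, nrow(delta))
  w <- .som_train_cpp(delta, grid$weights,
                      as.integer(grid$coords[, "x"]),
                      as.integer(grid$coords[, "y"]),
                      as.integer(sv$order - 1L), sv$rate, sv$radius)
  if (!all(is.finite(w)))
    stop("non-finite metagene weights after training")
  dimnames(w) <- dimnames(grid$weights)
  grid$weights <- w
  attr(grid, "schedule") <- schedule
  grid
}

#' Map genes to their best-matching metagenes
#'
#' @param delta genes x samples matrix.
#' @param grid trained `som_grid`.
#' @return object of class `som_assignment`: `bmu` (named 1-based tile
#'   index per gene), `clusters` (list of gene-id vectors per tile, empty
#'   tiles allowed) and `n_k` (cluster sizes summing to N).
#' @export
map_genes <- function(delta, grid) {
  delta <- as.matrix(delta)
  stopifnot(inherits(grid, "som_grid"), ncol(delta) == ncol(grid$weights))
  if (is.null(rownames(delta)))
    rownames(delta) <- paste0("g", seq_len(nrow(delta)))
  bmu <- .som_bmu_cpp(delta, grid$weights)
  names(bmu) <- rownames(delta)
  clusters <- split(rownames(delta), factor(bmu, levels = seq_len(grid$k)))
  names(clusters) <- NULL
  n_k <- lengths(clusters)
  structure(list(bmu = bmu, clusters = clusters, n_k = n_k, k = grid$k),
            class = "som_assignment")
}

#' Extract one sample's metagene expression state
#'
#' @param grid trained `som_grid`.
#' @param m sample index (1-based) or sample name.
#' @return numeric K-vector: column `m` of the metagene weight matrix.
#' @export
metagene_expression_state <- function(grid, m) {
  stopifnot(inherits(grid, "som_grid"))
  if (is.character(m)) {
    m <- match(m, colnames(grid$weights))
    if (is.na(m)) stop("unknown sample name")
  }
  if (m < 1L || m > ncol(grid$weights))
    stop("sample index out of range")
  grid$weights[, m]
}

#' One-call SOM model: initialize, train, map
#'
#' @inheritParams som_train
#' @param dims grid dimensions `c(kx, ky)`.
#' @return object of class `som_model`: `grid` (trained), `assignment`,
#'   `dims`, `samples`.
#' @export
train_som <- function(delta, dims = c(60L, 60L), schedule = som_schedule()) {
  grid <- som_linear_init(delta, dims)
  grid <- som_train(delta, grid, schedule)
  structure(list(grid = grid, assignment = map_genes(delta, grid),
                 dims = c(grid$kx, grid$ky),
                 samples = colnames(delta)),
            class = "som_model")
}

#' Export SOM weights as TSV
#'
#' One row per tile with grid coordinates and the metagene profile.
#'
#' @param grid trained `som_grid`.
#' @param path output TSV path.
#' @export
write_som_weights <- function(grid, path) {
  df <- data.frame(tile = seq_len(grid$k),
                   x = grid$coords[, "x"], y = grid$coords[, "y"],
                   grid$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
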