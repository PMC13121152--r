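#' Hexagonal SOM grid
#'
#' Builds a `rows x cols` hexagonal lattice. Nodes are laid out in offset
#' coordinates (odd rows shifted by half a unit, vertical spacing
#' `sqrt(3)/2`) so that interior nodes have six unit-distance neighbours.
#' Neighbourhood relations during training use the link distance: the hop
#' count on the adjacency graph of the lattice, computed by breadth-first
#' search rather than a closed form.
#'
#' @param rows,cols positive integers.
#' @return An object of class `som_grid` with components `rows`, `cols`,
#'   `n_nodes`, `positions` (`K x 2` lattice coordinates), `adjacency`
#'   (binary `K x K`), and `link_dist` (integer `K x K` hop-count matrix).
#' @examples
#' g <- som_grid(4, 4)
#' g$link_dist[1, 2]  # adjacent nodes are 1 hop apart
#' @export
som_grid <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L)
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- (rc$col - 1) + 0.5 * ((rc$row - 1) %% 2)
  y <- (rc$row - 1) * sqrt(3) / 2
  pos <- cbind(x = x, y = y)
  K <- rows * cols
  d <- as.matrix(stats::dist(pos))
  adj <- (d > 0 & d < 1 + 1e-6) + 0L
  if (K > 1L) {
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ld <- igraph::distances(gr)
  } else {
    ld <- matrix(0, 1, 1)
  }
  structure(list(rows = rows, cols = cols, n_nodes = K,
                 positions = pos, adjacency = adj,
                 link_dist = ld),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("som_grid:", x$rows, "x", x$cols, "hexagonal,", x$n_nodes, "nodes\n")
  invisible(x)
}

#' Link distance between two grid nodes
#'
#' Minimum number of lattice edges connecting two nodes.
#'
#' @param grid a [som_grid()].
#' @param i,j node indices.
#' @return Non-negative integer hop count.
#' @export
link_distance <- function(grid, i, j) {
  K <- grid$n_nodes
  if (any(c(i, j) < 1L) || any(c(i, j) > K))
    stop_somase("som_invalid_node", "node index out of range")
  grid$link_dist[i, j]
}

#' Initialize SOM model vectors
#'
#' `mode = "random"` samples training points (with replacement) as initial
#' models. `mode = "linear"` places the models on a regular lattice in the
#' plane spanned by the first two principal components of the data, through
#' the data mean, which typically speeds up convergence.
#'
#' @param grid a [som_grid()].
#' @param data numeric matrix, observations in rows.
#' @param mode `"linear"` (default) or `"random"`.
#' @return An untrained `som_model`: list with `grid`, `codes` (`K x d`
#'   model vectors), `d`, `trained`, `schedule`.
#' @export
init_models <- function(grid, data, mode = c("linear", "random")) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("empty data")
  K <- grid$n_nodes
  d <- ncol(data)
  if (mode == "random") {
    codes <- data[sample.int(nrow(data), K, replace = TRUE), , drop = FALSE]
  } else {
    if (nrow(unique(data)) < 2L)
      stop_somase("som_degenerate_init",
                  "linear initialization needs at least 2 distinct points")
    ctr <- colMeans(data)
    pc <- stats::prcomp(data, center = TRUE, scale. = FALSE, rank. = 2L)
    v1 <- pc$rotation[, 1L]
    s1 <- pc$sdev[1L]
    if (ncol(pc$rotation) >= 2L && length(pc$sdev) >= 2L) {
      v2 <- pc$rotation[, 2L]; s2 <- pc$sdev[2L]
    } else {
      v2 <- rep(0, d); s2 <- 0
    }
    u <- if (grid$cols > 1L)
      seq(-1, 1, length.out = grid$cols) else 0
    w <- if (grid$rows > 1L)
      seq(-1, 1, length.out = grid$rows) else 0
    uv <- expand.grid(u = u, w = w)  # matches node order (col fastest)
    codes <- outer(uv$u * s1, v1) + outer(uv$w * s2, v2)
    codes <- sweep(codes, 2L, ctr, "+")
  }
  dimnames(codes) <- list(NULL, colnames(data))
  structure(list(grid = grid, codes = codes, d = d,
                 trained = FALSE, schedule = NULL),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$grid$rows, "x", x$grid$cols, "hex grid, d =", x$d,
      if (isTRUE(x$trained)) "(trained)" else "(untrained)", "\n")
  invisible(x)
}

# squared Euclidean cross-distances, n x K
cross_dist2 <- function(X, W) {
  D <- matrix(rowSums(X^2), nrow(X), nrow(W)) -
    2 * X %*% t(W) +
    matrix(rowSums(W^2), nrow(X), nrow(W), byrow = TRUE)
  D[D < 0] <- 0
  D
}

#' Batch neighbourhood radius schedules
#'
#' `batch_radius_schedule()` builds the default two-phase schedule: an
#' ordering phase over the first half of the epochs at constant radius
#' `r_ordering` (each node averages the points assigned to itself and to
#' its lattice neighbours within that radius), then a tuning phase at
#' `r_tuning`. The default ordering radius 1 restricts cooperation to the
#' six immediate hexagonal neighbours, and the default tuning radius 0
#' makes the second half pure competitive vector quantization — the
#' k-means limit a batch SOM approaches as its neighbourhood shrinks to
#' zero. `decaying_radius_schedule()` is the classical alternative with
#' the integer radius shrinking linearly from `r_start` to `r_end` over
#' the ordering phase and held at `r_end` afterwards.
#'
#' @param epochs total number of batch epochs.
#' @param r_ordering,r_tuning constant radii of the two phases.
#' @param r_start,r_end start/end radii of the linearly decaying variant.
#' @return Integer vector of length `epochs`.
#' @export
batch_radius_schedule <- function(epochs, r_ordering = 1L, r_tuning = 0L) {
  ordering <- max(1L, floor(epochs / 2))
  as.integer(c(rep(r_ordering, ordering),
               rep(r_tuning, epochs - ordering)))
}

#' @rdname batch_radius_schedule
#' @export
decaying_radius_schedule <- function(epochs, r_start = 3L, r_end = 1L) {
  ordering <- max(1L, floor(epochs / 2))
  r <- c(round(seq(r_start, r_end, length.out = ordering)),
         rep(r_end, epochs - ordering))
  as.integer(r[seq_len(epochs)])
}

#' Train a SOM
#'
#' Batch mode (default): per epoch, every point is assigned to its
#' best-matching unit (BMU), then each model vector is replaced by the mean
#' of all points whose BMU lies within the current neighbourhood radius
#' (link distance) of the node; nodes receiving no points keep their
#' previous vector. Membership in the batch neighbourhood is binary (a step
#' function of link distance). The default radius schedule is
#' [batch_radius_schedule()]: half the epochs at radius 1, half at radius
#' 0. With the radius pinned at 0 the update is exactly Lloyd's k-means
#' iteration on the node vectors.
#'
#' Online mode: classical per-sample rule
#' `w_i <- w_i + alpha(t) * h(i, bmu; t) * (x - w_i)` with a Gaussian
#' neighbourhood `h` over lattice positions; `alpha` decays linearly from
#' `alpha0` to `alpha1`, the Gaussian width `sigma` decays exponentially
#' from half the grid diameter to `sigma1`.
#'
#' @param model an initialized `som_model` (see [init_models()]).
#' @param data numeric matrix, observations in rows.
#' @param mode `"batch"` or `"online"`.
#' @param epochs number of passes over the data (default 200).
#' @param radius_schedule optional integer vector of per-epoch batch radii,
#'   overriding [batch_radius_schedule()].
#' @param alpha0,alpha1,sigma1 online-mode learning-rate and neighbourhood
#'   parameters.
#' @return The trained `som_model`.
#' @export
som_train <- function(model, data, mode = c("batch", "online"),
                      epochs = 200L, radius_schedule = NULL,
                      alpha0 = 0.5, alpha1 = 0.01, sigma1 = 0.5) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("empty data")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (ncol(data) != model$d) stop("dimension mismatch")
  W <- model$codes
  K <- model$grid$n_nodes
  ld <- model$grid$link_dist
  if (mode == "batch") {
    radii <- if (is.null(radius_schedule))
      batch_radius_schedule(epochs) else as.integer(radius_schedule)
    if (length(radii) < epochs) stop("radius schedule shorter than epochs")
    for (e in seq_len(epochs)) {
      bmu <- max.col(-cross_dist2(data, W), ties.method = "first")
      M <- (ld <= radii[e]) + 0
      tb <- rowsum(data, bmu)
      S <- matrix(0, K, model$d)
      S[as.integer(rownames(tb)), ] <- tb
      cnt <- tabulate(bmu, K)
      num <- M %*% S
      den <- as.vector(M %*% cnt)
      upd <- den > 0
      W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
    sched <- list(mode = "batch", epochs = epochs,
                  radii = radii[seq_len(epochs)])
  } else {
    n <- nrow(data)
    total <- n * epochs
    pos <- model$grid$positions
    sigma0 <- max(ld) / 2
    if (sigma0 <= 0) sigma0 <- sigma1
    step <- 0L
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (t in ord) {
        frac <- step / max(1L, total - 1L)
        alpha <- alpha0 + (alpha1 - alpha0) * frac
        sigma <- sigma0 * (sigma1 / sigma0)^frac
        x <- data[t, ]
        bmu <- which.min(colSums((t(W) - x)^2))
        d2 <- rowSums((pos - matrix(pos[bmu, ], K, 2, byrow = TRUE))^2)
        h <- exp(-d2 / (2 * sigma^2))
        W <- W + alpha * h * (matrix(x, K, model$d, byrow = TRUE) - W)
        step <- step + 1L
      }
    }
    sched <- list(mode = "online", epochs = epochs, alpha0 = alpha0,
                  alpha1 = alpha1, sigma0 = sigma0, sigma1 = sigma1)
  }
  model$codes <- W
  model$trained <- TRUE
  model$schedule <- sched
  model
}

#' Best and second-best matching units
#'
#' @param model a `som_model`.
#' @param x numeric vector (one observation) or matrix (rows =
#'   observations).
#' @return For a vector input, a list with `bmu`, `sbmu` (node indices,
#'   ties broken towards the lowest index), `bmu_vector`, `sbmu_vector`.
#'   For a matrix, a list of integer vectors `bmu` and `sbmu`.
#' @export
som_assign <- function(model, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$d)
    stop_somase("som_dim_mismatch", "input dimension mismatch")
  D <- cross_dist2(X, model$codes)
  bmu <- max.col(-D, ties.method = "first")
  D[cbind(seq_len(nrow(X)), bmu)] <- Inf
  sbmu <- max.col(-D, ties.method = "first")
  if (single)
    list(bmu = bmu[1L], sbmu = sbmu[1L],
         bmu_vector = model$codes[bmu[1L], ],
         sbmu_vector = model$codes[sbmu[1L], ])
  else
    list(bmu = bmu, sbmu = sbmu)
}

#' Mean squared quantization error
#'
#' Mean squared Euclidean distance between each observation and its BMU
#' model vector.
#'
#' @param model a `som_model`.
#' @param data numeric matrix.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(model, data) {
  data <- as.matrix(data)
  D <- cross_dist2(data, model$codes)
  mean(D[cbind(seq_len(nrow(data)), max.col(-D, ties.method = "first"))])
}

#' k-means baseline clustering
#'
#' Lloyd's algorithm with `k` centroids, used as a comparison backend for
#' the reconstruction pipeline (a SOM whose neighbourhood radius shrinks to
#' zero performs the same competitive vector quantization).
#'
#' @param data numeric matrix.
#' @param k number of clusters.
#' @param iter_max maximum Lloyd iterations.
#' @param nstart random restarts.
#' @return A `stats::kmeans` fit.
#' @export
kmeans_baseline <- function(data, k, iter_max = 100L, nstart = 1L) {
  if (k < 1L) stop("k must be >= 1")
  data <- as.matrix(data)
  if (k > nrow(data)) stop("k exceeds the number of points")
  stats::kmeans(data, centers = k, iter.max = iter_max,
                nstart = nstart, algorithm = "Lloyd")
}

#' Serialize / restore a SOM model
#'
#' Plain-text (JSON) dump of the grid shape, training schedule and model
#' vectors; `read_som_model(write_som_model(m, f))` restores an equivalent
#' model.
#'
#' @param model a `som_model`.
#' @param path file path.
#' @return `path` (writer) or the restored `som_model` (reader).
#' @export
write_som_model <- function(model, path) {
  obj <- list(rows = model$grid$rows, cols = model$grid$cols,
              d = model$d, trained = model$trained,
              schedule = model$schedule, codes = model$codes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_som_model
#' @export
read_som_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- som_grid(obj$rows, obj$cols)
  codes <- obj$codes
  if (!is.matrix(codes))
    codes <- matrix(as.numeric(unlist(codes)), grid$n_nodes, obj$d,
                    byrow = TRUE)
  structure(list(grid = grid, codes = codes, d = obj$d,
                 trained = isTRUE(obj$trained),
                 schedule = obj$schedule),
            class = "som_model")
}
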