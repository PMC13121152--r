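#' Jaccard similarity graph of a population
#'
#' Pairwise multiset Jaccard similarity between individual signatures:
#' the sum of shared allele multiplicities over the sum of union
#' multiplicities. Homozygous genes weigh their single expressed allele
#' with multiplicity 2, so agreement on homozygosity counts double.
#'
#' @param x an [ase_matrix()] with at least 2 individuals.
#' @param self_similarity value placed on the diagonal; the default 1
#'   (every signature is identical to itself) makes the Nystrom extension
#'   of a training individual reproduce its in-sample embedding exactly.
#'   Set to 0 for the zero-diagonal convention.
#' @return An `m x m` symmetric matrix of class `similarity_graph` with
#'   entries in `[0, 1]` and attribute `empty_signatures` naming
#'   individuals with no expressed allele (similarity 0 to everyone).
#' @export
jaccard_graph <- function(x, self_similarity = 1) {
  m <- ncol(x$counts)
  if (m < 2L) stop("need at least 2 individuals")
  S <- signature_matrix(x)
  W <- jaccard_from_multiplicities(S, S)
  diag(W) <- ifelse(colSums(S) > 0, self_similarity, 0)
  dimnames(W) <- list(colnames(x$counts), colnames(x$counts))
  empties <- colnames(x$counts)[colSums(S) == 0]
  structure(W, class = c("similarity_graph", "matrix"),
            empty_signatures = empties)
}

# multiplicity matrix (rows = alleles, entries 0/1/2) of all columns
signature_matrix <- function(x) {
  S <- apply(x$counts, 2L,
             function(col) signature_multiplicities(col, x$family))
  matrix(S, nrow = x$family$n_alleles,
         dimnames = list(x$family$row_labels, colnames(x$counts)))
}

# multiset Jaccard between the columns of two multiplicity matrices;
# min(a, b) decomposes over the level indicators 1{.>=1}, 1{.>=2}
jaccard_from_multiplicities <- function(A, B) {
  inter <- crossprod((A >= 1) + 0, (B >= 1) + 0) +
    crossprod((A >= 2) + 0, (B >= 2) + 0)
  ta <- colSums(A); tb <- colSums(B)
  uni <- outer(ta, tb, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  unname(J)
}

#' Spectral embedding from the normalized symmetric Laplacian
#'
#' Computes the normalized symmetric Laplacian
#' `L = I - Deg^{-1/2} W Deg^{-1/2}` of the similarity graph and embeds
#' each individual by the eigenvectors of its `K` smallest eigenvalues
#' (equivalently the `K` largest eigenvalues of the normalized affinity).
#' Eigenvector signs follow a deterministic convention (first non-zero
#' coordinate positive); rows of the coordinate matrix are optionally
#' normalized to unit length.
#'
#' @param graph a [jaccard_graph()] (or any symmetric non-negative
#'   similarity matrix).
#' @param K embedding dimension, at most the number of individuals.
#' @param row_normalize normalize each individual's coordinate row to unit
#'   Euclidean length (default `TRUE`).
#' @return List of class `spectral_basis` with: `coords` (`m x K`
#'   in-sample coordinates), `vectors` (unnormalized eigenvectors),
#'   `affinity_values` (eigenvalues of the normalized affinity, descending),
#'   `laplacian_values` (`1 -` the former, ascending, in `[0, 2]`),
#'   `degrees`, `row_normalize`.
#' @export
laplacian_embedding <- function(graph, K, row_normalize = TRUE) {
  W <- unclass(graph)
  m <- nrow(W)
  stopifnot(K >= 1L, K <= m)
  deg <- rowSums(W)
  if (any(deg <= 0)) {
    who <- rownames(W)[deg <= 0]
    if (is.null(who)) who <- which(deg <= 0)
    stop_somase("spectral_isolated_vertex",
                paste0("isolated individual(s) in the similarity graph: ",
                       paste(who, collapse = ", ")))
  }
  dhalf <- 1 / sqrt(deg)
  A <- W * outer(dhalf, dhalf)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  idx <- seq_len(K)  # eigen() returns values in decreasing order
  U <- eg$vectors[, idx, drop = FALSE]
  # deterministic sign: first coordinate of non-negligible magnitude > 0
  for (k in seq_len(K)) {
    nz <- which(abs(U[, k]) > 1e-12)
    if (length(nz) && U[nz[1L], k] < 0) U[, k] <- -U[, k]
  }
  coords <- if (row_normalize) normalize_rows(U) else U
  rownames(coords) <- rownames(W)
  structure(list(coords = coords, vectors = U,
                 affinity_values = eg$values[idx],
                 laplacian_values = 1 - eg$values[idx],
                 degrees = deg, row_normalize = row_normalize),
            class = "spectral_basis")
}

normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat("spectral_basis:", nrow(x$coords), "individuals embedded in",
      ncol(x$coords), "dimensions\n")
  invisible(x)
}

#' Nystrom out-of-sample extension
#'
#' Projects a new (e.g. corrupted) individual into the trained eigenspace
#' from its similarity vector to the training individuals, without
#' recomputing the graph spectrum: the similarities are degree-normalized
#' like the training affinity and each coordinate is the scaled inner
#' product with the corresponding eigenvector,
#' `u[k] = sum_j a[j] U[j, k] / lambda[k]`. Feeding a training
#' individual's own similarity row reproduces its in-sample coordinates.
#'
#' @param basis a [laplacian_embedding()] result.
#' @param similarities numeric vector of similarities to the training
#'   individuals (length m), including the self-similarity entry when the
#'   point is one of them.
#' @return Length-`K` coordinate vector (row-normalized when the basis
#'   was); all zeros with attribute `flagged = TRUE` when the point has no
#'   similarity to any training individual.
#' @export
nystrom_extend <- function(basis, similarities) {
  m <- length(basis$degrees)
  stopifnot(length(similarities) == m)
  d_new <- sum(similarities)
  K <- ncol(basis$vectors)
  if (d_new <= 0)
    return(structure(rep(0, K), flagged = TRUE))
  a <- similarities / sqrt(d_new * basis$degrees)
  u <- as.vector(crossprod(basis$vectors, a))
  lam <- basis$affinity_values
  safe <- abs(lam) > 1e-10
  u[safe] <- u[safe] / lam[safe]
  u[!safe] <- 0
  if (basis$row_normalize) {
    nrm <- sqrt(sum(u^2))
    if (nrm > 0) u <- u / nrm
  }
  u
}

#' Nystrom projection of corrupted individuals
#'
#' Convenience wrapper: computes the Jaccard similarities of each column
#' of `x_new` to the training individuals and applies [nystrom_extend()].
#'
#' @param basis a [laplacian_embedding()] result.
#' @param x_train the training [ase_matrix()] the basis was built from.
#' @param x_new an `ase_matrix` of individuals to project (same gene
#'   family), or a single count column.
#' @param self_similarity diagonal convention used when the graph was
#'   built (see [jaccard_graph()]).
#' @return Matrix of coordinates, one row per projected individual.
#' @export
nystrom_project <- function(basis, x_train, x_new, self_similarity = 1) {
  S_train <- signature_matrix(x_train)
  cols <- if (inherits(x_new, "ase_matrix")) x_new$counts else
    matrix(x_new, ncol = 1L)
  S_new <- apply(cols, 2L,
                 function(col) signature_multiplicities(col, x_train$family))
  S_new <- matrix(S_new, nrow = x_train$family$n_alleles)
  Wn <- jaccard_from_multiplicities(S_train, S_new)  # m_train x m_new
  out <- t(vapply(seq_len(ncol(Wn)),
                  function(j) nystrom_extend(basis, Wn[, j]),
                  numeric(ncol(basis$vectors))))
  out
}
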