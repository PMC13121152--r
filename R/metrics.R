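#' Clustering validity and reconstruction accuracy indices
#'
#' `sqi()`, `fmi()` and `nmi()` compare a clustering `C` with a
#' ground-truth labeling `G` over the same elements; `rand_similarity()`
#' compares the clusterings of a population and of its corrupted copy. All
#' four equal 1 on identical partitions and are invariant under block
#' relabeling.
#'
#' The Simple Quality Index (SQI) is the product of two averaged
#' best-overlap fractions: over clusters, the probability that a random
#' member of a cluster carries the cluster's most common label, and the
#' same with the roles of clusters and labels swapped.
#'
#' @param C,G vectors of block labels, one entry per element, in the same
#'   element order.
#' @return Scalar in `[0, 1]`.
#' @name validity_indices
NULL

check_partitions <- function(C, G) {
  if (length(C) != length(G))
    stop_somase("metrics_element_mismatch",
                "partitions are over different element sets")
  list(C = as.character(C), G = as.character(G))
}

#' @rdname validity_indices
#' @export
sqi <- function(C, G) {
  p <- check_partitions(C, G)
  tab <- table(p$C, p$G)
  f1 <- mean(apply(tab, 1L, max) / rowSums(tab))
  f2 <- mean(apply(tab, 2L, max) / colSums(tab))
  f1 * f2
}

# pair-counting summary shared by fmi and rand_similarity
pair_counts <- function(C, G) {
  tab <- table(C, G)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2L))
  sum_i <- sum(choose(rowSums(tab), 2L))
  sum_j <- sum(choose(colSums(tab), 2L))
  list(TP = sum_ij, FP = sum_i - sum_ij, FN = sum_j - sum_ij,
       TN = choose(n, 2L) - sum_i - sum_j + sum_ij, total = choose(n, 2L))
}

#' @rdname validity_indices
#' @export
fmi <- function(C, G) {
  p <- check_partitions(C, G)
  if (length(p$C) < 2L)
    stop_somase("metrics_too_few_elements", "need at least 2 elements")
  pc <- pair_counts(p$C, p$G)
  if (pc$TP + pc$FP == 0 || pc$TP + pc$FN == 0) return(0)
  sqrt((pc$TP / (pc$TP + pc$FP)) * (pc$TP / (pc$TP + pc$FN)))
}

#' @rdname validity_indices
#' @export
nmi <- function(C, G) {
  p <- check_partitions(C, G)
  tab <- table(p$C, p$G) / length(p$C)
  hx <- -sum(ifelse(rowSums(tab) > 0,
                    rowSums(tab) * log(rowSums(tab)), 0))
  hy <- -sum(ifelse(colSums(tab) > 0,
                    colSums(tab) * log(colSums(tab)), 0))
  if (hx == 0 || hy == 0) return(0)
  ex <- outer(rowSums(tab), colSums(tab))
  nzidx <- tab > 0
  mi <- sum(tab[nzidx] * log(tab[nzidx] / ex[nzidx]))
  mi / sqrt(hx * hy)
}

#' Rand similarity between a population and its corrupted copy
#'
#' Standard pairwise Rand index between the cluster assignments of the
#' original individuals and those of their corrupted copies (copy j is
#' matched to individual j): the fraction of unordered element pairs on
#' which the two clusterings agree (co-clustered in both or separated in
#' both), out of `choose(m, 2)`. The cruder per-individual agreement is
#' available as [same_cluster_fraction()].
#'
#' @param C_orig,C_corr cluster assignments of the original and corrupted
#'   populations, matched element-wise.
#' @return Scalar in `[0, 1]`.
#' @export
rand_similarity <- function(C_orig, C_corr) {
  p <- check_partitions(C_orig, C_corr)
  if (length(p$C) < 2L)
    stop_somase("metrics_too_few_elements",
                "pairwise Rand index needs at least 2 elements")
  pc <- pair_counts(p$C, p$G)
  (pc$TP + pc$TN) / pc$total
}

#' @rdname rand_similarity
#' @export
same_cluster_fraction <- function(C_orig, C_corr) {
  p <- check_partitions(C_orig, C_corr)
  mean(p$C == p$G)
}

#' Reconstruction outcome for one individual
#'
#' Bookkeeping container for scoring one reconstructed individual:
#' `deleted` are the allele keys zeroed by corruption, `guessed` the subset
#' the completion rule correctly restored, and `true_counts` /
#' `predicted_counts` the read counts on the guessed alleles.
#'
#' @param deleted character vector of deleted allele keys.
#' @param guessed character subset of `deleted` correctly predicted.
#' @param true_counts,predicted_counts positive counts on `guessed`, in
#'   the same order.
#' @return An object of class `reconstruction_outcome`.
#' @export
reconstruction_outcome <- function(deleted, guessed,
                                   true_counts = numeric(0),
                                   predicted_counts = numeric(0)) {
  if (!all(guessed %in% deleted))
    stop("guessed must be a subset of deleted")
  stopifnot(length(true_counts) == length(guessed),
            length(predicted_counts) == length(guessed))
  structure(list(deleted = as.character(deleted),
                 guessed = as.character(guessed),
                 true_counts = as.numeric(true_counts),
                 predicted_counts = as.numeric(predicted_counts)),
            class = "reconstruction_outcome")
}

#' Allele accuracy of a reconstruction
#'
#' Fraction of deleted alleles whose identity the completion rule
#' recovered, regardless of the predicted read count.
#'
#' @param outcome a [reconstruction_outcome()].
#' @return Scalar in `[0, 1]`, or `NA` when nothing was deleted (such
#'   not-applicable cells are excluded from averages).
#' @export
allele_accuracy <- function(outcome) {
  if (length(outcome$deleted) == 0L) return(NA_real_)
  length(outcome$guessed) / length(outcome$deleted)
}

#' Read error of a reconstruction
#'
#' Mean relative absolute error of the predicted read counts over the
#' correctly guessed alleles; a value of 1.2 means predicted reads equal
#' 2.2 times the actual reads on average.
#'
#' @param outcome a [reconstruction_outcome()].
#' @return Non-negative scalar, or `NA` when no allele was guessed.
#' @export
read_error <- function(outcome) {
  if (length(outcome$guessed) == 0L) return(NA_real_)
  mean(abs(outcome$true_counts - outcome$predicted_counts) /
         outcome$true_counts)
}
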