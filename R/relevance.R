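#' Local error contribution index
#'
#' Shares out the squared distance between an input profile and its BMU
#' model vector across features:
#' `R[k] = (x[k] - bmu[k])^2 / sum_l (x[l] - bmu[l])^2`. High values flag
#' alleles pulling the individual away from its cluster centroid.
#'
#' @param x input vector (a corrupted individual's profile).
#' @param bmu_vector model vector of its best-matching unit.
#' @return Numeric vector summing to 1, entries in `[0, 1]`. When `x`
#'   equals the BMU vector the contribution is undefined: an all-zero
#'   vector with attribute `degenerate = TRUE` is returned.
#' @export
local_error_contribution <- function(x, bmu_vector) {
  stopifnot(length(x) == length(bmu_vector))
  d2 <- (x - bmu_vector)^2
  tot <- sum(d2)
  if (tot == 0)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  d2 / tot
}

#' Discriminative index
#'
#' Signed per-feature margin between the distances to the second-best and
#' best matching units: `delta[k] = (x[k] - sbmu[k])^2 - (x[k] - bmu[k])^2`,
#' normalized as `D[k] = delta[k] / sum_l |delta[l]|`. Positive entries
#' support the winning assignment; negative entries favour the runner-up.
#' The margins always sum to a non-negative value because the BMU is at
#' least as close as the sBMU.
#'
#' @param x input vector.
#' @param bmu_vector,sbmu_vector model vectors of the best and second-best
#'   matching units.
#' @return Numeric vector with `sum(abs(D)) == 1`, entries in `[-1, 1]`;
#'   all zeros with attribute `degenerate = TRUE` when every margin is 0.
#' @export
discriminative_index <- function(x, bmu_vector, sbmu_vector) {
  stopifnot(length(x) == length(bmu_vector),
            length(x) == length(sbmu_vector))
  delta <- (x - sbmu_vector)^2 - (x - bmu_vector)^2
  tot <- sum(abs(delta))
  if (tot == 0)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  delta / tot
}

#' Relevance profiles of a test population
#'
#' Computes, for every row of `X`, the BMU/sBMU assignment on the trained
#' map and the two per-feature relevance indices.
#'
#' @param model a trained `som_model`.
#' @param X matrix of profiles (rows = individuals).
#' @return List with matrices `R` and `D` (individuals x features) and the
#'   integer vectors `bmu`, `sbmu`.
#' @export
relevance_profiles <- function(model, X) {
  X <- as.matrix(X)
  asg <- som_assign(model, X)
  Rm <- matrix(0, nrow(X), ncol(X))
  Dm <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    Rm[i, ] <- local_error_contribution(X[i, ], model$codes[asg$bmu[i], ])
    Dm[i, ] <- discriminative_index(X[i, ], model$codes[asg$bmu[i], ],
                                    model$codes[asg$sbmu[i], ])
  }
  colnames(Rm) <- colnames(X); colnames(Dm) <- colnames(X)
  list(R = Rm, D = Dm, bmu = asg$bmu, sbmu = asg$sbmu)
}

#' Population-level relevance and Z-scores
#'
#' Averages per-individual relevance vectors over a corrupted test
#' population, then across repeated test populations generated at the same
#' corruption level, and standardizes the resulting mean vectors across
#' alleles: `Z[k] = (mean[k] - mean(mean)) / sd(mean)`.
#'
#' @param R_list list of `R` matrices (one per test population repeat,
#'   individuals x features), as produced by [relevance_profiles()].
#' @param D_list matching list of `D` matrices.
#' @return An object of class `population_relevance`: list with `Rbar`,
#'   `Dbar` (per-allele means), `Z_R`, `Z_D`, and `degenerate` flags set
#'   when a mean vector has zero variance (no selection is then possible).
#' @export
population_relevance <- function(R_list, D_list) {
  if (!is.list(R_list)) R_list <- list(R_list)
  if (!is.list(D_list)) D_list <- list(D_list)
  stopifnot(length(R_list) > 0L, length(R_list) == length(D_list))
  Rbar <- Reduce(`+`, lapply(R_list, colMeans)) / length(R_list)
  Dbar <- Reduce(`+`, lapply(D_list, colMeans)) / length(D_list)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(list(z = rep(0, length(v)), flag = TRUE))
    list(z = (v - mean(v)) / s, flag = FALSE)
  }
  zr <- zscore(Rbar); zd <- zscore(Dbar)
  structure(list(Rbar = Rbar, Dbar = Dbar,
                 Z_R = stats::setNames(zr$z, names(Rbar)),
                 Z_D = stats::setNames(zd$z, names(Dbar)),
                 degenerate = c(R = zr$flag, D = zd$flag)),
            class = "population_relevance")
}

#' @export
print.population_relevance <- function(x, ...) {
  cat("population_relevance:", length(x$Rbar), "alleles; max Z_R =",
      round(max(x$Z_R), 2), ", max |Z_D| =",
      round(max(abs(x$Z_D)), 2), "\n")
  invisible(x)
}

#' Select statistically relevant alleles and genes by Z-score
#'
#' An allele is R-selected when its local-error-contribution Z-score is at
#' least `critical` at one or more corruption levels (right tail: alleles
#' contributing significantly more error than average), and D-selected when
#' the magnitude of its discriminative-index Z-score reaches `critical` at
#' one or more levels; the sign of the extreme Z is recorded. Selected
#' alleles are mapped to genes through the gene family; the gene set is the
#' union of the selected alleles' genes.
#'
#' @param pop_levels list of [population_relevance()] objects, one per
#'   corruption level (names = levels).
#' @param family a [gene_family()] whose row order matches the relevance
#'   vectors.
#' @param critical Z threshold; the default 1.96 corresponds to a 95%
#'   two-sided normal confidence level.
#' @return List with data frames `R_selected` (`allele`, `gene`, `max_z`)
#'   and `D_selected` (`allele`, `gene`, `max_abs_z`, `sign`), plus
#'   character vectors `R_genes` and `D_genes`.
#' @export
zscore_select <- function(pop_levels, family, critical = 1.96) {
  if (inherits(pop_levels, "population_relevance"))
    pop_levels <- list(pop_levels)
  ZR <- do.call(rbind, lapply(pop_levels, `[[`, "Z_R"))
  ZD <- do.call(rbind, lapply(pop_levels, `[[`, "Z_D"))
  drop_deg <- vapply(pop_levels, function(p) p$degenerate[["R"]], logical(1))
  if (any(drop_deg)) ZR <- ZR[!drop_deg, , drop = FALSE]
  drop_deg_d <- vapply(pop_levels, function(p) p$degenerate[["D"]],
                       logical(1))
  if (any(drop_deg_d)) ZD <- ZD[!drop_deg_d, , drop = FALSE]
  labels <- family$row_labels
  r_max <- if (nrow(ZR)) apply(ZR, 2L, max) else rep(-Inf, length(labels))
  r_sel <- which(r_max >= critical)
  d_ext <- if (nrow(ZD)) apply(ZD, 2L, function(v) v[which.max(abs(v))])
  else rep(0, length(labels))
  d_sel <- which(abs(d_ext) >= critical)
  R_selected <- data.frame(allele = labels[r_sel],
                           gene = family$row_gene[r_sel],
                           max_z = unname(r_max[r_sel]),
                           stringsAsFactors = FALSE)
  D_selected <- data.frame(allele = labels[d_sel],
                           gene = family$row_gene[d_sel],
                           max_abs_z = abs(unname(d_ext[d_sel])),
                           sign = sign(unname(d_ext[d_sel])),
                           stringsAsFactors = FALSE)
  list(R_selected = R_selected, D_selected = D_selected,
       R_genes = unique(R_selected$gene), D_genes = unique(D_selected$gene))
}
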