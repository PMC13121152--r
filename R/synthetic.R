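#' Configuration of the artificial study population
#'
#' Defaults describe the simulated RNA-seq design used throughout the
#' package's validation: 10 genes with 10 observed alleles each, a genoset
#' of 100 distinct signatures, every signature heterozygous at every gene
#' (2 distinct alleles per gene, 20 alleles in total), and integer read
#' counts drawn uniformly from 1..700.
#'
#' @param n_genes number of genes.
#' @param alleles_per_gene observed alleles per gene.
#' @param genoset_size number of distinct signatures.
#' @param count_range inclusive integer range of read counts.
#' @return List of class `artificial_config`.
#' @export
artificial_config <- function(n_genes = 10L, alleles_per_gene = 10L,
                              genoset_size = 100L,
                              count_range = c(1L, 700L)) {
  stopifnot(n_genes >= 1L, alleles_per_gene >= 2L, genoset_size >= 1L,
            length(count_range) == 2L, count_range[1L] >= 1L,
            count_range[2L] >= count_range[1L])
  n_pairs <- choose(alleles_per_gene, 2L)
  if (genoset_size > n_pairs^n_genes)
    stop("infeasible config: fewer possible signatures than genoset_size")
  structure(list(n_genes = as.integer(n_genes),
                 alleles_per_gene = as.integer(alleles_per_gene),
                 genoset_size = as.integer(genoset_size),
                 alleles_per_signature = 2L * as.integer(n_genes),
                 count_range = as.integer(count_range)),
            class = "artificial_config")
}

artificial_family <- function(cfg) {
  genes <- sprintf("g%d", seq_len(cfg$n_genes))
  labs <- stats::setNames(
    rep(list(sprintf("A%d", seq_len(cfg$alleles_per_gene))), cfg$n_genes),
    genes)
  gene_family(genes, labs)
}

#' Generate a genoset of distinct signatures
#'
#' Each signature picks 2 distinct alleles per gene uniformly at random;
#' duplicate signatures are redrawn until the requested number of distinct
#' signatures is reached.
#'
#' @param cfg an [artificial_config()].
#' @return Integer matrix `genoset_size x (2 * n_genes)` of expression-row
#'   indices (class `signature_set`), two sorted rows per gene.
#' @export
generate_genoset <- function(cfg) {
  draw_one <- function() {
    unlist(lapply(seq_len(cfg$n_genes), function(g) {
      offset <- (g - 1L) * cfg$alleles_per_gene
      offset + sort(sample.int(cfg$alleles_per_gene, 2L))
    }))
  }
  sigs <- matrix(0L, cfg$genoset_size, 2L * cfg$n_genes)
  keys <- character(0)
  i <- 1L
  while (i <= cfg$genoset_size) {
    s <- draw_one()
    k <- paste(s, collapse = ",")
    if (!k %in% keys) {
      sigs[i, ] <- s
      keys <- c(keys, k)
      i <- i + 1L
    }
  }
  structure(sigs, class = c("signature_set", "matrix"))
}

#' Generate an artificial population with known ground truth
#'
#' Every individual draws its signature uniformly from the genoset and an
#' independent uniform integer read count for each of its expressed
#' alleles, so the population represents the whole genoset almost
#' uniformly. The signature index serves as the ground-truth label.
#'
#' @param cfg an [artificial_config()].
#' @param m population size.
#' @param genoset optional [generate_genoset()] result to share between
#'   training and test populations; generated fresh when `NULL`.
#' @return List with `matrix` (an [ase_matrix()]), `labels` (integer
#'   signature index per individual), and `genoset`.
#' @export
generate_artificial_population <- function(cfg, m, genoset = NULL) {
  if (is.null(genoset)) genoset <- generate_genoset(cfg)
  fam <- artificial_family(cfg)
  m <- as.integer(m)
  labels <- sample.int(nrow(genoset), m, replace = TRUE)
  rows_per <- ncol(genoset)
  rowidx <- t(genoset[labels, , drop = FALSE])
  vals <- sample.int(cfg$count_range[2L] - cfg$count_range[1L] + 1L,
                     rows_per * m, replace = TRUE) + cfg$count_range[1L] - 1L
  cnt <- matrix(0L, fam$n_alleles, m)
  cnt[cbind(as.vector(rowidx), rep(seq_len(m), each = rows_per))] <- vals
  mat <- ase_matrix(cnt, fam,
                    individuals = sprintf("ind%d", seq_len(m)))
  list(matrix = mat, labels = labels, genoset = genoset)
}

# ---- evolutionary expansion ------------------------------------------------

#' Paired (allele-index, read-count) representation of an individual
#'
#' One row per expression-matrix row: the first column holds the allele's
#' index within its gene when expressed (0 otherwise), the second the read
#' count. This is the representation parents and offspring take during
#' evolutionary expansion.
#'
#' @param x an [ase_matrix()].
#' @param individual column identifier.
#' @return Integer matrix `n_alleles x 2` with columns `index`, `count`.
#' @export
parent_matrix <- function(x, individual) {
  j <- match(as.character(individual), colnames(x$counts))
  if (is.na(j))
    stop_somase("ase_unknown_individual",
                paste("unknown individual:", individual))
  cnt <- x$counts[, j]
  within <- stats::ave(seq_along(cnt), x$family$row_gene,
                       FUN = seq_along)
  cbind(index = ifelse(cnt > 0L, within, 0L), count = cnt)
}

#' Selected parent pair
#'
#' @param x an [ase_matrix()].
#' @param father,mother column identifiers of the two parents.
#' @return List of class `parent_pair` with the two [parent_matrix()]
#'   representations and the variances of their read-count vectors.
#' @export
parent_pair <- function(x, father, mother) {
  pm <- parent_matrix(x, father)
  pf <- parent_matrix(x, mother)
  structure(list(father = pm, mother = pf,
                 var_father = stats::var(as.numeric(pm[, "count"])),
                 var_mother = stats::var(as.numeric(pf[, "count"]))),
            class = "parent_pair")
}

#' Mating index of a parent pair
#'
#' `I = 1 + var(father counts) - var(mother counts)`; a non-negative value
#' makes the father the primary contributor during recombination, a
#' negative value the mother.
#'
#' @param pair a [parent_pair()], or the father's count variance when
#'   `var_mother` is given.
#' @param var_mother mother's count variance (scalar interface).
#' @return Signed scalar.
#' @export
mating_index <- function(pair, var_mother = NULL) {
  if (inherits(pair, "parent_pair"))
    return(1 + pair$var_father - pair$var_mother)
  1 + pair - var_mother
}

#' Hardy-Weinberg offspring of a parent pair
#'
#' Random-mating recombination: for each locus an independent fair
#' Bernoulli indicator selects exactly one parent, and the offspring
#' copies that parent's (allele index, read count) entry, producing a
#' mosaic of the parental profiles. The sign of the mating index decides
#' which parent the indicator refers to (primary parent), which matters
#' only for reproducibility of the draw, not for the offspring
#' distribution.
#'
#' @param pair a [parent_pair()].
#' @return Offspring matrix (`n_alleles x 2`, columns `index`, `count`)
#'   with attribute `from_father`, the per-locus provenance.
#' @export
hw_offspring <- function(pair) {
  L <- nrow(pair$father)
  primary_first <- mating_index(pair) >= 0
  alpha <- stats::runif(L) < 0.5
  from_father <- if (primary_first) alpha else !alpha
  child <- pair$father
  child[!from_father, ] <- pair$mother[!from_father, , drop = FALSE]
  structure(child, from_father = from_father)
}

#' Mutate an individual's paired representation
#'
#' Touches exactly `ceiling(rate * n_alleles)` loci (matrix rows), chosen
#' uniformly. `scramble` randomly permutes the selected loci's
#' (index, count) pairs; `swap` cyclically exchanges them (a plain swap for
#' two loci); `reset` replaces each selected locus with the (index, count)
#' state of a uniformly drawn reference individual at the same locus, so
#' new allele states always lie in the locus's observed state set and new
#' counts follow the empirical read-count distribution. With
#' `within_gene = TRUE` (default) scramble and swap only move content
#' between loci of the same gene, which preserves the per-gene expressed
#' allele count.
#'
#' @param ind individual as a [parent_matrix()]-style matrix.
#' @param support an [ase_matrix()] providing the empirical per-locus
#'   state distribution for `reset`.
#' @param rate fraction of loci to mutate (default 0.03).
#' @param operator one of `"scramble"`, `"swap"`, `"reset"`.
#' @param within_gene confine scramble/swap moves to gene blocks.
#' @return Mutated matrix with attribute `mutated_loci` (the selected
#'   rows).
#' @export
mutate_individual <- function(ind, support,
                              operator = c("scramble", "swap", "reset"),
                              rate = 0.03, within_gene = TRUE) {
  operator <- match.arg(operator)
  stopifnot(rate >= 0, rate <= 1)
  L <- nrow(ind)
  k <- ceiling(rate * L)
  if (k == 0L) return(structure(ind, mutated_loci = integer(0)))
  loci <- sort(sample_n(seq_len(L), min(k, L)))
  out <- ind
  if (operator == "reset") {
    m <- ncol(support$counts)
    donors <- sample.int(m, length(loci), replace = TRUE)
    within <- stats::ave(seq_len(L), support$family$row_gene,
                         FUN = seq_along)
    for (t in seq_along(loci)) {
      r <- loci[t]
      v <- support$counts[r, donors[t]]
      out[r, ] <- c(if (v > 0L) within[r] else 0L, v)
    }
  } else {
    groups <- if (within_gene)
      split(loci, support$family$row_gene[loci]) else list(loci)
    for (grp in groups) {
      if (length(grp) < 2L) next
      perm <- if (operator == "scramble") sample(length(grp)) else
        c(seq_along(grp)[-1L], 1L)  # swap: single cycle over the group
      out[grp, ] <- ind[grp[perm], , drop = FALSE]
    }
  }
  structure(out, mutated_loci = loci)
}

# enforce the diploid constraint on one count column: keep the two
# largest entries of any gene block with >2 expressed alleles
repair_diploid_column <- function(cnt, family) {
  for (g in family$genes) {
    rows <- gene_rows(family, g)
    nz <- which(cnt[rows] > 0L)
    if (length(nz) > 2L) {
      keep <- nz[order(cnt[rows][nz], decreasing = TRUE)[1:2]]
      drop <- setdiff(nz, keep)
      cnt[rows[drop]] <- 0L
    }
  }
  cnt
}

#' Expand a population with evolutionary synthetic individuals
#'
#' Iteratively appends synthetic individuals: each iteration selects two
#' random parents, computes the mating index, produces a Hardy-Weinberg
#' offspring, generates several mutated candidates (operator drawn at
#' random per candidate), and keeps the candidate whose read-count vector
#' is closest (Euclidean) to the empirical population mean count vector.
#' A validation pass restores the diploid constraint before a candidate is
#' appended. Synthetic individuals are labelled `SYN-E-<i>`.
#'
#' @param x an [ase_matrix()] with at least 2 individuals.
#' @param n_new number of synthetic individuals to append.
#' @param candidates_per_iter mutated candidates per iteration.
#' @param rate mutation rate.
#' @param within_gene see [mutate_individual()].
#' @param fitness_ref `"mean"` (default) or `"median"` population count
#'   vector as the fitness reference.
#' @return List with `matrix` (the extended `ase_matrix`) and `manifest`
#'   (data frame: individual, origin `real`/`evolutionary`).
#' @export
evolutionary_expand <- function(x, n_new, candidates_per_iter = 5L,
                                rate = 0.03, within_gene = TRUE,
                                fitness_ref = c("mean", "median")) {
  fitness_ref <- match.arg(fitness_ref)
  stopifnot(ncol(x$counts) >= 2L)
  fam <- x$family
  cnt <- x$counts
  ids <- colnames(cnt)
  for (i in seq_len(n_new)) {
    cur <- structure(list(counts = cnt, family = fam),
                     class = "ase_matrix")
    js <- sample.int(ncol(cnt), 2L)
    pair <- parent_pair(cur, ids[js[1L]], ids[js[2L]])
    child <- hw_offspring(pair)
    ref <- if (fitness_ref == "mean") rowMeans(cnt) else
      apply(cnt, 1L, stats::median)
    best <- NULL; best_fit <- Inf
    for (c_i in seq_len(candidates_per_iter)) {
      op <- sample(c("scramble", "swap", "reset"), 1L)
      cand <- mutate_individual(child, cur, operator = op, rate = rate,
                                within_gene = within_gene)
      col <- repair_diploid_column(cand[, "count"], fam)
      fit <- sqrt(sum((col - ref)^2))
      if (fit < best_fit) { best_fit <- fit; best <- col }
    }
    cnt <- cbind(cnt, as.integer(best))
    ids <- c(ids, sprintf("SYN-E-%d", i))
    colnames(cnt) <- ids
  }
  out <- ase_matrix(cnt, fam, individuals = ids)
  manifest <- data.frame(
    individual = ids,
    origin = c(rep("real", ncol(x$counts)), rep("evolutionary", n_new)),
    stringsAsFactors = FALSE)
  list(matrix = out, manifest = manifest)
}

# ---- SMC augmentation ------------------------------------------------------

#' Sequential Monte Carlo augmentation
#'
#' Selects a random subset of individuals and generates
#' `ceiling(augment_fraction * subset size)` synthetic individuals whose
#' per-feature counts preserve the subset's empirical distributions. For
#' each feature, particles are initialized by resampling the observed
#' counts; each synthetic value is proposed from the current particle set,
#' after which a quarter of the particles are resampled with an
#' exponentially decreasing kernel of their distance to the proposal
#' (scale = the feature's median absolute deviation) and the remainder are
#' rejuvenated from the empirical distribution, avoiding
#' over-concentration of the particle set on recent proposals. Synthetic counts therefore always
#' lie in the observed per-feature support. Presence/absence of the
#' allele-specific signal follows by a sign transform, and a diploid
#' repair pass trims gene blocks that the feature-independent sampling
#' overfilled. Synthetic individuals are labelled `SYN-S-<i>`.
#'
#' @param x an [ase_matrix()].
#' @param subset_fraction fraction of individuals used as the empirical
#'   source (default 0.5).
#' @param augment_fraction synthetic individuals as a fraction of the
#'   subset size (default 0.3).
#' @param n_particles particles per feature.
#' @return List with `matrix` (extended `ase_matrix`), `manifest`, and
#'   `subset` (the identifiers of the selected source individuals).
#' @export
smc_augment <- function(x, subset_fraction = 0.5, augment_fraction = 0.3,
                        n_particles = 200L) {
  m <- ncol(x$counts)
  stopifnot(m >= 1L)
  s <- max(1L, round(subset_fraction * m))
  subset <- sort(sample_n(seq_len(m), s))
  n_new <- ceiling(augment_fraction * s)
  fam <- x$family
  synth <- matrix(0L, fam$n_alleles, n_new)
  for (r in seq_len(fam$n_alleles)) {
    obs <- as.numeric(x$counts[r, subset])
    particles <- obs[sample.int(length(obs), n_particles, replace = TRUE)]
    scale <- stats::mad(obs)
    if (!is.finite(scale) || scale <= 0) scale <- 1
    n_keep <- n_particles %/% 4L
    for (i in seq_len(n_new)) {
      v <- sample_n(particles, 1L)
      w <- exp(-abs(particles - v) / scale)
      # resample a quarter of the particles by the distance weights and
      # rejuvenate the rest from the empirical distribution, which keeps
      # the particle support from collapsing onto recent proposals
      surv <- sample(particles, n_keep, replace = TRUE, prob = w)
      fresh <- obs[sample.int(length(obs), n_particles - n_keep,
                              replace = TRUE)]
      particles <- c(surv, fresh)
      synth[r, i] <- as.integer(v)
    }
  }
  for (i in seq_len(n_new))
    synth[, i] <- repair_diploid_column(synth[, i], fam)
  ids <- c(colnames(x$counts), sprintf("SYN-S-%d", seq_len(n_new)))
  out <- ase_matrix(cbind(x$counts, synth), fam, individuals = ids)
  manifest <- data.frame(
    individual = ids,
    origin = c(rep("real", m), rep("smc", n_new)),
    stringsAsFactors = FALSE)
  list(matrix = out, manifest = manifest,
       subset = colnames(x$counts)[subset])
}
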