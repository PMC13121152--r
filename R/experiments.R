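#' Corrupt every individual of a population
#'
#' Applies [corrupt()] to each column: `num_del` expressed entries per
#' individual, chosen uniformly without replacement, are zeroed.
#'
#' @param x an [ase_matrix()].
#' @param num_del deletions per individual.
#' @return List with `counts` (corrupted count matrix) and `records`
#'   (per-individual corruption records).
#' @export
corrupt_population <- function(x, num_del) {
  cnt <- x$counts
  records <- vector("list", ncol(cnt))
  for (j in seq_len(ncol(cnt))) {
    res <- corrupt(x, colnames(cnt)[j], num_del)
    cnt[, j] <- res$column
    records[[j]] <- res$record
  }
  list(counts = cnt, records = records)
}

# reconstruct every corrupted individual and score allele accuracy and
# read error against the corruption records
score_reconstruction <- function(rules, clusters, corrupted_counts,
                                 records, family) {
  n <- ncol(corrupted_counts)
  all_acc <- rep(NA_real_, n)
  read_err <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    rec <- records[[j]]
    if (length(rec$rows) == 0L) next
    genes <- unique(family$row_gene[rec$rows])
    res <- reconstruct_individual(rules, clusters[j],
                                  corrupted_counts[, j], genes)
    restored <- res$column[rec$rows] > 0
    outcome <- reconstruction_outcome(
      deleted = rec$labels,
      guessed = rec$labels[restored],
      true_counts = rec$original[restored],
      predicted_counts = res$column[rec$rows][restored])
    all_acc[j] <- allele_accuracy(outcome)
    read_err[j] <- read_error(outcome)
  }
  list(all_acc = all_acc, read_err = read_err)
}

# train one network on a fresh training population; returns everything the
# evaluation of its test populations needs
train_network <- function(cfg, train_m, grid, epochs, mode,
                          representation, spectral_K,
                          radius_schedule = NULL) {
  genoset <- generate_genoset(cfg)
  train <- generate_artificial_population(cfg, train_m, genoset)
  g <- som_grid(grid[1L], grid[2L])
  basis <- NULL
  if (representation == "spectral") {
    basis <- laplacian_embedding(jaccard_graph(train$matrix),
                                 K = spectral_K)
    X <- basis$coords
  } else {
    X <- t(train$matrix$counts)
  }
  model <- som_train(init_models(g, X, mode = "linear"), X,
                     mode = mode, epochs = epochs,
                     radius_schedule = radius_schedule)
  clustering <- som_assign(model, X)$bmu
  rules <- build_completion_rules(train$matrix, clustering)
  list(genoset = genoset, train = train, model = model, rules = rules,
       basis = basis)
}

# cluster assignment of a (possibly corrupted) count matrix under the
# chosen representation
assign_counts <- function(net, counts, family, representation) {
  if (representation == "spectral") {
    mat <- structure(list(counts = counts, family = family),
                     class = "ase_matrix")
    coords <- nystrom_project(net$basis, net$train$matrix, mat)
    som_assign(net$model, coords)$bmu
  } else {
    som_assign(net$model, t(counts))$bmu
  }
}

#' Run the train / corrupt / classify / reconstruct / score experiment
#'
#' End-to-end evaluation on artificial populations with known ground
#' truth: for each network, a fresh genoset and training population are
#' generated and a SOM is trained (on raw counts or on the spectral
#' embedding); for each test population and corruption level, every test
#' individual is corrupted, assigned to a cluster, and reconstructed, and
#' the clustering quality (SQI, FMI, NMI against the signature labels),
#' similarity (Rand index between the clusterings of the original and
#' corrupted copies, plus the per-individual same-cluster fraction), and
#' reconstruction accuracy (allele accuracy, read error) are recorded.
#' Per-individual metrics are averaged within each test population; the
#' summary then averages over test populations and finally over networks.
#' Cells where a metric does not apply (e.g. allele accuracy at 0
#' deletions) are excluded from averages, not zero-filled.
#'
#' @param cfg an [artificial_config()].
#' @param train_m,test_m training / test population sizes.
#' @param networks,test_pops number of independently trained networks and
#'   of test populations evaluated per network.
#' @param deletions integer vector of per-individual deletion counts.
#' @param grid SOM grid shape `c(rows, cols)`.
#' @param epochs training epochs.
#' @param mode `"batch"` or `"online"`.
#' @param radius_schedule optional per-epoch batch radius vector forwarded
#'   to [som_train()].
#' @param representation `"raw"` counts or `"spectral"` embedding.
#' @param spectral_K embedding dimension (defaults to the node count).
#' @param seed optional integer; seeds a hierarchical scheme in which
#'   every network and test population receives its own recorded sub-seed,
#'   so any cell of the result is independently reproducible.
#' @return List of class `recovery_experiment`: `cells` (one data-frame
#'   row per network x test population x deletion level) and `summary`
#'   (per deletion level, averaged over test populations then networks).
#' @export
run_recovery_experiment <- function(cfg = artificial_config(),
                                    train_m = 5000L, test_m = 500L,
                                    networks = 3L, test_pops = 10L,
                                    deletions = c(0L, 2L, 4L, 6L),
                                    grid = c(10L, 10L), epochs = 200L,
                                    mode = "batch", radius_schedule = NULL,
                                    representation = c("raw", "spectral"),
                                    spectral_K = NULL, seed = NULL) {
  representation <- match.arg(representation)
  stopifnot(networks >= 1L, test_pops >= 1L, all(deletions >= 0L))
  if (is.null(spectral_K)) spectral_K <- prod(grid)
  if (!is.null(seed)) set.seed(seed)
  net_seeds <- sample.int(.Machine$integer.max, networks)
  cells <- list()
  for (r in seq_len(networks)) {
    set.seed(net_seeds[r])
    net <- train_network(cfg, train_m, grid, epochs, mode,
                         representation, spectral_K, radius_schedule)
    tp_seeds <- sample.int(.Machine$integer.max, test_pops)
    for (tp in seq_len(test_pops)) {
      set.seed(tp_seeds[tp])
      test <- generate_artificial_population(cfg, test_m, net$genoset)
      fam <- test$matrix$family
      bmu_orig <- assign_counts(net, test$matrix$counts, fam,
                                representation)
      for (d in deletions) {
        corr <- corrupt_population(test$matrix, d)
        bmu_corr <- assign_counts(net, corr$counts, fam, representation)
        sc <- score_reconstruction(net$rules, bmu_corr, corr$counts,
                                   corr$records, fam)
        cells[[length(cells) + 1L]] <- data.frame(
          network = r, test_pop = tp, num_del = d,
          sqi = sqi(bmu_corr, test$labels),
          fmi = fmi(bmu_corr, test$labels),
          nmi = nmi(bmu_corr, test$labels),
          rand = rand_similarity(bmu_orig, bmu_corr),
          same_cluster = same_cluster_fraction(bmu_orig, bmu_corr),
          all_acc = mean(sc$all_acc, na.rm = TRUE),
          read_err = mean(sc$read_err, na.rm = TRUE),
          net_seed = net_seeds[r], tp_seed = tp_seeds[tp])
      }
    }
  }
  cells <- do.call(rbind, cells)
  cells$all_acc[is.nan(cells$all_acc)] <- NA_real_
  cells$read_err[is.nan(cells$read_err)] <- NA_real_
  metrics <- c("sqi", "fmi", "nmi", "rand", "same_cluster",
               "all_acc", "read_err")
  per_net <- stats::aggregate(cells[metrics],
                              by = cells[c("network", "num_del")],
                              FUN = mean, na.rm = TRUE)
  summary <- stats::aggregate(per_net[metrics],
                              by = per_net["num_del"],
                              FUN = mean, na.rm = TRUE)
  for (cname in metrics) {
    summary[[cname]][is.nan(summary[[cname]])] <- NA_real_
  }
  structure(list(cells = cells, summary = summary,
                 config = list(cfg = cfg, train_m = train_m,
                               test_m = test_m, networks = networks,
                               test_pops = test_pops,
                               deletions = deletions, grid = grid,
                               epochs = epochs, mode = mode,
                               representation = representation,
                               spectral_K = spectral_K, seed = seed)),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("recovery_experiment:", nrow(x$cells), "cells (",
      x$config$networks, "networks x", x$config$test_pops,
      "test populations x", length(x$config$deletions),
      "deletion levels )\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Population-level relevance analysis on a trained map
#'
#' For each corruption level, repeatedly corrupts the test population,
#' computes per-individual relevance profiles against the trained SOM,
#' averages them into population means and Z-scores (standardized across
#' alleles within each level), and selects significant alleles and genes
#' at the critical Z value.
#'
#' @param model a trained `som_model` (raw count representation).
#' @param x test [ase_matrix()].
#' @param deletions corruption levels (deletions per individual).
#' @param repeats corrupted test populations generated per level.
#' @param critical Z threshold for selection (default 1.96, 95%
#'   confidence).
#' @param perturb optional function applied to each corrupted count matrix
#'   before profiling (used to inject controlled anomalies in validation
#'   studies).
#' @return List of class `relevance_analysis`: `levels` (named list of
#'   [population_relevance()] objects), `selection` (see
#'   [zscore_select()]), and `report` (long-format data frame: level,
#'   allele, gene, Rbar, Dbar, Z_R, Z_D).
#' @export
run_relevance_analysis <- function(model, x, deletions = c(2L, 4L, 6L),
                                   repeats = 5L, critical = 1.96,
                                   perturb = NULL) {
  fam <- x$family
  levels_out <- list()
  rows <- list()
  for (d in deletions) {
    R_list <- vector("list", repeats)
    D_list <- vector("list", repeats)
    for (t in seq_len(repeats)) {
      cnt <- corrupt_population(x, d)$counts
      if (!is.null(perturb)) cnt <- perturb(cnt)
      prof <- relevance_profiles(model, t(cnt))
      R_list[[t]] <- prof$R
      D_list[[t]] <- prof$D
    }
    pr <- population_relevance(R_list, D_list)
    levels_out[[as.character(d)]] <- pr
    rows[[as.character(d)]] <- data.frame(
      level = d, allele = fam$row_labels, gene = fam$row_gene,
      Rbar = unname(pr$Rbar), Dbar = unname(pr$Dbar),
      Z_R = unname(pr$Z_R), Z_D = unname(pr$Z_D),
      stringsAsFactors = FALSE)
  }
  selection <- zscore_select(levels_out, fam, critical = critical)
  structure(list(levels = levels_out, selection = selection,
                 report = do.call(rbind, rows)),
            class = "relevance_analysis")
}

#' @export
print.relevance_analysis <- function(x, ...) {
  cat("relevance_analysis:", length(x$levels), "corruption levels;",
      nrow(x$selection$R_selected), "R-selected alleles (",
      length(x$selection$R_genes), "genes ),",
      nrow(x$selection$D_selected), "D-selected alleles (",
      length(x$selection$D_genes), "genes )\n")
  invisible(x)
}
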