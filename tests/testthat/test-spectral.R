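make_sig_matrix <- function(cols) {
  # cols: list of count vectors over a 3-gene x 2-allele family
  fam <- gene_family(c("g1", "g2", "g3"),
                     list(g1 = c("A1", "A2"), g2 = c("B1", "B2"),
                          g3 = c("C1", "C2")))
  cnt <- do.call(cbind, cols)
  storage.mode(cnt) <- "integer"
  ase_matrix(cnt, fam)
}

test_that("multiset Jaccard similarities follow hand counts", {
  # identical signatures -> 1; disjoint -> 0
  x <- make_sig_matrix(list(c(1, 2, 3, 0, 5, 0), c(1, 2, 3, 0, 5, 0),
                            c(0, 0, 0, 9, 0, 9)))
  W <- jaccard_graph(x)
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], 0)
  expect_equal(diag(W), setNames(rep(1, 3), colnames(x$counts)))
  # half-overlapping all-heterozygous signatures
  y <- make_sig_matrix(list(c(4, 7, 2, 9, 0, 0), c(0, 0, 2, 5, 1, 3)))
  # sig1 = {A1,A2,B1,B2}, sig2 = {B1,B2,C1,C2}: inter 2, union 6
  expect_equal(jaccard_graph(y)[1, 2], 2 / 6)
  # homozygous agreement counts double: {A1 x2} vs {A1 x2, B1, B2}
  z <- make_sig_matrix(list(c(5, 0, 0, 0, 0, 0), c(3, 0, 2, 4, 0, 0)))
  expect_equal(jaccard_graph(z)[1, 2], 2 / 4)
})

test_that("Laplacian spectra of canonical graphs are recovered", {
  # complete graph with unit weights: eigenvalue 0 once, rest n/(n-1)
  W <- matrix(1, 6, 6); diag(W) <- 0
  b <- laplacian_embedding(W, 6, row_normalize = FALSE)
  expect_equal(b$laplacian_values[1], 0, tolerance = 1e-12)
  expect_equal(b$laplacian_values[-1], rep(6 / 5, 5), tolerance = 1e-9)
  expect_true(all(b$laplacian_values >= -1e-9 &
                    b$laplacian_values <= 2 + 1e-9))
  # constant-direction leading eigenvector
  expect_equal(stats::sd(b$vectors[, 1]), 0, tolerance = 1e-9)
  # two disconnected cliques: eigenvalue 0 with multiplicity 2
  W2 <- matrix(0, 7, 7)
  W2[1:3, 1:3] <- 1; W2[4:7, 4:7] <- 1
  b2 <- laplacian_embedding(W2, 7, row_normalize = FALSE)
  expect_equal(sum(abs(b2$laplacian_values) < 1e-9), 2L)
  # eigenpairs satisfy the eigen equation of the normalized affinity
  set.seed(80)
  S <- matrix(runif(64), 8, 8); S <- (S + t(S)) / 2; diag(S) <- 1
  b3 <- laplacian_embedding(S, 5, row_normalize = FALSE)
  dhalf <- 1 / sqrt(rowSums(S))
  A <- S * outer(dhalf, dhalf)
  for (k in 1:5)
    expect_equal(A %*% b3$vectors[, k],
                 b3$affinity_values[k] * b3$vectors[, k, drop = FALSE],
                 tolerance = 1e-8)
  expect_equal(crossprod(b3$vectors), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # isolated vertices are reported by name
  W3 <- diag(0, 3); W3[1, 2] <- W3[2, 1] <- 1
  expect_error(laplacian_embedding(W3, 2),
               class = "spectral_isolated_vertex")
})

test_that("Nystrom extension is self-consistent on training individuals", {
  set.seed(81)
  # the genoset must exceed the embedding dimension: the affinity matrix
  # has rank at most the number of distinct signatures, and null-space
  # eigenvectors are not extendable
  cfg <- artificial_config(n_genes = 5, alleles_per_gene = 6,
                           genoset_size = 30)
  pop <- generate_artificial_population(cfg, 120)
  W <- jaccard_graph(pop$matrix)
  b <- laplacian_embedding(W, 16)
  for (j in c(1, 17, 60, 120)) {
    u <- nystrom_extend(b, W[, j])
    expect_equal(u, unname(b$coords[j, ]), tolerance = 1e-6)
  }
  # the wrapper over raw count columns agrees
  proj <- nystrom_project(b, pop$matrix, pop$matrix)
  expect_equal(proj, unname(b$coords), tolerance = 1e-6)
  # duplicated individual -> identical coordinates
  dup <- pop$matrix$counts[, c(seq_len(120), 1)]
  x2 <- ase_matrix(dup, pop$matrix$family,
                   individuals = c(colnames(pop$matrix$counts), "copy"))
  p2 <- nystrom_project(b, pop$matrix, x2)
  expect_equal(p2[121, ], p2[1, ], tolerance = 1e-9)
  # no similarity at all -> flagged zero vector
  u0 <- nystrom_extend(b, rep(0, 120))
  expect_true(attr(u0, "flagged"))
  expect_true(all(u0 == 0))
})

test_that("a 0-deletion corrupted copy embeds exactly like the original", {
  set.seed(82)
  cfg <- artificial_config(n_genes = 4, alleles_per_gene = 5,
                           genoset_size = 8)
  pop <- generate_artificial_population(cfg, 60)
  b <- laplacian_embedding(jaccard_graph(pop$matrix), 8)
  corr <- corrupt_population(pop$matrix, 0)
  xc <- ase_matrix(corr$counts, pop$matrix$family,
                   individuals = colnames(pop$matrix$counts))
  expect_identical(nystrom_project(b, pop$matrix, xc),
                   nystrom_project(b, pop$matrix, pop$matrix))
})

test_that("embedding coordinates permute with the individuals", {
  set.seed(83)
  cfg <- artificial_config(n_genes = 4, alleles_per_gene = 5,
                           genoset_size = 10)
  pop <- generate_artificial_population(cfg, 40)
  W <- jaccard_graph(pop$matrix)
  p <- sample(40)
  b1 <- laplacian_embedding(W, 5)
  b2 <- laplacian_embedding(unclass(W)[p, p], 5)
  # compare through the rotation-invariant Gram matrices
  expect_equal(tcrossprod(b1$coords)[p, p], tcrossprod(b2$coords),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("SOM on spectral coordinates stays stable under corruption", {
  set.seed(84)
  cfg <- artificial_config(n_genes = 6, alleles_per_gene = 6,
                           genoset_size = 12)
  ex <- run_recovery_experiment(cfg, train_m = 300, test_m = 100,
                                networks = 1, test_pops = 2,
                                deletions = c(0, 6), grid = c(4, 4),
                                epochs = 40, representation = "spectral",
                                seed = 9)
  s <- ex$summary
  drop <- s$rand[s$num_del == 0] - s$rand[s$num_del == 6]
  expect_lte(drop, 0.1)
})
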