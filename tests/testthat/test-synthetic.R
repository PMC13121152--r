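test_that("artificial populations realize the declared design", {
  set.seed(90)
  cfg <- artificial_config()  # 10 genes x 10 alleles, genoset 100
  pop <- generate_artificial_population(cfg, 5000)
  expect_identical(dim(pop$matrix$counts), c(100L, 5000L))
  # every individual expresses exactly 20 alleles, 2 per gene
  expect_true(all(colSums(pop$matrix$counts > 0) == 20))
  nz_per_gene <- rowsum((pop$matrix$counts > 0) + 0,
                        pop$matrix$family$row_gene)
  expect_true(all(nz_per_gene == 2))
  # counts live in [1, 700]
  v <- pop$matrix$counts[pop$matrix$counts > 0]
  expect_gte(min(v), 1)
  expect_lte(max(v), 700)
  # signatures are distinct and used almost uniformly
  expect_identical(nrow(unique(pop$genoset)), 100L)
  chi <- suppressWarnings(
    stats::chisq.test(tabulate(pop$labels, 100)))
  expect_gt(chi$p.value, 0.01)
  # degenerate genoset of size one
  cfg1 <- artificial_config(n_genes = 3, alleles_per_gene = 4,
                            genoset_size = 1)
  p1 <- generate_artificial_population(cfg1, 10)
  expect_true(all(p1$labels == 1))
  expect_error(artificial_config(n_genes = 1, alleles_per_gene = 2,
                                 genoset_size = 5))
})

test_that("the mating index follows its definition and sign rule", {
  expect_equal(mating_index(2, 2), 1)
  expect_equal(mating_index(2, 5), -2)
  expect_equal(mating_index(3, 4), 0)
  set.seed(91)
  cfg <- artificial_config(n_genes = 4, alleles_per_gene = 5,
                           genoset_size = 6)
  pop <- generate_artificial_population(cfg, 10)
  pr <- parent_pair(pop$matrix, "ind1", "ind2")
  expect_equal(mating_index(pr),
               1 + var(as.numeric(pop$matrix$counts[, "ind1"])) -
                 var(as.numeric(pop$matrix$counts[, "ind2"])))
})

test_that("HW offspring are per-locus mosaics of their parents", {
  set.seed(92)
  cfg <- artificial_config(n_genes = 4, alleles_per_gene = 5,
                           genoset_size = 6)
  pop <- generate_artificial_population(cfg, 10)
  pr <- parent_pair(pop$matrix, "ind1", "ind2")
  off <- hw_offspring(pr)
  ff <- attr(off, "from_father")
  for (r in seq_len(nrow(off))) {
    src <- if (ff[r]) pr$father else pr$mother
    expect_identical(off[r, ], src[r, ])
  }
  # identical parents produce an identical offspring
  pid <- parent_pair(pop$matrix, "ind3", "ind3")
  offid <- hw_offspring(pid)
  expect_identical(unname(offid[, "count"]),
                   unname(pid$father[, "count"]))
  # provenance is a fair coin over many loci (+- 3 binomial sd)
  n_loci <- 1e4
  big <- list(father = cbind(index = rep(1L, n_loci),
                             count = rep(1L, n_loci)),
              mother = cbind(index = rep(2L, n_loci),
                             count = rep(2L, n_loci)),
              var_father = 0, var_mother = 0)
  class(big) <- "parent_pair"
  frac <- mean(attr(hw_offspring(big), "from_father"))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_loci))
})

test_that("mutation operators honour their contracts", {
  set.seed(93)
  cfg <- artificial_config(n_genes = 5, alleles_per_gene = 4,
                           genoset_size = 8)
  pop <- generate_artificial_population(cfg, 30)
  ind <- parent_matrix(pop$matrix, "ind1")
  a_hat <- nrow(ind)
  # rate 0 is the identity
  m0 <- mutate_individual(ind, pop$matrix, "scramble", rate = 0)
  expect_identical(m0[, ], ind[, ])
  expect_length(attr(m0, "mutated_loci"), 0)
  for (op in c("scramble", "swap", "reset")) {
    mu <- mutate_individual(ind, pop$matrix, op, rate = 0.15)
    loci <- attr(mu, "mutated_loci")
    expect_length(loci, ceiling(0.15 * a_hat))
    # untouched loci are bit-identical
    expect_identical(unclass(mu)[-loci, ], ind[-loci, ])
  }
  # swap preserves the multiset of (allele, count) values
  msw <- mutate_individual(ind, pop$matrix, "swap", rate = 0.5)
  expect_identical(sort(unname(msw[, "count"])),
                   sort(unname(ind[, "count"])))
  # reset draws states from the locus's observed support, many seeds
  for (s in 1:100) {
    mr <- mutate_individual(ind, pop$matrix, "reset", rate = 0.1)
    for (r in attr(mr, "mutated_loci")) {
      expect_true(mr[r, "count"] %in% pop$matrix$counts[r, ])
    }
  }
})

test_that("evolutionary expansion appends plausible synthetic individuals", {
  set.seed(94)
  cfg <- artificial_config(n_genes = 4, alleles_per_gene = 5,
                           genoset_size = 6)
  pop <- generate_artificial_population(cfg, 25)
  # n_new = 0 is the identity
  e0 <- evolutionary_expand(pop$matrix, 0)
  expect_identical(e0$matrix$counts, pop$matrix$counts)
  ee <- evolutionary_expand(pop$matrix, 8)
  expect_identical(ncol(ee$matrix$counts), 33L)
  expect_identical(sum(ee$manifest$origin == "evolutionary"), 8L)
  # outputs satisfy the diploid constraint (ase_matrix validates) and
  # synthetic counts only use values observed in the same gene block
  # (scramble/swap move expression between alleles of one gene)
  syn <- ee$matrix$counts[, 26:33]
  fam <- pop$matrix$family
  for (g in fam$genes) {
    rows <- which(fam$row_gene == g)
    support <- c(0L, as.vector(pop$matrix$counts[rows, ]))
    expect_true(all(syn[rows, ] %in% support))
  }
  # identical population with no mutation reproduces itself
  one <- pop$matrix$counts[, rep(1, 5)]
  xid <- ase_matrix(one, pop$matrix$family,
                    individuals = paste0("c", 1:5))
  eid <- evolutionary_expand(xid, 3, rate = 0)
  for (j in 6:8)
    expect_identical(eid$matrix$counts[, j], pop$matrix$counts[, 1])
})

test_that("SMC augmentation preserves per-feature distributions", {
  set.seed(95)
  cfg <- artificial_config(n_genes = 5, alleles_per_gene = 4,
                           genoset_size = 5)
  pop <- generate_artificial_population(cfg, 1000)
  sa <- smc_augment(pop$matrix)
  s <- length(sa$subset)
  expect_identical(s, 500L)
  n_new <- ncol(sa$matrix$counts) - 1000L
  expect_identical(n_new, as.integer(ceiling(0.3 * s)))
  syn <- sa$matrix$counts[, 1000L + seq_len(n_new), drop = FALSE]
  sub <- pop$matrix$counts[, sa$subset]
  # synthetic non-zero values lie in the observed per-feature support
  for (r in seq_len(nrow(syn))) {
    nz <- syn[r, syn[r, ] > 0]
    expect_true(all(nz %in% sub[r, ]))
  }
  # KS distance below 0.2 on well-observed features
  for (r in which(rowSums(sub > 0) >= 20)) {
    d <- suppressWarnings(
      stats::ks.test(as.numeric(syn[r, ]), as.numeric(sub[r, ])))$statistic
    expect_lt(unname(d), 0.2)
  }
  # constant feature: synthetic values all equal that constant
  fam1 <- gene_family("g1", list(g1 = c("A1", "A2")))
  xc <- ase_matrix(matrix(c(7L, 3L), 2, 10)[, 1:10], fam1,
                   individuals = paste0("i", 1:10))
  sc <- smc_augment(xc, subset_fraction = 1)
  expect_true(all(sc$matrix$counts[1, ] == 7L))
})
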