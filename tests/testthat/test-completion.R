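# worked micro-cluster: members (A1,A2):(10,30), (A1,A2):(20,40),
# (A1,A3):(5,50)
worked_cluster <- function() {
  members <- list(list(a = "A1", b = "A2", ca = 10, cb = 30),
                  list(a = "A1", b = "A2", ca = 20, cb = 40),
                  list(a = "A1", b = "A3", ca = 5, cb = 50))
  x <- matrix_from_members(members)
  list(x = x, members = members,
       rules = build_completion_rules(x, rep(1L, 3)))
}

test_that("the three completion cases reproduce hand-computed values", {
  wc <- worked_cluster()
  # both unknown: most frequent pair with ceilinged conditional means
  r <- reconstruct_gene(wc$rules, 1, "g1")
  expect_identical(r$alleles, c("A1", "A2"))
  expect_identical(r$counts, c(15, 35))
  expect_identical(r$case, "both-unknown")
  # one known, seen: pi(A1,A2) = 2/3 beats pi(A1,A3) = 1/3
  r <- reconstruct_gene(wc$rules, 1, "g1", known_allele = "A1",
                        known_count = 10)
  expect_identical(r$alleles, c("A1", "A2"))
  expect_identical(r$counts[2], ceiling(10 * 35 / 15))  # 24
  expect_identical(r$case, "one-known-seen")
  # one known, unseen: most frequent g-allele by occurrence (A1: 3)
  r <- reconstruct_gene(wc$rules, 1, "g1", known_allele = "A5",
                        known_count = 10)
  expect_identical(r$alleles[2], "A1")
  expect_identical(r$case, "one-known-unseen")
})

test_that("single-member and homozygous statistics are exact", {
  members <- list(list(a = "A1", b = "A2", ca = 10, cb = 30))
  rules <- build_completion_rules(matrix_from_members(members), 1L)
  r <- reconstruct_gene(rules, 1, "g1")
  expect_identical(r$alleles, c("A1", "A2"))
  expect_identical(r$counts, c(10, 30))
  # homozygous member contributes the pair (A, A)
  hom <- list(list(a = "A3", b = "A3", ca = 12, cb = 12))
  rh <- build_completion_rules(matrix_from_members(hom), 1L)
  r <- reconstruct_gene(rh, 1, "g1")
  expect_identical(r$alleles, c("A3", "A3"))
  expect_identical(r$counts, c(12, 12))
})

test_that("reconstruction matches the enumeration oracle on random clusters", {
  set.seed(77)
  for (t in 1:150) {
    members <- random_members(sample(1:10, 1))
    x <- matrix_from_members(members)
    rules <- build_completion_rules(x, rep(1L, length(members)))
    ora <- oracle_reconstruct(members)
    imp <- reconstruct_gene(rules, 1, "g1")
    expect_identical(imp$alleles, ora$alleles)
    expect_identical(imp$counts, as.numeric(ora$counts))
    known <- sample(paste0("A", 1:6), 1)  # A6 is never observed
    kc <- sample.int(60, 1)
    ora <- oracle_reconstruct(members, known, kc)
    imp <- reconstruct_gene(rules, 1, "g1", known, kc)
    expect_identical(imp$case, ora$case)
    expect_identical(imp$alleles, ora$alleles)
    expect_identical(imp$counts, as.numeric(ora$counts))
  }
})

test_that("pair statistics are invariant to the stored pair orientation", {
  set.seed(91)
  for (t in 1:20) {
    members <- random_members(6)
    swapped <- lapply(members, function(mb)
      list(a = mb$b, b = mb$a, ca = mb$cb, cb = mb$ca))
    r1 <- build_completion_rules(matrix_from_members(members), rep(1L, 6))
    r2 <- build_completion_rules(matrix_from_members(swapped), rep(1L, 6))
    expect_identical(reconstruct_gene(r1, 1, "g1"),
                     reconstruct_gene(r2, 1, "g1"))
    expect_identical(reconstruct_gene(r1, 1, "g1", "A2", 7),
                     reconstruct_gene(r2, 1, "g1", "A2", 7))
  }
})

test_that("reconstruct_individual is local and respects diploidy", {
  set.seed(13)
  cfg <- artificial_config(n_genes = 4, alleles_per_gene = 5,
                           genoset_size = 6)
  pop <- generate_artificial_population(cfg, 60)
  rules <- build_completion_rules(pop$matrix, pop$labels)
  col <- pop$matrix$counts[, 1]
  lab <- pop$labels[1]
  # empty mask -> identity
  r <- reconstruct_individual(rules, lab, col, character(0))
  expect_identical(r$column, as.numeric(col))
  # deleting one full gene changes only that gene block
  fam <- pop$matrix$family
  rows_g2 <- which(fam$row_gene == "g2")
  col2 <- col; col2[rows_g2] <- 0
  r <- reconstruct_individual(rules, lab, col2, "g2")
  expect_identical(r$column[-rows_g2], as.numeric(col[-rows_g2]))
  expect_identical(sum(r$column[rows_g2] > 0) <= 2, TRUE)
  expect_identical(r$report$case, "both-unknown")
  # result always satisfies the diploid constraint
  nz_per_gene <- rowsum((r$column > 0) + 0, fam$row_gene)
  expect_true(all(nz_per_gene <= 2))
})

test_that("a pure cluster recovers its shared signature exactly", {
  set.seed(29)
  cfg <- artificial_config(n_genes = 5, alleles_per_gene = 6,
                           genoset_size = 4)
  pop <- generate_artificial_population(cfg, 80)
  rules <- build_completion_rules(pop$matrix, pop$labels)
  for (j in c(2, 10, 25)) {
    cr <- corrupt(pop$matrix, colnames(pop$matrix$counts)[j], 4)
    genes <- unique(pop$matrix$family$row_gene[cr$record$rows])
    r <- reconstruct_individual(rules, pop$labels[j], cr$column, genes)
    expect_true(all(r$column[cr$record$rows] > 0))
  }
})

test_that("fallback chain and unreconstructable genes behave as specified", {
  # cluster 2 never expresses g2: falls back to whole-population stats
  fam <- gene_family(c("g1", "g2"),
                     list(g1 = c("A1", "A2"), g2 = c("B1", "B2")))
  cnt <- matrix(0L, 4, 3)
  cnt[, 1] <- c(3L, 4L, 10L, 20L)
  cnt[, 2] <- c(5L, 6L, 10L, 20L)
  cnt[1:2, 3] <- c(7L, 8L)
  x <- ase_matrix(cnt, fam, individuals = c("a", "b", "c"))
  rules <- build_completion_rules(x, c(1L, 1L, 2L))
  r <- reconstruct_gene(rules, 2, "g2")
  expect_identical(r$alleles, c("B1", "B2"))
  expect_identical(r$counts, c(10, 20))
  # a gene absent everywhere cannot be reconstructed
  fam3 <- gene_family(c("g1", "g2", "g3"),
                      list(g1 = c("A1", "A2"), g2 = c("B1", "B2"),
                           g3 = c("C1", "C2")))
  cnt3 <- rbind(cnt, matrix(0L, 2, 3))
  x3 <- ase_matrix(cnt3, fam3, individuals = c("a", "b", "c"))
  rules3 <- build_completion_rules(x3, c(1L, 1L, 2L))
  expect_error(reconstruct_gene(rules3, 1, "g3"),
               class = "completion_unreconstructable")
})
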