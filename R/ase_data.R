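#' Gene family index for an ASE expression matrix
#'
#' Describes the row layout of an allele-specific expression (ASE) matrix:
#' an ordered set of genes, each contributing a contiguous block of rows,
#' one row per observed allele of that gene. Row labels take the canonical
#' form `"gene:allele"`.
#'
#' @param genes character vector of gene identifiers, in row-block order.
#' @param allele_labels named list, one entry per gene, each an ordered
#'   character vector of allele identifiers for that gene.
#' @return An object of class `gene_family` with components `genes`,
#'   `allele_counts` (named integer vector), `allele_labels`, `n_alleles`
#'   (total number of allele rows), `row_gene` and `row_allele` (per-row
#'   gene/allele), and `row_labels` (`"gene:allele"` strings).
#' @examples
#' fam <- gene_family(c("g1", "g2"),
#'                    list(g1 = c("A1", "A2"), g2 = c("B1", "B2")))
#' fam$n_alleles
#' @export
gene_family <- function(genes, allele_labels) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers")
  if (!setequal(names(allele_labels), genes))
    stop("allele_labels must be named by the genes")
  allele_labels <- allele_labels[genes]
  ac <- vapply(allele_labels, length, integer(1))
  if (any(ac < 1L))
    stop("every gene needs at least one allele")
  if (any(vapply(allele_labels, anyDuplicated, integer(1)) > 0L))
    stop("duplicate allele identifiers within a gene")
  row_gene <- rep(genes, ac)
  row_allele <- unlist(allele_labels, use.names = FALSE)
  structure(list(
    genes = genes,
    allele_counts = ac,
    allele_labels = allele_labels,
    n_alleles = sum(ac),
    row_gene = row_gene,
    row_allele = row_allele,
    row_labels = paste(row_gene, row_allele, sep = ":")
  ), class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene_family:", length(x$genes), "genes,", x$n_alleles,
      "allele rows\n")
  invisible(x)
}

# row indices of one gene's block
gene_rows <- function(family, gene) {
  which(family$row_gene == gene)
}

#' ASE expression matrix
#'
#' Bundles a non-negative integer read-count matrix (rows = alleles grouped
#' in gene blocks, columns = individuals) with its [gene_family()] row index.
#' Validation enforces the diploid constraint: within every gene block each
#' individual has at most two non-zero entries (two for a heterozygously
#' expressed gene, one for a homozygously expressed gene, none when the gene
#' is not expressed).
#'
#' @param counts integer matrix, `n_alleles x m`, non-negative.
#' @param family a [gene_family()] describing the rows.
#' @param individuals optional character vector of column identifiers
#'   (defaults to the column names of `counts`).
#' @return An object of class `ase_matrix` with components `counts` and
#'   `family`.
#' @export
ase_matrix <- function(counts, family, individuals = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != family$n_alleles)
    stop("row count does not match the gene family (",
         nrow(counts), " vs ", family$n_alleles, ")")
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(ncol(counts)))
  if (anyDuplicated(individuals))
    stop("duplicate individual identifiers")
  storage <- counts
  if (!is.numeric(storage))
    stop_somase("ase_noninteger", "counts must be numeric integers")
  if (any(is.na(storage)))
    stop_somase("ase_noninteger", "counts contain missing values")
  if (any(storage < 0) || any(storage != floor(storage)))
    stop_somase("ase_noninteger",
                "counts must be non-negative integers")
  mode(storage) <- "integer"
  dimnames(storage) <- list(family$row_labels, as.character(individuals))
  obj <- structure(list(counts = storage, family = family),
                   class = "ase_matrix")
  check_diploid(obj)
  obj
}

# error helper with a named condition class so callers can test for
# specific failure modes
stop_somase <- function(class, msg) {
  stop(structure(class = c(class, "somase_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_diploid <- function(x) {
  cnt <- x$counts
  nz <- rowsum((cnt > 0L) + 0L, x$family$row_gene, reorder = FALSE)
  bad <- which(nz > 2L, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    g <- rownames(nz)[bad[1L, 1L]]
    ind <- colnames(cnt)[bad[1L, 2L]]
    stop_somase("ase_diploid_violation",
                paste0("diploid constraint violated: gene ", g,
                       " has >2 expressed alleles in individual ", ind))
  }
  invisible(x)
}

#' @export
print.ase_matrix <- function(x, ...) {
  cat("ase_matrix:", nrow(x$counts), "allele rows x", ncol(x$counts),
      "individuals (", length(x$family$genes), "genes )\n")
  invisible(x)
}

#' @export
dim.ase_matrix <- function(x) dim(x$counts)

#' Number of individuals / allele rows
#' @param x an `ase_matrix`.
#' @return Integer count.
#' @rdname ase_matrix_dims
#' @export
n_individuals <- function(x) ncol(x$counts)

#' @rdname ase_matrix_dims
#' @export
n_alleles <- function(x) nrow(x$counts)

#' Read an ASE expression matrix from TSV
#'
#' The dialect is: first header row holds individual identifiers, first
#' column holds `"gene:allele"` row labels, remaining cells are integer read
#' counts. Rows belonging to one gene must be contiguous (gene blocks).
#'
#' @param path file path.
#' @return An [ase_matrix()].
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE)
  if (ncol(dt) < 2L)
    stop_somase("ase_no_individuals", "no individuals: header only")
  labels <- dt[[1L]]
  parts <- strsplit(labels, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_somase("ase_malformed_header",
                "row labels must have the form gene:allele")
  row_gene <- vapply(parts, `[[`, character(1), 1L)
  row_allele <- vapply(parts, `[[`, character(1), 2L)
  # gene blocks must be contiguous
  rl <- rle(row_gene)
  if (anyDuplicated(rl$values))
    stop_somase("ase_malformed_header",
                paste0("gene rows are not contiguous: ",
                       rl$values[duplicated(rl$values)][1L]))
  fam <- gene_family(rl$values,
                     split(row_allele, factor(row_gene, levels = rl$values)))
  cnt <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(cnt) || any(is.na(cnt)) || any(cnt != floor(cnt)))
    stop_somase("ase_noninteger", "non-integer count in matrix body")
  ase_matrix(cnt, fam, individuals = colnames(dt)[-1L])
}

#' Write an ASE expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; the round trip is bit-exact.
#'
#' @param x an `ase_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(allele = rownames(x$counts), x$counts,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Expression signature of an individual
#'
#' The signature is the multiset of expressed alleles: a heterozygously
#' expressed gene contributes its two alleles with multiplicity 1 each, a
#' homozygously expressed gene contributes its single expressed allele with
#' multiplicity 2, an unexpressed gene contributes nothing.
#'
#' @param x an `ase_matrix`.
#' @param individual individual (column) identifier.
#' @return Named integer vector of multiplicities keyed by `"gene:allele"`,
#'   of class `ase_signature`.
#' @export
signature_of <- function(x, individual) {
  j <- match(as.character(individual), colnames(x$counts))
  if (is.na(j))
    stop_somase("ase_unknown_individual",
                paste("unknown individual:", individual))
  signature_from_column(x$counts[, j], x$family)
}

# multiplicity vector (0/1/2 per allele row) for one count column
signature_multiplicities <- function(column, family) {
  expressed <- column > 0L
  nz_per_gene <- rowsum(expressed + 0L, family$row_gene, reorder = FALSE)
  per_row_nz <- nz_per_gene[family$row_gene, 1L]
  mult <- integer(length(column))
  mult[expressed & per_row_nz == 1L] <- 2L
  mult[expressed & per_row_nz == 2L] <- 1L
  mult
}

signature_from_column <- function(column, family) {
  mult <- signature_multiplicities(column, family)
  keep <- mult > 0L
  structure(stats::setNames(mult[keep], family$row_labels[keep]),
            class = "ase_signature")
}

#' @export
print.ase_signature <- function(x, ...) {
  cat("ase_signature:", sum(unclass(x)), "allele copies over",
      length(x), "distinct alleles\n")
  invisible(x)
}

# canonical string key of a signature, used for genoset identity
signature_key <- function(sig) {
  paste(names(sig), unclass(sig), sep = "x", collapse = ";")
}

#' Genoset of a population
#'
#' The set of distinct signatures present among the columns of `x`.
#'
#' @param x an `ase_matrix`.
#' @return List of distinct `ase_signature` objects (class `ase_genoset`).
#' @export
genoset_of <- function(x) {
  sigs <- lapply(colnames(x$counts), function(id) signature_of(x, id))
  keys <- vapply(sigs, signature_key, character(1))
  structure(sigs[!duplicated(keys)], class = "ase_genoset")
}

#' Corrupt an individual by deleting expressed-allele read counts
#'
#' Emulates the experimental failure mode in which some expressed alleles of
#' an individual could not be quantified: `num_del` non-zero entries of the
#' individual's column, chosen uniformly without replacement, are set to 0.
#' The deletion operates on matrix entries, so deleting the single entry of
#' a homozygously expressed gene removes both signature copies at once.
#'
#' @param x an `ase_matrix` (left unchanged).
#' @param individual column identifier.
#' @param num_del number of expressed entries to delete.
#' @return List with `column` (the corrupted count vector) and `record`, a
#'   `corruption_record` holding the deleted row indices (`rows`), their row
#'   labels, and the original counts.
#' @export
corrupt <- function(x, individual, num_del) {
  j <- match(as.character(individual), colnames(x$counts))
  if (is.na(j))
    stop_somase("ase_unknown_individual",
                paste("unknown individual:", individual))
  column <- x$counts[, j]
  nz <- which(column > 0L)
  num_del <- as.integer(num_del)
  if (num_del > length(nz))
    stop_somase("ase_too_many_deletions",
                paste0("num_del (", num_del, ") exceeds the ",
                       length(nz), " expressed entries"))
  rows <- if (num_del > 0L) sort(sample_n(nz, num_del)) else integer(0)
  rec <- structure(list(individual = as.character(individual),
                        rows = rows,
                        labels = rownames(x$counts)[rows],
                        original = column[rows]),
                   class = "corruption_record")
  column[rows] <- 0L
  list(column = column, record = rec)
}

# sample() without its length-1 surprise
sample_n <- function(v, k) {
  if (length(v) == 1L) rep(v, length.out = k) else sample(v, k)
}

#' Keep individuals expressing at least a minimum number of alleles
#'
#' @param x an `ase_matrix`.
#' @param threshold minimum number of non-zero entries per column.
#' @return An `ase_matrix` with the retained columns, order preserved.
#' @export
filter_min_expressed <- function(x, threshold) {
  stopifnot(threshold >= 0)
  keep <- colSums(x$counts > 0L) >= threshold
  structure(list(counts = x$counts[, keep, drop = FALSE],
                 family = x$family),
            class = "ase_matrix")
}
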