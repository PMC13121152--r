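# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use naive enumeration so they stay independent of
# the implementation paths they check.

# breadth-first search hop count on an adjacency matrix
bfs_distance <- function(adj, from, to) {
  n <- nrow(adj)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] > 0 & is.na(dist))
    dist[nb] <- dist[v] + 1L
    queue <- c(queue, nb)
  }
  dist[to]
}

# pairwise enumeration of the four partition-comparison indices
bf_pair_stats <- function(C, G) {
  m <- length(C)
  TP <- FP <- FN <- TN <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sc <- C[i] == C[j]; sg <- G[i] == G[j]
    if (sc && sg) TP <- TP + 1
    else if (sc && !sg) FP <- FP + 1
    else if (!sc && sg) FN <- FN + 1
    else TN <- TN + 1
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}

bf_fmi <- function(C, G) {
  s <- bf_pair_stats(C, G)
  if (s$TP + s$FP == 0 || s$TP + s$FN == 0) return(0)
  sqrt(s$TP / (s$TP + s$FP) * s$TP / (s$TP + s$FN))
}

bf_rand <- function(C, G) {
  s <- bf_pair_stats(C, G)
  (s$TP + s$TN) / (s$TP + s$FP + s$FN + s$TN)
}

bf_sqi <- function(C, G) {
  cs <- split(seq_along(C), C)
  gs <- split(seq_along(G), G)
  f1 <- mean(sapply(cs, function(c) {
    max(sapply(gs, function(g) length(intersect(c, g)))) / length(c)
  }))
  f2 <- mean(sapply(gs, function(g) {
    max(sapply(cs, function(c) length(intersect(c, g)))) / length(g)
  }))
  f1 * f2
}

bf_nmi <- function(C, G) {
  m <- length(C)
  joint <- table(C, G) / m
  px <- rowSums(joint); py <- colSums(joint)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  }
  as.numeric(mi / sqrt(hx * hy))
}

# plain Lloyd iteration: assignment to nearest centroid (ties -> lowest
# index), centroid = mean of its points, empty centroids unchanged
lloyd_step <- function(X, centers) {
  D <- sapply(seq_len(nrow(centers)),
              function(k) colSums((t(X) - centers[k, ])^2))
  asg <- apply(D, 1L, which.min)
  newc <- centers
  for (k in seq_len(nrow(centers))) {
    pts <- which(asg == k)
    if (length(pts)) newc[k, ] <- colMeans(X[pts, , drop = FALSE])
  }
  list(centers = newc, assignment = asg)
}

# enumeration oracle for the three completion cases, working directly on
# a cluster's list of per-member gene pairs (each: alleles a, b and
# counts ca, cb; homozygous members have a == b, ca == cb)
oracle_reconstruct <- function(members, known = NULL, known_count = NULL) {
  key <- sapply(members, function(mb) {
    al <- c(mb$a, mb$b); cn <- c(mb$ca, mb$cb)
    o <- order(al)
    paste(al[o], collapse = "|")
  })
  pair_of <- function(k) strsplit(k, "|", fixed = TRUE)[[1]]
  mean_counts <- function(k) {
    sel <- members[key == k]
    al <- pair_of(k)
    c1 <- sapply(sel, function(mb) {
      if (mb$a == mb$b) mb$ca
      else if (mb$a == al[1]) mb$ca else mb$cb
    })
    c2 <- sapply(sel, function(mb) {
      if (mb$a == mb$b) mb$cb
      else if (mb$a == al[2]) mb$ca else mb$cb
    })
    c(mean(c1), mean(c2))
  }
  tab <- table(key)
  if (is.null(known)) {
    best <- names(tab)[order(-as.vector(tab), names(tab))][1]
    al <- pair_of(best)
    mc <- pmax(1, ceiling(mean_counts(best)))
    return(list(alleles = al, counts = mc, case = "both-unknown"))
  }
  seen <- any(sapply(members, function(mb) known %in% c(mb$a, mb$b)))
  if (seen) {
    ks <- names(tab)[sapply(names(tab), function(k) known %in% pair_of(k))]
    others <- sapply(ks, function(k) {
      p <- pair_of(k); if (p[1] == known) p[2] else p[1]
    })
    best <- ks[order(-as.vector(tab[ks]), others)][1]
    p <- pair_of(best)
    other <- if (p[1] == known) p[2] else p[1]
    mc <- mean_counts(best)
    m_known <- if (p[1] == known) mc[1] else mc[2]
    m_other <- if (p[1] == known) mc[2] else mc[1]
    r2 <- max(1, ceiling(known_count * m_other / m_known))
    return(list(alleles = c(known, other), counts = c(known_count, r2),
                case = "one-known-seen"))
  }
  freq <- list()
  for (mb in members) {
    if (mb$a == mb$b) {
      freq[[mb$a]] <- (freq[[mb$a]] %||% 0) + 2
    } else {
      freq[[mb$a]] <- (freq[[mb$a]] %||% 0) + 1
      freq[[mb$b]] <- (freq[[mb$b]] %||% 0) + 1
    }
  }
  fv <- unlist(freq)
  a2 <- names(fv)[order(-fv, names(fv))][1]
  ks <- names(tab)[sapply(names(tab), function(k) a2 %in% pair_of(k))]
  ratios <- sapply(ks, function(k) {
    p <- pair_of(k); mc <- mean_counts(k)
    n_rep <- 1  # ratio is per distinct pair
    if (p[1] == a2 && p[2] == a2) 1
    else if (p[1] == a2) mc[1] / mc[2]
    else mc[2] / mc[1]
  })
  r2 <- max(1, ceiling(known_count * mean(ratios)))
  list(alleles = c(known, a2), counts = c(known_count, r2),
       case = "one-known-unseen")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# builds an ase_matrix for one gene from a list of member pairs (as used
# by oracle_reconstruct), plus optional extra genes to pad the family
matrix_from_members <- function(members, gene = "g1",
                                alleles = paste0("A", 1:5)) {
  fam <- gene_family(gene, stats::setNames(list(alleles), gene))
  cnt <- matrix(0L, length(alleles), length(members))
  for (j in seq_along(members)) {
    mb <- members[[j]]
    if (mb$a == mb$b) {
      cnt[match(mb$a, alleles), j] <- mb$ca
    } else {
      cnt[match(mb$a, alleles), j] <- mb$ca
      cnt[match(mb$b, alleles), j] <- mb$cb
    }
  }
  ase_matrix(cnt, fam)
}

# random cluster of members over <=5 alleles of one gene
random_members <- function(n, alleles = paste0("A", 1:5),
                           max_count = 50L) {
  lapply(seq_len(n), function(i) {
    if (runif(1) < 0.25) {
      a <- sample(alleles, 1)
      v <- sample.int(max_count, 1)
      list(a = a, b = a, ca = v, cb = v)
    } else {
      ab <- sample(alleles, 2)
      ab <- ab[order(ab)]
      list(a = ab[1], b = ab[2], ca = sample.int(max_count, 1),
           cb = sample.int(max_count, 1))
    }
  })
}

# small two-gene fixture used by the data-model tests
tiny_matrix <- function() {
  fam <- gene_family(c("g1", "g2"),
                     list(g1 = c("A1", "A2"), g2 = c("B1", "B2")))
  # ind1: g1 het (A1=5, A2=7), g2 hom (B2=3)
  # ind2: g1 hom (A2=9), g2 het (B1=4, B2=6)
  cnt <- matrix(0L, 4, 2)
  cnt[, 1] <- c(5L, 7L, 0L, 3L)
  cnt[, 2] <- c(0L, 9L, 4L, 6L)
  ase_matrix(cnt, fam, individuals = c("ind1", "ind2"))
}
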