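# Independent brute-force oracles and tiny fixture builders.  These never
# call the code paths they check.

# random genotype table with optional missingness
random_table <- function(seed, n_sites = 12, n_acc = 6, missing_rate = 0.1) {
  withr::with_seed(seed, {
    dos <- matrix(sample(0:2, n_sites * n_acc, replace = TRUE), n_sites, n_acc)
    if (missing_rate > 0)
      dos[matrix(runif(length(dos)) < missing_rate, n_sites, n_acc)] <- NA
    sites <- data.frame(chrom = rep(c("Gm01", "chr2"), length.out = n_sites),
                        pos = seq_len(n_sites) * 10L,
                        ref = "A", alt = "G")
    genotype_table(sites, sprintf("ACC%02d", seq_len(n_acc)), dos)
  })
}

# hand-rolled per-site allele recount (the MAF oracle)
oracle_maf <- function(dos) {
  apply(dos, 1L, function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0L) return(NA_real_)
    f <- sum(row) / (2 * length(row))
    min(f, 1 - f)
  })
}

# dense eigendecomposition PCA oracle: centered (sites x acc) matrix in,
# loadings (k x sites), evr, scores (k x acc) out, same sign convention
oracle_pca <- function(centered, k) {
  X <- t(centered)                 # acc x sites
  C <- crossprod(X)                # sites x sites scatter
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  evr <- lam / sum(lam)
  loadings <- t(eg$vectors[, seq_len(k), drop = FALSE])
  for (i in seq_len(k))
    if (loadings[i, which.max(abs(loadings[i, ]))] < 0)
      loadings[i, ] <- -loadings[i, ]
  list(loadings = loadings, evr = evr[seq_len(k)],
       scores = loadings %*% centered)
}

# brute-force complete-linkage agglomeration; returns merge heights in order
oracle_complete_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; bh <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# same machinery with single linkage (min), for the dominance property
oracle_single_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; bh <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- min(D[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Hudson FST estimator (ratio of averages, Bhatia-style sample-size
# correction), computed from raw dosage matrices, independent of the
# generator's internals.  Returns the estimate and a leave-one-site-out
# jackknife standard error.
hudson_fst <- function(d1, d2) {
  n1 <- 2 * rowSums(!is.na(d1)); n2 <- 2 * rowSums(!is.na(d2))
  p1 <- rowSums(d1, na.rm = TRUE) / n1
  p2 <- rowSums(d2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- is.finite(num) & is.finite(den) & den > 0
  num <- num[keep]; den <- den[keep]
  fst <- sum(num) / sum(den)
  jk <- (sum(num) - num) / (sum(den) - den)
  se <- sqrt((length(jk) - 1) / length(jk) * sum((jk - mean(jk))^2))
  list(fst = fst, se = se)
}

# small simulated world shared by several test files (kept modest for speed)
small_sim <- function(seed = 42, n_sites = 800, per_pop = 8) {
  simulate_collection(sim_config(
    n_populations = 3, fst = 0.2, n_sites = n_sites,
    n_accessions_per_pop = per_pop, n_redundant = 1, n_cross_offspring = 1,
    missing_rate = 0.02, seed = seed))
}
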