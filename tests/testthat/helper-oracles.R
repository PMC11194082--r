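# Independent brute-force oracles used to pin down expected values.
# Everything here is written as explicit loops over the defining sums, kept
# deliberately separate from the package's vectorized implementations.

oracle_diversity <- function(m) {
  out <- numeric(nrow(m))
  for (c in seq_len(nrow(m))) for (g in seq_len(ncol(m))) out[c] <- out[c] + m[c, g]
  out
}

oracle_ubiquity <- function(m) {
  out <- numeric(ncol(m))
  for (g in seq_len(ncol(m))) for (c in seq_len(nrow(m))) out[g] <- out[g] + m[c, g]
  out
}

# reflections recursion, element by element
oracle_reflections <- function(m, n_max) {
  kc0 <- oracle_diversity(m)
  kg0 <- oracle_ubiquity(m)
  kc <- matrix(NA_real_, nrow(m), n_max + 1)
  kg <- matrix(NA_real_, ncol(m), n_max + 1)
  kc[, 1] <- kc0
  kg[, 1] <- kg0
  if (n_max >= 1) {
    for (N in seq_len(n_max)) {
      for (c in seq_len(nrow(m))) {
        acc <- 0
        for (g in seq_len(ncol(m))) acc <- acc + m[c, g] * kg[g, N]
        kc[c, N + 1] <- acc / kc0[c]
      }
      for (g in seq_len(ncol(m))) {
        acc <- 0
        for (c in seq_len(nrow(m))) acc <- acc + m[c, g] * kc[c, N]
        kg[g, N + 1] <- acc / kg0[g]
      }
    }
  }
  list(cell = kc, gene = kg)
}

# cell-cell matrix, triple loop over the defining sum
oracle_mtilde <- function(m) {
  kc0 <- oracle_diversity(m)
  kg0 <- oracle_ubiquity(m)
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (c1 in seq_len(n)) for (c2 in seq_len(n)) {
    acc <- 0
    for (g in seq_len(ncol(m))) acc <- acc + m[c1, g] * m[c2, g] / (kc0[c1] * kg0[g])
    out[c1, c2] <- acc
  }
  out
}

# RCA with all four sums spelled out
oracle_rca <- function(m) {
  grand <- 0
  for (c in seq_len(nrow(m))) for (g in seq_len(ncol(m))) grand <- grand + m[c, g]
  out <- matrix(0, nrow(m), ncol(m))
  for (c in seq_len(nrow(m))) for (g in seq_len(ncol(m))) {
    cell_tot <- sum(m[c, ])
    gene_tot <- sum(m[, g])
    if (cell_tot > 0 && gene_tot > 0) {
      out[c, g] <- (m[c, g] / cell_tot) / (gene_tot / grand)
    }
  }
  out
}

# proximity via explicit advantage-set intersections
oracle_proximity <- function(rca, threshold = 1) {
  ng <- ncol(rca)
  out <- matrix(0, ng, ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    si <- which(rca[, i] >= threshold)
    sj <- which(rca[, j] >= threshold)
    if (length(si) == 0 || length(sj) == 0) next
    both <- length(intersect(si, sj))
    out[i, j] <- min(both / length(sj), both / length(si))
  }
  out
}

# maximum spanning tree weight by exhaustive enumeration (small graphs only)
oracle_max_tree_weight <- function(phi) {
  n <- nrow(phi)
  idx <- which(upper.tri(phi) & phi > 0, arr.ind = TRUE)
  ne <- nrow(idx)
  stopifnot(n <= 7)
  best <- -Inf
  if (ne < n - 1) return(NA_real_)
  combs <- utils::combn(ne, n - 1)
  for (k in seq_len(ncol(combs))) {
    sel <- combs[, k]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    for (e in sel) {
      ri <- find(idx[e, 1]); rj <- find(idx[e, 2])
      if (ri == rj) { acyclic <- FALSE; break }
      parent[ri] <- rj
    }
    if (acyclic) {
      roots <- unique(vapply(seq_len(n), find, integer(1)))
      if (length(roots) == 1L) best <- max(best, sum(phi[idx[sel, , drop = FALSE]]))
    }
  }
  best
}

# random connected non-negative fixture with no zero margins: a ubiquitous
# backbone gene keeps the bipartite graph connected
rand_connected_matrix <- function(n_cells, n_genes, seed, density = 0.2) {
  set.seed(seed)
  m <- matrix(stats::rbinom(n_cells * n_genes, 1, density) *
                stats::runif(n_cells * n_genes, 0.5, 3),
              n_cells, n_genes)
  m[, 1] <- stats::runif(n_cells, 0.5, 3)
  empty <- which(colSums(m) == 0)
  for (g in empty) m[sample.int(n_cells, 1), g] <- stats::runif(1, 0.5, 3)
  rownames(m) <- paste0("c", seq_len(n_cells))
  colnames(m) <- paste0("g", seq_len(n_genes))
  m
}

# average-rank Spearman from first principles: Pearson on mid-ranks
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
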