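# Independent brute-force oracles. Deliberately naive: direct definitions,
# no shared code with the package internals they check.

# Erosion oracle: habitat pixels whose whole Chebyshev-radius-k neighbourhood
# (clipped at the border) is habitat; border-clipped neighbourhoods that would
# extend outside the grid count as non-habitat, and NA counts as non-habitat.
oracle_core <- function(grid, k) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(grid[i, j]) || grid[i, j] != 1) next
      if (i - k < 1 || i + k > nr || j - k < 1 || j + k > nc) next
      nb <- grid[(i - k):(i + k), (j - k):(j + k)]
      out[i, j] <- !anyNA(nb) && all(nb == 1)
    }
  }
  out
}

# All-pairs signed-distance oracle (pixel centres, metres).
oracle_signed_distance <- function(grid, res) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  idx <- which(!is.na(grid))
  ri <- ((idx - 1) %% nr) + 1
  ci <- ((idx - 1) %/% nr) + 1
  hab <- grid[idx] == 1
  out <- matrix(NA_real_, nr, nc)
  for (k in seq_along(idx)) {
    opp <- which(hab != hab[k])
    d2 <- (ri[opp] - ri[k])^2 + (ci[opp] - ci[k])^2
    out[idx[k]] <- sqrt(min(d2)) * res * (if (hab[k]) -1 else 1)
  }
  out
}

# Queue-based 8-connected flood fill, labels in row-major order of discovery.
oracle_label <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  m <- !is.na(mask) & mask
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  all_idx <- as.vector(t(matrix(seq_len(nr * nc), nr, nc)))  # row-major scan
  for (s in all_idx) {
    if (!m[s] || lab[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    lab[s] <- nextlab
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i <- ((cur - 1) %% nr) + 1
      j <- ((cur - 1) %/% nr) + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        i2 <- i + di
        j2 <- j + dj
        if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
        t <- (j2 - 1) * nr + i2
        if (m[t] && lab[t] == 0L) {
          lab[t] <- nextlab
          queue <- c(queue, t)
        }
      }
    }
  }
  lab
}

# Min pairwise centre-to-centre distance (metres) between two pixel index sets.
oracle_patch_gap <- function(idx_a, idx_b, nr, res) {
  ra <- ((idx_a - 1) %% nr) + 1
  ca <- ((idx_a - 1) %/% nr) + 1
  rb <- ((idx_b - 1) %% nr) + 1
  cb <- ((idx_b - 1) %/% nr) + 1
  min(sqrt(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2)) * res
}

# Patch-graph gap-crossing oracle: patches whose min pairwise pixel distance
# is <= crossing merge transitively; returns list(cluster = cluster id per
# patch, gaps = all pairwise min gaps, labels = patch label matrix).
oracle_fc_partition <- function(efe_grid, crossing, res) {
  lab <- oracle_label(efe_grid == 1)
  n <- max(lab)
  px <- lapply(seq_len(n), function(p) which(lab == p))
  cluster <- seq_len(n)
  gaps <- c()
  if (n >= 2) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      g <- oracle_patch_gap(px[[a]], px[[b]], nrow(efe_grid), res)
      gaps <- c(gaps, g)
      if (g <= crossing) {
        # merge clusters of a and b
        old <- cluster[b]
        cluster[cluster == old] <- cluster[a]
      }
    }
  }
  list(cluster = match(cluster, unique(cluster)), gaps = gaps, labels = lab)
}

# Welch t oracle from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Seeded random binary grid with both classes guaranteed.
random_grid <- function(nr, nc, p = 0.4, seed) {
  set.seed(seed)
  g <- matrix(rbinom(nr * nc, 1, p), nr, nc)
  if (!any(g == 1)) g[1] <- 1
  if (!any(g == 0)) g[2] <- 0
  g
}
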