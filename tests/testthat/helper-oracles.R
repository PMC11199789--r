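# Brute-force enumeration oracles for the texture matrices, deliberately
# written with different algorithms than the production C++ (line walking +
# rle, explicit voxel loops, BFS), plus small shared fixtures.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

NEI26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
NEI26 <- NEI26[rowSums(abs(NEI26)) > 0, ]

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# ordered-pair enumeration over +/- each direction
bf_glcm <- function(lev, ng) {
  d <- dim(lev)
  out <- array(0, c(ng, ng, 13))
  vox <- which(lev > 0, arr.ind = TRUE)
  for (k in 1:13) {
    for (s in c(1, -1)) {
      dir <- s * DIRS13[k, ]
      for (r in seq_len(nrow(vox))) {
        p <- vox[r, ]; q <- p + dir
        if (!in_grid(q, d)) next
        b <- lev[q[1], q[2], q[3]]
        if (b == 0) next
        a <- lev[p[1], p[2], p[3]]
        out[a, b, k] <- out[a, b, k] + 1
      }
    }
  }
  out
}

# full-line extraction + rle
bf_glrlm <- function(lev, ng) {
  d <- dim(lev)
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, 13))
  for (k in 1:13) {
    dir <- DIRS13[k, ]
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      p <- c(x, y, z)
      if (in_grid(p - dir, d)) next  # not a line start
      line <- integer(0)
      while (in_grid(p, d)) {
        line <- c(line, lev[p[1], p[2], p[3]])
        p <- p + dir
      }
      r <- rle(line)
      for (j in seq_along(r$values)) {
        if (r$values[j] > 0)
          out[r$values[j], r$lengths[j], k] <- out[r$values[j], r$lengths[j], k] + 1
      }
    }
  }
  out
}

# BFS flood fill under 26-connectivity; returns sorted (level, size) pairs
bf_glszm <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- NULL
  vox <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p0 <- vox[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    g <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (i in seq_len(nrow(NEI26))) {
        q <- p + NEI26[i, ]
        if (!in_grid(q, d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones <- rbind(zones, c(g, size))
  }
  zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
}

bf_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  out <- matrix(0, ng, 2)
  vox <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]
    a <- lev[p[1], p[2], p[3]]
    nb <- numeric(0)
    for (i in seq_len(nrow(NEI26))) {
      q <- p + NEI26[i, ]
      if (!in_grid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b > 0) nb <- c(nb, b)
    }
    out[a, 1] <- out[a, 1] + 1
    if (length(nb)) out[a, 2] <- out[a, 2] + abs(a - mean(nb))
  }
  out
}

bf_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  out <- matrix(0, ng, 27)
  vox <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]
    a <- lev[p[1], p[2], p[3]]
    dep <- 1
    for (i in seq_len(nrow(NEI26))) {
      q <- p + NEI26[i, ]
      if (!in_grid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b > 0 && abs(a - b) <= alpha) dep <- dep + 1
    }
    out[a, dep] <- out[a, dep] + 1
  }
  out
}

# random small discretized volumes for oracle comparisons
random_level_grid <- function(dim3, ng, seed, p_mask = 0.8) {
  set.seed(seed)
  lev <- array(0L, dim3)
  sel <- array(runif(prod(dim3)) < p_mask, dim3)
  lev[sel] <- sample.int(ng, sum(sel), replace = TRUE)
  lev
}

as_disc <- function(lev) {
  structure(list(levels = lev, ng = max(1L, max(lev)), bin_width = 1,
                 dim = dim(lev), n_voxels = sum(lev > 0)),
            class = "discretized_volume")
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  exp_ <- si * sj / choose(n, 2)
  (sij - exp_) / (0.5 * (si + sj) - exp_)
}

# small fast lesion used across module tests
small_phantom <- function(seed = 1L, k_true = 2L, noise_sd = 8, ...) {
  phantom_spec(grid_shape = c(20L, 20L, 20L), lesion_radii = c(7, 6.5, 6),
               k_true = k_true,
               habitat_means = seq(-40, 80, length.out = k_true),
               habitat_texture_scales = seq(1.5, 3, length.out = k_true),
               noise_sd = noise_sd, seed = seed, ...)
}

dice <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))
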