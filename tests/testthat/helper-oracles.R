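# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: flood fill is a plain R
# breadth-first search, span is an all-pairs distance scan, extents are
# direct projections, and Otsu is an exhaustive intra-class-variance search.

# enclosed-void areas by border flood fill: seed a 4-connected fill from
# every border background pixel; remaining background components are voids.
oracle_enclosed_areas <- function(grid, pixel_size) {
  nr <- nrow(grid); nc <- ncol(grid)
  visited <- grid # root pixels count as visited barriers
  flood <- function(seeds) {
    stack <- integer(nr * nc)
    top <- 0L
    for (s in seeds) {
      if (!visited[s]) {
        visited[s] <<- TRUE
        top <- top + 1L; stack[top] <- s
      }
    }
    comp <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      comp <- comp + 1L
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          idx <- r2 + (c2 - 1L) * nr
          if (!visited[idx]) {
            visited[idx] <<- TRUE
            top <- top + 1L; stack[top] <- idx
          }
        }
      }
    }
    comp
  }
  border_idx <- unique(c(
    seq_len(nr), # first column
    seq_len(nr) + (nc - 1L) * nr, # last column
    1L + (seq_len(nc) - 1L) * nr, # first row
    nr + (seq_len(nc) - 1L) * nr # last row
  ))
  flood(border_idx)
  areas <- integer(0)
  repeat {
    left <- which(!visited)
    if (length(left) == 0) break
    areas <- c(areas, flood(left[1]))
  }
  sort(areas * pixel_size^2 / 100, decreasing = TRUE)
}

# all-pairs maximum center-to-center distance (mm), O(n^2)
oracle_max_feret <- function(mask) {
  idx <- which(mask$grid, arr.ind = TRUE)
  pts <- cbind((idx[, 2] - 1) * mask$pixel_size, (idx[, 1] - 1) * mask$pixel_size)
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

# extent of root pixel centers along direction theta (radians), direct scan
oracle_extent <- function(mask, theta) {
  idx <- which(mask$grid, arr.ind = TRUE)
  proj <- (idx[, 2] - 1) * mask$pixel_size * cos(theta) +
    (idx[, 1] - 1) * mask$pixel_size * sin(theta)
  max(proj) - min(proj)
}

# maximum extent over a dense angle scan (3600 directions over a half turn)
oracle_angle_scan <- function(mask, n_angles = 3600) {
  thetas <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  ext <- vapply(thetas, function(th) oracle_extent(mask, th), numeric(1))
  list(d_max = max(ext), theta = thetas[which.max(ext)])
}

# exhaustive Otsu: threshold minimizing the weighted intra-class variance,
# searched over 256 levels on the [0, 1] scale
oracle_otsu <- function(img) {
  v <- as.vector(img)
  cand <- seq(0, 1, length.out = 257)[-1]
  icv <- vapply(cand, function(th) {
    lo <- v[v <= th]; hi <- v[v > th]
    if (length(lo) == 0 || length(hi) == 0) return(Inf)
    (length(lo) * var1(lo) + length(hi) * var1(hi)) / length(v)
  }, numeric(1))
  cand[which.min(icv)]
}

var1 <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)

# seeded random binary mask for oracle-equivalence sweeps
random_mask <- function(seed, nr = 24, nc = 24, p = 0.4, pixel_size = 1) {
  g <- withr::with_seed(seed, matrix(stats::runif(nr * nc) < p, nr, nc))
  root_mask(g, pixel_size, source_id = paste0("rand-", seed))
}

# the canonical 5x5 ring fixture: root pixels on the image border ring,
# enclosing a 3x3 interior
ring_mask_5x5 <- function(pixel_size = 1) {
  g <- matrix(FALSE, 5, 5)
  g[1, ] <- TRUE; g[5, ] <- TRUE; g[, 1] <- TRUE; g[, 5] <- TRUE
  root_mask(g, pixel_size, "ring")
}

# explicit finite-volume simulation of the 1-D diffusion column: constant
# nutrient influx J at the top face, reservoir concentration pinned at the
# bottom. Run to steady state; returns the top-node concentration excess.
oracle_pde_delta_C <- function(J_mg_cm2_day, h_cm, D_cm2_s, n_nodes = 200,
                               n_tau = 12) {
  J <- J_mg_cm2_day / 86400
  dx <- h_cm / (n_nodes - 1)
  dt <- 0.45 * dx^2 / D_cm2_s
  steps <- ceiling(n_tau * (2 * h_cm / pi)^2 / D_cm2_s / dt)
  C <- numeric(n_nodes)
  i <- 2:(n_nodes - 1)
  r <- D_cm2_s * dt / dx^2
  for (s in seq_len(steps)) {
    top <- C[n_nodes] + dt * (J - D_cm2_s * (C[n_nodes] - C[n_nodes - 1]) / dx) / (dx / 2)
    C[i] <- C[i] + r * (C[i + 1] - 2 * C[i] + C[i - 1])
    C[n_nodes] <- top
  }
  C[n_nodes] * 1000 # mg/cm3 -> mg/L
}
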