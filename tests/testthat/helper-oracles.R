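# Independent brute-force oracles used to cross-check the implementation.
# All of these are deliberately written as plain loops over definitions,
# not as calls into the package's vectorized/C++ paths.

# Two-way ANOVA by explicit cell-by-cell summation.
brute_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - g)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - g)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - g)^2
  list(ms_rows = ss_rows / (n - 1),
       ms_cols = ss_cols / (k - 1),
       ms_error = (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1)))
}

brute_icc3 <- function(m) {
  a <- brute_anova(m)
  k <- ncol(m)
  den <- a$ms_rows + (k - 1) * a$ms_error
  if (den <= 0) return(NA_real_)
  (a$ms_rows - a$ms_error) / den
}

# ICC(3,1) via stats::aov mean squares (fully independent fitting route).
aov_icc3 <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

# The 13 unique 3D direction offsets, matching the package convention.
oracle_dirs <- rbind(
  c(1,0,0), c(0,1,0), c(0,0,1),
  c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
  c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))

# lev: 3D integer array, 0 outside ROI.
brute_glcm_dir <- function(lev, dir, ngray) {
  d <- dim(lev)
  P <- matrix(0, ngray, ngray)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    X <- x + dir[1]; Y <- y + dir[2]; Z <- z + dir[3]
    if (X < 1 || Y < 1 || Z < 1 || X > d[1] || Y > d[2] || Z > d[3]) next
    lj <- lev[X, Y, Z]
    if (lj == 0) next
    P[li, lj] <- P[li, lj] + 1
  }
  P
}

brute_glrlm_dir <- function(lev, dir, ngray) {
  d <- dim(lev)
  maxrun <- max(d)
  P <- matrix(0, ngray, maxrun)
  inside <- function(x, y, z)
    x >= 1 && y >= 1 && z >= 1 && x <= d[1] && y <= d[2] && z <= d[3]
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    px <- x - dir[1]; py <- y - dir[2]; pz <- z - dir[3]
    if (inside(px, py, pz) && lev[px, py, pz] == li) next  # not a run start
    len <- 1
    X <- x + dir[1]; Y <- y + dir[2]; Z <- z + dir[3]
    while (inside(X, Y, Z) && lev[X, Y, Z] == li) {
      len <- len + 1
      X <- X + dir[1]; Y <- Y + dir[2]; Z <- Z + dir[3]
    }
    P[li, len] <- P[li, len] + 1
  }
  P
}

# 26-connected equal-level zones by repeated frontier growth.
brute_zones <- function(lev) {
  d <- dim(lev)
  lab <- array(0L, d)
  nxt <- 0L
  zones <- list()
  coords <- which(lev != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    if (lab[p[1], p[2], p[3]] != 0) next
    nxt <- nxt + 1L
    frontier <- matrix(p, 1)
    lab[p[1], p[2], p[3]] <- nxt
    size <- 1L
    lv <- lev[p[1], p[2], p[3]]
    while (nrow(frontier) > 0) {
      newf <- NULL
      for (q in seq_len(nrow(frontier))) {
        c0 <- frontier[q, ]
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          X <- c0[1] + dx; Y <- c0[2] + dy; Z <- c0[3] + dz
          if (X < 1 || Y < 1 || Z < 1 || X > d[1] || Y > d[2] || Z > d[3]) next
          if (lev[X, Y, Z] == lv && lab[X, Y, Z] == 0) {
            lab[X, Y, Z] <- nxt
            size <- size + 1L
            newf <- rbind(newf, c(X, Y, Z))
          }
        }
      }
      frontier <- if (is.null(newf)) matrix(0, 0, 3) else newf
    }
    zones[[nxt]] <- c(level = lv, size = size)
  }
  do.call(rbind, zones)
}

brute_gldm <- function(lev, ngray, alpha = 0) {
  d <- dim(lev)
  P <- matrix(0, ngray, 27)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      X <- x + dx; Y <- y + dy; Z <- z + dz
      if (X < 1 || Y < 1 || Z < 1 || X > d[1] || Y > d[2] || Z > d[3]) next
      lj <- lev[X, Y, Z]
      if (lj != 0 && abs(lj - li) <= alpha) dep <- dep + 1
    }
    P[li, dep + 1] <- P[li, dep + 1] + 1
  }
  P
}

brute_ngtdm <- function(lev, ngray) {
  d <- dim(lev)
  out <- matrix(0, ngray, 2)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    s <- 0; cnt <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      X <- x + dx; Y <- y + dy; Z <- z + dz
      if (X < 1 || Y < 1 || Z < 1 || X > d[1] || Y > d[2] || Z > d[3]) next
      lj <- lev[X, Y, Z]
      if (lj != 0) { s <- s + lj; cnt <- cnt + 1 }
    }
    out[li, 1] <- out[li, 1] + 1
    if (cnt > 0) out[li, 2] <- out[li, 2] + abs(li - s / cnt)
  }
  out
}

# Random discretized ROI on a small grid: ~70% of voxels in-mask.
random_droi <- function(seed, dims = c(5, 5, 5), ngray = 4) {
  set.seed(seed)
  lev <- array(sample(0:ngray, prod(dims), replace = TRUE,
                      prob = c(0.3, rep(0.7 / ngray, ngray))), dims)
  if (all(lev == 0)) lev[1, 1, 1] <- 1L
  vol <- image_volume(array(as.numeric(lev), dims), c(1, 1, 1))
  msk <- roi_mask(lev != 0, c(1, 1, 1))
  droi <- discretize(vol, msk, bin_width = 1)
  list(droi = droi, lev = droi$level_array, ngray = droi$n_levels)
}

# Small constant-intensity cube volume/mask pair.
constant_roi <- function(value = 7, dims = c(3, 3, 3)) {
  list(volume = image_volume(array(value, dims), c(1, 1, 1)),
       mask = roi_mask(array(1L, dims), c(1, 1, 1)))
}
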