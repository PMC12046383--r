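# Fixtures and independent brute-force oracles used across the suite.

# Axis-aligned slab: WM fills low z, GM the next n_gm slices, background above.
# GM/WM span the full lateral extent so the only pial contact is the top face.
slab_masks <- function(n_gm = 10, nx = 8, ny = 8, n_wm = 3, n_bg = 3) {
  nz <- n_wm + n_gm + n_bg
  gm <- array(FALSE, c(nx, ny, nz))
  wm <- array(FALSE, c(nx, ny, nz))
  wm[, , seq_len(n_wm)] <- TRUE
  gm[, , n_wm + seq_len(n_gm)] <- TRUE
  list(gm = gm, wm = wm, n_wm = n_wm, n_gm = n_gm)
}

# 6-neighbourhood adjacency scan, plain loops
brute_boundaries <- function(gm, wm) {
  dm <- dim(gm)
  pial <- array(FALSE, dm)
  wmb <- array(FALSE, dm)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!gm[i, j, k]) next
    for (o in seq_len(6)) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
      if (wm[ii, jj, kk]) wmb[i, j, k] <- TRUE
      else if (!gm[ii, jj, kk]) pial[i, j, k] <- TRUE
    }
  }
  list(pial = pial, wm = wmb)
}

# brute-force Euclidean distance transform (pairwise distances)
brute_edt <- function(mask, spacing) {
  dm <- dim(mask)
  feats <- which(mask, arr.ind = TRUE)
  if (!nrow(feats)) return(array(Inf, dm))
  fp <- sweep(feats - 1, 2, spacing, `*`)
  out <- array(NA_real_, dm)
  all_idx <- which(array(TRUE, dm), arr.ind = TRUE)
  ap <- sweep(all_idx - 1, 2, spacing, `*`)
  for (v in seq_len(nrow(all_idx))) {
    d2 <- colSums((t(fp) - ap[v, ])^2)
    out[all_idx[v, , drop = FALSE]] <- sqrt(min(d2))
  }
  out
}

# exhaustive moment-mismatch search over realizable cuts: the two-level image
# preserves m1 and m2 exactly; the cut minimizing the |m3| mismatch wins
oracle_moment_cut <- function(vals, n_levels = 256L) {
  rng <- range(vals)
  lev <- round((vals - rng[1]) / (rng[2] - rng[1]) * (n_levels - 1))
  p <- tabulate(lev + 1L, nbins = n_levels) / length(lev)
  z <- seq_len(n_levels) - 1
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  cum <- cumsum(p)
  best <- Inf; best_p <- NA_real_
  for (t in 0:(n_levels - 2L)) {
    p0 <- cum[t + 1]
    if (p0 <= 0 || p0 >= 1) next
    z0 <- m1 - sqrt((1 - p0) / p0 * cd)
    z1 <- m1 + sqrt(p0 / (1 - p0) * cd)
    mis <- abs(p0 * z0^3 + (1 - p0) * z1^3 - m3)
    if (mis < best - 1e-15) { best <- mis; best_p <- p0 }
  }
  best_p  # below-threshold mass of the winning partition
}

# hand-rolled BH step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# largest-i rejection set per the BH definition
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  i_max <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  if (!is.finite(i_max)) return(rep(FALSE, m))
  p <= ps[i_max]
}

# Beer-Lambert forward render of per-stain density maps
forward_render <- function(density_list, stain_matrix, i0 = 255) {
  h <- nrow(density_list[[1]]); w <- ncol(density_list[[1]])
  od <- array(0, c(h, w, 3))
  for (si in seq_along(density_list)) {
    for (ch in 1:3) {
      od[, , ch] <- od[, , ch] + density_list[[si]] * stain_matrix[si, ch]
    }
  }
  i0 * 10^(-od)
}

# random symmetric positive-definite tensor with eigenvalues ~ diffusivities
random_spd_tensor <- function(scale = 1e-3) {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  lam <- sort(runif(3, 0.2, 2.5) * scale, decreasing = TRUE)
  Q %*% diag(lam) %*% t(Q)
}

tensor_to_6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])

# tensor field on a tiny grid from a list of 3x3 tensors
tensor_field_from_list <- function(tensors, spacing = c(1, 1, 1)) {
  n <- length(tensors)
  dm <- c(n, 1, 1)
  D <- array(0, c(dm, 6))
  for (i in seq_len(n)) D[i, 1, 1, ] <- tensor_to_6(tensors[[i]])
  structure(
    list(D = D, log_s0 = array(0, dm), mask = array(TRUE, dm),
         flagged = array(FALSE, dm), spacing = spacing),
    class = "tensor_field"
  )
}

# null cohort with exchangeable groups: no injected effect, homogeneous
# covariate distributions across groups
null_cohort_spec <- function(seed) {
  cohort_spec(
    effect_spec = tibble::tibble(group = character(), layer = integer(),
                                 roi = integer(), metric = character(),
                                 multiplier = numeric()),
    thickness_mean = c(HC = 3, PART = 3, AbPos = 3),
    age_mean = c(HC = 65, PART = 65, AbPos = 65),
    seed = seed
  )
}
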