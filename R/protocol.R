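#' Diffusion acquisition protocol
#'
#' Defaults follow the ex vivo acquisition the pipeline targets: 20 b0 images
#' and 60 non-colinear diffusion directions at b = 6000 s/mm^2. Directions are
#' spread by seeded electrostatic repulsion on the sphere (antipodally
#' symmetric energy), so the set is deterministic for a given seed.
#'
#' @param b0_count number of b = 0 volumes.
#' @param n_directions number of diffusion-weighted directions.
#' @param b_value diffusion weighting (s/mm^2), positive.
#' @param snr signal-to-noise ratio defined as S0 / sigma on the complex
#'   channel; `Inf` for noiseless data.
#' @param noise_model `"rician"` (magnitude data; the default) or `"gaussian"`.
#' @param direction_seed seed for the repulsion optimizer.
#' @return object of class `dwi_protocol` with `bvals` (length
#'   `b0_count + n_directions`) and `bvecs` (matrix, one unit row per volume;
#'   zero rows for b0).
#' @export
dwi_protocol <- function(b0_count = 20L, n_directions = 60L, b_value = 6000,
                         snr = 30, noise_model = c("rician", "gaussian"),
                         direction_seed = 42L) {
  noise_model <- match.arg(noise_model)
  stopifnot(b0_count >= 1, n_directions >= 6, b_value > 0, snr > 0)
  dirs <- repulsion_directions(n_directions, seed = direction_seed)
  bvals <- c(rep(0, b0_count), rep(b_value, n_directions))
  bvecs <- rbind(matrix(0, b0_count, 3), dirs)
  structure(
    list(b0_count = as.integer(b0_count),
         n_directions = as.integer(n_directions),
         b_value = b_value, snr = snr, noise_model = noise_model,
         bvals = bvals, bvecs = bvecs),
    class = "dwi_protocol"
  )
}

#' Electrostatic-repulsion gradient directions
#'
#' Distributes `n` unit vectors on the sphere by minimizing the antipodally
#' symmetric Coulomb energy `sum 1/|d_i - d_j|^2 + 1/|d_i + d_j|^2` by
#' projected gradient descent from a seeded random start. Guarantees
#' pairwise non-colinearity for n >= 6 in practice.
#'
#' @param n number of directions.
#' @param seed RNG seed for the starting configuration.
#' @param n_iter descent iterations.
#' @return n x 3 matrix of unit row vectors.
#' @export
repulsion_directions <- function(n, seed = 42L, n_iter = 200L) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  for (it in seq_len(n_iter)) {
    step <- 0.1 * 0.98^it
    grad <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      dif <- sweep(v[-i, , drop = FALSE], 2, v[i, ], `-`)
      sum_ <- sweep(v[-i, , drop = FALSE], 2, v[i, ], `+`)
      r2d <- pmax(rowSums(dif^2), 1e-8)
      r2s <- pmax(rowSums(sum_^2), 1e-8)
      # repulsive force on v_i for E = sum r^-2 (both hemispheres)
      grad[i, ] <- -2 * colSums(dif / r2d^2) + 2 * colSums(sum_ / r2s^2)
    }
    # tangential, per-point-normalized move keeps the descent stable
    grad <- grad - v * rowSums(grad * v)
    gn <- sqrt(rowSums(grad^2))
    grad[gn > 0, ] <- grad[gn > 0, , drop = FALSE] / gn[gn > 0]
    v <- v + step * grad
    v <- v / sqrt(rowSums(v^2))
  }
  v
}

#' Synthesize diffusion-weighted signal from a tensor field
#'
#' Monoexponential tensor forward model: per voxel and volume,
#' `S(g, b) = S0 exp(-b g' D g)`, with optional Gaussian or Rician noise of
#' standard deviation `sigma = S0_ref / snr` added per volume (`S0_ref` is the
#' mean S0 over the mask). b0 volumes carry b = 0 and equal S0 before noise.
#'
#' @param tensor_field a `tensor_field` (from [make_phantom()] or
#'   [fit_tensor()]); tensors must be finite on the mask.
#' @param s0 S0 map: scalar or array on the tensor grid (default 100).
#' @param protocol a [dwi_protocol()].
#' @param seed RNG seed for the noise draw.
#' @return DWI dataset: list with `signal` (4D array), `bvals`, `bvecs`,
#'   `spacing`, `mask`.
#' @export
synthesize_dwi <- function(tensor_field, s0 = 100, protocol = dwi_protocol(),
                           seed = 1L) {
  D <- tensor_field$D
  dm <- dim(D)[1:3]
  mask <- tensor_field$mask
  idx <- which(mask)
  D6 <- matrix(D, nrow = prod(dm), ncol = 6)[idx, , drop = FALSE]
  if (any(!is.finite(D6))) stop("non-finite tensor entries on the mask")
  if (length(s0) == 1) {
    s0_vox <- rep(s0, length(idx))
    s0_ref <- s0
  } else {
    check_same_grid(array(0, dm), s0)
    s0_vox <- s0[idx]
    s0_ref <- mean(s0_vox)
  }
  bvals <- protocol$bvals
  bvecs <- protocol$bvecs
  n_vol <- length(bvals)
  sig <- array(0, c(dm, n_vol))
  sig_m <- matrix(sig, nrow = prod(dm), ncol = n_vol)
  g <- bvecs
  # quadratic form g'Dg for all voxels x volumes: (n_vox x 6) %*% (6 x n_vol)
  Q <- rbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  gDg <- D6 %*% Q
  S <- s0_vox * exp(-sweep(gDg, 2, bvals, `*`))
  if (is.finite(protocol$snr)) {
    set.seed(seed)
    sigma <- s0_ref / protocol$snr
    if (protocol$noise_model == "gaussian") {
      S <- S + sigma * matrix(rnorm(length(S)), nrow(S), ncol(S))
    } else {
      n1 <- sigma * matrix(rnorm(length(S)), nrow(S), ncol(S))
      n2 <- sigma * matrix(rnorm(length(S)), nrow(S), ncol(S))
      S <- sqrt((S + n1)^2 + n2^2)
    }
  }
  sig_m[idx, ] <- S
  list(signal = array(sig_m, c(dm, n_vol)), bvals = bvals, bvecs = bvecs,
       spacing = tensor_field$spacing, mask = mask)
}
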