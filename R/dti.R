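#' Fit the diffusion tensor by log-linear least squares
#'
#' Ordinary least squares of `log(S)` on the standard 7-column tensor design
#' `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`,
#' voxel-wise within a mask. All volumes (b0 and diffusion-weighted) enter the
#' regression. Non-positive signals are clipped to a small epsilon before the
#' log and the voxel is flagged.
#'
#' @param dwi a DWI dataset: list with `signal` (4D array), `bvals`, `bvecs`
#'   (N x 3 matrix of unit vectors), `spacing` — as produced by
#'   [synthesize_dwi()] or assembled from [read_nifti()]/[read_bval_bvec()].
#' @param mask logical 3D array of voxels to fit (default: all voxels).
#' @return object of class `tensor_field`: list with `D` (4D array, 6 unique
#'   components per voxel in the order xx, yy, zz, xy, xz, yz, mm^2/s),
#'   `log_s0`, `mask`, `flagged` (voxels with clipped signals) and `spacing`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  sig <- dwi$signal
  dm <- dim(sig)
  if (length(dm) != 4) stop("signal must be a 4D array")
  n_vol <- dm[4]
  bvals <- dwi$bvals
  bvecs <- dwi$bvecs
  if (length(bvals) != n_vol || nrow(bvecs) != n_vol) {
    stop("bvals/bvecs length does not match volume count")
  }
  if (n_vol < 7) stop("need at least 7 volumes to fit the tensor")
  if (is.null(mask)) mask <- array(TRUE, dm[1:3]) else mask <- as_mask(mask)
  check_same_grid(array(0, dm[1:3]), mask)

  g <- bvecs
  X <- cbind(
    1,
    -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
    -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
    -2 * bvals * g[, 2] * g[, 3]
  )
  qrX <- qr(X)
  if (qrX$rank < 7) {
    stop("rank-deficient tensor design (collinear gradient directions): rank ",
         qrX$rank, " < 7")
  }

  vox <- which(mask)
  n_mask <- length(vox)
  nxyz <- prod(dm[1:3])
  S <- matrix(sig, nrow = nxyz, ncol = n_vol)[vox, , drop = FALSE]
  bad <- S <= 0 | !is.finite(S)
  flagged_vox <- rowSums(bad) > 0
  if (any(bad)) {
    eps <- {
      pos <- S[!bad]
      if (length(pos)) min(pos) * 1e-6 else 1e-12
    }
    S[bad] <- eps
  }
  beta <- qr.coef(qrX, t(log(S)))  # 7 x n_mask

  D <- array(NA_real_, c(dm[1:3], 6))
  Dm <- matrix(D, nrow = nxyz, ncol = 6)
  Dm[vox, ] <- t(beta[2:7, , drop = FALSE])
  D <- array(Dm, c(dm[1:3], 6))
  log_s0 <- array(NA_real_, dm[1:3])
  log_s0[vox] <- beta[1, ]
  flagged <- array(FALSE, dm[1:3])
  flagged[vox] <- flagged_vox

  structure(
    list(D = D, log_s0 = log_s0, mask = mask, flagged = flagged,
         spacing = dwi$spacing),
    class = "tensor_field"
  )
}

# eigenvalues (descending) of symmetric 3x3 tensors given as n x 6 matrix
tensor_eigenvalues <- function(D6) {
  t(apply(D6, 1, function(d) {
    if (any(!is.finite(d))) return(c(NA_real_, NA_real_, NA_real_))
    M <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }))
}

fa_from_eigenvalues <- function(lams) {
  md <- rowMeans(lams)
  num <- sqrt(rowSums((lams - md)^2))
  den <- sqrt(rowSums(lams^2))
  fa <- sqrt(1.5) * num / den
  fa[den == 0] <- 0  # FA of the zero tensor
  fa
}

#' Scalar maps from a fitted tensor field
#'
#' Eigen-decomposes every voxel's tensor and derives the standard scalar
#' metrics: MD (mean eigenvalue), AD (largest), RD (mean of the two smaller),
#' and FA. FA of the zero tensor is defined as 0. Voxels with non-finite
#' tensors are flagged and left `NA`.
#'
#' @param tensors a `tensor_field` from [fit_tensor()] (or the equivalent list
#'   from [make_phantom()]).
#' @return object of class `metric_maps`: list of arrays `FA`, `MD`, `AD`,
#'   `RD` plus `mask`, `flagged`, `spacing`.
#' @export
tensor_metrics <- function(tensors) {
  D <- tensors$D
  dm <- dim(D)[1:3]
  mask <- tensors$mask
  vox <- which(mask)
  D6 <- matrix(D, nrow = prod(dm), ncol = 6)[vox, , drop = FALSE]
  lams <- tensor_eigenvalues(D6)
  nonfinite <- !is.finite(lams[, 1])

  mk <- function(v) {
    a <- array(NA_real_, dm)
    a[vox] <- v
    a
  }
  md <- rowMeans(lams)
  flagged <- tensors$flagged
  flagged[vox][nonfinite] <- TRUE
  structure(
    list(
      FA = mk(fa_from_eigenvalues(lams)),
      MD = mk(md),
      AD = mk(lams[, 1]),
      RD = mk((lams[, 2] + lams[, 3]) / 2),
      mask = mask, flagged = flagged, spacing = tensors$spacing
    ),
    class = "metric_maps"
  )
}

#' Normalize a metric map by its mean over the cortex
#'
#' Divides every voxel by the map's mean over `cortex_mask`, yielding the
#' unitless "m" variants (mFA, mMD, ...) whose cortex mean is exactly 1.
#'
#' @param map numeric array.
#' @param cortex_mask logical array, non-empty; the map must be finite on it.
#' @return normalized array.
#' @export
normalize_metric <- function(map, cortex_mask) {
  cortex_mask <- as_mask(cortex_mask)
  check_same_grid(map, cortex_mask)
  if (!any(cortex_mask)) stop("cortex mask is empty")
  vals <- map[cortex_mask]
  if (any(!is.finite(vals))) stop("map has non-finite values on the cortex mask")
  m <- mean(vals)
  if (!is.finite(m) || m <= 0) stop("cortex mean is not positive")
  map / m
}

#' Per-layer, per-ROI metric profile
#'
#' Reduces scalar maps to the arithmetic mean within each (ROI, layer) cell.
#' Cells with no voxels are emitted with `NA` value and zero count rather than
#' silently dropped.
#'
#' @param maps named list of metric arrays (e.g. the `FA`/`MD`/... elements of
#'   a `metric_maps`, possibly normalized), all on one grid.
#' @param layers integer array of retained layer labels (1..6) as from
#'   [retain_layers()].
#' @param roi_atlas integer array of parcel labels (0/`NA` = unlabelled).
#' @param subject_id identifier copied into every row.
#' @return tibble with columns `subject`, `roi`, `layer`, `metric`, `value`,
#'   `n_voxels`.
#' @export
layer_roi_profile <- function(maps, layers, roi_atlas, subject_id = "subj") {
  stopifnot(is.list(maps), !is.null(names(maps)))
  check_same_grid(maps[[1]], layers, roi_atlas)
  layer_ids <- sort(unique(layers[!is.na(layers)]))
  rois <- sort(unique(roi_atlas[!is.na(roi_atlas) & roi_atlas > 0]))
  cells <- tidyr::expand_grid(roi = rois, layer = layer_ids,
                              metric = names(maps))
  rows <- purrr::pmap(cells, function(roi, layer, metric) {
    sel <- !is.na(roi_atlas) & roi_atlas == roi &
      !is.na(layers) & layers == layer
    v <- maps[[metric]][sel]
    v <- v[!is.na(v)]
    tibble(
      subject = subject_id, roi = roi, layer = as.integer(layer),
      metric = metric,
      value = if (length(v)) mean(v) else NA_real_,
      n_voxels = length(v)
    )
  })
  dplyr::bind_rows(rows)
}
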