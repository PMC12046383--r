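#' Standard stain optical-density presets
#'
#' Unit-norm optical-density row vectors for common brightfield stain
#' combinations, from the standard color-deconvolution literature. Any matrix
#' of unit rows can be supplied instead wherever a preset is accepted; real
#' slides are usually deconvolved with a manually chosen vector.
#'
#' @param which `"h_dab"` (hematoxylin + DAB + orthogonal complement),
#'   `"h_e"` (hematoxylin + eosin) or `"lfb"` (Luxol-fast-blue-style myelin
#'   stain + nuclear counterstain).
#' @return 3 x 3 matrix, rows named by stain, unit norm.
#' @export
stain_presets <- function(which = c("h_dab", "h_e", "lfb")) {
  which <- match.arg(which)
  unit <- function(v) v / sqrt(sum(v^2))
  m <- switch(which,
    h_dab = rbind(
      hematoxylin = unit(c(0.650, 0.704, 0.286)),
      abeta = unit(c(0.268, 0.570, 0.776)),   # DAB chromogen
      residual = c(0, 0, 0)
    ),
    h_e = rbind(
      hematoxylin = unit(c(0.644, 0.717, 0.267)),
      eosin = unit(c(0.093, 0.954, 0.283)),
      residual = c(0, 0, 0)
    ),
    lfb = rbind(
      myelin = unit(c(0.850, 0.510, 0.130)),  # blue stain: absorbs red/green
      nuclear = unit(c(0.650, 0.704, 0.286)),
      residual = c(0, 0, 0)
    )
  )
  m[3, ] <- complete_third_vector(m[1, ], m[2, ])
  m
}

# orthogonal complement of two stain vectors, unit norm (Ruifrok's rule for a
# missing third stain)
complete_third_vector <- function(v1, v2) {
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  n <- sqrt(sum(v3^2))
  if (n < 1e-12) stop("stain vectors are collinear")
  v3 / n
}

#' Color deconvolution of a brightfield RGB image
#'
#' Converts intensities to optical density, `OD_c = -log10(max(I_c, 1) / I0)`,
#' and unmixes through the inverse of the stain matrix, returning one density
#' channel per stain. A two-row stain matrix is completed with the unit
#' orthogonal complement as the third basis vector.
#'
#' @param rgb height x width x 3 intensity array in `[0, i0]`.
#' @param stain_matrix 2 or 3 unit-norm optical-density row vectors, rows
#'   named by stain.
#' @param i0 white reference (default 255).
#' @return named list of density matrices, in stain-matrix row order.
#' @export
color_deconvolve <- function(rgb, stain_matrix, i0 = 255) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (nrow(stain_matrix) == 2) {
    stain_matrix <- rbind(stain_matrix,
                          residual = complete_third_vector(stain_matrix[1, ],
                                                           stain_matrix[2, ]))
  }
  if (nrow(stain_matrix) != 3) stop("stain matrix must have 2 or 3 rows")
  if (abs(det(stain_matrix)) < 1e-10) stop("singular stain matrix")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  I <- matrix(rgb, ncol = 3)
  od <- -log10(pmax(I, 1) / i0)
  dens <- od %*% solve(stain_matrix)
  out <- lapply(seq_len(3), function(i) matrix(dens[, i], h, w))
  names(out) <- rownames(stain_matrix)
  out
}

#' Moment-preserving (Tsai) threshold
#'
#' Binarizes a gray-level channel so that the two-level image preserves the
#' channel's first three moments. For every realizable cut the two
#' representative levels `z0 < z1` are chosen to preserve the first and second
#' moments exactly; the threshold is the cut whose two-level image best
#' matches the third moment. Whenever the closed-form moment-preserving
#' below-fraction `p0` is exactly attainable in the cumulative histogram this
#' reduces to Tsai's percentile rule; on discrete histograms where `p0` falls
#' between attainable cuts it picks the better neighbour rather than always
#' rounding up. The channel is quantized to 256 levels between its minimum
#' and maximum (the moment formulation is histogram-based); positive pixels
#' are those strictly above the threshold.
#'
#' @param channel numeric matrix (a deconvolved stain density channel).
#' @param n_levels quantization levels (default 256).
#' @return object of class `moment_threshold`: list with `threshold` (on the
#'   original scale), `mask` (logical matrix of positive pixels), `p0`, the
#'   quantization `range`, and the representative levels `z0`, `z1`.
#' @export
moment_threshold <- function(channel, n_levels = 256L) {
  v <- as.numeric(channel)
  if (any(!is.finite(v))) stop("channel has non-finite values")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant channel: empty positive mask")
    return(structure(
      list(threshold = NA_real_, mask = channel > Inf, p0 = 1,
           range = rng, z0 = rng[1], z1 = rng[1]),
      class = "moment_threshold"
    ))
  }
  lev <- round((v - rng[1]) / (rng[2] - rng[1]) * (n_levels - 1))
  hist_counts <- tabulate(lev + 1L, nbins = n_levels)
  p <- hist_counts / length(v)
  z <- seq_len(n_levels) - 1
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  # closed-form moment-preserving solution (reported for interpretability)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- max(c1^2 - 4 * c0, 0)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- if (z1 == z0) 0.5 else (z1 - m1) / (z1 - z0)
  # realizable cut whose m1/m2-preserving two-level image best matches m3
  cum <- cumsum(p)
  pc <- cum[seq_len(n_levels - 1L)]
  ok <- pc > 0 & pc < 1
  zlo <- m1 - sqrt((1 - pc) / pc * cd)
  zhi <- m1 + sqrt(pc / (1 - pc) * cd)
  mis3 <- abs(pc * zlo^3 + (1 - pc) * zhi^3 - m3)
  mis3[!ok] <- Inf
  t_lev <- which.min(mis3) - 1L
  thr <- rng[1] + (t_lev + 0.5) / (n_levels - 1) * (rng[2] - rng[1])
  structure(
    list(threshold = thr, mask = channel > thr, p0 = p0, range = rng,
         z0 = rng[1] + z0 / (n_levels - 1) * (rng[2] - rng[1]),
         z1 = rng[1] + z1 / (n_levels - 1) * (rng[2] - rng[1])),
    class = "moment_threshold"
  )
}

#' Per-layer positive-pixel fractions of a thresholded slide
#'
#' For each retained layer, the fraction of positive pixels among the layer's
#' pixels. Layers with zero pixels are omitted (with a message).
#'
#' @param mask logical matrix of stain-positive pixels.
#' @param layers integer matrix of retained layer labels (from
#'   [layering_2d()] or a slide's ground truth), `NA` outside the band.
#' @param stain stain name recorded in the output.
#' @param slide_id slide identifier recorded in the output.
#' @return tibble with columns `slide`, `stain`, `layer`, `fraction`,
#'   `n_pixels` (a DensityProfile).
#' @export
layer_density <- function(mask, layers, stain = "stain", slide_id = "slide") {
  check_same_grid(mask, layers)
  ids <- sort(unique(layers[!is.na(layers)]))
  rows <- purrr::map(ids, function(l) {
    sel <- !is.na(layers) & layers == l
    n <- sum(sel)
    if (n == 0) {
      message("layer ", l, " has no pixels; omitted")
      return(NULL)
    }
    tibble(slide = slide_id, stain = stain, layer = as.integer(l),
           fraction = sum(mask[sel]) / n, n_pixels = as.integer(n))
  })
  dplyr::bind_rows(rows)
}
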