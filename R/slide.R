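#' Specification of a synthetic stained slide
#'
#' Describes a layered histology image: a horizontal gray-matter band between
#' a CSF-GM (pial, top) and WM-GM (bottom) boundary, partitioned into
#' equidistant laminae, with stain-positive blobs placed to hit per-layer
#' target positive-pixel fractions. Pixels are rendered by Beer-Lambert
#' mixing through the stain optical-density matrix. The default targets
#' emulate amyloid deposition rising nonlinearly with cortical depth.
#'
#' @param width,height image size in pixels.
#' @param band_rows integer range (top, bottom row) of the gray-matter band;
#'   default leaves a margin of 10% of the height on each side.
#' @param n_laminae number of equidistant laminae (default 8; the six interior
#'   layers carry the targets).
#' @param targets named list: per stain, a numeric vector of per-retained-layer
#'   (pial to WM) target positive fractions in `[0, 1]`.
#' @param blob_radius_range inclusive integer range of blob radii (pixels).
#' @param stain_matrix optical-density matrix, unit-norm rows named by stain;
#'   must cover all names in `targets` (default [stain_presets()] `"h_dab"`).
#' @param amplitude stain optical-density amplitude at a positive pixel.
#' @param i0 white reference intensity (default 255).
#' @param seed integer seed.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(width = 300L, height = 400L,
                       band_rows = NULL, n_laminae = 8L,
                       targets = list(abeta = c(0.02, 0.05, 0.10, 0.15, 0.15, 0.12)),
                       blob_radius_range = c(1L, 3L),
                       stain_matrix = NULL, amplitude = 1.0,
                       i0 = 255, seed = 1L) {
  if (is.null(band_rows)) {
    m <- round(0.1 * height)
    band_rows <- c(m + 1L, height - m)
  }
  if (is.null(stain_matrix)) stain_matrix <- stain_presets("h_dab")
  missing_stains <- setdiff(names(targets), rownames(stain_matrix))
  if (length(missing_stains)) {
    stop("stain(s) not in the stain matrix: ",
         paste(missing_stains, collapse = ", "))
  }
  n_ret <- n_laminae - 2L
  for (s in names(targets)) {
    tf <- targets[[s]]
    if (length(tf) != n_ret) stop("targets$", s, " must have length ", n_ret)
    if (any(tf < 0 | tf > 1)) stop("target fractions must be in [0, 1]")
  }
  nrm <- sqrt(rowSums(stain_matrix^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("stain matrix rows must be unit-norm")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         band_rows = as.integer(band_rows), n_laminae = as.integer(n_laminae),
         targets = targets, blob_radius_range = as.integer(blob_radius_range),
         stain_matrix = stain_matrix, amplitude = amplitude, i0 = i0,
         seed = as.integer(seed)),
    class = "slide_spec"
  )
}

# place blobs in the pixel set `rows` (row indices within band) x full width
# until the positive count reaches exactly `n_target`, trimming the overshoot
place_layer_blobs <- function(mask, row_range, n_target, radius_range) {
  if (n_target == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  n_band <- (row_range[2] - row_range[1] + 1L) * w
  if (n_target > 0.6 * n_band) {
    stop("target fraction exceeds packable density for the blob size")
  }
  count <- 0L
  guard <- 0L
  placed <- matrix(FALSE, h, w)
  while (count < n_target) {
    guard <- guard + 1L
    if (guard > 50L * n_target + 1000L) {
      stop("target fraction exceeds packable density for the blob size")
    }
    r0 <- sample(row_range[1]:row_range[2], 1)
    c0 <- sample.int(w, 1)
    rad <- sample(radius_range[1]:radius_range[2], 1)
    rr <- max(row_range[1], r0 - rad):min(row_range[2], r0 + rad)
    cc <- max(1L, c0 - rad):min(w, c0 + rad)
    sub <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2 <= rad^2)
    new_px <- which(sub & !placed[rr, cc, drop = FALSE])
    if (!length(new_px)) next
    sel <- placed[rr, cc, drop = FALSE]
    sel[new_px] <- TRUE
    placed[rr, cc] <- sel
    count <- count + length(new_px)
  }
  if (count > n_target) {
    pos <- which(placed)
    drop <- sample(pos, count - n_target)
    placed[drop] <- FALSE
  }
  mask | placed
}

#' Render a synthetic stained slide with known per-layer positive fractions
#'
#' Lays out the gray-matter band, splits it into equidistant laminae, places
#' stain-positive blobs so each retained layer's realized positive fraction
#' equals its target to within one pixel, and renders RGB intensities by
#' Beer-Lambert mixing: `I_c = I0 * 10^(-sum_s d_s M_sc)`. With all targets
#' zero the image is pure background at `I0`. The excluded outermost and
#' innermost laminae reuse the nearest retained layer's target.
#'
#' @param spec a [slide_spec()].
#' @return list with `rgb` (height x width x 3 array in `[0, i0]`),
#'   `truth` (tibble: stain, layer, target and realized fraction, pixel
#'   count), `truth_masks` (per-stain logical matrices), `boundaries` (tibble
#'   of pial/WM polyline vertices), `band_mask`, `layers` (retained-layer
#'   label matrix) and the spec.
#' @export
render_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  K <- spec$n_laminae
  top <- spec$band_rows[1]; bot <- spec$band_rows[2]
  band <- matrix(FALSE, h, w)
  band[top:bot, ] <- TRUE

  # equidistant laminae by row: depth of row r is (r - top) / (bot - top)
  depth_row <- (seq(top, bot) - top) / (bot - top)
  lam_row <- pmin(floor(depth_row * K) + 1L, K)
  lam_to_layer <- pmin(pmax(seq_len(K) - 1L, 1L), K - 2L)
  layer_row <- lam_to_layer[lam_row]          # extended (laminae 1/K clamped)
  retained_row <- lam_row >= 2L & lam_row <= K - 1L

  layers <- matrix(NA_integer_, h, w)
  layers[top:bot, ] <- ifelse(retained_row, layer_row, NA_integer_)

  density <- array(0, c(h, w, nrow(spec$stain_matrix)))
  truth_masks <- list()
  truth <- list()
  for (s in names(spec$targets)) {
    si <- match(s, rownames(spec$stain_matrix))
    mask <- matrix(FALSE, h, w)
    # each lamina filled to its (clamped) layer target; blobs are clipped to
    # the lamina's rows so realized per-layer counts are exact
    for (lam in seq_len(K)) {
      rows_lam <- seq(top, bot)[lam_row == lam]
      if (!length(rows_lam)) next
      tgt <- spec$targets[[s]][lam_to_layer[lam]]
      n_target <- round(tgt * length(rows_lam) * w)
      mask <- place_layer_blobs(mask, range(rows_lam), n_target,
                                spec$blob_radius_range)
    }
    truth_masks[[s]] <- mask
    density[, , si] <- density[, , si] + spec$amplitude * mask
    realized <- purrr::map(seq_len(K - 2L), function(lay) {
      rows_l <- seq(top, bot)[layer_row == lay & retained_row]
      n_px <- length(rows_l) * w
      tibble(stain = s, layer = lay,
             target = spec$targets[[s]][lay],
             fraction = sum(mask[rows_l, ]) / n_px,
             n_pixels = n_px)
    })
    truth[[s]] <- dplyr::bind_rows(realized)
  }

  od <- array(0, c(h, w, 3))
  for (si in seq_len(nrow(spec$stain_matrix))) {
    for (ch in 1:3) {
      od[, , ch] <- od[, , ch] + density[, , si] * spec$stain_matrix[si, ch]
    }
  }
  rgb <- spec$i0 * 10^(-od)

  boundaries <- dplyr::bind_rows(
    tibble(boundary = "pial", x = c(1, w), y = c(top, top)),
    tibble(boundary = "wm", x = c(1, w), y = c(bot, bot))
  )

  list(rgb = rgb, truth = dplyr::bind_rows(truth), truth_masks = truth_masks,
       boundaries = boundaries, band_mask = band, layers = layers,
       spec = spec)
}
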