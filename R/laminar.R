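#' Extract pial and white-matter boundary voxels of the cortical ribbon
#'
#' The white-matter boundary is the set of gray-matter voxels face-adjacent to
#' white matter; the pial boundary is the set of gray-matter voxels
#' face-adjacent to anything that is neither gray nor white matter (CSF or
#' background). Adjacency is 6-connected in 3D and 4-connected in 2D. Both
#' sets are subsets of the gray-matter mask.
#'
#' @param gm_mask,wm_mask logical arrays on the same grid; must be disjoint.
#' @return list with logical arrays `pial` and `wm`.
#' @export
extract_boundaries <- function(gm_mask, wm_mask) {
  gm_mask <- as_mask(gm_mask)
  wm_mask <- as_mask(wm_mask)
  check_same_grid(gm_mask, wm_mask)
  if (any(gm_mask & wm_mask)) stop("GM and WM masks overlap")
  if (!any(gm_mask)) {
    warning("empty GM mask: boundary sets are empty")
    return(list(pial = gm_mask, wm = gm_mask))
  }
  outside <- !gm_mask & !wm_mask
  list(
    pial = gm_mask & adjacent_to(outside),
    wm = gm_mask & adjacent_to(wm_mask)
  )
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  m <- x != 0
  dim(m) <- dim(x)
  m
}

#' Equidistant cortical depth
#'
#' Assigns each gray-matter voxel a relative depth
#' `d = D_pial / (D_pial + D_wm)`, where `D_pial` and `D_wm` are Euclidean
#' distances (mm) to the pial and white-matter boundary voxel sets. Depth is 0
#' on the pial boundary and 1 on the WM boundary; a voxel belonging to both
#' sets (one-voxel-thick ribbon) is assigned 0.5.
#'
#' @param gm_mask logical array of gray-matter voxels.
#' @param pial_boundary,wm_boundary logical arrays as from
#'   [extract_boundaries()]; both must be non-empty.
#' @param spacing per-axis voxel size in mm.
#' @return list with `depth` (array in `[0,1]` on GM, `NA` elsewhere) and the
#'   distance transforms `dist_pial`, `dist_wm` (mm, whole grid).
#' @export
compute_depth <- function(gm_mask, pial_boundary, wm_boundary,
                          spacing = rep(1, length(dim(gm_mask)))) {
  gm_mask <- as_mask(gm_mask)
  check_same_grid(gm_mask, pial_boundary, wm_boundary)
  if (!any(pial_boundary)) stop("pial boundary set is empty (open ribbon)")
  if (!any(wm_boundary)) stop("WM boundary set is empty (open ribbon)")
  d_pial <- distance_transform(pial_boundary, spacing)
  d_wm <- distance_transform(wm_boundary, spacing)
  depth <- array(NA_real_, dim(gm_mask))
  tot <- d_pial + d_wm
  both <- pial_boundary & wm_boundary
  depth[gm_mask] <- d_pial[gm_mask] / tot[gm_mask]
  depth[both & gm_mask] <- 0.5
  list(depth = depth, dist_pial = d_pial, dist_wm = d_wm)
}

#' Bin cortical depth into equidistant laminae
#'
#' Lamina `k` covers depths in `[(k-1)/K, k/K)`; depth 1 is clamped into
#' lamina `K`. Ties at bin edges therefore go to the deeper lamina.
#'
#' @param depth depth array (or the list returned by [compute_depth()]).
#' @param K number of laminae (default 8).
#' @return integer array of lamina labels 1..K on GM voxels, `NA` elsewhere.
#' @export
assign_laminae <- function(depth, K = 8L) {
  if (is.list(depth)) depth <- depth$depth
  if (K < 3) stop("K must be at least 3")
  vals <- depth[!is.na(depth)]
  if (length(vals) && (any(vals < 0) || any(vals > 1))) {
    stop("depth values outside [0, 1]")
  }
  lam <- array(NA_integer_, dim(depth))
  idx <- !is.na(depth)
  lam[idx] <- pmin(as.integer(floor(depth[idx] * K)) + 1L, as.integer(K))
  lam
}

#' Retain the six interior layers of an eight-lamina partition
#'
#' Drops the outermost (pial-most, label 1) and innermost (label `K`) laminae
#' and relabels the remainder `1..K-2`; with the default `K = 8` this yields
#' the six cortical layers I--VI, layer I being the pial-most retained one.
#'
#' @param laminae integer lamina array from [assign_laminae()].
#' @param K the number of laminae the input was built with.
#' @return integer array with labels `1..K-2`, `NA` on dropped/non-GM voxels.
#' @export
retain_layers <- function(laminae, K = 8L) {
  if (K < 3) stop("K must be at least 3")
  out <- array(NA_integer_, dim(laminae))
  keep <- !is.na(laminae) & laminae >= 2L & laminae <= (K - 1L)
  out[keep] <- laminae[keep] - 1L
  out
}

roman_layers <- function(layer) as.character(utils::as.roman(layer))

#' Parcel thickness quality control
#'
#' Estimates each parcel's cortical thickness as the mean of
#' `D_pial + D_wm` over its gray-matter voxels and retains parcels whose
#' estimate is within `tol_mm` of a reference thickness.
#'
#' @param gm_mask logical gray-matter array.
#' @param depth list from [compute_depth()] (uses its distance transforms).
#' @param roi_atlas integer array of parcel labels (0 or `NA` = unlabelled).
#' @param reference_thickness data frame with columns `roi` and
#'   `thickness_mm`, covering every parcel label present.
#' @param tol_mm retention tolerance in mm (default 0.5).
#' @return tibble with one row per parcel: estimated and reference thickness,
#'   absolute difference, voxel count and a `retained` flag.
#' @export
parcel_thickness_qc <- function(gm_mask, depth, roi_atlas, reference_thickness,
                                tol_mm = 0.5) {
  gm_mask <- as_mask(gm_mask)
  check_same_grid(gm_mask, depth$dist_pial, roi_atlas)
  thick <- depth$dist_pial + depth$dist_wm
  rois <- sort(unique(roi_atlas[!is.na(roi_atlas) & roi_atlas > 0]))
  ref <- as_tibble(reference_thickness)
  if (!all(rois %in% ref$roi)) {
    stop("reference_thickness does not cover ROI label(s): ",
         paste(setdiff(rois, ref$roi), collapse = ", "))
  }
  rows <- purrr::map(rois, function(r) {
    sel <- !is.na(roi_atlas) & roi_atlas == r & gm_mask
    n <- sum(sel)
    if (n == 0) {
      warning("ROI ", r, " has no GM voxels; excluded")
      return(tibble(roi = r, thickness_mm = NA_real_, n_voxels = 0L))
    }
    tibble(roi = r, thickness_mm = mean(thick[sel]), n_voxels = as.integer(n))
  })
  dplyr::bind_rows(rows) |>
    dplyr::left_join(ref, by = "roi", suffix = c("", "_ref")) |>
    dplyr::mutate(
      diff_mm = abs(.data$thickness_mm - .data$thickness_mm_ref),
      retained = !is.na(.data$diff_mm) & .data$diff_mm < tol_mm
    )
}

# rasterize a polyline (data frame with x = column, y = row, 1-based pixel
# coordinates) onto a grid, sampling each segment at sub-pixel steps
rasterize_polyline <- function(poly, dim2d) {
  stopifnot(all(c("x", "y") %in% names(poly)))
  mask <- array(FALSE, dim2d)
  n <- nrow(poly)
  if (n == 1) {
    r <- round(poly$y[1]); c <- round(poly$x[1])
    if (r >= 1 && r <= dim2d[1] && c >= 1 && c <= dim2d[2]) mask[r, c] <- TRUE
    return(mask)
  }
  for (i in seq_len(n - 1)) {
    len <- max(abs(poly$x[i + 1] - poly$x[i]), abs(poly$y[i + 1] - poly$y[i]))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
    r <- round(poly$y[i] + t * (poly$y[i + 1] - poly$y[i]))
    c <- round(poly$x[i] + t * (poly$x[i + 1] - poly$x[i]))
    ok <- r >= 1 & r <= dim2d[1] & c >= 1 & c <= dim2d[2]
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polylines_intersect <- function(a, b) {
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      if (segments_intersect(c(a$x[i], a$y[i]), c(a$x[i + 1], a$y[i + 1]),
                             c(b$x[j], b$y[j]), c(b$x[j + 1], b$y[j + 1]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Laminar segmentation of a 2D histology region
#'
#' Rasterizes the CSF-GM (pial) and WM-GM boundary polylines onto the image
#' grid and applies the same equidistant depth machinery as the volumetric
#' pipeline: depth, `K` laminae, exclusion of the innermost and outermost.
#'
#' @param region_mask logical matrix marking the gray-matter band.
#' @param pial_polyline,wm_polyline data frames with vertex columns `x`
#'   (column) and `y` (row) in pixel coordinates; must not intersect.
#' @param K number of laminae (default 8).
#' @param spacing pixel size (default isotropic 1).
#' @return list with `depth`, `laminae` (1..K) and `layers` (retained,
#'   relabelled 1..K-2) matrices.
#' @export
layering_2d <- function(region_mask, pial_polyline, wm_polyline, K = 8L,
                        spacing = c(1, 1)) {
  region_mask <- as_mask(region_mask)
  if (!any(region_mask)) stop("empty region mask")
  if (polylines_intersect(pial_polyline, wm_polyline)) {
    stop("pial and WM polylines intersect")
  }
  dm <- dim(region_mask)
  pial <- rasterize_polyline(pial_polyline, dm)
  wm <- rasterize_polyline(wm_polyline, dm)
  if (!any(pial) || !any(wm)) stop("a boundary polyline rasterized to nothing")
  d_pial <- distance_transform(pial, spacing)
  d_wm <- distance_transform(wm, spacing)
  depth <- array(NA_real_, dm)
  depth[region_mask] <- d_pial[region_mask] / (d_pial + d_wm)[region_mask]
  depth[region_mask & pial & wm] <- 0.5
  lam <- assign_laminae(depth, K)
  list(depth = depth, laminae = lam, layers = retain_layers(lam, K))
}
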