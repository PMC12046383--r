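#' Euclidean distance transform to a voxel set
#'
#' Computes, for every grid element, the Euclidean distance in millimetres to
#' the nearest `TRUE` voxel of `feature_mask`, honouring anisotropic voxel
#' spacing. Uses the separable lower-envelope squared-distance transform.
#'
#' @param feature_mask logical array (2D or 3D); `TRUE` marks the target set.
#' @param spacing numeric vector of per-axis voxel sizes in mm (length =
#'   number of array dimensions).
#' @return numeric array of distances (mm), `Inf` if the set is empty.
#' @export
distance_transform <- function(feature_mask, spacing = rep(1, length(dim(feature_mask)))) {
  dm <- dim(feature_mask)
  if (is.null(dm)) stop("feature_mask must be a 2D or 3D array")
  if (length(spacing) != length(dm)) stop("spacing length must match array dimensions")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  sq <- .edt_sq(as.logical(feature_mask), as.integer(dm), as.numeric(spacing))
  d <- sqrt(sq)
  dim(d) <- dm
  d
}

# indices of face neighbours: shift a logical array by one voxel along axis/dir,
# padding with FALSE; used for 6-connected (3D) / 4-connected (2D) adjacency
shift_mask <- function(mask, axis, dir) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  idx_src <- lapply(dm, seq_len)
  idx_dst <- idx_src
  n <- dm[axis]
  if (n < 2) return(out)
  if (dir > 0) {
    idx_src[[axis]] <- 1:(n - 1)
    idx_dst[[axis]] <- 2:n
  } else {
    idx_src[[axis]] <- 2:n
    idx_dst[[axis]] <- 1:(n - 1)
  }
  out_sub <- do.call(`[`, c(list(mask), idx_src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), idx_dst, list(out_sub)))
  out
}

# TRUE where any face neighbour (6-connectivity in 3D, 4 in 2D) is TRUE in `of`
adjacent_to <- function(of) {
  dm <- dim(of)
  acc <- array(FALSE, dm)
  for (ax in seq_along(dm)) {
    acc <- acc | shift_mask(of, ax, +1L) | shift_mask(of, ax, -1L)
  }
  acc
}

check_same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) length(d) == length(ref) && all(d == ref), logical(1))
  if (!all(ok)) stop("input grids have mismatched dimensions")
  invisible(ref)
}
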