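#' Read a NIfTI volume
#'
#' @param path `.nii` / `.nii.gz` file.
#' @return array (3D or 4D) with attribute `spacing` (per-axis mm).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  sp <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("non-positive voxel spacing in ", path)
  attr(arr, "spacing") <- sp
  arr
}

#' Write a NIfTI volume
#'
#' Integer label volumes round-trip losslessly; float maps round-trip within
#' storage precision.
#'
#' @param x 3D or 4D array.
#' @param path output `.nii` / `.nii.gz` file.
#' @param spacing per-axis voxel size in mm (first three dims).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = attr(x, "spacing") %||% c(1, 1, 1)) {
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be positive")
  }
  datatype <- if (is.integer(x) || all(x == round(x), na.rm = TRUE)) "int32" else "double"
  x[is.na(x)] <- 0
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read FSL-style bval/bvec files
#'
#' Whitespace-delimited text: one row of b-values and a 3 x N direction
#' matrix (an N x 3 layout is auto-detected and accepted with a warning).
#' Directions of diffusion-weighted volumes must be unit-norm within 1e-6;
#' b-values below 50 s/mm^2 are treated as b0.
#'
#' @param bval_path,bvec_path file paths.
#' @param n_volumes if given, validated against the parsed length.
#' @return list with `bvals`, `bvecs` (N x 3, zero rows on b0 volumes),
#'   `is_b0`.
#' @export
read_bval_bvec <- function(bval_path, bvec_path, n_volumes = NULL) {
  parse_numeric <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    vals <- lapply(seq_along(lines), function(i) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(toks))
      if (any(is.na(v))) {
        stop("non-numeric token in ", path, " at line ", i, ", column ",
             which(is.na(v))[1])
      }
      v
    })
    vals
  }
  bv <- parse_numeric(bval_path)
  if (length(bv) != 1) stop("bval file must have a single row")
  bvals <- bv[[1]]
  n <- length(bvals)
  rows <- parse_numeric(bvec_path)
  lens <- lengths(rows)
  if (length(rows) == 3 && all(lens == n)) {
    bvecs <- t(do.call(rbind, rows))
  } else if (all(lens == 3) && length(rows) == n) {
    warning("bvec file appears transposed (N x 3); accepting")
    bvecs <- do.call(rbind, rows)
  } else {
    stop("bvec layout does not match ", n, " volumes")
  }
  if (!is.null(n_volumes) && n != n_volumes) {
    stop("bval/bvec length ", n, " does not match volume count ", n_volumes)
  }
  is_b0 <- bvals < 50
  nrm <- sqrt(rowSums(bvecs^2))
  off <- abs(nrm[!is_b0] - 1) > 1e-6
  if (any(off)) {
    stop("non-unit bvec row(s) for diffusion-weighted volume(s): ",
         paste(which(!is_b0)[off], collapse = ", "))
  }
  list(bvals = bvals, bvecs = bvecs, is_b0 = is_b0)
}

#' Write FSL-style bval/bvec files
#' @param bvals,bvecs protocol arrays (`bvecs` N x 3).
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bval_bvec <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Write an RGB image to PNG
#' @param rgb height x width x 3 array in `[0, i0]`.
#' @param path output path.
#' @param i0 white reference used for scaling (default 255).
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(rgb, path, i0 = 255) {
  png::writePNG(pmin(pmax(rgb / i0, 0), 1), path)
  invisible(path)
}

#' Read an RGB PNG as intensities in `[0, i0]`
#' @param path PNG file.
#' @param i0 white reference (default 255).
#' @return height x width x 3 array.
#' @export
read_slide_png <- function(path, i0 = 255) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * i0
}
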