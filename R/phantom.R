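#' Specification of a cortical-ribbon phantom
#'
#' Describes a synthetic cortical ribbon: either a spherical shell (gray
#' matter between an inner white-matter ball and outer background/CSF — the
#' default, since a closed surface has no edge artifacts) or an axis-aligned
#' slab. Per-layer MD and FA targets define radially oriented, axially
#' symmetric tensors whose principal axis is the local surface normal, so
#' that FA rises and diffusivity falls from the pial to the WM surface.
#'
#' Defaults emulate formalin-fixed ex vivo cortex: ~3 mm ribbon thickness,
#' 0.5 mm isotropic voxels, MD of order 1e-4 mm^2/s decreasing with depth and
#' FA increasing with depth across the six retained layers.
#'
#' @param geometry `"shell"` or `"slab"`.
#' @param inner_radius_mm,outer_radius_mm shell radii (GM between them).
#' @param thickness_mm slab ribbon thickness.
#' @param extent_mm slab lateral extent.
#' @param voxel_size_mm voxel size, length 1 or 3 (mm).
#' @param n_laminae number of equidistant laminae (default 8).
#' @param layer_md_profile,layer_fa_profile per-retained-layer (pial to WM,
#'   length `n_laminae - 2`) MD (mm^2/s) and FA targets. The excluded
#'   outermost/innermost laminae reuse the nearest retained layer's targets.
#' @param wm_md,wm_fa white-matter tensor targets.
#' @param roi_count number of equal angular/axial ROI sectors.
#' @param seed integer seed (the phantom itself is deterministic; the seed is
#'   recorded for downstream stages).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("shell", "slab"),
                         inner_radius_mm = 8, outer_radius_mm = 11,
                         thickness_mm = 3, extent_mm = 16,
                         voxel_size_mm = 0.5,
                         n_laminae = 8L,
                         layer_md_profile = seq(2.4e-4, 1.4e-4,
                                                length.out = n_laminae - 2L),
                         layer_fa_profile = seq(0.10, 0.35,
                                                length.out = n_laminae - 2L),
                         wm_md = 1.5e-4, wm_fa = 0.45,
                         roi_count = 4L, seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (geometry == "shell" && outer_radius_mm <= inner_radius_mm) {
    stop("outer_radius_mm must exceed inner_radius_mm")
  }
  if (n_laminae < 3) stop("n_laminae must be at least 3")
  n_ret <- n_laminae - 2L
  if (length(layer_md_profile) != n_ret || length(layer_fa_profile) != n_ret) {
    stop("layer profiles must have length n_laminae - 2 (retained layers)")
  }
  if (any(layer_md_profile <= 0)) stop("all MD targets must be positive")
  if (any(layer_fa_profile < 0 | layer_fa_profile >= 1)) {
    stop("FA targets must lie in [0, 1)")
  }
  if (roi_count < 1) stop("roi_count must be at least 1")
  thick <- if (geometry == "shell") outer_radius_mm - inner_radius_mm else thickness_mm
  if (thick < 2 * min(voxel_size_mm)) {
    stop("ribbon thinner than 2 voxels: laminae unresolvable")
  }
  structure(
    list(geometry = geometry,
         inner_radius_mm = inner_radius_mm, outer_radius_mm = outer_radius_mm,
         thickness_mm = thickness_mm, extent_mm = extent_mm,
         voxel_size_mm = voxel_size_mm, n_laminae = as.integer(n_laminae),
         layer_md_profile = layer_md_profile,
         layer_fa_profile = layer_fa_profile,
         wm_md = wm_md, wm_fa = wm_fa,
         roi_count = as.integer(roi_count), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Axially symmetric eigenvalues from (MD, FA) targets
#'
#' For a prolate tensor with eigenvalues (a, b, b), `MD = (a + 2b)/3` and
#' `FA = (a - b) / sqrt(a^2 + 2 b^2)`. Writing `a = MD (1 + 2 delta)`,
#' `b = MD (1 - delta)` gives `FA = 3 delta / sqrt(3 + 6 delta^2)`, hence the
#' closed form `delta = FA / sqrt(3 - 2 FA^2)`.
#'
#' @param md mean diffusivity (mm^2/s), positive.
#' @param fa fractional anisotropy in `[0, 1)`.
#' @return list with `axial` (a) and `radial` (b) eigenvalues.
#' @export
md_fa_to_eigenvalues <- function(md, fa) {
  stopifnot(all(md > 0), all(fa >= 0), all(fa < 1))
  delta <- fa / sqrt(3 - 2 * fa^2)
  list(axial = md * (1 + 2 * delta), radial = md * (1 - delta))
}

# pack an axially symmetric tensor b*I + (a-b) n n' into 6 components
# (xx, yy, zz, xy, xz, yz) given unit normals n (n x 3)
axially_symmetric_tensor <- function(a, b, n) {
  d <- a - b
  cbind(
    b + d * n[, 1]^2, b + d * n[, 2]^2, b + d * n[, 3]^2,
    d * n[, 1] * n[, 2], d * n[, 1] * n[, 3], d * n[, 2] * n[, 3]
  )
}

#' Build a cortical-ribbon phantom with known ground truth
#'
#' Realizes a [phantom_spec()] as label volumes and a voxel-wise tensor field:
#' gray matter is the ribbon between the pial and WM surfaces, white matter
#' fills the interior, background/CSF lies outside. Every GM tensor's
#' principal eigenvector is the local surface normal (radial direction), and
#' its eigenvalues realize the layer MD/FA targets at that voxel's true
#' lamina. ROIs partition the ribbon into equal angular (shell) or axial
#' (slab) sectors. Ground-truth depth, lamina/layer labels, and the
#' per-(ROI, layer) metric table are returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @return list with `gm_mask`, `wm_mask`, `roi_atlas`, `tensor_field`
#'   (a `tensor_field` usable by [tensor_metrics()]), `spacing`, and `truth`
#'   (list: `depth`, `lamina`, `layer` arrays and `layer_metrics` tibble).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size_mm
  K <- spec$n_laminae

  if (spec$geometry == "shell") {
    R <- spec$outer_radius_mm
    half <- R + 2 * max(vs)
    dims <- as.integer(ceiling(2 * half / vs))
    ax <- lapply(1:3, function(i) (seq_len(dims[i]) - (dims[i] + 1) / 2) * vs[i])
    X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    r <- sqrt(X^2 + Y^2 + Z^2)
    wm <- r <= spec$inner_radius_mm
    gm <- r > spec$inner_radius_mm & r <= R
    depth_true <- array(NA_real_, dims)
    # pial (depth 0) is the outer surface; WM (depth 1) the inner one.
    # Ground truth follows the equidistant distance-fraction convention on the
    # voxel grid: boundary voxel centers sit ~half a voxel inside the
    # geometric surfaces, so the reference radii are inset accordingly.
    inset <- 0.5 * mean(vs)
    r_pial <- R - inset
    r_wm <- spec$inner_radius_mm + inset
    depth_true[gm] <- pmin(pmax((r_pial - r[gm]) / (r_pial - r_wm), 0), 1)
    # radial unit normals on GM
    idx <- which(gm)
    nrm <- cbind(X[idx], Y[idx], Z[idx]) / r[idx]
    # angular sectors by azimuth
    phi <- atan2(Y[idx], X[idx])  # (-pi, pi]
    sector <- pmin(as.integer(floor((phi + pi) / (2 * pi) * spec$roi_count)) + 1L,
                   spec$roi_count)
  } else {
    nz <- as.integer(ceiling(spec$thickness_mm / vs[3]))
    nxy <- as.integer(ceiling(spec$extent_mm / vs[1:2]))
    # one WM slab below and background above along z
    dims <- c(nxy, nz + 2L * as.integer(ceiling(2 / vs[3])))
    pad <- as.integer(ceiling(2 / vs[3]))
    gm <- array(FALSE, dims)
    wm <- array(FALSE, dims)
    zidx <- (pad + 1L):(pad + nz)
    gm[, , zidx] <- TRUE
    wm[, , seq_len(pad)] <- TRUE
    depth_true <- array(NA_real_, dims)
    # WM slab sits at low z, so depth is 1 on the WM-adjacent GM slice and 0
    # on the pial-most slice, linear in between (voxel-center convention)
    for (j in seq_along(zidx)) {
      depth_true[, , zidx[j]] <- 1 - (j - 1) / (nz - 1)
    }
    idx <- which(gm)
    nrm <- matrix(rep(c(0, 0, 1), each = length(idx)), ncol = 3)
    # sectors along x
    xi <- ((idx - 1L) %% dims[1]) + 1L
    sector <- pmin(as.integer(floor((xi - 1L) / dims[1] * spec$roi_count)) + 1L,
                   spec$roi_count)
  }

  lam_true <- assign_laminae(depth_true, K)
  layer_true <- retain_layers(lam_true, K)
  # map lamina -> retained layer index, clamping excluded laminae to nearest
  lam_to_layer <- pmin(pmax(seq_len(K) - 1L, 1L), K - 2L)
  layer_of_vox <- lam_to_layer[lam_true[idx]]

  ev <- md_fa_to_eigenvalues(spec$layer_md_profile[layer_of_vox],
                             spec$layer_fa_profile[layer_of_vox])
  D6_gm <- axially_symmetric_tensor(ev$axial, ev$radial, nrm)

  dims3 <- dim(gm)
  D <- array(0, c(dims3, 6))
  Dm <- matrix(D, nrow = prod(dims3), ncol = 6)
  Dm[idx, ] <- D6_gm
  wm_idx <- which(wm)
  ev_wm <- md_fa_to_eigenvalues(spec$wm_md, spec$wm_fa)
  # WM fibers: fixed orientation along x (direction is irrelevant downstream)
  nrm_wm <- matrix(rep(c(1, 0, 0), each = length(wm_idx)), ncol = 3)
  Dm[wm_idx, ] <- axially_symmetric_tensor(ev_wm$axial, ev_wm$radial, nrm_wm)
  D <- array(Dm, c(dims3, 6))

  roi_atlas <- array(0L, dims3)
  roi_atlas[idx] <- sector

  tensor_field <- structure(
    list(D = D, log_s0 = array(0, dims3), mask = gm | wm,
         flagged = array(FALSE, dims3), spacing = vs),
    class = "tensor_field"
  )

  ev_all <- md_fa_to_eigenvalues(spec$layer_md_profile, spec$layer_fa_profile)
  layer_metrics <- tibble(
    layer = rep(seq_len(K - 2L), times = spec$roi_count),
    roi = rep(seq_len(spec$roi_count), each = K - 2L)
  ) |>
    dplyr::mutate(
      MD = spec$layer_md_profile[.data$layer],
      FA = spec$layer_fa_profile[.data$layer],
      AD = ev_all$axial[.data$layer],
      RD = ev_all$radial[.data$layer]
    ) |>
    tidyr::pivot_longer(c("MD", "FA", "AD", "RD"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("roi", "layer", "metric", "value")

  list(
    gm_mask = gm, wm_mask = wm, roi_atlas = roi_atlas,
    tensor_field = tensor_field, spacing = vs,
    truth = list(depth = depth_true, lamina = lam_true, layer = layer_true,
                 layer_metrics = layer_metrics),
    spec = spec
  )
}
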