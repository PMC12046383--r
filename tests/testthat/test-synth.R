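test_that("shell phantom geometry and tensors honour the spec", {
  spec <- phantom_spec(inner_radius_mm = 20, outer_radius_mm = 23,
                       voxel_size_mm = 0.5)
  ph <- make_phantom(spec)
  # GM voxel count within 5% of the analytic shell volume / voxel volume
  vol_analytic <- 4 / 3 * pi * (23^3 - 20^3)
  n_expected <- vol_analytic / prod(spec$voxel_size_mm)
  expect_lt(abs(sum(ph$gm_mask) - n_expected) / n_expected, 0.05)
  # WM fills the interior, background outside, all disjoint
  expect_false(any(ph$gm_mask & ph$wm_mask))
  # ROIs partition the GM ribbon
  expect_identical(ph$roi_atlas > 0, ph$gm_mask)
  expect_identical(sort(unique(ph$roi_atlas[ph$gm_mask])), 1:4)
})

test_that("GM tensors are radial and realize the layer MD/FA targets", {
  spec <- phantom_spec(inner_radius_mm = 6, outer_radius_mm = 9,
                       voxel_size_mm = 0.6)
  ph <- make_phantom(spec)
  dims <- dim(ph$gm_mask)
  idx <- which(ph$gm_mask)
  set.seed(5)
  idx <- sample(idx, 300)
  ai <- arrayInd(idx, dims)
  ctr <- (dims + 1) / 2
  rad <- sweep(ai, 2, ctr) %*% diag(ph$spacing)
  rad <- rad / sqrt(rowSums(rad^2))
  D6 <- matrix(ph$tensor_field$D, ncol = 6)[idx, ]
  for (i in seq_len(300)) {
    M <- matrix(c(D6[i, 1], D6[i, 4], D6[i, 5],
                  D6[i, 4], D6[i, 2], D6[i, 6],
                  D6[i, 5], D6[i, 6], D6[i, 3]), 3, 3)
    e <- eigen(M, symmetric = TRUE)
    expect_gte(abs(sum(e$vectors[, 1] * rad[i, ])), 0.999)
    lay <- ph$truth$layer[idx[i]]
    lam <- ph$truth$lamina[idx[i]]
    lay <- if (is.na(lay)) min(max(lam - 1L, 1L), 6L) else lay
    expect_equal(mean(e$values), spec$layer_md_profile[lay], tolerance = 1e-12)
  }
})

test_that("phantom construction is deterministic and validates its spec", {
  a <- make_phantom(phantom_spec(seed = 3))
  b <- make_phantom(phantom_spec(seed = 3))
  expect_identical(a$gm_mask, b$gm_mask)
  expect_identical(a$tensor_field$D, b$tensor_field$D)
  expect_identical(a$roi_atlas, b$roi_atlas)

  expect_error(phantom_spec(inner_radius_mm = 9, outer_radius_mm = 8), "exceed")
  expect_error(phantom_spec(inner_radius_mm = 8, outer_radius_mm = 8.4,
                            voxel_size_mm = 0.5), "thinner")
  expect_error(phantom_spec(layer_fa_profile = rep(1, 6)), "FA")
  expect_error(phantom_spec(layer_md_profile = c(-1, rep(1e-4, 5))), "positive")
})

test_that("the MD/FA eigenvalue parameterization is exact", {
  md <- c(1e-4, 2e-4, 7e-4)
  fa <- c(0, 0.3, 0.9)
  ev <- md_fa_to_eigenvalues(md, fa)
  md_back <- (ev$axial + 2 * ev$radial) / 3
  fa_back <- abs(ev$axial - ev$radial) /
    sqrt(ev$axial^2 + 2 * ev$radial^2)
  expect_equal(md_back, md, tolerance = 1e-12)
  expect_equal(fa_back, fa, tolerance = 1e-12)
})

test_that("noiseless DWI synthesis follows the monoexponential tensor model", {
  proto <- dwi_protocol(snr = Inf)
  # default protocol: 20 b0 + 60 unit directions at b = 6000
  expect_length(proto$bvals, 80)
  expect_identical(sum(proto$bvals == 0), 20L)
  expect_true(all(proto$bvals[21:80] == 6000))
  expect_equal(sqrt(rowSums(proto$bvecs[21:80, ]^2)), rep(1, 60),
               tolerance = 1e-8)

  d <- 7e-4
  tensors <- replicate(5, diag(rep(d, 3)), simplify = FALSE)
  tf <- tensor_field_from_list(tensors)
  dwi <- synthesize_dwi(tf, s0 = 100, protocol = proto)
  sig <- matrix(dwi$signal, ncol = 80)
  # b0 volumes equal S0 exactly
  expect_true(all(sig[, 1:20] == 100))
  # isotropic tensor: every DWI volume equals S0 exp(-b d)
  expect_equal(as.numeric(sig[, 21:80]), rep(100 * exp(-6000 * d), 5 * 60),
               tolerance = 1e-10)

  tf$D[1, 1, 1, 1] <- NaN
  expect_error(synthesize_dwi(tf, 100, proto), "non-finite")
})

test_that("Rician noise biases b0 magnitude upward, Gaussian does not", {
  tensors <- replicate(400, diag(rep(5e-4, 3)), simplify = FALSE)
  tf <- tensor_field_from_list(tensors)
  ric <- synthesize_dwi(tf, 100, dwi_protocol(snr = 10, noise_model = "rician"),
                        seed = 4)
  gau <- synthesize_dwi(tf, 100, dwi_protocol(snr = 10, noise_model = "gaussian"),
                        seed = 4)
  b0_ric <- matrix(ric$signal, ncol = 80)[, 1:20]
  b0_gau <- matrix(gau$signal, ncol = 80)[, 1:20]
  se <- 10 / sqrt(length(b0_gau))
  expect_gt(mean(b0_ric), 100 + 3 * se)          # positive Rician bias
  expect_lt(abs(mean(b0_gau) - 100), 4 * se)     # Gaussian unbiased
  # seeded determinism
  ric2 <- synthesize_dwi(tf, 100, dwi_protocol(snr = 10), seed = 4)
  expect_identical(ric$signal, ric2$signal)
})

test_that("phantom truth laminae agree with the laminar module on a resolved ribbon", {
  # ribbon spanning 15 voxels so each of the 8 laminae is ~2 voxels thick
  ph <- make_phantom(phantom_spec(inner_radius_mm = 6, outer_radius_mm = 12,
                                  voxel_size_mm = 0.4))
  b <- extract_boundaries(ph$gm_mask, ph$wm_mask)
  dep <- compute_depth(ph$gm_mask, b$pial, b$wm, ph$spacing)
  lam <- assign_laminae(dep, 8)
  dis <- abs(lam[ph$gm_mask] - ph$truth$lamina[ph$gm_mask])
  expect_gte(mean(dis == 0), 0.95)
  expect_lte(max(dis), 1)  # disagreement only at bin edges
})

test_that("cohort generation reproduces the study design", {
  spec <- cohort_spec(seed = 2)
  co <- make_cohort(spec, phantom_spec(voxel_size_mm = 1), dwi_protocol())
  expect_identical(nrow(co$cohort), 15L)
  expect_identical(as.integer(table(co$cohort$group)[c("HC", "PART", "AbPos")]),
                   c(4L, 3L, 8L))
  # stage pattern: amyloid 0 for HC/PART, >= 1 for AbPos
  expect_true(all(co$cohort$amyloid_stage[co$cohort$group != "AbPos"] == 0))
  expect_true(all(co$cohort$amyloid_stage[co$cohort$group == "AbPos"] >= 1))
  # ground-truth effect table: 1.10 exactly in layers II/III of AbPos, 1 elsewhere
  eff <- co$effects
  hit <- eff$group == "AbPos" & eff$layer %in% 2:3 & eff$metric == "MD"
  expect_true(all(eff$multiplier[hit] == 1.10))
  expect_true(all(eff$multiplier[!hit] == 1))
  # profiles: one row per (subject, roi, layer, metric)
  expect_identical(nrow(co$profiles), 15L * 4L * 6L * 4L)
  # determinism
  co2 <- make_cohort(spec, phantom_spec(voxel_size_mm = 1), dwi_protocol())
  expect_identical(co$profiles, co2$profiles)
  expect_identical(co$cohort, co2$cohort)

  expect_error(cohort_spec(n_hc = 0, n_part = 0, n_abpos = 0), "empty")
})

test_that("full-mode cohort scales the MD profile of affected subjects", {
  spec <- cohort_spec(n_hc = 1, n_part = 0, n_abpos = 1, seed = 9)
  ps <- phantom_spec(inner_radius_mm = 5, outer_radius_mm = 8, voxel_size_mm = 1)
  co <- make_cohort(spec, ps, dwi_protocol(snr = Inf), mode = "full")
  expect_length(co$datasets, 2)
  hc_id <- co$cohort$subject[co$cohort$group == "HC"]
  ab_id <- co$cohort$subject[co$cohort$group == "AbPos"]
  ph <- make_phantom(ps)
  lay <- ph$truth$layer
  for (ids in list(hc_id, ab_id)) {
    dwi <- co$datasets[[ids]]
    mm <- tensor_metrics(fit_tensor(dwi, ph$gm_mask))
    md2 <- mean(mm$MD[!is.na(lay) & lay == 2L])
    md4 <- mean(mm$MD[!is.na(lay) & lay == 4L])
    ratio2 <- md2 / ps$layer_md_profile[2]
    ratio4 <- md4 / ps$layer_md_profile[4]
    if (ids == ab_id) {
      expect_equal(ratio2, 1.10, tolerance = 0.02)  # injected layers scaled
    } else {
      expect_equal(ratio2, 1.00, tolerance = 0.02)
    }
    expect_equal(ratio4, 1.00, tolerance = 0.02)    # unaffected layer
  }
})

test_that("rendered slides hit their per-layer targets with known truth", {
  ss <- slide_spec(seed = 21)
  sl <- render_slide(ss)
  expect_true(all(abs(sl$truth$fraction - sl$truth$target) <= 0.01))
  # truth fractions counted directly on the ground-truth mask
  m <- sl$truth_masks$abeta
  for (i in seq_len(nrow(sl$truth))) {
    rows_l <- which(apply(!is.na(sl$layers) & sl$layers == sl$truth$layer[i], 1, any))
    frac <- sum(m[rows_l, ]) / (length(rows_l) * ncol(m))
    expect_equal(frac, sl$truth$fraction[i], tolerance = 1e-12)
  }
  # zero targets give a pure-background image
  sl0 <- render_slide(slide_spec(targets = list(abeta = rep(0, 6))))
  expect_true(all(sl0$rgb == 255))
  # seeded determinism, to the byte
  sl2 <- render_slide(slide_spec(seed = 21))
  expect_identical(sl$rgb, sl2$rgb)
  expect_identical(sl$truth, sl2$truth)
  # unpackable density is rejected
  expect_error(render_slide(slide_spec(targets = list(abeta = rep(0.9, 6)))),
               "packable")
})
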