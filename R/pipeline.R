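#' Default pipeline configuration
#'
#' Stage toggles, module parameters and seeds for [run_pipeline()]. Any subset
#' of these keys may be overridden via a YAML file or a named list; unknown
#' keys are rejected.
#'
#' @return named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "laminaprof_out",
    stages = c("simulate", "layer", "dti", "histo", "stats"),
    k_laminae = 8L,
    phantom = list(geometry = "shell", inner_radius_mm = 8,
                   outer_radius_mm = 11, voxel_size_mm = 0.5, roi_count = 4L),
    protocol = list(b0_count = 20L, n_directions = 60L, b_value = 6000,
                    snr = 30, noise_model = "rician"),
    cohort = list(n_hc = 4L, n_part = 3L, n_abpos = 8L),
    slide = list(width = 300L, height = 400L),
    stats = list(alpha = 0.05, metrics = c("FA", "MD"),
                 covariates = c("age", "sex", "thickness_mm", "pmi_min",
                                "ft_days")),
    qc_tol_mm = 0.5
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values override [default_config()]; unknown top-level keys are an error.
#'
#' @param path YAML file (or a named list already in memory).
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && is.list(cfg[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(base[[k]]))
      if (length(bad)) stop("unknown config key(s): ",
                            paste(paste0(k, "$", bad), collapse = ", "))
      base[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else {
      base[[k]] <- cfg[[k]]
    }
  }
  base
}

#' Run the laminar profiling pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' `simulate` builds the phantom, cohort and slide; `layer` runs boundary
#' extraction, equidistant depth, lamina assignment, layer retention and the
#' parcel-thickness QC on the phantom; `dti` synthesizes one reference
#' subject's DWI, fits tensors, derives normalized metric maps and the layer
#' profile; `histo` deconvolves and thresholds the slide and extracts layer
#' densities; `stats` runs the group t-tests with FDR, the stage mixed model,
#' matched-pair deltas and the layer-wise Spearman correlation on the cohort
#' profiles. All tabular outputs are written as CSV under `out_dir`, together
#' with exactly one provenance log (`provenance.json`). Reruns with the same
#' configuration are bit-identical for label and CSV outputs.
#'
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  res <- list()

  write_csv0 <- function(df, name) {
    # fixed-format CSV so identical runs are byte-identical
    utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
  }

  if ("simulate" %in% stages) {
    pspec <- do.call(phantom_spec, c(cfg$phantom, list(seed = cfg$seed)))
    proto <- do.call(dwi_protocol, cfg$protocol)
    cspec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
    res$cohort <- make_cohort(cspec, pspec, proto, mode = "fast")
    res$phantom <- res$cohort$phantom
    res$protocol <- proto
    sspec <- do.call(slide_spec, c(cfg$slide, list(seed = cfg$seed)))
    res$slide <- render_slide(sspec)
    write_csv0(res$cohort$cohort, "cohort.csv")
    write_csv0(res$cohort$profiles, "profiles.csv")
    write_csv0(res$cohort$effects, "effects_truth.csv")
    write_slide_png(res$slide$rgb, file.path(cfg$out_dir, "slide.png"),
                    i0 = sspec$i0)
    write_csv0(res$slide$boundaries, "slide_boundaries.csv")
  }

  if ("layer" %in% stages) {
    if (is.null(res$phantom)) stop("stage 'layer' requires stage 'simulate'")
    ph <- res$phantom
    bnd <- extract_boundaries(ph$gm_mask, ph$wm_mask)
    dep <- compute_depth(ph$gm_mask, bnd$pial, bnd$wm, ph$spacing)
    lam <- assign_laminae(dep, cfg$k_laminae)
    res$layers <- retain_layers(lam, cfg$k_laminae)
    res$depth <- dep
    ref <- tibble(
      roi = sort(unique(ph$roi_atlas[ph$roi_atlas > 0])),
      thickness_mm = ph$spec$outer_radius_mm - ph$spec$inner_radius_mm
    )
    res$qc <- parcel_thickness_qc(ph$gm_mask, dep, ph$roi_atlas, ref,
                                  cfg$qc_tol_mm)
    write_csv0(res$qc, "thickness_qc.csv")
    write_nifti(res$layers, file.path(cfg$out_dir, "layers.nii.gz"),
                ph$spacing)
  }

  if ("dti" %in% stages) {
    if (is.null(res$layers)) stop("stage 'dti' requires stage 'layer'")
    ph <- res$phantom
    dwi <- synthesize_dwi(ph$tensor_field, s0 = 100, protocol = res$protocol,
                          seed = cfg$seed)
    tf <- fit_tensor(dwi, mask = ph$gm_mask | ph$wm_mask)
    mm <- tensor_metrics(tf)
    cortex <- !is.na(res$layers)
    norm <- lapply(mm[c("FA", "MD", "AD", "RD")], normalize_metric, cortex)
    names(norm) <- paste0("m", names(norm))
    res$reference_profile <- layer_roi_profile(
      c(mm[c("FA", "MD", "AD", "RD")], norm),
      res$layers, ph$roi_atlas, subject_id = "reference"
    )
    write_csv0(res$reference_profile, "reference_profile.csv")
    for (nm in names(norm)) {
      write_nifti(norm[[nm]], file.path(cfg$out_dir, paste0(nm, ".nii.gz")),
                  ph$spacing)
    }
  }

  if ("histo" %in% stages) {
    if (is.null(res$slide)) stop("stage 'histo' requires stage 'simulate'")
    sl <- res$slide
    chans <- color_deconvolve(sl$rgb, sl$spec$stain_matrix, sl$spec$i0)
    lay2d <- layering_2d(
      sl$band_mask,
      dplyr::filter(sl$boundaries, .data$boundary == "pial"),
      dplyr::filter(sl$boundaries, .data$boundary == "wm"),
      K = sl$spec$n_laminae
    )
    dens <- purrr::map(names(sl$spec$targets), function(s) {
      th <- moment_threshold(chans[[s]])
      layer_density(th$mask, lay2d$layers, stain = s, slide_id = "slide1")
    })
    res$density <- dplyr::bind_rows(dens)
    write_csv0(res$density, "density.csv")
  }

  if ("stats" %in% stages) {
    if (is.null(res$cohort)) stop("stage 'stats' requires stage 'simulate'")
    prof <- res$cohort$profiles
    cov <- res$cohort$cohort
    res$ttests <- group_ttest(prof, cov,
                              metrics = cfg$stats$metrics,
                              covariates = cfg$stats$covariates)
    write_csv0(res$ttests, "stat_results.csv")
    lmm <- fit_stage_lmm(prof, cov, metric = "MD", scope = "layer")
    res$lmm <- lmm
    write_csv0(tidy(lmm), "lmm_coefficients.csv")
    # pair each amyloid-positive case with an HC by rank order
    hc <- cov$subject[cov$group == "HC"]
    cases <- cov$subject[cov$group == "AbPos"]
    if (length(hc) && length(cases)) {
      pairs <- tibble(case = cases,
                      control = rep(hc, length.out = length(cases)))
      res$deltas <- delta_profile(prof, pairs)
      write_csv0(res$deltas, "delta_profiles.csv")
      if (!is.null(res$density)) {
        d1 <- res$deltas |>
          dplyr::filter(.data$case == cases[1], .data$roi == 1,
                        .data$metric == "MD") |>
          dplyr::arrange(.data$layer)
        s1 <- dplyr::arrange(res$density, .data$layer)
        if (nrow(d1) == nrow(s1)) {
          res$spearman <- spearman_layers(d1$delta, s1$fraction)
          write_csv0(res$spearman, "spearman.csv")
        }
      }
    }
  }

  log <- list(
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("laminaprof")),
    config = cfg
  )
  jsonlite::write_json(log, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
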