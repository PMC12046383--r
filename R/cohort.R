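#' Specification of a synthetic autopsy cohort
#'
#' Emulates a small ex vivo hemisphere cohort of healthy controls (HC),
#' primary age-related tauopathy (PART) and amyloid-positive (AbPos) cases.
#' Default group sizes are 4 / 3 / 8 (fifteen subjects). Covariates mirror a
#' typical brain-bank sample: age by group, predominantly male sex,
#' postmortem interval in minutes, fixation time in days, mean cortical
#' thickness in mm (thinner in the amyloid-positive group), Braak stage drawn
#' per group, and Amyloid stage 0 for HC/PART and >= 1 for AbPos.
#'
#' `effect_spec` injects multiplicative metric shifts into designated cells of
#' the amyloid-positive subjects' layer profiles; the default raises MD by 10%
#' in layers II and III across all ROIs, the direction and laminar locus the
#' pipeline is designed to detect.
#'
#' @param n_hc,n_part,n_abpos group sizes.
#' @param age_mean named vector of group mean ages (years); `age_sd` common SD.
#' @param p_female probability of female sex.
#' @param pmi_range postmortem interval range (minutes), sampled uniformly.
#' @param ft_range fixation time range (days), sampled uniformly.
#' @param thickness_mean named vector of group mean cortical thickness (mm);
#'   `thickness_sd` common SD.
#' @param braak_range named list of group-wise inclusive Braak stage ranges.
#' @param amyloid_range inclusive Amyloid stage range for AbPos subjects.
#' @param effect_spec tibble with columns `group`, `layer`, `roi` (`NA` = all
#'   ROIs), `metric`, `multiplier` (> 0).
#' @param subject_sd,cell_sd multiplicative log-normal variation: a shared
#'   per-subject scale factor and independent per-cell noise (SDs on the log
#'   scale), used by the fast profile-level generator.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 4L, n_part = 3L, n_abpos = 8L,
                        age_mean = c(HC = 56, PART = 75, AbPos = 70),
                        age_sd = 8,
                        p_female = 1 / 15,
                        pmi_range = c(150, 1100),
                        ft_range = c(30, 80),
                        thickness_mean = c(HC = 3.0, PART = 3.0, AbPos = 2.7),
                        thickness_sd = 0.12,
                        braak_range = list(HC = c(0L, 0L), PART = c(1L, 4L),
                                           AbPos = c(0L, 3L)),
                        amyloid_range = c(1L, 2L),
                        effect_spec = default_effect_spec(),
                        subject_sd = 0.02, cell_sd = 0.02,
                        seed = 1L) {
  stopifnot(n_hc >= 0, n_part >= 0, n_abpos >= 0)
  if (n_hc + n_part + n_abpos == 0) stop("empty cohort")
  if (any(effect_spec$multiplier <= 0)) stop("multiplicative shifts must be > 0")
  structure(
    list(n_hc = as.integer(n_hc), n_part = as.integer(n_part),
         n_abpos = as.integer(n_abpos),
         age_mean = age_mean, age_sd = age_sd, p_female = p_female,
         pmi_range = pmi_range, ft_range = ft_range,
         thickness_mean = thickness_mean, thickness_sd = thickness_sd,
         braak_range = braak_range, amyloid_range = amyloid_range,
         effect_spec = effect_spec,
         subject_sd = subject_sd, cell_sd = cell_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default injected group effect: +10% MD in layers II-III of AbPos
#' @return tibble usable as `effect_spec` in [cohort_spec()].
#' @export
default_effect_spec <- function() {
  tibble(group = "AbPos", layer = c(2L, 3L), roi = NA_integer_,
         metric = "MD", multiplier = 1.10)
}

sample_covariates <- function(spec) {
  groups <- rep(c("HC", "PART", "AbPos"),
                times = c(spec$n_hc, spec$n_part, spec$n_abpos))
  n <- length(groups)
  ids <- paste0(tolower(groups), stats::ave(seq_len(n), groups, FUN = seq_along))
  braak <- vapply(groups, function(g) {
    r <- spec$braak_range[[g]]
    if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
  }, integer(1))
  amyloid <- ifelse(
    groups == "AbPos",
    if (spec$amyloid_range[1] == spec$amyloid_range[2]) spec$amyloid_range[1]
    else sample(spec$amyloid_range[1]:spec$amyloid_range[2], n, replace = TRUE),
    0L
  )
  tibble(
    subject = ids,
    group = groups,
    age = round(pmin(pmax(rnorm(n, spec$age_mean[groups], spec$age_sd), 45), 92)),
    sex = ifelse(runif(n) < spec$p_female, "F", "M"),
    pmi_min = round(runif(n, spec$pmi_range[1], spec$pmi_range[2])),
    ft_days = round(runif(n, spec$ft_range[1], spec$ft_range[2])),
    thickness_mm = round(rnorm(n, spec$thickness_mean[groups],
                               spec$thickness_sd), 2),
    braak_stage = as.integer(braak),
    amyloid_stage = as.integer(amyloid)
  )
}

effect_multiplier <- function(effect_spec, group, roi, layer, metric) {
  m <- rep(1, length(layer))
  if (is.null(effect_spec) || nrow(effect_spec) == 0) return(m)
  for (i in seq_len(nrow(effect_spec))) {
    e <- effect_spec[i, ]
    roi_ok <- if (is.na(e$roi)) TRUE else !is.na(roi) & roi == e$roi
    hit <- group == e$group & layer == e$layer & metric == e$metric & roi_ok
    m[hit] <- m[hit] * e$multiplier
  }
  m
}

#' Generate a synthetic cohort of layer profiles (and optionally raw DWI)
#'
#' In `"fast"` mode each subject's layer profile is the phantom's ground-truth
#' per-(ROI, layer) metric table perturbed by multiplicative log-normal
#' variation (a shared per-subject factor plus independent per-cell noise),
#' with `effect_spec` multipliers applied to the designated cells of affected
#' groups. In `"full"` mode each subject additionally gets a phantom DWI
#' dataset synthesized under `protocol` (MD profile scaled per the subject's
#' effects), for end-to-end runs through the tensor-fitting pipeline.
#'
#' @param spec a [cohort_spec()].
#' @param phantom_spec a [phantom_spec()] defining the common geometry.
#' @param protocol a [dwi_protocol()] (used in full mode).
#' @param mode `"fast"` (profile-level) or `"full"` (per-subject DWI).
#' @param phantom optionally, a prebuilt [make_phantom()] result for
#'   `phantom_spec` (avoids rebuilding the geometry in repeated simulations).
#' @return list with `cohort` (covariate tibble), `profiles` (LayerProfile
#'   tibble across subjects), `effects` (ground-truth multiplier table over
#'   all (group, roi, layer, metric) cells), and in full mode `datasets`
#'   (named list of per-subject DWI datasets).
#' @export
make_cohort <- function(spec, phantom_spec = laminaprof::phantom_spec(),
                        protocol = dwi_protocol(), mode = c("fast", "full"),
                        phantom = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cov <- sample_covariates(spec)
  phant <- if (is.null(phantom)) make_phantom(phantom_spec) else phantom
  base <- phant$truth$layer_metrics

  effects_full <- base |>
    dplyr::select("roi", "layer", "metric") |>
    tidyr::expand_grid(group = c("HC", "PART", "AbPos")) |>
    dplyr::mutate(multiplier = effect_multiplier(
      spec$effect_spec, .data$group, .data$roi, .data$layer, .data$metric
    ))

  profiles <- purrr::map(seq_len(nrow(cov)), function(i) {
    subj_scale <- exp(rnorm(1, 0, spec$subject_sd))
    mult <- effect_multiplier(spec$effect_spec, cov$group[i],
                              base$roi, base$layer, base$metric)
    base |>
      dplyr::mutate(
        subject = cov$subject[i],
        value = .data$value * mult * subj_scale *
          exp(rnorm(dplyr::n(), 0, spec$cell_sd)),
        n_voxels = NA_integer_
      ) |>
      dplyr::select("subject", "roi", "layer", "metric", "value", "n_voxels")
  }) |>
    dplyr::bind_rows()

  out <- list(cohort = cov, profiles = profiles, effects = effects_full,
              phantom = phant)

  if (mode == "full") {
    out$datasets <- purrr::map(seq_len(nrow(cov)), function(i) {
      mult_md <- effect_multiplier(
        spec$effect_spec, cov$group[i],
        roi = rep(NA_integer_, phantom_spec$n_laminae - 2L),
        layer = seq_len(phantom_spec$n_laminae - 2L),
        metric = rep("MD", phantom_spec$n_laminae - 2L)
      )
      ps <- phantom_spec
      ps$layer_md_profile <- ps$layer_md_profile * mult_md
      subj_phantom <- make_phantom(ps)
      synthesize_dwi(subj_phantom$tensor_field, s0 = 100, protocol = protocol,
                     seed = spec$seed + i)
    })
    names(out$datasets) <- cov$subject
  }
  out
}
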