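#' Residualize values against nuisance covariates
#'
#' Ordinary least squares of the values on an intercept plus the covariate
#' columns, pooled over all subjects (no group term), returning the residuals.
#' Sex is coded 0/1; constant covariate columns are dropped with a message;
#' collinear covariates raise an error naming the offending column.
#'
#' @param values numeric vector, one value per subject.
#' @param covariates data frame of covariate columns aligned with `values`
#'   (e.g. the age/sex/thickness/PMI/FT columns of a cohort table).
#' @return numeric residuals (mean zero).
#' @export
residualize <- function(values, covariates) {
  stopifnot(length(values) == nrow(covariates))
  X <- lapply(names(covariates), function(nm) {
    col <- covariates[[nm]]
    if (is.character(col) || is.factor(col)) {
      col <- as.integer(factor(col)) - 1
    }
    as.numeric(col)
  })
  names(X) <- names(covariates)
  keep <- vapply(X, function(col) length(unique(col)) > 1, logical(1))
  if (any(!keep)) {
    message("dropping constant covariate(s): ",
            paste(names(X)[!keep], collapse = ", "))
    X <- X[keep]
  }
  Xm <- cbind(`(Intercept)` = rep(1, length(values)),
              if (length(X)) do.call(cbind, X) else NULL)
  if (length(values) <= ncol(Xm)) {
    stop("need more observations than covariates")
  }
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    bad <- colnames(Xm)[setdiff(seq_len(ncol(Xm)), qrX$pivot[seq_len(qrX$rank)])]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, values))
}

#' Covariate-adjusted two-sample t-tests per layer (and per ROI-layer cell)
#'
#' For each cell, residualizes the metric against the nuisance covariates
#' (pooled over all subjects) and compares the two amyloid-status groups with
#' a Student pooled-variance two-sample t-test. Two granularities are
#' computed: per (ROI, layer) cell, and per layer pooled over ROIs (each
#' subject contributing its across-ROI mean). The t statistic is signed as
#' group1 minus group2 with the default order (amyloid-negative,
#' amyloid-positive), so positive pathology effects on MD appear as negative
#' t. BH-FDR q-values are attached within each (metric, scope) family.
#'
#' @param profiles LayerProfile tibble (`subject`, `roi`, `layer`, `metric`,
#'   `value`).
#' @param cohort cohort tibble with `subject`, `group` and covariate columns.
#' @param metrics metrics to test (default FA and MD).
#' @param covariates covariate column names to regress out; `NULL` or empty
#'   for unadjusted tests.
#' @param group_order the two status labels, tested as first minus second.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return tibble (StatResult) with `scope`, `roi`, `layer`, `metric`,
#'   `estimate`, `t`, `df`, `p`, `q`, `n1`, `n2`, `model`.
#' @export
group_ttest <- function(profiles, cohort,
                        metrics = c("FA", "MD"),
                        covariates = c("age", "sex", "thickness_mm",
                                       "pmi_min", "ft_days"),
                        group_order = c("AbNeg", "AbPos"),
                        var_equal = TRUE) {
  cohort <- dplyr::mutate(
    cohort,
    .status = ifelse(.data$group == "AbPos", "AbPos", "AbNeg")
  )
  run_cell <- function(df, scope, roi_label) {
    df <- dplyr::inner_join(df, cohort, by = "subject")
    df <- df[is.finite(df$value), ]
    n1 <- sum(df$.status == group_order[1])
    n2 <- sum(df$.status == group_order[2])
    if (n1 < 2 || n2 < 2) return(NULL)
    vals <- df$value
    if (!is.null(covariates) && length(covariates)) {
      vals <- residualize(vals, df[, covariates, drop = FALSE])
    }
    g1 <- vals[df$.status == group_order[1]]
    g2 <- vals[df$.status == group_order[2]]
    tt <- stats::t.test(g1, g2, var.equal = var_equal)
    tibble(scope = scope, roi = roi_label,
           estimate = mean(g1) - mean(g2),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, n1 = n1, n2 = n2,
           model = if (var_equal) "student_t" else "welch_t")
  }

  res <- list()
  for (m in metrics) {
    pm <- dplyr::filter(profiles, .data$metric == m)
    if (!nrow(pm)) next
    # per (roi, layer)
    cell_res <- pm |>
      dplyr::group_by(.data$roi, .data$layer) |>
      dplyr::group_modify(function(df, key) {
        out <- run_cell(df, "roi_layer", as.character(key$roi))
        if (is.null(out)) {
          message("metric ", m, " roi ", key$roi, " layer ", key$layer,
                  ": a group has < 2 subjects; cell skipped")
          return(tibble())
        }
        dplyr::select(out, -"roi")
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(roi = as.character(.data$roi), metric = m)
    # per layer, pooled over ROIs (subject means)
    pooled <- pm |>
      dplyr::group_by(.data$subject, .data$layer) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::group_by(.data$layer) |>
      dplyr::group_modify(function(df, key) {
        out <- run_cell(df, "layer", "pooled")
        if (is.null(out)) return(tibble())
        out
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(metric = m)
    res[[m]] <- dplyr::bind_rows(cell_res, pooled)
  }
  res <- dplyr::bind_rows(res)
  if (!nrow(res)) return(res)
  # BH within each (metric, scope) family
  res |>
    dplyr::group_by(.data$metric, .data$scope) |>
    dplyr::mutate(q = fdr_bh(.data$p)$q) |>
    dplyr::ungroup() |>
    dplyr::select("scope", "roi", "layer", "metric", "estimate", "t", "df",
                  "p", "q", "n1", "n2", "model")
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` clipped at 1, mapped back to the
#' input order; flags tests with `q < alpha`.
#'
#' @param pvals numeric p-values in `[0, 1]` (non-finite values are an error).
#' @param alpha significance level for the flags.
#' @return tibble with `p`, `q`, `significant`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  tibble(p = pvals, q = q, significant = q < alpha)
}

#' Stage linear mixed model per layer
#'
#' Fits `value ~ age + sex + braak_stage + amyloid_stage + (1 | subject)` by
#' REML within each layer (each subject contributes one observation per ROI,
#' so the random intercept captures subject-level repetition), reporting Wald
#' t (Satterthwaite df) per fixed effect. With `scope = "roi_layer"` each
#' (ROI, layer) cell has a single observation per subject, so the random
#' intercept is inestimable and the fit degrades to OLS with a flag.
#' Constant predictor columns are dropped from the design with a message.
#'
#' @param profiles LayerProfile tibble.
#' @param cohort cohort tibble with `age`, `sex`, `braak_stage`,
#'   `amyloid_stage`.
#' @param metric metric to model (default `"MD"`).
#' @param scope `"layer"` (pooling ROIs; default) or `"roi_layer"`.
#' @return object of class `stage_lmm`; see [tidy.stage_lmm()] and
#'   [glance.stage_lmm()].
#' @export
fit_stage_lmm <- function(profiles, cohort, metric = "MD",
                          scope = c("layer", "roi_layer")) {
  scope <- match.arg(scope)
  pm <- dplyr::filter(profiles, .data$metric == !!metric)
  if (!nrow(pm)) stop("no rows for metric ", metric)
  dat <- dplyr::inner_join(pm, cohort, by = "subject") |>
    dplyr::mutate(sex01 = as.integer(factor(.data$sex)) - 1L)

  terms_all <- c(age = "age", sex = "sex01", braak = "braak_stage",
                 amyloid = "amyloid_stage")
  groups <- if (scope == "layer") {
    dplyr::group_split(dat, .data$layer)
  } else {
    dplyr::group_split(dat, .data$roi, .data$layer)
  }

  fits <- purrr::map(groups, function(df) {
    keep <- vapply(terms_all, function(v) length(unique(df[[v]])) > 1,
                   logical(1))
    if (any(!keep)) {
      message("layer ", df$layer[1], ": constant term(s) excluded: ",
              paste(names(terms_all)[!keep], collapse = ", "))
    }
    rhs <- paste(terms_all[keep], collapse = " + ")
    per_subj <- table(df$subject)
    use_lmm <- scope == "layer" && any(per_subj > 1)
    fallback <- FALSE
    coefs <- NULL
    if (use_lmm) {
      f <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject)"))
      fit <- tryCatch(
        suppressMessages(lmerTest::lmer(f, data = df, REML = TRUE)),
        error = function(e) NULL
      )
      if (!is.null(fit) && !any(grepl("singular", fit@optinfo$conv$lme4$messages %||% ""))) {
        sm <- stats::coef(summary(fit))
        coefs <- tibble(
          term = rownames(sm), estimate = unname(sm[, "Estimate"]),
          se = unname(sm[, "Std. Error"]), df = unname(sm[, "df"]),
          t = unname(sm[, "t value"]), p = unname(sm[, "Pr(>|t|)"])
        )
      } else {
        fallback <- TRUE
      }
    } else {
      fallback <- TRUE
    }
    if (fallback) {
      f <- stats::as.formula(paste("value ~", rhs))
      fit <- stats::lm(f, data = df)
      sm <- stats::coef(summary(fit))
      coefs <- tibble(
        term = rownames(sm), estimate = unname(sm[, "Estimate"]),
        se = unname(sm[, "Std. Error"]), df = fit$df.residual,
        t = unname(sm[, "t value"]), p = unname(sm[, "Pr(>|t|)"])
      )
    }
    coefs$term[coefs$term == "sex01"] <- "sex"
    this_layer <- df$layer[1]
    this_roi <- if (scope == "roi_layer") as.character(df$roi[1]) else "pooled"
    n_obs_fit <- nrow(df)
    coefs |>
      dplyr::mutate(
        layer = this_layer,
        roi = this_roi,
        model = if (fallback) "ols_fallback" else "lmm_reml",
        n_obs = n_obs_fit, n_subjects = length(per_subj)
      )
  })
  structure(
    list(coefficients = dplyr::bind_rows(fits), metric = metric,
         scope = scope),
    class = "stage_lmm"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn fit_stage_lmm Coefficient table: one row per fixed effect per
#'   (layer, ROI) fit, with estimate, SE, t, df and p.
#' @param x a `stage_lmm` object.
#' @param ... unused.
#' @export
tidy.stage_lmm <- function(x, ...) {
  dplyr::select(x$coefficients, "roi", "layer", "term", "estimate", "se",
                "t", "df", "p", "model")
}

#' @describeIn fit_stage_lmm One-row-per-fit summary: model type, sizes.
#' @export
glance.stage_lmm <- function(x, ...) {
  x$coefficients |>
    dplyr::distinct(.data$roi, .data$layer, .data$model, .data$n_obs,
                    .data$n_subjects) |>
    dplyr::mutate(metric = x$metric, scope = x$scope)
}

#' @export
print.stage_lmm <- function(x, ...) {
  cat("Stage linear mixed model (", x$metric, ", scope = ", x$scope, ")\n",
      sep = "")
  print(tidy(x), n = 20)
  invisible(x)
}

#' Matched-pair delta profiles
#'
#' Cell-wise difference (case minus matched control) of two subjects' layer
#' profiles on matching (ROI, layer, metric) cells, for explicitly declared
#' case-control pairs. Cells missing in either partner yield `NA` deltas
#' (logged).
#'
#' @param profiles LayerProfile tibble covering cases and controls.
#' @param pairs data frame with columns `case` and `control` (subject ids).
#' @return tibble (DeltaProfile) with `case`, `control`, `roi`, `layer`,
#'   `metric`, `delta`.
#' @export
delta_profile <- function(profiles, pairs) {
  stopifnot(all(c("case", "control") %in% names(pairs)))
  missing_subj <- setdiff(c(pairs$case, pairs$control),
                          unique(profiles$subject))
  if (length(missing_subj)) {
    stop("subject(s) absent from profiles: ",
         paste(missing_subj, collapse = ", "))
  }
  purrr::pmap(pairs[, c("case", "control")], function(case, control) {
    pc <- dplyr::filter(profiles, .data$subject == case)
    ph <- dplyr::filter(profiles, .data$subject == control)
    joined <- dplyr::full_join(
      dplyr::select(pc, "roi", "layer", "metric", case_value = "value"),
      dplyr::select(ph, "roi", "layer", "metric", hc_value = "value"),
      by = c("roi", "layer", "metric")
    )
    n_miss <- sum(!complete.cases(joined[, c("case_value", "hc_value")]))
    if (n_miss) message(case, "-", control, ": ", n_miss,
                        " cell(s) missing in one partner")
    dplyr::transmute(joined, case = case, control = control,
                     roi = .data$roi, layer = .data$layer,
                     metric = .data$metric,
                     delta = .data$case_value - .data$hc_value)
  }) |>
    dplyr::bind_rows()
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 kept small
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman correlation across cortical layers
#'
#' Spearman rho with average ranks for ties. The two-sided p-value is
#' computed by exact enumeration of all rank permutations for `n <= 8`
#' observations (counting permutations with `|rho| >= |rho_observed|`), and by
#' the asymptotic t approximation for larger n.
#'
#' @param x,y paired numeric vectors (e.g. per-layer delta-MD and stain
#'   density), length >= 3.
#' @return tibble with `rho`, `p`, `n`, `method`.
#' @export
spearman_layers <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired layers")
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a, b)
  }
  rho <- rho_of(rx, ry)
  if (is.na(rho)) stop("a variable is constant; rho undefined")
  if (n <= 8) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(pm) rho_of(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t_approximation"
  }
  tibble(rho = rho, p = p, n = n, method = method)
}
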