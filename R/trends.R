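#' Fit a covariate-adjusted trend model for one response
#'
#' Ordinary linear model (Gaussian, identity link) of a CLR abundance,
#' alpha-diversity value, pH or BMI on a focal variable plus covariates
#' (typically gender, age and log town population). When the focal variable
#' is age and `quadratic_age = TRUE`, age enters through an orthogonal
#' degree-2 polynomial so a parabolic trend is detectable as a single
#' 2-df term. Per-term p-values come from type-II ANOVA (each term tested
#' against the model containing all other terms at its level), which makes
#' them invariant to the order of terms.
#'
#' @param y numeric response vector.
#' @param data data frame holding the focal variable and covariates.
#' @param focal name of the focal column in `data`.
#' @param covariates names of adjustment columns (default
#'   `c("gender", "age", "log_population")` minus the focal).
#' @param quadratic_age use a degree-2 age basis for the age term.
#' @return list with `p` (type-II p of the focal term), `coef` (focal
#'   coefficient: slope for numeric focal, yes-effect for a yes/no factor,
#'   linear-component sign for quadratic age), `p_all` (named p per term),
#'   `shape` (for quadratic age: fitted age curve on a grid plus the
#'   quadratic coefficient sign), and the residual df `df_residual`.
#' @export
fit_trend <- function(y, data, focal, covariates = NULL,
                      quadratic_age = FALSE) {
  stop_if_not(all(is.finite(y[!is.na(y)])), "response must be finite")
  data <- as.data.frame(data)
  if (is.null(covariates)) {
    covariates <- intersect(c("gender", "age", "log_population"), names(data))
  }
  covariates <- setdiff(covariates, focal)
  term_of <- function(v) {
    if (v == "age" && quadratic_age && v == focal) "poly(age, 2)" else v
  }
  terms <- c(term_of(focal), covariates)
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  df <- data.frame(y = y, data, check.names = FALSE)
  df <- df[complete.cases(df[, c("y", focal, covariates), drop = FALSE]), ,
           drop = FALSE]
  npar <- length(terms) + 1 + as.integer(quadratic_age && focal == "age")
  stop_if_not(nrow(df) >= npar + 2, "too few observations (%d) for %d parameters",
              nrow(df), npar)
  for (v in c(focal, covariates)) {
    vals <- df[[v]]
    stop_if_not(length(unique(vals)) > 1, "term '%s' is constant", v)
  }
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    drop <- covariates[vapply(covariates, function(v)
      any(startsWith(bad, v)), logical(1))]
    warning(sprintf("rank-deficient design; dropping term(s): %s",
                    paste(drop, collapse = ", ")))
    covariates <- setdiff(covariates, drop)
    terms <- c(term_of(focal), covariates)
    fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    fit <- lm(fml, data = df)
  }
  a2 <- car::Anova(fit, type = 2)
  pn <- rownames(a2)
  p_all <- setNames(a2$`Pr(>F)`[seq_along(pn)], pn)
  p_all <- p_all[!is.na(p_all)]
  focal_term <- term_of(focal)
  cf <- coef(fit)
  out <- list(p = unname(p_all[focal_term]), p_all = p_all,
              df_residual = fit$df.residual)
  if (focal == "age" && quadratic_age) {
    b <- cf[grep("^poly\\(age, 2\\)", names(cf))]
    grid <- seq(min(df$age), max(df$age), length.out = 50)
    basis <- predict(poly(df$age, 2), grid)
    curve <- as.numeric(basis %*% b)
    out$coef <- unname(b[1])
    out$shape <- list(age_grid = grid, curve = curve,
                      quad_coef = unname(b[2]))
  } else if (is.numeric(df[[focal]])) {
    out$coef <- unname(cf[focal])
  } else {
    hit <- grep(paste0("^", focal), names(cf), value = TRUE)
    out$coef <- unname(cf[hit[1]])
  }
  out
}

classify_age_direction <- function(mean_curve, age_grid, p_lin, p_quad,
                                   alpha = 0.05) {
  if (is.null(mean_curve)) return(NA_character_)
  lo <- age_grid < 50
  rise_total <- mean_curve[length(mean_curve)] - mean_curve[1]
  span <- max(mean_curve) - min(mean_curve)
  flat_below_50 <- span > 0 &&
    abs(mean_curve[max(which(lo))] - mean_curve[1]) < 0.25 * span
  vertex_interior <- {
    i <- which.min(mean_curve); j <- which.max(mean_curve)
    k <- if (abs(mean_curve[i] - mean_curve[1]) + abs(mean_curve[i] - mean_curve[length(mean_curve)]) >
             abs(mean_curve[j] - mean_curve[1]) + abs(mean_curve[j] - mean_curve[length(mean_curve)]))
      i else j
    k > 3 && k < length(mean_curve) - 3
  }
  if (!is.na(p_quad) && p_quad < alpha && vertex_interior) {
    if (flat_below_50 && rise_total > 0) "late-rise" else "parabolic"
  } else if (flat_below_50 && rise_total > 0) {
    "late-rise"
  } else if (rise_total >= 0) "increase" else "decrease"
}

#' Consensus trend tests across a subsample ensemble
#'
#' The workhorse of the differential-abundance stage: for every subsample
#' in the ensemble, each response (genus/phylum CLR value, alpha-diversity
#' measure, pH, BMI, ...) is fit with [fit_trend()], the focal-term
#' p-values are Benjamini-Hochberg adjusted across the responses of that
#' subsample, and results are aggregated per response into the mean
#' adjusted p-value and the number of subsamples in which the test is
#' significant (`adjusted p < alpha`). The reported direction is the
#' majority sign of the focal coefficient, or for quadratic age models a
#' shape label: `increase`, `decrease`, `parabolic` (significant quadratic
#' term with an interior vertex), or `late-rise` (flat below age 50,
#' positive overall).
#'
#' @param ensemble a `subsample_ensemble` ([subsample_binary()] or
#'   [subsample_age_bins()]).
#' @param responses numeric matrix, samples in rows (named), one column per
#'   response.
#' @param meta metadata supplying the covariates.
#' @param focal focal variable: a metadata column name, or `"age"`. For a
#'   binary ensemble the group labels of each subsample define the focal
#'   factor, so matched controls and yes-samples are taken as drawn.
#' @param covariates adjustment terms (default gender, age, log population;
#'   age is omitted when focal).
#' @param quadratic_age degree-2 age basis for age-as-focal fits.
#' @param alpha significance level for counting (default 0.05).
#' @return data frame of class `consensus_result`: `response`, `direction`,
#'   `mean_adjusted_p`, `n_significant`, `n_reps_used`, `mean_coef`;
#'   per-subsample records in `attr(, "records")`, failed subsample count
#'   in `attr(, "n_failed")`.
#' @export
consensus <- function(ensemble, responses, meta, focal = ensemble$variable,
                      covariates = NULL, quadratic_age = FALSE,
                      alpha = 0.05) {
  stop_if_not(inherits(ensemble, "subsample_ensemble"),
              "ensemble must be a subsample_ensemble")
  responses <- as.matrix(responses)
  stop_if_not(!is.null(rownames(responses)), "responses must have sample row names")
  stop_if_not(!is.null(colnames(responses)), "responses must have column names")
  meta2 <- prepare_covariate_frame(meta)
  n_resp <- ncol(responses)
  recs <- vector("list", ensemble$n_reps)
  n_failed <- 0L
  for (r in seq_len(ensemble$n_reps)) {
    s <- ensemble$sets[[r]]
    idx <- match(s$sample_id, rownames(responses))
    stop_if_not(!anyNA(idx), "ensemble and responses not aligned")
    dat <- meta2[match(s$sample_id, meta2$sample_id), , drop = FALSE]
    if (focal != "age" && !is.null(s$group) && is.factor(s$group) &&
        all(levels(s$group) %in% c("no", "yes"))) {
      dat[[focal]] <- s$group
    }
    res <- tryCatch({
      fits <- lapply(seq_len(n_resp), function(j)
        fit_trend(responses[idx, j], dat, focal,
                  covariates = covariates, quadratic_age = quadratic_age))
      p <- vapply(fits, function(f) f$p %||% NA_real_, numeric(1))
      padj <- p.adjust(p, method = "fdr")
      list(p = p, padj = padj,
           coef = vapply(fits, function(f) f$coef %||% NA_real_, numeric(1)),
           p_quad = vapply(fits, function(f)
             if (!is.null(f$shape)) f$p else NA_real_, numeric(1)),
           curves = lapply(fits, function(f) f$shape))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
    } else {
      recs[[r]] <- res
    }
  }
  ok <- !vapply(recs, is.null, logical(1))
  stop_if_not(any(ok), "all subsample fits failed")
  padj_mat <- do.call(rbind, lapply(recs[ok], `[[`, "padj"))
  coef_mat <- do.call(rbind, lapply(recs[ok], `[[`, "coef"))
  out <- data.frame(
    response = colnames(responses),
    mean_adjusted_p = colMeans(padj_mat),
    n_significant = colSums(padj_mat < alpha),
    n_reps_used = sum(ok),
    mean_coef = colMeans(coef_mat),
    stringsAsFactors = FALSE)
  out$direction <- vapply(seq_len(n_resp), function(j) {
    if (quadratic_age && focal == "age") {
      curves <- lapply(recs[ok], function(rc) rc$curves[[j]])
      curves <- curves[!vapply(curves, is.null, logical(1))]
      if (length(curves) == 0) return(NA_character_)
      grid <- curves[[1]]$age_grid
      mc <- rowMeans(vapply(curves, `[[`, numeric(length(grid)), "curve"))
      quad_ps <- vapply(recs[ok], function(rc) rc$p_quad[j], numeric(1))
      classify_age_direction(mc, grid, p_lin = NA, p_quad = mean(quad_ps),
                             alpha = alpha)
    } else {
      if (out$mean_coef[j] >= 0) "increase" else "decrease"
    }
  }, character(1))
  out <- out[, c("response", "direction", "mean_adjusted_p",
                 "n_significant", "n_reps_used", "mean_coef")]
  rownames(out) <- NULL
  attr(out, "records") <- recs
  attr(out, "n_failed") <- n_failed
  attr(out, "alpha") <- alpha
  class(out) <- c("consensus_result", "data.frame")
  out
}

prepare_covariate_frame <- function(meta) {
  meta <- as.data.frame(meta)
  if ("town_population" %in% names(meta) && !"log_population" %in% names(meta)) {
    meta$log_population <- log(meta$town_population)
  }
  meta
}

#' Associations of oral pH with diversity and taxon abundances
#'
#' Runs the consensus linear-model machinery with pH as the focal
#' covariate against alpha-diversity measures and/or CLR taxon abundances,
#' adjusting for gender, age and log town population.
#'
#' @param meta metadata with a `pH` column (>= 30 non-missing values).
#' @param responses matrix of responses (samples x measures), e.g.
#'   `cbind` of alpha diversity columns and genus CLR values.
#' @param ensemble optional `subsample_ensemble`; by default a single
#'   "subsample" containing every sample with pH is used.
#' @param alpha significance level.
#' @return a `consensus_result` (see [consensus()]).
#' @export
ph_correlations <- function(meta, responses, ensemble = NULL, alpha = 0.05) {
  ok <- !is.na(meta$pH)
  stop_if_not(sum(ok) >= 30, "need pH for at least 30 samples (have %d)", sum(ok))
  stop_if_not(length(unique(meta$pH[ok])) > 1, "pH is constant")
  if (is.null(ensemble)) {
    ids <- intersect(meta$sample_id[ok], rownames(responses))
    ensemble <- new_ensemble("pH", list(data.frame(sample_id = ids,
                                                   stringsAsFactors = FALSE)),
                             list(NULL), seed = 0L, sizes = length(ids))
  }
  consensus(ensemble, responses, meta, focal = "pH", alpha = alpha)
}
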