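#' Natural cubic spline basis
#'
#' Wraps [splines::ns()] with the two knot-placement rules used in the
#' model: `"equidistant"` places the internal knots at equal steps of the
#' observed range (2 knots sit at its interior thirds), and `"monthly"`
#' places them at the warm-season month boundaries (Jun 1, Jul 1, Aug 1,
#' Sep 1 as day-of-season 32, 62, 93, 124) for the seasonal smooth.
#' Boundary knots are the observed min/max (day-of-season 1 and 153 for
#' monthly placement), beyond which the basis is linear.
#'
#' @param x Numeric vector (a temperature covariate, or day-of-season
#'   1..153 for monthly placement).
#' @param n_internal_knots Number of internal knots for equidistant
#'   placement (default 2).
#' @param placement `"equidistant"` or `"monthly"`.
#' @param boundary Optional explicit boundary knots (default: the observed
#'   range, or day-of-season 1 and 153 for monthly placement).
#' @return Basis matrix (`n_internal_knots + 1` columns for equidistant;
#'   5 for monthly) with attributes `knots` and `boundary`.
#' @export
natural_cubic_basis <- function(x, n_internal_knots = 2L,
                                placement = c("equidistant", "monthly"),
                                boundary = NULL) {
  placement <- match.arg(placement)
  xf <- x[is.finite(x)]
  if (placement == "monthly") {
    knots <- c(32, 62, 93, 124)
    if (is.null(boundary)) boundary <- c(1, 153)
  } else {
    if (length(unique(xf)) < n_internal_knots + 2L)
      stop_invalid("too few distinct values for a natural cubic basis")
    if (is.null(boundary)) boundary <- range(xf)
    rg <- boundary
    if (diff(rg) <= 0) stop_invalid("degenerate covariate: constant values")
    knots <- rg[1] + seq_len(n_internal_knots) / (n_internal_knots + 1L) * diff(rg)
  }
  b <- splines::ns(xf, knots = knots, Boundary.knots = boundary)
  out <- matrix(NA_real_, length(x), ncol(b))
  out[is.finite(x), ] <- unclass(b)
  attr(out, "knots") <- knots
  attr(out, "boundary") <- boundary
  out
}

#' Build the time-series design matrix
#'
#' Assembles the covariate blocks of the quasi-Poisson model: intercept,
#' optional binary exposure H, natural cubic splines (2 internal knots) of
#' same-day temperature, lag 1-3 mean temperature and same-day maximum
#' dew point, year indicators (first year reference), a seasonal smooth
#' with monthly knots interacted with year, day-of-week indicators
#' (Sunday reference), and any holiday and hospital-availability indicator
#' columns present in `health`. When the exposure metric is apparent
#' temperature the dew-point block is omitted. Rows outside the warm
#' season or with any missing covariate are excluded.
#'
#' @param health Data frame with `date`, `count` and optional columns
#'   named `holiday_*` and `hosp_*`.
#' @param covariates Data frame from [continuous_temp_covariates()].
#' @param h Optional binary exposure series aligned by date (data frame
#'   `date`, `h`, or a vector aligned to `health$date`).
#' @param include_dpt Include the dew-point spline (set `FALSE` when
#'   apparent temperature is the exposure of interest).
#' @return Object of class `heat_design`: list with the model matrix `x`,
#'   response `y`, `dates`, and `blocks` (named column-index list).
#' @export
build_design <- function(health, covariates, h = NULL, include_dpt = TRUE) {
  idx <- match(health$date, covariates$date)
  if (anyNA(idx)) stop_invalid("covariates missing for some health dates")
  cov <- covariates[idx, , drop = FALSE]
  dates <- health$date
  warm <- is_warm_season(dates)

  hvec <- NULL
  if (!is.null(h)) {
    hvec <- if (is.data.frame(h)) h$h[match(dates, h$date)] else h
    if (length(hvec) != length(dates)) stop_invalid("H series misaligned")
  }

  ok <- warm & is.finite(cov$temp) & is.finite(cov$temp_bar) &
    is.finite(health$count)
  if (include_dpt) ok <- ok & is.finite(cov$dpt)
  if (!is.null(hvec)) ok <- ok & !is.na(hvec)
  n_drop <- sum(warm) - sum(ok)
  if (n_drop > 0)
    message("build_design: excluded ", n_drop,
            " warm-season rows with missing covariates")

  d <- dates[ok]
  y <- health$count[ok]
  blocks <- list()
  cols <- list(`(Intercept)` = rep(1, length(d)))
  blocks$intercept <- "(Intercept)"

  if (!is.null(hvec)) {
    cols$H <- as.numeric(hvec[ok])
    blocks$exposure <- "H"
  }

  add_basis <- function(cols, values, prefix, placement = "equidistant") {
    b <- natural_cubic_basis(values, 2L, placement)
    for (j in seq_len(ncol(b))) cols[[paste0(prefix, j)]] <- b[, j]
    cols
  }
  cols <- add_basis(cols, cov$temp[ok], "ns_temp")
  blocks$temp <- paste0("ns_temp", 1:3)
  cols <- add_basis(cols, cov$temp_bar[ok], "ns_tbar")
  blocks$temp_bar <- paste0("ns_tbar", 1:3)
  if (include_dpt) {
    cols <- add_basis(cols, cov$dpt[ok], "ns_dpt")
    blocks$dpt <- paste0("ns_dpt", 1:3)
  }

  year <- factor(format(d, "%Y"))
  yrs <- levels(year)
  if (length(yrs) > 1L) {
    for (yy in yrs[-1]) cols[[paste0("year", yy)]] <- as.numeric(year == yy)
    blocks$year <- paste0("year", yrs[-1])
  }

  dos <- day_of_season(d)
  sb <- natural_cubic_basis(dos, placement = "monthly")
  seas_cols <- character(0)
  for (yy in yrs) for (j in seq_len(ncol(sb))) {
    nm <- paste0("seas", j, "_y", yy)
    cols[[nm]] <- sb[, j] * (year == yy)
    seas_cols <- c(seas_cols, nm)
  }
  blocks$season_by_year <- seas_cols

  dow <- factor(dow_label(d),
                levels = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
  for (dd in levels(dow)[-1]) cols[[paste0("dow", dd)]] <- as.numeric(dow == dd)
  blocks$dow <- paste0("dow", levels(dow)[-1])

  extra <- function(prefix) grep(paste0("^", prefix), names(health), value = TRUE)
  for (grp in c("holiday", "hosp")) {
    nm_all <- extra(grp)
    kept <- character(0)
    for (nm in nm_all) {
      v <- health[[nm]][ok]
      if (length(unique(v)) > 1L) {
        cols[[nm]] <- as.numeric(v)
        kept <- c(kept, nm)
      } else message("build_design: dropping constant indicator column ", nm)
    }
    if (length(kept)) blocks[[grp]] <- kept
  }

  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    blk <- names(blocks)[vapply(blocks, function(b) any(bad %in% b), TRUE)]
    stop_invalid("rank-deficient design; offending block(s): ",
                 paste(blk, collapse = ", "))
  }
  structure(list(x = x, y = y, dates = d, blocks = blocks,
                 has_h = !is.null(hvec)),
            class = "heat_design")
}

# add/replace the exposure column in an existing design (same rows)
design_with_h <- function(design, h) {
  hvec <- if (is.data.frame(h)) h$h[match(design$dates, h$date)] else h
  if (length(hvec) != nrow(design$x) || anyNA(hvec))
    stop_invalid("H series misaligned with design rows")
  x <- design$x
  if (design$has_h) {
    x[, "H"] <- as.numeric(hvec)
  } else {
    x <- cbind(x[, 1, drop = FALSE], H = as.numeric(hvec),
               x[, -1, drop = FALSE])
  }
  design$x <- x
  design$has_h <- TRUE
  design$blocks$exposure <- "H"
  design
}

#' Fit the quasi-Poisson log-linear model
#'
#' Log-link Poisson IRLS (via [stats::glm.fit()]) with quasi-likelihood
#' dispersion: phi is the Pearson chi-square divided by the residual
#' degrees of freedom, and the coefficient covariance is the inverse
#' Fisher information scaled by phi.
#'
#' @param design A `heat_design` from [build_design()].
#' @param counts Optional response overriding `design$y` (same length).
#' @return Object of class `qp_fit`: coefficients, `dispersion`, `vcov`,
#'   `fitted`, `deviance`, `qaic`, `n`, `p`, and the design.
#' @export
fit_quasipoisson <- function(design, counts = NULL) {
  y <- if (is.null(counts)) design$y else counts
  if (length(y) != nrow(design$x)) stop_invalid("counts misaligned with design")
  if (any(y < 0)) stop_invalid("counts must be non-negative")
  fit <- stats::glm.fit(design$x, y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 100L))
  if (!fit$converged) stop_invalid("quasi-Poisson IRLS did not converge")
  mu <- fit$fitted.values
  n <- length(y); p <- fit$rank
  phi <- sum((y - mu)^2 / mu) / (n - p)
  xtwx <- crossprod(design$x * sqrt(mu))
  vc <- phi * chol2inv(chol(xtwx))
  dimnames(vc) <- list(colnames(design$x), colnames(design$x))
  structure(list(coefficients = fit$coefficients, dispersion = phi,
                 vcov = vc, fitted = mu, deviance = fit$deviance,
                 qaic = fit$deviance / phi + 2 * p,
                 n = n, p = p, y = y, design = design),
            class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("quasi-Poisson fit: n = %d, p = %d, phi = %.3f, deviance = %.1f, QAIC = %.1f\n",
              x$n, x$p, x$dispersion, x$deviance, x$qaic))
  if (x$design$has_h) {
    re <- risk_estimate(x)
    cat(sprintf("exposure RR = %.3f (95%% CI %.3f, %.3f)\n",
                re$rr, re$ci_low, re$ci_high))
  }
  invisible(x)
}

#' Pearson residuals of a quasi-Poisson fit
#'
#' r_t = (Y_t - mu_t) / sqrt(phi * mu_t): the scaled difference between
#' observed and expected counts fed to the stage-2 logic-tree search. By
#' construction of phi, the residual sum of squares equals n - p.
#'
#' @param fit A `qp_fit`.
#' @param counts Optional observed counts (default: those used in the fit).
#' @return Numeric residual vector aligned with `fit$design$dates`.
#' @export
pearson_residuals <- function(fit, counts = NULL) {
  y <- if (is.null(counts)) fit$y else counts
  mu <- fit$fitted
  if (any(mu <= 0)) stop_invalid("non-positive fitted mean")  # impossible under log link
  (y - mu) / sqrt(fit$dispersion * mu)
}

#' Quasi-AIC of a fit
#'
#' deviance / phi + 2p, used to compare heat-metric/threshold grid cells.
#' By default each model's own dispersion is used; pass `phi` to score
#' several fits against a common (e.g. richest-model) dispersion.
#'
#' @param fit A `qp_fit`.
#' @param phi Optional external dispersion.
#' @return The QAIC value.
#' @export
qaic <- function(fit, phi = NULL) {
  if (is.null(phi)) phi <- fit$dispersion
  fit$deviance / phi + 2 * fit$p
}

#' Relative risk of the binary exposure
#'
#' exp of the H coefficient with a 95 percent Wald interval on the
#' quasi-likelihood standard error.
#'
#' @param fit A `qp_fit` whose design contains the exposure column.
#' @return List of class `risk_estimate`: `rr`, `ci_low`, `ci_high`,
#'   `beta_hat`, `se`.
#' @export
risk_estimate <- function(fit) {
  if (!fit$design$has_h) stop_invalid("fit has no exposure column H")
  b <- fit$coefficients[["H"]]
  se <- sqrt(fit$vcov["H", "H"])
  structure(list(rr = exp(b), ci_low = exp(b - 1.96 * se),
                 ci_high = exp(b + 1.96 * se), beta_hat = b, se = se),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("RR = %.3f (95%% CI %.3f, %.3f)\n", x$rr, x$ci_low, x$ci_high))
  invisible(x)
}
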