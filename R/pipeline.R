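# Three-stage estimation: (1) quasi-Poisson base model without the extreme
# heat term, (2) logic-tree search on its Pearson residuals over lagged
# exceedance indicators, (3) refit of the full model with the selected
# binary exposure H(X).

#' Control settings for the stage-2 logic-tree search
#'
#' @param candidate_sizes Leaf counts compared by cross-validation
#'   (default 1:3; include 0 to allow the no-exposure model).
#' @param n_folds CV folds (default 10).
#' @param cv_schedule Annealing schedule for per-fold searches.
#' @param final_schedule Annealing schedule for the final full-data search.
#' @param cv_restarts,final_restarts Annealing restarts in each phase.
#' @return A `logic_control` list.
#' @export
logic_control <- function(candidate_sizes = 1:3, n_folds = 10L,
                          cv_schedule = annealing_schedule(n_iterations = 2000L),
                          final_schedule = annealing_schedule(n_iterations = 10000L),
                          cv_restarts = 1L, final_restarts = 2L) {
  structure(list(candidate_sizes = candidate_sizes, n_folds = n_folds,
                 cv_schedule = cv_schedule, final_schedule = final_schedule,
                 cv_restarts = cv_restarts, final_restarts = final_restarts),
            class = "logic_control")
}

#' Stage 1: base model fit without the exposure term
#'
#' @param health Daily counts data frame (`date`, `count`, optional
#'   `holiday_*`/`hosp_*` indicator columns).
#' @param covariates Continuous temperature covariates from
#'   [continuous_temp_covariates()].
#' @param include_dpt Include the dew-point spline (FALSE when apparent
#'   temperature is the exposure of interest).
#' @return A `qp_fit` whose design has no H column.
#' @export
stage1_fit <- function(health, covariates, include_dpt = TRUE) {
  fit_quasipoisson(build_design(health, covariates, h = NULL,
                                include_dpt = include_dpt))
}

#' Stage 2: logic-tree search on Pearson residuals
#'
#' Selects the tree size by ten-fold cross-validation, anneals a tree of
#' that size on the full residual series, and orients it so exposed days
#' are the minority.
#'
#' @param fit The stage-1 `qp_fit`.
#' @param indicators An `exposure_indicators` data frame covering the
#'   fit's dates.
#' @param control A [logic_control()].
#' @param seed Integer seed.
#' @return The selected `logic_tree` (with attribute `cv`, the
#'   cross-validation table), or `NULL` when the no-exposure model is
#'   selected or the indicators carry no variation.
#' @export
stage2_logic <- function(fit, indicators, control = logic_control(),
                         seed = NULL) {
  lag_cols <- grep("^lag", names(indicators), value = TRUE)
  x <- as.matrix(indicators[match(fit$design$dates, indicators$date),
                            lag_cols, drop = FALSE])
  r <- pearson_residuals(fit)
  if (all(x == 0, na.rm = TRUE)) {
    message("stage2: indicators are all zero; no exposure to search")
    return(NULL)
  }
  sel <- select_tree_size(x, r, candidate_sizes = control$candidate_sizes,
                          n_folds = control$n_folds,
                          schedule = control$cv_schedule,
                          n_restarts = control$cv_restarts,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, "cv"))
  if (sel$size == 0L) {
    message("stage2: cross-validation selected the no-exposure model")
    return(NULL)
  }
  tree <- anneal_logic_tree(x, r, max_leaves = sel$size,
                            schedule = control$final_schedule,
                            n_restarts = control$final_restarts,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, "final"))
  tree <- orient_reference(tree, x)
  attr(tree, "cv") <- sel$cv
  tree
}

#' Stage 3: refit the full model with the selected exposure
#'
#' @param fit The stage-1 `qp_fit` (its design rows are reused).
#' @param h Binary exposure series: data frame `date`, `h` or a vector
#'   aligned to the fit's dates.
#' @return List with the refit `qp_fit` (`fit`) and the exposure
#'   [risk_estimate()] (`risk`); `risk` is `NULL` when `h` never fires.
#' @export
stage3_refit <- function(fit, h) {
  hvec <- if (is.data.frame(h)) h$h[match(fit$design$dates, h$date)] else h
  if (all(hvec == 0, na.rm = TRUE)) {
    message("stage3: exposure never fires; reporting null finding")
    return(list(fit = fit, risk = NULL))
  }
  design <- design_with_h(fit$design, hvec)
  refit <- fit_quasipoisson(design, fit$y)
  list(fit = refit, risk = risk_estimate(refit))
}

# exposure series of a tree over indicator rows (NA lags treated as given)
tree_exposure <- function(tree, indicators, dates = NULL) {
  lag_cols <- grep("^lag", names(indicators), value = TRUE)
  x <- as.matrix(indicators[, lag_cols, drop = FALSE])
  h <- evaluate_tree(tree, x)
  out <- data.frame(date = indicators$date, h = h)
  if (!is.null(dates)) out <- out[match(dates, out$date), , drop = FALSE]
  out
}

run_cell <- function(health, daily, dpt, percentile, max_lag, truncate,
                     include_dpt, control, seed, basis_dates = NULL) {
  thr <- percentile_threshold(daily, percentile, basis_dates)
  covs <- continuous_temp_covariates(daily,
                                     dpt = if (include_dpt) dpt else NULL,
                                     threshold = thr, truncate = truncate)
  ind <- lag_matrix(extreme_indicator(daily, thr), max_lag = max_lag)
  s1 <- stage1_fit(health, covs, include_dpt = include_dpt)
  tree <- stage2_logic(s1, ind, control = control, seed = seed)
  if (is.null(tree)) {
    return(list(tree = NULL, h = NULL, stage1 = s1, stage3 = NULL,
                risk = NULL, qaic = qaic(s1), frequency = 0L,
                threshold = thr, indicators = ind))
  }
  h <- tree_exposure(tree, ind, dates = s1$design$dates)
  s3 <- stage3_refit(s1, h)
  list(tree = tree, h = h, stage1 = s1, stage3 = s3$fit, risk = s3$risk,
       qaic = if (is.null(s3$risk)) qaic(s1) else qaic(s3$fit),
       frequency = sum(h$h == 1L, na.rm = TRUE),
       threshold = thr, indicators = ind)
}

#' Grid specification for the metric/threshold scan
#'
#' @param metrics Character subset of `TMX`, `TMN`, `TAvg`, `ATMX`,
#'   `ATMN`, `ATAvg` (default all six).
#' @param percentiles Subset of 95, 98, 99 (default all three).
#' @param max_lag Largest indicator lag (default 3).
#' @param truncate Truncate the continuous temperature at the threshold
#'   (default TRUE; FALSE gives the "added effect" interpretation).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(metrics = names(all_heat_metrics()),
                      percentiles = c(95, 98, 99),
                      max_lag = 3L, truncate = TRUE) {
  known <- names(all_heat_metrics())
  if (length(metrics) == 0L || !all(metrics %in% known))
    stop_invalid("metrics must be a non-empty subset of ",
                 paste(known, collapse = ", "))
  if (length(percentiles) == 0L || !all(percentiles %in% c(95, 98, 99)))
    stop_invalid("percentiles must be a non-empty subset of 95, 98, 99")
  structure(list(metrics = metrics, percentiles = percentiles,
                 max_lag = as.integer(max_lag), truncate = isTRUE(truncate)),
            class = "grid_spec")
}

#' Run the three-stage algorithm over the heat-metric/threshold grid
#'
#' Executes stages 1-3 for every metric-percentile cell and selects the
#' cell with the smallest QAIC; ties go to fewer exposed days, then to
#' lexicographic metric order. Cells whose fit fails are logged and
#' skipped.
#'
#' @param health Daily counts data frame.
#' @param hourly An [hourly_weather()] record.
#' @param grid A [grid_spec()].
#' @param control A [logic_control()].
#' @param seed Master seed; each cell derives an independent seed from it.
#' @param min_hours Daily completeness minimum passed to [daily_metric()].
#' @return Object of class `pipeline_result`: `selected` (cell list with
#'   tree, exposure frequency, risk estimate), `cells` (per-cell summary
#'   data frame) and `details` (per-cell result lists).
#' @export
run_grid <- function(health, hourly, grid = grid_spec(),
                     control = logic_control(), seed = 1L, min_hours = 18L) {
  specs <- all_heat_metrics()[grid$metrics]
  dpt <- daily_max_dewpoint(hourly, min_hours)
  details <- list()
  rows <- list()
  for (mname in names(specs)) {
    spec <- specs[[mname]]
    daily <- daily_metric(hourly, spec, min_hours)
    for (p in grid$percentiles) {
      cell_id <- paste0(mname, "-", p)
      res <- tryCatch(
        run_cell(health, daily, dpt, p, grid$max_lag, grid$truncate,
                 include_dpt = spec$variable == "T", control,
                 seed = derive_seed(seed, cell_id)),
        error = function(e) {
          message("cell ", cell_id, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      details[[cell_id]] <- res
      rows[[cell_id]] <- data.frame(
        metric = mname, percentile = p, qaic = res$qaic,
        exposure = if (is.null(res$tree)) NA_character_
                   else describe_exposure(res$tree),
        frequency = res$frequency,
        rr = if (is.null(res$risk)) NA_real_ else res$risk$rr,
        ci_low = if (is.null(res$risk)) NA_real_ else res$risk$ci_low,
        ci_high = if (is.null(res$risk)) NA_real_ else res$risk$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop_invalid("all grid cells failed")
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  ord <- order(cells$qaic, cells$frequency, cells$metric)
  sel_id <- paste0(cells$metric[ord[1]], "-", cells$percentile[ord[1]])
  structure(list(selected = c(details[[sel_id]],
                              list(metric = cells$metric[ord[1]],
                                   percentile = cells$percentile[ord[1]])),
                 cells = cells[ord, ], details = details),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  sel <- x$selected
  cat("selected cell:", sel$metric, "at P", sel$percentile, "\n")
  if (!is.null(sel$tree)) {
    cat("exposure:", describe_exposure(sel$tree), "\n")
    cat("frequency:", sel$frequency, "days\n")
    if (!is.null(sel$risk)) print(sel$risk)
  } else cat("no exposure selected (null finding)\n")
  cat("\nper-cell grid results:\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Render an exposure rule for reporting
#'
#' Canonical DNF with complements marked, e.g.
#' `"(lag0 AND lag1) OR (lag1 AND lag3)"`.
#'
#' @param tree A `logic_tree`.
#' @param labels Predictor labels (default `lag0`, `lag1`, ...).
#' @param sep Separator between OR-clauses (use `"\n  OR "` for one
#'   clause per line).
#' @return A single string.
#' @export
describe_exposure <- function(tree, labels = NULL, sep = " OR ") {
  s <- dnf_string(to_dnf(tree), labels)
  if (sep != " OR ") s <- gsub(" OR ", sep, s, fixed = TRUE)
  s
}

#' Conventional consecutive-day heat-wave indicator
#'
#' 1 on day t when days t, t-1, ..., t-(min_consecutive-1) all exceed the
#' threshold; equivalent to the AND of the first `min_consecutive` lag
#' columns.
#'
#' @param indicator Data frame `date`, `x` from [extreme_indicator()].
#' @param min_consecutive Required run length (default 2).
#' @return Data frame `date`, `h`.
#' @export
conventional_heatwave <- function(indicator, min_consecutive = 2L) {
  if (min_consecutive < 1L) stop_invalid("min_consecutive must be >= 1")
  lm <- lag_matrix(indicator, max_lag = min_consecutive - 1L)
  x <- as.matrix(lm[, -1, drop = FALSE])
  rs <- rowSums(x)
  # leading days with unavailable lags cannot be confirmed as a run: 0
  data.frame(date = lm$date, h = as.integer(!is.na(rs) & rs == ncol(x)))
}

#' Gap-filled, complement-free alternative exposure
#'
#' Transforms each DNF clause of an estimated tree into a conventional
#' consecutive-lag rule: complemented literals are dropped, then every lag
#' between the clause's smallest and largest remaining lag is included.
#' Clauses containing only complemented literals are dropped with a
#' warning. The result is the OR of the transformed clauses.
#'
#' @param tree A `logic_tree`.
#' @return A `logic_tree`, or `NULL` if every clause was dropped.
#' @export
fill_gaps_alternative <- function(tree) {
  dnf <- to_dnf(tree)
  out <- list()
  for (cl in dnf) {
    pos <- cl[cl > 0]
    if (length(pos) == 0L) {
      warning("dropping clause with only complemented literals: ",
              dnf_string(structure(list(cl), class = "dnf")))
      next
    }
    out[[length(out) + 1L]] <- seq(min(pos), max(pos))
  }
  if (length(out) == 0L) return(NULL)
  dnf_to_tree(to_dnf(dnf_to_tree(structure(unique(out), class = "dnf"))))
}
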