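#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the variable-slope 4PL model
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / IC_{50})^{hill}}}
#' with the IC50 at the curve midpoint between the fitted plateaus. The fit
#' is parameterised in log(IC50) for numerical stability and solved with
#' Levenberg-Marquardt least squares. The 95% confidence interval comes from
#' a case-resampling bootstrap (percentile interval over `n_boot` refits);
#' the interval is marked `"wide"` when it crosses the tested dose range, and
#' an IC50 beyond the highest tested dose is reported censored
#' (`"> max dose"`).
#'
#' Zero doses (vehicle anchors) are retained as response anchors in the
#' residual sum only through their effect on the top plateau estimate; they
#' are excluded from the log-dose model evaluation, so `doses` passed to the
#' optimiser are strictly positive.
#'
#' @param doses Concentrations (any consistent unit; nM in the validation
#'   tables). Zero doses are dropped from fitting.
#' @param responses Percent survival, same length as `doses`.
#' @param n_boot Bootstrap replicates for the CI. Default 500; `0` skips the
#'   CI.
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `dose_response_fit`: `top`, `bottom`,
#'   `hill_slope`, `ic50`, `ic50_ci_low`, `ic50_ci_high`, `ci_wide`
#'   (logical), `censored` (logical: IC50 above the tested range),
#'   `converged`, `residual_sd`, `n_points`, `dose_range`.
#' @export
fit_4pl <- function(doses, responses, n_boot = 500L, seed = 1L) {
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  x <- doses[keep]
  y <- responses[keep]
  if (length(unique(x)) < 4) {
    stop_glio("need at least 4 distinct positive doses", "input_error")
  }
  fit <- fit_4pl_core(x, y)
  if (is.null(fit)) {
    return(structure(list(top = NA_real_, bottom = NA_real_,
                          hill_slope = NA_real_, ic50 = NA_real_,
                          ic50_ci_low = NA_real_, ic50_ci_high = NA_real_,
                          ci_wide = NA, censored = NA, converged = FALSE,
                          residual_sd = NA_real_, n_points = length(x),
                          dose_range = range(x)),
                     class = "dose_response_fit"))
  }
  ci <- c(NA_real_, NA_real_)
  ci_wide <- NA
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(x), replace = TRUE)
        bf <- fit_4pl_core(x[idx], y[idx])
        if (is.null(bf)) NA_real_ else bf$ic50
      }, 0)
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 0.5 * n_boot) {
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
      ci_wide <- ci[1] <= min(x) || ci[2] >= max(x)
    }
  }
  structure(list(top = fit$top, bottom = fit$bottom,
                 hill_slope = fit$hill, ic50 = fit$ic50,
                 ic50_ci_low = ci[1], ic50_ci_high = ci[2],
                 ci_wide = ci_wide, censored = fit$ic50 > max(x),
                 converged = TRUE, residual_sd = fit$residual_sd,
                 n_points = length(x), dose_range = range(x)),
            class = "dose_response_fit")
}

# Core Levenberg-Marquardt fit in log-IC50; NULL on non-convergence.
fit_4pl_core <- function(x, y) {
  top0 <- max(y)
  bottom0 <- min(y)
  mid <- (top0 + bottom0) / 2
  lic0 <- log(x[which.min(abs(y - mid))])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (x / exp(lic50))^hill),
      data = data.frame(x = x, y = y),
      start = list(bottom = bottom0, top = top0, lic50 = lic0, hill = 1),
      lower = c(-Inf, -Inf, log(min(x)) - 15, 0.05),
      upper = c(Inf, Inf, log(max(x)) + 15, 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  # a plateau-only fit (top ~ bottom) has no identifiable midpoint
  if (abs(cf[["top"]] - cf[["bottom"]]) <
      0.02 * max(1, abs(cf[["top"]]))) return(NULL)
  list(top = cf[["top"]], bottom = cf[["bottom"]], hill = cf[["hill"]],
       ic50 = exp(cf[["lic50"]]),
       residual_sd = stats::sd(stats::residuals(fit)))
}

#' Format an IC50 with its confidence interval
#' @param fit A `dose_response_fit`.
#' @return Character like `"52 [44-61]"`, `"> 10000"` for censored fits,
#'   `"[Wide]"` CIs when the interval spans the tested range, `"no fit"`
#'   when unconverged.
#' @export
format_ic50 <- function(fit) {
  if (!fit$converged) return("no fit")
  if (fit$censored) return(sprintf("> %.4g", fit$dose_range[2]))
  ci <- if (is.na(fit$ic50_ci_low)) "" else if (isTRUE(fit$ci_wide)) {
    " [Wide]"
  } else {
    sprintf(" [%.3g-%.3g]", fit$ic50_ci_low, fit$ic50_ci_high)
  }
  paste0(sprintf("%.3g", fit$ic50), ci)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: IC50 %s (top %.1f, bottom %.1f, hill %.2f, n = %d)\n",
    format_ic50(x), x$top, x$bottom, x$hill_slope, x$n_points))
  invisible(x)
}

#' Fit dose-response curves for every compound x cell line pair
#'
#' @param data Long-format data.frame with columns `compound_id`,
#'   `cell_line`, `dose`, `survival_percent` (replicate rows allowed).
#' @param n_boot Bootstrap replicates per fit.
#' @param seed Base seed; pair `i` uses `seed + i`.
#' @return Data.frame with one row per pair: 4PL parameters, `ic50`, CI
#'   bounds, `ic50_label` (formatted with censoring / wide flags), and an
#'   `error` column for pairs whose fit failed (other pairs are unaffected).
#' @export
batch_fit <- function(data, n_boot = 500L, seed = 1L) {
  pairs <- unique(data[, c("compound_id", "cell_line")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- data$compound_id == pairs$compound_id[i] &
      data$cell_line == pairs$cell_line[i]
    fit <- tryCatch(
      fit_4pl(data$dose[sel], data$survival_percent[sel],
              n_boot = n_boot, seed = seed + i),
      error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(compound_id = pairs$compound_id[i],
                 cell_line = pairs$cell_line[i],
                 top = NA_real_, bottom = NA_real_, hill_slope = NA_real_,
                 ic50 = NA_real_, ic50_ci_low = NA_real_,
                 ic50_ci_high = NA_real_, converged = FALSE,
                 ic50_label = "error", error = conditionMessage(fit))
    } else {
      data.frame(compound_id = pairs$compound_id[i],
                 cell_line = pairs$cell_line[i],
                 top = fit$top, bottom = fit$bottom,
                 hill_slope = fit$hill_slope, ic50 = fit$ic50,
                 ic50_ci_low = fit$ic50_ci_low,
                 ic50_ci_high = fit$ic50_ci_high,
                 converged = fit$converged,
                 ic50_label = format_ic50(fit), error = NA_character_)
    }
  })
  do.call(rbind, rows)
}
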