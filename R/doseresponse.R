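#' @title Hill dose-response analysis
#' @name doseresponse
#' @description Fits the Hill inhibition model
#'   \deqn{I_{rel} = 1 - a / (1 + (IC_{50}/[C])^{n_H})}
#'   to concentration-response measurements (currents normalised to the
#'   no-compound current), estimating IC50, the Hill coefficient and the
#'   maximal inhibition `a` (optionally fixed to 1), and forms
#'   mutant/wild-type IC50 fold-change ratios.
NULL

#' Hill inhibition model
#'
#' Relative current at concentration `conc`:
#' `1 - a / (1 + (ic50/conc)^n_h)`. Decreases monotonically from 1 (no
#' compound) to `1 - a` (saturating compound); at `conc = ic50` it equals
#' `1 - a/2`.
#'
#' @param conc concentration(s), nM (> 0).
#' @param ic50 half-maximal inhibitory concentration, nM (> 0).
#' @param n_h Hill coefficient.
#' @param a maximal inhibition in (0, 1].
#' @return relative current, dimensionless.
#' @examples
#' hill_model(130, ic50 = 130, n_h = 1, a = 0.95)  # 0.525
#' @export
hill_model <- function(conc, ic50, n_h = 1, a = 1) {
  if (any(conc <= 0)) usage_error("concentrations must be > 0")
  if (ic50 <= 0) usage_error("ic50 must be > 0")
  1 - a / (1 + (ic50 / conc)^n_h)
}

#' Assemble dose-response points
#'
#' @param concentration_nM concentrations, nM (> 0).
#' @param i_rel mean relative current per concentration (>= 0).
#' @param sd optional standard deviation per point.
#' @param n_obs optional replicate count per point.
#' @return A `dose_response` data.frame.
#' @export
dose_response_points <- function(concentration_nM, i_rel, sd = NA_real_,
                                 n_obs = NA_integer_) {
  if (any(concentration_nM <= 0)) usage_error("concentrations must be > 0")
  if (any(i_rel < 0)) usage_error("i_rel must be >= 0")
  out <- data.frame(concentration_nM = concentration_nM, i_rel = i_rel,
                    sd = sd, n_obs = n_obs)
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Read dose-response points from CSV
#'
#' Expected columns: `concentration_nM`, `i_rel`, optional `sd`, `n`.
#'
#' @param file CSV path.
#' @return A `dose_response` data.frame.
#' @export
read_dose_csv <- function(file) {
  if (!file.exists(file)) usage_error(paste0("file not found: ", file))
  df <- utils::read.csv(file)
  need <- c("concentration_nM", "i_rel")
  if (!all(need %in% names(df))) {
    parse_error(paste0("dose-response CSV needs columns: ",
                       paste(need, collapse = ", ")))
  }
  dose_response_points(df$concentration_nM, df$i_rel,
                       sd = df$sd %||% NA_real_,
                       n_obs = df$n %||% NA_integer_)
}

#' Write dose-response points as CSV
#'
#' @param points a `dose_response` data.frame.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_dose_csv <- function(points, file) {
  df <- data.frame(concentration_nM = points$concentration_nM,
                   i_rel = points$i_rel,
                   sd = points$sd %||% NA_real_,
                   n = points$n_obs %||% NA_integer_)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Fit the Hill inhibition model
#'
#' Bounded Levenberg-Marquardt least squares (via
#' [minpack.lm::nls.lm()]) on `i_rel`, with multi-start initialisation:
#' IC50 starts at the concentration quartiles (log scale) and the Hill
#' coefficient at 0.7 / 1.0 / 1.4, spanning the slopes typical of these
#' antagonists. The best final residual wins; exact ties go to the lower
#' IC50. Bounds: `n_h` in [0.2, 5], `a` in (0, 1]; IC50 is fitted on the log
#' scale. Weighted least squares (1/sd^2) is available when the points carry
#' standard deviations; uniform weights are the default.
#'
#' @param points a `dose_response` data.frame (or anything with
#'   `concentration_nM` and `i_rel` columns). At least 3 distinct
#'   concentrations are required, 4 when `a` is free.
#' @param fix_a fix the maximal inhibition to 1.0 instead of fitting it.
#' @param weights "uniform" or "inverse_variance".
#' @return A `hill_fit`: `ic50` (nM), `n_h`, `a`, `a_fixed`, `se` (named
#'   standard errors of the free parameters), `converged`, `ssr`,
#'   `n_points`.
#' @examples
#' pts <- dose_response_points(c(10, 40, 130, 400, 1300, 4000),
#'                             hill_model(c(10, 40, 130, 400, 1300, 4000),
#'                                        130, 1, 0.95))
#' fit_hill(pts)
#' @export
fit_hill <- function(points, fix_a = FALSE,
                     weights = c("uniform", "inverse_variance")) {
  weights <- match.arg(weights)
  conc <- points$concentration_nM
  y <- points$i_rel
  ok <- is.finite(conc) & is.finite(y) & conc > 0
  conc <- conc[ok]
  y <- y[ok]
  n_free <- if (fix_a) 2L else 3L
  n_conc <- length(unique(conc))
  if (n_conc < n_free + 1L) {
    usage_error(sprintf(
      "need >= %d distinct concentrations for %d free parameters (got %d)",
      n_free + 1L, n_free, n_conc
    ))
  }
  w <- rep(1, length(y))
  if (weights == "inverse_variance") {
    sd <- points$sd[ok]
    if (anyNA(sd) || any(sd <= 0)) {
      usage_error("inverse-variance weighting needs positive sd for every point")
    }
    w <- 1 / sd^2
  }
  sw <- sqrt(w)

  resid_fn <- function(par) {
    a <- if (fix_a) 1.0 else par[["a"]]
    sw * (y - hill_model(conc, exp(par[["lic50"]]), par[["n_h"]], a))
  }
  lo_l <- log(min(conc)) - 10
  hi_l <- log(max(conc)) + 10
  lower <- c(lic50 = lo_l, n_h = 0.2)
  upper <- c(lic50 = hi_l, n_h = 5)
  if (!fix_a) {
    lower <- c(lower, a = 1e-4)
    upper <- c(upper, a = 1)
  }
  q <- stats::quantile(conc, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- expand.grid(lic50 = unique(log(q)), n_h = c(0.7, 1.0, 1.4))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(lic50 = starts$lic50[i], n_h = starts$n_h[i])
    if (!fix_a) par0 <- c(par0, a = min(0.95, max(0.3, 1 - min(y))))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) ||
        ssr < best$ssr - 1e-12 ||
        (abs(ssr - best$ssr) <= 1e-12 &&
           fit$par[["lic50"]] < best$fit$par[["lic50"]])) {
      best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(ic50 = NA_real_, n_h = NA_real_, a = if (fix_a) 1.0 else NA_real_,
           a_fixed = fix_a, se = NULL, converged = FALSE, ssr = NA_real_,
           n_points = length(y), weights = weights),
      class = "hill_fit"
    ))
  }
  fit <- best$fit
  converged <- fit$info %in% 1:3
  par <- fit$par
  se <- tryCatch({
    covm <- best$ssr / max(1, length(y) - n_free) *
      solve(fit$hessian)
    s <- sqrt(pmax(diag(covm), 0))
    names(s) <- names(par)
    # delta method: se on ic50 from se on log(ic50)
    c(ic50 = unname(s["lic50"]) * exp(par[["lic50"]]),
      n_h = unname(s["n_h"]),
      if (!fix_a) c(a = unname(s["a"])))
  }, error = function(e) NULL)

  structure(
    list(
      ic50 = exp(par[["lic50"]]),
      n_h = par[["n_h"]],
      a = if (fix_a) 1.0 else par[["a"]],
      a_fixed = fix_a,
      se = se,
      converged = converged,
      ssr = best$ssr,
      n_points = length(y),
      weights = weights
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> IC50 = %.4g nM, n_H = %.3g, a = %.3g%s (%s, SSR %.3g, n = %d)\n",
    x$ic50, x$n_h, x$a, if (x$a_fixed) " [fixed]" else "",
    if (x$converged) "converged" else "NOT converged", x$ssr, x$n_points))
  invisible(x)
}

#' Predicted relative current from a fit
#'
#' @param object a `hill_fit`.
#' @param conc concentrations, nM.
#' @param ... unused.
#' @return predicted `i_rel` values.
#' @export
predict.hill_fit <- function(object, conc, ...) {
  hill_model(conc, object$ic50, object$n_h, object$a)
}

#' Mutant / wild-type IC50 fold change
#'
#' @param mutant,wt converged `hill_fit` objects.
#' @return the dimensionless ratio `mutant$ic50 / wt$ic50` (full precision;
#'   use [format_fold_change()] for reporting).
#' @export
ic50_ratio <- function(mutant, wt) {
  stopifnot(inherits(mutant, "hill_fit"), inherits(wt, "hill_fit"))
  if (!isTRUE(mutant$converged) || !isTRUE(wt$converged)) {
    numeric_error("ic50_ratio requires converged fits on both sides")
  }
  mutant$ic50 / wt$ic50
}

#' Format a fold change at reporting precision
#'
#' Two significant figures, matching how fold-change ratios are commonly
#' tabulated; values are stored full-precision and rounded only for display.
#'
#' @param ratio numeric fold change(s).
#' @return character vector.
#' @examples
#' format_fold_change(c(6.58, 801.5))  # "6.6" "800"
#' @export
format_fold_change <- function(ratio) {
  formatC(signif(ratio, 2), format = "fg", flag = "#", digits = 2,
          drop0trailing = TRUE)
}
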