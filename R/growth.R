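#' Sliding-window log-linear growth-rate estimate
#'
#' Estimates the maximum specific growth rate as the steepest slope of
#' ln(OD) against time over all contiguous windows of `window_size`
#' points, the classic "easy linear" estimator for batch growth curves.
#' Non-positive OD values (blank-subtraction artifacts) are excluded
#' before windowing and counted in the result. The reported window is
#' the best-fitting one: the maximum slope among windows with
#' r-squared at least `min_r2`, falling back (flagged) to the window
#' with the highest r-squared when none qualifies. A non-positive best
#' slope is reported as `mu_max = 0` with a `non_growth` flag.
#'
#' @param times Time points (h).
#' @param od OD600 values, same length as `times`.
#' @param window_size Points per window (default 5, minimum 3).
#' @param min_r2 Window-quality floor (default 0.95).
#' @return Object of class `growth_fit` with `mu_max` (1/h), `N0`
#'   (OD at the back-extrapolated window intercept), `K` (`NA`; not
#'   estimated by this method), `method = "easylinear"`, `r2`, `window`
#'   (index range into the positive-OD series), `n_excluded`, `flags`.
#' @export
fit_easylinear <- function(times, od, window_size = 5L, min_r2 = 0.95) {
  stopifnot(length(times) == length(od), window_size >= 3L)
  keep <- !is.na(od) & od > 0
  n_excluded <- sum(!keep)
  t <- times[keep]; y <- log(od[keep])
  if (length(t) < window_size)
    stop("fewer positive OD points (", length(t),
         ") than window_size (", window_size, ")")
  n_win <- length(t) - window_size + 1L
  slope <- inter <- r2 <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- i:(i + window_size - 1L)
    f <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    slope[i] <- f$coefficients[2]
    inter[i] <- f$coefficients[1]
    ss_tot <- sum((y[idx] - mean(y[idx]))^2)
    r2[i] <- if (ss_tot == 0) NA_real_ else 1 - sum(f$residuals^2) / ss_tot
  }
  ok <- which(!is.na(r2) & r2 >= min_r2)
  flags <- character(0)
  best <- if (length(ok)) ok[which.max(slope[ok])]
          else { flags <- "low_r2"; which.max(ifelse(is.na(r2), -Inf, r2)) }
  if (all(is.na(r2))) best <- 1L  # flat series: any window, slope 0
  mu <- slope[best]
  if (!is.finite(mu) || mu <= 0) {
    mu <- 0
    flags <- c(flags, "non_growth")
  }
  structure(list(mu_max = mu, K = NA_real_, N0 = exp(inter[best]),
                 method = "easylinear", r2 = r2[best],
                 window = c(best, best + window_size - 1L),
                 n_excluded = n_excluded, flags = flags,
                 times = times, od = od, converged = TRUE),
            class = "growth_fit")
}

#' Parametric logistic growth fit
#'
#' Least-squares fit of the logistic curve
#' N(t) = K / (1 + ((K - N0) / N0) exp(-mu t)) by Levenberg-Marquardt
#' with multiple starting points (carrying capacity near the observed
#' maximum, growth rate from a log-slope scan). Series that never rise
#' above their starting density, and fits where no start converges, are
#' flagged as failures with no parameter values.
#'
#' @param times Time points (h).
#' @param od OD600 values.
#' @param n_starts Number of starting-point combinations (default 6).
#' @return Object of class `growth_fit` with `mu_max`, `K`, `N0`,
#'   `method = "logistic"`, `r2`, `converged`, `flags`.
#' @export
fit_logistic <- function(times, od, n_starts = 6L) {
  stopifnot(length(times) == length(od), length(times) >= 5L)
  failed <- structure(list(mu_max = NA_real_, K = NA_real_, N0 = NA_real_,
                           method = "logistic", r2 = NA_real_,
                           window = NULL, n_excluded = 0L,
                           flags = "fit_failed", times = times, od = od,
                           converged = FALSE),
                      class = "growth_fit")
  if (max(od) <= od[1] || max(od) <= 0) return(failed)
  df <- data.frame(t = times, y = od)
  K0 <- max(od) * c(1.0, 1.2)
  N00 <- max(min(od[od > 0], na.rm = TRUE), max(od) * 1e-4)
  mu0 <- tryCatch(
    max(fit_easylinear(times, od, window_size = min(5L, sum(od > 0)))$mu_max,
        0.05),
    error = function(e) 0.3)
  starts <- expand.grid(K = K0, mu = c(mu0, mu0 * 3, mu0 / 3))
  best <- NULL
  for (i in seq_len(min(n_starts, nrow(starts)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ K / (1 + ((K - N0) / N0) * exp(-mu * t)), data = df,
        start = list(K = starts$K[i], mu = starts$mu[i], N0 = N00),
        lower = c(K = max(od) * 0.2, mu = 1e-6, N0 = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed)
  p <- stats::coef(best$fit)
  ss_tot <- sum((od - mean(od))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - best$rss / ss_tot
  structure(list(mu_max = unname(p["mu"]), K = unname(p["K"]),
                 N0 = unname(p["N0"]), method = "logistic", r2 = r2,
                 window = NULL, n_excluded = 0L, flags = character(0),
                 times = times, od = od, converged = TRUE,
                 nls = best$fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Growth fit (", x$method, ")\n", sep = "")
  if (!x$converged) {
    cat("  fit failed:", paste(x$flags, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat("  mu_max:", signif(x$mu_max, digits), "1/h\n")
  if (!is.na(x$K)) cat("  K:     ", signif(x$K, digits), "OD600\n")
  cat("  N0:    ", signif(x$N0, digits), "OD600\n")
  if (!is.na(x$r2)) cat("  r2:    ", signif(x$r2, digits), "\n")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method coef growth_fit
coef.growth_fit <- function(object, ...) {
  c(mu_max = object$mu_max, K = object$K, N0 = object$N0)
}

#' @export
#' @method predict growth_fit
predict.growth_fit <- function(object, times = object$times, ...) {
  if (object$method == "logistic" && object$converged)
    logistic_od(times, object$mu_max, object$K, object$N0)
  else if (object$converged)
    object$N0 * exp(object$mu_max * times)
  else rep(NA_real_, length(times))
}

#' @export
#' @method plot growth_fit
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$times, x$od, xlab = "time (h)", ylab = "OD600",
                 pch = 16, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  if (x$converged) graphics::lines(tt, predict(x, tt), col = "firebrick")
  invisible(x)
}

#' @export
#' @method residuals growth_fit
residuals.growth_fit <- function(object, ...) {
  object$od - predict(object)
}

#' Two-sample comparison of fitted growth parameters
#'
#' Independent two-tailed two-sample t test on a fitted parameter
#' (e.g. mu_max or K across replicates), pooled-variance Student form by
#' default with Welch behind a flag. When both groups are constant and
#' equal the statistic is defined as t = 0, p = 1.
#'
#' @param a,b Numeric parameter vectors (at least 2 values each), or
#'   lists of `growth_fit` objects (their `mu_max` is compared).
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch (unequal-variance) form (default `FALSE`).
#' @param parameter Which coefficient to extract from `growth_fit`
#'   lists (default `"mu_max"`).
#' @return List of class `strain_comparison`: `t`, `df`, `p`,
#'   `significant`, `alpha`, `mean_a`, `mean_b`, `method`.
#' @examples
#' compare_strains(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
#' @export
compare_strains <- function(a, b, alpha = 0.05, welch = FALSE,
                            parameter = "mu_max") {
  if (is.list(a)) a <- vapply(a, function(f) f[[parameter]], numeric(1))
  if (is.list(b)) b <- vapply(b, function(f) f[[parameter]], numeric(1))
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2L, p = 1)
    } else {
      res <- list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2L, p = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch,
                        alternative = "two.sided")
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(c(res, list(significant = res$p < alpha, alpha = alpha,
                        mean_a = mean(a), mean_b = mean(b),
                        method = if (welch) "welch" else "student")),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("Two-sample %s t test: t = %.3f, df = %.3g, p = %.4g (%s at alpha = %g)\n",
              x$method, x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Fit every replicate curve in a growth table
#'
#' @param curves Growth table (`condition`, `strain`, `replicate`,
#'   `time_h`, `od600`), as from [gen_growth_curves()] or
#'   [read_growth_table()].
#' @param method `"easylinear"`, `"logistic"`, or `"both"`.
#' @param window_size Window for the log-linear method.
#' @return Data frame with one row per (condition, strain, replicate,
#'   method): fitted `mu_max`, `K`, `N0`, `r2`, `converged`.
#' @export
fit_growth_table <- function(curves, method = c("both", "easylinear",
                                                "logistic"),
                             window_size = 5L) {
  method <- match.arg(method)
  methods_run <- if (method == "both") c("easylinear", "logistic") else method
  key <- unique(curves[, c("condition", "strain", "replicate")])
  out <- list()
  for (i in seq_len(nrow(key))) {
    sel <- curves$condition == key$condition[i] &
      curves$strain == key$strain[i] & curves$replicate == key$replicate[i]
    tt <- curves$time_h[sel]; od <- curves$od600[sel]
    for (m in methods_run) {
      f <- tryCatch(
        if (m == "easylinear") fit_easylinear(tt, od, window_size)
        else fit_logistic(tt, od),
        error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        key[i, , drop = FALSE], method = m,
        mu_max = if (is.null(f)) NA_real_ else f$mu_max,
        K = if (is.null(f)) NA_real_ else f$K,
        N0 = if (is.null(f)) NA_real_ else f$N0,
        r2 = if (is.null(f)) NA_real_ else f$r2,
        converged = !is.null(f) && f$converged,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
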