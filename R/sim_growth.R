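#' Logistic growth curve
#'
#' N(t) = K / (1 + ((K - N0) / N0) * exp(-mu * t)).
#'
#' @param t Time (h); vectorized.
#' @param mu Maximum specific growth rate (1/h).
#' @param K Carrying capacity (OD600 units).
#' @param N0 Initial population (OD600 units).
#' @return Population size at `t`.
#' @export
logistic_od <- function(t, mu, K, N0) {
  K / (1 + ((K - N0) / N0) * exp(-mu * t))
}

#' Simulate replicate OD600 growth curves
#'
#' Logistic growth with additive Gaussian noise, truncated at zero --
#' the shape of optical-density time series from batch culture.
#'
#' @param mu Maximum specific growth rate (1/h); must be > 0.
#' @param K Carrying capacity (OD600); must exceed `N0`.
#' @param N0 Inoculum density (OD600); must be > 0.
#' @param times Strictly increasing time vector (h).
#' @param noise_sd Gaussian noise standard deviation (OD600 units).
#' @param n_rep Number of replicate curves.
#' @param seed Integer RNG seed.
#' @param condition,strain Labels carried into the output table.
#' @return Data frame: `condition`, `strain`, `replicate`, `time_h`,
#'   `od600`.
#' @export
gen_growth_curves <- function(mu, K, N0, times, noise_sd = 0.01,
                              n_rep = 3L, seed = 1L,
                              condition = "sim", strain = "WT") {
  stopifnot(mu > 0, K > N0, N0 > 0, n_rep >= 1)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  set.seed(seed)
  clean <- logistic_od(times, mu, K, N0)
  out <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    od <- clean + stats::rnorm(length(times), 0, noise_sd)
    data.frame(condition = condition, strain = strain, replicate = r,
               time_h = times, od600 = pmax(od, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
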