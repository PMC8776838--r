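#' Simulate an LC-MS feature table with planted siderophores
#'
#' Plants one feature per (compound, adduct) pair at the theoretical m/z,
#' optionally jittered by a Gaussian ppm error, and adds uniform decoy
#' features. Decoy m/z values within 10 ppm of any true feature are
#' rejected and redrawn, so the truth labels are unambiguous.
#'
#' @param reference Reference table ([siderophore_reference()] shape).
#' @param adducts Adduct names to plant (default `"[M+H]+"`).
#' @param n_noise Number of decoy features.
#' @param mz_range Numeric length-2 range for decoy m/z; must span every
#'   planted adduct m/z.
#' @param jitter_ppm Gaussian standard deviation of the planted-mass error
#'   in ppm (0 = exact theoretical m/z).
#' @param seed Integer RNG seed.
#' @return Data frame: `sample_id`, `mz`, `rt_min`, `intensity`, `ms2`,
#'   plus truth columns `compound` and `adduct` (`NA` for decoys).
#' @export
gen_ms_features <- function(reference = siderophore_reference(),
                            adducts = "[M+H]+", n_noise = 100L,
                            mz_range = c(100, 1200), jitter_ppm = 0,
                            seed = 1L) {
  stopifnot(length(mz_range) == 2L, mz_range[1] < mz_range[2])
  set.seed(seed)
  grid <- expand.grid(ref = seq_len(nrow(reference)), adduct = adducts,
                      stringsAsFactors = FALSE)
  theo <- mapply(function(i, a) adduct_mz(reference$neutral_mass[i], a),
                 grid$ref, grid$adduct)
  if (any(theo < mz_range[1] | theo > mz_range[2]))
    stop("mz_range must span all planted adduct m/z (",
         paste(sprintf("%.3f", range(theo)), collapse = "-"), ")")
  mz_true <- theo * (1 + stats::rnorm(length(theo), 0, jitter_ppm * 1e-6))
  truth <- data.frame(
    mz = mz_true,
    rt_min = stats::runif(length(theo), 1, 30),
    intensity = 10^stats::runif(length(theo), 4, 7),
    ms2 = reference$ms2[grid$ref],
    compound = reference$name[grid$ref],
    adduct = grid$adduct,
    stringsAsFactors = FALSE)

  if (n_noise == 0L) {
    out <- cbind(sample_id = "sim", truth, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  decoys <- numeric(0)
  while (length(decoys) < n_noise) {
    cand <- stats::runif(n_noise - length(decoys), mz_range[1], mz_range[2])
    # keep decoys at least 10 ppm from every true m/z
    ok <- vapply(cand, function(m)
      all(abs(m - theo) / theo * 1e6 > 10), logical(1))
    decoys <- c(decoys, cand[ok])
  }
  noise <- data.frame(
    mz = decoys,
    rt_min = stats::runif(n_noise, 1, 30),
    intensity = 10^stats::runif(n_noise, 3, 6),
    ms2 = NA_character_,
    compound = NA_character_, adduct = NA_character_,
    stringsAsFactors = FALSE)
  out <- rbind(truth, noise)
  out <- cbind(sample_id = "sim", out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
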