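#' Match LC-MS features against a siderophore reference
#'
#' Screens an MS1 feature table against formula-derived theoretical adduct
#' m/z values. A feature matches a (compound, adduct) pair when the relative
#' mass error |observed - theoretical| / theoretical is at most `tol_ppm`
#' parts per million. All qualifying pairs are returned, sorted by absolute
#' ppm error. The iron form is `"ferric"` for the Fe-substituted adduct and
#' `"apo"` otherwise.
#'
#' @param features Data frame with at least an `mz` column; optional
#'   `sample_id`, `rt_min`, `intensity`, `ms2` columns are carried through.
#' @param reference Reference table as from [siderophore_reference()] or
#'   [read_siderophore_table()].
#' @param tol_ppm MS1 mass tolerance in ppm (default 5).
#' @param adducts Character vector of adduct names to screen
#'   (default `"[M+H]+"`; see [supported_adducts()]).
#' @return Data frame of class `ms_match` with one row per (feature,
#'   compound, adduct) match: feature index/metadata, `compound`, `adduct`,
#'   `theoretical_mz`, `ppm_error` (signed), `iron_form`.
#' @export
match_features <- function(features, reference, tol_ppm = 5,
                           adducts = "[M+H]+") {
  stopifnot(is.data.frame(features), tol_ppm > 0)
  if (!"mz" %in% names(features)) stop("features must have an 'mz' column")
  empty <- data.frame(
    feature = integer(0), mz = numeric(0), compound = character(0),
    adduct = character(0), theoretical_mz = numeric(0),
    ppm_error = numeric(0), iron_form = character(0),
    stringsAsFactors = FALSE)
  class(empty) <- c("ms_match", "data.frame")
  if (nrow(features) == 0L) return(empty)
  if (is.null(reference) || nrow(reference) == 0L) {
    warning("empty reference table; no matches possible")
    return(empty)
  }
  theo <- expand.grid(ref = seq_len(nrow(reference)), adduct = adducts,
                      stringsAsFactors = FALSE)
  theo$mz <- mapply(function(i, a) adduct_mz(reference$neutral_mass[i], a),
                    theo$ref, theo$adduct)
  out <- lapply(seq_len(nrow(features)), function(i) {
    ppm <- (features$mz[i] - theo$mz) / theo$mz * 1e6
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) return(NULL)
    data.frame(
      feature = i, mz = features$mz[i],
      compound = reference$name[theo$ref[hit]],
      adduct = theo$adduct[hit],
      theoretical_mz = theo$mz[hit],
      ppm_error = ppm[hit],
      iron_form = ifelse(grepl("Fe", theo$adduct[hit], fixed = TRUE),
                         "ferric", "apo"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  for (extra in intersect(c("sample_id", "rt_min", "intensity"),
                          names(features)))
    out[[extra]] <- features[[extra]][out$feature]
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ms_match", "data.frame")
  out
}

#' Count confirmed MS2 fragments
#'
#' Counts how many reference fragment ions are confirmed by an observed MS2
#' peak list: a reference fragment is confirmed when at least one observed
#' peak lies within `tol_mz` Th of it. Each reference fragment is counted at
#' most once, though a single observed peak may confirm several references.
#'
#' @param observed Numeric vector of observed MS2 peak m/z, or `NULL`/empty
#'   when the feature carries no MS2 scan.
#' @param reference_fragments Numeric vector of reference fragment m/z.
#' @param tol_mz Fragment tolerance in Th (default 0.5).
#' @return List with `n_matched` (integer), `matched` (logical per reference
#'   fragment) and `no_ms2` (`TRUE` when no observed spectrum was supplied).
#' @examples
#' match_ms2(c(194, 282, 438, 565), c(194, 282, 438, 565))$n_matched  # 4
#' @export
match_ms2 <- function(observed, reference_fragments, tol_mz = 0.5) {
  stopifnot(tol_mz > 0, is.numeric(reference_fragments))
  if (is.null(observed) || length(observed) == 0L ||
      all(is.na(observed))) {
    return(list(n_matched = 0L,
                matched = rep(FALSE, length(reference_fragments)),
                no_ms2 = TRUE))
  }
  observed <- observed[!is.na(observed)]
  matched <- vapply(reference_fragments,
                    function(r) any(abs(observed - r) <= tol_mz),
                    logical(1))
  list(n_matched = sum(matched), matched = matched, no_ms2 = FALSE)
}

#' Read an MS1 feature table
#'
#' TSV with columns `mz` and optionally `sample_id`, `rt_min`, `intensity`,
#' `ms2` (semicolon-joined fragment m/z per feature).
#'
#' @param path TSV file path.
#' @return Data frame of features; `ms2` parsed into a list column
#'   `ms2_peaks` of numeric vectors.
#' @export
read_ms_features <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(tab)) stop("feature table needs an 'mz' column")
  tab$ms2_peaks <- parse_ms2_column(tab$ms2)
  tab
}

# ";"-joined m/z strings -> list of numeric vectors
parse_ms2_column <- function(x) {
  if (is.null(x)) return(vector("list", 0L))
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Full MS screen: MS1 matching plus MS2 confirmation
#'
#' Convenience wrapper: runs [match_features()] and, for every match whose
#' reference compound has recorded fragments and whose feature carries an
#' MS2 scan, adds the confirmed-fragment count.
#'
#' @inheritParams match_features
#' @param ms2_tol MS2 fragment tolerance in Th (default 0.5).
#' @return The [match_features()] result with `n_ms2_matched` and
#'   `n_ms2_reference` columns (`NA` where no reference spectrum exists).
#' @export
screen_ms_features <- function(features, reference, tol_ppm = 5,
                               adducts = "[M+H]+", ms2_tol = 0.5) {
  matches <- match_features(features, reference, tol_ppm, adducts)
  ms2_obs <- if ("ms2_peaks" %in% names(features)) features$ms2_peaks
             else parse_ms2_column(features$ms2)
  matches$n_ms2_matched <- NA_integer_
  matches$n_ms2_reference <- NA_integer_
  if (nrow(matches) == 0L) return(matches)
  refs <- parse_ms2_column(reference$ms2)
  names(refs) <- reference$name
  for (i in seq_len(nrow(matches))) {
    frag <- refs[[matches$compound[i]]]
    if (length(frag) == 0L) next
    obs <- if (length(ms2_obs)) ms2_obs[[matches$feature[i]]] else numeric(0)
    matches$n_ms2_reference[i] <- length(frag)
    matches$n_ms2_matched[i] <- match_ms2(obs, frag, ms2_tol)$n_matched
  }
  matches
}
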