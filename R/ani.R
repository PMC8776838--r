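#' MAG assembly container
#'
#' A genome assembly with its CheckM-style completeness estimate, the
#' unit of ANI comparison and species grouping.
#'
#' @param mag_id Assembly identifier.
#' @param sequences Contig sequences ([Biostrings::DNAStringSet] or
#'   named character vector).
#' @param completeness Estimated completeness fraction in (0, 1\].
#' @return List of class `mag_assembly`: `mag_id`, `sequences`,
#'   `total_length`, `completeness`.
#' @export
mag_assembly <- function(mag_id, sequences, completeness = 1) {
  if (inherits(sequences, "sim_genome")) sequences <- sequences$sequence
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  stopifnot(completeness > 0, completeness <= 1)
  structure(list(mag_id = mag_id, sequences = sequences,
                 total_length = sum(Biostrings::width(sequences)),
                 completeness = completeness),
            class = "mag_assembly")
}

#' @export
print.mag_assembly <- function(x, ...) {
  cat("MAG", x$mag_id, "-", length(x$sequences), "contig(s),",
      x$total_length, "bp, completeness", x$completeness, "\n")
  invisible(x)
}

.as_contigs <- function(x) {
  if (inherits(x, "mag_assembly")) return(x$sequences)
  if (inherits(x, "sim_genome")) return(x$sequence)
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(x)
}

#' Cut a genome into non-overlapping fragments
#'
#' Consecutive non-overlapping windows of `fragment_length` bp per
#' contig; a trailing remainder shorter than `fragment_length` is
#' discarded. This is the fragmentation scheme of fragment-based ANI
#' (default 1500 bp).
#'
#' @param sequences Contigs (any form accepted by [mag_assembly()]).
#' @param fragment_length Window size in bp.
#' @return [Biostrings::DNAStringSet] of fragments, named
#'   `<contig>|<start>` (1-based window start).
#' @export
fragment_genome <- function(sequences, fragment_length = 1500L) {
  stopifnot(fragment_length > 0)
  contigs <- .as_contigs(sequences)
  out <- list()
  for (i in seq_along(contigs)) {
    len <- Biostrings::width(contigs)[i]
    n <- len %/% fragment_length
    if (n == 0L) next
    starts <- (seq_len(n) - 1L) * fragment_length + 1L
    frags <- Biostrings::DNAStringSet(contigs[[i]], start = starts,
                                      width = fragment_length)
    names(frags) <- sprintf("%s|%d", names(contigs)[i], starts)
    out[[length(out) + 1L]] <- frags
  }
  if (!length(out)) return(Biostrings::DNAStringSet())
  do.call(c, out)
}

#' Map one fragment onto a reference genome
#'
#' Seed-and-extend placement: exact `kmer_size`-mers sampled along the
#' fragment are located in the reference ([Biostrings::matchPattern]),
#' candidate diagonals are ranked by seed votes, and the best diagonals
#' are scored by gap-free comparison (identity = matching positions /
#' fragment length). When the best gap-free identity falls below
#' `min_identity` and `band > 0`, a banded local-in-global alignment
#' ([Biostrings::pairwiseAlignment]) around the best diagonal is tried
#' and identity becomes matches / alignment columns (gaps included).
#' A fragment with no shared seed, or best identity below
#' `min_identity`, is unmapped.
#'
#' @param fragment A [Biostrings::DNAString], single-sequence set, or
#'   character string.
#' @param reference Reference contigs.
#' @param kmer_size Seed length (default 16).
#' @param min_identity Mapping floor in \[0, 1\] (default 0.80).
#' @param band Half-width (bp) of the reference window slack for the
#'   gapped fallback (default 32); 0 disables the fallback.
#' @param n_probes Number of seed k-mers sampled evenly along the
#'   fragment (default 15).
#' @return List: `mapped` (logical), `identity` (fraction, `NA` when
#'   unmapped), `contig`, `ref_start` (diagonal of the best placement).
#' @export
map_fragment <- function(fragment, reference, kmer_size = 16L,
                         min_identity = 0.80, band = 32L, n_probes = 15L) {
  if (methods::is(fragment, "DNAStringSet")) fragment <- fragment[[1]]
  if (is.character(fragment)) fragment <- Biostrings::DNAString(fragment)
  contigs <- .as_contigs(reference)
  nf <- length(fragment)
  stopifnot(nf >= kmer_size)
  offsets <- unique(round(seq(1L, nf - kmer_size + 1L,
                              length.out = min(n_probes, nf - kmer_size + 1L))))
  unmapped <- list(mapped = FALSE, identity = NA_real_,
                   contig = NA_character_, ref_start = NA_integer_)
  # collect (contig, diagonal) votes from exact seed matches
  votes <- list()
  for (ci in seq_along(contigs)) {
    subj <- contigs[[ci]]
    for (off in offsets) {
      probe <- Biostrings::subseq(fragment, off, off + kmer_size - 1L)
      m <- Biostrings::matchPattern(probe, subj)
      if (length(m) == 0L || length(m) > 50L) next  # absent or repetitive seed
      votes[[length(votes) + 1L]] <- data.frame(
        contig = ci, diag = BiocGenerics::start(m) - off + 1L)
    }
  }
  if (!length(votes)) return(unmapped)
  votes <- do.call(rbind, votes)
  key <- paste(votes$contig, votes$diag)
  tab <- sort(table(key), decreasing = TRUE)
  best <- list(identity = -1)
  for (k in names(tab)[seq_len(min(3L, length(tab)))]) {
    parts <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    ci <- parts[1]; diag <- parts[2]
    subj <- contigs[[ci]]
    if (diag >= 1L && diag + nf - 1L <= length(subj)) {
      ed <- Biostrings::neditStartingAt(fragment, subj, starting.at = diag)
      ident <- 1 - ed / nf
    } else ident <- -1  # placement runs off the contig; leave to fallback
    if (ident > best$identity)
      best <- list(identity = ident, contig = ci, diag = diag)
  }
  if (best$identity < min_identity && band > 0 && !is.null(best$contig)) {
    subj <- contigs[[best$contig]]
    ws <- max(1L, best$diag - band)
    we <- min(length(subj), best$diag + nf - 1L + band)
    al <- Biostrings::pairwiseAlignment(
      fragment, Biostrings::subseq(subj, ws, we), type = "global-local")
    cols <- Biostrings::nchar(al)  # alignment columns incl. internal gaps
    ident <- Biostrings::nmatch(al) / cols
    if (ident > best$identity) best$identity <- ident
  }
  if (is.null(best$contig) || best$identity < min_identity) return(unmapped)
  list(mapped = TRUE, identity = best$identity,
       contig = names(contigs)[best$contig], ref_start = best$diag)
}

#' Fragment-based average nucleotide identity
#'
#' Cuts the query into `fragment_length` bp fragments, maps each onto the
#' reference with [map_fragment()], and averages the identity of the
#' mapped fragments: ANI = 100 x mean identity, with the aligned fraction
#' (mapped / total fragments) reported alongside. The result is flagged
#' undefined when the query yields no fragments or none map.
#'
#' @param query,reference Genomes (any form accepted by
#'   [mag_assembly()]).
#' @param fragment_length Fragment size in bp (default 1500).
#' @param kmer_size,min_identity,band Passed to [map_fragment()].
#' @return One-row data frame of class `ani_result`: `query`,
#'   `reference`, `ani` (percent, `NA` when undefined),
#'   `aligned_fraction`, `n_fragments`, `n_mapped`, `undefined`.
#' @export
compute_ani <- function(query, reference, fragment_length = 1500L,
                        kmer_size = 16L, min_identity = 0.80, band = 32L) {
  qid <- if (inherits(query, "mag_assembly")) query$mag_id
         else if (inherits(query, "sim_genome")) query$mag_id else "query"
  rid <- if (inherits(reference, "mag_assembly")) reference$mag_id
         else if (inherits(reference, "sim_genome")) reference$mag_id
         else "reference"
  frags <- fragment_genome(query, fragment_length)
  refc <- .as_contigs(reference)
  n <- length(frags)
  ident <- rep(NA_real_, n)
  mapped <- logical(n)
  for (i in seq_len(n)) {
    m <- map_fragment(frags[[i]], refc, kmer_size, min_identity, band)
    mapped[i] <- m$mapped
    if (m$mapped) ident[i] <- m$identity
  }
  undefined <- n == 0L || !any(mapped)
  out <- data.frame(
    query = qid, reference = rid,
    ani = if (undefined) NA_real_ else 100 * mean(ident[mapped]),
    aligned_fraction = if (n == 0L) NA_real_ else mean(mapped),
    n_fragments = n, n_mapped = sum(mapped), undefined = undefined,
    stringsAsFactors = FALSE)
  class(out) <- c("ani_result", "data.frame")
  out
}

#' All-pairs directional ANI
#'
#' Runs [compute_ani()] in both directions for every pair of MAGs.
#'
#' @param mags Named list of genomes (any form accepted by
#'   [mag_assembly()]); names become MAG ids when the elements carry
#'   none.
#' @param ... Passed to [compute_ani()].
#' @return Data frame of directional results (both orders per pair).
#' @export
ani_matrix <- function(mags, ...) {
  ids <- names(mags)
  if (is.null(ids)) stop("mags must be a named list")
  out <- list()
  for (i in seq_along(mags)) for (j in seq_along(mags)) {
    if (i == j) next
    r <- compute_ani(mags[[i]], mags[[j]], ...)
    r$query <- ids[i]; r$reference <- ids[j]
    out[[length(out) + 1L]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group MAGs into species at an ANI threshold
#'
#' Builds an undirected graph with an edge between two MAGs when the
#' larger of the two directional ANI values strictly exceeds
#' `threshold` (percent), and takes connected components as species
#' (single linkage, the default) or complete-linkage groups cut at the
#' same threshold. Pairs with no ANI value are treated as unlinked with
#' a warning.
#'
#' @param mag_ids Character vector of all MAG ids (so isolated MAGs
#'   become singletons).
#' @param ani Data frame of directional results from [ani_matrix()] /
#'   [compute_ani()].
#' @param threshold Species boundary in percent (default 95).
#' @param linkage `"single"` (connected components) or `"complete"`.
#' @return Data frame of class `species_groups`: `mag_id`, `species`
#'   (integer group label; each MAG in exactly one group).
#' @export
cluster_species <- function(mag_ids, ani, threshold = 95,
                            linkage = c("single", "complete")) {
  stopifnot(threshold > 0, threshold <= 100)
  linkage <- match.arg(linkage)
  n <- length(mag_ids)
  sym <- matrix(NA_real_, n, n, dimnames = list(mag_ids, mag_ids))
  diag(sym) <- 100
  if (nrow(ani)) {
    for (r in seq_len(nrow(ani))) {
      a <- ani$query[r]; b <- ani$reference[r]
      if (!(a %in% mag_ids) || !(b %in% mag_ids)) next
      v <- ani$ani[r]
      if (is.na(v)) next
      cur <- sym[a, b]
      sym[a, b] <- sym[b, a] <- if (is.na(cur)) v else max(cur, v)
    }
  }
  miss <- which(is.na(sym) & upper.tri(sym), arr.ind = TRUE)
  if (nrow(miss)) {
    warning(nrow(miss), " MAG pair(s) without an ANI value treated as unlinked")
    sym[is.na(sym)] <- 0
  }
  if (linkage == "single") {
    adj <- sym > threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    membership <- igraph::components(g)$membership
  } else {
    hc <- stats::hclust(stats::as.dist(100 - sym), method = "complete")
    membership <- stats::cutree(hc, h = 100 - threshold - 1e-9)
  }
  out <- data.frame(mag_id = mag_ids,
                    species = as.integer(membership[mag_ids]),
                    stringsAsFactors = FALSE)
  class(out) <- c("species_groups", "data.frame")
  out
}

#' Estimate the complete genome length of a species
#'
#' Pools the member MAGs of one species into a single genome-length
#' estimate used for species-level RPKM normalization. The default
#' `completeness_corrected` mode averages length / completeness, which
#' estimates the length of the complete genome each partial MAG
#' represents. The `as_printed` mode averages length x completeness,
#' the literal arithmetic some workflows state; it under-estimates for
#' incomplete MAGs and is retained behind this flag.
#'
#' @param members Data frame with columns `length` (bp) and
#'   `completeness` (fraction), or a list of [mag_assembly()] objects.
#' @param mode `"completeness_corrected"` (default) or `"as_printed"`.
#' @return Estimated species genome length in bp.
#' @export
estimate_species_genome_length <- function(members,
                                           mode = c("completeness_corrected",
                                                    "as_printed")) {
  mode <- match.arg(mode)
  if (!is.data.frame(members)) {
    members <- data.frame(
      length = vapply(members, function(m) m$total_length, numeric(1)),
      completeness = vapply(members, function(m) m$completeness, numeric(1)))
  }
  stopifnot(nrow(members) >= 1L,
            all(!is.na(members$length)), all(!is.na(members$completeness)))
  if (mode == "completeness_corrected") {
    if (any(members$completeness <= 0))
      stop("completeness must be > 0 for completeness-corrected estimation")
    mean(members$length / members$completeness)
  } else {
    mean(members$length * members$completeness)
  }
}
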