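#' Filter read alignments by identity and aligned fraction
#'
#' Applies the competitive-recruitment filter: keep mapped records whose
#' gap-compensated identity, 1 - NM / aligned_length, is at least
#' `min_identity` and whose aligned fraction of the read,
#' aligned_length / read_length, is at least `min_aligned_fraction`.
#' Both boundaries are inclusive -- the filter removes records strictly
#' below the thresholds. Defaults reproduce the 95% identity / 75%
#' alignment rule used for marine MAG recruitment.
#'
#' @param records Alignment records as from [read_sam_alignments()].
#' @param min_identity Identity floor in (0, 1\] (default 0.95).
#' @param min_aligned_fraction Aligned-fraction floor in (0, 1\]
#'   (default 0.75).
#' @param on_missing_nm `"drop"` (default; drops such records with a
#'   warning) or `"error"` for records lacking an edit distance.
#' @return The retained subset of `records`, with `identity` and
#'   `aligned_fraction` columns added.
#' @export
filter_alignments <- function(records, min_identity = 0.95,
                              min_aligned_fraction = 0.75,
                              on_missing_nm = c("drop", "error")) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_aligned_fraction > 0, min_aligned_fraction <= 1)
  on_missing_nm <- match.arg(on_missing_nm)
  records <- records[records$mapped, , drop = FALSE]
  bad <- is.na(records$edit_distance)
  if (any(bad)) {
    if (on_missing_nm == "error")
      stop(sum(bad), " mapped record(s) lack an NM edit distance")
    warning(sum(bad), " mapped record(s) without NM dropped")
    records <- records[!bad, , drop = FALSE]
  }
  records$identity <- 1 - records$edit_distance / records$aligned_length
  records$aligned_fraction <- records$aligned_length / records$read_length
  keep <- records$identity >= min_identity &
    records$aligned_fraction >= min_aligned_fraction
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count retained reads per contig and per MAG
#'
#' Counts primary alignments per contig (secondary and supplementary
#' records are excluded: competitive mapping assigns each read once) and
#' sums contig counts into MAG totals via the contig-to-MAG map. Contigs
#' absent from the map are tallied under `"unassigned"` with a warning.
#'
#' @param records Filtered alignment records.
#' @param contig_map Data frame with columns `contig_id`, `mag_id`.
#' @return List: `contig_counts` (data frame `contig_id`, `mag_id`,
#'   `count`), `mag_counts` (data frame `mag_id`, `count`),
#'   `n_unassigned`.
#' @export
count_per_contig <- function(records, contig_map) {
  stopifnot(all(c("contig_id", "mag_id") %in% names(contig_map)))
  if (anyDuplicated(contig_map$contig_id))
    stop("each contig may be assigned to at most one MAG")
  primary <- records[!records$secondary, , drop = FALSE]
  tab <- table(primary$contig_id)
  contig_counts <- data.frame(contig_id = names(tab),
                              count = as.integer(tab),
                              stringsAsFactors = FALSE)
  contig_counts$mag_id <- contig_map$mag_id[
    match(contig_counts$contig_id, contig_map$contig_id)]
  n_unassigned <- sum(contig_counts$count[is.na(contig_counts$mag_id)])
  if (n_unassigned > 0) {
    warning(n_unassigned, " read(s) on contig(s) absent from the MAG map ",
            "counted as unassigned")
    contig_counts$mag_id[is.na(contig_counts$mag_id)] <- "unassigned"
  }
  agg <- stats::aggregate(count ~ mag_id, contig_counts, sum)
  list(contig_counts = contig_counts[, c("contig_id", "mag_id", "count")],
       mag_counts = agg, n_unassigned = n_unassigned)
}

#' Recruitment RPKM
#'
#' Reads per kbp of genome per Gbp of metagenome:
#' `count / ((genome_length / 1e3) * (metagenome_size / 1e9))`.
#'
#' @param count Retained read count (vectorized).
#' @param genome_length Genome (or contig) length in bp.
#' @param metagenome_size Total bases sequenced in the sample (bp).
#' @return RPKM value(s).
#' @examples
#' rpkm(1000, 1e6, 1e9)  # 1.0
#' @export
rpkm <- function(count, genome_length, metagenome_size) {
  if (any(genome_length <= 0) || any(metagenome_size <= 0))
    stop("genome_length and metagenome_size must be positive")
  count / ((genome_length / 1e3) * (metagenome_size / 1e9))
}

#' Species-pooled RPKM
#'
#' Sums the retained read counts of every MAG in a species and
#' normalizes by the estimated complete species genome length (see
#' [estimate_species_genome_length()]), so reads split among redundant
#' MAG assemblies of one species are recovered into a single abundance.
#'
#' @param member_mag_ids MAG ids of the species members.
#' @param mag_counts Data frame `mag_id`, `count` (MAGs with no
#'   retained reads may be absent; they count 0).
#' @param estimated_length Estimated complete species genome length (bp).
#' @param metagenome_size Total bases in the sample (bp).
#' @param require_all When `TRUE` (default), error if a member MAG is
#'   missing from `mag_counts` *and* the table carries no evidence the
#'   sample was counted (empty table).
#' @return Species RPKM value.
#' @export
pooled_species_rpkm <- function(member_mag_ids, mag_counts,
                                estimated_length, metagenome_size,
                                require_all = TRUE) {
  stopifnot(length(member_mag_ids) >= 1L, estimated_length > 0)
  if (require_all && nrow(mag_counts) == 0L && length(member_mag_ids))
    stop("no counts supplied for species members: ",
         paste(member_mag_ids, collapse = ", "))
  idx <- match(member_mag_ids, mag_counts$mag_id)
  counts <- mag_counts$count[idx]
  counts[is.na(counts)] <- 0
  rpkm(sum(counts), estimated_length, metagenome_size)
}

#' Per-sample abundance profile from SAM recruitment
#'
#' End-to-end convenience wrapper: parse one sample's competitive
#' alignments, filter, count, and normalize to per-MAG RPKM, optionally
#' pooling species.
#'
#' @param sam Path to the sample's SAM file.
#' @param contig_map Data frame `contig_id`, `mag_id`.
#' @param mag_lengths Named numeric vector of MAG lengths (bp).
#' @param metagenome_size Total bases in the sample (bp).
#' @param sample_id Sample label for the output.
#' @param min_identity,min_aligned_fraction Filter thresholds.
#' @param species Optional [cluster_species()] table (`mag_id`,
#'   `species`).
#' @param species_lengths Optional named vector of estimated complete
#'   genome length per species label (required with `species`).
#' @return List of class `abundance_profile`: `sample_id`,
#'   `contig_counts`, `mag_table` (mag_id, count, length, rpkm),
#'   `species_table` (species, count, estimated_length, rpkm) or
#'   `NULL`, `metagenome_size`, `n_unassigned`.
#' @export
abundance_profile <- function(sam, contig_map, mag_lengths,
                              metagenome_size, sample_id = "sample",
                              min_identity = 0.95,
                              min_aligned_fraction = 0.75,
                              species = NULL, species_lengths = NULL) {
  aln <- read_sam_alignments(sam)
  kept <- filter_alignments(aln$records, min_identity, min_aligned_fraction)
  counts <- count_per_contig(kept, contig_map)
  mags <- counts$mag_counts[counts$mag_counts$mag_id != "unassigned", ,
                            drop = FALSE]
  # MAGs with zero retained reads still appear with rpkm 0
  all_mags <- unique(contig_map$mag_id)
  mag_table <- data.frame(mag_id = all_mags,
                          count = mags$count[match(all_mags, mags$mag_id)],
                          stringsAsFactors = FALSE)
  mag_table$count[is.na(mag_table$count)] <- 0L
  mag_table$length <- mag_lengths[mag_table$mag_id]
  if (any(is.na(mag_table$length)))
    stop("missing length for MAG(s): ",
         paste(mag_table$mag_id[is.na(mag_table$length)], collapse = ", "))
  mag_table$rpkm <- rpkm(mag_table$count, mag_table$length, metagenome_size)
  species_table <- NULL
  if (!is.null(species)) {
    if (is.null(species_lengths))
      stop("species_lengths required when pooling species")
    species_table <- do.call(rbind, lapply(
      sort(unique(species$species)), function(sp) {
        members <- species$mag_id[species$species == sp]
        est <- species_lengths[as.character(sp)]
        data.frame(species = sp,
                   count = sum(mag_table$count[mag_table$mag_id %in% members]),
                   estimated_length = unname(est),
                   rpkm = pooled_species_rpkm(members, mag_table, est,
                                              metagenome_size),
                   stringsAsFactors = FALSE)
      }))
  }
  structure(list(sample_id = sample_id, contig_counts = counts$contig_counts,
                 mag_table = mag_table, species_table = species_table,
                 metagenome_size = metagenome_size,
                 n_unassigned = counts$n_unassigned),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("Abundance profile for", x$sample_id, "-",
      sum(x$mag_table$count), "retained reads over",
      nrow(x$mag_table), "MAG(s);", x$n_unassigned, "unassigned\n")
  print(x$mag_table, ...)
  if (!is.null(x$species_table)) {
    cat("Species-pooled:\n")
    print(x$species_table, ...)
  }
  invisible(x)
}
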