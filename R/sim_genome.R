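#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults follow
#' the study conditions the pipeline is designed for: a petrobactin-like
#' cluster of two NIS synthases (pfam04183) and one 3-dehydroshikimate
#' dehydratase (pfam01261) planted among unannotated background genes,
#' short-read recruitment at ~10x, and OD600 noise typical of a bench
#' spectrophotometer.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param genome_length Genome length (bp).
#' @param n_genes Number of protein-coding genes to place.
#' @param cluster_spec Data frame with columns `role` and `pfam`
#'   (`NA` for unlabeled accessory genes) describing the planted cluster in
#'   gene order; zero rows plants no cluster.
#' @param substitution_rate Per-site substitution probability for
#'   [mutate_genome()] workflows, in \[0, 1\].
#' @param read_length Read length (bp) for [gen_reads()].
#' @param depth Mean fold coverage for [gen_reads()].
#' @param error_rate Per-base sequencing error probability.
#' @param ms_noise_peaks Number of decoy MS features for [gen_ms_features()].
#' @param od_noise_sd OD600 noise standard deviation for
#'   [gen_growth_curves()].
#' @param completeness MAG completeness fraction in (0, 1\].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       n_genes = 40L,
                       cluster_spec = petrobactin_cluster_spec(),
                       substitution_rate = 0.03,
                       read_length = 100L,
                       depth = 10,
                       error_rate = 0,
                       ms_noise_peaks = 100L,
                       od_noise_sd = 0.01,
                       completeness = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            completeness > 0, completeness <= 1,
            genome_length > 0, n_genes >= 0, read_length > 0)
  if (!is.data.frame(cluster_spec) ||
      !all(c("role", "pfam") %in% names(cluster_spec)))
    stop("cluster_spec must be a data frame with 'role' and 'pfam' columns")
  if (n_genes < nrow(cluster_spec))
    stop("n_genes must be at least the number of cluster genes")
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes), cluster_spec = cluster_spec,
    substitution_rate = substitution_rate,
    read_length = as.integer(read_length), depth = depth,
    error_rate = error_rate, ms_noise_peaks = as.integer(ms_noise_peaks),
    od_noise_sd = od_noise_sd, completeness = completeness
  ), class = "sim_config")
}

#' Default petrobactin-like cluster layout
#'
#' Two NIS siderophore synthases (asbA/asbB analogs, pfam04183) and one
#' 3-dehydroshikimate dehydratase (asbF analog, pfam01261), the diagnostic
#' gene complement of a complete petrobactin-like pathway, plus one
#' unlabeled accessory gene mimicking a neighboring transporter.
#'
#' @return Data frame with columns `role`, `pfam`.
#' @export
petrobactin_cluster_spec <- function() {
  data.frame(
    role = c("asbA", "asbB", "asbF", "accessory"),
    pfam = c("pfam04183", "pfam04183", "pfam01261", NA),
    stringsAsFactors = FALSE)
}

.dna_bases <- c("A", "C", "G", "T")

#' Simulate a genome with a planted gene cluster
#'
#' Draws a random genome, places `n_genes` genes (lengths 300-1500 bp,
#' intergenic gaps 20-200 bp) along a single contig, and plants the
#' `cluster_spec` genes as a consecutive run at a random position in gene
#' order. Pfam-labeled cluster genes get strong domain hits in the returned
#' hit table. Everything needed to score downstream recovery is in `truth`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome`:
#'   `sequence` (named [Biostrings::DNAStringSet]), `genes` (data frame:
#'   `gene_id`, `contig_id`, `start`, `end`, `strand`, `ordinal`, `role`,
#'   `pfam`), `hits` (data frame: `gene_id`, `pfam_accession`, `evalue`,
#'   `bitscore`), `truth` (planted locus coordinates, member gene ids,
#'   completeness), and `mag_id`.
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  spec <- config$cluster_spec
  gene_len <- if (n) sample(seq(300L, 1500L, by = 3L), n, replace = TRUE)
              else integer(0)
  gap <- if (n) sample(20:200, n, replace = TRUE) else integer(0)
  span <- sum(gene_len) + sum(gap)
  if (span > config$genome_length)
    stop("genome_length (", config$genome_length,
         ") too small for ", n, " genes spanning ", span, " bp")
  offset <- sample.int(config$genome_length - span + 1L, 1L)
  starts <- offset + cumsum(c(0L, head(gene_len + gap, -1L)))
  ends <- starts + gene_len - 1L
  contig <- "contig_1"
  genes <- data.frame(
    gene_id = sprintf("gene_%03d", seq_len(n)),
    contig_id = rep(contig, n),
    start = starts, end = ends,
    strand = if (n) sample(c("+", "-"), n, replace = TRUE) else character(0),
    ordinal = seq_len(n),
    role = rep(NA_character_, n), pfam = rep(NA_character_, n),
    stringsAsFactors = FALSE)

  truth <- list(has_cluster = nrow(spec) > 0L, completeness = config$completeness)
  if (nrow(spec) > 0L) {
    cstart <- sample.int(n - nrow(spec) + 1L, 1L)
    idx <- cstart:(cstart + nrow(spec) - 1L)
    genes$role[idx] <- spec$role
    genes$pfam[idx] <- spec$pfam
    carriers <- idx[!is.na(spec$pfam)]
    truth$cluster_gene_ids <- genes$gene_id[idx]
    truth$carrier_gene_ids <- genes$gene_id[carriers]
    truth$locus_start <- min(genes$start[idx])
    truth$locus_end <- max(genes$end[idx])
    truth$contig_id <- contig
  }

  seq <- paste(sample(.dna_bases, config$genome_length, replace = TRUE),
               collapse = "")
  sequence <- Biostrings::DNAStringSet(stats::setNames(seq, contig))

  labeled <- which(!is.na(genes$pfam))
  hits <- data.frame(
    gene_id = genes$gene_id[labeled],
    pfam_accession = genes$pfam[labeled],
    evalue = 10^stats::runif(length(labeled), -60, -20),
    bitscore = stats::runif(length(labeled), 100, 400),
    stringsAsFactors = FALSE)

  structure(list(mag_id = sprintf("simMAG_%d", config$seed),
                 sequence = sequence, genes = genes, hits = hits,
                 truth = truth, config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Simulated genome", x$mag_id, "-", sum(Biostrings::width(x$sequence)),
      "bp,", nrow(x$genes), "genes,",
      sum(!is.na(x$genes$pfam)), "pfam-labeled\n")
  invisible(x)
}

#' Point-mutate a genome
#'
#' Substitutes each position independently with probability `rate`; the
#' replacement base is drawn uniformly from the three alternatives, so a
#' "substituted" position never retains its original base. Indels are off
#' by default, keeping position-wise identity an exact oracle for ANI;
#' `indel_rate > 0` additionally applies single-base insertions/deletions.
#'
#' @param genome Character string, [Biostrings::DNAStringSet] (first
#'   sequence used per contig, all contigs mutated), or `sim_genome`.
#' @param rate Per-site substitution probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param indel_rate Per-site probability of a 1 bp insertion or deletion
#'   (half each); default 0.
#' @return Same container type as the input, with attribute
#'   `n_substituted` (total substituted positions over all contigs).
#' @export
mutate_genome <- function(genome, rate, seed = 1L, indel_rate = 0) {
  stopifnot(rate >= 0, rate <= 1, indel_rate >= 0, indel_rate < 1)
  if (inherits(genome, "sim_genome")) {
    out <- genome
    out$sequence <- mutate_genome(genome$sequence, rate, seed, indel_rate)
    attr(out, "n_substituted") <- attr(out$sequence, "n_substituted")
    return(out)
  }
  is_set <- methods::is(genome, "DNAStringSet")
  seqs <- if (is_set) as.character(genome) else as.character(genome)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    warning("empty genome; returning empty output")
    return(genome)
  }
  set.seed(seed)
  total_sub <- 0L
  mutated <- vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    if (length(hit)) {
      # uniform over the 3 alternative bases
      alt <- vapply(b[hit], function(x) sample(setdiff(.dna_bases, x), 1L), "")
      b[hit] <- alt
    }
    total_sub <<- total_sub + length(hit)
    if (indel_rate > 0) {
      ind <- which(stats::runif(length(b)) < indel_rate)
      if (length(ind)) {
        del <- ind[stats::runif(length(ind)) < 0.5]
        ins <- setdiff(ind, del)
        pieces <- b
        pieces[ins] <- paste0(b[ins],
                              sample(.dna_bases, length(ins), replace = TRUE))
        pieces[del] <- ""
        b <- pieces
      }
    }
    paste(b, collapse = "")
  }, "")
  out <- if (is_set) Biostrings::DNAStringSet(stats::setNames(mutated, names(genome)))
         else unname(mutated)
  attr(out, "n_substituted") <- total_sub
  out
}

#' Simulate reads with truth alignments
#'
#' Draws reads uniformly from the genome (forward strand), applies
#' independent per-base errors, and emits the true alignment of every read
#' as a SAM record: 1-based POS, all-match CIGAR, and an NM tag equal to
#' the number of injected errors. The read count is Poisson with mean
#' `depth * genome_length / read_length`.
#'
#' @param genome Character string, [Biostrings::DNAStringSet] (single
#'   contig), or `sim_genome`.
#' @param read_length Read length (bp); must not exceed the genome length.
#' @param depth Mean fold coverage; `depth <= 0` yields an empty read set.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer RNG seed.
#' @return List of class `sim_reads`: `reads`
#'   ([Biostrings::DNAStringSet]), `sam` (data frame: `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `seq`, `nm`), `contig_lengths`
#'   (named integer), `truth` (`positions`, `n_errors` per read).
#' @export
gen_reads <- function(genome, read_length, depth, error_rate = 0, seed = 1L) {
  if (inherits(genome, "sim_genome")) {
    contig <- names(genome$sequence)[1]
    s <- as.character(genome$sequence[[1]])
  } else if (methods::is(genome, "DNAStringSet")) {
    contig <- if (!is.null(names(genome))) names(genome)[1] else "contig_1"
    s <- as.character(genome[[1]])
  } else {
    contig <- "contig_1"
    s <- as.character(genome)
  }
  L <- nchar(s)
  stopifnot(read_length <= L)
  set.seed(seed)
  n_reads <- if (depth <= 0) 0L else stats::rpois(1L, depth * L / read_length)
  empty <- list(
    reads = Biostrings::DNAStringSet(),
    sam = data.frame(qname = character(0), flag = integer(0),
                     rname = character(0), pos = integer(0),
                     mapq = integer(0), cigar = character(0),
                     seq = character(0), nm = integer(0),
                     stringsAsFactors = FALSE),
    contig_lengths = stats::setNames(L, contig),
    truth = list(positions = integer(0), n_errors = integer(0)))
  class(empty) <- "sim_reads"
  if (n_reads == 0L) return(empty)
  pos <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  base <- strsplit(s, "", fixed = TRUE)[[1]]
  n_err <- integer(n_reads)
  reads <- vapply(seq_len(n_reads), function(i) {
    r <- base[pos[i]:(pos[i] + read_length - 1L)]
    if (error_rate > 0) {
      e <- which(stats::runif(read_length) < error_rate)
      if (length(e))
        r[e] <- vapply(r[e], function(x) sample(setdiff(.dna_bases, x), 1L), "")
      n_err[i] <<- length(e)
    }
    paste(r, collapse = "")
  }, "")
  qname <- sprintf("read_%06d", seq_len(n_reads))
  out <- empty
  out$reads <- Biostrings::DNAStringSet(stats::setNames(reads, qname))
  out$sam <- data.frame(
    qname = qname, flag = 0L, rname = contig, pos = pos, mapq = 60L,
    cigar = sprintf("%dM", read_length), seq = reads, nm = n_err,
    stringsAsFactors = FALSE)
  out$truth <- list(positions = pos, n_errors = n_err)
  out
}
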