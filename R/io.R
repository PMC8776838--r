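#' Write genome sequences as FASTA
#'
#' @param x `sim_genome`, [Biostrings::DNAStringSet], or named character
#'   vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  if (inherits(x, "sim_genome")) x <- x$sequence
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA path.
#' @return [Biostrings::DNAStringSet] (names truncated at first space).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write gene calls as GFF3
#'
#' One `CDS` feature per gene, 1-based inclusive coordinates, with the
#' gene identifier in the `ID` attribute -- the dialect produced by
#' standard prokaryotic gene callers.
#'
#' @param genes Gene table (`gene_id`, `contig_id`, `start`, `end`,
#'   `strand`) or a `sim_genome`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  if (inherits(genes, "sim_genome")) genes <- genes$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "sidescan"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read gene calls from GFF3
#'
#' Keeps CDS/gene features, takes `gene_id` from the `ID` attribute, and
#' assigns ordinals by start position within each contig.
#'
#' @param path GFF3 path.
#' @return Gene table: `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `ordinal`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  genes <- data.frame(
    gene_id = as.character(gr$ID),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "+"
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                              FUN = seq_along)
  rownames(genes) <- NULL
  genes
}

#' Write domain hits in HMMER domtblout layout
#'
#' Emits the per-domain tabular format: whitespace-aligned columns with
#' '#' comment lines; target name in column 1, query (profile) accession
#' in column 5, full-sequence E-value in column 7, full-sequence bit
#' score in column 8. Columns not carried by the hit table are filled
#' with placeholders.
#'
#' @param hits Hit table (`gene_id`, `pfam_accession`, `evalue`,
#'   `bitscore`) or a `sim_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  if (inherits(hits, "sim_genome")) hits <- hits$hits
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%-21s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      hits$gene_id, "-", 400L, hits$pfam_accession, hits$pfam_accession,
      300L, hits$evalue, hits$bitscore, 0.1, 1L, 1L,
      hits$evalue, hits$evalue, hits$bitscore, 0.1,
      1L, 300L, 50L, 350L, 45L, 355L, 0.95)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read HMMER domtblout domain hits
#'
#' Parses the whitespace-delimited per-domain table ('#' lines are
#' comments). Only the columns the screen consumes are returned: target
#' gene, profile accession (column 5; falls back to the query name when
#' the accession field is "-"), full-sequence E-value and bit score.
#'
#' @param path domtblout path.
#' @return Hit table: `gene_id`, `pfam_accession`, `evalue`, `bitscore`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene_id = character(0), pfam_accession = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(lengths(fields) < 8L)
  if (length(short))
    stop("malformed domtblout line(s): ", paste(short, collapse = ", "))
  acc <- vapply(fields, `[[`, "", 5L)
  qname <- vapply(fields, `[[`, "", 4L)
  data.frame(
    gene_id = vapply(fields, `[[`, "", 1L),
    pfam_accession = ifelse(acc == "-", qname, acc),
    evalue = as.numeric(vapply(fields, `[[`, "", 7L)),
    bitscore = as.numeric(vapply(fields, `[[`, "", 8L)),
    stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Writes a minimal, valid SAM file (header with `@SQ` lines, one record
#' per alignment, NM tag) for simulated truth alignments.
#'
#' @param x `sim_reads` or a data frame with columns `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `seq`, `nm`.
#' @param path Output SAM path.
#' @param contig_lengths Named integer vector of reference lengths;
#'   taken from `x` when it is a `sim_reads`. Extra references (for
#'   competitive-mapping emulation) may be included.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, contig_lengths = NULL) {
  if (inherits(x, "sim_reads")) {
    if (is.null(contig_lengths)) contig_lengths <- x$contig_lengths
    else contig_lengths <- c(x$contig_lengths,
                             contig_lengths[setdiff(names(contig_lengths),
                                                    names(x$contig_lengths))])
    x <- x$sam
  }
  if (is.null(contig_lengths)) stop("contig_lengths required")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(x)) {
    qual <- strrep("I", nchar(x$seq))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       x$qname, x$flag, x$rname, x$pos, x$mapq, x$cigar,
                       x$seq, qual, x$nm), con)
  }
  invisible(path)
}

#' Read SAM alignments into alignment records
#'
#' Parses a SAM file (via on-the-fly BAM conversion) into the flat record
#' shape the recruitment filter consumes. `aligned_length` counts the read
#' bases in alignment columns (CIGAR M/I/=/X); `read_length` additionally
#' includes soft clips. Secondary and supplementary alignments are flagged
#' but retained, so counting rules can exclude them explicitly.
#'
#' @param path SAM file path.
#' @return List: `records` (data frame: `read_id`, `contig_id`,
#'   `read_length`, `aligned_length`, `edit_distance`, `mapped`,
#'   `secondary`), `contig_lengths` (named integer from the header).
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar"), tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) {
    rec <- data.frame(read_id = character(0), contig_id = character(0),
                      read_length = integer(0), aligned_length = integer(0),
                      edit_distance = integer(0), mapped = logical(0),
                      secondary = logical(0), stringsAsFactors = FALSE)
    return(list(records = rec, contig_lengths = hdr))
  }
  cigar <- b$cigar
  cigar[is.na(cigar)] <- ""
  ops <- GenomicAlignments::cigarOpTable(cigar)
  aligned <- ops[, "M"] + ops[, "I"] + ops[, "="] + ops[, "X"]
  readlen <- aligned + ops[, "S"]
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  rec <- data.frame(
    read_id = b$qname,
    contig_id = as.character(b$rname),
    read_length = as.integer(readlen),
    aligned_length = as.integer(aligned),
    edit_distance = as.integer(nm),
    mapped = !bitwAnd(b$flag, 4L),
    secondary = bitwAnd(b$flag, 256L) > 0L | bitwAnd(b$flag, 2048L) > 0L,
    stringsAsFactors = FALSE)
  list(records = rec, contig_lengths = hdr)
}

#' Write a growth-curve table as TSV
#' @param curves Growth table (`condition`, `strain`, `replicate`,
#'   `time_h`, `od600`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a growth-curve table from TSV
#' @param path TSV with columns `condition`, `strain`, `replicate`,
#'   `time_h`, `od600`.
#' @return Data frame.
#' @export
read_growth_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "strain", "replicate", "time_h", "od600")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("growth table missing column(s): ", paste(miss, collapse = ", "))
  tab
}
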