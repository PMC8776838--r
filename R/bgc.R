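#' Load gene calls and filtered domain hits
#'
#' Reads a GFF3 gene table and a HMMER domtblout hit table, discards hits
#' whose full-sequence E-value exceeds `evalue_max` (boundary inclusive:
#' a hit exactly at the cutoff is kept), and keeps the single best hit per
#' (gene, pfam) pair -- lowest E-value, ties broken by bit score.
#'
#' @param gff3 GFF3 path, or an already-parsed gene table.
#' @param domtblout domtblout path, or an already-parsed hit table.
#' @param evalue_max Full-sequence E-value cutoff (default 1e-5).
#' @return List with `genes` and `hits` (filtered, deduplicated).
#' @export
load_annotations <- function(gff3, domtblout, evalue_max = 1e-5) {
  stopifnot(evalue_max > 0)
  genes <- if (is.character(gff3)) read_gff3(gff3) else gff3
  hits <- if (is.character(domtblout)) read_domtblout(domtblout) else domtblout
  orphans <- setdiff(hits$gene_id, genes$gene_id)
  if (length(orphans))
    stop("domain hits reference gene(s) absent from the gene calls: ",
         paste(unique(orphans), collapse = ", "))
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) > 1L) {
    hits <- hits[order(hits$gene_id, hits$pfam_accession,
                       hits$evalue, -hits$bitscore), , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("gene_id", "pfam_accession")]), ,
                 drop = FALSE]
  }
  rownames(hits) <- NULL
  list(genes = genes, hits = hits)
}

#' Find co-localized synthase/dehydratase loci
#'
#' Groups the genes carrying either diagnostic domain into loci: two
#' consecutive carriers on the same contig belong to the same locus when
#' at most `max_gene_gap` non-carrier genes lie between them (gene-order
#' distance; strand is ignored). A locus is a candidate petrobactin-like
#' cluster iff it contains at least one synthase carrier and at least one
#' dehydratase carrier.
#'
#' @param genes Gene table (`gene_id`, `contig_id`, `ordinal`, ...).
#' @param hits Filtered hit table from [load_annotations()].
#' @param synthase_pfam NIS-synthase domain accession
#'   (default `"pfam04183"`).
#' @param dehydratase_pfam 3-dehydroshikimate dehydratase accession
#'   (default `"pfam01261"`).
#' @param max_gene_gap Maximum number of intervening non-carrier genes
#'   within a locus (default 3).
#' @return Data frame of loci (one row each): `locus_id`, `contig_id`,
#'   `start_ordinal`, `end_ordinal`, `carrier_gene_ids` and `gene_ids`
#'   (comma-joined, the latter including intervening genes),
#'   `n_synthase`, `has_dehydratase`, `candidate`.
#' @export
find_colocalized <- function(genes, hits,
                             synthase_pfam = "pfam04183",
                             dehydratase_pfam = "pfam01261",
                             max_gene_gap = 3L) {
  stopifnot(max_gene_gap >= 0)
  empty <- data.frame(
    locus_id = character(0), contig_id = character(0),
    start_ordinal = integer(0), end_ordinal = integer(0),
    carrier_gene_ids = character(0), gene_ids = character(0),
    n_synthase = integer(0), has_dehydratase = logical(0),
    candidate = logical(0), stringsAsFactors = FALSE)
  keep <- hits$pfam_accession %in% c(synthase_pfam, dehydratase_pfam)
  if (!any(keep)) return(empty)
  hits <- hits[keep, , drop = FALSE]
  carriers <- merge(genes, hits, by = "gene_id")
  # per-gene domain flags (a gene may carry both domains)
  syn_genes <- unique(carriers$gene_id[carriers$pfam_accession == synthase_pfam])
  deh_genes <- unique(carriers$gene_id[carriers$pfam_accession == dehydratase_pfam])
  cg <- unique(carriers[, c("gene_id", "contig_id", "ordinal")])
  cg <- cg[order(cg$contig_id, cg$ordinal), , drop = FALSE]
  loci <- list()
  for (contig in unique(cg$contig_id)) {
    cc <- cg[cg$contig_id == contig, , drop = FALSE]
    gap <- c(Inf, diff(cc$ordinal) - 1L)
    grp <- cumsum(gap > max_gene_gap)
    for (g in unique(grp)) {
      members <- cc[grp == g, , drop = FALSE]
      span <- genes$gene_id[genes$contig_id == contig &
                            genes$ordinal >= min(members$ordinal) &
                            genes$ordinal <= max(members$ordinal)]
      span <- span[order(genes$ordinal[match(span, genes$gene_id)])]
      n_syn <- sum(members$gene_id %in% syn_genes)
      has_deh <- any(members$gene_id %in% deh_genes)
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = sprintf("%s_locus_%02d", contig, length(loci) + 1L),
        contig_id = contig,
        start_ordinal = min(members$ordinal),
        end_ordinal = max(members$ordinal),
        carrier_gene_ids = paste(members$gene_id, collapse = ","),
        gene_ids = paste(span, collapse = ","),
        n_synthase = n_syn,
        has_dehydratase = has_deh,
        candidate = n_syn >= 1L && has_deh,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Classify the completeness of a candidate locus
#'
#' Applies the pathway-completeness rule for petrobactin-like clusters:
#' `complete` needs at least two distinct synthase genes (the asbA/asbB
#' pair) plus a dehydratase gene (asbF analog); one synthase plus the
#' dehydratase is `partial`; anything else with a synthase is
#' `synthase_only`. Locus genes without a diagnostic domain are reported
#' as accessory, labeled with any supplied extra domain hits
#' (e.g. transporters); accessories are never required for completeness.
#'
#' @param locus One row of the [find_colocalized()] table.
#' @param genes Gene table.
#' @param hits Full filtered hit table (may include accessory pfams).
#' @param synthase_pfam,dehydratase_pfam Diagnostic accessions.
#' @return A list of class `gene_cluster`: `contig_id`, `gene_ids`,
#'   `n_synthase`, `has_dehydratase`, `completeness_class`,
#'   `accessory` (data frame: `gene_id`, `pfam` or `NA`).
#' @export
classify_cluster <- function(locus, genes, hits,
                             synthase_pfam = "pfam04183",
                             dehydratase_pfam = "pfam01261") {
  gene_ids <- strsplit(locus$gene_ids, ",", fixed = TRUE)[[1]]
  lh <- hits[hits$gene_id %in% gene_ids, , drop = FALSE]
  syn <- unique(lh$gene_id[lh$pfam_accession == synthase_pfam])
  deh <- unique(lh$gene_id[lh$pfam_accession == dehydratase_pfam])
  n_syn <- length(syn)
  has_deh <- length(deh) > 0L
  cls <- if (n_syn >= 2L && has_deh) "complete"
         else if (n_syn == 1L && has_deh) "partial"
         else "synthase_only"
  acc_ids <- setdiff(gene_ids, c(syn, deh))
  acc_hits <- lh[lh$gene_id %in% acc_ids, c("gene_id", "pfam_accession"),
                 drop = FALSE]
  accessory <- data.frame(gene_id = acc_ids,
                          pfam = acc_hits$pfam_accession[
                            match(acc_ids, acc_hits$gene_id)],
                          stringsAsFactors = FALSE)
  structure(list(contig_id = locus$contig_id, gene_ids = gene_ids,
                 n_synthase = n_syn, has_dehydratase = has_deh,
                 completeness_class = cls, accessory = accessory),
            class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat("Gene cluster on", x$contig_id, "-", length(x$gene_ids), "genes;",
      x$n_synthase, "NIS synthase(s);",
      if (x$has_dehydratase) "dehydratase present;" else "no dehydratase;",
      "class:", x$completeness_class, "\n")
  invisible(x)
}

#' Screen a set of annotated genomes for petrobactin-like clusters
#'
#' Runs the co-localization screen on each genome and tallies how many
#' genomes carry at least one synthase hit, how many show synthase +
#' dehydratase co-localization, and how many carry a complete pathway.
#' Per-genome failures are caught and reported, the remaining genomes
#' are still screened.
#'
#' @param genomes Named list; each element either a `sim_genome`, a list
#'   with `genes` and `hits`, or a list with `gff3` and `domtblout`
#'   paths.
#' @param evalue_max E-value cutoff passed to [load_annotations()].
#' @param synthase_pfam,dehydratase_pfam,max_gene_gap Screen parameters,
#'   see [find_colocalized()].
#' @return List of class `bgc_screen`: `summary` (named counts
#'   `n_with_synthase`, `n_with_colocalization`, `n_complete`),
#'   `clusters` (data frame: genome, contig, class, gene ids per
#'   candidate locus), `loci` (per-genome loci tables), `failed`
#'   (named character vector of per-genome error messages).
#' @export
screen_genome_set <- function(genomes, evalue_max = 1e-5,
                              synthase_pfam = "pfam04183",
                              dehydratase_pfam = "pfam01261",
                              max_gene_gap = 3L) {
  stopifnot(length(genomes) >= 1L)
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("genome_%02d", seq_along(genomes))
  failed <- character(0)
  n_syn <- n_coloc <- n_complete <- 0L
  loci_list <- list()
  rows <- list()
  for (nm in names(genomes)) {
    g <- genomes[[nm]]
    res <- tryCatch({
      ann <- if (inherits(g, "sim_genome"))
        load_annotations(g$genes, g$hits, evalue_max)
      else if (!is.null(g$genes))
        load_annotations(g$genes, g$hits, evalue_max)
      else load_annotations(g$gff3, g$domtblout, evalue_max)
      has_syn <- synthase_pfam %in% ann$hits$pfam_accession
      loci <- find_colocalized(ann$genes, ann$hits, synthase_pfam,
                               dehydratase_pfam, max_gene_gap)
      cand <- loci[loci$candidate, , drop = FALSE]
      classes <- character(0)
      if (nrow(cand)) {
        classes <- vapply(seq_len(nrow(cand)), function(i)
          classify_cluster(cand[i, ], ann$genes, ann$hits,
                           synthase_pfam, dehydratase_pfam)$completeness_class,
          "")
      }
      list(has_syn = has_syn, loci = loci, cand = cand, classes = classes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[nm] <- conditionMessage(res)
      next
    }
    n_syn <- n_syn + res$has_syn
    n_coloc <- n_coloc + (nrow(res$cand) > 0L)
    n_complete <- n_complete + any(res$classes == "complete")
    loci_list[[nm]] <- res$loci
    if (nrow(res$cand))
      rows[[nm]] <- data.frame(genome = nm, res$cand,
                               completeness_class = res$classes,
                               stringsAsFactors = FALSE)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome = character(0))
  rownames(clusters) <- NULL
  structure(list(
    summary = c(n_with_synthase = n_syn, n_with_colocalization = n_coloc,
                n_complete = n_complete),
    clusters = clusters, loci = loci_list, failed = failed),
    class = "bgc_screen")
}

#' @export
print.bgc_screen <- function(x, ...) {
  s <- x$summary
  cat("BGC screen:", s["n_with_synthase"], "genome(s) with a synthase hit;",
      s["n_with_colocalization"], "with synthase/dehydratase co-localization;",
      s["n_complete"], "with a complete pathway\n")
  if (length(x$failed))
    cat("Failed genomes:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}
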