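# Shared fixture builders. Everything is generated in code at test time.

# A gene table laid out on one contig with given per-gene pfam labels
# (NA = unlabeled), genes 1 kb apart.
make_gene_table <- function(pfams, contig = "c1") {
  n <- length(pfams)
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    contig_id = contig,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = rep(c("+", "-"), length.out = n),
    ordinal = seq_len(n),
    stringsAsFactors = FALSE)
}

make_hits <- function(genes, pfams, evalue = 1e-30) {
  keep <- !is.na(pfams)
  data.frame(gene_id = genes$gene_id[keep],
             pfam_accession = pfams[keep],
             evalue = evalue, bitscore = 200,
             stringsAsFactors = FALSE)
}

# Random DNA string of length n under a local RNG seed.
random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Position-wise identity (percent) between two equal-length sequences,
# restricted to the first `n_frag` whole fragments of `fl` bp: the exact
# oracle for substitution-only ANI.
positionwise_identity <- function(a, b, fl = 1500L) {
  a <- as.character(a); b <- as.character(b)
  n <- (min(nchar(a), nchar(b)) %/% fl) * fl
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  100 * mean(av == bv)
}
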