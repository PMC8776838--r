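test_that("hit loading filters then keeps the best hit per gene/pfam", {
  genes <- make_gene_table(rep(NA, 3))
  hits <- data.frame(gene_id = "g01", pfam_accession = "pfam04183",
                     evalue = c(1e-10, 1e-3, 1e-20),
                     bitscore = c(50, 10, 80), stringsAsFactors = FALSE)
  ann <- load_annotations(genes, hits, evalue_max = 1e-5)
  expect_equal(nrow(ann$hits), 1L)
  expect_equal(ann$hits$evalue, 1e-20)
  # boundary: a hit exactly at the cutoff is retained
  at_cut <- hits[1, ]; at_cut$evalue <- 1e-5
  expect_equal(nrow(load_annotations(genes, at_cut, 1e-5)$hits), 1L)
  # orphan hits are an error naming the gene
  orphan <- data.frame(gene_id = "gX", pfam_accession = "pfam04183",
                       evalue = 1e-30, bitscore = 100)
  expect_error(load_annotations(genes, orphan), "gX")
})

test_that("empty domtblout files parse to zero hits", {
  p <- tempfile()
  writeLines("# target name ...", p)
  expect_equal(nrow(read_domtblout(p)), 0L)
})

test_that("annotation files round-trip through GFF3 and domtblout", {
  g <- gen_genome(sim_config(seed = 4))
  gff <- tempfile(fileext = ".gff3"); dom <- tempfile()
  write_gff3(g, gff); write_domtblout(g, dom)
  genes <- read_gff3(gff)
  expect_equal(genes[, c("gene_id", "start", "end", "strand")],
               g$genes[, c("gene_id", "start", "end", "strand")])
  hits <- read_domtblout(dom)
  expect_equal(hits$gene_id, g$hits$gene_id)
  expect_equal(hits$pfam_accession, g$hits$pfam_accession)
  # written E-values keep 2 significant digits; same filter decisions
  expect_equal(hits$evalue, g$hits$evalue, tolerance = 0.05)
  # the screen gives identical loci from files and in-memory tables
  from_files <- load_annotations(gff, dom)
  loci <- find_colocalized(from_files$genes, from_files$hits)
  expect_equal(loci[loci$candidate, "carrier_gene_ids"],
               paste(g$truth$carrier_gene_ids, collapse = ","))
})

test_that("co-localization applies the gene-gap rule at its boundary", {
  gap <- 3L
  for (sep in c(gap, gap + 1L)) {
    pf <- rep(NA_character_, 10 + sep)
    pf[4] <- "pfam04183"
    pf[4 + sep + 1] <- "pfam01261"
    genes <- make_gene_table(pf)
    loci <- find_colocalized(genes, make_hits(genes, pf), max_gene_gap = gap)
    if (sep == gap) {
      expect_equal(nrow(loci), 1L)
      expect_true(loci$candidate)
    } else {
      expect_equal(nrow(loci), 2L)
      expect_false(any(loci$candidate))
    }
  }
})

test_that("co-localization requires both domains on the same contig", {
  pfA <- c(NA, "pfam04183", NA)
  pfB <- c(NA, "pfam01261", NA)
  genes <- rbind(make_gene_table(pfA, contig = "cA"),
                 make_gene_table(pfB, contig = "cB"))
  genes$gene_id <- sprintf("g%02d", 1:6)
  hits <- rbind(data.frame(gene_id = "g02", pfam_accession = "pfam04183",
                           evalue = 1e-30, bitscore = 200),
                data.frame(gene_id = "g05", pfam_accession = "pfam01261",
                           evalue = 1e-30, bitscore = 200))
  loci <- find_colocalized(genes, hits)
  expect_equal(nrow(loci), 2L)
  expect_false(any(loci$candidate))
})

test_that("completeness classification follows the synthase-pair rule", {
  cases <- list(
    list(pf = c("pfam04183", "pfam04183", "pfam01261"), class = "complete"),
    list(pf = c("pfam04183", "pfam01261"), class = "partial"),
    list(pf = c("pfam04183", "pfam04183"), class = "synthase_only"))
  for (cs in cases) {
    pf <- c(NA, cs$pf, NA)
    genes <- make_gene_table(pf)
    hits <- make_hits(genes, pf)
    loci <- find_colocalized(genes, hits)
    cl <- classify_cluster(loci[1, ], genes, hits)
    expect_s3_class(cl, "gene_cluster")
    expect_equal(cl$completeness_class, cs$class)
  }
})

test_that("accessory genes are reported but never required", {
  pf <- c("pfam04183", NA, "pfam04183", "pfam01261")
  genes <- make_gene_table(pf)
  hits <- rbind(make_hits(genes, pf),
                data.frame(gene_id = "g02", pfam_accession = "pfam07715",
                           evalue = 1e-12, bitscore = 90))
  loci <- find_colocalized(genes, hits)
  cl <- classify_cluster(loci[1, ], genes, hits)
  expect_equal(cl$completeness_class, "complete")
  expect_equal(cl$accessory$gene_id, "g02")
  expect_equal(cl$accessory$pfam, "pfam07715")
})

test_that("candidate count is monotone in the gap window", {
  pf <- rep(NA_character_, 30)
  pf[c(3, 9, 15, 16, 25)] <- c("pfam04183", "pfam01261", "pfam04183",
                               "pfam01261", "pfam04183")
  genes <- make_gene_table(pf)
  hits <- make_hits(genes, pf)
  n_cand <- vapply(0:12, function(gap)
    sum(find_colocalized(genes, hits, max_gene_gap = gap)$candidate),
    integer(1))
  expect_true(all(diff(n_cand) >= 0))
  # wide enough windows join everything into one candidate locus
  expect_equal(n_cand[length(n_cand)], 1L)
})

test_that("record order and strand do not change reported loci", {
  g <- gen_genome(sim_config(seed = 6))
  base <- find_colocalized(g$genes, g$hits)
  withr::with_seed(1, {
    shuf_genes <- g$genes[sample(nrow(g$genes)), ]
    shuf_hits <- g$hits[sample(nrow(g$hits)), ]
  })
  shuffled <- find_colocalized(shuf_genes, shuf_hits)
  expect_equal(base$carrier_gene_ids, shuffled$carrier_gene_ids)
  flipped <- g$genes
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  expect_equal(find_colocalized(flipped, g$hits)$carrier_gene_ids,
               base$carrier_gene_ids)
})

test_that("genome-set screening tallies the three summary counts", {
  synthase_only_spec <- data.frame(role = c("asbA", "asbB"),
                                   pfam = c("pfam04183", "pfam04183"))
  g_complete <- gen_genome(sim_config(seed = 10))
  g_partial <- gen_genome(sim_config(seed = 11,
                                     cluster_spec = synthase_only_spec))
  res <- screen_genome_set(list(a = g_complete, b = g_partial))
  expect_equal(unname(res$summary),
               c(2L, 1L, 1L))
  # no pfam hits at all
  empty <- gen_genome(sim_config(seed = 12,
                                 cluster_spec = petrobactin_cluster_spec()[0, ]))
  res0 <- screen_genome_set(list(x = empty))
  expect_equal(unname(res0$summary), c(0L, 0L, 0L))
  # per-genome failure is reported, others continue
  bad <- list(gff3 = tempfile(), domtblout = tempfile())
  res_mix <- suppressWarnings(screen_genome_set(list(ok = g_complete,
                                                     bad = bad)))
  expect_equal(names(res_mix$failed), "bad")
  expect_equal(unname(res_mix$summary), c(1L, 1L, 1L))
})
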