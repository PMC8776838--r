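make_records <- function(read_length, aligned_length, nm,
                         mapped = TRUE, secondary = FALSE,
                         contig = "c1") {
  n <- max(length(read_length), length(aligned_length), length(nm))
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             contig_id = contig,
             read_length = read_length, aligned_length = aligned_length,
             edit_distance = nm, mapped = mapped, secondary = secondary,
             stringsAsFactors = FALSE)
}

test_that("the 95%/75% filter keeps boundary cases inclusively", {
  rec <- make_records(read_length = c(100, 100, 100, 100),
                      aligned_length = c(80, 100, 100, 74),
                      nm = c(2, 6, 5, 0))
  kept <- filter_alignments(rec)
  # 80 bp aligned, NM=2: identity 0.975, fraction 0.80 -> retained
  expect_true("r001" %in% kept$read_id)
  # NM=6 over 100 aligned: identity 0.94 < 0.95 -> removed
  expect_false("r002" %in% kept$read_id)
  # identity exactly 0.95 -> retained (boundary inclusive)
  expect_true("r003" %in% kept$read_id)
  # aligned fraction 0.74 < 0.75 -> removed even at identity 1
  expect_false("r004" %in% kept$read_id)
  # unmapped records are removed regardless of thresholds
  unm <- make_records(100, 100, 0, mapped = FALSE)
  expect_equal(nrow(filter_alignments(unm)), 0L)
  # missing NM: dropped with a warning by default, error on request
  na_rec <- make_records(100, 100, NA_integer_)
  expect_warning(out <- filter_alignments(na_rec), "without NM")
  expect_equal(nrow(out), 0L)
  expect_error(filter_alignments(na_rec, on_missing_nm = "error"), "NM")
})

test_that("stricter thresholds retain a subset", {
  withr::with_seed(51, {
    rec <- make_records(read_length = 100,
                        aligned_length = sample(50:100, 200, TRUE),
                        nm = sample(0:8, 200, TRUE))
  })
  strict <- filter_alignments(rec, 0.95, 0.75)
  loose <- filter_alignments(rec, 0.90, 0.50)
  expect_true(all(strict$read_id %in% loose$read_id))
})

test_that("counting is per primary alignment with MAG summation", {
  map <- data.frame(contig_id = c("c1", "c2"), mag_id = "magA")
  rec <- make_records(rep(100, 10), rep(100, 10), rep(0, 10))
  cnt <- count_per_contig(rec, map)
  expect_equal(cnt$contig_counts$count, 10L)
  expect_equal(cnt$mag_counts$count[cnt$mag_counts$mag_id == "magA"], 10L)
  # reads split across two contigs of one MAG sum to the MAG count
  rec2 <- rec; rec2$contig_id <- rep(c("c1", "c2"), c(6, 4))
  cnt2 <- count_per_contig(rec2, map)
  expect_equal(sort(cnt2$contig_counts$count), c(4L, 6L))
  expect_equal(cnt2$mag_counts$count, 10L)
  # secondary alignments are excluded from counts
  rec3 <- rbind(rec, make_records(100, 100, 0, secondary = TRUE))
  expect_equal(count_per_contig(rec3, map)$mag_counts$count, 10L)
  # unknown contigs go to "unassigned" with a warning
  rec4 <- make_records(100, 100, 0, contig = "cX")
  expect_warning(cnt4 <- count_per_contig(rec4, map), "unassigned")
  expect_equal(cnt4$n_unassigned, 1L)
  # conservation: contig counts sum to MAG counts (incl. unassigned)
  expect_equal(sum(cnt4$contig_counts$count), sum(cnt4$mag_counts$count))
  # duplicate contig assignment is rejected
  expect_error(count_per_contig(rec, rbind(map, map[1, ])), "at most one")
})

test_that("rpkm implements reads per kbp genome per Gbp metagenome", {
  expect_equal(rpkm(1000, 1e6, 1e9), 1.0)
  expect_equal(rpkm(0, 1e6, 1e9), 0)
  expect_equal(rpkm(1000, 1e6, 2e9), 0.5)  # doubling metagenome halves it
  expect_equal(rpkm(3000, 1e6, 1e9), 3 * rpkm(1000, 1e6, 1e9))
  expect_error(rpkm(10, 0, 1e9), "positive")
  expect_error(rpkm(10, 1e6, 0), "positive")
})

test_that("species pooling reduces to per-MAG RPKM for one complete MAG", {
  counts <- data.frame(mag_id = "magA", count = 420L)
  est <- estimate_species_genome_length(
    data.frame(length = 2.5e6, completeness = 1))
  expect_equal(pooled_species_rpkm("magA", counts, est, 1e9),
               rpkm(420, 2.5e6, 1e9))
  # worked pooling: counts 100 + 50 over an estimated 2 Mbp in 1 Gbp
  two <- data.frame(mag_id = c("magA", "magB"), count = c(100L, 50L))
  expect_equal(pooled_species_rpkm(c("magA", "magB"), two, 2e6, 1e9), 0.075)
  # members absent from a non-empty count table count zero
  expect_equal(pooled_species_rpkm(c("magA", "magC"), two, 2e6, 1e9),
               100 / 2000)
  expect_error(pooled_species_rpkm("magA", two[0, ], 2e6, 1e9), "magA")
})

test_that("end-to-end recruitment recovers planted depth", {
  gA <- gen_genome(sim_config(seed = 61, genome_length = 60000))
  names(gA$sequence) <- "ctgA"
  gB_seq <- random_dna(40000, seed = 62)
  reads <- gen_reads(gA$sequence, 100, 10, error_rate = 0, seed = 63)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, sam, contig_lengths = c(ctgB = 40000L))
  map <- data.frame(contig_id = c("ctgA", "ctgB"),
                    mag_id = c("magA", "magB"))
  meta_bp <- length(reads$reads) * 100
  prof <- abundance_profile(sam, map,
                            mag_lengths = c(magA = 60000, magB = 40000),
                            metagenome_size = meta_bp, sample_id = "s1")
  tabA <- prof$mag_table[prof$mag_table$mag_id == "magA", ]
  tabB <- prof$mag_table[prof$mag_table$mag_id == "magB", ]
  # >=99% of reads recruit to the source genome (here: all)
  expect_gte(tabA$count / sum(prof$mag_table$count), 0.99)
  expect_equal(tabB$count, 0L)
  # RPKM agrees with the nominal-depth expectation within 5%
  expected <- (10 * 60000 / 100) / ((60000 / 1e3) * (meta_bp / 1e9))
  expect_lt(abs(tabA$rpkm - expected) / expected, 0.05)
  # species pooling with a single complete MAG reproduces the MAG RPKM
  sp <- data.frame(mag_id = c("magA", "magB"), species = c(1L, 2L))
  prof2 <- abundance_profile(sam, map,
                             mag_lengths = c(magA = 60000, magB = 40000),
                             metagenome_size = meta_bp,
                             species = sp,
                             species_lengths = c("1" = 60000, "2" = 40000))
  expect_equal(prof2$species_table$rpkm[1], tabA$rpkm)
})
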