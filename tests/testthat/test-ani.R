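test_that("fragmentation windows per contig and drops remainders", {
  one <- Biostrings::DNAStringSet(c(c1 = random_dna(4500, 1)))
  expect_length(fragment_genome(one, 1500), 3L)
  short <- Biostrings::DNAStringSet(c(c1 = random_dna(1499, 2)))
  expect_length(fragment_genome(short, 1500), 0L)
  two <- Biostrings::DNAStringSet(c(c1 = random_dna(3000, 3),
                                    c2 = random_dna(1600, 4)))
  frags <- fragment_genome(two, 1500)
  expect_length(frags, 3L)
  expect_equal(names(frags), c("c1|1", "c1|1501", "c2|1"))
  expect_length(fragment_genome(Biostrings::DNAStringSet(), 1500), 0L)
})

test_that("fragment mapping scores identity exactly on substitutions", {
  ref <- random_dna(20000, seed = 21)
  frag <- substr(ref, 5001, 6500)
  hit <- map_fragment(frag, ref)
  expect_true(hit$mapped)
  expect_equal(hit$identity, 1)
  expect_equal(hit$ref_start, 5001L)
  # 15 substitutions over 1500 bp -> identity 0.99 exactly
  fv <- strsplit(frag, "")[[1]]
  pos <- seq(50, by = 100, length.out = 15)
  fv[pos] <- vapply(fv[pos],
                    function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  hit15 <- map_fragment(paste(fv, collapse = ""), ref)
  expect_true(hit15$mapped)
  expect_equal(hit15$identity, 1 - 15 / 1500)
  # unrelated fragment: no shared 16-mer seed, unmapped
  expect_false(map_fragment(random_dna(1500, 99), ref)$mapped)
})

test_that("self-ANI is 100 with full aligned fraction", {
  g <- random_dna(30000, seed = 22)
  res <- compute_ani(g, g)
  expect_equal(res$ani, 100)
  expect_equal(res$aligned_fraction, 1)
  expect_false(res$undefined)
})

test_that("ANI of a substituted copy matches the position-wise oracle", {
  g <- random_dna(60000, seed = 23)
  mut <- mutate_genome(g, 0.03, seed = 24)
  res <- compute_ani(g, mut)
  expect_false(res$undefined)
  expect_equal(res$aligned_fraction, 1)
  oracle <- positionwise_identity(g, mut)
  expect_lt(abs(res$ani - oracle), 0.1)
  expect_lt(abs(res$ani - 97), 0.5)
})

test_that("genomes below the fragment length are flagged undefined", {
  res <- compute_ani(random_dna(1000, 1), random_dna(1000, 2))
  expect_true(res$undefined)
  expect_true(is.na(res$ani))
  # unrelated genomes: fragments exist but none map
  res2 <- compute_ani(random_dna(10000, 3), random_dna(10000, 4))
  expect_true(res2$undefined)
})

test_that("species grouping is single linkage over the max of directions", {
  ani <- data.frame(query = c("A", "B", "A", "B", "C"),
                    reference = c("B", "A", "C", "C", "A"),
                    ani = c(96, 95.5, 94, 96, 94.2))
  # D has no measured pair: warned, left unlinked
  expect_warning(sp <- cluster_species(c("A", "B", "C", "D"), ani,
                                       threshold = 95),
                 "without")
  expect_equal(length(unique(sp$species)), 2L)
  expect_equal(sp$species[sp$mag_id == "A"], sp$species[sp$mag_id == "B"])
  expect_equal(sp$species[sp$mag_id == "B"], sp$species[sp$mag_id == "C"])
  expect_equal(sum(sp$species == sp$species[sp$mag_id == "D"]), 1L)
  # all pairs below the threshold: all singletons
  low <- ani; low$ani <- 90
  expect_warning(sp_low <- cluster_species(c("A", "B", "C", "D"), low),
                 "without")
  expect_equal(length(unique(sp_low$species)), 4L)
  # missing pairs warn and act as no edge
  expect_warning(cluster_species(c("A", "B", "E"), ani[1:2, ]), "without")
})

test_that("raising the threshold never merges groups", {
  withr::with_seed(31, {
    ids <- LETTERS[1:8]
    pairs <- t(combn(ids, 2))
    ani <- data.frame(query = pairs[, 1], reference = pairs[, 2],
                      ani = runif(nrow(pairs), 80, 100))
  })
  prev <- NULL
  for (th in c(85, 90, 95, 99)) {
    sp <- cluster_species(ids, ani, threshold = th)
    if (!is.null(prev)) {
      # refinement: members of one group at th were together at lower th
      for (s in unique(sp$species)) {
        members <- sp$mag_id[sp$species == s]
        expect_equal(length(unique(prev$species[prev$mag_id %in% members])),
                     1L)
      }
      expect_gte(length(unique(sp$species)), length(unique(prev$species)))
    }
    prev <- sp
  }
})

test_that("complete linkage requires all pairs above threshold", {
  ani <- data.frame(query = c("A", "B", "A"),
                    reference = c("B", "C", "C"),
                    ani = c(96, 96, 90))
  single <- cluster_species(c("A", "B", "C"), ani, linkage = "single")
  expect_equal(length(unique(single$species)), 1L)
  complete <- cluster_species(c("A", "B", "C"), ani, linkage = "complete")
  expect_equal(length(unique(complete$species)), 2L)
})

test_that("species genome-length estimation implements both modes", {
  one <- data.frame(length = 4e6, completeness = 1)
  expect_equal(estimate_species_genome_length(one), 4e6)
  expect_equal(estimate_species_genome_length(one, "as_printed"), 4e6)
  half <- data.frame(length = 2e6, completeness = 0.5)
  expect_equal(estimate_species_genome_length(half), 4e6)
  expect_equal(estimate_species_genome_length(half, "as_printed"), 1e6)
  two <- data.frame(length = c(3e6, 4e6), completeness = c(0.75, 1))
  expect_equal(estimate_species_genome_length(two), 4e6)
  zero <- data.frame(length = 1e6, completeness = 0)
  expect_error(estimate_species_genome_length(zero), "completeness")
  # mag_assembly list input
  mags <- list(mag_assembly("m1", random_dna(3000, 1), completeness = 0.5))
  expect_equal(estimate_species_genome_length(mags), 6000)
  # bounds: corrected >= as_printed always (completeness <= 1)
  withr::with_seed(41, {
    for (i in 1:10) {
      m <- data.frame(length = runif(3, 1e6, 5e6),
                      completeness = runif(3, 0.3, 1))
      expect_gte(estimate_species_genome_length(m),
                 estimate_species_genome_length(m, "as_printed"))
      expect_lte(estimate_species_genome_length(m, "as_printed"),
                 mean(m$length))
    }
  })
})
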