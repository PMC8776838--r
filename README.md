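# sidescan

Tools for linking siderophore biosynthesis to marine iron cycling.
Siderophores are small iron-chelating metabolites that bacteria secrete
to acquire Fe(III), a scarce nutrient over much of the surface ocean.
`sidescan` implements the computational stages that connect one such
compound — petrobactin, C<sub>34</sub>H<sub>50</sub>N<sub>6</sub>O<sub>11</sub> —
to its producers and their global distribution:

- **LC–MS screening.** Formula-derived adduct m/z matching
  ([M+H]<sup>+</sup> = M + 1.00727646, with [M+2H]<sup>2+</sup>,
  [M−H]<sup>−</sup> and the ferric complex [M+Fe−2H]<sup>+</sup> also
  supported) at a configurable ppm tolerance, plus MS2 fragment
  confirmation. For petrobactin: [M+H]<sup>+</sup> = 719.361,
  diagnostic fragments 194/282/438/565 m/z.
- **Biosynthetic gene-cluster detection.** Co-localization of NIS
  siderophore synthase domains (pfam04183, asbA/asbB analogs) with
  3-dehydroshikimate dehydratase (pfam01261, asbF analog) in GFF3 +
  HMMER domtblout annotations; a cluster is *complete* with ≥2 synthase
  genes plus the dehydratase.
- **Species grouping by ANI.** Fragment-based average nucleotide
  identity (1500 bp fragments, k-mer seeded mapping), single-linkage
  grouping at the >95% species boundary, and complete-species genome
  length estimation from MAG completeness.
- **Read-recruitment abundance.** SAM alignment filtering (≥95%
  identity, ≥75% of the read aligned), primary-alignment counting, and
  RPKM — reads per kbp genome per Gbp metagenome — per MAG and pooled
  per species:
  `rpkm = count / ((genome_length/1e3) * (metagenome_size/1e9))`.
- **Growth kinetics.** µ<sub>max</sub> by sliding-window log-linear
  regression and (µ, K, N0) by logistic least squares
  `N(t) = K / (1 + ((K−N0)/N0) e^(−µt))`, compared across strains with
  a pooled two-tailed Student t test.
- **Synthetic data with ground truth** for every stage: genomes with
  planted clusters, point-mutated copies, reads with exact truth SAM,
  MS feature tables with decoys, and noisy logistic growth curves —
  so the full pipeline runs and is tested offline.

## Worked example

```r
library(sidescan)

# --- MS screen: recover planted siderophores among 100 decoys ---------
ref   <- siderophore_reference()
feats <- gen_ms_features(ref, n_noise = 100, jitter_ppm = 2, seed = 7)
hits  <- screen_ms_features(feats, ref, tol_ppm = 5)
head(hits[, c("mz", "compound", "adduct", "ppm_error", "n_ms2_matched")], 4)
#>        mz               compound adduct ppm_error n_ms2_matched
#> 1 565.235             aerobactin [M+H]+ -0.824586            NA
#> 2 561.360         ferrioxamine B [M+H]+ -1.388585            NA
#> 3 691.328 petrobactin derivative [M+H]+ -2.393543            NA
#> 4 719.364            petrobactin [M+H]+  4.574494             4
```

All four planted compounds are matched within 5 ppm of their
formula-derived [M+H]<sup>+</sup> m/z, none of the 100 decoys match, and
all 4 reference MS2 fragments of petrobactin are confirmed at 0.5 Th.

```r
# --- BGC screen: find the planted petrobactin-like cluster ------------
g <- gen_genome(sim_config(seed = 1))
screen_genome_set(list(simMAG_1 = g))
#> BGC screen: 1 genome(s) with a synthase hit; 1 with synthase/dehydratase
#> co-localization; 1 with a complete pathway

# --- Growth: producer vs non-producer under iron limitation -----------
curves <- rbind(
  gen_growth_curves(0.55, 1.0, 0.01, seq(0, 24, 1), noise_sd = 0.01,
                    seed = 1, strain = "WT"),
  gen_growth_curves(0.35, 0.7, 0.01, seq(0, 24, 1), noise_sd = 0.01,
                    seed = 2, strain = "mutant"))
fits <- fit_growth_table(curves, method = "logistic")
aggregate(cbind(mu_max, K) ~ strain, fits, mean)
#>   strain mu_max     K
#> 1 mutant  0.341 0.706
#> 2     WT  0.547 1.002
compare_strains(fits$mu_max[fits$strain == "WT"],
                fits$mu_max[fits$strain == "mutant"])
#> Two-sample student t test: t = 59.846, df = 4, p = 4.669e-07
#> (significant at alpha = 0.05)
```

The logistic fits recover the simulated growth rates (0.55 vs
0.35 h<sup>−1</sup>) and carrying capacities (1.0 vs 0.7 OD600) from
noisy triplicate curves, and the pooled t test separates the strains.

A thin command-line dispatcher over the same functions is installed at
`system.file("cli", "sidescan.R", package = "sidescan")` with
subcommands `simulate`, `masscreen`, `bgcscan`, `ani`, `recruit`, and
`growth`.

See the methods vignette (`vignettes/siderophore-pipeline.Rmd`) for the
models, defaults, and their rationale.

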