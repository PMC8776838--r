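---
title: "Methods: siderophore screening from mass spectra to ocean-scale abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: siderophore screening from mass spectra to ocean-scale abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidescan)
```

# The problem

Siderophores are small (roughly 500–1500 Da) iron-chelating metabolites
that bacteria secrete to scavenge Fe(III). Petrobactin
(C~34~H~50~N~6~O~11~) is a photoreactive catecholate/citrate siderophore
made by *Alteromonas macleodii* and relatives, and its biosynthetic gene
cluster has a distinctive genetic signature: two NRPS-independent (NIS)
siderophore synthases (asbA/asbB analogs, Pfam domain pfam04183)
co-located with a 3-dehydroshikimate dehydratase (asbF analog,
pfam01261). `sidescan` links this compound to its producers and their
distribution through five analysis stages, each usable on its own:

1. **mass_screen** — identify siderophores in LC–MS feature tables by
   formula-derived adduct m/z and MS2 fragment matching.
2. **bgc_screen** — detect petrobactin-like gene clusters in annotated
   genomes by domain co-localization and classify pathway completeness.
3. **ani_species** — group metagenome-assembled genomes (MAGs) into
   species with fragment-based average nucleotide identity (ANI).
4. **recruit_abundance** — turn competitive read recruitment into
   identity-filtered, RPKM-normalized abundance profiles, pooled at the
   species level.
5. **growth_kinetics** — estimate growth parameters (µ~max~, K) from
   OD600 curves and compare producer vs non-producer strains.

A sixth stage, the synthetic-data generator, produces every input these
stages consume with machine-readable ground truth, so the whole pipeline
is testable without any external download.

# Mass screening

Monoisotopic masses are summed from per-element isotope masses (C exactly
12, H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117,
Fe 55.93493633). Ion m/z uses the *proton* mass (1.00727646 Da), not the
hydrogen-atom mass, because an ion's m/z is the mass of the charged
species divided by its charge:

- `[M+H]+` = M + 1.00727646
- `[M+2H]2+` = (M + 2 × 1.00727646) / 2
- `[M−H]−` = M − 1.00727646
- `[M+Fe−2H]+` = M − 2 m(H) + m(Fe) − m(e⁻) = M + 53.918738

The last form expresses a ferric complex detected as a singly charged
ion: Fe(III) bound to the deprotonated ligand. Its offset is fixed by
exact composition arithmetic (two hydrogen atoms out, one iron atom in,
one electron removed for the net +1 charge); the familiar ≈52.911 Da gap
between the apo `[M+H]+` ion and the ferric ion is recovered as
Fe − 3H. Ferric screening is available but off by default: apo and
ferric forms are distinguishable in the match report via `iron_form`.

For petrobactin this yields `[M+H]+` = 719.361 and, for its
C~32~H~46~N~6~O~11~ derivative, 691.330 (3 dp) — the two ions the
screen is designed to recover from marine extracts.

**Tolerances.** MS1 matching uses a relative tolerance, default 5 ppm,
typical of high-resolution orbitrap-class instruments; MS2 fragment
confirmation uses an absolute tolerance, default 0.5 Th, appropriate for
unit-resolution fragment lists such as petrobactin's diagnostic
194/282/438/565 ions. Both are configurable; neither is sacred, and the
matching-set monotonicity property (larger tolerance ⇒ superset of
matches) holds by construction. Reference masses are always recomputed
from formulas at load time; a mass column in a user table is validated
and overridden with a warning if inconsistent. Peak height (the
`intensity` column) is carried as the abundance proxy; no area
integration is attempted.

# Cluster detection

The screen consumes standard upstream outputs — GFF3 gene calls and
HMMER `domtblout` domain hits — rather than running gene calling or HMM
search in-process. Hits are filtered at a full-sequence E-value of
1e-5 (inclusive boundary), keeping the best hit per (gene, domain).
The cutoff is a conventional HMMER significance level, configurable.

Co-localization, historically a manual inspection step, is codified as a
gene-order gap rule: genes carrying either diagnostic domain belong to
one locus when at most `max_gene_gap` (default 3) non-carrier genes
intervene on the same contig. Known petrobactin clusters are contiguous,
so a small gap tolerates split or mis-called genes without joining
unrelated loci. Strand is deliberately ignored — real clusters occur in
mixed orientations across taxa — and recorded only for reporting.

Completeness classification: `complete` requires **two or more distinct
synthase genes** plus the dehydratase, because petrobactin biosynthesis
uses two NIS synthases; a single gene carrying two pfam04183 domains
counts once. One synthase plus dehydratase is `partial`; otherwise
`synthase_only`. Neighboring transporter-like genes (TBDT/ABC) are
reported as accessories but never required, since their requirement in
published screens is unclear.

# ANI and species grouping

ANI is computed fragment-wise from its stated parameters: the query is
cut into non-overlapping 1500 bp fragments (trailing remainder
discarded), each fragment is placed on the reference by exact 16-mer
seeding with diagonal voting, and scored by gap-free comparison at the
best diagonal; identity is matching positions / fragment length. When
the gap-free score falls below the 80% mapping floor, a banded
local-in-global alignment (±32 bp slack) around the best diagonal is
tried, with identity = matches / alignment columns. ANI is 100 × the
mean identity of mapped fragments; the aligned fraction is reported
alongside, and a comparison with no mapped fragments is flagged
undefined rather than given a number.

With substitution-only divergence the gap-free path is exact, so ANI
equals the position-wise identity oracle; the test suite verifies
agreement to 0.1 ANI points on a 3%-substituted copy. The seeding math
also sets the sensitivity envelope: at 3% divergence a given 16-mer
survives with probability 0.97^16 ≈ 0.61, and with 15 probes per
fragment the chance that no seed survives is < 10⁻⁶ — fragments of
same-species genomes essentially always map, while unrelated random
sequence shares a specific 16-mer with vanishing probability and stays
unmapped.

Species are connected components of the graph with an edge where the
**larger of the two directional ANI values strictly exceeds 95%**.
Taking the max is conservative for grouping (assembly incompleteness
depresses one direction more than the other); single linkage matches the
common practice of calling mutually >95% MAGs one species, and a
complete-linkage alternative is available. Raising the threshold can
only split groups, never merge them.

**Species genome length.** Pooled RPKM needs one genome length per
species. The default `completeness_corrected` estimator averages
length ÷ completeness over member MAGs, which estimates the *complete*
genome length each partial assembly represents — the stated intent of
such normalizations. The literal length × completeness average
(`as_printed`) appears in some descriptions and is retained behind a
flag; it shrinks with incompleteness and is never the default. Both are
exposed because the published arithmetic is ambiguous; neither is
asserted as the original computation.

# Read recruitment and RPKM

Alignment records are filtered with the 95%/75% rule: identity
= 1 − NM/aligned_length ≥ 0.95 and aligned fraction
= aligned_length/read_length ≥ 0.75, where aligned_length counts read
bases in alignment columns (CIGAR M/I/=/X) and read_length additionally
includes soft clips. Boundaries are **inclusive** because the original
rule removes reads strictly *below* the thresholds. Only primary
alignments are counted — competitive mapping assigns each read once —
and paired reads count per mate. Counts sum contig → MAG → species.

RPKM here is reads per kbp of genome per Gbp of metagenome:

count / ((genome_length / 10³) × (metagenome_size / 10⁹))

with `metagenome_size` the total bases sequenced in the sample (from a
sample manifest), not the filtered subset, so normalization reflects
sequencing effort. Species-level RPKM divides the summed member counts
by the estimated complete species genome length, recovering reads split
among redundant assemblies of one species.

# Growth kinetics

Two estimators are provided, since published growth analyses often name
a package without the method:

- `fit_easylinear()` — sliding-window log-linear regression: µ~max~ is
  the steepest slope of ln(OD) vs time over windows of 5 points, taken
  among windows with r² ≥ 0.95 (falling back, flagged, to the best-r²
  window). Non-positive OD values — blank-subtraction artifacts — are
  excluded and counted. Exact on noiseless exponentials; scale
  equivariant and time-shift invariant by construction.
- `fit_logistic()` — Levenberg–Marquardt least squares on
  N(t) = K / (1 + ((K − N0)/N0) e^(−µt)) with multi-start
  initialization (K near the observed maximum, µ from a log-slope
  scan). Series that never rise above their starting density, or where
  no start converges, are flagged failures with no values reported.

Strains are compared with an independent two-tailed two-sample t test,
pooled-variance Student form by default (Welch behind a flag), at
α = 0.05, with no multiple-testing correction by default, mirroring
per-condition testing practice; the degenerate all-constant-equal case
is defined as t = 0, p = 1.

# The synthetic-data generator

The generator emulates, with known truth: (a) bacterial genomes
(default 50 kbp, 40 genes of 300–1500 bp, intergenic gaps 20–200 bp)
with a planted contiguous cluster of two pfam04183 genes and one
pfam01261 gene among unlabeled background genes; (b) point-mutated
genome copies (independent per-site substitution, replacement uniform
over the three alternatives, indels behind a flag) and uniformly drawn
error-free or error-bearing reads with exact truth SAM records
(1-based POS, all-match CIGAR, NM = injected errors); (c) MS1 feature
tables with planted adduct peaks, optional ppm jitter, and uniform
decoys rejected within 10 ppm of any true mass so labels are
unambiguous; (d) logistic OD600 curves with additive Gaussian noise
truncated at zero (default sd 0.01, a realistic bench
spectrophotometer noise floor).

It deliberately does **not** model read-quality profiles, chimeras,
isotope envelopes, retention-time structure, genome repeats, or real
strain-level pangenome variation. Passing tests therefore demonstrate
the correctness of the pipeline's *rules and arithmetic* under the
stated generative assumptions, not robustness to every artifact of real
MAGs or cruise samples.

Substitution-only mutation is the default precisely so the ANI oracle
stays exact; the recruitment truth SAM uses the same dialect the parser
consumes (M/I/D CIGARs, NM), so injected and recovered identities agree
by bookkeeping, not by luck.

# Numerical choices and problem sizes

All generators are seed-deterministic (identical seed ⇒ byte-identical
outputs). Ties in window selection resolve to the earliest window;
hit deduplication resolves E-value ties by bit score. The test-suite
and acceptance-script problem sizes — 50–60 kbp genomes for cluster and
recruitment checks, a 200 kbp genome for the 3%-divergence ANI check,
100 noisy curves for logistic recovery, 1000 null simulations for the
type-I error rate — were chosen so every property has enough resolution
for its stated tolerance (e.g. Poisson and binomial 3σ bands, median
relative error < 5%) while a full run remains a desk exercise.

# Limitations

- The fragment mapper is a faithful small-scale ANI implementation, not
  a MinHash-accelerated one; all-pairs comparisons of many large
  genomes are out of scope.
- MS identification is screening-grade: formula match plus fragment
  count, no isotope-envelope or retention-time scoring.
- The co-localization gap rule and the 1e-5 E-value cutoff are declared
  defaults for a historically manual decision, not inferred constants.
- Whether fragment (pair) or mate granularity, and raw or
  quality-filtered bases, feed published RPKM values varies; this
  implementation counts per mate against raw sample bases and says so
  rather than guessing.
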