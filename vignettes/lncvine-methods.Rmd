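---
title: "lncvine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncvine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncvine)
```

# Scope and model

`lncvine` re-implements, as a tested and reusable pipeline, a
computational workflow for discovering and annotating long non-coding
RNAs (lncRNAs) in a multi-tissue, multi-stage plant RNA-seq study — the
motivating system is grapevine (*Vitis vinifera*) with leaf,
inflorescence and berry tissues sampled across ten developmental
stages. The pipeline covers:

1. **Identification**: a funnel of four filters over assembled
   transcripts — length (> 200 nt), six-frame ORF (no open reading
   frame longer than 100 amino acids), an ingested coding-potential
   score (retained only when strictly negative), and an ingested
   protein-homology screen (retained only when no hit exists).
2. **Genomic context**: placement of candidates on a genome from
   alignment tables (identity > 90 %, e-value < 1e-10, best hit by bit
   score), per-chromosome distribution and density (count per Mbp),
   length histograms, and Cuffcompare-style class codes relative to
   reference gene models.
3. **Expression**: per-condition consensus (replicate mean),
   differential expression (at least 4-fold and BH-FDR <= 0.001 in any
   pairwise comparison), the printed FPKM abundance bins, and a
   tissue/stage specificity index (per-condition consensus divided by
   the row total; specific when the maximum reaches 0.7).
4. **Co-expression**: a mean-expression filter (>= 30 FPKM over
   conditions), Pearson edges at r² >= 0.9 over condition-consensus
   profiles with 100-run bootstrap support, annotation transfer from
   partners, hypergeometric term enrichment, and organelle homology
   screening (alignment length strictly > 200 nt).
5. **miRNA interactions**: penalty-scored target sites, hairpin
   precursor matches with a base-pair-maximization foldback check, and
   endogenous target mimics (eTMs) with the characteristic 3-nt bulge
   opposite miRNA positions 10/11.
6. **Synthetic data**: a seed-deterministic generator that emits every
   input the pipeline consumes plus a ground-truth manifest, so the
   whole analysis is verifiable end to end without external data.

All internal coordinates are 0-based half-open; conversion to the
1-based inclusive conventions of GTF and BLAST tabular files happens
only at file boundaries. `U` is normalized to `T` on input so the miRNA
(RNA) and transcript (DNA) alphabets unify.

# Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_len` | 201 nt | length filter; "more than 200 nt" taken strictly |
| `max_orf_aa` | 100 aa | ORFs longer than this, in any of six frames, disqualify |
| `score_cutoff` | 0 | coding-potential scores must be strictly below this |
| `min_identity`, `max_evalue` | 90 %, 1e-10 | genome placement thresholds (both strict) |
| `min_fold`, `max_fdr` | 4, 0.001 | DE filter on consensus fold change and BH-FDR |
| `specificity` | 0.7 | threshold on the maximum specificity index |
| `min_mean` | 30 FPKM | co-expression mean filter (removal strict below) |
| `r2` | 0.9 | Pearson r² edge threshold (`abs_r` criterion by flag) |
| `bootstrap_runs` | 100 | condition-column resamples per edge |
| `target_max_score` | 3.0 | maximum duplex penalty for a target site |
| `etm_ratio` | 0.7 | minimum pairing-strength ratio for an eTM |
| `organelle_min_align` | 200 nt | organelle homology length (strict >) |
| `runon_window` | 2000 nt | class-code `p` distance window |

# Numerical and rule-level choices

**Incomplete ORFs.** Assembled fragments may lack stop codons, so ORFs
truncated by the transcript end count toward the > 100 aa exclusion by
default (the conservative choice — it removes more candidates);
`require_complete = TRUE` counts only stop-terminated ORFs.

**Missing external evidence.** Transcripts absent from an ingested
coding-potential or homology table are kept with a warning: the funnel
removes candidates only on positive evidence of coding capacity.

**Class-code precedence** is `=, c, j, e, o, i, x, s, p, u`; the most
specific code across all reference models wins, ties resolved to the
lexicographically smallest reference id, so classification is total and
deterministic. The `p` (polymerase run-on) window is direction-free:
a transcript with no exon overlap within 2,000 nt of a reference on
*either* side is `p`. A "downstream of the 3' end only" rule was
considered and rejected because it breaks strand-relabel symmetry
(flipping every strand moves the 3' end to the other side of the
reference while coordinates stay put), a property both the test oracle
and classification consumers rely on. Overlap is judged on query exons
throughout: a query whose intron merely straddles a reference does not
overlap it.

**Consensus and DE.** The "consensus expression value" is the replicate
arithmetic mean (median by flag). Log2 fold changes use a 1-FPKM
pseudocount. The built-in test is a two-sample t on log2(FPKM + 1) with
limma-style empirical-Bayes variance moderation (`limma::squeezeVar`)
by default. A plain Welch t-test was the original design, but with
three replicates its ~4 degrees of freedom cannot push p-values low
enough to clear an FDR of 0.001 reliably even for unambiguous 8-fold
changes (measured power ≈ 0.83 in an all-positive cohort); variance
moderation is the field-standard remedy for exactly this design and
restores power ≈ 1 at the stated noise level. `var_moderation = FALSE`
recovers the unmoderated Welch test, and an ingested p-value table
bypasses the built-in test entirely (the DE contract of this package is
the threshold filter, not the test). BH adjustment is implemented
directly (step-up with `cummin`) and checked against `stats::p.adjust`
as an independent oracle.

**Specificity degenerate case.** An all-zero consensus row has an
undefined index; it is flagged (`all_zero`) and never called specific.

**Edges and bootstrap.** Correlations are computed over condition
consensus vectors (not samples); zero-variance profiles yield no edges
because r is undefined. "Filtering threshold 0.9" is read as r² >= 0.9,
consistent with how the threshold is quoted alongside results; an
`abs_r` criterion is available by flag. Negative-sign edges are kept
and labeled. The bootstrap resamples condition columns (the
observational units of the correlation); resamples with a degenerate
profile are excluded from the support denominator; support is reported,
never used to prune.

**eTM geometry.** A candidate window has miRNA length + 3; the three
extra transcript nucleotides form a bulge between the bases pairing
miRNA positions 10 and 11 (the cleavage site), and both flanks must
pair at every position — Watson–Crick or G:U, no mismatches, no gaps.
The pairing-strength ratio (G:C = 3, A:U = 2, G:U = 1, summed and
divided by the perfect-duplex score) must reach 0.7, mirroring the
mfe_ratio >= 0.7 of thermodynamic mimic searches while staying purely
combinatorial. An earlier variant tolerated flank mismatches, scoring
them zero; on random sequence it admitted roughly twenty chance matches
per default synthetic study, which would defeat the bulge geometry as a
classifier — requiring fully paired flanks reduces the chance-match
probability per window to about 0.375^21 ≈ 1e-9 while leaving planted
canonical mimics (ratio 1.0) untouched. Thermodynamic folding (RNAfold,
TAPIR energies) is deliberately out of scope; the hairpin foldback
check is Nussinov-style base-pair maximization (minimum loop 3),
reported as a paired fraction and never used to filter by default.

**Alignment.** The internal aligner is exact Smith–Waterman
(match +1, mismatch −2, gap −2.5) in compiled code; a k-mer-seeded
heuristic was considered for speed but rejected — at desk scale exact
DP is fast enough and identical to the quadratic oracle by
construction. Ingested tabular hits always take precedence when
supplied.

# The synthetic study: what it emulates, and what it does not

`simulate_study()` states a world rather than tuning one: 100 coding
and 100 non-coding transcripts on a 10 × 150 kb genome; ten conditions
labeled as four leaf, three inflorescence and three berry stages with
three replicates each; multiplicative log-normal replicate noise with
CV 0.1. Planted structure: condition-specific transcripts at index 0.8,
8-fold DE transcripts, lncRNA–mRNA pairs with identical condition
profiles, lncRNA–organelle-CDS pairs, miRNA target sites (the exact
reverse complement of a mature miRNA), embedded hairpins
(mature + 8-nt loop + reverse complement), and eTM sites (a perfect
site split by a 3-nt insertion between the bases pairing miRNA
positions 10/11). Class codes are planted by construction: ~29 % of
non-coding loci inside reference introns (`i`), ~14 % overlapping
reference exons antisense (`x`), the rest intergenic (`u`), echoing the
intronic/antisense/intergenic proportions reported for real grapevine
data.

Several generator choices exist to make every manifest claim exactly
recoverable, and are worth knowing when interpreting a green test:

* Planted feature sets are **orthogonal**: condition-specific and DE
  hosts stay below the 30-FPKM co-expression mean filter, because their
  spiky profiles would otherwise correlate almost perfectly with any
  partner profile peaking in the same condition. Real data has no such
  separation.
* Planted shared profiles have a >= 16-fold dynamic range above a
  2-FPKM floor, so the pair is unambiguously differentially expressed
  under replicate noise; non-planted profiles vary less than 2-fold, so
  they are unambiguously not. Real fold-change distributions are
  continuous across the 4-fold threshold; the generator deliberately
  avoids the boundary.
* A hairpin embedding necessarily contains a perfect target site on its
  3' arm; the manifest records these arm-derived sites as planted
  targets, which also produces the precursor-and-target role overlap
  seen in real interaction surveys.
* Sequences are random apart from planted structure: there is no codon
  bias, GC structure, repeat content or assembly artifact. A green
  recovery test establishes that the *rules* are implemented correctly
  and invertibly, not that the thresholds are well-calibrated for real
  transcriptomes.

Replicate noise is multiplicative log-normal with the stated CV
(`meanlog = -sdlog²/2`, so the noise has mean 1 and consensus is
unbiased). With `fpkm_noise_cv = 0` the bundle is exactly noiseless,
which the co-expression recovery tests exploit.

# Testing strategy

Every operation with a stated contract is tested against an
independent oracle built by enumeration: a per-codon walk for ORFs, an
integer-position-set rule evaluator for class codes, an explicit
combinatorial tail sum for the hypergeometric test, a window-by-window
rescan for target sites, unmemoized recursion over all nested
structures for the foldback count, and a plain-R dynamic program for
the aligner. The acceptance suite (`test-acceptance.R`) implements the
eleven stated criteria one test each, including a 1,000-sequence ORF
oracle sweep, a 500-case class-code sweep with strand-relabel symmetry,
20-seed specificity recovery at CV 0.2, a 2,200-transcript DE
power/type-I simulation, and a byte-identity rerun of the full
pipeline. Multi-seed interaction-recovery properties run on a
scaled-down configuration (30 + 30 transcripts, 4 chromosomes) to stay
inside the time budget; the scaling is in the fixture helper, not in
any threshold.

# Known limitations

* Coding-potential scoring and protein homology are ingested as tables;
  the package never runs CPC or BLAST itself.
* The duplex penalty scheme emulates the plant target-scoring family
  (mismatch 1, G:U 0.5, positions 2–13 doubled, cutoff 3.0); it is not
  a byte-level reproduction of any specific server's output, and eTM
  energetics are combinatorial, not thermodynamic.
* Class codes follow the documented precedence and definitions; exact
  agreement with any particular Cuffcompare release at pathological
  edge cases (zero-length introns, contained references) is not
  guaranteed.
* The DE machinery is a filtering contract around a moderated t on
  log-FPKM, not a count-model method; with real count data an
  exact-test table can be ingested instead.
* GraphML/edge-list export covers the network contract; layout and
  visualization are out of scope.
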