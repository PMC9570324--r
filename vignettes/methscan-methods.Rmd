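---
title: "Bacterial SMRT methylome analysis with methscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bacterial SMRT methylome analysis with methscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscan)
```

## Scope and problem

Bacterial DNA methyltransferases (MTases) methylate adenines (m6A) or
cytosines (m4C) at short, often degenerate sequence motifs. Single-molecule
real-time (SMRT) sequencing detects these marks through polymerase kinetics:
a methylated template base delays nucleotide incorporation, elevating the
inter-pulse duration (IPD) at that position. `methscan` implements the
downstream analysis of such data for a bacterial chromosome:

1. kinetic calling of modified positions and Phred-scaled quality filtering;
2. strand-aware scanning of IUPAC motifs and per-motif methylation summaries;
3. detection of unmethylated motif sites and Fisher exact testing of their
   enrichment in putative promoter windows;
4. in-silico simulation of methylation-sensitive restriction enzyme (MSRE)
   PCR assays;
5. comparative genomics of MTase repertoires (presence/absence profiling,
   UPGMA and neighbor-joining trees, species clustering);
6. a fully seeded synthetic-data generator providing ground truth for every
   stage.

Upstream steps (base calling, assembly, polishing, BlastP, Mash sketching)
are out of scope: the package consumes their standard outputs (FASTA, GFF3,
a PacBio-style `modifications.gff` or equivalent CSV, identity tables and
distance matrices).

## Coordinate conventions

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
BED (0-based half-open) conversions are confined to the I/O layer, so there
is exactly one place where off-by-one logic can exist. Chromosome
circularity is an explicit flag read from a `circular=true` FASTA header
token; circular scanning examines exactly L windows, counting origin-spanning
matches once.

## Kinetic calling model

For each (position, strand) the caller receives the observed IPDs and the
in-silico reference moments (mean, sd, effective n) for that position. The
test statistic is Welch's t,

$$ t = \frac{\bar{x} - \mu_{ref}}{\sqrt{s^2/n + \sigma_{ref}^2/n_{ref}}}, $$

with Welch–Satterthwaite degrees of freedom, tested one-sided (methylation
only elevates IPD). The p-value maps to a Phred-scaled modification QV,
$QV = -10\log_{10} p$, so QV 30 corresponds exactly to p = 0.001, the
conventional calling threshold. Filtering happens on the *unrounded* QV —
a candidate at QV 29.95 is rejected at threshold 30 regardless of its
integer-rounded report value of 30 — which avoids threshold artifacts at
29.5. The modification type is assigned from the genomic base under the call
in read orientation (A → m6A, C → m4C, otherwise `modified_base`); the
default filter keeps adenine and cytosine calls only. The reference-model
construction used by production SMRT pipelines is proprietary-adjacent and
is not reproduced; only the Welch-on-IPD skeleton is, with the reference
supplied as per-position moments.

## Motif model

A motif is an IUPAC string plus the 0-based offset of its methylated base
and a modification type; the base at the offset must be able to emit an A
(m6A) or C (m4C). Scanning matches both strands: a plus-strand match
starting at $s$ has its methylatable base at $s + o$; a minus-strand match
(pattern matches the reverse complement of the window) at $s + L - 1 - o$.
Each strand match is a separate site, so a palindromic duplex locus (e.g.
GATC) contributes two sites — this is the convention under which a ~4 Mb
enterobacterial genome carries ~30 000 GATC sites, matching published
two-strand counts. Genome letters outside A/C/G/T never match any pattern
code: a modification call cannot sit on an ambiguous base. Partner motifs
are exact reverse complements of one another as IUPAC strings (a palindrome
is its own partner); they mark the two strands of the same duplex
recognition site and necessarily have equal genome-wide site counts.

For bipartite motifs conveyed in print with the methylated base underlined,
the underline does not survive plain text, so the methylated offset is a
required user input rather than something the package infers.

## Summaries and motif discovery

The per-motif summary row is: fraction (nDetected/nGenome, reported rounded
half-up to 3 decimals, kept unrounded internally), detected and genome-wide
site counts, means of QV / IPD ratio / coverage over detected sites, and a
heuristic objective score defined as
`round(fraction × sum of detected QVs)`. The exact objective-score formula
of production motif finders is unpublished; this heuristic tracks published
values within a few percent at large n and is used only for ranking.

De novo discovery is a greedy loop over candidate patterns anchored at the
methylated base of each call's ±20 bp context (read 5'→3' on the call
strand): contiguous ACGT words up to 8 bp, and bipartite forms
word1–N(g)–word2 with gap up to 9 and words up to 5 bp — the shape of Type I
restriction-modification recognition sites. Candidates are ranked by an
upper bound (the summed QVs of their supporting calls) and evaluated
genome-wide by scan + call assignment; the candidate maximising the
objective subject to a minimum fraction (default 0.5, below the weakest
published accepted motif at 0.691 but above noise) is accepted, its
explained calls removed, and the loop repeats. Two guards that the published
description leaves open were fixed here as design choices: a candidate must
have at least `min_sites = 5` genome-wide occurrences (otherwise any
near-unique long pattern trivially reaches fraction 1), and ties break to
the higher objective, then the shorter pattern, then lexicographic order,
for determinism. Accepted non-palindromic motifs trigger a search for their
reverse-complement partner among the remaining calls, trying every A/C
anchor offset.

## Promoter context and enrichment

A position is in a *putative promoter* iff it lies strictly less than 100 bp
(distances 1–99, configurable) upstream of an annotated start codon,
strand-aware; otherwise *gene body* iff inside an ORF; otherwise
*intergenic*. The "<100 bp" wording is read strictly because the complement
is described as ">100 bp from a start codon": distance 100 itself is not
promoter. Promoter takes precedence over gene body when a position is inside
one ORF but upstream of another, since promoter occupancy is the question of
interest; a site upstream of two divergent genes is counted once, labelled
by the closer start. Promoter windows are not wrapped across the origin of
circular chromosomes (a negligible edge at genome scale).

Enrichment of unmethylated sites in promoters is tested on the 2×2 table of
promoter vs gene-body counts — intergenic sites are excluded, following the
published convention of comparing "upstream region vs gene body" — for the
unmethylated set against a reference set. The default reference is *all*
motif sites, exactly as the published figure does (despite the
non-independence of including the unmethylated sites themselves);
`mode = "vs_methylated"` offers the statistically cleaner contrast. The
Fisher exact test is implemented in-package by hypergeometric enumeration
with the point-probability rule for the two-sided p (sum of all tables with
the same margins whose probability is at most the observed one, within
relative tolerance 1e-7); `stats::fisher.test` serves as an independent
oracle in the test suite, and the two agree to 1e-9 on every 2×2 table with
total at most 40.

## MSRE-PCR simulation

MboI cuts a GATC duplex iff neither strand is methylated; DpnI iff both
are; Bsp143I always; the undigested control never. Hemimethylated sites are
refractory to both MboI and DpnI — the published protocol wording ("only
unmethylated" / "only methylated") does not address hemimethylation, and
this is the standard enzymology. An amplicon is predicted iff no cut falls
strictly between the primer bounds. The preliminary EcoRI linearisation of
the wet protocol cuts outside the amplicon by design and is modelled as a
no-op.

## MTase repertoire comparative genomics

Presence of an MTase ortholog in a genome requires a hit with identity
strictly greater than 70% (the published criterion is ">70%"); the query's
own genome is always present. A *persistent* MTase is present in every
genome of the set. MTase profiles are compared by Jaccard distance
(1 − intersection/union; two empty profiles are at distance 0) and clustered
with UPGMA (size-weighted average linkage, node height d/2, ties broken to
the pair containing the lexicographically smallest member). Genome trees are
built by Saitou–Nei neighbor joining from a supplied distance matrix
(D ≈ 1 − ANI); negative branch lengths are clamped to 0 and Q-matrix ties
break to the smallest id pair. Species clusters are single-linkage connected
components at distance ≤ 0.06 (≈ 94% ANI), the threshold being inclusive —
note single linkage can chain A–B–C into one cluster even when d(A,C)
exceeds the threshold. Both tree builders are authored in-package because
the tie-break and clamping behaviour is part of the contract; `ape` supplies
the tree container and acts as the independent NJ oracle in the tests, and
`stats::hclust(method = "average")` as the UPGMA oracle. Ortholog collapsing
into row groups is available (`ortholog_groups`), keyed by the smallest
member id; the published grouping procedure is unstated, so no automatic
inference is attempted.

## Synthetic data: the stated world

The generator emulates the data regime the analysis was designed for, not a
tunable benchmark:

* genome: i.i.d. bases at GC 0.44 (typical of the motivating genus),
  circular, 100 kb by default for desk-scale runs; the bundled
  `paper_like_config()` uses 2 Mb;
* annotations: non-overlapping ORFs of 600–1200 bp with 100–400 bp
  intergenic gaps and random strands, so promoter windows are well-defined;
* methylome: each motif methylated at fraction f (default 0.998, the
  published Dam rate); the unmethylated count u = round((1−f)·n) is drawn
  without replacement with odds weight θ for promoter-context sites;
  methylated sites emit calls with QV ~ Normal(95.6, 20) floored just above
  the QV-30 threshold, IPD ratio ~ Normal(5.52, 1) truncated > 1, coverage ~
  Normal(56.9, 10) truncated ≥ 1 — the published GATC summary statistics;
  unmethylated sites emit, with probability 0.5, a sub-threshold call
  (QV < 30), so the filter boundary is exercised;
* a single seed governs everything; per-stage sub-seeds are derived from it.

What the generator does *not* emulate: sequence composition structure
(oligonucleotide bias, GC skew), operon structure, read-level noise,
coverage heterogeneity along the genome, and context-dependent kinetic
variation. A green test therefore establishes the correctness of the
computations on data with the stated statistical structure, not robustness
to every artifact of real SMRT data.

Two consequences of the sampling design are worth noting. First, because
exactly u sites are planted unmethylated, the recovered fraction equals
(n−u)/n deterministically; fraction-recovery tests check the pipeline
plumbing, not estimator noise. Second, θ is a *sampling weight* in a draw
without replacement; the recovered promoter/gene-body odds ratio converges
to θ only in the sparse regime where u is small relative to the promoter
class (the weighted draw depletes the promoter class otherwise). The
convergence test therefore runs at the paper-like 2 Mb scale, while the
power simulations (u = 77, θ = 10, p < 0.005 in ≥ 80% of seeds) run on
250 kb genomes: Fisher power depends on u and the promoter proportion, not
on genome size, and the smaller genomes keep the suite inside its time
budget. In the θ = 1 type-I simulation the realised rejection rate sits at
or below the nominal 5%, as expected for an exact conditional test with
discrete support.

## Numerical choices and degenerate inputs

* QV/p conversions are exact inverses before rounding; p-values are clamped
  to [1e-300, 1].
* A Welch test with both variances zero and equal means returns t = 0,
  p = 1 (no evidence), not an error; a single observation against a
  zero-variance reference is undefined and errors.
* Fraction rounding is half-up (printed-table convention), so 2021/2022
  reports 1.000.
* An all-zero contingency table is an error; a degenerate row or column
  gives p = 1.
* Duplicate modification calls at one (contig, position, strand) keep the
  highest score with a warning.
* `read_fasta` is parsed in-package because the standard readers silently
  drop illegal letters, whereas this contract requires a format error naming
  the offending position.

## Known limitations

* No operon-aware promoter model; "promoter" is a fixed upstream window.
* The objective score is a documented heuristic, not the production formula.
* Discovery enumerates anchored contiguous and bipartite candidate shapes
  only; motifs with two gaps or degenerate non-N codes (e.g. the published
  17-mer AANNNCCGGGNNNNNGA) are representable and scannable but not
  discoverable de novo by the candidate generator.
* Deposited-data checks against the public accessions of the motivating
  study require network access and are not run offline; the identical code
  path is exercised on synthetic data instead.
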