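---
title: "Calling single-nucleotide m6A sites from miCLIP mutation signatures"
author: "cimscall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling single-nucleotide m6A sites from miCLIP mutation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

miCLIP exploits a property of UV-crosslinked anti-m⁶A antibody–RNA
complexes: during reverse transcription the crosslink scar induces a
C→T transition in the cDNA at the cytosine immediately 3′ of the
methylated adenosine. In a deep library this turns methylation into a
counting problem. For a stranded genomic position, let *k* be the number
of deduplicated aligned reads ("unique tags") spanning it and *m* the
number carrying the transition. At a genuine m⁶A site *m*/*k* reflects
crosslinking efficiency (a per-molecule event, well below 1); at a
sequencing error it is tiny; at a genomic variant it clusters near 0.5
(heterozygous) or 1 (homozygous/alternate). The caller therefore applies,
in order:

1. **Transition class restriction.** Only stranded C→T tallies become
   candidates. All substitution classes are retained in a diagnostics
   table so the class composition can be inspected; the C→T class is the
   one that concentrates at A-preceded positions.
2. **Upstream adenosine.** The stranded base immediately 5′ of the
   mutated C must be A; that adenosine is the inferred m⁶A coordinate.
   The mutated C remains the site's canonical coordinate (it is what the
   data measure); the adenosine is a derived coordinate reported
   alongside.
3. **Known SNPs.** Candidates whose C or A coordinate is a known SNP
   position are removed, strand-agnostically. This is the only filter
   that can catch heterozygous variants, whose *m*/*k* ≈ 0.5 passes the
   ratio window.
4. **Mutation-ratio window.** Retain 0.01 ≤ *m*/*k* ≤ 0.50. The lower
   bound suppresses isolated errors at deep positions; the upper bound
   removes homozygous variants and systematic mismatches. Both
   boundaries are inclusive — the printed endpoints are kept — and the
   comparison is done in rational form (`m` against `lo*k`, `hi*k` with
   a 1e-9 guard) so exact boundary cases like 1/100 and 50/100 are not
   lost to floating-point representation.

Sites are stratified by mutation support: high (*m* > 10), medium
(5 ≤ *m* ≤ 10), low (*m* < 5). The medium stratum is read as a closed
interval so the three strata partition the site set exactly.

Independently of site calling, unique tags are clustered by transitive
same-strand overlap; a cluster's height is its maximum per-base depth
and clusters of height ≥ 4 are retained as peaks. Peaks and sites are
parallel outputs by default; `pipelineConfig(intersect_peaks = TRUE)`
restricts the catalogue to sites inside retained peaks for users who
want the stricter intersection.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_k` | 5 | unique tags | No coverage floor is inherent to the method; k ≥ 5 prevents ratio degeneracy at tiny k (at k ≤ 4 a single error already yields *m*/*k* ≥ 0.25). It changes site counts, so the caller logs it prominently. |
| `ratio_lo`, `ratio_hi` | 0.01, 0.50 | fraction | The published mutation-ratio window; inclusive at both ends. |
| `min_peak_height` | 4 | stacked tags | The published peak retention threshold. |
| `flank` | 10 | nt | Context half-width; contexts are 21-nt stranded strings with the C at position 11. |
| `metagene_lengths` | 200/1000/300 | bins | Meta-feature lengths for 5′UTR/CDS/3′UTR, reflecting typical transcript proportions. |
| `enrichment_fold` | 2.0 | ratio | Strictly-greater-than threshold for miCLIP/mRNA FPKM enrichment. |
| `upstream_window`, `downstream_window` | 5000, 1000 | bp | Annotation flanks around transcript spans. |
| `background_factor` | 10 | × sites | Background contexts per site for enrichment testing. |

## What the synthetic-data generator emulates

The generator builds a random single-contig genome with non-overlapping
genes on both strands (1–4 exons; 1–3 isoforms formed by intron
retention, which diversifies exon/intron structure while preserving the
CDS span and all segment invariants), plants adenosines in stranded
DRACH 5-mers inside exons and introns (exon share 0.9 by default,
reflecting the rarity of intronic sites; the intronic count is drawn
binomially), and plants SNPs at stranded A-preceded C positions within
read range of planted sites with alternate allele T. The SNP placement
is deliberate: heterozygous SNPs then produce exactly the A-preceded
~50% C→T candidates that only the SNP filter can remove, and homozygous
ones additionally exceed the ratio ceiling — so both filters are
genuinely exercised rather than passing vacuously.

Reads are single-end tags: Poisson(coverage) unique tags per planted
site plus background tags along each transcript, each tag spanning a
planted C acquiring the transition independently with probability
`cims_rate` (default 0.2), SNP alleles applied per class, uniform
substitution errors at `base_error_rate` (default 0.001), and
1 + Poisson(`pcr_duplication_mean`) PCR copies per unique tag sharing
one UMI realisation. Every mismatch is recorded with its provenance
(crosslink / snp / error); when a later event overwrites an earlier one
the final state wins, and substitutions that restore the reference are
not recorded — so the provenance table explains the emitted reads
exactly. The matched mRNA-seq simulation samples fragments uniformly
within exons with log-normal per-gene abundance and no crosslink
mutations.

Properties real data have that the generator does not: quality-score-
dependent error profiles, indels, adaptor read-through, spliced
alignments, fuzzy UMI families (UMIs are guaranteed distinct among tags
sharing an alignment start, which makes duplicate collapse exactly
invertible against the truth — a generator guarantee, not a property of
real libraries), reverse-transcription truncations (CITS; the package
calls CIMS only), crosslinking-efficiency heterogeneity across sites,
and any coupling between miCLIP tag density and mRNA abundance. Passing
tests therefore demonstrate the correctness of the counting, filtering
and bookkeeping machinery under the stated statistical model — not
robustness to alignment artefacts or library-specific biases.

One consequence worth noting: because simulated miCLIP depth is driven
by site placement rather than transcript abundance, the miCLIP/mRNA
rank correlation on synthetic data is near zero by design; the
correlation is reported descriptively, never thresholded.

## Numerical and design choices

* **Coordinates.** Internally everything is 0-based half-open; GTF is
  converted at the read/write boundary (1-based closed) and BED written
  0-based half-open. A single conversion boundary prevents off-by-one
  drift between stages.
* **Strand handling.** Tallies are expressed in read-strand space: a
  minus-strand tag reading A over plus-strand G is a stranded C→T. The
  full caller is invariant under reverse-complementing the genome and
  flipping all strands (checked as a property test).
* **Metagene rebinning.** Per-feature per-nucleotide coverage is
  rebinned by linear interpolation of the cumulative sum — each source
  nucleotide spreads over the destination bins it overlaps — so mass is
  conserved for any length ratio (a 37-nt UTR onto 200 bins included),
  each transcript's 1500-bin vector is normalised to total exactly 1,
  and the profile is the mean over transcripts.
* **Metagene isoform choice.** For multi-isoform genes the default is
  the isoform with the longest CDS; `isoform = "all"` averages every
  CDS-bearing isoform. Transcripts missing a UTR or with zero coverage
  are excluded and counted.
* **Annotation precedence.** Where isoforms disagree the site-level
  category follows cds > 5′UTR > 3′UTR > exon > intron > upstream >
  downstream > intergenic (configurable). The annotator accepts any
  transcript set, so all-isoform versus representative-isoform
  annotation is the caller's choice rather than a hard-wired guess.
* **Deduplication.** Both a pre-alignment collapse keyed on
  (UMI, sequence) and a post-alignment collapse keyed on
  (position, strand, UMI) are provided and composable, since sequencing
  errors can defeat the sequence key; representatives are the
  lexicographically smallest read id for determinism. The simulator's
  truth SAM contains unique tags, so the post-alignment pass is an
  idempotence check there.
* **Enrichment testing.** The default is a one-sided binomial test of
  the site motif-match count against the background match fraction,
  with background drawn as random stranded A-preceded C positions from
  exonic space at 10× the site count — assumption-explicit and cheap. A
  permutation test (p = (1 + #{null ≥ obs}) / (1 + B), B = 10,000
  default) guards against composition bias; the two agree within an
  order of magnitude away from the permutation floor. Enrichment
  p-values on real data depend on the (unpublished) background model,
  so they are treated as qualitative direction.
* **Expression enrichment space.** The >2-fold filter is applied in
  FPKM space after median-of-ratios size-factor scaling (raw-count mode
  available via `computeFpkm` inputs); reads overlapping exons of more
  than one gene are discarded as ambiguous, and both libraries are
  counted stranded.
* **Multi-mapping and indels.** Only primary alignments of
  substitution-only (all-`M` CIGAR) reads are consumed; deletions and
  insertions are outside the C→T-transition focus.

## Problem sizes

The demonstration experiment is 20 genes on a 100-kb contig, 50 planted
sites at coverage 50, 30 SNPs and 20,000 mRNA-seq reads — small enough
that the full pipeline, including its byte-identical rerun, completes in
a few minutes on one CPU, and large enough that per-site binomial
statistics are informative. Module tests use smaller instances (8 genes
/ 40 kb, or fixtures of a few hand-built transcripts); the brute-force
pileup oracle runs on ≤ 500-tag instances where the O(positions × tags)
recount is fast. The motif-test calibration resamples 150 sites per
replicate from a 4,000-context background pool, 1,000 replicates; at
that size the exact size of the one-sided binomial test at α = 0.05
lies between 0.035 and 0.048 over the plausible range of background
DRACH fractions, comfortably inside the acceptance band.

## Known limitations

* No CITS (truncation-based) calling and no FDR model over tallies; the
  ratio window is the noise control, as in the published procedure.
* The annotator is internal and GTF-only (no GFF3 dialects, no external
  annotation services); category conventions are explicit but simpler
  than full-featured annotators.
* `readTagAlignments` rejects spliced or indel-containing alignments by
  design; real spliced BAMs would need upstream projection onto
  contiguous intervals.
* Size-factor estimation with exactly two libraries (miCLIP vs mRNA) is
  the degenerate median-of-ratios case; it is exact for the simulated
  design but real multi-timepoint designs should pass all libraries at
  once.
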