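---
title: "RNA-Seq-based genotyping of inbred strains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA-Seq-based genotyping of inbred strains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transgeno)
```

## The problem

Marker-assisted selection in crop breeding needs DNA markers that separate
*closely related* strains — the advanced parents used inside one breeding
program — where prefixed SNP arrays suffer from ascertainment bias.
RNA-Seq offers a cheap route: reads sample the transcribed fraction of the
genome, so aligning RNA-Seq libraries from many strains against a reference
and calling variants yields genic polymorphisms genome-wide, at the price of
expression-dependent, often shallow coverage.

`transgeno` implements the downstream half of such a pipeline: everything
after read alignment and variant calling. It takes gene models, a merged
multi-sample VCF and sample metadata, and produces a filtered marker panel,
genotype-matrix analytics and concordance diagnostics. Read trimming,
alignment, transcript assembly and the variant caller itself are out of
scope; any GT+DP multi-sample VCF is accepted.

## Transcribed regions

Low-coverage RNA-Seq truncates transcript ends, so the mapping target is not
the transcript models themselves but *transcribed regions*: each gene locus
span (exons plus introns) extended by a fixed flank on both sides, then
concatenated where the extended spans overlap.

* **Flank length** (`flank_bp`, default 3000 bp). Flanks are symmetric and
  strand-agnostic: an "upstream/downstream" rule that depended on strand
  would be undefined for the strand-unknown novel loci assembled from
  RNA-Seq evidence, so both sides get the same extension.
* **Merging** uses the canonical minimal representation: overlapping *and*
  book-ended (touching, e.g. `[0,100)` + `[100,200)`) intervals become one
  region. Merging is idempotent and order-invariant, and the test suite
  checks it against an independent per-base boolean-mask union on toy
  chromosomes.
* **Coordinates** are 0-based half-open everywhere inside the package; GFF3
  (1-based closed) and VCF `POS` (1-based) are converted at the boundary.
  This makes length arithmetic (`end - start`) exact and matches the BED
  output format directly. Flanks are clipped at position 0 and at the
  chromosome length, so region sets are always valid intervals.

`region_stats()` reports the region count, the exact total bp and the ratio
against a reference set (typically the high-confidence annotated loci),
rendered to two decimals.

## The filter cascade

Raw merged VCFs from many shallow RNA-Seq libraries are dominated by
unreliable calls. The cascade applies five rules in a fixed order; each
stage's survivor set is a subset of the previous stage's:

1. **Depth** (`min_reads = 2`): a per-sample call supported by fewer than
   two reads is set to missing — the site is not removed, only that call.
   The rule defaults to all calls; a `het_only` mode restricts it to
   heterozygous calls, which in fully inbred material are the likely
   artifacts. Depth is the per-sample `DP`; when only `AD` is present its
   sum is used.
2. **Singleton**: a site where at most one strain carries the non-reference
   allele is discarded — a polymorphism seen in a single strain cannot be
   validated against any other strain and is disproportionately often a
   calling artifact. This stage also removes sites left monomorphic or
   data-free by stage 1.
3. **Replicate conflict**: when a strain has several libraries and two of
   them make different non-missing calls at a site, the site is discarded.
   The underlying wording ("different calls from multiple strains") is
   grammatically ambiguous; we implement the within-strain reading — the
   only one that uses the replicate structure — and expose
   `drop_conflicts = FALSE` to disable it rather than silently asserting
   intent.
4. **Multi-allele exclusion**: sites with two or more alternate alleles are
   tallied but excluded from the marker panel by default; assay design for
   multi-allelic sites is unreliable.
5. **Neighbour window** (`neighbor_window = 60` bp): a marker is kept only
   if no other polymorphism lies within 60 bp on either side, so its
   flanking sequence is clean for primer/probe design. *Both* members of a
   too-close pair are dropped. The boundary is inclusive — distance exactly
   60 removes — read as "polymorphism-free including the neighbouring 60 bp
   on both sides"; `neighbor_boundary = "lt"` selects the alternative.
   Distance is measured between the `POS` fields of left-normalized
   records; indel spans are not expanded, the simplest reproducible
   convention. The filter runs on the *reliable* site set (after stages
   1–4), matching the accounting order of the rendered report, and is a
   single sorted sweep verified against an all-pairs oracle.

When a strain has several libraries, one library genotypes the strain
(`select_library()`: first tissue-preference match, then lexicographically
smallest id — deterministic); the conflict rule still sees all libraries.
Sites homozygous-reference across every sample never enter the cascade.

## Matrix analytics

* **Pairwise differences** count sites where two strains are both called
  and differ (het vs hom differs), split SNP/indel. Missing never counts as
  a difference, so missingness cannot inflate distances.
* **Group filter** (`maf_min = 0.1`, `miss_max = 0.5`): within a strain
  group (e.g. a row type), a site is dropped when its minor allele
  frequency is below 0.1 *or* its missing fraction reaches 0.5. MAF is
  computed over called alleles with homozygotes contributing two copies and
  heterozygotes one of each; with inbred material heterozygotes are rare,
  but the convention is fixed so results are reproducible.
* **Gap scan** (`min_len` 1 Mbp, strict `>`): adjacent retained markers
  whose positions differ by more than the threshold define a
  polymorphism-free region; the length is the *difference of the flanking
  marker positions* (endpoints exclusive) — the convention fixed by the
  arithmetic of the quantities it must reproduce. Chromosome-end gaps are
  excluded by default (there is no flanking marker); passing chromosome
  lengths includes them.

## Concordance evaluation

**Replicate libraries.** Sites called in both libraries are agreed
(identical genotype) or disagreed; sites called in exactly one library are
tallied separately and excluded from the rate denominator, since absence in
a shallow library reflects expression, not genotype. The agreement rate is
`100 * agreed / (agreed + disagreed)`, undefined (and flagged) when no site
is shared.

**Cross-platform.** An amplicon resequencing panel provides high-depth
orthogonal genotypes at selected markers. Markers whose mean amplicon depth
across strains is below 100× are gated out before comparison (the
comparison should not be confounded by amplicon coverage failures). Per
strain and marker: if either platform lacks a call the marker is *not
detected* (platform-specific missing counts are also reported, since either
side's absence triggers the category); otherwise genotype equality is
scored true/false, stratified by the panel's SNP/indel class. Row rates are
rounded **half-up to three decimals**; summary means to one decimal. The
aggregate SNP and indel rates are the *arithmetic means of the per-strain
rates* — this is what reproduces the published summary values from the
packaged per-strain count table — with pooled-count rates reported
alongside. The high-agreement strain count uses `rate_total >= 90`: the
packaged table contains a row printing exactly 90.000 and only the
inclusive comparison reproduces the published count of 34.

Genotypes are compared as unordered, case-folded allele pairs; for
heterozygous pairs sharing sequence, the common suffix then prefix is
trimmed (keeping at least one base) so indels anchored differently by the
two platforms' callers still compare equal.

`marker_summary()` aggregates the same comparisons per marker: markers with
any missing strain call, markers with zero mismatches, and markers with one
to four mismatches. Because the published denominator convention for the
"complete match" percentage is ambiguous (it equals the complete-match
count over markers *without* missing data, not over all markers), the
function reports raw counts and leaves percentage choices to the caller.

## The synthetic-data generator

Every stage is testable offline: `simulate_bundle()` writes a genome,
gene models, a multi-sample VCF, metadata, amplicon tables and a
planted-truth manifest. The generator emulates the statistical structure of
the real study — inbred strains, shallow overdispersed coverage, replicate
libraries, a high-depth amplicon validation panel — at toy scale (defaults:
2 chromosomes x 200 kb, 40 loci, 12 strains of which 4 have replicate
libraries, 60 clean markers, 10 singletons, 6 close pairs, 5 multi-allelic
sites).

Planted categories map one-to-one onto cascade rules: *clean* markers are
polymorphic in at least two strains with depth >= 2 and no neighbour within
the window (they must survive); *singletons* have exactly one alt carrier;
*close pairs* are spaced 40 bp apart; *multi-allelic* sites carry two
alternate alleles. Planted features are at least 150 bp apart so only pair
members fall inside each other's window. Depth is `2 + NB(mu - 2, size)`
(defaults mu 20, size 5) — overdispersed like expression-dependent RNA-Seq
coverage, with a floor of two reads so planted genotypes are not silently
erased by the depth rule; a separate `single_read_het_rate` plants
single-read heterozygotes to exercise that rule explicitly. Default noise
rates are chosen to resemble the real data's observed behaviour:
`replicate_discordance_rate = 0.09` reproduces replicate agreement near
91%, `amplicon_error_rate = 0.08` and `amplicon_missing_rate = 0.1` give
cross-platform rates near 90%, and `amplicon_frac_low_depth = 11/384`
mirrors the fraction of panel markers failing the 100x gate.

What the generator does **not** emulate: read-level errors and alignment
artifacts, expression-dependent *per-gene* coverage correlation, linkage
disequilibrium and population structure, and platform-specific indel
representation quirks. Passing parameter-recovery tests therefore shows the
*rules* are implemented correctly, not that the thresholds are optimal for
real data.

All randomness lives in the generator (seeded, byte-reproducible); pipeline
stages are deterministic, so identical inputs always produce identical
reports.

## Numerical conventions and degenerate inputs

* Half-up rounding (`round_half_up()`) for all rendered rates; base R's
  banker's rounding would disagree at exact half-way values.
* Rates with zero denominators are `NA` and flagged, never 0 or 100.
* Empty inputs are legal everywhere: an empty VCF yields a zero report and
  an empty panel; an empty region list has `total_bp = 0`.
* Ties in library selection break lexicographically; no RNG is involved
  outside the generator.
* Thousands separators appear only in rendered tables, never in TSV/JSON.

## Problem sizes in the test suite

Unit fixtures use handfuls of sites. Property suites run the neighbour
sweep against an all-pairs oracle on 1,000 random site sets (2–40 sites
each) and interval merging against a per-base mask on 100-kb toy
chromosomes. Rate-recovery checks use ~2,200 planted sites, enough for a
binomial 95% confidence interval of about +/-1 percentage point around a 5%
discordance rate, which the tests assert contains the planted value.

## Known limitations

* The cascade assumes left-normalized VCF records; it does not re-normalize.
* Depth handling trusts `DP` (or the `AD` sum); callers that report
  filtered depths will shift the depth-rule boundary accordingly.
* The within-strain reading of the conflict rule is a documented
  interpretation, not an established convention (see above).
* Genome-scale discovery counts from the original 150-library dataset
  cannot be reproduced at fixture scale; the package reproduces the rules,
  the accounting identities and the published summary statistics computable
  from packaged tables.
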