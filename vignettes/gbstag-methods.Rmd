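---
title: "Tag-based GBS genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based GBS genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The assay and its data model

A GBS library reduces a genome to the ends of restriction fragments.
Every read is `barcode + cut-site remnant + genomic sequence`; because
all reads from one locus start at the same cut site with the same
orientation, a locus is identified by `(chromosome, strand, cut-site
coordinate)` rather than by per-read alignment. The pipeline exploits
this three ways:

1. **Reads collapse into tags.** A *tag* is a unique trimmed read
   (barcode removed, truncated to 64 bp and at any internal restriction
   site). Tags are stored packed at 2 bits per base (`A=00, C=01, G=10,
   T=11`, first base in the most significant bits, zero-padded) with the
   length kept alongside, so a 64 bp tag costs 16 bytes and the pair
   `(payload, length)` is the identity. Only tags seen at least
   `min_count` times (default 5) experiment-wide are kept: observation
   count, not base quality, is the quality signal, because quality decays
   with read position and a GBS SNP sits at a *fixed* position in its
   reads — quality filtering would systematically starve distal SNPs of
   depth. Base qualities are therefore ignored throughout.
2. **Only unique tags are aligned.** The master tag list (thousands to
   millions of entries) is aligned once, instead of billions of reads.
   Placement lives in the TOPM (tags on physical map): one entry per
   master tag — `UNIQUE` entries carry `(chrom, strand, cut_pos)`;
   `MULTIPLE` and `UNALIGNED` tags are retained so positional evidence
   can be added later. For a minus-strand placement `cut_pos` is the
   rightmost aligned base, so the cut-site end of the tag anchors the
   locus on either strand.
3. **Depth is per tag per taxon.** The TBT matrix records how often each
   tag was seen in each taxon, saturating at 127 (one signed byte). In
   diverse populations most tags occur in few taxa, so the matrix is
   mostly zeros; the run-length-encoded persistence stores zero runs in
   two bytes and literals in one, with a whole-matrix checksum.

## Genotype calling

At a site with major/minor allele depths `(d₁, d₂)`, `n = d₁+d₂`, and a
per-base error rate `e` (default 0.01), three exact binomial likelihoods
are compared:

* homozygous major: `Binom(d₂ | n, e)` — minor reads are errors,
* homozygous minor: `Binom(d₁ | n, e)`,
* heterozygous: `Binom(d₁ | n, ½)`.

The maximum-likelihood genotype is called; zero depth is missing. A
threshold `lr_threshold` (default 1, i.e. pure maximum likelihood) calls
the heterozygote whenever the best homozygous likelihood is within that
factor of the heterozygous one, with exact ties going to the heterozygote
— the conservative direction, since low coverage under-calls
heterozygotes. This three-hypothesis construction is the package's own
reconstruction of the quantitative-calling idea it implements; its
contract is fixed by an enumeration test against a direct
likelihood-comparison oracle for every depth pair with `n ≤ 40`.

At low depth the caller is deliberately simple: one single read calls a
homozygote. The population-level filters, not the caller, are the error
control.

## TagLocus alignment

Tags at a locus share an anchored 5' start but differ in length and may
carry indels. They are multiple-aligned by centre-star progressive
alignment: the highest-count tag (ties broken by canonical tag order) is
the guide; every other member is aligned to it by Needleman–Wunsch
(match +2, mismatch −1, gap −3, linear) with *trailing* gaps free, and
the pairwise gap patterns are merged into one frame. Trailing gaps mean
"tag ended", not a deletion allele, and are treated as missing data
downstream; internal gaps are the GAP allele. For a two-tag locus the
result is exactly the optimal pairwise alignment — the tested contract
(a DP oracle over 500 random pairs). Equivalence with any particular
published MSA heuristic is *not* promised; the requirement is consistent,
deterministic indel placement.

Each alignment column with two or more observed symbols is a SNP
candidate. Per-taxon allele depths are sums of member-tag TBT depths;
alleles are ordered by total depth (ties by `A<C<G<T<gap`); genotypes are
called on the top two alleles, and taxa carrying only third-or-lower
alleles are missing. Positions are reported in plus-strand orientation
(`pos = cut_pos ± offset`, alleles complemented on minus loci); when an
overlapping locus on the opposite strand rediscovers the same physical
position, the deeper copy is kept.

## Filters

With minor allele frequency `q` (from called genotypes, heterozygotes
contributing one allele each), `Ho` observed and `He = 2q(1−q)` expected
heterozygosity, the inbreeding coefficient (index of panmixia) is
`F_IT = 1 − Ho/He`. A site is retained iff:

| clause | form | default |
|---|---|---|
| locus coverage (taxa with reads at the locus) | `>=` | 0.10 |
| minor allele frequency | `>=` | 0.001 |
| `F_IT` | `>=` | 0.80 |
| inbred coverage | `>` (strict) | 0.15 |
| inbred heterozygosity score | `<` (strict) | 0.21 |

When a pedigree of expected inbreeding coefficients is supplied, taxa
with `F >= min_f` (default 0.8) form the inbred subset used for `q`,
`Ho`, `F_IT` and the two inbred-specific clauses; without a pedigree the
inbred clauses are skipped and `F_IT` is computed over all taxa. The
strict/non-strict forms above are deliberate and tested. A monomorphic
subpopulation has `He = 0`, an undefined `F_IT`, and fails the `F_IT`
clause by convention. The rationale: true SNPs in inbreds are almost
never heterozygous, so excess heterozygosity flags either error-prone
positions or paralogous tags collapsed onto one locus (which look
heterozygous in *every* taxon and drive `F_IT` towards −1). The inbred
heterozygosity score `nInbredHets/(nInbredsGT1ReadHomoMin + nInbredHets
+ 0.5)` separates genuine minor-allele homozygotes (seen at depth > 1)
from scattered heterozygous calls.

## Error-rate estimation from biparental families

In an F2-derived RIL family a real segregating SNP shows ~1:1 allele
frequencies; a non-segregating SNP should be monomorphic. For every
SNP × family with at least `min_n = 19` non-missing calls, the family
allele frequency is computed from the calls (heterozygotes count half to
each allele — residual heterozygosity exists in real RILs) and the
minor-genotype-equivalent count `round(MAF·n)` is tested against
`Binomial(n, ½)`, two-sided by doubling the smaller tail (capped at 1).
Minor-allele calls are errors iff `0 < MAF < 0.25` *and* the family
deviates at `p < 0.001`; the per-SNP rate divides total error calls by
total calls in deviating families. Monomorphic families count in the
denominator: MAF 0 deviates maximally, and at `min_n ≥ 19` its p-value
(`2·0.5^n`) is far below any sensible `alpha`. The test statistic on the
rounded count is a design choice (the procedure is defined on allele
frequencies, and calls in RILs are nearly haploid); it reproduces the
package's frozen worked examples exactly.

## The synthetic-data generator

Everything the generator emits is a pure function of its configuration,
including the seed. It emulates: a reference in which every
recognition-site occurrence is planted deliberately (spontaneous ones
are disrupted, so the cut-site list is exact); reads of the form
`barcode + remnant + genomic window`, chimera-truncation included when a
neighbouring full recognition site falls inside the read; per-taxon
per-locus Poisson depth; substitution sequencing errors outside the
barcode/remnant (a switch allows hitting them too); inbred panels with
residual heterozygosity `0.5^g`; biparental RIL families; blank negative
controls; and unassembled divergent locus duplicates (paralogs) whose
reads collapse onto the original locus, with divergence placed in the
distal tag region where recent paralogs are conserved proximally.

Defaults (the package's study conditions): 1 Mb single-contig reference,
mean cut-site spacing 1000 bp (ApeKI-like density), both orientations
per site, 96 fully inbred homozygous taxa (an inbred-panel design — the
regime where the population-genetic filters have maximal power and an
error-free run has an exactly recoverable truth), 500 substitution SNPs
with alternate-allele frequency uniform on [0.05, 0.5], mean depth 2
(the low-coverage regime the pipeline targets), error rate 0.003,
equal-length 6 bp barcodes (trivially prefix-free). Indel SNPs and
paralogs are off by default and switched on where an experiment needs
them.

What it does **not** emulate — and therefore what passing tests do not
show about real data: PCR duplicates and fragment-size effects, indel
sequencing errors (indels exist only as true variants), base-quality
structure (irrelevant here since qualities are ignored), adapter
read-through (reads continue into genomic sequence past a chimeric
junction), reference errors, and population structure beyond
inbred/outbred/biparental designs.

The generator also ships a cut-site-anchored tag placement tool
(`align_tags`) that writes SAM: candidate placements are the scanned
recognition-site anchors whose proximal 12 bp (either of two seed
windows) match the tag exactly, scored by Hamming distance with a gapped
fallback for indels, with equal-best candidates emitted as primary plus
secondary records carrying equal `AS`/`XS` scores. `import_sam()` is
independent of it and accepts any SAM 1.x with the usual
flags/MAPQ/score tags.

## Numerical and representational choices

* Tag order is the lexicographic order of the packed payload (equal to
  sequence order with `A`-padding), ties by length — total,
  deterministic, locale-independent; every tag-keyed table iterates in
  it.
* `merge_tag_counts` sums exactly (counts are doubles, exact below
  2^53); merging is associative and commutative and tested against a
  dictionary oracle.
* Depth saturates at 127 everywhere (TBT build, replicate merging,
  production tallies) — a byte would allow 255, but 127 is the stated
  operating limit of the depth model and keeping one limit makes the
  Discovery = Production contract exact.
* Persistence: tag counts and the TOPM have documented little-endian
  binaries plus TSV text forms; the TOPM and TBT additionally round-trip
  through a structured serialized container (RDS). All forms are
  round-trip tested for content identity.
* "Unique best alignment" is operationalised as: a mapped primary record,
  MAPQ at or above `mapq_min`, and no equal-score secondary (`XS >= AS`
  on the primary, or an equal-`AS` secondary record, means `MULTIPLE`;
  with no score tags, MAPQ 0 on a mapped record means `MULTIPLE`).
* At most `max_variants = 8` variants are recorded per tag; a retained
  site that would push a member tag over the bound is dropped (in
  deterministic offset order) and reported as such.
* In VCF output the REF allele comes from the reference FASTA when one is
  supplied (header-flagged), else the major allele; indel alleles are
  anchored at the preceding base. HapMap encodes heterozygotes as IUPAC
  codes, indels as `+`/`-` with `0` for the heterozygote.

## Problem sizes

The test suite exercises unit fixtures at toy scale and three synthetic
experiments chosen to finish comfortably on one CPU: the full default
preset at mean depth 10 and zero error (~2 million reads; exact truth
recovery and the Discovery = Production identity), a 200 kb / 48-taxa /
1%-error experiment with 12 paralog loci (filter efficacy), and
RIL-family designs of 4 × 40 lines for the error-rate estimator
(recovery of injected rates 0, 0.005 and 0.02 within binomial confidence
intervals, exactly zero at zero). `scripts/acceptance.R` re-runs the
same experiments from a caller-supplied seed.

## Known limitations

* Exact truth recovery is a property of the error-free, fully inbred
  default; with heterozygous taxa, low-depth heterozygote under-calling
  is expected and intentional (imputation is downstream and out of
  scope).
* Tags longer than 64 bp, depths above 127, fuzzy barcode matching and
  alternative genotype callers are out of scope.
* SNP positions inside an alignment that contains insertions shift by
  the number of insertion columns before them; positions are exact for
  substitution-only loci (the default simulation regime).
* The TBT's sparsity — and hence its compression ratio — reflects
  allelic diversity, not merely low depth: a low-diversity inbred panel
  yields a dense TBT, and the compression contract is demonstrated on a
  diversity-matched configuration.
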