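---
title: "Inferring reticulate evolution in apogamous fern complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring reticulate evolution in apogamous fern complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reticulator)
```

## The problem and the model

Hybridization between closely related plant lineages produces non-treelike
("reticulate") evolutionary histories. In fern complexes such as the
*Pteris fauriei* group, the signature is particularly clean because three
independent data types constrain each hybrid:

* **Chloroplast haplotypes are strictly maternally inherited.** A hybrid's
  cpDNA identifies its maternal lineage.
* **Nuclear loci are biparental and additive with ploidy.** A diploid hybrid
  carries one allele from each parent; a triploid carries three alleles, the
  extra set arriving through an unreduced gamete (often from an apogamous
  donor, whose gametophytes produce functional sperm without meiotic
  reduction).
* **Spore counts diagnose the reproductive mode.** Sexual plants of this
  group produce 64 spores per sporangium; apogamous plants 32 or fewer.

The model fitted by `infer_reticulation()` treats parental taxa as lineages
fixed for "private" nuclear alleles. Its assumptions, in decreasing order of
importance:

1. Parental taxa are (or were) homozygous at the marker loci, so a genotype
   with a single allele type is parental; a sexual diploid whose two alleles
   belong to one lineage group (a within-lineage heterozygote such as
   `A1A6`) is likewise parental. Apogamous heterozygotes are not granted
   this exemption: apogamy fixes hybrid genotypes, so heterozygosity in an
   apogamous plant is evidence of hybrid origin even within a group.
2. Backcrossing and introgression are negligible — sexual plants are rare in
   the group — so every hybrid is the direct product of one maternal and one
   paternal contribution.
3. Alleles cluster into lineage groups (clade-level bundles, `A`–`H` for the
   primary locus) that are reliable units of parental attribution even where
   the exact allele is unsampled.

Classification runs on a *primary* nuclear locus (the more variable one;
`Knox3` in the shipped data), falling back to the second locus only when the
primary was not amplified. Entries with no nuclear data at all cannot be
shown homozygous and are carried as (unresolvable) hybrids, with a note.

## Maternal lineage: the co-occurrence cascade

The published analyses describe the outcome of maternal-lineage inference
("haplotype X was always present along with group Y"), not an algorithm.
The implemented cascade makes it deterministic. For each haplotype:

1. **Parental carriers.** If exactly one nuclear group occurs among
   parental-status carriers of the haplotype, that group is the maternal
   lineage. This resolves most haplotypes (e.g. `cf`, `cb` → group A;
   `ca` → D; `ci` → G).
2. **Universal co-occurrence.** Otherwise, the group(s) present in *every*
   carrier. This resolves haplotypes carried only by hybrids (`ck`,
   `ch` → H; `cw` → D).
3. **Ambiguity set.** Otherwise all co-occurring groups, flagged. The `cs`
   haplotype, whose carriers share no group, stays honestly ambiguous
   ({B, C, D, H}); the published per-sample calls for those rows also vary,
   and the package does not pretend to resolve them.

When a hybrid formula is assembled, maternal-group alleles are matched
exactly against the registry of homozygous parental taxa; among several
matches the taxon whose own haplotype set contains the hybrid's haplotype is
preferred (this is what assigns `D4D7`/`cy` a *P. wulaiensis* mother and a
*P. latipinna* father rather than the reverse). Exact match failing, taxa of
the right group carrying the right haplotype are used, then any taxa of the
group (flagged ambiguous), then an explicit `unknown` placeholder — hybrids
of extinct or unsampled parents are expected in such complexes and must not
be silently attributed.

## Bookkeeping choices

Three counting conventions were genuinely open and are fixed as follows:

* **The genotype unit is one row of the published genotype table** — a
  distinct sampled combination of taxon, nuclear genotypes, haplotype and
  ploidy, keyed by its representative sample. This reproduces the published
  totals (72 entries = 14 parental + 58 hybrid). Collapsing to
  (taxon, primary-locus string, haplotype) triples would give 63 and is not
  what the source counted.
* **Parental taxa are counted over confidently determined names.** The
  homozygosity rules admit eight taxa, but one (*P.* aff. *confusa*) is an
  uncertain determination with almost no accompanying data; the headline
  count excludes "aff."/"cf." qualified names (giving the published seven)
  and the unrestricted count is reported alongside.
* **Per-lineage hybrid counts are over distinct hybrid primary-locus
  genotype strings**, with membership decided by exact allele match to a
  homozygous parental taxon, in either parental role. Under this definition
  the `D7` lineage (*P. latipinna*) contributes to 18 distinct hybrid
  genotypes and `D4` (*P. wulaiensis*) to 8, matching the published counts;
  maternal-only and paternal-only counts are reported too, since the source
  does not state its role convention.

## Amplicon processing parameters

| parameter | default | why |
|---|---|---|
| barcode length / mismatches | 8 bases, 0 | barcodes are synthesised 8-mers; exact matching is the published behaviour, a tolerance is exposed |
| clustering identity | 0.99 | not stated in the source; 0.99 over ~500 bp separates alleles ≥ 5 substitutions apart while absorbing stray errors |
| retained clusters | top 3 (diploid) / top 4 (triploid or unknown) | the published ploidy-aware rule |
| minimum cluster reads | 100 | the published removal threshold, exposed as a flag |
| rare-allele filter | ≥ 2 samples | the published error-control rule |
| grouping threshold | 0.05 p-distance | groups are clades in the source; single-linkage at 5% reproduces clade-level bundles for lineages ~10% divergent |

Numerical determinism: clusters sort by read count then lexicographic
consensus, so top-k ties resolve to the smaller consensus; consensus
ties per column resolve to the lexicographically smallest base; haplotype
labels are assigned in order of first appearance; every stochastic function
takes a `seed` and restores the global RNG state.

Identity is computed position-wise on equal-length reads (binned by length);
indel-tolerant alignment is deliberately not implemented — the simulator
emits equal-length amplicons, and real indel-bearing loci would need an
aligner upstream. Gap handling in `collapse_haplotypes()` follows the
gaps-as-missing convention (columns with gaps excluded by default).

## The simulator: what it emulates, what it does not

`simulate_parental_panel()` grows parental taxa on a star phylogeny from a
shared ancestral sequence (per-locus binomial substitution counts, uniform
base choice), with defaults matching the published marker lengths
(2184 / 493 / 397 bp) and a 5% per-lineage divergence. It emulates exactly
the features the inference relies on: homozygous diploid parents with
private alleles, hybrids carrying allele unions, strict maternal chloroplast
inheritance, triploids via unreduced gametes from either side, 64- vs
32-spore modes, and Poisson read clusters with independent per-base errors.
Within-group allele diversity (e.g. how far `A1` is from `A6`) is not stated
in the source and is exposed as a parameter rather than guessed.

It does *not* simulate coalescent variation, recombination, selection,
introgression or backcrossing (assumed negligible), chimeric reads by
default, quality-score artefacts, or indels. A green end-to-end test
therefore establishes that the pipeline inverts its own generative
assumptions — 100% parent-pair recovery on zero-error data with distinct
parental groups — not that it is robust to every artefact of real amplicon
data. The per-base error model is exercised separately (binomial mismatch
calibration) and the clustering against brute-force oracles.

The shipped character matrix deserves the same honesty: the source reports
allele–state associations but no per-sample character matrix, so
`fixture_character_matrix()` reconstructs one *from* those associations
(D4 ↔ red-brown stipes; G group ↔ areolate, F ↔ triangular venation, F×G
hybrids areolate). Tests on it verify that `associate_states()` recovers the
planted associations — the mining logic, not an independent biological
discovery.

## Degenerate inputs and edge cases

* More distinct alleles than chromosome sets is an error (contamination or a
  wrong ploidy call), never silently truncated.
* A single allele in a diploid completes to a homozygote; in a triploid it
  yields the unassorted mark (`F7*`) — triple homozygotes are never
  manufactured, though verbatim ones in input (`F7F7F7`) are preserved.
* Unknown ploidy: observed alleles with `unassorted = NA`, retained top-4 in
  clustering.
* Spore counts strictly between 32 and 64 (or above 64) match neither
  syndrome: `unknown`, with a warning.
* Samples without a chloroplast haplotype are excluded from co-occurrence
  (logged) and their formulas flagged unresolved.
* Empty inputs (no reads, no clusters, header-only tables) return empty,
  well-typed results.

## Known limitations

* Lineage groups substitute for gene-tree clades; with the distance
  clusterer, groups are only as good as the 5% cut. A fixture-style prefix
  map should be preferred when a curated phylogeny exists.
* The maternal cascade cannot resolve haplotypes whose carriers share no
  group (`cs`), and does not attempt subgenome phasing; a Bayesian phasing
  approach could, at the cost of determinism.
* Second-locus information is used only as a fallback and consistency
  check, not fused into the formulas.
* The chimera check flags only perfect two-parent mosaics of equal length.
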