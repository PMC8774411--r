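---
title: "Screening for recessive lethal variants behind homozygote-deficient haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for recessive lethal variants behind homozygote-deficient haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recleth)
```

## The inference chain

A recessive juvenile-lethal allele hiding behind a SNP-array haplotype
leaves three fingerprints that this package turns into a single pipeline:

1. a *homozygote deficit* in large genotyped cohorts — homozygous
   haplotype carriers are observed far less often than Hardy–Weinberg
   proportions predict, because most die before genotyping age;
2. a *concordance pattern* in sequenced genomes — the causal variant must
   be heterozygous in every sequenced haplotype carrier and absent
   (homozygous reference) from every non-carrier, within the haplotype
   region;
3. a *validated mode of action* — typically a protein-truncating variant
   whose homozygotes, produced on purpose through at-risk carrier×carrier
   matings, segregate 1:2:1, grow worse and die young.

`concordance_filter()` + `impact_filter()` implement step 2,
`call_consequence()` the annotation behind it, and the `stats` functions
(`deficiency_test()`, `fisher_exact_2x2()`, `hwe_chisq()`,
`segregation_test()`, `wilcoxon_exact()`, `allele_frequency()`,
`concordance_audit()`, `attributable_mortality()`) step 3.
`run_pipeline()` sequences them.

## Models and assumptions

**Deficiency test.** With `O` observed and `E` expected homozygotes, the
p-value is the Poisson lower tail `P(X ≤ O)` for `X ~ Poisson(E)`, and
the deficit is `D = (E − O)/E`. The Poisson form treats the expected
count as the rate of a counting process over many near-independent
matings; with `O = 3`, `E = 72` it gives `p = 3.49e-27`, matching the
screen literature's reported value for those counts, which is why it is
the default. A binomial variant (`n_trials`, `p_hom`) is provided for
sensitivity; at cohort scale the two are indistinguishable.

```{r}
deficiency_test(3, 72)
```

**Association and HWE.** The haplotype–genotype association uses the
conventional two-sided Fisher exact test (probability-mass rule) on the
2×2 table of non-homozygous animals; `stats::fisher.test()` supplies the
computation (its tie tolerance can push the sum a hair above 1, so the
wrapper clamps at 1). The Hardy–Weinberg test is the Pearson chi-square
against expectations computed from the allele frequency estimated on the
same counts, with 1 degree of freedom and *no* continuity correction —
with Yates' correction the canonical at-risk-mating counts (5, 6, 5)
would give p ≈ 0.52 instead of the exact-arithmetic 0.317, so the
uncorrected statistic is the right convention here.

**Segregation.** `segregation_test()` pools offspring over matings using
each mating type's Mendelian class probabilities (het×het → ¼, ½, ¼;
het×hom_ref → ½, ½, 0; …), flags and excludes offspring impossible given
their parents, and reports the Pearson chi-square with df = classes − 1
by default (`df = "one"` gives the HWE-style convention).

**Exact rank sum.** Growth comparisons involve a handful of lambs, often
with tied weights. `wilcoxon_exact()` computes the exact permutation
distribution of the midrank sum by dynamic programming over doubled
ranks (so midranks stay integral), valid with ties — which
`stats::wilcox.test()`'s exact mode is not — and caps the two-sided
p-value `2·min(tails)` at 1. Exact mode is limited to 25 observations;
beyond that the DP is still exact but such sizes do not occur in this
design.

**Attributable mortality.** Assuming Hardy–Weinberg conception
frequencies and full juvenile lethality, homozygote conceptions are a
fraction `q²` of births, hence `q²/m` of all deaths when overall
juvenile mortality is `m`. For `q = 0.06`, `m = 0.15` this is 0.024 —
2%, about one dead lamb in 50. The "one in N" rendering snaps to a round
denominator from {10, 20, 25, 50, 100}.

## The prioritization filter

`filter_config()` carries the screen's tunables:

* `region` — the haplotype span, 1-based inclusive;
* `flank_bp` — flank added to each side, default 1,000,000 bp (1 Mb),
  covering variants in linkage disequilibrium just outside the marker
  window; pass 0 when the region is already extended;
* `min_qual` — variants must satisfy `qual > min_qual` (strict
  inequality), default 30;
* `carrier_ids` / `noncarrier_ids` — the sequenced carriers and the
  samples required to be homozygous reference; `noncarrier_ids = NULL`
  means *all* other samples, matching screens that use both same-breed
  non-carriers and unrelated breeds as the exclusion panel.

A missing genotype at any required sample *fails* the variant. This is
the conservative reading of a condition phrased over "every carrier" and
"all non-carriers": an uncalled genotype cannot certify concordance.
Missing-driven failures carry their own reasons (`carrier_missing`,
`noncarrier_missing`) so relaxed re-runs can be audited. Each failing
variant records exactly one *first-fail* reason in the fixed order
region → quality → carrier condition → non-carrier condition, which
makes reports reproducible and the funnel counts monotone. Multi-allelic
VCF records are rejected with a logged reason by default (the screen
considers biallelic polymorphisms); `split_multiallelic = TRUE` recodes
them per alternate allele.

## The consequence engine

A `transcript_model()` is exon geometry (genomic intervals in transcript
order, strand-aware) plus the spliced sense-strand sequence and the
transcript offset of the CDS start. The CDS is defined to run from
`cds_start_tx` to the *first in-frame stop* of the reference sequence —
the model must reach one — so the reference frame can contain no
internal stop by construction. All user-facing coordinates are 1-based
inclusive (VCF/HGVS convention); interval arithmetic happens internally
on cumulative exon lengths.

Classification translates the reference and mutant CDS and compares the
proteins: an earlier mutant stop is `stop_gained` (impact `HIGH`), a
changed residue `missense` (`MODERATE`), an identical protein
`synonymous` (`LOW`), a lost stop `stop_lost` (`MODERATE`), and
non-coding positions are `MODIFIER`. Two guards catch coordinate bugs
early: the model base at the mapped position must equal the
strand-adjusted VCF reference allele (hard error on mismatch), and for
every `stop_gained` call `alt_protein_len == codon_index − 1` by
construction.

**Coding-coordinate dialects.** Strict HGVS numbers `c.` positions from
the first CDS base (`dialect = "cds"`, the default). Some annotation
chains instead print transcript-origin numbering. The two dialects
reconcile on the packaged CCDC65-like fixture only if the 5′UTR is
190 nt: transcript position 521 minus 190 lands on CDS base 331, the
first base of codon 111. The fixture therefore sets a 190-nt 5′UTR and
uses `dialect = "transcript"` to reproduce the printed strings — that
UTR length is a reconciling assumption of the fixture, not an annotated
value, and is documented as such on `gene_model_fixture()`.

```{r}
gm <- gene_model_fixture()
call_consequence(gm$model, gm$variant, dialect = "transcript")
```

`truncation_summary()` classifies protein domains against the premature
stop residue (`retained` / `partially_retained` / `lost`); the packaged
domain bounds are synthetic, chosen so the truncated protein keeps the
N-terminal NYD-SP28 domain and loses the two distal coiled-coil domains.

## What the synthetic data emulate — and what they do not

`sim_config()` fixes the study conditions; defaults are the published
values wherever one is printed:

| parameter | default | origin |
|---|---|---|
| `n_cohort` | 2952 | genotyped cohort size |
| `q_causal` | 0.06 | estimated allele frequency (≈12% carriers) |
| `lethality_survival` | 3/72 | observed/expected homozygotes |
| `n_matings_at_risk`, `ai_success_rate` | 17, 0.65 | at-risk mating design |
| `birthweight` | M 4.9 ± 1.0, F 3.9 ± 0.6 kg | printed means |
| `n_sequenced_carriers/noncarriers` | 2 / 86 | sequenced panel |

Unprinted rates were set once to values a breeding-program geneticist
would call realistic and are not tuned: the recombination-shortened
haplotype rate 0.022 (≈ the 9-in-408 discordance pattern of such
cohorts), the haplotype-call error rate 0.0012 (≈ 3 in 2543), a twin
probability of 0.45 (16 lambs from 11 pregnancies), ADG 260 ± 60 g/day
with a −120 g/day homozygote deficit, and juvenile survival 0.2 for
homozygous lambs (deaths at days 15–25).

The generator draws conception genotypes at Hardy–Weinberg proportions,
removes non-surviving homozygotes, derives haplotype status from the
true genotype and perturbs it by the two discordance mechanisms; the
variant assay itself is taken as error-free (such assays are validated
by sequencing), so discordance arises only on the haplotype side. The
27 array markers are *not* individually simulated — only their
downstream consequence (status discordance) matters to the pipeline —
and there is no pedigree structure beyond parent–offspring, no
age-structured death hazard (survival to genotyping age is a single
Bernoulli), no linkage map, and no selection or drift across years.
Passing tests on these data therefore certify the *inference machinery*,
not the sequencing or haplotyping processes of a real screen.

## Numerical choices and degenerate inputs

* Poisson and binomial tails come from `ppois()`/`pbinom()`, accurate in
  the far tail (verified against independent log-space term summation to
  nine digits for `E ≤ 200`).
* Monomorphic HWE input returns chi² = 0, p = 1 with a warning; `n = 0`
  is an error.
* Percent renderings round half-up (64.7% → 65%, 12.5% → 13%).
* Phase in VCF genotypes is ignored (`|` read as `/`); the analysis
  never uses it.
* An empty VCF or a region on an absent chromosome yields an empty,
  well-typed table (with a warning), and the pipeline records skipped
  stages with reasons instead of failing.
* Pipeline reports are written atomically (temp file + rename) and carry
  a config hash, seed and package version.

## Problem sizes

The test suite exercises the exact statistics against enumeration
oracles (all 2×2 tables with totals ≤ 10 plus random tables to total 40;
full permutation enumeration for rank sums up to 11 observations),
property checks over randomly generated transcript models (every exonic
position round-tripped; ~600 random SNVs against an independent
translate-both oracle), and parameter recovery on seeded simulations of
10⁵ cohort members and ~10⁴ offspring — sizes at which binomial standard
errors make 3-s.e. recovery checks meaningful while the whole suite runs
in well under a minute.

## Known limitations

* Only single-nucleotide substitutions are classified; InDels are out of
  the engine's scope (the screen's candidates are SNVs).
* No splice-site, UTR-regulatory or nonsense-mediated-decay prediction;
  one transcript per gene model.
* The Fisher p-value underflows to 0 for extreme tables (the 2×2 cohort
  association); the acceptance bound `p < 1e-4` is unaffected, but exact
  log-scale p-values for such tables are not provided.
* `sequenced_panel_fixture()` embeds the published candidate variants
  verbatim; its decoys, and everything in `simulate_cohort()` /
  `simulate_matings()`, are synthetic.
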