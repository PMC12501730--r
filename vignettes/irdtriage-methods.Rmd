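---
title: "Variant triage and ACMG classification for IRD gene panels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant triage and ACMG classification for IRD gene panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdtriage)
```

## The problem

Inherited retinal dystrophies (IRDs) — retinitis pigmentosa, Leber
congenital amaurosis, Stargardt disease, Usher and Bardet-Biedl
syndromes, and rarer subtypes — are caused by variants in well over a
hundred genes under autosomal recessive, autosomal dominant and
X-linked recessive inheritance. Targeted gene-panel sequencing of an
affected patient yields hundreds of annotated calls; the desk work of
molecular diagnosis is a fixed triage protocol that reduces them to a
handful of reportable variants, an evidence-combination step that
assigns each survivor one of five pathogenicity tiers, and a
per-patient decision of whether the surviving genotype explains the
phenotype. This package implements that desk work as tested, reusable
code, together with the cohort-level statistics a diagnostic study
reports (diagnostic yield, pathogenicity and variant-type
distributions, gene recurrence, novelty counts).

The package ships the variant and demographic tables of a published
94-patient Turkish IRD panel cohort, transcribed verbatim into
plain-text fixtures (97 reported patient-variant pairs, 28 novel
variants, eight clinical subgroups). These tables are both worked
examples and the validation surface: every headline statistic the
package computes from them is checked against the printed value.

## The triage cascade

Annotated calls pass four filters, applied in protocol order:

1. **Variant fraction**: kept iff the fraction of reads supporting the
   alternate allele lies in the inclusive interval [0.15, 1.0]. A
   missing fraction removes the call with reason `missing_vaf`.
2. **Population frequency**: kept iff the *maximum* over the available
   database frequencies (gnomAD, 1000 Genomes, ESP) is strictly below
   0.1%. "Below" is read literally as a strict inequality, while
   interval bounds elsewhere are inclusive. A call absent from all
   three databases is kept: a rare-variant triage must not discard
   unobserved variants.
3. **ClinVar assertion**: Benign and Likely benign assertions are
   removed; conflicting assertions and unasserted calls are kept.
4. **Consequence class**: missense, nonsense, frameshift, in-frame
   indels, delins, deletions, duplications and splice-site calls are
   kept. Intronic substitutions are splice-site within ±20 bp of the
   junction and removed beyond it. Synonymous calls are removed only
   when every *available* splice predictor (MutationTaster, Human
   Splicing Finder) calls them `no_effect`; with no predictor
   available they are kept, since nothing demonstrated them inert.
   (`synonymous_rescue = "any_predictor"` switches to elimination on a
   single dismissal.)

Each filter is an independent per-call predicate, so the survivor
*set* is invariant under all 24 stage orderings — only the stage at
which a multiply-failing call is removed depends on the order. The
funnel report materializes the per-stage bookkeeping and satisfies a
conservation invariant: removals across stages plus survivors
partition the input exactly.

Two wordings of the splice-window step circulate in protocol
descriptions — "intronic variants within 20 bp eliminated" versus
"20 bp junction variants selected". We resolve the window as KEEP
inside ±20 bp, remove beyond: the reported cohort contains an intronic
substitution at +13 (IFT172 c.3228+13G>A), which only the
keep-inside reading admits. Both readings are preserved here for the
record; the window is configurable.

Upstream of the cascade, `qc_sample()` applies the DNA-sample gate:
both absorbance ratios (A260/280, A260/230) within the inclusive
interval [1.8, 2.2] and at least 100 ng of DNA.

## HGVS-lite parsing and consequence typing

The parsers cover the subset of HGVS that panel reports actually
print: coding-DNA substitutions, deletions (with or without stated
bases), duplications, insertions and delins over anchor+offset
positions, and protein substitutions, stop-gains, frameshifts
(`fs*N` and `fsTerN` are the same syntax), synonymous changes and the
unknown effect `p.?`. Published tables typeset the intronic minus as
an en dash and occasionally break a residue name with a space
(`p.Arg 4192Gly`); all unicode dash look-alikes and stray spaces are
normalized before parsing, and parsing round-trips through formatting
up to that normalization. There is no inversion support, no
genomic/mitochondrial coordinates, and no reference-sequence
validation — transcripts are carried verbatim and never checked.

Consequence typing gives protein-level evidence precedence: a
frameshift, stop-gain, residue substitution or synonymous protein
change decides the class outright, so a DNA delins that produces
`p.Ile582*` counts as nonsense. Only for `p.?` does the DNA edit
decide, and non-substitution intronic edits keep their DNA edit kind
rather than becoming splice-site. This choice is visible in the
packaged cohort: the classifier reports the two intronic deletions
(KCNV2 c.1356+3_1356+6del, ABCA4 c.1554+3_1554+4del) as deletions and
the PROM1 c.2118G>T (p.Gly706Gly) row as synonymous, where the
cohort's printed tally bins them as one splice-site + one deletion and
as missense respectively. The printed tally is itself ambiguous about
which intronic deletion went where, so `variant_type_distribution()`
accepts an expected tally and *flags* divergent classes instead of
absorbing them; the unambiguous classes (nonsense 23, frameshift 13,
delins 2) are reproduced outright.

## Evidence combination

Evidence codes arrive as the concatenated token strings reports print
(`"PVS1PM2PS4PP5"`), parsed against the closed 28-token vocabulary
(PVS1, PS1–PS4, PM1–PM6, PP1–PP5, BA1, BS1–BS4, BP1–BP7). Two
combination modes exist:

* **Rule-table mode** (`combine_richards()`): the published combining
  rules — Pathogenic for PVS1 with (≥1 strong | ≥2 moderate | 1
  moderate + 1 supporting | ≥2 supporting), ≥2 strong, or 1 strong
  with (≥3 moderate | 2 moderate + ≥2 supporting | 1 moderate + ≥4
  supporting); Likely pathogenic for PVS1 + 1 moderate, 1 strong +
  1–2 moderate, 1 strong + ≥2 supporting, ≥3 moderate, 2 moderate +
  ≥2 supporting, or 1 moderate + ≥4 supporting; Benign for BA1 or ≥2
  benign-strong; Likely benign for 1 benign-strong + 1
  benign-supporting or ≥2 benign-supporting; otherwise VUS. P wins
  when P and LP both fire.
* **Points mode** (`combine_points()`): signed integer weights per
  strength (very strong 8, strong 4, moderate 2, supporting 1; benign
  strong −4, benign supporting −1; BA1 disqualifying) with thresholds
  P ≥ 10, LP 6–9, VUS 0–5, LB −6…−1, B ≤ −7. These are the stated
  defaults of this package, overridable in `combiner_config()`; they
  follow the published Bayesian-points convention and make no claim
  to reproduce any commercial tool's internals.

Mixed evidence is governed by a conflict policy. The default,
`pathogenic_dominant`, lets a firing pathogenic combination stand even
when benign evidence is present; this was a deliberate choice because
the packaged cohort contains a row carrying BS2 alongside
PVS1+PM3+PM2+PP5 that is nonetheless reported Pathogenic, so a
strict policy would misrepresent the pipeline that produced the data.
The `strict` policy returns VUS whenever evidence from both categories
coexists with a firing combination — including when the benign side is
a lone code that fires no rule of its own, which we treat as
unresolved conflict rather than ignorable noise.

Codes are consumed at face-value strength. Strength modulation (PM2
used as supporting, PVS1 downgrades, and the other adjustments
interpretation tools apply internally) is intentionally not modelled:
reports print only the face-value tokens, and guessing hidden
adjustments would manufacture concordance. The consequence is
measurable: `reconcile_with_reported()` classifies every fixture row
and counts agreement with the printed classification, and rows such
as `PM2PP4` printed as LP (which no face-value combination explains)
are required — by test — to surface as discordant. Concordance is a
reported quantity here, never an assertion.

## Case solving and cohort statistics

A patient is molecularly solved when, among their P/LP records, they
carry (a) a homozygous or hemizygous record, (b) at least two
heterozygous records in one gene whose modes include AR, or (c) a
heterozygous record in a gene whose modes include AD. The rules are
tried in that order; genes annotated "AD, AR" can solve by either
recessive or dominant logic, and hemizygous males in XLR genes solve
by rule (a). Cohort studies rarely state this rule explicitly even
though their yield arithmetic implies one; here it is explicit,
and every solved patient carries its rule and records in the output.
Compound-heterozygote phase is *assumed* in trans — panel tables carry
no phasing — and the output flags the assumption. Under this rule the
packaged table's 97 rows across 76 patients resolve into 70 solved
patients and 6 unsolved carriers (each holding only single
heterozygous hits in AR-only genes), giving the 74% yield.

Percentages use half-up rounding: two decimals for distribution
shares, nearest integer for the headline yield (70/94 = 74.47% → 74%).
`reconstruct_counts_from_percentages()` inverts the printed
demographic percentages back to integer counts by summing
`round(n · pct/100)` per subgroup under the same convention;
on the packaged demographic table it recovers 69 consanguineous
and 52 male patients. The demographic table is carried for this
reconstruction only — no per-patient demographics exist and none are
fabricated. Novelty is reconciled, not trusted: `flag_novel()`
requires a bijection between the novel-variant list and cohort rows
on (patient, gene, normalized cDNA) and errors on any unmatched or
doubly-matched entry. The raw novel ratio in the packaged data is
28/97 = 28.87%; printed summaries round it variously to 28% or 29%,
so the package reports the count and leaves rounding to the caller.

## Segregation checks

`check_trio_consistency()` formalizes the confirmation step performed
on first-degree relatives. For an AR homozygous proband both available
parents must carry at least one alternate allele (an available
hom_ref parent is inconsistent); an AD heterozygous proband needs one
carrier parent, with both parents hom_ref yielding possible-de-novo;
an XLR hemizygous male needs a carrier mother, the father's genotype
never deciding. Any required relative being unavailable — and any
zygosity/mode configuration without a rule, such as a lone
heterozygous record in an AR gene — yields an uninformative verdict.
Consanguinity is recorded metadata but never evidence, and sibling
genotypes carry no decision rule. The implementation is tested
exhaustively against an independent allele-enumeration oracle over
all genotype configurations per mode, and AR verdicts are symmetric
in the parents. Segregation results annotate records; they never
feed back into the evidence codes (no automatic PP1), because the
source protocol gives no rule for doing so.

## The synthetic cohort generator

`generate_cohort()` exists so every pipeline stage is testable
end-to-end without any external data. Its defaults emulate the
packaged cohort: 94 patients, a 74% solved rate, a 73.4%
consanguinity rate, criteria sets drawn from the empirical
distribution of the 97 fixture strings, and genes (with inheritance
modes, unioned per gene) from the 45 fixture genes. Background calls
average 8 per patient — a plausible post-annotation panel residue —
split across planted fates.

Ground truth is *constructed, not sampled post hoc*: each record is
built either to survive every filter or to violate exactly one named
filter and pass all others, so cascade recovery is exact by design,
and the tests assert zero-error recovery rather than statistical
agreement. To keep fates off decision boundaries, failing frequencies
are sampled in [2, 10] × threshold and surviving ones in
[0, threshold/2] or absent; failing VAFs in [0.01, 0.10] against the
0.15 cutoff. Planted solved patients receive genotypes satisfying one
of the case-solving rules, with criteria drawn only from fixture
strings whose face-value rule-table class is P or LP, so recovery
cannot depend on the engine mode; background survivors carry empty
criteria and classify VUS, so they can never solve a patient. Trios
are generated consistent with each causal variant. The generator is
deterministic for a fixed seed (R's default Mersenne-Twister integer
state) and restores the caller's RNG state on exit.

What the generator does *not* emulate: linkage and haplotype
structure, sequence context (no reads, no reference), annotation
noise (every planted fate is clean-cut where real annotations
conflict), multi-gene phenocopies, and the long tail of structural
variants a panel can miss. Passing recovery tests therefore
demonstrates the pipeline's bookkeeping and rule logic, not its
behaviour on the messiness of real annotation sources.

## Numerical and interface choices

* All interval bounds inclusive (VAF 15% kept, QC ratio 1.8 passes);
  strict inequality only for "below 0.1%".
* Half-up rounding everywhere a printed percentage is matched, with a
  1e-9 epsilon absorbing binary representation error.
* Ties in the gene distribution break alphabetically; recurrence keys
  normalize HGVS typography so an en-dash and a hyphen spelling of
  one variant count once.
* Degenerate inputs are defined: empty cascades produce zero-count
  funnels, empty cohorts summarize without division by zero, the
  empty criteria string is a valid empty set (VUS).
* Fixture integrity is enforced on load: row counts (9/97/28),
  subgroup sizes summing to 94, every criteria string parsing, and an
  md5 checksum over line-ending-normalized content, so transcription
  drift fails loudly.
* The command-line front end (`inst/cli/ird-triage.R`) is a thin
  wrapper over the exported functions with subcommands `classify`,
  `reconcile`, `triage`, `summarize`, `segregate`, `simulate`; it
  exits 0 on success, 2 on schema/validation rejections, 1 otherwise,
  and logs stage counts to standard error. Configuration files are
  YAML with the `cascade_config()` keys. A minimal VCF ingestion path
  (`read_vcf_minimal()`, via the vcfR reader) maps the documented
  INFO/FORMAT keys and splits multi-allelic sites.

Problem sizes used by the test suite are deliberately desk-scale: the
rule-table engine is checked against its oracle on all 24,158 token
subsets of size ≤ 4 plus randomized larger sets, order-invariance on
generated batches of a few hundred calls under all 24 permutations,
and exact recovery at 200 synthetic patients — sizes chosen because
they already cover every code path and boundary the larger versions
would.

## Known limitations

* Evidence codes are inputs; the package never assigns them from raw
  annotations (no PS1/PM5 lookup, no PP3 from in-silico scores).
* Face-value strength means reconciliation against tools that modulate
  strength internally will show discordance by construction; the
  report quantifies that gap but cannot attribute it.
* The case-solving rule is genotype-only; it does not check phenotype
  fit, and "AD, AR" annotations make rule (c) available to genes whose
  dominant mechanism may not apply to the observed variant class.
* HGVS coverage is the panel-report subset; descriptions outside it
  (inversions, complex alleles) are rejected rather than guessed.
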