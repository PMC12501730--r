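# irdtriage

Variant triage, ACMG classification and diagnostic-yield computation for
inherited retinal dystrophy (IRD) gene panels.

## What this is for

Targeted panel sequencing of an IRD patient (retinitis pigmentosa, Leber
congenital amaurosis, Stargardt disease, Usher/Bardet-Biedl syndromes, ...)
produces hundreds of annotated calls per patient. Turning them into a
molecular diagnosis is desk work with a fixed shape, and this package
implements that shape as tested code for clinical bioinformaticians and
methodologists:

* **HGVS-lite parsing** of the coding-DNA and protein change descriptions
  panel reports print (`c.802-8_810delinsGC`, `p.Glu4Glyfs*41`), tolerant
  of published-table typography (en dashes, stray spaces), plus
  consequence typing with protein-over-DNA precedence.
* **Triage cascade**: variant fraction in [15%, 100%] → max population
  frequency (gnomAD/1000G/ESP) < 0.1% → ClinVar Benign/Likely-benign
  exclusion → consequence-class selection with splice-predictor rescue of
  synonymous calls; every run emits a conservation-checked funnel report.
* **ACMG/AMP evidence combination** over the 28-token vocabulary
  (PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4, BP1–7), in rule-table mode —
  e.g. Pathogenic for `PVS1 + ≥1 strong`, `≥2 strong`, `PVS1 + ≥2
  moderate`, ... ; Likely pathogenic for `PVS1 + 1 moderate`, `1 strong +
  1–2 moderate`, `≥3 moderate`, ... — and in a points mode
  (VS 8, S 4, M 2, P 1; benign −4/−1; P ≥ 10, LP 6–9, B ≤ −7), with an
  explicit conflict policy for mixed evidence and a reconciliation report
  against classifications a table already carries.
* **Case solving**: a patient is solved by a homozygous/hemizygous P/LP
  record, two heterozygous P/LP records in one AR gene (phase assumed in
  trans, flagged), or a heterozygous P/LP record in an AD-capable gene;
  diagnostic yield, pathogenicity/type/gene distributions, recurrence and
  novelty reconciliation follow.
* **Trio segregation checks** per inheritance mode, verified against an
  exhaustive Mendelian enumeration.
* **A seeded synthetic-cohort generator** that plants per-record fates
  (survive, or fail exactly one named filter) and per-patient solved
  genotypes, so the whole pipeline is validated by exact recovery.

The package ships the variant tables of a published 94-patient IRD panel
cohort as plain-text fixtures (97 reported variants, 28 novel variants,
demographic subgroups) and reproduces that cohort's headline statistics
from them.

## Worked example

```r
library(irdtriage)

combine_richards("PVS1PM2")
#> [1] "LP"

tab2 <- load_fixture("table2")   # 97 patient-variant pairs
tab3 <- load_fixture("table3")   # 28 novel variants
summarize_cohort(tab2, 94, novel_list = tab3)
```

```
<cohort_summary>
  97 variants in 76 patients of 94 tested; yield 70/94 = 74.47% (74%)
  pathogenicity:
    P     58 ( 59.79%)
    LP    39 ( 40.21%)
  consequence types (nonzero):
    missense        45 ( 46.39%)
    nonsense        23 ( 23.71%)
    frameshift      13 ( 13.40%)
    splice_site     11 ( 11.34%)
    delins           2 (  2.06%)
    deletion         2 (  2.06%)
    synonymous       1 (  1.03%)
  genes: 45 distinct; top ABCA4 with 20 variants in 16 patients
  novel variants: 28
```

Reading the output: 70 of the 94 patients are molecularly solved (74%
diagnostic yield) — the remaining six variant carriers hold only single
heterozygous hits in AR-only genes. The classifier reports the one
synonymous row and both intronic deletions at face value (hence 45
missense / 11 splice-site / 2 deletions); the published tally bins them
as 46/12/1, and `variant_type_distribution(tab2, expected = ...)` flags
exactly that divergence rather than absorbing it. Reconciliation of the
ACMG engine against the table's printed classifications
(`reconcile_with_reported(tab2)`) yields 71 concordant and 26 discordant
rows — discordance is expected, since reports apply internal
evidence-strength adjustments the printed tokens do not show, and the
package deliberately consumes tokens at face value.

A command-line front end wraps the same functions:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "ird-triage.R", package = "irdtriage"))')
Rscript "$cli" classify --criteria PVS1PM2PS4PP5          # P
Rscript "$cli" triage --calls calls.tsv --config cfg.yaml \
               --funnel funnel.tsv --out survivors.tsv
Rscript "$cli" simulate --seed 7 --n-patients 94 --out-dir sim/
```

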