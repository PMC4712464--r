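---
title: "Screening exome CNV predictions with an in-house database: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exome CNV predictions with an in-house database: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscreen)
```

## The problem

Exonic CNV prediction from read depth is sensitive but noisy: the callers
in common use (ExomeCopy, ExCopyDepth, ExomeDepth, CoNIFER, XHMM)
normalise a sample's coverage against a *reference collection* of exomes,
and anything that perturbs coverage — capture efficiency, GC content,
mapping in repeats — produces spurious calls. Crucially, those
perturbations are shared across the collection, so the same false call
recurs in many samples. Each caller also emits a quality score (a Bayes
factor, a log-odds, XHMM's Q_SOME, CoNIFER's SVD-ZRPKM), but on scales
that are not comparable across programs.

`cnvscreen` turns these two observations into a screening statistic and
wraps it with annotation, filtration and benchmarking. This vignette is
the package's own account of the model, its assumptions, the parameters
that matter, and the design decisions that were genuinely open.

## The screening model

Let $D_P$ be the set of CNV calls predicted by program $P$ from the
reference collection, each carrying a location, a quality score $s_i$ and
a sample ID. For a query call $q$ from the same program, define its match
set $M(q) \subseteq D_P$: the database calls sharing at least one base
with $q$, carrying the same CNV type (DEL/DUP), excluding calls from
$q$'s own sample. Then

* **database CNV count** $n(q)$ = number of *distinct* sample IDs in
  $M(q)$, and
* **CNVQ** $= \operatorname{median}\{ s_i : i \in M(q)\}$, missing when
  $M(q) = \varnothing$.

The working hypothesis is that recurrent technical artifacts are called
in many samples with low scores, while true variants are rarer and score
high; so artifacts separate from real calls jointly in $(n, \mathrm{CNVQ})$.
Because score scales differ, one database is kept per program, and
screening a call set against another program's database is a hard error.

Three boundary decisions were open and are resolved as follows:

* **CNVQ with a single match.** The median over a set is classically
  quoted for two or more members; we define the singleton case as the
  call's own score (the median of one), so `db_count = 1` calls are not
  score-less. This is an extension and is documented as such.
* **Self-exclusion.** When the query sample is itself part of the
  reference collection, its own database entries would trivially match
  every query, forcing $n(q) \ge 1$ everywhere. They are excluded by
  default (`keep_self = FALSE` reverses this for collections that do not
  contain the query sample).
* **Type-aware matching.** Whether a database duplication should support
  a deletion query is a substantive choice; treating the two as the same
  event is biologically wrong, so matching is typed by default with a
  `type_blind` switch for parity experiments. The same choice recurs in
  catalog annotation and TP labeling, with the same default and switch.

Counting *distinct samples* rather than overlapping entries matters when
a fragmented caller emits two overlapping pieces in one sample; the count
is meant to estimate "in how many exomes was this locus called", not "how
many rows overlap".

## Coordinates and the overlap rule

All coordinates are 1-based and fully closed — the native convention of
the callers' outputs — and every overlap test in the package (database
matching, annotation, TP labeling) uses the same rule: at least one
shared base, i.e. $\max(s_a, s_b) \le \min(e_a, e_b)$ on the same
chromosome. Adjacent intervals do not overlap. The rule is deliberately
permissive because breakpoints disagree across platforms and programs;
requiring reciprocal overlap would silently drop cross-platform matches.
BED-style input (0-based, half-open) is converted once, at the parser
boundary (`parse_calls()` with the `bed` dialect), never downstream.
Chromosome names are normalised to the `chr` dialect; `X` and `chrX` are
the same chromosome.

Calls on X and Y can be dropped before screening and before benchmarking
(`exclude_xy`): mixed-sex reference collections make sex-chromosome
coverage bimodal, and prediction there is unreliable for reasons the
screening statistic cannot repair.

CoNIFER's SVD-ZRPKM statistic is signed (negative for deletions, roughly
$[-3, 3]$); its magnitude is the quality score, so ingestion stores the
absolute value and keeps the signed value in a `raw_score` passthrough
column.

The caller-native input layouts shipped as built-in dialects are
best-effort reconstructions of each program's documented output and are
marked as such; any layout can be described exactly with a YAML dialect
file (`read_dialect()`), which is the robust path for pinned program
versions.

## Annotation

Eleven track schemas cover three families: gene/functional (gene models
with exons and UTRs, conserved elements with scores, per-gene
haploinsufficiency and genic-intolerance scores), known CNVs from
healthy-population catalogs (Sanger high-resolution, raw DGV, curated
DGV at two stringency levels with population frequencies, 1000 Genomes
split by type), and clinical (OMIM morbid map, DECIPHER DDD genes,
ClinVar variants). Specifics worth knowing:

* `exon_count_internal` counts exons **fully contained** in the CNV, not
  merely touched — the quantity that matters when judging whether a
  deletion removes coding sequence outright (e.g. a deletion of exons
  3–8 with intact flanking exons 2 and 9 counts 6).
* Conserved-element scores are summarised as the maximum over
  overlapping elements (the most conserved element hit is the relevant
  one for impact assessment); per-element scores are also emitted.
* Gene-keyed scores join by gene symbol *through the gene overlap set*,
  so a haploinsufficiency record never appears for a gene the CNV does
  not touch.
* "Known CNV" status — the filtration input — is driven only by the
  healthy-population catalogs: Sanger, type-matched 1000 Genomes, and
  the *curated* DGV maps (either stringency by default;
  `stringent_only` restricts it). The raw DGV count is annotation, not
  filtration: DGV's heterogeneous contents are known to be problematic
  as a clinical filter, which is why the curated maps exist.

Annotation is total (a CNV overlapping nothing annotates to
zeros/empties) and never mutates the call fields, so stages can be
re-ordered or re-run freely.

## Filtration

A call is kept iff it passes every enabled rule; removals are logged with
the first failing rule, tested in the order known → score → CNVQ →
database count → gene panel (most interpretable first). Parameters:

| parameter | default | meaning |
|---|---|---|
| `min_score` | −Inf (presets: 10/40) | program quality score, strict `>` |
| `min_cnvq` | −Inf (presets: 10/40) | CNVQ, strict `>`; missing CNVQ passes |
| `exclude_known` | FALSE (presets: TRUE) | drop catalog-known calls |
| `max_db_count` | unset | keep `db_count <` this; conventional value 5 |
| `candidate_genes` | unset | keep only panel-gene hits |

The strict inequalities are exactly as the stringency thresholds are
printed (score > 10/40); a score of exactly 40 fails the high preset, and
the tests pin this.

Two decisions deserve their rationale:

* **Missing CNVQ passes the CNVQ rule.** A call with `db_count = 0` was
  never seen in the reference collection — the rarest, most interesting
  case. Failing it for lack of a score would preferentially discard
  exactly the disease candidates the workflow exists to find. A
  `strict_cnvq` switch fails closed for users who want symmetric
  behaviour.
* **The database-count filter is off in both presets.** A genuine
  disease variant shared by related samples in the collection would be
  removed by a count cut; the count is therefore surfaced as evidence
  and as an optional flag (`max_db_count`, conventionally 5), not baked
  into the presets.

## Benchmarking against array CGH

Array CGH on the same samples provides the orthogonal truth. A
prediction is **TP** when a same-type array call overlaps it; otherwise
it is **FP** only when the predicted interval contains at least 4 array
probes — if the design could not have seen the event, the prediction is
**INDETERMINATE** and excluded from all curves (the count is reported).
The probe rule is applied only to FP eligibility; array CNV calling
itself (segmentation, log-ratio thresholds) is upstream and out of
scope — the package consumes called array intervals.

From labeled calls the package derives: the cumulative curve (distinct
scores descending; cTP/cFP at score ≥ q; FDR = cFP/(cTP+cFP); FP/TP
ratio, infinite until the first TP), the CNVQ-ratio table (median TP
CNVQ / median FP CNVQ per database-count stratum, typically restricted
to counts < 5 where the separation is cleanest; strata lacking either
class emit no ratio), and a joint score/CNVQ threshold sweep mirroring
the filtration rule. Curves are cumulative by design — they answer "what
survives threshold q" — with the per-score variant available by
recomputation on subsets.

## The synthetic fixture

`generate_fixture()` writes every input format the pipeline reads, from
one seeded generator (byte-identical per seed, no global RNG state left
behind). The toy genome is three 10-Mb autosomes plus chrX (to exercise
`exclude_xy`); genes sit every 60 kb with 5–9 exons and UTRs. The
defaults are the package's reference study conditions:

* 20 reference exomes; 12 artifact loci recurring in ≥ 8 samples (two on
  chrX), scores from the false-call distribution;
* 40 real CNV loci in 1–4 samples (recurrence cycling 1,2,3,4 so every
  low count stratum is populated), scores from the true-call
  distribution; 40 % planted into the synthetic public catalogs,
  cycling through Sanger / 1000 Genomes / curated DGV;
* 24 sporadic false loci in 1–4 samples at low scores — without these,
  every FP would carry a database count ≥ 8 and the low-count strata
  would contain no FPs at all, making the CNVQ-ratio analysis vacuous;
* 2 disease deletions on candidate-panel genes, absent from the
  reference collection and all catalogs, scores above the high preset;
* score distributions are overlapping lognormals with the true-call
  median ≈ 3× the false-call median (45 vs 15), so filtration is
  non-trivial — some true calls fall below any threshold that removes
  all false ones;
* an array truth set covering the real and disease loci, and a probe
  grid with 6 probes inside every planted locus so unconfirmed calls are
  FP-eligible under the ≥ 4-probe rule.

What the fixture does **not** model: read-level noise, capture-kit
coverage structure (only its downstream signature — recurrent low-score
calls — is planted), breakpoint uncertainty beyond a few hundred bases
of jitter, overlapping genes, and population allele-frequency structure.
Passing tests therefore demonstrate that the statistics and filters
behave as designed *given* the recurrence/score structure, not that any
particular caller attains a particular FDR on real exomes.

## Numerical and degenerate-input choices

* Percentages are rounded half-up to 2 decimals (base R rounds
  half-even; accounting output should match hand arithmetic).
* Medians use the standard even-count convention (mean of the middle
  two).
* Non-finite scores are rejected when the database is built; row-level
  parse failures (bad coordinates, unparseable scores, unknown CNV
  types) drop the row and report it with its line number — counts always
  reconcile (`rows in = rows out + errors`).
* Empty inputs are legal everywhere they can be: an empty call file
  parses to an empty set, an empty track annotates to zeros; an empty
  reference collection is an error (a database of nothing is
  meaningless).
* The FP/TP ratio is `Inf` while no TP has been reached, never a silent
  `NaN`; FDR over an empty labeled set is an error rather than a number.

## Scale of the shipped checks

The test suite regenerates all fixtures at run time: oracle-equivalence
checks run brute-force scans against the indexed implementations on
hundreds of random fixtures of up to 300 intervals, and the
structure-recovery checks run the full pipeline on the default fixture
across 10 seeds — sizes chosen to exercise every code path while keeping
the whole suite fast enough to run habitually. Known limitations beyond
the fixture realism above: no liftover between genome builds, no
breakpoint refinement, no cross-program score normalisation (by design),
and clinical interpretation of the surviving calls remains a manual
step — the package ends at a short, annotated candidate list.
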