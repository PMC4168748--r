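---
title: "Clone-based somatic SNV analysis of the hnRNP A1 M9 amplicon"
author: "cloneSNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based somatic SNV analysis of the hnRNP A1 M9 amplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneSNV)
```

## The assay and what the package models

hnRNP A1 is an RNA-binding protein that shuttles between nucleus and
cytoplasm; its M9 domain (residues 268-305) is a PY-type nuclear
localization signal bound by transportin-1 (TPNO-1) and contains the
epitope (293-304) targeted by IgG in multiple sclerosis (MS) patients.
The assay this package models amplifies a 611-bp region of hnRNP A1
genomic DNA covering exons 8 and 9 (local coordinates g.3080-3690, cDNA
c.752-963, protein residues 252-320), clones the PCR product into a
plasmid, screens clones for the insert by EcoRI digestion, and
Sanger-sequences individual clones. Because every clone derives from one
template molecule, a substitution seen in a small fraction of clones is a
candidate *somatic* SNV present in a subset of peripheral blood
mononuclear cells, provided it exceeds what the polymerase error process
(0.10% of clones) can explain.

The pipeline covers each step in software: a coordinate-aware reference
model with HGVS c./p. naming (`transcript_model()`, `consequence()`,
`parse_hgvs()`), per-clone variant calling by global alignment
(`align_clones()`, `call_snvs()`, `call_clone_set()`), annotation against
the functional-domain map and local variant catalogs
(`annotate_variants()`), cohort rate statistics against the error model
(`rate_table()`), mutagenic primer design (`design_primer_pair()`),
cross-species conservation reports (`column_conservation()`), and a
synthetic data generator (`build_reference()`, `simulate_clone_set()`).

## Coordinate system and codon framing

Coordinates are 1-based and inclusive on the coding strand throughout.
Genomic positions are the assay's local gene coordinates (g.3080 style),
not chromosome coordinates. Codon `n` occupies c.(3n-2)..(3n); this is
the unique framing consistent with the published (c., p.) pairs (c.826
in codon 276, c.900 closing codon 300). The modeled cDNA window
c.752-963 therefore opens with the last two bases of codon 251; the
first fully represented residue is 252 and c.961-963 is the stop codon
(residue 321). The exact exon 8/9 boundary inside the amplicon is not
fixed by any published value; it is a configurable model field
(`exon8_end_c`, default c.800) on which no in-scope result depends
except intron placement.

Amino acids are rendered one-letter (`F273L`) to match the source
tables; `format_hgvs_p()` renders the `p.` form.

## The constraint-built reference

The true genomic sequence of the amplicon is not part of the packaged
inputs, so `build_reference()` constructs a stand-in by constraint
satisfaction. For every codon of residues 252-321 it enumerates the 64
codons, keeps those compatible with all nucleotide and protein anchors,
then searches for the largest jointly satisfiable subset of the variant
event constraints attached to that codon, and finally picks the
lexicographically smallest satisfying codon (a deterministic tie-break).
The anchors are all derived from packaged printed data:

* every variant event pins its reference base, and its
  (ref aa, alt base → alt aa) pair where satisfiable;
* the wild-type context of the three mutagenesis primers pins c.805-857
  base-by-base (each printed primer is a single-base design, so all
  other primer bases are template sequence);
* the PY-NLS alignment table pins the protein sequence of residues
  262-289;
* catalog stand-in records pin their reference bases;
* c.900A with c.900A>G synonymous at arginine 300 forces the R300 codon
  to CGA, and c.963A with c.963A>G stop-retained forces the stop codon
  to TAA.

Unconstrained coding positions receive seeded random *sense* codons, and
intron/flank sequence is seeded random with the PCR primer footprints
fixed verbatim; all in-scope results depend only on the constrained
positions. Editable fill is kept free of the EcoRI motif because the
insert screen presupposes exactly two vector sites — a generator design
constraint, not an empirical claim.

Three published event rows are jointly unsatisfiable with the rest under
the standard genetic code and are excluded and reported rather than
silently repaired: c.817T>G labeled F273L (computes F273V), c.898C>T
labeled R300S (computes R300* given CGA), and c.922T>G labeled S308P
(computes S308A). `validate_printed_pairs()` flags exactly these three;
the package takes no position on whether the nucleotide or the protein
label is the typo.

```{r discrepancies}
ref <- build_reference()
ref$discrepancies[, c("subject", "c_pos", "ref", "alt", "label")]
```

## Domain conventions and event counting

`domain_map()` carries two published interval conventions: the default
(PrLD 233-267, TPNO-1 core 268-289) and the overlap variant (PrLD
233-272, core 263-289). Switching conventions only adds tags for
residues 263-272; the default keeps PrLD and M9 disjoint, which makes
PrLD and M9 event counts additive.

Rates count one event per event-table row (equivalently per clone), at
most one counted event per clone — the only reading under which the
published percentages equal the published counts (7/317 = 2.21%). The
default consequence-class filter is *amino-acid-altering* (missense plus
nonsense): the source counts "SNVs that resulted in an amino acid
substitution", and one counted event (c.898C>T) computes as a nonsense
change under the standard code although its printed label is missense.
A strict missense-only filter would silently drop that event; the
broader filter reproduces the published counts from computed
consequences. Synonymous and stop-retained events are excluded and can
be tabulated separately.

```{r rates}
ann <- annotate_variants(table1_events(), ref$model,
                         catalogs = make_catalog_standins())
ann$residue <- ann$aa_index
rate_table(ann)[, c("region", "group", "events", "clones", "rate_pct",
                    "fold_over_error", "exceeds_one_log")]
```

`region_rate()` compares each rate with the polymerase error model
(default 0.001 per clone). "Exceeds the error rate by more than a log"
is formalized as `fold_over_error > 10`. The exact one-sided binomial
tail `p_exceedance` is an extension beyond the source's informal
comparison and is labeled as such. Percentages are rounded half-up to
two decimals to match the published printing.

## PY-NLS epitopes and the FUS alignment

The packaged alignment pairs hnRNP A1 residues 262-289 with FUS residues
507-526 column by column, including the gap columns. Epitope intervals
default to: epitope 1 hydrophobic 273-276 (FGPM), epitope 2 the basic
residue R284 (assigned from the aligned FUS 522R — the hnRNP A1-side
assignment is a documented default), epitope 3 the C-terminal
R-X(2-5)-P-Y motif 284-289 (RSSGPY).

`fus_mutation_overlap()` supports two readings of "SNV positions
aligning with ALS-associated FUS mutations". The table's star row marks
two columns (275 ↔ 510 and 284 ↔ 522), and that is the default
(`criterion = "starred"`). A strict column-by-column intersection of the
SNV positions with the FUS ALS mutation row additionally yields 280
(↔ G515C) and 281 (↔ E516V), so `criterion = "mutation_row"` reports
the superset {275, 280, 281, 284}. The two readings disagree in the
source material itself; both are exposed and the starred one is treated
as the headline claim.

## The clone caller

Global (Needleman-Wunsch) alignment with affine gaps replaces the
heuristic local aligner used interactively in the original workflow: the
amplicon is short, clones are near-identical, and an exact aligner is
deterministic. Default scores: match +1, mismatch −2, a gap of length k
costs 5 + 2k. Orientation is detected by aligning both the read and its
reverse complement and keeping the higher score (ties to forward).
Acceptance requires ≥98% identity over aligned columns; rejected clones
leave both numerator and denominator and are logged in the QC report.
The published denominators count clones sequenced, which presupposes
usable reads; whether any clones were rejected upstream of those
denominators is not stated, so the acceptance policy is configuration,
not an assertion. Primer footprints are masked from calling because
primer-derived sequence cannot report template variants; read bases `N`
never produce calls. Indel-bearing clones default to
"exclude-from-calls, keep-in-denominator" (`indel_policy =
"mask_calls"`).

The alignment scores are verified against an independent brute-force
dynamic-programming oracle on randomized short pairs in the test suite.

## The simulator

`simulate_clone_set()` plants, per clone, at most one somatic
amino-acid-changing SNV (uniform residue in the target region, uniform
nonsynonymous single-base change in that codon) with the configured
probability, and independently one uniform polymerase-error substitution
anywhere in the amplicon with probability 0.001. The per-clone Bernoulli
error model matches the granularity of the published 0.10% per-clone
figure, which the source compares directly to per-clone SNV rates; a
per-base reading is not modeled. Everything is reproducible from the
seed.

What the simulator does *not* emulate — and hence what passing
round-trip tests do not show about real data: chromatogram noise and
base-calling uncertainty, indel errors (the assay reports substitutions
only), cloning bias among template molecules, and contamination. The
round-trip guarantees are: with error probability 0 the pipeline's calls
equal the simulator truth exactly; with error 0.001 the fraction of
error-bearing clones is binomially calibrated; planted somatic rates are
recovered without bias up to Monte-Carlo error.

## Mutagenesis primers

`melting_temperature()` evaluates the kit formula
Tm = 81.5 + 0.41·%GC − 675/N − %mismatch, with %GC computed on the
primer as synthesized and %mismatch = 100·(mismatched bases)/N (the
natural reading; the kit documentation does not define it).
`design_primer_pair()` picks the codon for the desired amino acid
reachable with the fewest nucleotide changes, ties broken
lexicographically — all three published designs are single-base changes
consistent with this rule — and emits the reverse primer as the exact
reverse complement. `validate_primer_pair()` applied to the published
pairs reports, verbatim: the F281L pair is internally consistent; the
F273L reverse differs from the reverse complement of its forward at two
positions; the M276L reverse is a different length than its forward (and
matches the reverse complement of the F273L forward). No intended
sequences are guessed.

## Conservation reports

`column_conservation()` consumes an aligned ortholog set (it does not
build alignments) and reports, per column, the fraction of non-gap,
non-reference rows matching the reference residue; gapped rows leave the
denominator because cross-taxa indels are expected in this region. The
ortholog sequences themselves are not published in machine-readable
form, so `make_ortholog_fixture()` ships *synthetic* alignments shaped
like the published comparison — mammals identical to human except five
rhesus differences, exactly one of which (residue 300) coincides with an
observed SNV position. The four non-overlapping rhesus positions are
fixture parameters, not assertions about the real rhesus sequence.

## Numerical and engineering choices

* Percentages: round half-up to 2 decimals (`floor(x·100 + 0.5)/100`).
* Codon and primer-design tie-breaks: lexicographic (A < C < G < T).
* Alignment tie-breaks follow the exact-scoring aligner; score equality
  between orientations resolves to forward.
* Binomial tails via `stats::pbinom`; translation via the standard
  genetic code table; no floating-point comparison anywhere in event
  counting.
* Degenerate inputs: empty catalogs classify everything `novel`; empty
  event tables give all-zero rate tables; an empty species subset gives
  an empty conservation overlap; a zero clone denominator is an error.
* Problem sizes exercised by the test suite and acceptance script,
  chosen as desk-scale analogues of the study: 200 error-free
  round-trip replicates of 20 clones, 20 replicates of 50,000 clones
  for error-rate calibration, 15 replicates of 317-clone PPMS-like
  cohorts for rate recovery, 1,000 randomized pairs for the alignment
  oracle.

## Known limitations

Only isoform A numbering (320 residues) is supported; splice-site
effects, base-quality-aware calling, IUPAC mixed-base genotyping and
population allele frequencies are out of scope. Catalog lookups are
local TSV stand-ins, so novelty classes describe agreement with the
packaged records, not with live database releases. The reference
amplicon is a constraint-satisfying stand-in: positions not pinned by
printed data are synthetic, and analyses that depended on them would not
transfer to the real gene. The accession oddity in the published
submission list (a protein accession paired with c.-style names) is
preserved as-is by the parser, which treats `NM_002136.2` as the cDNA
accession; likewise both published spellings of the ALS mutation
position (D262V/D263V) are carried as annotations without adjudication.
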