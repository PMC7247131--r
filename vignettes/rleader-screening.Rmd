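---
title: "Screening candidate ribosomal leaders: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate ribosomal leaders: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rleaderScreen)
```

## The screening problem

Ribosomal leaders (r-leaders) are structured RNA elements in the 5′ UTRs of
mRNAs encoding ribosomal proteins. An excess r-protein binds the leader of
its own transcript and represses the operon, closing a feedback loop that
keeps r-protein synthesis matched to rRNA synthesis. Candidate r-leaders
produced by comparative genomics are alignments with a proposed consensus
secondary structure; before an experimentalist invests in one, several
independent lines of evidence should agree:

1. the proposed structure is supported by *covariation* — paired mutations
   that preserve base pairing and therefore indicate selection on structure;
2. the motif sits consistently upstream of r-protein genes, so a regulated
   operon can be inferred from gene context;
3. a plausible r-protein ligand can be named;
4. the motif lies between a transcription start site (TSS) and the first
   regulated gene, as a *cis*-regulator must;
5. the motif is not a rediscovery of a published RNA.

`rleaderScreen` implements each line as a separately callable stage plus an
orchestrator, `run_screen()`. This vignette records the models behind each
stage, the tunable parameters and their defaults, and the design choices
made where the design was genuinely open. No empirical claim is made here
beyond what the package's tests and the repository's acceptance script
themselves compute.

## Coordinates and alignment conventions

All genomic intervals are **1-based, closed**, the convention of GFF and of
the R/Bioconductor interval stack used for I/O (`rtracklayer`,
`GenomicRanges`); BED's 0-based half-open coordinates are converted at the
boundary by `rtracklayer`. One convention everywhere prevents off-by-one
drift; the intergenic gap between two features is the number of nucleotides
strictly between them, so features that abut have gap 0.

Alignment columns are likewise 1-based. `T` and `U` are equivalent for all
pairing logic but sequences are never rewritten on output, and case (often
used to encode alignment confidence) is ignored by every computation.
Only the per-column consensus structure line (`#=GC SS_cons`) is consumed;
per-sequence structure lines are preserved verbatim but not interpreted,
because all covariation statistics are defined against the consensus
pairing. Unknown `#=GF/#=GS/#=GR/#=GC` annotations survive a read → write
round trip unchanged, since upstream alignment archives routinely carry
nonstandard metadata.

## Covariation evaluation

For an annotated pair `(i, j)`, every sequence is classified exactly once:

* **canonical** — its two residues form one of `AU, UA, GC, CG, GU, UG`;
* **non-canonical** — any other residue combination;
* **gapped** — a gap character in either column.

Two detectors then run per pair.

**Permissive rule.** The pair "covaries" when (a) at least two observed
canonical pair *types* differ at both positions — so `GC` vs `AU` counts
and `GC` vs `GU` does not — and (b) *fewer than* 10 % of sequences are
non-canonical (strict inequality; exactly 10 % fails). Two decisions here
were open and are now fixed:

* the 10 % denominator is **all** sequences; a half-gapped pair is neither
  canonical nor non-canonical. This reads the fraction literally over the
  alignment rather than over ungapped rows, and makes gap-rich columns
  harder, not easier, to flag.
* "differ at both positions" is evaluated over distinct canonical *types*,
  not over sequence pairs; this is the only reading under which a pure
  `GC`→`GU` wobble column is not covariation, consistent with standard
  usage.

**Permutation G-test.** The association statistic is the likelihood-ratio
statistic of the joint residue table of the two columns (sequences gapped
at either column excluded pairwise; score 0 when either column is
constant). The null distribution permutes the residues of each column
independently across sequences, preserving composition while destroying
association; the p-value uses the add-one rule
`p = (1 + #{G_null ≥ G_obs}) / (1 + B)`, so it is never 0 and is exactly 1
for constant columns. Null draws start from the *sorted* residue multisets,
which makes the p-value invariant under row permutation of the alignment
for a fixed seed. Across a motif's pairs, p-values are Benjamini–Hochberg
adjusted — a standard, per-motif choice matching the per-motif scope of the
screen's claims.

This test is a deliberately simple stand-in for phylogenetically corrected
covariation statistics: it treats sequences as exchangeable, so shared
ancestry inflates apparent association when an alignment consists of a few
deep clades. The package documents it as screening evidence; it does not
attempt a null from simulated phylogenies, APC correction, or E-value
calibration, and it never proposes pairs absent from the consensus
structure.

**Rating.** A motif is rated `Y` (likely RNA) when at least 1 pair is
BH-significant at `alpha = 0.05` *and* at least 2 pairs satisfy the
permissive rule, else `?` (borderline). The published criteria behind such
ratings live in supplementary curation notes rather than a formula, so the
thresholds are configurable arguments with these defaults.

## Operon inference

Gene-context heuristics mirror manual curation practice:

* **8 kb rule** (`min_downstream = 8000`): an occurrence is usable only if
  ≥ 8 kb of sequence exists downstream of the motif in transcription
  direction. This guards against truncated contigs, so "available sequence"
  is measured to the contig end regardless of gene content.
* **500 nt rule** (`max_gap = 500`): genes chain while the intergenic gap
  is ≤ 500 nt (gap 500 chains, 501 breaks). Overlapping or nested
  same-strand genes chain with gap 0, since operonic overlaps
  (translational coupling) are common. An opposite-strand gene ends the
  chain; genes overlapping the motif itself are skipped because r-leaders
  sit in 5′ UTRs.
* **Consensus support** (`min_support = 0.75`): a gene enters the consensus
  operon when it appears in ≥ 75 % of usable chains. The curation notion of
  "consistently located" has no published numeric threshold; 0.75 is this
  package's default and is configurable. Genes with support in
  `[0.25, 0.75)` are reported separately as "often-extended", mirroring the
  plus-sign convention of published operon tables rather than silently
  dropping them. Retained genes are ordered by modal rank across chains,
  ties broken by median rank then symbol (smallest mode on multimodal
  ties) — fully deterministic.

## Ligand prediction

The governing assumption — true in all experimentally characterised
cases — is that the ligand is encoded by a regulated gene. Let `P` be the
distinct r-proteins of the operon's retained genes, after collapsing
declared dimers (if S6 and S18 are both present they become the single
ligand `S6:S18`; the dimer table is editable config):

1. `|P| = 1` → that protein, basis **Only**.
2. exactly one member of `P` in the known-ligand table → basis **Prior**.
3. otherwise → the first r-protein gene in transcription order, basis
   **Closest**. The fallback picks the first *r-protein* gene, not the
   first gene of any kind, because only r-proteins are plausible ligands.

Inference is two-pass: pass 1 resolves all motifs against the literature
table; ligands of the resulting Only calls are added with provenance
`this-run`; pass 2 re-resolves the remaining motifs, so a ligand first
established within the screen can justify a Prior call (reported with an
`@` tag). One refinement proved necessary: when augmentation itself creates
multiple known-ligand hits in one operon, **literature entries take
precedence** — if exactly one hit is literature-established, the call is
Prior on that hit. Without this rule, a screen that establishes, say, L17
from a single-gene motif would demote every multi-gene operon containing
`rplQ` alongside an established ligand from Prior to Closest, which
contradicts how such tables are curated. Calls are independent of motif
input order, and per-motif failures are quarantined rather than aborting
the batch.

The packaged known-ligand table is a best-effort literature transcription
(17 entries, including the dimer `S6:S18`) and is explicitly
user-replaceable; provenance `this-run` is reserved for the second pass.
Confidence is surfaced as an ordinal tag (Only > Prior > Closest), not a
probability — the bases differ in kind, not on a common scale.

One fixture row documents a printed inconsistency: the L20 motif's
regulated gene is printed as `rpsT` (conventionally S20) while its ligand
column reads L20 from a single-gene operon. The packaged table keeps the
symbol as printed and adds a per-motif `ligand_override` so the printed
ligand column is reproduced without guessing which symbol was intended;
the gene→protein map itself is not distorted.

## TSS consistency and novelty

A TSS verdict is computed per occurrence against the first chained gene:
`consistent` when some same-strand TSS within the locus window (default
2000 nt upstream of the gene's transcription-sense start) lies upstream of
the motif with no annotated same-strand gene start strictly between TSS and
motif; `inconsistent` when TSSes exist in the window but all fall inside
the motif or between motif and gene; `no-data` otherwise. The window
default is an artifact decision — per-study matching criteria in the
transcriptomics literature vary — and is configurable.

The novelty filter eliminates a motif when any occurrence overlaps a
same-strand published RNA by ≥ 50 % of the shorter interval. Published
practice says only "overlap"; the 50 % default tolerates sloppy boundary
annotations, and a strict mode eliminates on any 1-nt overlap. Manual
structural-similarity comparisons (deciding that two motifs are "the same
RNA" without coordinate overlap) are out of scope by design — only
coordinate overlap is automated.

## Synthetic data

`simulate_alignment()` draws a root sequence with canonical pairs at every
annotated pair column, evolves it down a random bifurcating topology
(`ape::rtree`) with i.i.d. exponential branch lengths, and emits the tips.
A pair-column substitution event (probability `1 − exp(−bl)` per branch)
is compensatory — both partners change to a different canonical pair —
with probability `compensatory_rate`, else leaves a non-canonical pair;
after evolution each tip/pair is independently forced non-canonical with
probability `noncanonical_noise`. Defaults (24 sequences, mean branch
length 0.5 substitutions/site, compensation 0.95, noise 0.02) describe a
well-sampled, structure-conserving family of the size typical for curated
RNA motif alignments. Compensation is instantaneous rather than a two-step
rate model: sufficient to produce the covariation signal the detectors
consume, which is the generator's purpose.

What the generator does *not* emulate — indels, alignment error, base
composition bias, rate heterogeneity, rRNA-mimicry sequence content —
bounds what passing tests show: they validate the detectors against their
own stated models, not against the messiness of genuine alignments.
`generate_genome_fixture()` is fully deterministic given its layout and is
used to realize boundary cases (gap exactly 500 vs 501; 7,999 vs 8,000 nt
of downstream sequence) as real GFF3/BED files.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise each property at
desk scale: permutation counts of 200–1000 per pair; type-I error measured
over 100 independent-column alignments of 30 sequences × 6 pairs; detection
power over 100 generator seeds at 100 sequences with 5 % noise (the
permissive rule's 10 % bound leaves adequate headroom at that depth);
parameter recovery at 200 sequences × 12 pairs against a 3-standard-error
band. The genome-scale screen that motivates the package — multi-database
homology search plus manual curation — is not reproducible at desk scale;
the suite substitutes distributional properties of the detectors plus exact
replay of the published motif table, and the packaged aggregate counts
(20 novel motifs against 35 prior r-leaders, a > 50 % increase) are
asserted from the packaged fixtures at test time.

Degenerate inputs are defined, not accidental: empty pair tables rate `?`;
constant columns score 0 with p = 1; operons without r-protein genes return
an explicit "no candidate ligand" result; zero usable occurrences flag the
operon rather than inventing one.

## Known limitations

* The permutation null ignores phylogeny (above); its significance calls
  are anti-conservative on clade-structured alignments.
* Consensus-operon support is a proxy for the curator's judgment of
  "consistently positioned"; no distance statistic is modeled for genes
  that are consistently far away.
* The ligand vocabulary is table-driven; organisms with nonstandard gene
  symbols need an extended gene→protein map, and unknown symbols are
  deliberately classed `other` (with a warning) rather than guessed.
* De novo motif discovery, covariance-model homology search, rRNA mimicry
  assessment and figure drawing are out of scope; the package starts from
  an existing structure-annotated alignment.
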