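---
title: "Consensus orthology calling: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus orthology calling: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthovote)
```

## The consensus model

`orthovote` aggregates the outputs of six independent orthology-inference
tools into 1:1 ortholog calls for one ordered species pair. The statistical
idea is simple voting: tools make largely independent errors, so requiring
k-of-n agreement trades recall for a large gain in precision. A tool "votes"
for the pair `(a, b)` exactly when its *normalized* output contains an
orthogroup whose member set is precisely one gene per species, `{a, b}`.
Membership of the two genes in a larger cluster is deliberately **not** a
vote: a cluster with a second gene from either species is evidence of
co-orthology, under which no unique 1:1 assignment is safe. Calls are pairs
with at least `k` votes, pruned to a partial bijection.

The default `k = 3` follows the Alliance of Genome Resources convention for
integrative ortholog predictors. It is configurable (`consensus_config()`)
because this package runs six tools rather than the twelve-plus of a full
DIOPT-style suite; with six tools, `k = 3` means a majority-minus-one
threshold. The tools' own stringency settings (BLAST e-value 1e-40,
FastOrtho inflation 1.5) are carried as configuration metadata only — the
tools are run upstream, never by this package.

### Normalization assumptions

Tool outputs are protein-level and dialect-specific; voting is gene-level.
The normalization cascade is, in fixed order: filter single-species groups →
strip tokens to RefSeq accessions → map to Entrez gene IDs → drop unmapped
members → re-filter single-species remnants → collapse groups sharing a
gene → flag candidates. Two ordering decisions deserve note:

* **Re-filtering after mapping.** A group can *become* single-species when
  its only member from the other species fails to map. Such a remnant cannot
  witness orthology, so it is removed by default (`refilter = TRUE` in
  `to_gene_level()`); the audit reports how many groups each filter stage
  removed, so the effect is always visible.
* **Two collapse phenomena are audited separately.** Several proteins of one
  gene inside one group deduplicate silently (an artifact of isoform-level
  annotation, not of tool disagreement); distinct groups sharing a gene are
  merged transitively and counted as merge events. After collapsing, each
  `(species, gene)` occurs in at most one group per output — the property
  the candidate-1:1 definition relies on.

Unmappable identifiers are dropped and counted by default, mirroring a lossy
production pipeline; `strict = TRUE` aborts on the first loss, which is the
right mode for curated inputs where any loss indicates a broken key file.

### Identifier mapping

Keys come from two sources: GTF annotations (`protein_id` together with a
`db_xref "GeneID:…"` or numeric `gene_id` attribute) and RefSeq GPFF protein
records (`VERSION` accession plus CDS `GeneID` cross-reference). GTF
attribute extraction is key-based — one regular expression per attribute —
because attribute order is unspecified in the GTF ecosystem. On conflicting
gene IDs for the same accession, GPFF wins (it is the protein-authoritative
RefSeq source); same-source conflicts keep the smaller gene ID so that
merging is associative and order-independent. Versioned keys are stored, but
lookups fall back to a versionless view in which the highest stored version
wins, because tool outputs and annotation releases routinely disagree on
accession versions. All conflicts and skips are counted in the map's audit.

### Conflict resolution in calling

With exact-pair voting, one gene can only appear in two above-threshold
pairs when tools disagree about its partner. The package keeps the pair with
strictly more votes and, on a tie, drops every pair involving that gene:
preserving the 1:1 guarantee without inventing a preference between equally
supported alternatives. Dropped pairs are counted (`n_conflicts`), never
silently discarded. Within the suite this rule is cross-checked against a
brute-force per-gene maximum-vote oracle on randomized vote tables.

### Lateral inference

Consensus calls relate the anchor species to one other species. A map
between two non-anchor species X and Y is the relational composition of
anchor↔X and anchor↔Y: `(x, y)` is inferred iff some anchor gene maps to
both. Composing partial bijections yields a partial bijection, so the result
needs no further pruning; its size is bounded by the smaller input. Supports
are not propagated through composition (a deliberate v1 restriction: the
minimum-of-supports heuristic would suggest more confidence than the
composed evidence warrants), and composing an already-inferred map requires
an explicit flag so transitive chains cannot form silently.

### Expression units

`compute_fpkm()`, `compute_tpm()` and `fpkm_to_tpe()` are pure unit
conversions: FPKM divides counts by kilobases of transcript and millions of
mapped fragments; TPM normalizes length-corrected rates to a fixed per-sample
total of 10⁶ (so TPM columns always sum to one million — an invariant the
tests assert to 1e-6 relative tolerance); transcripts-per-embryo is FPKM
scaled by 60, an embryo-count calibration specific to the S. purpuratus
developmental series. The factor is exposed as `tpe_factor` because it
encodes biology (transcripts per embryo at the calibrated stages), not math.
Effective-length estimation belongs to the upstream quantifier and is out of
scope; callers supply whichever lengths they trust. Degenerate inputs are
handled explicitly: an all-zero count column yields an all-zero result with
a warning (not NaN), and non-positive lengths are an error.

## The fixture generator

`generate_truth()` plants a ground truth: 1:1 relations, many:1 and
many:many co-ortholog clusters, and unassigned genes, each gene carrying 1-2
synthetic RefSeq accessions (`proteins_per_gene_max = 2` by default, because
real RefSeq annotation assigns multiple isoform `XP_` accessions to most
genes, and exercising the many-proteins-per-gene collapse is precisely what
fixtures are for). `render_tool_outputs()` writes the truth into all six
dialects plus GTF/GPFF fragments carrying exactly the planted keys, so
fixtures traverse the same parsing and validation as real data.

The noise model acts on group structure and token text only: per-tool
independent group dropout (`p_drop`), merging of adjacent groups
(`p_merge`), splitting (`p_split`) and identifier decoration
(`p_decorate`, emulating FASTA-header prefixes and species suffixes).
Per-tool noise streams derive from a master seed as
`(seed + 7919·tool_index) mod (2³¹−1)`, so a fixed seed reproduces every
file byte-for-byte. Under pure dropout the number of tools retaining a
planted pair is Binomial(6, 1−p), so recall at threshold k should track
`P[Binom(6, 1−p) ≥ k]` — the suite checks the measured curve at
p ∈ {0.1, 0.3, 0.5} over 500 planted pairs against this tail within three
Monte-Carlo standard errors.

What the generator does **not** emulate: sequence evolution (tools disagree
in reality because alignments disagree — dropout is a structural surrogate),
correlated errors between tools sharing a BLAST stage, assembly artifacts,
or incomplete annotations where a protein exists in the proteome but not the
GTF. Passing the fixture suite therefore demonstrates that the aggregation
logic is correct, not that six real tools at these settings achieve any
particular precision on real proteomes.

## Problem sizes and determinism

The shipped tests run at desk scale, chosen to keep the suite fast while
leaving no code path unexercised: 200 planted 1:1 pairs (plus 50 many:1 and
50 unassigned) for zero-noise recovery, 500 pairs for the dropout curve,
1000 random 10-group instances for the collapse oracle, 100 random outputs
per dialect for round-trip identity, and 1000 random bijection pairs for the
lateral join oracle. All randomness is seeded; `run_all()` writes its TSVs
in sorted order so reruns on identical inputs are byte-identical.

## Known limitations

* Many:1 and many:many relations are detected (`has_coorthologs`) but never
  resolved into calls; with six tools the consensus on the "true" member of
  a co-ortholog cluster is too unstable to publish, and resolution is
  deferred until a DIOPT-scale suite (≥12 tools) is available.
* One output file dialect is supported per tool (the primary cluster-level
  output: OrthoFinder Orthogroups table, ProteinOrtho TSV, InParanoid
  sqltable, OMA groups file, SwiftOrtho cluster lines, FastOrtho `.end`);
  pairwise-score outputs are not parsed.
* GFF3 key files are not supported (GTF and GPFF only), and no network
  fetching is performed — annotation files are supplied locally.
* Vote counts are unweighted; there is no per-tool reliability model.
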