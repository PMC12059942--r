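---
title: "allobench: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{allobench: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allobench)
```

This vignette documents the scientific model behind the package, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-fixture tests do and do not demonstrate.

## The curation model

The pipeline treats a curated allosteric-protein record as a claim to be
verified against the deposited structure, not as ground truth. Its stages
run in a fixed order (identifier reconciliation, active-site merge,
structure parsing, model merging, residue synchronization, completeness and
resolution filters, gap detection, optional remodeling with an lDDT gate,
modulator resolution, geometric site extraction), and two bookkeeping
invariants hold everywhere:

* **No silent loss.** Every filter partitions its input into kept and
  dropped; dropped entries carry exactly one machine-readable reason, and
  per-stage counts telescope (`validate_report()` checks this on every run).
* **Derived over declared.** The allosteric site written to the output
  dataset is the set of residues observed in contact with the modulator,
  not the residue list in the annotation. When the two disagree (Jaccard
  index below 0.5) the entry is flagged `site_discrepant` for audit, because
  an annotation error and a genuinely remote secondary pocket cannot be
  distinguished automatically.

### Residue identity

A residue is identified by (chain, author number, insertion code); the
residue *name* is advisory only, because prediction tools report bare
numbers and name mismatches would otherwise make exact set comparison
impossible. Residue sets are canonical, sorted `chain:number[icode]` token
vectors so that serialized output diffs deterministically.

### Residue-numbering synchronization

Active-site annotations are positions in the canonical (UniProt-style)
sequence; structures use author numbering, which may be offset, insert-coded
or interrupted. The mapping is built by global pairwise alignment of the
canonical sequence against the observed residue sequence, with identity
scoring: match +1, mismatch −1, and a length-L gap costing 5 + L. A
substitution matrix is deliberately not used — the two sequences are
near-identical variants of the same protein, so all a BLOSUM-style matrix
could add is the risk of aligning chemically similar but positionally wrong
residues. Traceback ties are broken deterministically (diagonal, then gap in
the observed sequence, then gap in the canonical one; extension before
opening), so reruns are bit-identical. Alignments below 30 % identity are
flagged unalignable and the entry is dropped with that reason; the floor is
configurable and intentionally permissive, since truncated constructs of the
correct protein commonly align at modest global identity.

One subtlety worth knowing: when two unresolved segments lie within about
three residues of each other, the *optimal* alignment may merge them into
one gap plus substitutions. The gap detector flags such chains
`sequence_conflict` rather than pretending the deletion-only reading is
optimal; the property tests therefore generate gap patterns at least four
residues apart, where the pure-deletion alignment is provably preferred
under the scoring above.

### Geometric site extraction

"Within 4 Å of the modulator" is read as: a protein residue belongs to the
site when at least one of its heavy atoms lies at Euclidean distance ≤ 4.0 Å
(inclusive) from at least one modulator heavy atom. Hydrogens are excluded
on both sides — they are absent from most crystal structures, and including
them where present would make the cutoff dataset-dependent. The
implementation is exactly the all-pairs rule (verified against a brute-force
oracle over randomized structures in the test suite); a spatial index would
change speed, not results. Each bound copy of the modulator yields its own
site, and duplicate sites from identical protomers are retained — a
multimeric assembly genuinely presents each pocket once per protomer.
Waters and a documented list of common buffer components (glycerol,
ethylene glycol, sulfate, ...) are never accepted as modulators even when
aliased.

### Model quality gate (lDDT)

Structures with unresolved residues are handed to an external modeling
engine (a pluggable shell command taking a template PDB and a
target–template alignment JSON; the package emits both). The rebuilt model
is scored with the local distance difference test: all heavy-atom distances
between different residues that are below the 15 Å inclusion radius in the
*reference* are checked in the model at thresholds 0.5/1/2/4 Å (strict
`<`, per the canonical definition), each distance contributing the fraction
of thresholds at which it is preserved; a residue scores the mean over its
distances and the global score is the mean over residues with at least one
scored distance. Atoms absent from the model count as non-preserved, so
deleting a residue is penalized rather than ignored. Because atoms are
matched by identity and never superposed, the score is exactly invariant
under rigid motions. The stereochemistry penalties of the full published
protocol are omitted: for template-copied coordinates they are
uninformative, and the gate's purpose is only to reject models whose
geometry drifted from the deposited structure (global lDDT < 0.8 by
default). Whole structures are compared, not merely rebuilt segments, since
remodeling can in principle perturb retained regions.

### Filters and their boundaries

* Resolution: kept iff strictly better than 4.0 Å; a structure at exactly
  4.0 Å is dropped. Structures without a resolution record (NMR ensembles)
  are kept and flagged `no_resolution` — a "better than" criterion can only
  exclude structures whose resolution was measured — and the flag lets users
  exclude them downstream.
* Size: more than 8000 observed protein residues drops the entry; exactly
  8000 is kept.
* Nucleic acids: any polymer residue named A/C/G/U/I/DA/DC/DG/DT/DI drops
  the entry; a lone modified nucleotide bound as a hetero ligand does not.
* Training relatedness: an entry is dropped when *any* of its accessions
  falls in a sequence cluster (UniRef50-style, ≥ 50 % identity) occupied by
  a training-set protein; accessions with no known cluster drop the entry
  conservatively, flagged `unknown_cluster`.

The kept set is independent of filter order; for reason attribution the
canonical order is training overlap, modulator class, size, nucleic acids.
When more entries survive than the requested test-set size, a seeded uniform
sample without replacement is drawn with at most one structure per cluster;
sampling is a documented stand-in for an unspecified manual selection, and
`take_all = TRUE` disables it.

### Multi-model merging and other structure details

Models are merged by keeping model 1 as is and relabeling each chain of
later models (file order, chains alphabetically) to the first unused label
from A–Z then AA–ZZ; coordinates are copied verbatim, so total atom count
and every inter-atomic distance are preserved exactly. Alternate locations
collapse to the highest-occupancy conformer (ties by altloc identifier).
Modified amino acids that appear in SEQRES (MSE and friends) are polymer,
not heteroatoms — stripping them would create artificial gaps. mmCIF-only
input is detected and dropped with its own reason rather than parsed,
because the benchmarked prediction tools consume PDB format only.

## The benchmark

The agreement measure is the Jaccard index JI = |K∩P| / |K∪P| over residue
tokens. Only the *topmost* ranked prediction is scored by default (tools
return different numbers of sites, and several return fewer than three, so
deeper comparisons would not be uniform); `best_of_k = TRUE` reproduces a
best-of-all-ranked analysis. For multimers the topmost prediction is
compared against every known site and the best JI is kept, ties to the
lowest index. Tool confidence scores are carried but never re-rank sites.
Predictions with residue identifiers absent from the structure have those
residues removed before scoring (`normalize_prediction()`), predictions
without chain identifiers are matched against every chain and the
JI-maximizing assignment is used (logged `chain_inferred`), and failed or
fully-spurious predictions score 0 and remain in medians, means and curves.
The median is the headline summary: JI distributions pile up at zero, which
the mean hides. Centroid distances are computed between unweighted means of
Cα coordinates, and their inverse gives the 3-D proximity reading of the
same comparison; coincident centroids store the inverse as missing with a
`coincident` flag rather than infinity.

## What the synthetic fixtures emulate — and what they do not

The generators produce extended poly-peptide chains (Cα spacing 3.8 Å,
five heavy atoms per residue), planted ligands whose contact pocket is known
by construction and self-verified by a brute-force distance check before the
fixture is emitted, cross-referenced XML/tables with one curation defect per
knob, and mock predictions with exact expected JI m/(2|K|−m). They emulate
the *bookkeeping* hazards of real data: obsolete and discrepant identifiers,
numbering offsets (+24 in the default corpus), unresolved segments,
multi-model files, low resolution, wrong input format, missing annotations.

They deliberately do not emulate realistic folds, crystal packing, covalent
modulators, density-dependent disorder, or annotation errors with partial
truth. Passing tests therefore demonstrate that the rules are implemented
exactly as specified and are internally consistent — not that the rules are
optimal for any particular real archive snapshot. Default fixture sizes
(chains of 15–60 residues, corpora of 2–10 entries, 200 randomized
extraction oracles, 1000 randomized Jaccard trials) were chosen so the whole
suite exercises every code path at full oracle strength while remaining
quick to run on one CPU.

## Numerical choices and degenerate inputs

* Distance comparisons use an absolute 1e−9 slack on the squared cutoff to
  absorb float noise; planted fixtures keep all distances ≥ 0.3 Å away from
  every cutoff, so no test depends on the slack.
* `jaccard_index()` errors on an empty known site (an empty *prediction* is
  a legitimate failure and scores 0; an empty known site is a data bug).
* An empty derived site (modulator resolved but nothing within the cutoff)
  keeps the annotated site and flags the entry rather than emitting an
  empty site.
* Residue-set serialization sorts tokens lexicographically; CSV reruns are
  byte-identical.
* `parse_site_text()` accepts both `chain:number` and bare-number dialects;
  bare numbers with several candidate chains are flagged ambiguous, never
  guessed.

## Known limitations

* Alignment is O(nm) dynamic programming in R; adequate for per-chain
  sequences, not for proteome-scale scans.
* lDDT builds the full reference distance matrix; memory grows quadratically
  in atoms per structure. Fine for the QC gate's typical inputs; very large
  assemblies would need a banded implementation.
* The identifier resolver ships with a static-table backend only; a live
  backend (archive APIs) is an interface away but intentionally out of the
  test surface.
* Biological assemblies are taken as provided; symmetry expansion from
  crystallographic operators is out of scope, so interface pockets missing
  from the deposited assembly are invisible to the pipeline.
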