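---
title: "Methods: antibody Fv extraction, numbering and set construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody Fv extraction, numbering and set construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abfv)
```

This vignette explains the procedures implemented in `abfv`, the
assumptions behind them, the tunable parameters, and the design choices
made where the problem admitted more than one defensible answer. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Chain typing

Every polymer chain is aligned locally (Smith–Waterman via
`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10, extension 0.5)
against frozen consensus variable-domain sequences: a 107-residue
kappa-like VL and a 116-residue VH3-like VH (including the canonical
82A–82C framework positions). The score is
`100 × identities / consensus length`, so only a near-complete variable
domain can approach 100 and the 80% demotion threshold has a concrete
meaning. The consensus sequences were assembled once from human
germline-derived framework and loop segments and are shipped as versioned
data (`inst/extdata/consensus_fv.fasta`); they are a package design
choice, frozen so that scores are reproducible.

Both the SEQRES- and ATOM-derived sequences are scored and the
higher-scoring source is kept. This matters in two real situations:
residues missing from the coordinates depress the ATOM score, and SEQRES
records that still contain the secretion leader depress neither (the local
alignment simply skips the leader).

Decision rules, in order:

* provisional type = whichever consensus scores higher (ties go to light;
  they arise only for degenerate inputs);
* a provisional light (heavy) chain is demoted to antigen iff some other
  chain has a *strictly* higher light (heavy) score and its own score is
  below `chain_score_threshold` (default 80). Strictness means identical
  copies of one chain tie and none is demoted — identical sequences must
  receive identical types;
* nucleic-acid chains are always antigen;
* an entry whose best chain score is below the threshold is rejected as
  `fc_only`; a single chain that carries both a light-scoring and a
  heavy-scoring segment (detected by masking the winning segment with X
  and re-scoring the remainder against the other consensus, both ≥ 80%)
  is rejected as `scfv_hybrid`. The masking rule is this package's
  concrete formulation of hybrid detection; single-label scFv chains
  cannot be split reliably, so rejecting them keeps the dataset clean at
  the cost of a few structures.

A deliberate consequence of the literal demotion rule: in an entry
containing *only* non-antibody chains, the top scorer keeps its
provisional type. Such entries are caught downstream (fc-only gate, or
clean numbering failure), mirroring a fail-clean philosophy rather than a
fail-guess one.

## Numbering

Numbering is implemented as alignment-based label transfer against
per-scheme template tables (`inst/extdata/schemes/`), not as a port of any
existing numbering program; correctness is defined by invariants
(bijection between Fv residues and labels, exact sequence round-trip,
deterministic output) rather than byte-equivalence with external tools.

* Framework positions are labelled by direct transfer from the aligned
  reference position.
* Each hypervariable region is labelled by loop length: the query segment
  between the flanking aligned framework positions receives the region's
  canonical labels, with extra residues inserted as letter codes after the
  scheme's anchor (Kabat: L27/L54/L95/H35/H52/H100; Chothia and Martin:
  L30/L54/L95/H31/H52/H100) and shortfalls removed C-terminal of the
  anchor first. The encoded Martin tables coincide with Chothia at these
  anchors; the documented Martin-vs-Chothia differences concern rare
  framework indels outside the encoded anchor set, so the two schemes
  produce identical labels except where Chothia itself differs from
  Kabat (L1/H1).
* Residues before the domain (leaders) and after the last variable
  position (constant domains) receive no label and are trimmed.
* Failure is a value, not an exception: numbering returns `NULL` when
  fewer than half of the framework positions align, or when a loop is
  truncated so its boundary cannot be resolved, or when labels would
  collide. Any antibody chain failing any scheme rejects the whole entry
  (`numbering_failure`) — an entry is never partially renumbered.

Renumbering maps observed (ATOM) residues onto the numbered sequence by
alignment when the numbering came from SEQRES, so unobserved residues
carry labels but no atoms. An observed residue *inside* the Fv window that
cannot be mapped also fails the entry.

CDR membership for the contact rules uses the Kabat CDR definition by
default (L24–34, L50–56, L89–97, H31–35, H50–65, H95–102, insertion codes
inheriting their parent position). Which CDR definition the contact rules
should use was genuinely open; it is exposed as
`pipeline_params(cdr_definition = "kabat"|"chothia")` with Kabat as the
default because the ranges are the widest in the heavy chain and therefore
the most conservative for antigen assignment.

## Contacts, pairing and parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `contact_cutoff` | 4.0 | Å | atom-centre distance defining a contact |
| `dimer_ca_cutoff` | 20.0 | Å | L36/L87 Cα cutoff for light-dimer pairing |
| `min_cdr_contacts` | 15 | count | minimum CDR contacts for a polymer antigen |
| `chain_score_threshold` | 80 | % | chain-typing demotion threshold |

The contact cutoff is read as ≤ 4.0 Å (source descriptions vary between
strict and non-strict at the boundary; one convention is standardized and
exposed). Hydrogens are excluded from all contact computations — most
X-ray depositions lack them, so including them would make counts depend on
deposition details — but are kept in output files. Alternate locations are
reduced at parse time to the highest-occupancy conformer (ties: first in
file), so contact counts do not depend on alt-loc bookkeeping.

VL/VH pairing is greedy on the light-by-heavy contact matrix: repeatedly
take the unused pair with the most contacts, ties broken by chain-label
order, zero-contact pairs never formed. Real matrices are near
block-diagonal (an antibody's own chains make an order of magnitude more
contacts than lattice neighbours), so greedy matching is exact in practice
and simpler to reason about than optimal assignment. Light-dimer pairing
uses the L36/L87 Cα geometry; with more than two light chains the closest
distance-sum pairs win.

## Antigen assignment

For a candidate polymer chain, contacts from the antibody's numbered Fv
atoms are split by CDR membership of the antibody residue. The chain is
antigen iff `cdr > framework` **and** `cdr ≥ min_cdr_contacts`; a chain
touching the antibody without meeting the rule is an antibody-binding
protein and the antibody stays free; zero contacts means unrelated.
Multi-chain antigens: chains individually passing are grouped, and when
none passes alone, chains with at least one CDR contact and a CDR-majority
profile qualify jointly if their *summed* profile passes (per-chain
summing is an exposed option; summed is the default because epitopes can
genuinely span chains, and requiring 15 contacts per chain would reject
them).

HETATM groups (haptens, lipids, carbohydrates; waters excluded) are tested
only for antibodies still free: a group is antigen iff at least one of its
atoms contacts a CDR-residue atom and no CONECT record covalently links it
to the antibody. A single CDR contact suffices — haptens are small and a
15-contact minimum would exclude genuine ones; covalent links are chemical
modifications, not antigens. When several groups qualify, the one with the
most CDR contacts becomes the set's antigen (the output format carries one
antigen per set).

Anti-idiotype resolution applies to entries with at least two antibodies
and no non-antibody polymer chains: identical sequences mean multiple
copies (all stay free); otherwise each antibody is tested as a two-chain
antigen for each other antibody under the polymer rule, and each passing
antibody pair yields two protein-complex sets.

## Splitting, output and redundancy

Sets are ordered by first appearance of the antibody's atoms in the file
(`CODE_1`, `CODE_2`, ...). Antibody chains are written as L and H — for a
light-chain dimer the second chain is written under the positional label H
while remaining light-typed internally, with the REMARK 950 chain mapping
preserving the original labels. Antigen chains keep their original labels
except L/H which are lowered to l/h; a collision with a pre-existing
lowercase label is an error rather than a guess. The REMARK 950 grammar is
fixed (`REMARK 950 <KEY> <VALUE>`, keys SCHEME, METHOD, RESOLUTION,
RFACTOR, RFREE, CHAIN, ABNAME, ABSPECIES, AGNAME, AGSPECIES); molecule
names and species come from COMPND/SOURCE records and are simply blank
when the deposition lacks them. The writer is deliberately byte-stable:
identical input reproduces identical files, which the tests assert over a
full rerun.

Redundancy compares antibodies on the amino acids at position labels
observed in both (Martin labels; any single scheme gives a consistent
label space, and clusters are shared across the three scheme variants of a
dataset). Missing residues are ignored, which makes the relation
non-transitive; clusters are its single-linkage transitive closure.
Representatives are chosen by most observed residues, then best (smallest)
resolution with NMR/EM structures lacking a resolution ranked last, then
lexicographically smallest set id. Light-dimer sequences are compared once
per distinct chain. Each of the 36 datasets (3 forms × 4 classes × 3
schemes) gets a non-redundant mirror whose size equals its induced cluster
count.

## The synthetic corpus: what it does and does not show

Real depositions cannot be bundled, so every end-to-end test runs on
synthetic entries from the fixtures module. Chains are residue grids kept
hundreds of Å apart, and contacts exist *only* where the generator
relocates designated atoms onto isolated paired sites 3.5 Å apart — one
interface per zone, zones spaced far beyond the cutoff. Designed contact
counts are therefore exact ground truth, and the generator chooses CDR or
framework residues for each interface using the package's own numbering,
so the classification rules are exercised exactly at their thresholds.
The corpus covers all nine form × class combinations, anti-idiotypes with
a designed 128/20/10/117 contact matrix, BIOMT-only dimer partners,
covalent and non-covalent haptens, framework binders, leaders, missing
loops, alternate locations, multi-model blocks and all three rejection
branches (at the sizes used: 20 entries, up to 24 chains per entry,
~1000–5000 atoms each; the full suite runs in a few minutes on one CPU).

What passing these tests does **not** show: performance on real folds
(side-chain packing, genuinely ambiguous lattice contacts near the
thresholds), unusual species or heavily engineered frameworks whose
consensus scores sit near 80%, and numbering of rare framework indels
where the encoded Martin tables fall back to Chothia behaviour. The rules
themselves depend only on distances, labels and sequences — which the
synthetic geometry controls — but threshold calibration against real
crystal structures is outside what an offline synthetic corpus can
establish.

## Known limitations

* scFv/scFab single-label chains are rejected, not split.
* Biological-assembly expansion is used only to reconstruct light-chain
  dimers.
* mmCIF/PDBML and multi-character chain identifiers are not supported.
* One antigen per set: multiple qualifying HETATM groups reduce to the
  best-contacting one.
* The demotion rule trusts that entries contain at least one genuine
  antibody chain; archive-level identification of antibody entries is an
  upstream concern (the pipeline takes a code list as input).
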