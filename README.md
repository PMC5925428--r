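# abfv

Structural immunology works on the *Fv* region — the paired VL/VH variable
domains that carry the six complementarity-determining regions (CDRs) and
form the antigen-binding site. Getting clean Fv structures out of raw PDB
depositions is surprisingly intricate: a single entry may hold several
copies of the same antibody, several different antibodies bound to one
antigen, light-chain dimers whose second chain exists only through
crystallographic symmetry, haptens hidden in HETATM records, anti-idiotypic
antibody/antibody complexes, and antibody-binding proteins (such as
staphylococcal protein A) that touch the antibody without being antigens.
`abfv` automates that whole extraction for people who need curated,
consistently numbered antibody—antigen structure sets: antibody engineers,
epitope analysts and method developers.

## What it does

For each PDB entry the pipeline:

1. **Types every chain** as light, heavy or antigen by Smith–Waterman
   alignment against frozen consensus VL/VH sequences, scoring
   `100 × identities / consensus length` on both the SEQRES- and
   ATOM-derived sequences (the higher wins). A provisionally typed chain is
   demoted to antigen when another chain scores strictly higher and its own
   score is below 80%.
2. **Classifies the antibody form**: complete (VL+VH), light-chain-only
   (e.g. Bence-Jones dimers), heavy-chain-only (camelid VHH). Entries with
   no variable domain (Fc fragments), fused single-label scFv chains, or a
   chain that fails numbering are rejected whole — never mis-processed.
3. **Rebuilds light-chain dimers** from REMARK 350 BIOMT transforms when
   only one chain is deposited.
4. **Numbers the variable domains** under the Kabat, Chothia and Martin
   schemes by alignment-based label transfer (insertion codes at the
   scheme's loop anchors, e.g. L27A/L27B under Kabat), trimming constant
   domains.
5. **Pairs chains into antibodies**: VL/VH by maximal inter-chain contacts
   (atom centres within 4 Å); light dimers when the Cα atoms of residues
   L36 and L87 of the two chains lie within 20 Å.
6. **Assigns antigens**: a polymer chain is antigen only if it makes more
   contacts with the CDRs than with the framework *and* at least 15 CDR
   contacts — framework binders are flagged, not treated as antigen.
   Non-covalent HETATM groups contacting the CDRs become non-protein
   antigens; DNA/RNA chains route to the non-protein class; anti-idiotype
   pairs yield two sets with each antibody once as antibody and once as
   antigen.
7. **Splits and annotates**: one output file per antibody—antigen set
   (`CODE_1`, `CODE_2`, ...), shared antigens replicated, chains relabelled
   L/H (antigen labels L/H lowered to l/h), headers replaced by REMARK 950
   records carrying the scheme, method, resolution, R-factors, chain
   mapping and molecule names.
8. **Clusters redundancy**: antibodies are redundant when their amino acids
   agree at every numbered position present in both; single-linkage
   clusters get a representative (longest observed sequence, then best
   resolution). The run lays out 36 redundant + 36 non-redundant datasets
   (3 forms × 4 complex classes × 3 schemes), 12 redundancy lists, 3
   free/complexed lists and a chain-mapping list.

Because the cited crystal structures cannot be redistributed, the package
ships a seeded fixture generator (`fixture_*`) that builds synthetic
PDB entries with engineered contact geometry — every scenario above is
testable offline with exact ground truth.

## Worked example

An anti-idiotype complex: light chains A and C, heavy chains B and D, with
one antibody binding the CDRs of the other.

```r
library(abfv)
dir <- tempfile(); dir.create(dir)
writeLines(fixture_anti_idiotype("9DVF"), file.path(dir, "9dvf.pdb"))
m <- read_pdb_file(file.path(dir, "9dvf.pdb"))
count_contacts(m, "A", "B")$n_contacts   # 128
count_contacts(m, "A", "D")$n_contacts   #  20
count_contacts(m, "C", "B")$n_contacts   #  10
count_contacts(m, "C", "D")$n_contacts   # 117
res <- process_entry(m, "9DVF")
for (s in res$sets) print(s)
```

```
9DVF_1: complete antibody (L = A, H = B), class protein
9DVF_2: complete antibody (L = C, H = D), class protein
```

Chain A pairs with B (128 contacts) and C with D (117); the 20 + 10
cross-contacts fall on CDR residues, so each antibody is also the other's
antigen and two protein-complex sets are produced. The written file starts
with the annotation block:

```
REMARK 950 SCHEME Chothia
REMARK 950 METHOD X-RAY DIFFRACTION
REMARK 950 RESOLUTION 2.00
REMARK 950 RFACTOR 0.193
REMARK 950 RFREE 0.221
REMARK 950 CHAIN L A
REMARK 950 CHAIN H B
```

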