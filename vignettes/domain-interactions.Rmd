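---
title: "Calling domain interactions from atomic bond geometry"
author: "DomainContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling domain interactions from atomic bond geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomainContacts)
```

## The problem

High-resolution 3D structures are the only data that show, atom by atom,
how two protein domains or a domain and a small-molecule ligand touch.
`DomainContacts` takes a crystallographic structure (legacy PDB format,
asymmetric unit, first model) together with protein-family region
annotations on its chains, and answers two questions: *which pairs of
domain instances, and which domain–ligand pairs, are in physical
contact*, and *through which bonds*. A domain–domain interaction (DDI)
or domain–ligand interaction (DLI) is called as soon as **one** bond of
any class is detected between the two molecules; no minimum interface
size is imposed, because genuinely small interfaces — a handful of van
der Waals contacts — can be biologically meaningful.

## The bond model

Every atom pair between two molecules is classified from its Euclidean
distance $d$ and the chemical parameters of the two atoms: per-atom
covalent radii $r_c$, van der Waals radii $R$, a formal charge sign in
$\{-1, 0, +1\}$, and hydrogen-bond donor (D) / acceptor (A) flags. The
rules are evaluated in precedence order — covalent, electrostatic,
hydrogen, van der Waals — and the first that fires wins; the precedence
also defines the "most energetically significant" bond class used to
summarise each interface position:

1. **Covalent**: $d < r_c(a) + r_c(b)$.
2. **Electrostatic** (salt bridge): $r_c(a)+r_c(b) < d < R(a)+R(b)$
   and the two formal charges have opposite signs.
3. **Hydrogen**: for a pair failing both rules above, one atom a donor
   and the other an acceptor, $d < 3.6\,\text{Å}$, and the angle at the
   acceptor between the acceptor→donor vector and the
   acceptor→antecedent vector within $[90^\circ, 140^\circ]$ (inclusive).
4. **van der Waals**: $R(a)+R(b) < d < R(a)+R(b) + 1.5\,\text{Å}$.

All distance comparisons are strict, so a boundary-equal distance
classifies as none. Between the covalent and van der Waals windows
there is a deliberate gap: a neutral, non-D/A pair closer than its van
der Waals radius sum (a steric clash, or an unparameterised covalent
context) is reported as no bond. The package preserves this gap rather
than papering over it, since assigning such pairs to any class would
invent chemistry the rules do not state.

### Choices that were genuinely open

* **The acceptor-side angle.** The angle criterion is stated on "the
  vectors formed between D–A and A and [the] residue atom". We read
  this as the angle at the acceptor between acceptor→donor and
  acceptor→*antecedent*, the acceptor's covalently bonded heavy atom —
  the standard acceptor-geometry test and the only reading in which
  both vectors originate at A. The antecedent is found automatically as
  the nearest heavy atom of the same residue within covalent-bond
  distance. When an acceptor has no resolvable antecedent (an isolated
  single-atom residue), the hydrogen rule is skipped for that pair with
  a warning rather than aborting.
* **Both orientations are tried.** Donor/acceptor roles come from the
  flags, not argument order: if both atoms are both donor and acceptor,
  the pair is hydrogen-bonded if either orientation satisfies the
  criteria, and the reported angle is the smaller of the two valid
  ones. This keeps classification exactly symmetric in its arguments.
* **Electrostatic bonds use charges only** — no donor/acceptor
  compatibility is additionally required, as the rule names only the
  charge signs.
* **Hydrogens are ignored.** Most X-ray structures lack them; donors
  and acceptors are identified on heavy atoms, and file hydrogens are
  excluded from pair enumeration.

## Parameters

The shipped parameter table (`inst/extdata/atom_chemistry.csv`, fully
replaceable via `loadParams()`) combines standard published single-bond
covalent radii with the standard crystallographic van der Waals radii,
and assigns charges and D/A flags from amino-acid side-chain templates:
carboxylate oxygens of Asp/Glu are $-1$ acceptors; Lys NZ and the Arg
guanidinium nitrogens are $+1$ donors; Ser/Thr/Tyr hydroxyls are
donor+acceptor; His ring nitrogens are neutral donor+acceptor; the
element defaults make every nitrogen a donor and every oxygen an
acceptor, which covers backbone N–H···O=C hydrogen bonding; common
monatomic-ion component codes (ZN, MG, CA, NA, K, FE, …, CL, BR)
carry their ionic charge sign. Every entry satisfies
$0 < r_c < R$, which the class validity enforces — it is what makes the
electrostatic window non-empty. The numeric values of the historical
parameter file this table stands in for are not published, so
rule-level agreement, not number-level agreement with historical
output, is what the package can promise.

Tunable criteria (`bondCriteria()`): the donor–acceptor cutoff
(default 3.6 Å), the acceptor-angle window (90–140°), and the van der
Waals margin (1.5 Å). All are overridable from the command line.

## From annotations to interaction calls

Domain regions arrive as a 9-column TSV (`pdb_id`, chain, inclusive
author-numbered start/end with insertion codes, family accession and
id, E-value). Processing steps:

* **Obsolete-entry filtering** drops regions whose `pdb_id` is not in
  the caller's valid set.
* **Overlap resolution** (per chain) sorts by ascending E-value and
  accepts greedily, discarding any region that overlaps an accepted one
  — so whenever two matches overlap, only the most significant
  survives. Exact ties break toward the longer region, then the
  lexicographically smaller accession. An E-value of 0 is accepted as a
  curated-annotation sentinel that always wins. The result is provably
  overlap-free and idempotent, and the tests check it against a
  brute-force enumeration of all overlap-free subsets.
* **Attachment** resolves each region to the ATOM-record residues in
  its closed range; regions on missing chains or empty ranges are
  dropped with a warning, since coordinate/mapping mismatches are
  routine in real data.
* **Ligand identification**: every HETATM residue is a candidate
  ligand unless it is an aqueous solvent (HOH, DOD, …), a nucleic-acid
  component (A, C, G, U, I, DA, …; both lists are extensible), listed
  in MODRES, or LINKed to a polymer atom of its own chain (a covalent
  modification). A LINK to *another* chain's polymer does not exclude —
  metals and glycans bridging chains remain ligands.

Interaction calling then runs bond detection for every unordered
domain pair and every domain×ligand pair. One subtlety is deliberate:
**bonds between sequence-adjacent residues of one chain are discarded**
before calling. Without this, any two domains abutting on a chain would
trivially "interact" through their shared backbone peptide bond, which
is connectivity, not an interface.

Van der Waals bonds are by far the most numerous class; storing each
atom pair individually is what historically made contact databases
explode. They are therefore **stored per residue pair** — a flag plus
the contact's dominant bond class — while covalent, electrostatic and
hydrogen bonds ("higher-order" bonds) are kept atom-by-atom. The output
format enforces this: `bonds.tsv` never contains a vdw row.

Topology is *intramolecular* when both partners' residues lie on one
chain, else *intermolecular*; a DLI is classed by whether the ligand's
chain identifier equals the domain's. A DDI is *homodomain* when both
instances carry the same family accession. The 2×3 summary grid
(topology × homodomain/heterodomain/ligand) counts each interaction
exactly once. Cross-structure aggregation into family-pair statistics
is a database-build concern and out of scope here; the package reports
per-structure, instance-level calls.

## Detection performance and its oracle

Candidate pairs come from a cubic-cell spatial index at a cutoff of
$\max R(a) + \max R(b) + \text{margin}$ (never below the
donor–acceptor cutoff), which bounds every classification window, so
indexing is purely an optimisation: the test suite and the acceptance
script verify on 100 seeded random fixtures (50 atoms per side,
uniform in a 20 Å box) that the indexed result is *identical* to the
exhaustive all-pairs scan.

## Synthetic fixtures: what they do and do not show

The generator (`buildFixture()`, `fixtureSuite()`, `randomFixture()`)
produces geometric probes, not fold models. Engineered contacts are
placed at window midpoints — never at edges — so small parameter
revisions cannot flip a test; the builder *rejects* any engineered
contact at a window boundary, which would be ambiguous under the
strict-inequality rules. The canonical suite covers every bond class ×
DDI/DLI × intra-/inter-chain topology, the homodomain relation on both
topologies, the backbone-adjacency exclusion, all four ligand-exclusion
branches with a bridging-metal positive control, and a synthetic
stand-in for a minimal all-van-der-Waals interface between two adjacent
domains on one chain: five residues against four, no higher-order
bonds — the shape of a famously small SH3–SH2 contact. Each fixture
carries its expected inventory, derived from the constructed geometry
by hand, and the pipeline must reproduce it byte-deterministically
through the command-line layer.

Passing these fixtures demonstrates that the rules, the aggregation and
the bookkeeping are implemented exactly as specified. It does not
demonstrate numeric agreement with any historical database build: that
would require the original parameter values and real crystallographic
coordinates with their altloc/occupancy noise, partial side chains and
crystal-packing artifacts. Real structures are also analysed as
deposited (asymmetric unit, first model): biological-assembly expansion
from rotation matrices is explicitly not performed, so interfaces
present only in the assembly are missed and crystal contacts may be
reported — users should judge biological relevance themselves.

## Numerical and degenerate-input policy

* Distances are plain Euclidean; coordinates are finite by class
  validity. Angle cosines are clamped to $[-1, 1]$ before `acos`.
* Altloc selection keeps the highest-occupancy conformer, ties broken
  by the alphabetically smallest indicator, so parsing is
  deterministic.
* Zero-atom files, boundary-placed engineered contacts, coordinate
  overflow of the fixed-column format, malformed records (reported with
  their line number) and duplicate parameter keys (reported with their
  row number) are all hard errors; missing chains, empty ranges,
  unparameterised atoms and missing antecedents are warnings with a
  defined skip policy.
* All outputs are sorted on stable keys and written with fixed number
  formatting, so identical inputs give byte-identical files.

Problem sizes used by the shipped checks — 50 atoms per side and 100
seeds for the oracle comparison, 25 random annotation sets of up to 10
regions for the overlap oracle, 17 engineered fixtures — were chosen as
the smallest sets that exercise every rule branch and still probe the
index/oracle equivalence densely.

## Worked example

```{r example}
fx <- fixtureSuite()
f <- fx$elec_dli_intra     # a Glu carboxylate oxygen 2.1 A from a zinc ion
res <- runPipeline(paste(f$pdb, collapse = "\n"),
                   paste(f$domains, collapse = "\n"), verbose = TRUE)
res$interactions[[1]]
res$summary
```

The single electrostatic bond (distance inside the
covalent-sum-to-vdW-sum window, opposite charge signs) suffices to call
one intramolecular DLI, and the summary grid places it in exactly one
cell.

## Known limitations

* Legacy PDB input only; mmCIF is not parsed.
* No biological-assembly expansion, interface-area metrics, bond-order
  or protonation modelling, and no π-stacking/cation-π classes — the
  typology is the four classes above.
* Domain–nucleic-acid interactions are not called; nucleic-acid
  components are excluded from the ligand set.
* The shipped radii/charges are a documented, replaceable calibration,
  not the historical file.
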