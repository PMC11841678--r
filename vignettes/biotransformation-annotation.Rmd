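---
title: "Methods: biotransformation-based suspect annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biotransformation-based suspect annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bamanno` annotates an unknown ("suspect") MS/MS spectrum by chemical
analogy rather than library identity. The working assumption is that many
unknowns are single enzymatic transformation products of known molecules,
and that such reactant–product pairs share molecular substructures, hence
share fragment ions — directly for fragments untouched by the
transformation, and shifted by the transformation's mass delta for fragments
containing it. Three stages operationalize this:

**1. Anchor search by molecular networking.** Spectra are compared with
modified cosine similarity: square-root-transformed, L2-normalized peak
intensities, peaks pairable directly within a fragment tolerance or shifted
by the neutral precursor mass difference, each peak used at most once, and
the score maximized over all one-to-one pairings. A network edge is kept
when the score strictly exceeds the threshold. Every edge between
structurally distinct annotated spectra yields two directed anchor–suspect
pairs (biotransformations are reversible); edges whose annotations share the
first InChIKey block are discarded as the same 2D structure; an edge with a
single annotated endpoint anchors at that endpoint.

**2. Rule extraction and candidate generation.** Rules are learned from
reactant–product structure pairs. The pair is aligned with a maximum common
substructure (MCS; bond-order-sensitive, ring-atoms-match-ring-atoms);
atoms outside the MCS, plus MCS atoms whose bonds, hydrogen counts or
charges differ between the two sides, delimit the reaction center; one rule
is emitted per connected center. A rule stores (a) the center atom's type
code, (b) the multiset of its bonded neighbors' codes, (c) the structural
edit, and (d) the realized monoisotopic mass delta. Atom-type codes are
`element + environment class (aromatic / ring / chain) + sorted
neighbor-element-with-bond-order profile` — a compact stand-in for KEGG
atom types, which are not reproduced here; the scheme only has to be
self-consistent between extraction and application. The rule table indexes
rules by unit-rounded mass delta and serves all rules whose key equals the
unit-rounded observed precursor difference; applying a rule edits the anchor
at every atom whose code and full neighbor-code multiset match, discards
products that fail valence/aromaticity sanitization or yield no standard
InChI, and de-duplicates on the first InChIKey block while retaining every
(rule, site) provenance.

**3. Ranking by site-of-metabolism likelihood.** A site scorer maps a
molecule to one likelihood in [0, 1] per heavy atom; each candidate takes
the likelihood of the atom its rule was applied to (maximum over
provenances when several rules/sites give the same derivative). Candidates
are ordered by descending score with average-rank tie resolution: a block of
$t$ candidates occupying rank positions $p, \dots, p+t-1$ all receive
$(\sum_{i=0}^{t-1}(p+i))/t$, so assigned ranks always sum to $n(n+1)/2$.
Correctness is a first-InChIKey-block match against the truth; recall is
reported over queries that produced at least one derivative, together with
rank@k ($k = 1..5$, fractional ranks included, so a 3-way tie at the top,
rank 2, counts from $k \ge 2$) and the average rank of the truth.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `fragment_tol` | 0.02 | Da | typical high-resolution fragment tolerance in molecular networking; the source method states none |
| `network_threshold` | 0.8 | – | the stated network edge criterion; comparison is strict ("above") |
| `sqrt_intensity` | TRUE | – | dominant molecular-networking convention; configurable off |
| adduct | `[M+H]+` | – | proton 1.00728 Da; neutral mass = charge·(m/z − shift) |
| fingerprint | Morgan r=2, 2048 bits | – | Tanimoto thresholds are only meaningful under a fixed scheme; the source names none, so this is a convention, not a reproduction |
| `min_mcs_frac` | 0.5 | fraction of smaller molecule's heavy atoms | below this the MCS alignment is deemed unreliable and no rule is emitted |
| MCS `timeout` | 10 | s/pair | guard against pathological alignments |
| `max_sites` | 64 | sites/rule | guard against pathological inputs; logged when hit |
| delta rounding | half away from zero | integer Da | "unit resolution" with deterministic ±0.5 boundaries (base-R `round` is half-to-even) |

## What the synthetic generator emulates — and does not

`make_benchmark()` builds the world the pipeline is tested in: ~20 built-in
drug-like/steroid-like scaffolds; five transformation families
(hydroxylation +15.9949, methylation +14.0157, dehydrogenation −2.0157,
demethylation −14.0157, acetylation +42.0106 Da) applied at one seeded
random legal site each; pseudo-fragmentation spectra (each acyclic single
bond broken once, both pieces hydrogen-capped, peak at fragment+H with an
intensity from a deterministic polynomial hash of the fragment's canonical
SMILES, plus the precursor peak). Because unmodified fragments are
*identical* structures in anchor and suspect, they produce identical peaks;
modified fragments shift by the family delta — precisely the premise of
modified cosine. The generator keeps a pair only if its extracted rule
regenerates the product and the two spectra clear the 0.8 network
threshold, and regenerates from the pool otherwise, so "every non-withheld
pair is solvable" is true by construction.

Consequently a green end-to-end test establishes that the *pipeline logic*
(alignment, indexing, matching, editing, dedup, ranking, bookkeeping) is
correct — it does not establish chemical realism of fragmentation, nor
recall on real repositories, which depends on rule-collection coverage.
`simulate_spectrum()` accepts a `seed` argument for interface stability but
ignores it: intensities are a pure function of structure, which is what
makes byte-identical regeneration trivial to guarantee.

## Numerical and design choices

- **Peak assignment is an exact maximum-weight bipartite matching**
  (igraph, Hungarian). Greedy pairing changes scores when a peak is within
  tolerance of both a direct and a shifted partner; the matching resolves
  such conflicts globally. Verified against an exhaustive enumeration
  oracle to 1e-9 on 200 seeded random spectrum pairs.
- **Edits are operations at the center**: add a neighbor subtree, remove an
  acyclic neighbor subtree, change a center–neighbor bond order. Changes
  that cannot be written this way (ring opening/closure between persisting
  atoms, changes two bonds from any center) produce no rule, with a logged
  reason. This is the package's reading of a lookup-table scheme "defining
  the changes at the reaction center and its neighbors"; multi-center pairs
  emit one rule per connected center, each carrying its own realized delta.
- **Rule identity for dedup** is (center code, sorted neighbor codes,
  canonical edit serialization). Site matching and editing depend only on
  those fields, so identity implies behavioral equivalence and dedup is
  safe.
- **Hydrogens are implicit**; sanitization recomputes hydrogen counts after
  each edit, and explicit-hydrogen counts (e.g. pyrrole N–H) are decremented
  when an edit raises an atom's bonded valence.
- **MCS embedding choice**: among up to 24 embeddings per side the mapping
  minimizing the number of changed atoms is used — symmetric molecules
  otherwise produce spurious centers.
- **Tie display order** inside a rank block is lexicographic InChIKey, so
  outputs are byte-reproducible; assigned ranks are permutation-invariant.
- **The oracle scorer is query-aware.** One scaffold legitimately anchors
  several benchmark queries with different true sites, so a
  1-at-the-true-site scorer cannot be a pure function of the molecule; the
  oracle carries a `for_pair` hook that `evaluate()` binds per query. Real
  scorers (the default frequency heuristic, any plugged-in learned model)
  remain pure functions of the molecule.
- **Default scorer**: Laplace-smoothed frequency of each atom-type code
  among rule-table reaction centers, `(n(code)+1)/(n_rules+2)` — bounded in
  (0, 1), uniform on an empty table, deterministic.
- **Chemistry backend**: all structure handling runs through a bundled
  RDKit bridge invoked in batches (one process per pipeline stage, not per
  molecule). No R cheminformatics dependency exists in the target
  environment; the bridge script is part of the package and versioned with
  it.

## Known limitations

- Site matching requires the exact radius-2 environment; rules do not
  generalize beyond it. This is deliberate (loose matching inflates
  candidate sets) but means recall measures rule coverage as much as
  algorithm quality.
- Stereochemistry is ignored during MCS and editing; identity is 2D by
  design.
- Rules whose edit spans ring formation/opening between persisting atoms
  are not representable.
- The networking stage is a faithful small-scale stand-in: no wide-tolerance
  analog library search, no repository-scale topology filters, no
  minimum-matched-peak constraint (the source states none of these for its
  precomputed network).
- Multi-step (composed) biotransformations are out of scope.
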