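# bamanno — biotransformation-based annotation of MS/MS suspect spectra

Most MS/MS spectra collected in untargeted metabolomics never receive a
structure annotation: spectral libraries only cover known compounds measured
before. Yet many "unknowns" are one enzymatic step away from a known
molecule — a hydroxylation, a methylation, an acetylation. `bamanno`
implements biotransformation-based annotation (BAM) for exactly this case.
Given a query spectrum it:

1. **Finds an anchor** — an annotated spectrum highly similar to the query
   under *modified cosine* similarity, which matches fragment peaks either
   directly or shifted by the precursor mass difference, so that spectra of
   structurally related but non-identical molecules still align. Anchors
   come from a molecular network (edges above 0.8 modified cosine).
2. **Applies biotransformation rules** — rules are extracted from
   reactant–product structure pairs: the two structures are aligned by a
   maximum common substructure, the atoms that differ delimit the *reaction
   center*, and the rule records the center's atom-type code, its bonded
   neighborhood, the structural edit, and the monoisotopic mass delta.
   Rules are indexed by unit-rounded mass delta; those matching the observed
   precursor mass difference are applied to the anchor at every site whose
   atom-type environment matches, enumerating candidate *suspect* structures.
3. **Ranks the candidates** by site-of-metabolism likelihood: each candidate
   inherits the likelihood of the anchor atom its rule was applied to
   (pluggable scorer contract; a deterministic rule-table-frequency scorer
   ships as default). Ties receive the average of the tied rank positions:
   three candidates tied for first place all get rank
   (1 + 2 + 3) / 3 = 2.

Correctness of a candidate is judged by the first 14 InChIKey characters
(2D connectivity). Audience: computational metabolomics developers who want
a small, fully testable reimplementation of the annotation logic — not a
repository-scale system (see Limitations).

## The statistic at the core

For spectra $A, B$ with peak weight vectors $w = \sqrt{I}/\lVert\sqrt{I}\rVert_2$,

$$\mathrm{mod\cos}(A,B) \;=\; \max_{M} \sum_{(i,j)\in M} w_{A,i}\, w_{B,j},$$

maximized over one-to-one peak pairings $M$ where $(i,j)$ is admissible if
$|m_i - m_j| \le \tau$ or $|m_i + \Delta - m_j| \le \tau$, with $\Delta$ the
neutral precursor mass difference and $\tau$ the fragment tolerance
(default 0.02 Da). The maximization is solved exactly as a maximum-weight
bipartite matching (igraph), not greedily, and is verified in the tests
against an exhaustive enumeration oracle.

## Worked example

A steroid-like anchor and a suspect observed 2.0157 Da below it; two small
alcohol→ketone pairs supply the rules.

```r
library(bamanno)

anchor  <- canonicalize("CC(CCC(=O)O)C1CCC2C1(C)C(O)CC1C2C(O)CC2CC(O)CCC12C")
suspect <- canonicalize("CC(CCC(=O)O)C1CCC2C1(C)C(=O)CC1C2C(O)CC2CC(O)CCC12C")

pairs <- data.frame(
  pair_id         = c("dmch", "decalinol"),
  reactant_smiles = c("OC1CCCCC1(C)C",  "OC1CCC2CCCCC2C1"),
  product_smiles  = c("O=C1CCCCC1(C)C", "O=C1CCC2CCCCC2C1"))
tab <- build_rule_table(pairs, verbose = FALSE)

delta <- suspect$monoisotopic_mass - anchor$monoisotopic_mass  # -2.0157 Da
pair <- structure(list(anchor_id = "a", suspect_id = "s", anchor = anchor,
                       suspect_annotation = suspect, mass_difference = delta,
                       edge_score = 1), class = "bam_pair")

cands <- generate_candidates(pair, tab)
cands <- rank_candidates(score_candidates(anchor, cands, default_site_scorer(tab)))
print(cands)
```

```
<bam_candidates> 2 candidate(s)
      inchikey14                                              smiles     mass
1 MIHNUBCEFJLAGN CC(CCC(=O)O)C1CCC2C3C(O)CC4CC(O)CCC4(C)C3CC(=O)C12C 406.2719
2 OEKUSRBIIZNLHZ CC(CCC(=O)O)C1CCC2C3C(O)CC4CC(=O)CCC4(C)C3CC(O)C12C 406.2719
  score rank
1   0.5  1.5
2   0.5  1.5
```

Reading this: the observed −2 Da difference matched the dehydrogenation
rules; applying them to the anchor at every compatible hydroxyl-bearing ring
carbon produced two valid ketone candidates (406.2719 Da = anchor mass −
2.0157). One of them — rank 1.5, tied because the default scorer cannot
distinguish the two sites — is the true suspect structure
(`inchikey14_match` with `suspect` is `TRUE` for candidate 1). A
site-of-metabolism model that prefers the 12-position would break the tie;
plug one in via `site_scorer()`.

A fully synthetic, seeded end-to-end benchmark (spectra included) is one
call away:

```r
bench  <- make_benchmark(50, seed = 101)
report <- evaluate(bench$pairs, active_rule_table(bench), oracle_site_scorer(bench))
print(report)
#> <bam_evaluation> scorer 'oracle'
#>   queries: 50  with derivatives: 50  correct: 50
#>   recall (given a derivative): 1.000
#>   average rank of truth: 1.00   mean unique derivatives: 2.20
#>   rank@k: k1=1.00 k2=1.00 k3=1.00 k4=1.00 k5=1.00
```

## Command line

```sh
bam=$(Rscript -e 'cat(system.file("cli", "bam", package = "bamanno"))')
Rscript $bam make-fixtures --n 50 --seed 7 --out fixtures/
Rscript $bam network --in fixtures/spectra.mgf --threshold 0.8 --tol 0.02 --out edges.tsv
Rscript $bam extract-rules --pairs fixtures/rule_pairs.tsv --out rules.json
Rscript $bam annotate --spectra fixtures/spectra.mgf --rules rules.json --out candidates.tsv
Rscript $bam evaluate --benchmark fixtures/spectra.mgf --rules rules.json --out report.json
```

Exit codes: 0 ok, 1 input error, 2 internal error.

## Limitations

- Rules generalize only to sites whose radius-2 atom environment matches a
  stored rule exactly; coverage, and hence recall, is a property of the rule
  collection you load.
- The synthetic spectra are pseudo-fragmentation (acyclic single-bond
  breaks, hash intensities); they emulate shared/shifted peak structure, not
  fragmentation chemistry.
- Repository-scale networking, real rule-database ingestion, and learned
  site-of-metabolism models are out of scope; the scorer contract is the
  integration point for the latter.
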