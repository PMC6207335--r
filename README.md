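# earlyfold

Residue-level analysis of protein folding initiation sites.

Early folding residues (EFR) are the positions of a protein that become
protected from hydrogen–deuterium exchange in the first moments of
refolding; they nucleate the fold. Late folding residues (LFR) gain
protection later or never, and functional residues (active sites, ligand
binders) serve catalysis and recognition rather than folding. A recurring
question in structural bioinformatics is whether folding and function are
carried by *separate* sets of residues — and what structural signatures set
EFR apart. `earlyfold` provides the complete residue-level toolkit for that
question: descriptors computed from structure, stratified group statistics,
and an enrichment statistic for the overlap of two binary residue label
sets, plus a deterministic synthetic-structure generator so the entire
pipeline can be validated without external downloads.

## What it computes

**Residue contact graph.** Residues are nodes; edges connect pairs whose
Cα atoms lie within 8 Å (strict) plus all covalently adjacent pairs. Edges
with sequence separation ≤ 5 are *local*, > 5 *tertiary*. Per residue the
package reports betweenness (fraction of shortest paths through the node,
normalized by `(n−1)(n−2)/2`), closeness (inverse mean path length within
the component), clustering coefficient (edges among the `n_k` neighbors over
`n_k(n_k−1)/2`), and the *distinct neighborhood count* — the number of
sequence-separated neighbor groups a residue bridges.

**Solvent accessibility.** Shrake–Rupley ASA on a deterministic
golden-spiral point lattice (960 points/atom by default), normalized to
relative accessibility (RASA) by a fixed maximum-ASA scale. Residues with
RASA < 0.16 are *buried*.

**Knowledge-based energy profile.** From a reference set of structures the
buried/exposed occurrence of each amino acid is converted into a
pseudo-energy by the inverse Boltzmann relation
`e(a) = −ln((n_buried(a)+1)/(n_exposed(a)+1))`; the energy of a residue is
the sum of the pseudo-energies of its Cβ-contact partners (< 8 Å).
Hydrophobic, core-forming amino acids get negative energies.

**Non-covalent contacts.** Simplified heavy-atom detectors for hydrogen
bonds (N/O donor–acceptor pairs ≤ 3.5 Å) and hydrophobic interactions
(apolar side-chain carbons ≤ 4.0 Å, one per residue pair).

**Statistics.** Group comparisons (EFR vs LFR, functional vs
non-functional) report means over all residues and p-values on the buried
subset, where the burial confounder is controlled: Mann–Whitney U for
continuous features (significance < 0.05), Dunn's z with Bonferroni
correction for count features (< 0.025). The 2×2 contingency summary and
the **overlap shift** quantify label co-occurrence:

```
shift = 100 · [ n_obs/N − (n_A/N)·(n_B/N) ]
```

negative when two label sets co-occur less than independent labels would,
positive when they attract.

## Worked example

```r
library(earlyfold)

# a synthetic 80-residue globule with helices, strands and a hydrophobic core
g   <- assemble_globule(globule_spec(n_residues = 80, seed = 7))
ann <- attach_annotations(g$structure,
                          efr = c(12, 25, 26, 40, 41, 55),
                          functional = c(3, 68, 72), sse3 = g$sse3)
ft  <- featurize(g$structure, ann)
head(ft[, c("resno", "aa", "folding_class", "rasa", "buried",
            "betweenness", "contacts_tertiary", "n_hbond", "energy")], 3)
#>   resno  aa folding_class  rasa buried betweenness contacts_tertiary n_hbond energy
#> 1     1 ASN          LATE 0.555  FALSE    0.006600                 2       3   11.3
#> 2     2 ASN          LATE 0.250  FALSE    0.012212                 3       3   15.1
#> 3     3 ASP          LATE 0.463  FALSE    0.000811                 0       5   11.3
```

Each row is one residue: its RASA and burial call, graph centralities,
tertiary-contact and hydrogen-bond counts, and its energy-profile value
(here derived from the structure itself; pass `energy_table =` for a
reference-derived potential). `compare_features(ft)` then contrasts every
descriptor between EFR and LFR and between functional and non-functional
residues, and `overlap_table(ft)` summarizes label co-occurrence per
structure.

The overlap shift on explicit counts — 82 alignment positions of which 16
are predicted EFR and 4 bind ATP, with empty intersection:

```r
overlap_shift(n_obs = 0, n_A = 16, n_B = 4, N = 82)
#> overlap: 0/82 obs both (A=16, B=4); observed 0.00%, expected 0.95%, shift -0.95%
```

The folding class and functional role repel slightly: 0.95 percentage
points fewer joint labels than independence predicts. The 2×2 contingency
view over a full dataset:

```r
contingency_summary(list(early_functional = 22, early_nonfunctional = 324,
                         late_functional = 130, late_nonfunctional = 2014))
#>       functional non-functional
#> early         22            324
#> late         130           2014
#> observed joint 0.9%, expected 0.8% (of 2490 residues)
```

A thin command-line front end wrapping these functions ships in
`inst/cli/earlyfold-pipeline.R` (subcommands `simulate`, `featurize`,
`compare`, `overlap`).

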