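# mapscir

Multiple protein structure alignment with consensus identification, for
structural bioinformaticians who need to superpose a family of related
protein backbones, extract the conserved core, and summarise the family by a
single consensus pseudo-structure.

## The method

Each protein `P_i` is reduced to its ordered Cα trace, a sequence of
coordinate triples `p_i1 … p_il_i` (Å). A multiple alignment is a gapped
correspondence matrix `H` of `K + 1` rows — row 0 the consensus
pseudo-structure `P_0`, rows 1..K the proteins — and the quality of an
alignment is its **Sum-of-Consensus distance**

```
SC = Σ_j || H_0 − (H_j − e t_j) R_j ||²_F
```

where each protein moves by a rigid transform (rotation `R_j`, translation
`t_j`), a matched pair of triples contributes its squared Euclidean distance,
a triple against a gap costs the gap penalty `ρ²` (default 16 Ų, i.e. a gap
costs as much as a 4 Å mismatch), and two gaps cost nothing. The algorithm
(MAPSCI) approximately minimises SC by iterative refinement:

1. **Initial consensus** — one of the proteins, chosen by the `maxcore`
   strategy by default (the candidate whose merged initial alignment has the
   largest strict core); `median`, `center` and `minmax` are also available.
2. **Align** — every protein is aligned to the consensus: a bootstrap
   pairwise structure alignment (iterated superposition + dynamic
   programming) on the first pass, a plain Needleman–Wunsch-style DP over
   squared Cα distances in the current frames afterwards.
3. **Merge** — the pairwise alignments are combined center-star style into
   `H`; projecting `H` back onto any (consensus, protein) pair reproduces
   that pairwise alignment exactly.
4. **Transform + consensus** — interleaved closed-form steps: per-protein
   optimal rigid superposition onto the consensus (Kabsch/SVD with the
   determinant sign rule, so reflections are never returned) alternating
   with per-column consensus updates (arithmetic centroid versus gap,
   whichever minimises the column's SC contribution).
5. **Iterate** until the relative drop in SC falls below `η = 1e-4`.

Every step is individually non-increasing in SC, so the trace converges
monotonically. The conserved region is reported as the **strict core** — the
columns with no gap in any protein whose K superposed triples are mutually
within 4.0 Å — together with the **core RMSD** (average pairwise RMSD over
core columns, no re-fitting). Overall running time is `O(K²n²)`.

## Worked example

No input data is needed: the package generates structure families with known
ground truth. Here a 60-residue template produces 4 family members with
0.3 Å coordinate noise, a few deletions, and random rigid motions:

```r
library(mapscir)
fam <- makeFamily(familySpec(templateLength = 60, K = 4, noiseSigma = 0.3,
                             indelRate = 0.03, seed = 42))
res <- mapsci(fam$structures)
res
#> MapsciAlignment of 4 structures
#>   strategy: maxcore (initial consensus: member01 )
#>   outer iterations: 2
#>   SC-distance: 400.772 A^2
#>   correspondence width: 60 columns, 53 consensus positions

rep <- coreReport(res)
cat(sprintf("core: %d columns (%.1f%%), RMSD %.3f A\n",
            rep$core_size, rep$core_percent, rep$core_rmsd))
#> core: 46 columns (85.2%), RMSD 0.835 A

correspondenceRecovery(res, fam)
#> [1] 0.9708375
```

The final SC-distance of ~401 Ų is mostly gap cost from the deleted
residues; 46 of the 54 columns of the shortest member survive the strict 4 Å
core test with a core RMSD of 0.84 Å (about `√6 · σ`, as expected for
pairwise comparisons at this noise level), and 97% of the true
residue-to-residue correspondences are recovered. `exportAlignment(res,
"out/")` writes the transformed structures (PDB), the consensus
pseudo-structure (PDB, residue name UNK), the alignment (NBRF/PIR) and a
JSON report.

Real structures come in through `readStructure("file.pdb:A")` /
`readStructures()`, and `inst/scripts/mapsci.R` wraps the same pipeline for
the shell:

```sh
Rscript inst/scripts/mapsci.R align 1abc.pdb:A 2def.pdb 3ghi.pdb --outdir out
Rscript inst/scripts/mapsci.R synth --length 80 --k 5 --noise 0.3 --outdir fam
```

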