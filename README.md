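# netpharm

Network-pharmacology analysis of multi-component herbal medicines in R.

Traditional-medicine extracts act through many compounds hitting many
proteins at once. A now-standard way to propose a mechanism is to (i)
identify the extract's constituents by high-resolution LC-MS, (ii) assign
each constituent putative protein targets by structural similarity to
approved drugs with known targets, (iii) intersect those targets with
disease-associated genes in a protein–protein interaction network and
extract its topological core, (iv) ask which pathways the core genes
over-represent, and (v) validate a handful of core genes by qPCR.
`netpharm` implements that entire pipeline as tested, reusable functions,
together with seeded synthetic-data generators that plant known structure
at every stage so each step has a known-answer recovery test without any
external database.

## The statistics and algorithms at the core

- **MS1 annotation.** A peak with measured m/z *m* matches compound *M*
  under adduct rule *a* when
  |(*m* − *mz*(M,a)) / *mz*(M,a)| · 10⁶ ≤ tol, with
  *mz*(M,a) = (monoisotopic(M) + shift(a)) / z. Shifts use the
  charged-species convention (proton 1.0072765 Da; `[M]+` loses one
  electron; anion attachment adds the group plus an electron). Default
  tolerance 10 ppm.
- **MS2 neutral losses.** Fragment assignments name the precursor−fragment
  difference from combinations of H₂O, CO, CO₂, NH₃ (up to 3 units),
  matching exact mass within 0.01 Da and falling back to nominal integer
  mass for nominal-precision data.
- **Target transfer.** Tanimoto similarity T(A,B) = |A∩B|/|A∪B| of binary
  fingerprints; targets of every approved drug with T ≥ 0.8 are
  transferred to the query compound, unioned across drugs.
- **Hub filtering.** On the putative-target/disease-gene interaction
  network (edges kept at confidence ≥ 0.4), hubs are nodes with degree
  > 2 × median degree; major hubs additionally exceed the hub-subnetwork
  medians of degree, betweenness, and closeness simultaneously (strict
  inequalities throughout).
- **Over-representation.** Hypergeometric upper tail
  P(X ≥ k), X ~ Hyper(N, K, n), computed in log space; pathways with raw
  p < 0.05 are called significant (BH-adjusted p reported alongside).
- **qPCR.** Livak 2^−ΔΔCt relative quantification against a reference
  gene and a control group, replicates averaged on the Ct scale.

## Worked example

```r
library(netpharm)

# malic acid, printed measured m/z 133.0142 as [M-H]-
lib <- data.frame(id = "c1", name = "malic acid", formula = "C4H6O5")
pk  <- data.frame(rt_min = 1.0, mz = 133.0142, polarity = "neg")
annotate_peaks(pk, lib)
#>   peak rt_min       mz polarity compound_id compound_name adduct theoretical_mz  ppm_error
#> 1    1      1 133.0142      neg          c1    malic acid [M-H]-       133.0142 -0.3521296

# daidzein MS2: losses of 28 and 56 Da from the [M+H]+ ion at m/z 255
annotate_neutral_losses(255, c(227, 199))
#>   precursor_mz fragment_mz nominal_loss exact_loss loss_name match_type
#> 1          255         227           28         28        CO      exact
#> 2          255         199           56         56       2CO    nominal
```

The annotation lands 0.35 ppm from theory — comfortably inside the 10 ppm
acceptance window — and the fragment losses are named CO and 2CO, the
classic flavonoid CO-cascade.

An end-to-end run on synthetic data:

```r
cfg <- sim_config(seed = 5, n_compounds = 50)
sim <- simulate_inputs(cfg, "fixtures")
rep <- run_all(run_config(
  peaks = sim$paths$peaks, compound_library = sim$paths$compound_library,
  fingerprints = sim$paths$fingerprints, drug_library = sim$paths$drug_library,
  edges = sim$paths$edges, disease_genes = sim$paths$disease_genes,
  gene_sets = sim$paths$gene_sets, ct_table = sim$paths$ct_table,
  out_dir = "out", seed = 5))
#> [INFO] netpharm 0.1.0 run; seed=5 config=6f14ca29
#> [INFO] annotate: 50 annotations over 50 peaks
#> [INFO] predict: 71 putative targets
#> [INFO] network: 178 nodes, 330 edges; 11 hubs -> 3 major hubs
#> [INFO] enrich: 1 significant pathways
```

Every simulated peak is annotated, 71 drug targets transfer to the 20
query compounds, the two median filters reduce the 178-gene network to
3 major hubs of which 2 are putative compound targets, and one planted
pathway comes out significant. `out/report.json` records the counts plus
compound → target → pathway provenance chains, e.g.
`query005 → G0082 → set21`.

There is also a command-line surface:

```sh
Rscript inst/cli/netpharm.R simulate --seed 7 --out-dir fixtures
Rscript inst/cli/netpharm.R annotate --peaks fixtures/peaks.csv \
    --library fixtures/compound_library.tsv --out-dir out
```

## Package layout

| module | contents |
|---|---|
| `R/masses.R`, `R/formula.R`, `R/adducts.R`, `R/annotate.R`, `R/neutral_loss.R` | formula arithmetic, adduct m/z, ppm matching, MS2 losses |
| `R/fingerprint.R` | Tanimoto similarity and drug→target transfer |
| `R/network.R` | interaction network, centralities, two-stage hub filter |
| `R/enrich.R` | GMT gene sets and hypergeometric ORA |
| `R/qpcr.R` | 2^−ΔΔCt relative quantification |
| `R/simdata.R` | seeded planted-structure generators |
| `R/pipeline.R`, `R/cli.R`, `R/io.R` | orchestration, CLI, file formats |

See `vignettes/netpharm-methods.Rmd` for the model assumptions, parameter
choices, and limitations.
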