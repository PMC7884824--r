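---
title: "netpharm methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netpharm methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

`netpharm` chains five analyses that together form the standard
network-pharmacology workflow for multi-component herbal extracts:
LC-MS constituent annotation, similarity-based target transfer,
topological hub filtering of a target–disease interaction network,
pathway over-representation, and qPCR validation. This vignette explains
the model behind each stage, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish.

## 1. MS1 annotation

A neutral molecule M of molecular formula f has monoisotopic mass
$m(f) = \sum_e n_e \, m_e$ over the most abundant isotope masses $m_e$
(carbon exactly 12 Da). An adduct rule $a$ with mass shift $s_a$ and
charge $z_a$ yields the theoretical ion position
$mz(f, a) = (m(f) + s_a)/z_a$, and a measured peak $m$ matches when the
relative deviation $(m - mz)/mz \times 10^6$ is within the ppm
tolerance.

**Ionization convention.** Shifts are physically charged-species masses:
`[M+H]+` adds a proton (H minus an electron, 1.0072765 Da), `[M-H]-`
subtracts one, `[M]+` subtracts a single electron mass, `[M+Na]+` adds
22.9892207 Da, and the anion-attachment rules (`[M+HCOO]-`,
`[M+CH3COO]-`) add the neutral group plus one electron. The widely used
alternative — shifting by a full hydrogen atom and ignoring the electron
— differs by ~0.00055 Da, i.e. 1–4 ppm over the 130–600 m/z range; the
5–10 ppm tolerances in routine use absorb either convention, but the
electron-corrected one is the physically correct choice and is what the
acceptance checks use.

**Both formate and acetate ship in the negative-mode default set.**
Methods sections in this field frequently name acetate attachment while
the corresponding peak tables print formate adducts; carrying both rules
reproduces either table at no cost (a wrong rule simply never matches
within tolerance).

**All candidates are reported.** Matching never forces uniqueness: every
(peak, compound, adduct) triple within tolerance is returned, sorted per
peak by absolute ppm error, because disambiguation among isomers is done
downstream with MS2 spectra and literature, not by the mass filter.

**Parameters.** `tol` defaults to 10 ppm, the customary accuracy
threshold for benchtop QTOF data; 5 ppm is available for stricter work.
The optional scan-range check (50–1500 m/z) reflects typical acquisition
ranges and is off by default since peak lists normally arrive
pre-filtered.

## 2. MS2 neutral losses

Fragment ions are explained as the precursor minus combinations of small
neutral molecules (H₂O 18.0106, CO 27.9949, CO₂ 43.9898, NH₃ 17.0265 Da,
combined up to three units). Each fragment receives its nominal loss
(integer, rounded half away from zero) and, where possible, a loss name.

**Two-pass matching.** An exact-mass pass (default tolerance 0.01 Da)
runs first. Published fragmentation schemes, however, usually quote
nominal m/z ("loss of 56 Da"), and at nominal precision the 2×CO
(55.9898 Da) and CO₂ (43.9898 Da) losses sit 0.0102 Da from their
integers — just outside a 0.01 Da window. Rather than loosening the
exact tolerance (which would blur genuinely exact data), a second pass
matches on the nominal integer mass alone and flags the result
`match_type = "nominal"`. Unmatched fragments are kept and flagged
`"none"`, never dropped. This reproduces the canonical flavonoid CO
cascade (−28, −2×28 from the protonated aglycone; −44 from the
deprotonated ion) directly from integer m/z.

## 3. Target transfer

Compound fingerprints are binary structural descriptors compared by the
Tanimoto coefficient $T(A,B) = |A \cap B| / |A \cup B|$. Targets of
every approved drug with $T \ge 0.8$ (inclusive — "moderate–high
similarity") transfer to the query; per gene, supporting drugs are
aggregated and the maximum similarity recorded. Union over qualifying
drugs is the default (a best-match-only mode exists) because aggregate
target counts in published analyses are only attainable by union.
Fingerprint *generation* is deliberately out of scope: the proprietary
descriptors used by commercial tools cannot be reproduced, and the
transfer logic is independent of where the bit sets come from.

Two empty fingerprints score 0, not 1, with a warning: an empty bit set
carries no structural evidence and must not count as a perfect match.

## 4. Network construction and hub filtering

Nodes are the union of putative targets and disease genes, with role
`putative_target`, `disease_gene`, or `both`. Edges survive when their
combined confidence is ≥ 0.4 (the conventional "medium" cutoff;
0–1000-scaled scores are divided by 1000 on read), both endpoints are in
the node universe, and they are not self-loops; the graph is undirected
and simple.

Three centralities are computed per node: degree; shortest-path
betweenness normalized by $(n-1)(n-2)/2$ pairs; and closeness under the
within-component convention — (number of reachable nodes)/(sum of
distances to them), 0 for isolated nodes. Normalization choices applied
uniformly cannot change outcomes of median-threshold filters, and the
test suite checks exactly that invariance.

The hub filter is two-stage, with **strict** inequalities in both
stages (ties excluded, so an all-equal-degree network has no hubs):

1. **Hubs**: degree > 2 × median degree over all nodes. The median is
   taken over the full node universe (configurable), and the median of
   an even-length list is the mean of the two central order statistics.
2. **Major hubs**: induce the subnetwork of direct hub–hub edges,
   recompute all three centralities *on that subnetwork*, and keep nodes
   exceeding all three of its medians simultaneously. Recomputing on the
   induced subnetwork (rather than reusing full-network values) is the
   documented behavior of the workflow this package systematizes. A
   vertex-transitive hub subnetwork (clique, cycle) therefore yields no
   major hubs — nothing can strictly exceed its own median.

Major hubs are partitioned by role into candidate targets (role includes
`putative_target`) and disease genes (role includes `disease_gene`).
Dual-role nodes are counted in **both** subsets, and the dual-role set
is reported explicitly rather than silently resolved; published counts
produced this way can sum to more than the number of major hubs, and
making the overlap visible is the only honest presentation.

## 5. Pathway over-representation

For a query of $n$ genes against a set of $K$ genes in a background of
$N$, the over-representation p-value is the hypergeometric upper tail
$P(X \ge k)$, evaluated as a log-space sum of `lchoose` terms — stable
for genome-scale counts. The headline selection rule is raw $p < 0.05$
(strict); no multiple-testing correction is applied in that path because
the workflow being systematized selects on raw p, but a
Benjamini–Hochberg column is always emitted alongside. The EASE-style
conservative variant ($k-1$ in place of $k$) is available and off by
default. The background defaults to the union of all collection genes; a
user-supplied universe overrides it, since the "right" universe is a
genuinely open question in ORA.

One statistical subtlety: the hypergeometric test is discrete, so its
attainable size at nominal α = 0.05 depends on (N, K, n). The type-I
acceptance check uses N = 500, K = 100, n = 80, where the attainable
level is 0.0499; with very small sets the attained rate would sit far
below nominal purely through discreteness, which would test the
geometry of the support, not the implementation.

## 6. qPCR relative quantification

The Livak method: technical replicates are averaged on the Ct scale
(standard practice; averaging fold changes instead would bias upward by
Jensen's inequality), ΔCt = Ct(target) − Ct(reference) per sample,
ΔΔCt subtracts the control-group mean ΔCt per gene, and fold =
2^−ΔΔCt. Fold changes are invariant to any per-sample additive Ct
offset — the property that makes the reference-gene design work — and
that invariance is property-tested. Amplification-efficiency correction
(Pfaffl) is a declared non-goal.

## 7. The synthetic world

Each generator is a pure function of `sim_config(seed, ...)`; streams
are derived from the master seed via stable string labels, so adding a
generator never shifts another's output, and identical configs produce
byte-identical files.

Defaults state the world the tests assume:

- **MS fixture**: 500 compounds with C₄–C₃₀ H₄–H₄₀ N₀–₃ O₀–₁₀ S₀–₁
  formulas, one peak per compound at a random adduct with 2 ppm Gaussian
  noise. At 10 ppm tolerance a 5σ tail bound predicts ≥ 99% recovery of
  the generating (compound, adduct) pair, and the tests confirm it.
- **Fingerprints**: 1024 bits at density 0.3, queries are drug prints
  with each position flipped at 5%. Density matters: at 0.3 the
  source-drug similarity concentrates near 0.85 (above the 0.8
  threshold) while unrelated drugs sit near 0.18; at sparse realistic
  densities (~0.1) the same flip rate would push even the true source
  below 0.8 and the planted-recovery example would be unattainable.
  Density 0.3 was chosen once on that argument and not revisited.
- **Network**: 400 nodes, Erdős–Rényi background with mean degree 4,
  10 planted stars of degree 40. Star leaves are drawn from recycled
  random permutations of the non-hub nodes, capping how many stars any
  leaf joins, so the planted centers are the unambiguous degree
  outliers; 30% of confidences fall below 0.4 to exercise the edge
  filter.
- **Enrichment**: 50 sets of 20 genes over a 2000-gene universe; query
  genes come from the planted set with probability 0.6. Because the
  hypergeometric p is discrete, the null-uniformity test evaluates the
  randomized probability integral transform of the planted set's
  p-value, which is exactly U(0,1) under the null, rather than the raw
  discrete p.
- **qPCR**: three groups of six samples, four target genes with planted
  folds (0.4–2.5×), reference baseline Ct 18, gene baselines 22–28,
  replicate noise σ = 0.1 cycles, three replicates.

What a green test establishes — and what it does not: the generators
plant exactly the structure each stage is designed to recover, under
idealized noise (Gaussian ppm error, independent bit flips, ER
background, independent Ct noise). Real data violate all of these —
correlated adduct series and isotope interference, structured chemical
similarity, scale-free protein networks with confidence-correlated
degree, pipetting errors correlated within plates. Recovery on the
fixtures therefore validates the *algorithms*, not performance on any
particular instrument's output, and the published headline counts of
any specific study depend on proprietary database snapshots that no
desk-scale computation can reproduce.

## 8. Numerical and interface choices

- Nominal losses round half away from zero (base R's `round` rounds
  half to even, which is wrong for mass differences).
- Median: base `stats::median` (mean of central pair for even counts),
  consistent everywhere a median threshold appears.
- The pipeline always writes intermediates; every run writes a
  `report.json` carrying the package version, seed, and an FNV-1a hash
  of the configuration (excluding the output directory, so identical
  analyses hash identically wherever they land).
- Stage failures abort with the stage name; stages with missing inputs
  or disabled toggles are skipped silently.

## Known limitations

- No raw-spectrum processing: the package starts from a peak table.
- No isotope-pattern scoring or RT-based disambiguation; annotation is
  mass-and-polarity only, by design returning all candidates.
- Fingerprints are consumed, not computed.
- The PPI model is whatever edge list is supplied; no species mapping
  or evidence-channel decomposition.
- ORA only: no topology-aware pathway analysis or ranked GSEA.
- qPCR assumes 100% amplification efficiency.
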