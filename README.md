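# xlms

Cross-link search and FDR benchmarking for cross-linking mass
spectrometry (XL-MS) with MS-cleavable reagents.

## What problem this solves

XL-MS with a cleavable linker such as DSSO turns residue-residue
proximities into identifiable MS2 spectra: the linker bridge is cleaved
during fragmentation, leaving each linked peptide as a linear species
carrying one of two stub masses. Both stub forms of the same peptide
appear in the spectrum, producing *signature doublets* — peak pairs
separated by a fixed delta (one sulfur, 31.97207 Da, for DSSO). Reading
the doublets gives the masses of the two linked chains, so candidates
can be found by two narrow mass-window lookups instead of a quadratic
pair search.

`xlms` is for method developers and analysts who need a transparent,
fully testable implementation of this pipeline in R:

* **Search**: in-silico tryptic digestion with decoys, a mass-sorted
  peptide index, doublet-gated candidate generation, b/y-with-stub
  fragment matching, and a feature-based trainable discriminant.
* **FDR**: the cross-link target-decoy estimator
  `FDR(t) = max(TD − DD, 0) / TT` with q-values, applied separately to
  inter- and intralinks and sequentially at three tiers — cross-link
  spectrum matches (CSMs), unique residue pairs (ResPairs) and
  protein-protein interactions (PPIs).
* **Ground truth**: a pairwise mixing-scheme model (by default 32
  interaction groups × 8 proteins → 28 allowed PPIs per group, 896
  total) that classifies every identification as allowed or prohibited
  and yields an *empirical* FDR, plus an entrapment-database builder.
* **Simulation**: a Zipf (target α-site) / Poisson (decoy β-site)
  placement model estimating how often false links would masquerade as
  allowed ones, and a synthetic MS2 generator that plants cross-linked
  and linear-background spectra with known answers.
* **Structure mapping**: model confidence `0.8·ipTM + 0.2·pTM`,
  Cα–Cα distances and pLDDT-based disorder filtering for evaluating
  identified links on predicted structures.

## A worked example

Generate a small synthetic benchmark with planted answers, search it,
and evaluate against the known mixing scheme:

```r
library(xlms)

cfg <- synth_config(n_groups = 4, group_size = 4, n_entrapment = 10,
                    n_crosslink_spectra = 40,
                    n_linear_background_spectra = 80, seed = 7)
bm  <- generate_benchmark_dataset(cfg)
res <- xl_search(bm$spectra, bm$proteins,
                 digest = digest_params(variable_mods = list()), seed = 7)
res
#> xl_results:
#>   CSMs:        40 (1 inter / 39 intra)
#>   ResPairs:    40 (1 inter / 39 intra)
#>   PPIs:         1

planted_recovery(res, bm$truth)$recovery
#> [1] 1

benchmark_results(res, bm$scheme)
#> xl_benchmark_report (empirical FDR against the mixing scheme):
#>   CSM      n =    40, false =    0, FDR = 0.00%
#>   RESPAIR  n =    40, false =    0, FDR = 0.00%
#>   PPI      n =     1, false =    0, FDR = 0.00%
#>   PPI coverage of theoretical maximum: 4.2%
```

All 40 planted cross-link spectra are recovered at a 1% software-defined
FDR on every tier, and none of the reported identifications violates the
mixing scheme (empirical FDR 0%). (At this toy scale the search warns
that too few decoys were found to train the discriminant and falls back
to fixed feature weights; larger runs train the logistic model.) At full scale (540-protein database
with entrapment, 500 cross-link + 2,000 linear spectra) the same
pipeline recovers ≈ 99.6% of planted residue pairs in about three
minutes on one CPU.

## Documentation

The methods vignette (`vignettes/xlms-methods.Rmd`) describes the search
model, the discriminant and FDR machinery, the ground-truth and
simulation models, what the synthetic generator does and does not
emulate, numerical edge cases and known limitations.
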