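---
title: "Cross-link identification with cleavable linkers: models, scoring and FDR in xlms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link identification with cleavable linkers: models, scoring and FDR in xlms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlms)
```

# The problem

Cross-linking mass spectrometry (XL-MS) identifies pairs of residues that
were covalently bridged by a cross-linking reagent, yielding
residue-to-residue distance restraints and protein-protein interaction
(PPI) evidence at proteome scale.  With an MS-cleavable reagent such as
DSSO, the bridge is cleaved during MS2 fragmentation: each of the two
linked peptides appears in the spectrum as a *linear* peptide carrying
one of two characteristic stub masses.  Because both stub forms of the
same peptide occur, the spectrum contains *signature doublets* -- peak
pairs separated by a fixed mass difference (one sulfur, 31.97207 Da, for
DSSO).  Doublets let a search engine read off the masses of the two
linked chains directly, so the candidate space grows linearly rather than
quadratically with database size.

`xlms` implements this search strategy end to end, together with the
apparatus needed to *validate* it without any external data: a
pairwise-mixing ground-truth model, an empirical-FDR benchmark, a
false-link placement simulator and a synthetic spectrum generator with
planted answers.

# The search model

## Digestion and indexing

Proteins are digested in silico with trypsin (cleavage C-terminal of K/R
except before proline).  Defaults follow common cleavable-linker
practice: up to 3 missed cleavages, minimum length 6, peptide mass
500--6,000 Da, carbamidomethyl-C fixed, oxidation-M variable (at most
2 per peptide).  Non-standard residues (B, J, O, U, X, Z) have no defined
monoisotopic mass; peptides containing them are dropped with a warning
rather than poisoning the index.  A peptide maps to *all* proteins that
contain it; downstream, shared peptides propagate as explicitly flagged
ambiguous mappings.

Decoys are reversed sequences keeping the C-terminal residue (preserving
the tryptic terminus and the exact mass); palindromic collisions fall
back to seeded shuffling with up to ten retries and are flagged if
unresolved.  Targets and decoys share one mass-sorted index; window
queries are binary searches verified in the tests against a linear-scan
oracle.

Cross-linkable sites are lysines (plus the protein N-terminus).  A
C-terminal lysine of a fully tryptic peptide *is* allowed as a link site
(`allow_cterm_link_site = TRUE`): a cross-linked lysine resists
cleavage, but the missed-cleavage forms cover the same site either way,
and allowing it maximizes recall.

## Doublet detection and mass hypotheses

For each fragment charge $z$ from 1 to (precursor charge $-$ 1), every
peak pair whose spacing times $z$ equals the stub mass difference within
tolerance is reported as a doublet; the light peak gives the candidate
peptide mass $m = \mathrm{mz} \cdot z - z \cdot m_p - m_{\mathrm{stub,light}}$.
Hypotheses about the (alpha, beta) chain masses come from complementary
doublet pairs that reconstruct the precursor mass
($m_a + m_b + m_{\mathrm{bridge}} = M$ within the MS1 tolerance) and from
single doublets with the partner defined by difference.  Hypotheses are
deduplicated within the MS1 tolerance and ranked complementary-first,
then by doublet support, then intensity, capped at 8 per spectrum to
bound search cost.  Spectra with no doublets are normally not searched
(the doublet is the gate); an exhaustive mass-partition fallback exists
behind a flag for sensitivity-over-speed use.

## Candidate scoring

Candidates are all (alpha window) x (beta window) peptide pairs with at
least one link site each, capped at 5,000 pairs per hypothesis.  Each
chain's fragments depend only on its own link site, so the best site is
chosen per chain: b/y ladders at charges 1--2, with ions spanning the
link site generated in both stub variants.  Each theoretical ion
consumes at most one peak (the nearest within the MS2 tolerance); one
peak may serve several ions, which prevents coverage inflation without
discarding shared evidence.

A CSM is reported only if **both** chains have at least
`min_fragments_per_chain` (default 3) matched fragment ions.  This
minimum-evidence rule matters: linear background peptides occasionally
gate through chance doublets and then pair their own genuine ladder with
an arbitrary partner, producing one-sided target-target matches that the
decoy population does not model.  Requiring bilateral evidence removes
that failure mode at essentially no cost in sensitivity (planted chains
match ~10 or more ions).

The feature vector (fixed, versioned order) holds matched counts and
ladder coverages per chain, explained intensity, doublet support and
complementarity, absolute precursor error (ppm), longest consecutive
ladder runs, peptide lengths and charge.  One CSM per spectrum is
reported by default, ties broken deterministically on (score, matched
count, alpha sequence, beta sequence); alpha is always the longer
peptide (ties lexicographic) so residue-pair keys are stable.

## Discriminant and multi-tier FDR

A logistic discriminant (optionally a 16-unit single-hidden-layer MLP
via nnet) is trained on z-scored features with target-target CSMs as
label 1 and decoy-containing CSMs as label 0; with fewer than 50 decoys
a fixed linear combination is used and flagged.  The published engines
in this field use neural discriminants whose exact architectures are not
recoverable from the literature; the contract that matters -- a monotone
target/decoy-trained score per tier -- is preserved.

FDR uses the standard cross-link target-decoy estimator
$\widehat{\mathrm{FDR}}(t) = \max(\mathrm{TD} - \mathrm{DD}, 0)/\mathrm{TT}$
over records scoring at least $t$, with q-values as the running minimum
from the bottom of the score-sorted list; inter- and intralinks are
filtered separately.  Filtering is sequential: CSM filter, aggregation
to unique residue pairs (ResPairs, protein-coordinate keys, score = best
member, decoy classes aggregate pessimistically), ResPair filter,
aggregation of inter ResPairs to protein pairs, PPI filter.  Ambiguous
shared-peptide mappings are emitted per protein mapping but only the
first mapping (accession order) enters FDR denominators, so ambiguity
never double-counts.

# The ground-truth model

The benchmark design mixes recombinant proteins pairwise within
interaction groups -- by default 32 groups of 8 proteins, giving
$\binom{8}{2} = 28$ allowed PPIs per group and 896 overall; groups are
assigned to batches (8 groups per batch, so two batches span 448 allowed
pairs).  Any inter-protein identification within one group is allowed;
between groups, or touching an entrapment protein, it must be false.
Intralinks are allowed on present proteins; identifications at residue
positions outside a recombinant construct's range count as false.  The
*empirical FDR* is the fraction of reported target identifications that
violate these rules -- an external check on the engine's own
target-decoy estimate.  Entrapment databases are built by appending
pool proteins whose global-alignment identity (match 1 / mismatch 0 /
gap $-1$; identity = matches / alignment length -- the identity
definition is our explicit choice, configurable) to every standard
protein is below 85%.

# The false-link simulator

To ask how often a *false* residue pair would land within a group (and
so be wrongly counted as allowed), false links are modeled as a true
alpha-site and a false beta-site.  Alpha-site placement probabilities
follow a Zipfian curve fitted by log-log least squares to the ranked
per-protein target cross-link counts and are restricted to the standard
proteins (default 256); beta-sites follow a Poisson model (ML rate =
mean) over all database entries (540 or 4,000).  Fitted curves are
converted to probabilities by normalizing the curve evaluated at ranks
$1..n$, with the rank-to-protein assignment randomized per replicate
(the conversion is our documented choice; for the Poisson model the
expected ranked counts are approximated by quantiles at plotting
positions).  Alpha/beta co-occurrence on one protein is a false
intralink; within one group, a false within-group interlink; beta-beta
co-occurrence (decoy-decoy links) is ignored as negligible.  The tests
verify Monte-Carlo agreement with the closed-form co-occurrence
probability under uniform placement and monotonicity in database size.

# The synthetic-data generator

The generator emulates the *structure* of the benchmark datasets, not
their physics:

* random proteins (uniform residues with lysine weight x2, guaranteeing
  at least 3 link sites), 32 x 8 scheme plus 284 entrapment entries
  (540 total) by default;
* 500 cross-linked spectra drawn only from scheme-allowed pairs at an
  intra:inter ratio of 10 (cleavable-linker data show 1--2 orders of
  magnitude more intralinks than interlinks; 10 is the conservative end),
  precursor charges 4--8 (acquisition selects those charges for
  cross-linked precursors);
* per spectrum: b/y ladders of both chains with stub variants for
  link-spanning ions, each ion missing with probability 0.1; intact-chain
  stub doublets at fragment charges 1--2; 30 uniform noise peaks; 5 ppm
  peak jitter; log-normal ladder intensities (median ~10x noise);
* 2,000 linear background spectra from the present proteins -- these are
  what stress the FDR machinery, since only they can generate false
  matches through chance doublets.

What it does **not** emulate: isotope envelopes, co-isolation, retention
time, intensity structure of real fragmentation, modified peptides in
spectra, homologous sequence families.  Passing the planted-truth and
calibration tests therefore demonstrates correctness of the search and
FDR logic under realistic combinatorics, not instrument-level
performance on real data.

Problem sizes used in the checks are the package's own choices: the
recovery check runs the full default benchmark (540 proteins, 2,500
spectra) once; the ten-seed calibration check uses a reduced geometry
(15 groups x 8 + 60 entrapment, 150 cross-link + 400 linear spectra per
seed) so that repeated end-to-end searches remain quick on one CPU.

# Structure mapping

Identified residue pairs can be mapped onto predicted structures: the
combined model confidence is $0.8 \cdot \mathrm{ipTM} + 0.2 \cdot
\mathrm{pTM}$; Calpha--Calpha distances are Euclidean; pairs are kept
only when both residues have pLDDT strictly above 50 (disorder filter).
Among ranked models of one PPI the one with the highest cross-link
satisfaction is preferred, using a 35 angstrom Calpha cutoff as the
DSSO-class default -- the cutoff is our documented assumption.
Structure prediction itself is out of scope; coordinates come from
standard PDB files with pLDDT in the B-factor column.

# Numerical choices and degenerate inputs

* All tolerances are ppm-relative (10 ppm MS1, 20 ppm MS2 defaults);
  doublet peak deduplication at 1e-4 m/z.
* Spectra without a precursor charge are kept (charge 0) but never
  searched: the neutral precursor mass is undefined.  The searchable
  charge range defaults to 3--8, one wider than the acquisition's 4--8,
  to protect against mis-assigned charges.
* `estimate_fdr` floors the estimator numerator at zero, assigns q = 1
  where no targets score above threshold, and gives tied scores one
  shared q-value.
* Zero-decoy or all-target partitions degrade gracefully (q = 0), and
  the discriminant falls back to fixed weights rather than fitting an
  unidentifiable model.
* All randomized steps (decoy shuffles, generator, simulator,
  discriminant initialization) take explicit seeds and use an isolated
  RNG stream that leaves the caller's `.Random.seed` untouched.

# Known limitations

* Only b/y ions are modeled (no a/x/c/z ions, neutral losses or isotope
  error correction).
* MS3-driven acquisition, vendor raw files and mzIdentML export are out
  of scope; MGF is the tested input surface, mzML optional via mzR.
* The discriminant is intentionally lightweight; it reproduces the
  contract, not the learned weights, of GPU-scale engines.
* Empirical-FDR benchmarking of other engines' result files is not
  included.

# A minimal session

```{r example, eval = FALSE}
cfg <- synth_config(n_groups = 4, group_size = 4, n_entrapment = 10,
                    n_crosslink_spectra = 60,
                    n_linear_background_spectra = 150, seed = 42)
bm <- generate_benchmark_dataset(cfg)
res <- xl_search(bm$spectra, bm$proteins,
                 digest = digest_params(variable_mods = list()),
                 seed = 42)
res
planted_recovery(res, bm$truth)
benchmark_results(res, bm$scheme)
```
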