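---
title: "Methods: two-stage miRNA target prediction from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage miRNA target prediction from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

MicroRNAs (miRNAs) repress messenger RNAs by partial base pairing with
sites in the 3'-UTR, with recognition dominated by the *seed* (miRNA
nucleotides 2–7, extended to 8 with the m8 pair). `mirtarscan` predicts
miRNA regulation in two stages:

* **TS (target site)** — every canonical seed-match site in a 3'-UTR is
  enumerated and scored with a *binding confidence*, the probability that
  the site is a functional binding site.
* **TM (target mRNA)** — one transcript may host many sites, and
  repression depends on them collectively. Per-site probabilities are
  aggregated into four transcript-level features — their sum and the
  three largest values — on which a second classifier produces an
  *interaction confidence*, the probability that the miRNA represses the
  transcript.

Both classifiers are gradient-boosted decision-tree ensembles with
logistic loss. No boosted-tree package is assumed at run time; the
package ships a compact exact-greedy learner (in C++) that reproduces
the behaviours the pipeline depends on: internal handling of missing
feature values via learned default split directions, determinism, and
optional per-feature monotonicity constraints.

### Canonical site classes

Reading the UTR 5'→3', with `M6` the reverse complement of miRNA
positions 2–7: an offset whose 6 bases equal `M6` is a candidate core.
The base 5' of the core (opposite miRNA position 8) and the base 3' of
the core (opposite miRNA position 1) decide the class: both supporting →
**8mer**; m8 only → **7mer-m8**; a 3' adenine only → **7mer-A1**;
neither → **6mer**. The A1 base must be adenine regardless of the miRNA
position-1 identity, matching the field's convention that Argonaute
reads the A directly. Two deliberate choices, stated because the
canonical classes have no single authoritative operational definition:
G:U wobbles never count as seed matches, and a context base truncated by
the UTR boundary cannot support its extension (a site flush at the 3'
end can never be 7mer-A1/8mer). A brute-force oracle implementing the
four definitions independently is part of the test suite and the
acceptance report.

## The seven feature families (154 features)

| family | n | content |
|---|---|---|
| site type | 4 | one-hot over {6mer, 7mer-A1, 7mer-m8, 8mer} |
| binding stability | 4 | nearest-neighbor duplex energy (total, seed-only, per-pair, paired count) |
| accessibility | 13 | positional distances, AU/GC context, ensemble opening energy and unpaired propensities |
| 3'-supplementary | 7 | pairing counts/runs around miRNA positions 13–16, wobbles, best register offset |
| conservation | 16 | mean/min/max/fraction-above-threshold over core, site, and 30-nt flanks |
| SNP | 18 | any/disease indicators for the 3'-most eight site positions + two totals |
| descriptors | 92 | mono/di/trinucleotide composition, Z-curve, GC/AU/purine content, length, homopolymer run |

The family cardinalities (4/4/13/7/16/18/92) are fixed; the exact member
definitions are this package's own reconstruction, kept behind a
config-driven registry (`default_registry()`) so members can be swapped
without code changes. Absent resources (no conservation track, no SNP
table) propagate as missing values — never silent zeros — because the
classifier handles missingness internally; an empty-but-present SNP
table, by contrast, legitimately yields zero counts.

### Numerical backends

* **Duplex stability.** Watson–Crick pairs are laid out in the register
  fixed by the seed match (miRNA position *p* opposite UTR position
  `core + 7 − p`, no bulges); the energy is the sum of RNA/RNA
  dG37 nearest-neighbor stacking terms over consecutive paired
  positions. Since all pairs are Watson–Crick, each stack is determined
  by the target dinucleotide (16-entry table). Adding a complementary
  pair can only add non-positive stack terms, giving the monotonicity
  the tests assert.
* **Accessibility.** A Nussinov-style base-pair ensemble (pair energies
  GC −3, AU −2, GU −1 kcal/mol, minimum loop 3, RT at 37 °C) is solved
  by inside–outside dynamic programming on the window site ± 40 nt.
  This yields exact per-base unpaired probabilities under the model, and
  the opening energy `RT·ln(Z/Z_open)` with the site forced unpaired —
  the same ΔΔG-of-opening idea used by RNAplfold/PITA, at a cost of
  about a millisecond per site. External folding or interaction tools
  (ViennaRNA, IntaRNA) are deliberately not required; requesting an
  external backend raises an error instructing fallback to the built-in
  one.

### Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| target-region flank | 20 nt | context for descriptors/GC; unstated upstream, fixed here |
| conservation/AU flank | 30 nt | typical functional-context window |
| conservation threshold | 0.5 | midpoint of a [0,1] score track |
| folding window flank | 40 nt | local structure context, keeps O(n³) DP cheap |
| unpaired-propensity window | ±10 nt | near-site accessibility |
| TM repression bound | ≤ 0.60 relative expression | "at least 40% reduction" |
| TM unaffected range | [1.00, 1.10] inclusive | stated control range; boundary inclusivity is this package's declared choice |
| greedy selection cap / gain | 22 features / 1e-4 | the reference pipeline's outcome size; the gain floor stops when CV MCC no longer improves |
| boosting defaults | 50 rounds, η 0.3, depth 4, λ 1 | ordinary gradient-boosting defaults; no hyperparameter search is claimed |

## Dataset construction

Positives are verified site interactions; candidate negatives are all
other scanned sites. Two curation steps mirror the training-data logic
of CLIP-seq-based pipelines: candidate negatives whose (miRNA, gene)
pair appears in a validated-interaction list are removed (assay
sensitivity limits make "unobserved" unreliable as "non-interacting"),
and classes are balanced 1:1 by seeded uniform under-sampling of the
majority class. Under-sampling is global, not stratified by miRNA (a
stratified option would be a one-line change; the global form is the
declared default). Transcript-level labels come from relative expression
under miRNA transfection: ≤ 0.60 → repressed, [1.00, 1.10] →
unaffected, everything else excluded. Gene identifiers resolve to their
longest-UTR transcript, ties broken by lexicographically smallest
transcript id.

## Feature selection and evaluation

Forward stepwise greedy selection starts from the empty set and, at each
iteration, adds the candidate maximizing mean 10-fold cross-validated
MCC, ties broken by registry order; it stops at the feature cap or when
the gain drops below the floor. The fold assignment is fixed once per
selection run so candidate scores are comparable. Metrics: AUC (rank
statistic, ties averaged), balanced accuracy, F1, MCC (0 when a
denominator factor vanishes), precision, recall, specificity. With a
single-class truth the AUC is reported missing with a warning while the
threshold metrics are still computed. Evaluation splits: stratified
blind test (default 20%), k-fold cross-validation, and entity-held-out
splits (unseen miRNAs, unseen transcripts, or both) for generalisation
probes.

## The synthetic world

`generate_corpus()` states a world rather than offering a dial to turn
until tests pass:

* 5 miRNAs × 500 transcripts (UTRs 500–1500 nt, uniform background),
  implant probability 0.4 per pair → ≈ 1000 implanted sites, with class
  mix 20/25/30/25% over 6mer/7mer-A1/7mer-m8/8mer — sevenmers most
  frequent, as in real site censuses.
* Implanted sites get GC-biased flanks (+0.15 GC) and, with probability
  0.5, a perfect 3'-supplementary patch opposite miRNA 13–16 — so the
  thermodynamic and supplementary features carry signal.
* Conservation is uniform [0, 0.6] in the background and uplifted by
  0.4 (capped at 1) over implanted sites.
* SNPs are sprinkled uniformly (0.002/base, 20% disease-flagged),
  *independently of implants* — SNP features are intentional noise.
* 10% of implants are withheld from the positive list and their (miRNA,
  gene) pairs added to the validated list, so negative filtering has
  real work to do; 20 validated decoy pairs without sites are added too.
* Expression: pairs with ≥ 1 implant are repressed with probability 0.9
  (relative expression uniform [0.2, 0.6]), otherwise unaffected
  [1.0, 1.1]; 5% of implant-free pairs fall in the excluded middle.

What a green end-to-end test establishes: the scanner, featurizer,
dataset plumbing, selection and both classifiers interlock correctly and
recover strong planted signal. What it does **not** establish: real
CLIP-derived data has correlated noise, non-uniform base composition,
non-canonical sites and far weaker class separation — the reference
tool's published AUCs (~0.96) are properties of its data and cannot be
reproduced from this synthetic world, which typically separates more
cleanly. The *informative feature set* used by the selection test is the
causal closure of implantation (site type, stability, supplementary,
conservation, composition/structure features); position and SNP features
are independent of implantation by construction and must not be picked.

Because the first conservation feature alone separates this world almost
perfectly, greedy selection usually stops after very few picks under the
default gain floor; the selection test therefore checks that *all picks
made* (capped at five) are planted-informative, across ten seeds.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; user-facing reports
  are 1-based inclusive.
* DNA input (T) is accepted and normalized to RNA (U); any other
  character is an error naming record and position.
* Model bundles serialize to JSON with doubles rendered via `%.17g`, so
  a save/load round trip reproduces predictions bit for bit.
* The boosted-tree learner is fully deterministic (no subsampling; ties
  in split search resolve to the lowest feature index and left-most
  threshold), making byte-identical reruns a testable contract.
* Monotone constraints (off by default, used as a property probe for
  the TM model) follow the standard bounded-leaf scheme: a violating
  split is rejected and children inherit tightened value bounds.
* `aggregate_site_probs` of zero sites is (0, NA, NA, NA): "no site" is
  not "a site of probability 0", and top-k entries stay missing rather
  than being imputed.

## Known limitations

* Only canonical 3'-UTR sites: no bulged/offset/centered sites, no
  5'-UTR/CDS scanning.
* The accessibility model is a base-pair-counting ensemble, not a full
  nearest-neighbor loop model; its energies are meaningful relatively,
  not calibrated absolutely.
* Feature-family membership beyond the stated cardinalities is a
  reconstruction; the registry exists precisely so members can be
  replaced as better definitions become available.
* No trained model is shipped; models are artifacts of the data the
  user (or the synthetic generator) supplies.
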