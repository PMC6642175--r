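---
title: "Estimating dispensable interactome content from mutation edgotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dispensable interactome content from mutation edgotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgotype)
```

## The model

A protein–protein interaction (PPI) is *completely dispensable* when its
disruption is effectively neutral for organismal fitness. The package
estimates the dispensable fraction of an interactome from mutation
*edgotypes*: which PPIs each missense mutation disrupts.

Three fitness classes are assumed for new missense mutations — effectively
neutral (N), mildly deleterious (M), strongly detrimental (S) — with prior
probabilities P(N) = 0.27, P(M) = 0.53, P(S) = 0.20 taken from the
population-genetics literature (`fitness_priors()`). Common mutations from
healthy individuals stand in for class N, Mendelian disease mutations for
class M. Class S mutations are assumed quasi-null (they destabilize the
protein and remove all its interactions) rather than edgetic, so
P(E|S) = 0; allowing P(E|S) > 0 only lowers the estimate, which makes the
default an upper bound in that respect.

Writing E for "the mutation is edgetic" and using the observed class-wise
edgetic fractions P(E|N) = k_N/n_N and P(E|M) = k_M/n_M,

\[
P(E) = P(E|N)P(N) + P(E|M)P(M) + P(E|S)P(S), \qquad
P(N|E) = \frac{P(E|N)\,P(N)}{P(E)}.
\]

Under the reading that an edgetic mutation disrupts one PPI (true for most
edgetic calls in practice, and relaxed by the `mono_edgetic` variant),
P(N|E) is the dispensable fraction of the interactome. All arithmetic uses
exact count fractions; percentages are rounded only when printed.

Because the priors are constants, P(N|E) depends on the data only through
the ratio r = P(E|M)/P(E|N):
\( 1/P(N|E) = r \, P(M)/P(N) + 1 \).
The 95% CI is therefore computed on r with the Katz log-scale interval,

\[
\log r \pm z \sqrt{1/k_M - 1/n_M + 1/k_N - 1/n_N}, \quad z = 1.96,
\]

and each bound mapped through the identity above; the ratio's *lower* bound
yields the *upper* bound of P(N|E). `z` is configurable; 1.96 (not
1.959964) is the default. Zero edgetic counts make the interval undefined;
`ci95_dispensable()` refuses by default and offers a Haldane-style +0.5
continuity correction behind an explicit flag. A parametric-bootstrap
interval (binomial resampling of both rates) is kept in the test suite as an
independent check that the Katz interval is calibrated.

```{r}
estimate_dispensability(edgetic_counts(k_N = 19, n_N = 376, k_M = 27, n_M = 145))
```

## From structures to edgotypes

**Interfaces.** The distance between two residues is the minimum over all
atom pairs of the Euclidean distance; a residue is an interface residue when
that minimum is within 5 Å of any residue of the partner chain
(`compute_interface()`). The rule is applied *inclusively* (≤ 5 Å): "within
a distance of 5 Å" is read as containing the boundary, and a dedicated test
pins the behaviour at exactly 5.000 Å. All atoms present in the record are
used, hydrogens included when present; `heavy_only = TRUE` in
`parse_chain()` switches to heavy atoms. Residue numbering is everywhere the
1-based index into the chain's declared backbone sequence (SEQRES);
insertion codes are not supported in the minimal PDB dialect. Coordinate
residues that disagree with the SEQRES at their position are discarded at
parse time, and only the first model of a multi-model file is read.

**Structural interactome.** Alignment hits (consumed as tables, the package
does not run BLAST) are filtered at E-value ≤ 1e-10 and reduced to the
best hit per (protein, structure, chain), ties broken toward the longest
alignment. A candidate chain-pair annotation needs a nonempty chain-pair
interface and ≥ 50% of each chain's interface residues aligned to the
protein; the coverage denominator is the *chain-side* interface size. Up to
5 annotations with the smallest joint E-values are kept per PPI. The joint
E-value is the product of the two hits' E-values (equivalently the sum in
log space): "smallest joint E-value" is otherwise underdetermined, and the
product is order-preserving for independent hits. Zero E-values, as real
aligners report, sort before any positive value. The PPI interface is the
union over retained annotations of the mapped chain interface residues;
union (rather than best-annotation-only) is the default reading and
`max_annotations = 1` recovers the alternative. Self-interactions evaluate
both chains against the one protein and take the union of both images.

**Mutation mapping.** Disease records are kept when strictly pathogenic
only, with at least one review star and no conflicting interpretations;
common records when validated, not withdrawn, free of disease assertions
(blacklist: pathogenic, likely pathogenic, drug-response, uncertain
significance, other) and with minor allele frequency strictly above 1%.
Mapping requires the transcript flank — up to 10 residues on each side of
the mutated position, embedding the wild-type residue — to occur on the
protein *at the same position* as on the transcript; a looser unique-match
mode (`same_position = FALSE`) exists for real data with coordinate
offsets. Duplicate positions keep the smallest mutation id (the retained
record is otherwise unspecified); non-disease mutations overlapping disease
positions are discarded, so the two mapped sets are position-disjoint.

**Edgotypes.** Geometry: a mutation disrupts exactly the PPIs whose
interface on its protein contains its position; edgetic means ≥ 1
disruption, mono-edgetic exactly 1. Quasi-null is never *predicted*; it
exists only as a label convention in experimental-style inputs, handled by
the `quasi_null_as_edgetic` variant of `estimate_dispensability()`.
Physics: among a mutation's interfacial PPIs, disrupted means
ΔΔG > 0.5 kcal/mol, strictly — 0.5 itself does not disrupt. Interfacial
mutations with no ΔΔG record for any of their PPIs are excluded from
physics tallies (numerator and denominator), which is why physics
denominators are slightly smaller than geometry ones. γ, the probability
that an interfacial mutation disrupts its PPI, is computed per
(mutation, PPI) pair — not per mutation — with a binomial standard error;
the per-pair choice matches the threshold rule, which is evaluated per
pair.

**Comparative statistics.** `fisher_edgetic_comparison()` is the two-sided
Fisher's exact test on the 2×2 edgetic table.
`compare_substitution_scores()` compares PAM30 substitution scores between
classes with a two-sided bootstrap test: both groups are recentred to the
pooled mean, resampled with replacement (1e6 resamples by default), and the
p-value is the two-sided tail fraction with the +1 correction; the mean
difference is used as the statistic, which the bootstrap literature treats
as the default when the test only names the procedure. The PAM30 matrix
ships as a plain-text fixture in NCBI format; ambiguity codes (B, Z, X, *)
are rejected unless `strict = FALSE`.

## The synthetic world

`generate_world()` produces every input the pipeline consumes, with ground
truth. Its defaults are the study conditions used throughout the tests:
interfacial placement rates `true_pEgivenN = 0.051`,
`true_pEgivenM = 0.186`, disruption probabilities `gamma_N = 0.60`,
`gamma_M = 0.66`, and 5000 mutations per class. Structural scale defaults
(120 proteins of mean length 250, 150 PPIs, interface width 15 residues per
side) are desk-scale choices: wide enough that interface capacity
comfortably exceeds interfacial mutation demand, small enough that a full
world generates in about a second.

Design choices worth knowing:

* **Geometry is a lattice, not a fold.** Residues are Cα plus one dummy
  side-chain atom on a jittered lattice; paired contact residues sit
  ~3.8 Å apart and everything else is kept beyond a 6 Å guard band. Only
  inter-atomic distances matter to the 5 Å rule, so stereochemistry is
  irrelevant; the guard band makes interface ground truth unambiguous
  (jitter amplitude 0.15 Å per coordinate cannot move a contact past 5 Å
  nor a non-contact under 6 Å).
* **Interface windows are disjoint per protein**, so every interface
  position belongs to exactly one PPI and geometry calls have an exact
  truth. Real interfaces overlap; multi-PPI disruption is exercised through
  hand-built fixtures instead.
* **Mutation positions are sampled without replacement** (globally unique
  per protein). Interfacial mutations therefore hit interfaces at *exactly*
  the configured Bernoulli rates, and the position-deduplication and
  overlap filters downstream are no-ops on clean worlds — the placement
  rates survive the filter chain unchanged, which is what parameter-recovery
  tests need. Duplicate handling itself is tested on dedicated fixtures.
* **ΔΔG values are class-wise mixtures of truncated normals**: with
  probability γ a value above 0.5 kcal/mol (mean 2.0, sd 1.0), otherwise
  below (mean −0.5, sd 1.0). Only the exceedance at 0.5 is consumed
  downstream, so the exceedance probability *is* γ by construction.
* **Alignments are exact identity hits** (E-value 1e-50);
  `alignment_noise = TRUE` injects worse duplicates, sub-threshold hits and
  gapped alignments with sub-50% interface coverage to exercise the filter
  chain against an independent oracle.
* **One master seed, per-stage substreams**: each generation stage draws
  from its own derived seed, so enlarging the mutation set does not perturb
  structures or alignments. GO annotations give interacting pairs a shared
  leaf term and the expression matrix gives them a shared latent profile,
  so QC metrics separate interacting from random pairs by construction.

What the generator does *not* emulate: realistic folds or rotamers,
overlapping or discontinuous interfaces, homodimers (tested via fixtures),
insertion codes or altlocs, alignment paralogy, linkage between mutations,
and class-dependent substitution spectra (mutant residues are uniform).
Passing parameter-recovery tests therefore shows the pipeline's *logic* is
correct under known truth, not that real ClinVar/dbSNP/PDB data would meet
the same rates.

## Problem sizes and numerical notes

The test suite validates interface detection against a brute-force
all-pairs oracle on 100 random dimers, the filter chain against an
independent record-by-record reimplementation on noisy worlds, and
parameter recovery on one full-scale world (5000 mutations per class)
followed by 100 seeded geometry-pipeline replicates (100 proteins, 80 PPIs
each) checking that the 95% CI covers the analytic P(N|E) in at least 93 of
100; the whole suite runs in a few minutes on one core. Distances are exact
(no spatial approximation); the vectorised cross-distance uses the
squared-expansion identity with negative values clamped at 0 before the
square root. Probability boundaries (rates of 0 or 1) are honoured exactly
by the generator, and configuration errors name the offending field.

## Limitations

* P(N|E) is an interactome-wide average; the package deliberately does not
  model heterogeneity across PPI subsets.
* The priors are constants taken from the literature; no machinery is
  provided to re-estimate them.
* The mono-edgetic and quasi-null-as-edgetic variants accept externally
  tallied counts; the package does not decide which convention a given
  experimental dataset used.
* ΔΔG computation is out of scope: values are consumed as tables
  (BindProfX/FoldX-style), never calculated.
* The minimal PDB dialect covers ATOM records with single-character chain
  ids; real-world quirks (altlocs, insertion codes, multi-letter chains)
  are not parsed.
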