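---
title: "Designing epistasis-aware active-site libraries with pocketlib"
author: "pocketlib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing epistasis-aware active-site libraries with pocketlib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketlib)
```

## The problem

Active sites concentrate molecular interactions, so most mutations there
destabilize the protein, and combinations of individually tolerated
mutations often fail together: a mutation may be fine on its own yet
incompatible with a specific identity at a contacting position. A
combinatorial library built from per-mutation filters alone therefore
consists mostly of dead sequences. `pocketlib` implements a design
strategy that removes this pairwise incompatibility *before* the library
is built: instead of selecting the best individual mutants, it selects a
set of point mutations that remain low-energy when combined freely.

The pipeline has four stages:

1. **Conservation filtering.** A position-specific scoring matrix (PSSM)
   is derived from a homolog alignment; mutations scoring at or below a
   threshold (default −2 bits) are discarded.
2. **Pocket geometry.** Designed positions are grouped into overlapping
   spatial neighborhoods: each position is the center of one
   neighborhood containing every designed position in direct atomic
   contact with it (at least 2 heavy atoms within 6 Å). Because the
   contact criterion is symmetric, proximal neighborhoods overlap and no
   position-pair interaction is missed.
3. **Energy labeling.** Single mutations are scanned for their stability
   change (ΔΔG) on the reference background and filtered at a threshold
   chosen so the total neighborhood sequence space stays under a
   modeling budget (default 10^6^). Each neighborhood's combinatorial
   space is then enumerated (fully below 10^4^ designs, otherwise a 10%
   uniform sample) and scored; designs better than the reference are
   *successes*, the worst half are *failures*, the rest are discarded as
   undetermined.
4. **Network ranking and selection.** A multilayer perceptron with a
   single hidden layer as wide as the number of designed positions is
   trained on the one-hot-encoded, pooled neighborhood designs
   (80/20 split, up to 2000 iterations). Each tolerated point mutation
   is then scored on the reference background, mutations are ranked by
   score, and the library is grown by adding mutations in rank order
   until the combinatorial space reaches the experimental target size.

The resulting *enriched* space is validated in silico against the
*filtered* space (everything passing the per-mutation filters) by
sampling both and comparing energy distributions.

## The energy oracle and the synthetic landscape

Stage 3 needs an energy function. For production use this is an external
atomistic program whose per-mutation ΔΔG values are ingested as TSV. For
development, testing and methodological validation, the package provides
a synthetic landscape with exactly the epistatic structure the method
targets:

$$E(g) \;=\; \sum_p h_p(g_p) \;+\; \sum_{p<q} J_{pq}(g_p, g_q),$$

with Gaussian field terms $h$ (sd = `field_scale`, default 1) on every
non-reference identity, Gaussian couplings $J$ (sd = `coupling_scale`,
default 0.25) restricted to contacting position pairs, and all terms
vanishing on reference identities so the reference genotype scores
exactly 0 (energies are directly ΔΔG values). A configurable number of
*planted incompatible pairs* — specific (position-pair, identity-pair)
combinations on contacting positions — receive a large positive penalty
(default 8 × the field scale). These plants are the controlled analogue
of incompatible active-site interactions: each planted identity is
unremarkable alone but lethal with its partner. The generator records
the plants so tests can verify that the selection machinery removes
them.

What the synthetic landscape deliberately does *not* emulate:
higher-order (three-way and beyond) interactions, backbone-mediated
couplings between non-contacting positions, and the heavy-tailed energy
distributions of real force fields. Passing the synthetic validation
therefore shows that the machinery removes planted pairwise
incompatibilities under additive-plus-pairwise energetics; it does not
by itself guarantee performance on real atomistic scans.

## Why the network demotes incompatible mutations

The ranking step scores each mutation as the network's predicted success
probability for the corresponding single mutant. A planted incompatible
mutation is itself a perfectly good single mutant, so an *unregularized*
network — which can fully model the pairwise interaction — would score
it highly. The demotion works through the marginal statistics of the
training data: combinations containing the mutation fail whenever the
incompatible partner is present, and under strong L2 regularization the
network's one-hot weights are pulled toward those marginal
success rates. For this reason `train_epinnet()` defaults to
`decay = 0.5`, a deliberately strong weight decay; on the package's
synthetic fixtures this leaves held-out accuracy above 0.95 while
keeping single-mutation scores anchored to the marginal failure
statistics the ranking relies on.

Two further numerical choices matter here:

- **Score quantization for ranking.** Predicted probabilities saturate
  near 0 and 1, so meaningless differences in the fourth decimal would
  otherwise decide the order. `rank_mutations()` sorts on scores rounded
  to 3 decimals; ties are broken by lower ΔΔG, then position, then
  alphabetical identity. On a purely additive landscape with distinct
  field terms this makes the selected mutation set coincide with simply
  taking mutations in ascending ΔΔG order — the correct degenerate
  behavior when there is no epistasis to exploit.
- **Label precedence.** A neighborhood where most designs beat the
  reference puts some of them in the worst-50% tail; the success rule
  (energy strictly below reference) is applied after, and therefore
  overrides, the worst-half rule, since beating the reference is the
  primary definition of success.

## The evolutionary landscape model

To visualize a genotype–phenotype map, the package builds an
origin-fixation model of molecular evolution on the library's genotype
space. Genotypes differing by one amino acid are adjacent; time is
scaled so every possible amino-acid mutation arises at rate 1; and a
mutation with scaled selection coefficient $S$ fixes with relative rate

$$\mathrm{rate}(S) = \frac{S}{1 - e^{-S}},$$

which is 1 at $S = 0$ (neutral), approaches $S$ for strongly beneficial
mutations, and satisfies the detailed-balance identity
$\mathrm{rate}(S)/\mathrm{rate}(-S) = e^{S}$. With a binary functional
indicator $f$, $S_{ij} = c\,(f_j - f_i)$, so the chain is reversible
with stationary distribution $\pi_i \propto e^{c f_i}$. The selection
strength $c$ is calibrated in closed form so that the long-run
occupancy of functional genotypes equals a target (default 60%):
$c = \ln\!\big(\tfrac{t}{1-t}\cdot\tfrac{N_\mathrm{nonfunc}}{N_\mathrm{func}}\big)$.

Note on the rate function: the variant of this formula with $e^{+S}$ in
the denominator, which sometimes appears in print, fails both the
neutral limit (it gives −1 at $S \to 0^-$) and detailed balance; the
form above is the standard origin-fixation rate and reproduces both
properties exactly, as the test suite verifies.

Diffusion coordinates are the subdominant right eigenvectors of the
rate matrix with the smallest-magnitude nonzero eigenvalues,
$\pi$-orthonormalized and scaled by $1/\sqrt{-\lambda_k}$. With this
scaling the axes carry units of $\sqrt{\mathrm{time}}$ and squared
Euclidean distances approximate round-trip evolutionary times; on the
two-genotype neutral space the identity is exact (squared distance 2,
eigenvalue −2). The eigenproblem is solved after symmetrization with
$D_\pi^{1/2} Q D_\pi^{-1/2}$, which is exact for this reversible chain;
a dense solver is used below 5000 genotypes and a Lanczos solver above.
Signs follow a fixed convention (largest-magnitude entry positive) so
outputs are deterministic.

## Sequencing counts, features and fits

- **Enrichment** is the ratio of a genotype's read frequency in a sorted
  sample to its frequency in the presorted pool; values above 1 call a
  functional hit, and gate combinations yield the phenotype label.
  Genotypes seen only in the sorted sample get an infinite-enrichment
  sentinel and count as hits (the presorted pool is too large to be
  covered completely); a minimum sorted read support for this rule is
  configurable (default 1).
- **Classifier features** are sequence-derived only: per-position
  identity, total and per-neighborhood mutation counts, per-position
  conservation change (ΔPSSM), accessible-area change (ΔSASA, from
  tabulated per-identity maxima — no remodeling), and an amino-acid
  category-change flag (categories: aliphatic AVLIM, aromatic FWYH,
  polar STNQC, positive KR, negative DE, special GP), each with its
  mean and max. The two-stage classifier (functional vs. not, then
  phenotype class on the positives) uses gradient-boosted trees by
  default and reports accuracy on a class-balanced held-out set
  (majority classes subsampled).
- **Allele-preference logos** come from an L2-penalized additive
  logistic regression on one-hot genotypes (inverse regularization
  C = 0.5 by default, cross-validated when unset); coefficients are
  converted to log2 odds ratios and mean-centered within each position.
  An optional Hamming-radius filter restricts the fit to the
  neighborhood of a genotype cluster.
- **Mutational decline.** The functional fraction versus mutation count
  is fit by constrained nonlinear least squares to
  $F(n) = \exp(-A n - B\,n(n-1)/2)$ with robustness $A \ge 0$ and
  epistasis $B \ge 0$; the fit runs on the linear scale so near-zero
  fractions are handled. The equivalent quadratic form
  $\exp(-\alpha n - \beta n^2)$ has $\alpha = A - B/2$, $\beta = B/2$
  (matching the $n$ and $n^2$ coefficients).

## Solvent accessibility

Relative accessibility uses a sphere-sampling (Shrake–Rupley style)
numerical SASA with van der Waals radii C 1.70, N 1.55, O 1.52,
S/P 1.80 Å, probe 1.4 Å and 500 sample points per atom (an isolated
atom's sampled area matches the closed-form sphere area to well under
1%). Per-residue areas are normalized by tabulated theoretical maxima;
relative accessibility below 0.2 flags a residue as buried
(configurable).

## Degenerate inputs and tie-breaks

- ΔΔG filtering is boundary-inclusive (`ddg <= threshold`), and the
  reference identity always passes every filter.
- The ΔΔG threshold search returns the largest grid value under the
  budget, or the smallest grid value with a warning when nothing fits.
- A neighborhood with no passing mutations contributes a space of 1.
- Alignment columns aligned to reference gaps are dropped; gap
  characters never enter counts; an all-gap column scores 0 with a
  warning. With zero pseudocount mass, unobserved identities are
  clamped to −30 bits so scores stay finite.
- Library selection with an exhausted ranking warns and returns
  everything; a target of 1 returns the reference-only library.
- Energy labeling of a single design worse than the reference labels it
  a failure (it is its own worst half).

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
desk-scale problems chosen to keep every space exhaustively
verifiable: ring pockets of 6 positions with 3–4 identities each
(filtered spaces of ~10^3^, enriched spaces selected at 1/64 of that,
mirroring the enriched-to-filtered ratio of a production run), toy
structures of 8 residues around a central ligand, rate matrices on
256–2048 genotypes, and 10^4^-genotype exhaustive energy comparisons.
The end-to-end fixture plants two incompatible pairs at 8× the field
scale; across a 12-seed robustness panel the selected library broke
every planted pair in 11 cases — the mechanism is statistical, driven by
marginal failure rates, and a planted member that is itself strongly
stabilizing can survive selection when the cutoff is loose.

## Limitations

- The synthetic landscape is pairwise; nothing is claimed about
  higher-order epistasis.
- The network ranking scores mutations on the reference background
  only; context-specific rescue (a mutation useful only in combination)
  is invisible to it by design.
- The landscape visualization requires an enumerable genotype space
  (default cap 2×10^5^); production-scale libraries need label
  subsampling before visualization.
- Real sequencing pipelines (alignment, UMI collapse) are out of scope;
  the count-table interface starts from genotype-level counts.
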