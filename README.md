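# pocketlib

Epistasis-aware design of combinatorial active-site protein libraries,
with downstream genotype–phenotype analysis.

## The problem

Buried ligand-binding pockets are dense with molecular interactions, so
most pocket mutations destabilize the protein — and, worse, mutations
that are tolerated individually often fail in combination. A library
built by simply crossing all per-mutation-filtered substitutions is
therefore dominated by incompatible, non-functional combinations.
`pocketlib` is for protein engineers who want a combinatorial
active-site library that is *preselected* to consist of mutually
compatible, low-energy multipoint mutants, and for analysts working up
the sorted-library sequencing data such a design produces.

## The method

Given a structure with a designated ligand (e.g. a chromophore), a
homolog alignment and an energy oracle, the pipeline:

1. derives a PSSM and keeps mutations with conservation score > −2 bits
   (log-odds, background-smoothed);
2. partitions the pocket into overlapping spatial **neighborhoods** —
   each designed position plus all designed positions with ≥ 2 heavy
   atoms within 6 Å of it;
3. scans single-mutation ΔΔG values, picking the threshold that keeps
   the total neighborhood space under 10⁶ designs, then enumerates each
   neighborhood's space (fully below 10⁴, else a seeded 10% sample) and
   labels designs: energy below the reference ⇒ success (1), worst 50%
   ⇒ failure (0), rest discarded;
4. trains a single-hidden-layer MLP (width = number of designed
   positions, one-hot inputs, 80/20 split, ≤ 2000 iterations), scores
   every tolerated point mutation on the reference background, and adds
   mutations in rank order until the combinatorial space
   `Π_p (1 + m_p)` reaches the target size.

Mutations that frequently occur in failed combinations — the signature
of an incompatible pair — rank low and are excluded, so the selected
space is enriched in mutually compatible mutations. A synthetic
additive-plus-pairwise energy landscape with *planted* incompatible
pairs ships with the package and is used to validate exactly this
behavior end to end.

The package also implements the downstream analyses: sorted/presorted
enrichment ratios and hit calling, sequence-derived classifier features
and a two-stage (functional → phenotype class) gradient-boosted
classifier, mean-centered log₂-odds allele-preference logos, the
mutational-decline fit `F(n) = exp(−A·n − B·n(n−1)/2)` (robustness A,
epistasis B), and an origin-fixation evolutionary model
(`rate(S) = S/(1−e^{−S})`, stationary π ∝ e^{c·f}, c calibrated to 60%
functional occupancy) whose scaled subdominant eigenvectors give
diffusion coordinates in units of √time.

## Worked example

A fully synthetic demo: a ring-shaped 8-residue pocket around a central
chromophore, a generated homolog MSA, and a seeded energy landscape with
two planted incompatible mutation pairs.

```r
library(pocketlib)

fx <- make_fixture("design-demo", seed = 7, out_dir = tempfile())
cfg <- default_config(msa = fx$msa, reference_id = "ref", pdb = fx$pdb,
                      ligand = "CRO", designed = 1:8,
                      n_incompatible_pairs = 2, incompatible_penalty = 8,
                      target_size = 300, n_validation = 2000, seed = 42)
res <- run_design(cfg)
print(res$library)
print(res$validation)
head(res$ranking[, c("position", "from_aa", "to_aa", "score", "ddg")], 3)
```

```
Library: 8 positions, 10 mutations, space size 432
In-silico space validation (n = 2000 per space)
  enriched: mean -3.586, 99.8% below reference
  filtered: mean 1.858, 38.8% below reference
  position from_aa to_aa     score        ddg
1        6       S     I 0.9879320 -2.4404669
2        8       F     N 0.9864612 -1.7631631
3        7       I     K 0.9797768 -1.7813084
```

The selected 432-design library is almost entirely (99.8%) more stable
than the reference, while the space passing only the per-mutation
filters is mostly destabilized (mean ΔΔG +1.9, only 38.8% below the
reference) — the enrichment the method exists to produce. The ranking
table shows each mutation's network score (predicted probability of
appearing in low-energy combinations) and its single-mutation ΔΔG.

For the evolutionary-landscape side:

```r
fx2 <- make_fixture("two-island", seed = 7, out_dir = tempfile())
isl <- read.delim(fx2$islands)
allowed <- setNames(rep(list(c("A", "V")), 5), 1:5)
res <- run_landscape(allowed, function(G)
  isl$island[match(apply(G, 1, paste, collapse = ""), isl$genotype)] > 0)
sum(res$pi[res$functional])   # 0.6 — the calibrated occupancy
```

A thin CLI over the same functions is installed at
`system.file("scripts", "pocketlib-cli", package = "pocketlib")` with
`design`, `landscape`, `enrich` and `fixture` subcommands.

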