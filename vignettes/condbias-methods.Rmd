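---
title: "Methods: bounding phenotype transition probabilities with conditional Lempel–Ziv complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bounding phenotype transition probabilities with conditional Lempel-Ziv complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condbias)
```

## The model

A genotype–phenotype (GP) map assigns discrete genotypes (fixed-length
symbol sequences) deterministically to discrete phenotypes that have a
canonical string encoding — a binary expression pattern, a lattice-protein
fold written as a chain of directions, a polyomino occupancy grid read
row-major. For such maps, arguments from algorithmic information theory
predict an upper bound on the probability that a random single-point
mutation of a random genotype underlying phenotype $x$ produces phenotype
$y$:

$$P(x \to y) \le 2^{-a\,\tilde K(y|x) - b},$$

with default constants $a = 1$ (dimensionless) and $b = 0$ bits. The
conditional complexity $\tilde K(y|x)$ — the extra description length
needed to generate $y$ when $x$ is available — is estimated from string
complexities as $\tilde K(y|x) = \tilde K(xy) - \tilde K(x)$: cheap when
$y$ is simple, or similar to $x$ (including the copy $y = x$, which is why
the bound predicts high mutational robustness as a null model), and
expensive when $y$ is both complex and unrelated to $x$.

The point of the bound is that it uses *only the two phenotype patterns*.
It cannot be sharper than knowledge of the actual map, and many phenotypes
sit far below it (low-complexity, low-probability outcomes the map finds
"hard" to make); its value is that it is computable a priori when the map's
internals are unknown.

### Complexity estimation

True Kolmogorov complexity is uncomputable; we use the Lempel–Ziv-1976
estimator standard in this literature. For a string of length $n$,

* a uniform repetition of one symbol (or $n = 1$) scores $\log_2 n$, the
  designated minimal-complexity base case;
* otherwise $C_{LZ} = \log_2(n)\,[W(s) + W(\mathrm{rev}(s))]/2$, where $W$
  is the number of words in the LZ76 exhaustive-history parsing (computed
  with the Kaspar–Schuster algorithm; the final word counts even when
  incomplete). Averaging the forward and reversed parsings smooths the
  parser's small parity artefacts on short strings; the test suite pins
  this convention against a brute-force parser on every binary string up
  to length 12.

Raw $C_{LZ}$ values over-estimate absolute complexity, especially for short
strings, so they are rescaled affinely (`scale_complexity()`) to the range
$0 \ldots \log_2 N$ expected for $N$ distinct patterns:
$\tilde K = \log_2(N)(C - C_{\min})/(C_{\max} - C_{\min})$. In the
conditional setting $N$, $C_{\min}$ and $C_{\max}$ are taken over the
*accessible set* of the focal phenotype — the $N_y(x)$ phenotypes reachable
by single-point mutation with nonzero estimated probability. Values outside
$[C_{\min}, C_{\max}]$ extrapolate linearly rather than clip: mutants can
fall outside a min/max computed on a finite set, and clipping would create
artificial ties. Two scaled complexities closer than $10^{-9}$ bits are
treated as equal (pure float noise); conditional complexities are floored
at 0, since concatenation can parse into marginally fewer words and
negative information is meaningless in the bound. When every accessible
phenotype has the same raw complexity the scaling is undefined; such cases
are flagged and excluded from the level statistics rather than invented.

## The three levels of the bound

Each focal phenotype is assessed at three increasingly stringent levels,
on points $(\tilde K(y|x), \log_{10}\hat P(x\to y))$ with one point per
accessible phenotype $y$ (the $y = x$ robustness point included):

* **Level I** — Spearman's $\rho$ over all points is negative with
  two-sided $p < 0.05$ (t approximation). Two-sided is the conservative
  reading of "significant negative correlation".
* **Level II** — ordinary least squares through the *upper-bound points*
  (the maximum $\log_{10}\hat P$ at each unique $\tilde K$ value, or per
  occupied equal-width bin in the 10-bin variant) explains more than half
  the variance: $R^2 > 0.5$.
* **Level III** — the fitted upper-bound slope is statistically compatible
  with the bound-model slope $-a\log_{10}2 \approx -0.301$ per bit:
  the fixed upper points are resampled with replacement 1000 times (never
  re-extracted), each resample's slope minus the bound slope forms a
  difference distribution, and the level passes when the percentile 95% CI
  of the differences contains 0. Degenerate resamples in which all
  complexities coincide are redrawn. Level III is attempted only when
  Level II holds and the fit's slope is significant ($p < 0.05$).

Aggregates across focal phenotypes mirror the field's summary-table layout:
mean and sd of $\rho$; Level I pass proportion; mean and sd of $R^2$
*among Level II passers*; Level II proportion among Level I passers;
Level III proportion among Level II passers. We condition the $R^2$ mean on
Level II because the quantity describes the upper bound accepted as linear
— this is also why such reported means always exceed the 0.5 threshold —
whereas an unconditioned mean mixes in cases whose upper bound is not
linear at all. *Genotype* weighting multiplies each case by its neutral-set
size (the expectation for a randomly drawn genotype); *phenotype* weighting
counts each case once.

## Transition estimation protocol

For a map, the pipeline (i) samples 100,000 genotypes uniformly at random
(default; smaller values are fine for exploration), (ii) tabulates
phenotypes and keeps the distinct neutral genotypes found for each,
(iii) selects focal test cases stratified by raw complexity quartiles,
drawn round-robin across strata so that the cases span the complexity range
instead of only the high-probability (typically simple) phenotypes,
(iv) enumerates *all* single-point mutants of every neutral genotype — a
15-position, 8-letter genotype has exactly $15 \times 7 = 105$ —
(v) estimates $P(x\to y)$ as count/total over the mutant set, and
(vi) assesses the levels per case. Mutations are uniform over positions and
alternative symbols; multi-point regimes and mutational/compositional
biases are out of scope. Discarded outcomes (degenerate folds,
non-deterministic assemblies) stay in the probability denominator as a
reserved row — so probabilities still sum to 1 — but carry no encoded
pattern and hence no point in the assessment.

Each scatter point is one accessible phenotype, not one mutant event. We
checked the alternative (replicating each $y$ by its mutant count) and it
radically changes the rank statistics; one-point-per-$y$ is the convention
that matches the published per-map summaries, and is the package default.

## The map simulators

**Matrix-multiplication map.** $x = H(D g)$ with $g$ a binary genotype of
length $L = 15$, $D$ an $L\times L$ matrix with i.i.d. entries uniform on
$\{-1, 0, 1\}$ (seeded), and $H$ the Heaviside step applied component-wise
(strictly positive → 1). A deliberately "medium-complexity" map: the map
itself carries $O(L^2)$ bits — far more than any genotype, far less than
the $n_g \log_2 n_p$ bits of a random assignment
(`map_complexity_estimate()`).

**Polyomino self-assembly.** A 24-bit genotype encodes 2 tile types × 4
edges × 3-bit colours. Colour 0 is neutral; colour $2k-1$ binds only $2k$
(pairs 1–2, 3–4, 5–6; colour 7 unpaired) — the standard pairing of the
polyomino GP-map lineage, pinned here because the interaction rule is
otherwise underdetermined. Assembly seeds tile 0, then repeatedly picks a
random open bond and attaches a uniformly chosen matching tile/orientation.
A genotype is assigned a phenotype only when 20 independent random assembly
orders all terminate within a 16×16 bounding box with the identical
canonical shape (translation + 90° rotations; reflections are *not*
identified, matching the convention that a shape and its mirror are
distinct assemblies — an `identify_reflections` switch exposes the other
convention, which merges a few mirror-pair shapes and rescues no
non-deterministic genotypes in our samples). Anything else is UND
(unbounded or non-deterministic) and discarded. Twenty repeats trade
soundness against cost: a genotype whose assembly disagrees with
probability $q$ per repeat escapes detection with probability
$(1-q)^{19}$. Shapes are encoded for complexity by site occupation
(row-major 0/1 bounding-box grid; the hollow 4×4 square reads
`1111100110011111`) or, alternatively, by the clockwise perimeter walk
(one U/D/R/L symbol per exposed unit edge, hole loops appended in scan
order). Exhaustively enumerating all $2^{24}$ genotypes with
`poly_enumerate()` is a few minutes of compiled code; under exactly these
conventions our census finds 16 distinct deterministic shapes (with just
over half of genotype space UND). Published counts for two-tile
eight-colour systems derive from external datasets whose assembly
conventions (seed choice, determinism protocol, reflection treatment) are
not fully printed, and the census — and downstream transition statistics —
are sensitive to them; this is the main caveat when comparing our polyomino
numbers against published ones.

**HP lattice proteins.** Binary sequences (H/P) of length $L$ fold onto the
square lattice: every self-avoiding walk is a candidate structure, the
energy is $-1$ per lattice-adjacent, chain-non-adjacent H–H pair, and a
sequence folds to the unique minimum-energy walk — two or more
symmetry-distinct minima mean no stable structure, and the sequence is
discarded. Walks are enumerated once per length (`enumerate_saws()`), one
representative per symmetry class (8 lattice symmetries; the chain keeps
its N-to-C direction; canonical form = lexicographically smallest UDRL
image), with contact lists precomputed. Enumeration cost grows like
$2.64^L$: lengths up to ~16 are desk scale, and the suite exercises
$L \le 10$ plus the complete $2^8$ sequence space at $L = 8$ against a
symmetry-free brute-force oracle. A compact-variant flag restricts
candidates to walks filling an exact rectangle.

**Up–down discretizer.** A real-valued trajectory of $T$ points (e.g. an
activator concentration from a regulatory-oscillator simulation) becomes a
binary pattern: one bit per complete window of $W$ samples, 1 iff the
value increased across the window, 0 for "negative or flat". The output
length is $\lfloor (T-1)/W \rfloor$ — pinned by the reference case
$T = 499{,}999$, $W = 25{,}000 \to 19$ bits, which resolves the
off-by-one ambiguity. The oscillator ODE itself is out of scope; the
discretizer accepts any externally supplied series, and the pipeline's
`updown-series` mode reads plain-text series files (no genotype space, so
no transition stage).

## The synthetic null models

`sample_null_transitions()` draws $n$ i.i.d. mutant outcomes over a random
binary phenotype universe with $P(y) \propto 2^{-\alpha \tilde K(y|x)}$,
$\tilde K$ scaled over the universe. It emulates exactly the statistical
structure the bound assumes — and nothing else: there is no genotype layer,
no neutral-set correlation, no map-induced "hard" low-complexity phenotypes
far below the bound, and the universe's complexity spectrum is that of
uniform random strings. Passing recovery tests therefore validates the
*assessment statistics* (rank screen calibration, upper-bound extraction,
slope recovery), not any claim about real maps. The genotype path is
covered by a hand-enumerable 6-bit toy map (run-length-quantized genotype)
whose full transition structure the tests reproduce exactly by brute force.

Two calibration facts the suite computes are worth knowing. First, with
$\alpha = 0$ the Level I screen passes in about 2.5% of replicates — the
negative half of a two-sided 5% test, as designed. Second, with
$\alpha = 1$ the fitted upper-bound slope recovers $-\log_{10}2$ to within
1%, but the Level III *pass rate* plateaus around two-thirds rather than
near 1: string complexities of a 64-pattern universe tie into a handful of
groups, the per-group maximum of multinomial frequency estimates is
upward-biased by an amount that grows with group size, and because the
null points lie exactly on the bound line the bootstrap CI is razor-thin —
both the bias and the CI width scale as $1/\sqrt{n}$, so the effect does
not vanish with more sampling. On real maps, where upper points scatter
more, the CI is wider and this selection bias is immaterial; on an exact
null it is the dominant term. We keep the procedure faithful rather than
patching it, and record the measured rate.

## Numerical and design choices

* Seeds: every stochastic operation takes an explicit integer seed;
  identical seeds give identical outputs (the assembly engine uses its own
  splitmix64 stream keyed by genotype, so a genotype's phenotype does not
  depend on batch order).
* Quantities reported by the acceptance script are genotype-weighted
  aggregate means averaged over 8 (matrix) / 4 (polyomino) independent
  protocol replicates: a single run's genotype weighting is dominated by a
  few large neutral sets (seed-to-seed sd ≈ 0.07), and replicate averaging
  estimates the same quantity with less noise.
* Problem sizes used by the test suite: full protocol scale (100,000
  samples) for the per-map summary checks; 20,000–64,000 draws for
  calibration; complete enumerations for the toy map (64 genotypes),
  polyomino space ($2^{24}$), and HP $L = 8$ (256 sequences).
* Serialization is plain TSV/JSON with a manifest; identical manifests
  reproduce aggregate tables byte-for-byte.

## Limitations

The complexity estimator is pattern-based: pseudo-random but simple
patterns defeat it, and short strings carry coarse, heavily tied values.
The bound is one-sided — it says nothing about how far below it a
phenotype falls. Slope (Level III) prediction inherits every estimation
error in $N_y(x)$ and the min/max anchors. The polyomino census and
statistics depend on assembly conventions as discussed above. The HP model
at its published scale ($L = 25$, ~$10^9$ raw walks) is supported in code
but not exercised by the suite; the tooth-development and
oscillator-equation systems of the wider literature are intentionally not
simulated here.
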