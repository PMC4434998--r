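---
title: "Information-based detection of genomic rearrangements: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-based detection of genomic rearrangements: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmap)
```

## The problem

Large structural differences between two genomes — translocated, duplicated
and inverted blocks — are usually found by alignment. fcmap takes a
different, alignment-free route: it asks, position by position, *how many
bits* it would take to encode the target sequence using only statistical
knowledge of the reference. Stretches of the target that compress well
under a model of the reference share information with it (they are
homologous at the block scale); stretches that stay near the entropy
ceiling of random DNA share none. Because the measure is purely statistical
it works at chromosome scale, on unassembled or block-permuted references,
and is indifferent to where in the reference the shared material sits —
which is exactly what makes rearrangements visible.

## The model

The statistical engine is an order-$k$ finite-context model (FCM): a Markov
model in which the probability of the next nucleotide depends on the $k$
preceding ones. Training on a reference $y$ consists of exact counting: for
every position with a full context, the pair (context $c$, next symbol $s$)
increments a counter $N(s|c)$. The next-symbol probability is then
estimated with additive smoothing,

$$
P(s \mid c) = \frac{N(s|c) + \alpha}{N(c) + 4\alpha},
\qquad N(c) = \sum_{s'} N(s'|c),
$$

and the *code length* of a symbol is $-\log_2 P(s \mid c)$ bits. With the
default $\alpha = 0.001$ the estimator is nearly maximum-likelihood: a
symbol seen once after a once-seen context costs about $0.004$ bits, a
symbol following an unseen context costs exactly 2 bits (the uniform
fallback), and a *contradicted* context — seen in the reference but never
followed by this symbol — costs about $-\log_2 \frac{0.001}{1.004} \approx 10$
bits. This sharp contrast between "explained" and "unexplained" positions
is what makes the later thresholding easy, and it is why $\alpha$ is kept
small rather than at the Laplace value of 1.

Counts are stored densely for $k \le 12$ and in a hashed sparse table for
larger orders (a dense order-28 table would need $4^{28}$ contexts); the
two representations are value-identical and tested against each other. The
model is *static*: profiling a target never updates it, so every code
length is conditioned exclusively on the reference.

## From profile to regions

Profiling a target $x$ yields the information sequence $n_i$, one value per
target position ($2$ bits for the first $k$ positions, which lack a full
context — a simple convention that keeps the profile the same length as the
target and is negligible for sequences much longer than $k$).

The profile is noisy at single-position resolution, so it is smoothed with
a centred moving average (window truncated at the boundaries; default 1000
positions) and compared against a threshold $T$: maximal runs with smoothed
information strictly below $T$ become candidate regions. Two further knobs
make segmentation robust: `merge_gap` bridges brief above-threshold
excursions before filtering (default 0), and `min_block` discards matched
regions shorter than a floor (default 20 kb — block-scale comparison is the
goal, and tiny matches are disproportionately threshold noise).

$T$ lives in $[0, 2]$ bits, the admissible range implied by the 2-bit
ceiling of a 4-letter alphabet; this interval is a package convention. The
best value is data-dependent: closely related sequences warrant a small
$T$ (their shared regions sit far below 2 bits), distant ones a larger
$T$. The shipped default is 1.5 bits; the validation experiments on
near-identical synthetic pairs use 1.0. Ties at exactly $T$ count as
high-information — an arbitrary but fixed convention.

## Orientation and the two-pass procedure

Inversions are handled by symmetry: a second model is trained on the
reverse complement of the reference, and the target is profiled against
both. A region low under exactly one model gets that orientation. A region
low under *both* (possible when the reference carries both a block and its
inverse) is assigned, disputed run by disputed run, to the orientation with
the smaller mean smoothed information — the better-explained strand; only
the both-high case is fixed by first principles (the region shares no
information and stays unmarked), so this tie-break is our documented
choice, isolated in `resolve_overlaps()`. Unmarked regions are typically
unique sequence or originally unsequenced (N) stretches.

The first pass only says *which parts of the target* are shared, not where
they come from. The second pass inverts the roles: each surviving target
region becomes the training sequence (reverse-complemented first if
inverted) and the whole reference is profiled against it; the
below-threshold runs of the reference are the associated source regions. A
region may localise to several reference regions (duplications) — all are
reported and drawn in the pair's hue. Both passes deliberately reuse the
same $k$, $T$ and window: nothing suggests the role-inverted pass needs
different resolution, and one parameter set keeps runs reproducible from a
single record. Because thresholding is not perfectly symmetric, a
localisation can come back empty; such pairs are dropped with a warning
rather than reported without a source.

Run end to end the procedure is approximately commutative: swapping
reference and target recovers essentially the same pairs with sides
exchanged (the validation suite requires ≥ 90% reciprocal overlap and
observes ≈ 99.9% on the planted fixture).

## Preprocessing

Both sequences are reduced to the `{A,C,G,T}` alphabet before anything
else: every non-ACGT symbol — N runs, IUPAC ambiguity codes, lowercase
artefacts — is replaced by a uniform random nucleotide. Length is
preserved, and the filled stretches become incompressible random DNA that
cannot share information with anything, so they can never create spurious
pairs; their locations are kept as `masked_intervals`. The fill is seeded
(default 1) and the seed recorded in every map. The reported pairs do not
depend on the seed in structure (count, orientation, sources); region
boundaries adjacent to a masked block can move by a few base pairs between
seeds because the smoothed profile at the junction depends on the
particular random fill — boundary agreement should be judged at the
smoothing-window resolution, which is the method's native resolution
anyway.

## The synthetic-data generator

`random_dna()` and `apply_edit_script()` produce the validation fixtures: a
uniform i.i.d. random reference and a target assembled from an explicit
block script — direct or reverse-complemented copies with i.i.d. point
substitutions, novel random blocks, and all-N runs — together with the
planted truth table. The substitution convention is explicit: a position
selected at rate $r$ receives a uniform draw from the three *other*
nucleotides, so $r$ is the expected mismatch fraction. A single global
seed expands into independent per-operation streams, so extending a script
never perturbs earlier blocks.

The study fixture mirrors the canonical demonstration of the method: a
1 Mb reference and a target of a 300 kb direct copy, a 300 kb inverted
copy, a 200 kb novel block and a 200 kb direct copy, copies carrying 1%
substitutions. At $k = 14$ the per-position expectations are easy to state:
a clean position in a copied block costs ≈ 0.004 bits, a position whose
context spans a substitution (probability $1 - 0.99^{14} \approx 13\%$)
costs ≈ 2 bits, and a substituted symbol after a clean context costs
≈ 10 bits — a block mean of ≈ 0.35 bits, far below $T = 1$, while novel
blocks sit at ≈ 2 bits. Uniform i.i.d. DNA is of course an idealisation:
real genomes carry repeat families, skewed composition and indels, none of
which the generator emulates. Passing the planted-truth experiments
therefore demonstrates the mechanics of the method (segmentation,
orientation, localisation, robustness to permutation and masking), not its
behaviour on repeat-rich real chromosomes, where $T$ and `min_block` need
the data-dependent tuning described above.

## Parameters at a glance

| parameter | default | units | provenance |
|---|---|---|---|
| `k` | 14 | symbols | suited to ≳ 1 Mb sequences; admissible range [1, 28] |
| `alpha` | 0.001 | — | near-ML estimator; keeps segmentation contrast sharp |
| `threshold` | 1.5 (1.0 in the validation runs) | bits | data-dependent; smaller for similar sequences |
| `window` | 1000 | positions | smoothing resolution; breakpoint error is O(window) |
| `min_block` | 20000 | positions | discard matched regions smaller than 20 kb |
| `merge_gap` | 0 | positions | bridge brief excursions; used at reduced window sizes |
| `seed` | 1 | — | non-ACGT fill reproducibility |

## Numerical and degenerate-input choices

Smoothing truncates the window at the boundaries (constant profiles are
fixed points, output length equals input length); for even windows the
window extends one position further right. Coordinates are 0-based
half-open everywhere internally and in BED output. A reference shorter
than $k + 1$ trains an empty model, under which every position costs
2 bits. Segmentation of an empty profile returns no regions; a map between
unrelated sequences is a valid empty map and renders as two uncoloured
bars. Hues are assigned in target order as $i \cdot 360 / n$ degrees with
saturation 0.65 and value 0.95 fixed; inverted pairs carry a diagonal
hatch so orientation survives greyscale. SVG output is plain text with
fixed number formatting, so identical maps produce byte-identical files.

## Validation problem sizes

The shipped validation experiments run at the scales the method is meant
for while staying desk-sized: megabase fixtures for the pipeline
experiments (identity, planted rearrangements, commutativity, 50 kb block
permutation, 50 kb masked insert), a 100 kb pair for the entropy ceiling,
an exhaustive sweep of all DNA strings up to length 7 (plus sampled longer
strings) for count correctness, and 1000 random profiles for the
segmentation monotonicity and smoothing fixed-point properties. The unit
suite additionally exercises a 200 kb analogue of the planted fixture with
window 200 and `merge_gap` 400 — at that window, substitution clusters in
a 1%-mutated copy produce brief excursions above $T$ that would otherwise
fragment runs below `min_block`.

## Known limitations

Breakpoints are only resolved to the smoothing window, by construction;
refining them further is out of scope. Repeat families shared between the
two sequences are genuinely shared information and will be marked —
interpretation on repeat-rich genomes needs the threshold raised or the
repeats considered in the reading. One chromosome pair is compared per
run; whole-genome surveys are run pair-by-pair or on concatenated
sequences, at reduced visual granularity. Gzip streaming, FASTQ and
quality values are not supported.
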