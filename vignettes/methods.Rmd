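---
title: "Methods: shape spectra, morphospace sizing, and phenotype-bias tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape spectra, morphospace sizing, and phenotype-bias tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamorpho)
```

## The genotype–phenotype map and its coarse-graining

`rnamorpho` treats RNA folding as a genotype–phenotype (GP) map: sequences
of length $L$ over $\{A,C,G,U\}$ are genotypes, nested secondary structures
are phenotypes. Because tiny changes to a bonding pattern produce formally
distinct structures, frequencies of *individual* structures are too diluted
to estimate from realistic sample sizes. The package therefore works with
*abstract shapes*: five nested coarse-grainings of the dot-bracket string.

Every structure is first decomposed into the standard loop vocabulary
(`parse_dot_bracket()`): helices — maximal runs of directly stacked pairs —
plus hairpin loops, bulges (unpaired residues on exactly one strand between
consecutive helices), internal loops (both strands), multiloops (a helix
enclosing two or more helices), and the external loop. The five levels are
then:

| level | helices | unpaired runs |
|---|---|---|
| 1 | one `[ ]` per maximal helix | all, as `_` |
| 2 | one `[ ]` per maximal helix | external loop and multiloops only |
| 3 | one `[ ]` per maximal helix | none |
| 4 | helices merged across bulges/internal loops | external loop and multiloops only |
| 5 | helices merged across bulges/internal loops | none |

```{r}
db <- "((..((...))))"
vapply(1:5, function(k) abstract_shape(db, k), "")
```

Two independent implementations exist on purpose. `abstract_shape()` walks
the loop tree directly. `project_shape()` instead rewrites the level-1
string: drop `_` outside external/multiloop contexts (levels 2, 4) or
everywhere (3, 5), then merge to a fixed point every bracket enclosing
exactly one bracket and nothing else (4, 5). Since the level-1 string
determines all coarser levels, the two routes must agree on every
structure; the test suite asserts this factorization on more than a
thousand random structures, and the fast vectorized path (`rna_shapes()`,
compiled level-1 scan plus memoized projection) is checked against both.

**Conventions.** The open chain is `"_"` at *all* levels — a single uniform
rule, adopted because an unfolded phenotype has no published canonical
form at the underscore-free levels. Shape strings are canonicalized by
stripping whitespace, so the typeset form `[ [] [] [] ]` parses to
`[[][][]]`. A multiloop requires at least two enclosed helices; a loop
with exactly one enclosed helix is a bulge or internal loop and therefore
merges at levels 4–5. Lonely (single-pair) helices are legal everywhere.
Pseudoknot alphabets are rejected: the folding backends used here emit
nested structures only.

## Folding backends

Shape frequencies are properties of a *(sequence, folder)* pair, so the
folder is a pluggable function with a recorded backend identity.

* `maxpair_folder()` (default): the classic $O(L^3)$ base-pair-maximization
  recursion over Watson–Crick plus GU wobble pairs, with minimum hairpin
  length 3. Tie-breaking is fixed — the traceback prefers leaving a
  position unpaired over pairing and, among pairings, the smallest partner
  index — so every spectrum built with it is bit-reproducible. It is a
  combinatorial folder, not a thermodynamic one: it exists so the whole
  pipeline is fast, deterministic, and dependency-free, and its spectra are
  *not* expected to match free-energy spectra.
* `vienna_folder()` / `fold_external()`: minimum-free-energy structures
  from the external ViennaRNA `RNAfold` program at its default parameters
  (37 °C). `suboptimal_structures()` exposes `RNAsubopt` for structures
  within `delta_e` kcal/mol of the MFE, the set accessible by thermal
  fluctuation. A missing executable raises an explicit
  `backend_missing` condition — there is no silent fallback, precisely
  because frequencies are backend-dependent.

Every emitted structure is validated: equal length, allowed pairs only
(`AU, UA, CG, GC, GU, UG`), balanced nesting, hairpin loops of at least 3.

## G-sampling and spectrum estimation

`sample_sequences()` draws i.i.d. positions from a base distribution —
uniform by default, or the GC-parameterized family
$(\tfrac{1-g}{2}, \tfrac{g}{2}, \tfrac{g}{2}, \tfrac{1-g}{2})$ for
composition studies. Sampling is with replacement (collisions are
negligible at these scales except in the synthetic generators, which
deduplicate). The RNG is the Mersenne–Twister with rejection sampling, run
in a locally-scoped stream: an explicit integer seed makes any spectrum
reproducible across platforms without touching the caller's RNG state.

`build_spectrum()` tabulates shape counts; per shape it reports
$f = k/n$, a 95% Wilson score interval, and the neutral-set-size estimate
$f \cdot 4^L$. Wilson intervals were chosen (over Wald or exact) because
they behave sensibly at the tiny counts that dominate the low-frequency
tail and are needed by the comparison module's tolerance logic; the
underlying studies report no intervals at all. Zero-count shapes are
absent, never pseudocounted — downstream code must handle absence
explicitly. Ranking (`rank_spectrum()`) sorts by descending count with
ties broken by byte order of the shape string, a documented rule so ranks
are reproducible. The default abstraction level follows strand length —
level 3 up to $L = 55$, level 5 above (`default_shape_level()`) — trading
structural detail against obtaining repeated shapes; both are overridable.

## Morphospace sizing

Three routes, reported side by side and deliberately *not* reconciled:

1. `sequence_space_size(L)` $= 4^L$; the `_exact` variant computes the full
   decimal expansion with a small digit-vector multiply, so even $4^{126}$
   (a 76-digit integer) is available exactly.
2. `asymptotic_shape_count(L, level)`: the closed-form asymptotics
   $s_3(L) = 1.85 \cdot 1.46^L \cdot L^{-3/2}$ and
   $s_5(L) = 2.44 \cdot 1.32^L \cdot L^{-3/2}$ for minimum hairpin 3 and
   minimum ladder 1, the variant consistent with folders that allow lonely
   pairs. These are taken as given constants, not re-derived; they are
   asymptotic, so at small $L$ they disagree with exact counts and the
   package simply reports both. "Nearest power of ten"
   (`nearest_power_of_ten()`) is $\lfloor \log_{10} x + 0.5 \rfloor$, ties
   up — stated because order-of-magnitude summaries are the usual
   reporting form.
3. Exact small-$L$ counting: `count_structures()` implements
   $S(n) = S(n-1) + \sum_{i \le n-h-1} S(i-1)\,S(n-i-1)$ (hairpin $\ge h$),
   and `enumerate_structures()` generates every structure explicitly
   (default cap $L \le 18$, configurable; the count grows exponentially).
   Each is the other's oracle in the tests, and enumeration also feeds
   `count_shapes_exact()` and the brute-force folding oracle.

## Comparing a database against the G-sampling null

`load_natural()` ingests a FASTA export: uppercase, T→U, drop records with
other characters, keep one length, remove exact duplicates (databases are
analyzed duplicate-free; each distinct sequence contributes one count, so a
shape reached by many distinct sequences counts that many times). Lengths
are analyzed separately, never pooled.

`compare_spectra()` reports (i) **coverage**, the fraction of natural
shapes present in the G-sample — monotone in G-sample size; and (ii) the
**Pearson correlation** of $\log_{10} f_p$ against $\log_{10} f_{pG}$ over
shapes observed in both spectra. No pseudocounts are added for shapes
missing from one side; instead the number excluded is reported, and a
`min_natural_count` filter (used at 5 in the calibration runs) restricts
the correlation to shapes whose natural frequency is estimable at all.
With fewer than three usable shapes the correlation is declared undefined
rather than reported.

`overrepresentation_test()` asks, per shared shape, whether its natural
count $k$ out of $N$ is consistent with $\mathrm{Binomial}(N, f_{pG})$,
two-sided and exact, with Benjamini–Hochberg adjustment across shapes and a
default flagging threshold of adjusted $p < 0.05$. BH was chosen as a
standard, calibrated multiplicity rule; the direction field separates
over- from under-deposition. Note the null uses the *estimated* $f_{pG}$;
the G-sample should therefore be several times larger than the database
(the calibration runs use 50:1) so estimation error is negligible.

## What the synthetic databases emulate

Real database downloads and thermodynamic folding are deliberately outside
the test loop, so the generators construct databases with *known* truth:

* **null** — distinct uniform random sequences: shape usage tracks
  G-sampling by construction. Passing the pipeline over it is a
  parameter-recovery experiment: coverage near 1 and high log–log
  correlation must come out, and do in the acceptance run.
* **gc_biased** — the same with shifted base composition, for robustness
  checks against a composition-matched G-sample.
* **selected** — accept–reject with acceptance probability proportional to
  a per-shape fitness weight: a counterfactual database shaped by
  phenotype-level selection. Equal weights recover the null; penalizing
  the top shapes visibly degrades the correlation. A floor on the running
  acceptance rate turns pathological weight maps into an explicit error.
* **deposition_bias** — one shape's members are augmented with
  shape-preserving single-point mutants until its count is multiplied by a
  chosen factor, leaving every other count untouched: researcher
  over-deposition of a pet structure, the distortion
  `overrepresentation_test()` exists to flag.

What these generators do **not** emulate: family/homology redundancy beyond
exact duplicates, taxonomic composition, length mixtures, or thermodynamic
realism (they default to the max-pair folder). A green synthetic suite
therefore demonstrates pipeline correctness and calibration — not that any
particular natural database is unbiased.

## Problem sizes and numerical choices

The bundled checks run at sizes chosen to finish in minutes on one CPU
while leaving the statistics meaningful: G-samples of 50,000 sequences at
$L = 30$, level 5; synthetic databases of 1,000–5,000 sequences; exhaustive
oracles at $L \le 14$ (structure counting), $L \le 12$ (folding, 200 random
sequences), and the complete $4^8 = 65{,}536$ sequence space at $L = 8$.
False-positive calibration uses 20 independent null replicates against one
shared G-sample. At these scales the max-pair spectrum at $L = 30$ spans
four orders of magnitude in frequency over only ~20 level-5 shapes; a
thermodynamic folder at the lengths used for real databases yields far
richer spectra, which is why correlation checks here run over the ~9
shapes with at least 5 natural counts rather than the dozens available at
full scale.

Reproducing the full-scale published analysis is possible with this
package but is a compute-and-download exercise, not a test: export
length-filtered sequences from a database such as RNAcentral, fold both the
database and $10^6$–$5\times10^6$ random sequences per length with
`vienna_folder()` (level 3 for $L \in \{40, 55\}$, level 5 for
$L \ge 70$), and run `compare_spectra()` / `overrepresentation_test()` per
length.

## Known limitations

* The comparison excludes shapes absent from one spectrum instead of
  modelling them; at small G-sample sizes this biases the correlation
  toward well-sampled shapes (the excluded count is reported).
* Neutral-set-size estimates inherit the folder's determinism assumption:
  a sequence contributes its single returned structure, with no Boltzmann
  weighting (suboptimal enumeration is exposed but not integrated into
  spectra).
* The binomial overrepresentation test treats database sequences as
  independent draws; homologous families in real databases violate this,
  so flags on real data indicate deviation from the null, not its cause.
* Asymptotic shape counts are unreliable at small $L$; exact counts are
  capped by enumeration cost. The package reports both and leaves the gap
  visible.
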