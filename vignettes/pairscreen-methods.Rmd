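---
title: "Models and methods behind pairscreen"
author: "pairscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscreen)
```

# The measurement problem

A pairwise guide–target screen measures SaCas9 editing on thousands of
synthetic guide–target pairs integrated into the genome by lentivirus. Two
obstacles make naive quantification misleading. First, once Cas9 cuts, the
indel destroys the very sequence that identified the pair, so identity must
be carried by a barcode placed *outside* the edited region. Second,
array-synthesized oligo pools carry substantial synthesis error, so a
sizeable fraction of molecules harbour mismatches or indels that look exactly
like biology. The package implements the two-barcode answer: an
error-correcting Hamming barcode downstream of the cut site identifies the
member; a randomized barcode (rBC) identifies the physical molecule, and only
molecules proven error-free before nuclease delivery (the Day-0 whitelist)
contribute to editing rates.

# Hamming DNA barcodes

Barcodes are codewords of a quaternary single-error-correcting code with an
overall parity symbol (SECDED): ten data bases, four checksum bases at
positions 1, 2, 4, 8, and one parity base at position 15, under the base map
A=0, C=1, G=2, T=3. Each checksum base covers the positions whose binary
representation contains its position, and both the checksum and the parity
digits are chosen so that every coverage sum is ≡ 0 (mod 4) on a valid
codeword. Under this layout, enumerating all $4^{10} = 1{,}048{,}576$ data
words and excluding homopolymers longer than 3 nt and GC outside 30–70%
(inclusive) leaves **812,547** barcodes:

```{r enumerate, eval = FALSE}
length(generateBarcodes(barcodeSpec()))   # 812547, ~7 s
```

Sum-sign conventions differ between implementations of this construction; of
the four combinations (checksums and parity as plain or negated coverage
sums), only the zero-syndrome convention above yields this count, and it is
the shipped default.

Decoding follows the radius-1 nearest-codeword rule, expressed through
syndromes for speed: a single substitution of magnitude $e$ at position $p$
makes exactly the checks covering $p$ (plus the parity) read $e$. The decoder
corrects only when the nonzero syndromes agree and identify a unique
position; inconsistent or ambiguous syndromes fail rather than guess, so an
observation within Hamming distance 1 of a true codeword is never
mis-assigned. The minimum pairwise Hamming distance of the code is ≥ 3;
subsampling by Levenshtein distance ≥ 3 (`subsampleBarcodes()`, seeded
shuffle + greedy accept-if-far) additionally removes equal-length pairs whose
*edit* distance is 2 through shifted alignments.

# Library geometry

The cassette on the sequenced strand is

```
upstream | spacer | scaffold | rBC | mid | pad+target | PAM | linker | barcode | downstream
```

Within a spacer group, all guides share PAM-proximal positions 1–18 and vary
in length 19–24 nt at the PAM-distal 5′ end, with the 5′-most base forced to
G for U6 expression (a 19-mer is G + the 18-nt core). Positions are numbered
PAM-proximally throughout: position 1 abuts the PAM. All variation is written
into the target DNA, never the spacer, so sgRNA folding is identical across a
group. The PAM is constant (5′-CAGGGT-3′), and the blunt cut site is taken
3 bp 5′ of the PAM; with the 7-nt linker this places the Hamming barcode
16 bp downstream of the cut. The target segment is padded PAM-distally with
constant filler to a fixed 26-nt window so cassette and oligo lengths vary
only with spacer length. The shipped constant segments are synthetic
stand-ins chosen for mutual dissimilarity; every segment is configurable in
`cassetteLayout()`.

Variant enumeration follows closed forms per length $L$: $3L$ single
mismatches, $9\binom{L}{2}$ double mismatches, $4\binom{L}{2}$ double
transversions (each position takes one of its two purine↔pyrimidine
substitutions), $4(L{+}1)$ insertion candidates (DNA bulge) and $L$ deletion
candidates (RNA bulge) before collapsing duplicate sequences with recorded
multiplicity, plus scrambled controls constrained to differ from the spacer
at ≥ 50% of positions.

# The synthetic-data generator

`simConfig()` fixes the study conditions; the defaults emulate the pooled
screen regime rather than an idealized instrument:

* synthesis substitutions at 0.025 per base of the variable region
  (spacer + target) plus a 0.15 per-oligo chance of a 1-bp synthesis indel —
  together leaving roughly a quarter of molecules error-free, the regime in
  which whitelisting is essential;
* ~30 lentiviral integrations (rBCs) per member (Poisson), 5 reads per rBC,
  2 × 150 bp reads;
* sequencing substitutions at 0.001 per base;
* timepoints 0/3/14 with editing saturation multipliers 0/1/1.25 (editing
  saturates after the unsaturated Day-3 readout; no re-cutting model).

Ground truth draws guide activities from Beta(2, 2) and additive penalties
$\Delta\Delta G$ iid from Exponential(mean 1) per (position, type) cell and
length, so $f = e^{-\Delta\Delta G} \in (0,1]$. Bulges use two flat factors
(0.05 proximal, 0.9 distal — minimally tolerated at positions 1–18,
near-completely tolerated beyond); scrambled controls never edit. Each
integration carries a latent editing quantile drawn once, so edit status
nests across days. Edited cassettes receive a geometric-size deletion (or,
25% of the time, a 1–2 nt insertion) at the cut site; quantification is
deliberately insensitive to this spectrum choice.

Deliberate simplifications: synthesis errors never hit the constant anchors
or the Hamming barcode (so whitelist exactness is a sharp property —
real screens would lose a further fraction of reads to barcode failures);
no PCR jackpots or duplicates; no chromatin or position effects; no
lentiviral template switching. Passing tests therefore demonstrate the
pipeline's correctness and its error-suppression mechanism, not robustness
to every artefact of real libraries.

# Quantification rules

Parsing exploits the geometry: read 2 starts at the cassette 3′ end, so the
barcode, linker and PAM sit at fixed offsets regardless of indels, and only
the `mid` anchor is located by approximate matching (≤ 1 substitution by
default) to delimit the target region. Reads whose anchors fail are counted
as unmatched, never dropped silently.

The Day-0 whitelist admits a (member, rBC) pair only if **every** supporting
read has intact anchors and spacer/target regions exactly equal to the
design, with ≥ 2 supporting reads ("sufficiently represented" is not pinned
by a published threshold; 2 is the exposed default). An rBC observed under
two different Hamming barcodes is rejected outright — with 8-nt rBCs,
cross-member collisions are expected by the birthday bound at realistic
scale, and an ambiguous tag cannot anchor a lineage.

The indel caller classifies a target region as `intact` (exact match),
`discard` (same length with substitutions — substitutions cannot be nuclease
products; or indels entirely outside the window), or `indel` (a global
affine-gap alignment places an insertion/deletion overlapping the cut site
± 8 bp). Ties resolve toward `discard`. Rates are
$I = n_\mathrm{indel} / (n_\mathrm{reads} - n_\mathrm{discarded})$; members
with < 20 whitelisted rBCs are flagged excluded (the reproducibility
threshold), and off:on ratios are computed only where the matched member of
the same group and length exceeds 2% activity.

# The specificity model

For guide $j$ on a target with mismatch set $M$:

$$I_{j,M} = g_j \exp\Big(\sum_{k \in M} -\Delta\Delta G_k\Big) + \epsilon_{j,M}
         = g_j \prod_{k \in M} f(\mathrm{pos}(k), \mathrm{type}(k)) + \epsilon_{j,M}$$

with $\Delta\Delta G_k \ge 0$ under an Exponential(mean $\beta = 1$) prior,
$\epsilon \sim \mathcal N(0, 0.1)$ (the replicate-estimated noise), and
$g_j \in [0,1]$ under a uniform prior (the model definition itself implies
no prior for $g$; the uniform box is this package's choice). Mismatch type
is the ordered
RNA:DNA pair (12 classes); fits use raw indel rates, not off:on ratios,
since $g_j$ absorbs on-target activity; each spacer length is fitted on its
own disjoint data, yielding a separate $f_L$. Bulged members are outside the
model, and mismatches are assumed independent — the predicted double-mismatch
rate is the product of the two single-mismatch factors times $g$.

Two fitting modes share this posterior. `map` minimizes the exact negative
log posterior with L-BFGS-B and an analytic gradient (box constraints
$\Delta\Delta G \in [0, 30]$, $g \in [0,1]$; initialization from matched-member
rates): deterministic, seconds at screen scale, used throughout the test
suite. `mcmc` samples with JAGS using the default budget of
8 chains × 1500 draws with the first 500 discarded, and reports
per-parameter split R-hat (via coda), declaring convergence only when all
R-hat < 1.1. Chains are seeded per-chain, so sampled fits are reproducible.
Cells with no observations are prior-dominated and flagged via `fit@nObs`;
at the MAP they sit at the prior mode ($\Delta\Delta G = 0$), under sampling
at the prior mean ($\approx \beta$). Guides without a matched observation
are fitted but flagged weakly identified. The Gaussian likelihood is *not*
truncated to [0,1]; observed rates near the boundaries therefore exert
slight shrinkage — a known limitation inherited from the model definition.
Fits behind guides with very low on-target activity are unstable (low
signal-to-noise); this shows up as inflated posterior interval widths and is
asserted as such in the tests.

Scores for candidate off-target sites are $\prod f$ over featurized
mismatches — 1 for a perfect match, monotone non-increasing as mismatches are
added — and ranking breaks ties by fewer mismatches, then lexicographically,
for determinism. Bulged candidates receive no score.

# Numerical and design choices

* **Decoder ambiguity.** Distance-1 ties (impossible for the shipped
  distance-3 code, possible in degraded custom layouts) fail rather than
  guess.
* **GC bounds** are inclusive with a $10^{-9}$ tolerance so that exact
  rational boundaries (e.g. 4.5/15) behave as intended in floating point.
* **Alignment scoring** for indel calling: match +1, mismatch −1, gap open 4,
  gap extend 0.5. Only length-discordant regions are aligned (same-length
  substitutions are discards by rule), and unique (observed, expected) pairs
  are aligned once and memoized.
* **Seeds.** Every stochastic stage (group generation, barcode assignment,
  scrambled controls, truth, integrations, reads, MCMC chains) derives its
  own sub-seed from the user seed; identical configuration gives
  byte-identical designs, FASTQ files and map-mode fits.
* **Problem sizes in the tests** are scaled-down study conditions chosen for
  a laptop-class run: e.g. whitelist exactness at ~200 members × 30
  integrations × 5 reads with 5% synthesis error; rate recovery over 20
  seeded simulations; model recovery at 20 guides with all singles + 200
  doubles per guide at noise sd 0.1 (map), and 5 guides × 2 chains × 300
  draws (mcmc). A full-scale screen (~9 × 10^4 members) is a design input,
  not a test requirement.

# Known limitations

* The mcmc mode uses Gibbs/Metropolis sampling (JAGS); posterior summaries
  match the model, but mixing per iteration differs from gradient-based
  samplers, so short chains may need more iterations to converge.
* The whitelist requires Day-0 membership only; requiring support at later
  days as well is possible upstream but not implemented as a switch.
* Greedy minimum-distance subsampling is quadratic in practice and intended
  for design-time use, not for repeated in-loop calls at the 10^5 scale.
* The simulator's indel spectrum and saturation multipliers are modeling
  conveniences; conclusions should rest on the quantification rules, which
  do not depend on them.
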