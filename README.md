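# pairscreen

Design, simulation, and analysis of **pairwise guide–target library screens**
of *Staphylococcus aureus* Cas9 (SaCas9) genome-editing specificity.

In a pairwise screen, every library member is a synthetic cassette carrying
both an sgRNA and its (matched or deliberately mismatched) target site, so
thousands of guide–target relationships are measured in one pooled experiment.
Two barcodes make the readout robust: a 15-nt **error-correcting Hamming
barcode** placed downstream of the cut site uniquely identifies each member
even after editing destroys the target, and an 8-nt **randomized barcode
(rBC)** tags each lentiviral integration so that molecules carrying
oligo-synthesis errors can be excluded by a Day-0 **whitelist** before any
editing rates are computed.

The package is for computational biologists building or analysing such
screens. It provides:

* **Barcodes** — quaternary SECDED Hamming DNA barcodes (10 data + 4 checksum
  + 1 parity base): encoding, decoding with single-substitution correction,
  homopolymer/GC composition filters, full enumeration, and
  minimum-edit-distance subsampling.
* **Library design** — spacer groups sharing PAM-proximal positions 1–18 with
  lengths 19–24 nt and a forced 5′ G; enumeration of target variants (all
  single mismatches, double mismatches, double transversions, DNA/RNA bulges,
  scrambled controls); barcode assignment and oligo-pool emission.
* **Read simulation** — a generator with known ground truth: synthesis
  errors, rBC-tagged integrations, editing driven by a penalty model, and
  paired-end FASTQ output, so the whole pipeline is testable without
  sequencing data.
* **Quantification** — read parsing against the cassette layout, Day-0
  whitelisting, substitution-robust indel calling in a cut-site window,
  per-member indel rates, off:on-target ratios (gated at >2% on-target
  activity), and tolerance/reproducibility aggregations.
* **Specificity model** — the Bayesian nonlinear regression

  `I_{j,M} = g_j * exp(-sum_{k in M} ddG_k) + eps
           = g_j * prod_{k in M} f(pos_k, type_k) + eps`

  where `g_j` is the on-target activity of guide `j`, each mismatch `k`
  (position × RNA:DNA type) incurs a non-negative additive penalty `ddG_k`
  with an Exponential(mean β = 1) prior, errors are Gaussian (sd 0.1), and
  `f = exp(-ddG)` is the multiplicative penalty in (0, 1]. Fits are per
  spacer length (a separate matrix `f_L` per length), by deterministic MAP
  optimization or by MCMC (8 chains × 1500 draws, 500 warmup, convergence
  via R-hat < 1.1). Fitted matrices score and rank candidate off-target
  sites.

## Worked example

A miniature screen, end to end:

```r
library(pairscreen)

groups  <- generateSpacerGroups(3, seed = 11)
plan    <- rbind(variantPlan(groups, "matched", 19:24),
                 variantPlan(groups[1, ], "single_mismatch", 19:21))
design  <- assembleLibrary(groups, plan, sampleBarcodes(500, seed = 5), seed = 7)
design
#> GuideTargetDesign: 198 members, 3 spacer groups
#>   categories: matched=18 single_mismatch=180

cfg   <- simConfig(seed = 42, synthesisErrorRate = 0.05, sequencingErrorRate = 0)
truth <- simulateTruth(design, cfg)
sim   <- simulateIntegrations(design, cfg)
sim
#> ScreenSim: 5884 integrations over 198 members; seed 42
#>   error-free cassettes: 606

day0 <- simulateReads(sim, truth, 0)
obs0 <- parseReadPairs(day0$read1, day0$read2, design)
wl   <- buildWhitelist(obs0, design)
nrow(wl)
#> [1] 551

day3  <- simulateReads(sim, truth, 3)
rates <- computeIndelRates(parseReadPairs(day3$read1, day3$read2, design),
                           design, wl, minRbc = 0)
head(rates[, c("memberId", "nRbc", "nReads", "nIndel", "indelRate")], 3)
#>   memberId nRbc nReads nIndel indelRate
#> 1        1    5     25     20       0.8
#> 2        2    1      5      5       1.0
#> 3        3    3     15     15       1.0
```

Each record counts only whitelisted (member, rBC) cassettes: `nRbc` is the
number of independent error-free integrations observed, and `indelRate` is
the fraction of their non-discarded reads carrying a cut-site indel — the
editing efficiency of that guide–target pair. `offOnRatios()` then divides
each mismatched member's rate by its matched member's rate, and
`aggregateTolerance()` summarizes tolerance by mismatch position, RNA:DNA
type, or spacer length.

Fitting and using the specificity model on screen output:

```r
obs <- indelObservations(rates, design, length = 21)
fit <- fitPenaltyModel(obs, 21, modelConfig(mode = "map"))
rankOffTargets(spacer, candidateSites, fit)   # highest-risk sites first
```

## Command line

A thin CLI over the same functions ships in `inst/scripts/pairscreen.R`
(subcommands `barcodes`, `subsample`, `design`, `simulate`, `whitelist`,
`rates`, `fit`, `score`); see the header of that file for usage.
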