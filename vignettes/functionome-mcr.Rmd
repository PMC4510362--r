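---
title: "Module completion ratios and functionome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module completion ratios and functionome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrkit)
```

## The model

A KEGG module is a small functional unit — a pathway segment, a molecular
complex, a functional set or a signature — defined as a Boolean expression
over KEGG Orthology (KO) identifiers. A genome annotated with KOs either can
or cannot "fill" each component of the module. The **module completion
ratio (MCR)** summarizes this as the percentage of the module's reaction
steps that the genome's KO set satisfies:

$$\mathrm{MCR} = 100 \times \frac{\text{satisfied steps}}{\text{countable steps}}$$

A *step* is one top-level component of the definition. Within a step,
subunits joined by `+` form a complex and must all be present; branches
joined by `,` are interchangeable alternatives, any one of which suffices; a
component prefixed by `-` is non-essential and never falsifies a step. A
step is *countable* when it contains at least one non-essential-free leaf;
steps made only of optional components contribute to neither numerator nor
denominator. When every step is satisfied the MCR is exactly 100%.

Two deliberate consequences of this step-granular, all-or-nothing reading:

* a complex missing one mandatory subunit contributes nothing (no partial
  credit), which is what makes the worked examples come out at 6/7 = 85.7%
  and 7/10 = 70% rather than at some fractional-subunit value;
* the MCR is invariant to gene copy number — only presence matters. Copy
  counts feed the separate **module abundance**: the maximum number of
  mutually disjoint complete KO assignments the genome supports (e.g. the
  number of paralogous complete ABC-transporter operons). Abundance is at
  least 1 exactly when the MCR is 100.

## The definition dialect

Definitions use the KEGG DEFINITION dialect. Precedence, loosest to
tightest: space (consecutive steps), comma (alternatives), `+`/`-`
(complex subunits, `-` marking an optional one); parentheses group
arbitrarily. One wrinkle deserves spelling out: *inside parentheses a space
joins sub-components of the same step* rather than opening a new step, so
`(K00001 K00002) K00003` is a two-step module whose first step needs both
KOs. For that reason the normal form collapses single-child wrappers and
flattens nested alternatives-in-alternatives and complexes-in-complexes,
but deliberately does **not** flatten a multi-KO parenthesized group into
the surrounding step sequence — flattening would silently change the step
count and therefore the MCR denominator. The same rule makes a substituted
sub-module (an `M#####` leaf resolved via `resolve_submodules()`) count as a
single step of its parent.

Tokens are validated strictly (`K`/`M` plus exactly five digits); malformed
tokens, unbalanced parentheses and empty steps are errors with positions,
never silently dropped.

## The classification stage

Given an MCR matrix (genomes × modules, percentages):

1. **Constant-module filtering** removes every module whose MCR is
   identical in all genomes, whatever the shared value (0 through 100).
   Equality is tested at full stored precision, not at the one-decimal
   display precision, so display rounding can never change the analysis
   set.
2. **Clustering**: pairwise Euclidean distances between genome MCR
   vectors, complete-linkage agglomeration (`stats::hclust`; merge heights
   are monotone), Newick export via `ape`, and `cut_dendrogram()` to read
   off k groups.
3. **PCA** (`stats::prcomp`) on the filtered matrix with column-mean
   centering and, by default, *no* variance scaling: all MCRs already share
   the 0–100 scale, and standardizing would inflate near-constant modules.
   A `scaling = "standardize"` switch is provided for users who want the
   correlation route; the variance table records which was used. Sign
   convention: each loading column is flipped so its largest-magnitude
   entry is positive, making loadings tables reproducible.
   `top_loading_modules()` ranks modules by |loading| with lexicographic
   tie-breaking.

## Synthetic cohorts

`generate_catalog()` builds random catalogs exercising the whole grammar
(alternatives, 2–4-subunit complexes, optional subunits, configurable KO
sharing between modules to emulate enzymes used by several pathways).
`generate_profiles()` plants group structure: each group completes each
module with a stated probability (all KOs of one satisfying assignment are
added); otherwise, with a partial-fill probability, a uniform random subset
of steps is satisfied. The uniform-subset noise model is a deliberate,
simple choice: real incomplete modules have correlated gaps (missing
operons, shared enzymes), which this generator does not emulate. Passing
recovery tests on these cohorts therefore demonstrates that the pipeline
recovers structure *of the planted kind* — it does not certify performance
on real annotation error, horizontally transferred fragments, or
KAAS-style assignment noise.

The recovery tests use a 6-group × 10-genome cohort over 300 modules with
completion probabilities 0.9 (a group's own 50 modules) versus 0.1 (all
others) and partial-fill 0.2, cut at k = 6; and a two-group, 15 + 15 genome
cohort over 60 modules in which 10 designated marker modules are at
0.95/0.05 while the background sits at 0.9 in both groups, for the PC1
loading check. These sizes mirror, at desk scale, a cohort of dozens of
genomes by hundreds of modules; everything is seeded and bit-reproducible.

## Worked-example fixtures

`archaea_fixtures()` packages a transcription of eleven modules (glycolysis
M00001, gluconeogenesis M00003, TCA M00009, glyoxylate M00012, CAM-light
M00169, reductive TCA M00173, pyruvate oxidation M00307, HP–HB M00375, and
the M00207/M00221/M00237 ABC transporters) and KO profiles for four
archaeal genomes (csu, nmr, nga, csy). Printed KO identifiers are used
verbatim; steps whose KOs are not printed use placeholder IDs in the
`K9####` range, flagged in the provenance table, and nothing asserts a
placeholder's identity — only step counts and stated presences/absences.
Two source ambiguities are encoded explicitly and recorded in the
provenance table: gluconeogenesis step 1 follows the body text (the
phosphoenolpyruvate carboxykinase step, the one csu lacks) rather than the
figure caption's listing; and the 2-oxoglutarate:ferredoxin oxidoreductase
gap in the TCA module sits at caption position 4 (one body-text sentence
calls it step 3).

## Numerical choices

* MCR values are stored at full double precision; display rounding is one
  decimal, half-up (`format_mcr()`), so 85.714… prints as 85.7.
* Matrix TSV files are written at `%.17g` by default and round-trip
  bit-exactly; a decimals option produces display-rounded files.
* Abundance uses an exact branch-and-bound packing for modules with ≤ 12
  distinct KOs (all realistic transporter modules are far smaller) and a
  greedy bottleneck heuristic with a warning above that.
* Clustering tie-breaks are delegated to `hclust`, which is deterministic
  for a fixed input; repeated runs are bit-identical.
* PCA requires ≥ 3 genomes and ≥ 2 varying modules and refuses constant
  matrices (filter first).

## Limitations

* The MCR treats shared enzymes naively: a module can score high because
  its steps reuse enzymes of other pathways (the reductive-TCA example in
  the fixtures scores > 90% in a genome that cannot run the cycle). The
  per-step `missing_kos` diagnostics exist precisely to support that
  manual scrutiny.
* Module abundance assumes KO copies are freely assignable to sets; it
  knows nothing of operon structure.
* The synthetic generator draws steps independently; it does not model
  phylogenetic autocorrelation between genomes.
* KO assignment itself (annotation from sequence) is out of scope; the
  package starts from annotation tables.
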