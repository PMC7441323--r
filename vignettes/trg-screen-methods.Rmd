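---
title: "Screening for taxonomically restricted genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for taxonomically restricted genes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen

A taxonomically restricted gene (TRG) is a gene with detectable homologs
inside one clade and none outside it. `trgscreen` implements the classic
presence/absence formulation of that search for a focal proteome against a
panel of genomes grouped into ingroup phyla and outgroups:

1. **Ingroup criterion.** A focal gene must be detectable — best hit
   E-value strictly below `e_ingroup` (default `1e-7`) — in at least one
   genome of *every* ingroup phylum. Detection in many genomes of one
   phylum cannot compensate for a phylum with none: the criterion encodes
   conservation across the whole clade, not abundance within part of it.
2. **Rescue round.** Genome annotation misses genes. Before a gene is
   rejected for absence, every absent ingroup cell whose genome has
   scaffold DNA configured is re-tested by translated search (six-frame
   translation, frames split at stop codons) at `e_rescue` (default
   `1e-7`). A qualifying hit flips the cell to present with evidence
   `rescued`. Rescue runs *before* the ingroup criterion because that
   criterion is what it exists to serve, and never touches outgroup cells:
   the original screen applied its translated round to the clade genomes
   only. A config flag (`rescue_outgroups`) exposes the symmetric
   extension — translated *exclusion* via unannotated outgroup loci — but
   it is off by default.
3. **Outgroup / reference exclusion.** Any hit strictly below
   `e_exclusion` (default `1e-5`) in an outgroup proteome disqualifies the
   gene, as does any hit in a reference ("nr-like") exclusion database
   *whose subject is labeled with an extra-clade taxon*. The taxon filter
   matters: a comprehensive reference database inevitably contains clade
   entries — including the focal gene's own orthologs — and a taxon-blind
   reading would reject every candidate. Exclusion databases therefore
   require per-sequence taxon labels, and only extra-clade subjects count.

All three thresholds are strict `<` ("below"), and the boundary cases are
part of the test suite: a best ingroup E-value of exactly `1e-7` is
absence, an outgroup hit at exactly `1e-5` does not exclude.

**Self-hits.** The focal genome trivially contains every focal gene, so it
never supplies presence evidence: its phylum's criterion must be met by a
non-focal member genome. This is the only reading under which a screen
whose focal genome shares its phylum with one other genome is meaningful;
`allow_focal_evidence = TRUE` restores the permissive alternative for
screens fed by external hit tables that already exclude self-matches.

## Search engine and E-value model

The built-in engine is a desk-scale stand-in for a production search tool,
exact where it matters for the screen's semantics:

* **Alignment.** Affine-gap Smith–Waterman (Gotoh) in C++ over BLOSUM62,
  gap open −11, gap extend −1 (a gap of length $L$ scores
  $\mathrm{open} + L\cdot\mathrm{extend}$). The ambiguity residue `X`
  scores 0 against everything; the stop character `*` (translated frames
  only) scores −4 against everything, and frames are split at stops before
  searching, so no hit crosses one. When alignments tie, the one with the
  smallest start coordinates and then the shortest span is reported.
* **Statistics.** Ungapped Karlin–Altschul: $E = K m n e^{-\lambda S}$
  with defaults $\lambda = 0.3176$ nats, $K = 0.134$, $m$ the query
  length and $n$ the residues searched, summed **per genome** (the screen
  thresholds per-genome searches, not one pooled database). Bit scores are
  $S' = (\lambda S - \ln K)/\ln 2$. The gapped refinements (length
  adjustment, edge-effect and composition corrections) are deliberately
  omitted: the screen only *thresholds* E-values, and both the simulator
  calibration and the thresholds live on the same uncorrected scale. The
  parameters are plain fields of `scoring_scheme()` for anyone who needs
  different ones.
* **Seeding.** Word seeding (k = 3) prunes subjects that share no exact
  k-mer with the query; surviving pairs are scored with the exact DP
  kernel rather than a banded X-drop extension. At the scales this engine
  is meant for, the exact extension costs little and removes a heuristic
  failure mode entirely; the test suite still asserts the conservative
  contract (a seeded score never exceeds the exact score) rather than
  assuming equality.

External search tools remain first-class: `read_hit_table()` ingests the
package's 11-column TSV or the common 12-column tabular dialect, and
`run_screen(engine = "external_hits")` consumes those tables through the
identical filter logic.

## Conservation profiling and novelty classes

Candidates that survive the screen are either **fully novel** proteins or
**chimeras** that fuse an ancient, extra-clade-detectable domain to a
clade-specific conserved motif. The classifier operationalizes this:

1. **Center-star alignment** of the candidate's ingroup orthologs against
   the focal sequence (global pairwise alignments with free end gaps,
   merged under "once a gap, always a gap"). A full progressive aligner
   would be overkill: ortholog sets here are small, closely related, and
   anchored on one distinguished sequence whose coordinate system the
   downstream annotations use.
2. **Per-column conservation**: the mean over non-gap residue pairs of a
   normalized substitution score,
   $(s(a,b) - s_{\min}) / (\max(s(a,a), s(b,b)) - s_{\min})$, clamped to
   $[0,1]$. The per-pair ceiling (rather than one global diagonal
   maximum) is what makes an identical column score exactly 1 whatever
   the residue — BLOSUM62 diagonals range from 4 (Ala) to 11 (Trp), so a
   single global ceiling would grade columns by amino-acid identity
   rather than by conservation. Columns with fewer than two non-gap
   residues are masked. A sliding mean of width `w` (default 11 columns,
   shrinking at the edges) smooths the track.
3. **Segments**: maximal runs of at least `min_len` (default 20) columns
   with smoothed score at or above `high` (default 0.7) become conserved
   segments, mapped to focal coordinates. The defaults are calibrated on
   the simulator — at the simulated ingroup divergences, ortholog columns
   average well above 0.7 while fast-evolving linkers fall well below —
   and are plain arguments everywhere they appear, because "strongly
   conserved" is not a quantity with a community-standard value.
4. **Classification** against externally supplied domain annotations
   (profile-scan output is an *input*, not something this package
   recomputes): a conserved segment overlaps a domain when ≥ 50% of the
   segment's length is covered by a single extra-clade domain (robust to
   fuzzy domain boundaries). Chimeric = at least one overlapping and one
   non-overlapping conserved segment of length ≥ `min_len`; fully novel =
   conserved segments, none overlapping; known = all conserved segments
   explained by domains. Two degenerate cases needed decisions the class
   list leaves open: no conserved segments at all returns
   `"unclassified"`, and a mix where the only unexplained segments are
   shorter than `min_len` returns `"known"` — short leftovers are not
   evidence of a novel motif.

## The simulator

`simulate_clade()` generates the whole study design at desk scale: 8
ingroup proteomes in phyla of 2/2/4 plus 10 outgroups, on a fixed species
tree whose branch lengths are expressed in expected substitutions per
site. Planted families:

* **pan** (5): born at the root; present clade-wide and beyond; must be
  rejected via outgroup/reference hits.
* **clade-specific** (5): born on the branch leading to the clade
  ancestor; structurally guaranteed never to appear in outgroup proteomes
  or under extra-clade labels in the decoy database.
* **chimera** (2): a root-born domain (emitted stand-alone into outgroup
  proteomes and, diverged, into the decoy database under an extra-clade
  label) fused in ingroup tips to a clade-born motif via a linker
  evolving at 6× the base rate. The fast linker is what makes the domain
  and motif *separately* detectable as conserved segments.
* **fast** (2): root-born, evolving at 8× the base rate — realistic
  homology-detection failures. They are excluded from the sensitivity
  denominator and reported separately, because whether a fast family
  slips through is a property of the divergence draw, not of the filter
  logic.

Sequence evolution is a stationary F81-style substitution process over
BLOSUM-style background frequencies: per site, an event with probability
$1 - e^{-\rho t}$ redraws the residue from the background distribution,
giving the closed-form expected difference fraction
$(1 - e^{-\rho t})(1 - \sum_a f_a^2)$ that the tests check by simulation.
There are **no indels** in the default model, so true ortholog columns
stay in register and center-star output on simulated data is exactly
assessable; the cost is that the aligner's gap handling is exercised by
constructed fixtures rather than by the simulator. Per-branch loss
(probability 0.05) prunes whole subtrees; per-gene "unannotated" events
(probability 0.05, per-tip overridable) move a gene from the proteome
into scaffold DNA — reverse-translated with uniform synonymous codons,
embedded in random flanks on a random strand, in frame and intron-free.
Contiguous embeddings are a documented simplification of real gene
structure: the rescue stage being tested thresholds translated local
alignments, which intron fragmentation would weaken but not invalidate.

Branch lengths were calibrated once, when the defaults were fixed:
ingroup tip-to-tip paths of roughly 0.2–0.45 expected substitutions/site
keep ortholog E-values many orders of magnitude below `1e-7` at the
default protein lengths (120–300 aa), while root-to-outgroup paths near
1.0 leave pan-family orthologs clearly detectable (so their exclusion is
exercised) without being trivial. The seed fixes every draw; identical
configurations produce byte-identical output files.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: indel evolution, domain shuffling beyond the
two-block chimera, paralogy and gene families, composition bias,
low-complexity sequence (no SEG-style masking is applied, which on real
proteomes is a known source of spurious hits), intron structure, and
assembly/annotation error beyond clean gene dropout.

## Numerical choices and degenerate inputs

* Alignment scores, gap penalties and the substitution matrix are
  integers end to end; DP ties are resolved deterministically (smallest
  start, then shortest span for local alignments; gap-state preference in
  the overlap aligner keeps tied gaps internal rather than trading them
  for free end gaps).
* A best local score of 0 is the empty-hit convention: no hit is emitted,
  coordinates are `NA`.
* E-values are compared with strict `<` everywhere; report serialization
  uses `%.6e`, so write/read round trips preserve six significant digits.
* Masked profile columns (fewer than 2 non-gap residues) break conserved
  runs; windows shrink at track edges rather than padding.
* An empty focal proteome yields an empty, valid report; a rescue round
  with no absent ingroup cells is the identity.
* All screen stages are pure functions of their inputs: verdicts are
  invariant to the order of genes, genomes and hit rows, and a fixed
  simulation seed makes the whole pipeline byte-reproducible.

## Problem sizes

The shipped analyses and tests run the full pipeline on clades of 18
proteomes with 14 planted families (roughly 200 sequences of 120–300 aa
per replicate), 20 replicate seeds for the recovery experiments, 200
random pairs for the aligner-oracle comparison and all $2^8$ presence
patterns for the filter-logic enumeration. These sizes make every stage
of the screen — including the quadratic DP kernel — exact and fast enough
to verify end to end; nothing in the method is specific to them, and the
engine/ingestion split means a production-scale run can swap in an
external search tool without touching the filter logic.

## Known limitations

* The ungapped E-value model overstates significance relative to modern
  gapped statistics; thresholds are internally consistent but not
  comparable to production BLAST E-values.
* Center-star alignment is not a substitute for a profile or progressive
  MSA on deeply diverged or indel-rich ortholog sets.
* The screen's verdicts inherit every bias of its inputs: proteome
  completeness, annotation quality and reference-database composition.
  The rescue round mitigates only the annotation part.
* Conservation thresholds (0.7 / 20 / 11) are simulator-calibrated
  defaults, not fitted constants; real candidate sets deserve a
  sensitivity sweep, for which all three are plain arguments.
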