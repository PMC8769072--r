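---
title: "Methods: design and analysis of proteomic peptide phage display screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design and analysis of proteomic peptide phage display screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proppd)
```

Proteomic peptide phage display (ProP-PD) identifies short linear motifs
(SLiMs): 3-10 residue binding elements that live in intrinsically
disordered regions (IDRs) and are recognized by folded domains. A designed
phage library displays peptides tiling all IDRs of a proteome; panning the
library against an immobilized bait domain enriches binding clones, and
next-generation sequencing of the enriched pool reads out which peptides
bound. `proppd` implements the computational stack around such a screen:
library design, NGS processing, peptide annotation, motif discovery,
confidence classification, benchmarking statistics, library quality
control, and the downstream biophysical binding models.

## Defining the accessible search space

The search space is the set of proteome regions plausibly accessible to a
bait in solution: predicted disordered sequence plus surface-accessible
loops observed in structures.

Per-residue evidence enters as three tracks, used in a strict hierarchy
(experimental beats predicted):

* disorder propensity (an IUPred-style score in [0, 1]); residues with
  score >= 0.4 are called accessible. The cutoff is the field-standard
  permissive threshold for IUPred-type predictors; the boundary value
  counts as accessible (the package treats all cutoffs as closed on the
  accessible side, and they are configurable in
  `accessibility_config()`).
* surface accessibility from solved structures, expressed as percent of
  the residue's maximum accessibility in a Gly-Gly-X-Gly-Gly pentapeptide
  (the shipped table uses published theoretical maxima). Unresolved
  residues count as 100 % accessible - crystallographic invisibility is
  itself evidence of disorder. Several structures covering one residue
  are combined by the median; SA >= 33 % is accessible.
* homology-mapped surface accessibility: SA tracks of close structural
  homologues (screened upstream at e-value <= 1e-15 and >= 85 % structure
  coverage) transferred through a Smith-Waterman alignment under BLOSUM62.
  Gap penalties are not dictated by the screening step; the package uses
  the BLAST defaults (open 11, extend 1). Direct structural evidence takes
  precedence over homology-mapped evidence at the same residue.

The binary track is then cleaned in a fixed pass order: *binarize ->
merge hierarchy -> smooth -> order-island inclusion -> window filter*.
Smoothing flips runs of <= 4 residues whose two flanking runs agree on the
opposite category, iterating until stable; a short run whose flanks
disagree is left unchanged (the conservative reading of "inconsistent with
the flanking category"), and terminal runs are never flipped. Ordered
islands shorter than 25 residues inside disorder are re-marked accessible:
such segments rarely fold autonomously. Hard constraints - nonstandard
residues (X/U), transmembrane and extracellular spans, and fully secreted
proteins (keyword "Secreted" without "Cytoplasm"/"Nucleus") - are applied
*after* smoothing so that smoothing can never re-admit them. When
chain/topology segments are annotated, smoothing and island inclusion run
per segment, since disorder scores are computed per chain.

Finally, every 16-mer window with at least 8 accessible residues is
retained, and overlapping windows are merged into maximal regions. A note
on the 8-residue loop rule: any contiguous accessible run of >= 8 residues
automatically satisfies the 8-of-16 window rule in any protein of >= 16
residues, so retained loops are a consequence of the window filter rather
than a separate pass; the explicit padding branch in
`define_search_space()` only exists for configurations that decouple the
two lengths. We apply the window filter after order-island inclusion (the
natural reading of the pass order; the islands are part of the accessible
set the windows count).

Regions are tiled into 16-mers overlapping by 12 (step 4), with one extra
window anchored at the region end whenever the stepped grid does not reach
it, so region termini are always covered and every interior residue (>= 4
from a region edge) is covered by at least two peptides. Cysteines are
replaced by alanine in the displayed sequence to avoid disulfide artifacts
on the phage coat; the native sequence is retained alongside.

## Oligonucleotide design

Display peptides are reverse translated by sampling each codon
independently in proportion to its relative usage (an *E. coli* K-12
table ships as the default, as appropriate for phage propagation in
*E. coli*). The coding insert is flanked by the fixed annealing adapters
`CAGCCTCTTCATCTGGC` / `GGTGGAGGATCCGGAG` (full length 81 nt). Oligos are
rejected and locally resampled while they contain a SmaI-family site
(GGGCCC/CCCGGG, which would break downstream cloning) or a
self-complementary pair: any 8-mer (i.e., more than 7 contiguous
nucleotides) whose reverse complement occurs elsewhere in the same oligo,
the hairpin/dimer semantics of the rule. The scan covers the full oligo
including adapters, since a junction can create a site; a violation lying
entirely inside the constant adapters is unfixable by codon resampling and
is flagged rather than dropped. Only codons overlapping a violating span
are resampled (minimal perturbation), so the translation is invariant by
construction. Synthesis pools of 92,918 oligos are filled to capacity with
redundant peptides encoded by distinct synonymous oligos.

## NGS processing

Reads follow the fixed amplicon layout `barcode5 + adapter5 + 48-nt insert
+ adapter3 + barcode3`. Demultiplexing drops reads with mean Phred quality
below 20 (assessed on the whole read, Phred+33), then matches each barcode
and adapter allowing at most one substitution; a read within one mismatch
of two barcodes is ambiguous and excluded. Only substitutions are
considered - the barcodes sit at fixed positions in an amplicon, so indels
would shift the frame and fail the adapter match anyway. The four outcome
categories (assigned / low-quality / unassigned / ambiguous) partition the
input exactly.

Surviving inserts are translated in frame 0. Inserts of the wrong length
or containing a stop codon are tallied separately as non-conforming: they
feed the library QC statistics (fraction of correct-length, coding
sequences) but never the peptide tables. Counts of synonymous inserts
pool onto their common peptide. Peptides seen once in a sample are
discarded (singletons are dominated by PCR/sequencing errors); removal
happens per sample before normalization, since a singleton carries no
quantitative information regardless of what other days saw. Counts are
then normalized to per-sample fractions (so screens and sequencing
batches are comparable) and averaged over the sequenced days of each
replicate, with a peptide absent on a sequenced day contributing zero -
absence on a sequenced day is an observation, not missing data.

## Peptide mapping and merging

Peptides are mapped back to the proteome by exact search in which a
peptide-side alanine may match proteome cysteine (undoing the Cys->Ala
display substitution); the wildcard is deliberately asymmetric - proteome
alanine never matches peptide cysteine, because the library never emitted
cysteines. All occurrences are reported. Hits to several members of one
UniRef-style cluster collapse to the cluster representative so paralogous
families are counted once in benchmarking.

The merged per-bait table records, per peptide: the number of replicate
selections containing it, the mean normalized count over those replicates,
and the number of *distinct other* peptides whose mapping shares at least
one residue of a common protein (identical sequences across replicates are
replication, not overlap; one shared residue suffices, since the 12-residue
tiling overlap makes genuine overlaps large).

## Motif discovery and the specificity determinant score

Motif enrichment runs on the replicated, proteome-mapped peptides.
Restricting to mapped peptides matters in practice: recurrent sequencing
errors of a highly abundant clone pass the count filters but do not map,
and as near-copies of one sequence they would otherwise masquerade as a
strong sequence pattern.

The discovery core is a bounded SLiMFinder-style enumeration. Patterns are
sequences of defined positions - a fixed residue or one of nine
physicochemical equivalence classes (AGS, ILMV, IVMLFAP, IVMLFWHYA, FYWH,
KRH, ST, STNQ, DEST) - separated by up to 5 wildcards, with 2-5 defined
positions, first and last defined. Candidates are grown by appending one
defined position at a time; a candidate can only match peptides its parent
matched, so support is counted on the parent's match subset (this makes
the search linear in practice). Growth continues for patterns whose
uncorrected significance passes a permissive gate (0.05), with at most 50
patterns carried per depth.

Significance of a pattern with support $s$ among $n$ peptides is the
binomial upper tail $P(X \ge s)$ with per-peptide match probability $q =
1 - (1 - \prod_j p_{c_j})^{L - w + 1}$, where $p_{c_j}$ is the background
probability of class $c_j$, $L$ the peptide length and $w$ the pattern
span; background amino-acid frequencies default to the input peptides'
own composition. Because the guided search implicitly selects the best
pattern out of everything expressible, correcting only by the candidates
actually examined would be anticonservative (the support floor and the
guided extension are selection steps); each pattern is therefore
Bonferroni-corrected by the size of the enumerable pattern space at its
depth, $V (VG)^{k-1}$ for $V = 29$ position choices and $G = 6$ gap
choices. This is intentionally blunt - genuine motifs sit many orders of
magnitude below the 0.001 reporting cutoff, while chance patterns on null
input do not survive it; the original SLiMFinder significance model is a
different (clustering-based) construction that we deliberately do not
reproduce. Patterns with information content below 1.1 bits (computed as
$\sum_j \log_2(20/|c_j|)$ over defined positions) are discarded. Support
is counted over unique peptide sequences, so duplicated sequences cannot
inflate a pattern.

The top-ranked pattern aligns its matching peptides (on the matched span),
and a PSSM is built from the alignment with background-proportional
pseudocounts: $w(i,a) = \log_2\frac{n_{ia} + \alpha f_a}{(n + \alpha)
f_a}$ with $\alpha = 1$. A peptide's *specificity determinant score* is
the empirical p-value of its best-window PSSM score against null scores
obtained by scanning background sequences (by default the proteome) with
the position-reversed PSSM - the reversal preserves the matrix's
composition and information content while destroying its positional
meaning. Empirical p-values use add-one smoothing, $(r+1)/(N+1)$, so they
are never zero. Sequence-logo heights are $-\log_{10}$ binomial upper-tail
probabilities of each residue count against its background frequency.

## Confidence classification

Four binary criteria per peptide: observed in >= 2 replicates; >= 1
overlapping peptide; PSSM p-value < 1e-4; mean normalized count > 5e-4.
The count criteria are inclusive and the p-value/count bounds strict,
exactly as published. Peptides meeting all four are High confidence, two
or three Medium, one Low, none Filtered. When no motif passes the
reporting cutoff there is no PSSM; the specificity criterion is then unmet
for every peptide (p set to 1, with a warning) rather than silently
skipped. The ROC/Youden machinery that calibrated these thresholds is
exposed (`roc_curve()`, `youden_cutoff()`): Youden's J = TPR - FPR is
maximized with ties broken toward higher TPR and then the lower threshold,
so the cut sits at the permissive edge of the optimal plateau. Calibration
pools all baits by default; per-bait calibration is a matter of subsetting
the input table.

## Benchmarking and enrichment statistics

* **Recall/precision** against previously validated motif instances:
  recall is computed over *findable* instances only (those covered by at
  least one library peptide), an instance counting as found when any
  selected peptide's mapping overlaps it after paralogue collapse;
  precision is the fraction of selected peptides overlapping any validated
  instance.
* **Consensus enrichment**: binomial upper tail of the number of selected
  peptides matching a consensus, with the library-wide match fraction as
  the per-trial probability.
* **Interactor enrichment**: the number of distinct known interactors hit
  is compared to 10,000 same-size draws from the pooled peptides of all
  selections; the empirical p-value uses add-one smoothing.
* **GO and interactome enrichment**: hypergeometric with the strict upper
  tail $P(x > m)$ as printed in the source formula (a `tail` argument
  switches to $P(x \ge m)$ for comparison), counts taken over cluster
  representatives, Benjamini-Hochberg correction across terms, and fold
  enrichment $(m/n)/(M/N)$ - the printed rendering $(m/n)/(M/n)$ is
  treated as a typographic slip for the standard quantity.
* **Shared-term probability**: $p = N_g(N_g-1)/(N(N-1))$.
* **Amino-acid bias**: log2 frequency ratios against a disordered-proteome
  background, z-scored across the 20 ratios, |z| > 2 flagged.

## Library coverage extrapolation

Sequenced aliquots of the naive library are accumulated in 10 random
orders; cumulative unique design-matching sequences (percent of design)
against cumulative reads is fit with the two-hyperbola saturation model
$Y = Y_{max1}X/(a+X) + Y_{max2}X/(b+X)$, capturing an abundant
fast-saturating class and a rare slow one. The fit is nonlinear least
squares with multiple starts (plateau splits 0.5/0.7/0.9 for the
asymptotes, log-spaced half-saturation constants spanning the observed
read range), components canonicalized to $a \le b$ because they are
exchangeable, and the predicted maximum coverage $Y_{max1}+Y_{max2}$
reported with its propagated standard error
$\sqrt{V_{11}+V_{22}+2V_{12}}$. X counts reads contributed per aliquot.

## Fluorescence polarization models

Direct titrations use the closed-form quadratic (ligand-depletion) binding
equation $Y = A\,(pept + X + K_D - \sqrt{(pept + X + K_D)^2 - 4\,pept\,X})/2
+ B$, valid when the probe concentration is not negligible relative to
$K_D$; it reduces to the hyperbola $A\,pept\,X/(K_D+X)+B$ when $pept \ll
K_D$ (asserted numerically in the tests at $pept = K_D/100$). Fits are
unweighted nonlinear least squares with multiple starts; a numerically
negative discriminant is clamped at zero with a warning; flat titrations
(amplitude indistinguishable from zero) are flagged as
$K_D$-unidentifiable. Competition data are fit with a four-parameter
logistic on log10 concentration, reporting IC50; rising or flat
displacement curves are flagged. An optional Cheng-Prusoff-style
conversion `ic50_to_ki()` is provided as a documented convenience, not as
part of the core model.

## The synthetic campaign generator

`make_proteome()` and `simulate_selection()` emulate a full study:
proteins built from alternating segments whose disorder scores straddle
the 0.4 cutoff (disordered segments score 0.45-0.95 and use a
disorder-promoting residue composition, ordered segments 0.02-0.38), one
concrete instance of a planted consensus (default `PxLP`, three defined
positions) written into a disordered segment of each carrier protein
(10 % of proteins), localization keywords/GO terms, and a mostly-identity
paralogue cluster map. Selection reads are multinomially sampled from the
library's oligos with carrier oligos up-weighted 1000-fold - the
compounded over-representation of binding clones after several rounds of
panning, under which non-binders are largely washed out; a per-replicate
log-normal abundance spread (sd 1.5 in log space) emulates clonal
amplification noise, shared by the sequencing days within a replicate.
Reads receive substitution errors at 0.5 % per base and a 5 % admixture
of sub-threshold-quality reads. Barcodes are built from base-4 digit
blocks, giving pairwise Hamming distance >= 3 so one tolerated mismatch
can never cross samples.

What the generator does *not* emulate - and hence what passing tests do
not demonstrate about real data: PCR duplicates and chimeras, indel
sequencing errors, phage growth-rate biases uncoupled from binding,
multi-bait cross-reactivity, and real IDR sequence correlation structure
beyond single-residue composition. The defaults (200 proteins of 200-500
residues, 3 replicates x 2 days x 50,000 reads) are the package's
standard validation scenario; the cross-seed motif-recovery check runs
the same generative model at 50 proteins and 5,000 reads per sample so
that twenty independent campaigns remain affordable, and the discovery
problem is, if anything, harder at the smaller scale (fewer carriers
against the same pattern space).

## Numerical and degenerate-input conventions

1-based inclusive coordinates throughout. All accessibility cutoffs are
inclusive on the accessible side. Empirical p-values are add-one smoothed.
Binomial tails are upper tails $P(X \ge k)$ everywhere. Proteins shorter
than 16 residues yield no peptides. Peptides containing X/U are never
emitted. `find_enriched_motifs()` warns and returns an empty table below
5 peptides; identical sequences are collapsed before support counting. An
oligo that cannot be sanitized within the iteration budget is returned
flagged. Empty demultiplexed samples propagate as empty tables, not
errors.

## Known limitations

The motif significance model is a deliberate simplification of
SLiMFinder's; its absolute corrected p-values are conservative and should
be read as rankings with a hard reporting cutoff. PSSM alignment uses the
matched span of the top pattern only (no iterative realignment).
Motif-vs-motif similarity scoring (CompariMotif-style) is out of scope, as
are disorder prediction and structure processing themselves - score tracks
are inputs. The homology SA transfer assumes the caller has already
screened hits; the package does not run BLAST.
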