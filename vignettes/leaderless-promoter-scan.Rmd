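---
title: "Detecting -10-like promoter motifs and leaderless transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting -10-like promoter motifs and leaderless transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

In most bacteria, transcription initiates at a promoter whose -10 element
(the Pribnow box, ~TATAAT in *E. coli*) is recognized by the sigma factor
roughly 10 bp upstream of the transcription start site, and translation
initiates at a ribosome binding site (RBS) in the 5'-UTR. In
Deinococcus-Thermus genomes a hexameric TANNNT element — most often
TACACT — sits immediately upstream of a large share of ORFs, around 6-7 bp
before the start codon. A -10 element that close to the start codon leaves
no room for a 5'-UTR: transcription starts at (or within a few bases of)
the start codon and the mRNA is *leaderless*. This package implements the
genomic side of that analysis as a reusable, testable pipeline:

1. strand-aware extraction of upstream windows from FASTA + GFF3
   (`load_genome`, `extract_upstream`, `extract_scan_window`);
2. de novo ZOOPS motif discovery on 20-bp upstream windows
   (`discover_motifs`);
3. PWM scanning of 450-bp windows with exact p-values
   (`scan_gene_windows`);
4. spacer/location/fraction statistics (`spacer_distribution`,
   `classify_locations`, `motif_fraction`, `zoops_site_fraction`);
5. start-codon reannotation proposals for genes whose motif lies inside
   the annotated ORF (`propose_starts`);
6. classification of the coverage step increase expected just downstream
   of the motif of a leaderless gene (`step_statistic`,
   `aggregate_trends`);
7. a synthetic genome + coverage generator with a ground-truth table that
   makes every stage testable without downloads (`synthetic_spec`,
   `gen_genome`, `gen_coverage`, `end_to_end_fixture`).

## The ZOOPS model and its EM fit

Each training window either contains exactly one motif site (with prior
probability $\gamma$) at a position uniform over the valid offsets, or no
site ($1-\gamma$); non-site bases follow a 0-order background estimated
from the windows (floored at $10^{-6}$ so log-odds stay finite). The
E-step computes, per window, the posterior over "site at offset $j$" vs
"no site"; the M-step re-estimates the 4 x w position probability matrix
from posterior-weighted counts with a pseudocount of
$0.01 \cdot \text{background}$ per column, and $\gamma$ from the mean site
posterior.

Numerical notes:

* The pseudocount makes the M-step a MAP update under a Dirichlet prior.
  The quantity that ascends monotonically is therefore the EM objective
  (observed-data log likelihood *plus* the Dirichlet term); `zoops_em`
  records that objective in `ll_trace`, while `model$log_likelihood` is
  the observed-data likelihood at the fit. The bare likelihood can dip by
  ~1e-7 near convergence; the objective cannot.
* Convergence is declared when the objective changes by less than `tol`
  (default 1e-6, absolute) or after `max_iter` (200) iterations.
* $\gamma$ is clamped to $[10^{-6}, 1-10^{-6}]$ so its logs stay finite
  on degenerate inputs.
* Masked (N) positions contribute a likelihood ratio of 1, which is what
  makes multi-motif erasure (below) work.

Seeding follows the classical substring heuristic: every w-mer in the
windows is counted once, ranked by over-representation against the
background (count / background probability; ties broken lexicographically
for determinism), and the top words become seed matrices with probability
0.85 on the matching base. `discover_motifs` draws `n_seeds` restarts from
the top `5 * n_seeds` candidates, weighted by over-representation,
deterministically under the user seed — so different seeds explore
genuinely different restart sets while a fixed seed is fully reproducible.
Each restart runs a 5-iteration pilot EM; the three best pilots are run to
convergence and the best final fit wins. For the second motif, the
maximum-a-posteriori site of every window with site posterior > 0.5 is
erased to N and the procedure repeats.

Motif significance machinery (E-values) is deliberately out of scope;
models are ranked by training log likelihood.

On pure-noise windows the fit is recognizable not by a flat matrix but by
a collapsed $\gamma$: EM latches onto the most over-represented chance
pattern, whose columns can be moderately sharp, while the per-sequence
expected information $\gamma \times \overline{IC}$ stays far below that of
a genuinely planted motif (roughly 0.1-0.25 vs 0.45 bits under the
defaults). The test suite checks exactly that contrast.

## Exact p-values for PWM scanning

Scanning uses log-odds scores $\log_2(\theta'/\text{background})$ with
$\theta' = (\theta + 0.001)$ renormalized. Scores are discretized to
multiples of `granularity` (default 1e-3 bits) and the null distribution
of a background w-mer's total score is built by positional convolution
over the columns on the integer lattice — the survival function of that
distribution converts any observed score into an exact p-value, the same
construction FIMO uses. The reported site score is the discretized score,
so score order and p-value order agree exactly within a scan. For w = 6
the lattice is small; the implementation refuses lattices beyond 5e7
cells and advises a coarser granularity.

Scanning is given-strand only by default (promoter elements are
strand-specific, matching `--norc` semantics); w-mers containing N are
skipped rather than scored, since the background assigns N no
probability. Sites are reported when their p-value is at or below the
threshold (default 0.015), and `best_site_per_gene` keeps the minimum-p
site per gene, breaking ties toward the most 3' site because the
biological question concerns the element closest to the start codon.

The **spacer** of an upstream site is the number of bases strictly
between the motif's last base and the first base of the start codon
(`spacer = -offset - w`); "6-7 bp upstream" always refers to this gap.
Location classes: sites starting at or after the start codon are
`within-ORF`; upstream sites with spacer > 50 are `far-upstream` (50
mirrors the truncation distance at which promoter function is lost);
everything else, including sites overlapping the start codon, is
`proximal-upstream`.

## Two fraction estimators, and why they differ

The headline statistic — what share of genes carry the -10-like element
proximally — can be computed two ways, and they are *not* equivalent:

* `motif_fraction` counts genes whose best scan site's spacer falls in a
  band (default 0-20 bp). Over a 450-bp window at p <= 0.015, chance
  TANNNT-family words are common (the family's background probability is
  ~0.005 per offset, so ~2 chance family hits per window), and such a
  chance hit with favorable middle bases can out-score the true proximal
  site about half the time. The best-site-in-band count is therefore a
  *conservative, diluted* estimate (~0.18 when 0.30 of genes truly carry
  a site under the default generator).
* `zoops_site_fraction` counts training windows whose ZOOPS site
  posterior exceeds 0.5 on the 20-bp discovery windows. The short window
  leaves little room for chance matches and the model weighs every offset
  jointly, so this estimate tracks the true fraction closely (within
  ~0.01-0.03 at n = 3000).

The genome summaries report the scan-based fraction (it is the one tied
to explicit spacer bands), but the discovery-based estimate is the one to
quote as "fraction of genes carrying the motif", and it is what the
acceptance checks compare against the planted truth.

## Start-codon reannotation

If the -10 element is the promoter and transcription is leaderless, a
motif found *inside* an annotated ORF suggests the annotated start
overshoots the real one: the true start codon should sit within a few
bases of the motif's 3' end. `propose_start` scans the coding strand from
the base after the motif (up to `max_spacer = 15`, covering "immediately
followed" through the modal 6-7 bp spacer with margin) for an initiator
codon from {ATG, GTG, TTG}, preferring the nearest codon in frame with
the annotation; an out-of-frame codon is reported but flagged, never
applied, since a frame shift more likely reflects a sequencing error.
Proposals that would leave an ORF shorter than 30 nt are suppressed.
Because only `within-ORF` and `far-upstream` genes are eligible, applying
the in-frame proposals and re-running the procedure yields nothing — the
procedure is idempotent by construction.

## The coverage step statistic

Per-base transcript levels are consumed as a coverage track (bedGraph or
an alignment-interval table; intervals flagged as gapped or inverted are
excluded from depth and counted, mirroring the exclusion filter applied
to BLAST-style alignments). `gene_profile` orients depth to the coding
strand over the ORF +/- 100 bp; a -20..+60 zoom accessor reproduces the
bar-chart view around the start codon.

`step_statistic` compares mean depth over the 20 bases ending at the
motif's last base against the 60 bases after it:
$R = \bar d_{down} / (\bar d_{up} + 0.5)$. Classes: `low-coverage` when
the downstream mean is below 1 read; `step-increase` when $R \ge 2$;
`decrease` when $R \le 1/2$; otherwise `flat`. The 0.5 guards division by
zero; the thresholds are explicit, documented defaults with flags — the
three-class rule is this package's own operationalization of "a notable
increase in transcription after the motif", not a published criterion.
`aggregate_trends` additionally averages per-gene profiles (each
normalized by its own mean; zero-mean profiles excluded) on motif-anchored
coordinates, and `step_gradient_position` reports where the mean curve
rises fastest — a planted step lands at +1, the first base after the
motif.

## What the synthetic generator emulates — and what it does not

`synthetic_spec` defaults define the benchmark conditions:

* GC content 0.65 — a high-GC Deinococcus-Thermus-like background (the
  source genomes' GC is approximated, not copied);
* planted PWM with consensus TACACT: columns 1, 2 and 6 near-invariant at
  0.97 (the "first T, second A, sixth T" conservation pattern), middle
  columns weakly favoring C, A, C at 0.4;
* planted fraction 0.30 of genes, spacer drawn 50/50 from {6, 7};
* genes alternate strands, lengths 300-900 nt in codon multiples, with
  ATG starts and TAA stops written onto the coding strand;
* intergenic gaps 120-250 nt. The lower bound is geometric: a leadered
  neighbor's transcript extends 80 bp beyond its ORF and the step
  statistic's upstream window reaches ~33 bp out from a start codon, so
  gaps >= 113 bp guarantee no gene's windows overlap a neighbor's signal;
* coverage is drawn per base as independent Poisson draws: baseline rate
  1 everywhere, rising to 10 from the first base after the motif through
  the ORF end for leaderless genes, and from -80 for leadered genes. The
  drawn track can be decomposed into stacked alignment intervals whose
  rebuilt depth reproduces the track exactly, plus a configurable
  fraction of gapped/inverted flagged intervals to exercise the exclusion
  filter.

Deliberate simplifications, which bound what passing tests show about
real data: coverage is modeled at the per-nucleotide level rather than by
placing reads, so there is no read-length ramp at transcript 5' ends and
no strand-specific counting; genes never overlap and operons do not
exist; the background is i.i.d., without the codon structure, repeats or
skew of real genomes; and the planted motif is the only upstream signal —
real upstream regions also carry RBS-like words and -35-like elements.
Consequently the benchmark validates the *machinery* (coordinate
bookkeeping, EM correctness, p-value exactness, classifier behavior at a
known operating point), not biological effect sizes.

When a benchmark pins the planted fraction (the "exactly 30%" runs), the
generator plants `round(0.3 n)` sites by count rather than by per-gene
coin flips, so the condition itself carries no sampling noise and any
deviation is attributable to the estimator.

Problem sizes used by the shipped checks: discovery and scanning at
n = 3000 genes, restart-ensemble recovery at n = 1000 windows x 20
ensembles, the step-classifier benchmark at 500 leaderless + 500 leadered
+ 500 silent genes, reannotation at 40 planted cases — sizes at which the
binomial error bounds quoted in the tests are meaningful.

## Known limitations

* The ZOOPS positional prior is uniform; sequence-position-dependent
  priors (which MEME offers) are not implemented.
* Only 0-order backgrounds are supported, for both discovery and
  scanning; no q-value/FDR layer is provided on top of the raw p
  threshold.
* Reannotation proposals are advisory: no protein-level evidence
  (homology, structure) is consulted.
* The GenBank reader handles simple `a..b` / `complement(a..b)` CDS
  locations only; spliced gene models are out of scope.
* `gen_coverage`'s interval decomposition is quadratic in depth and
  intended for modest benchmark genomes, not chromosome-scale tracks.
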