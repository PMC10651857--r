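---
title: "Methods: differential splicing, reading-frame prediction and protein consequences"
author: "splicefx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential splicing, reading-frame prediction and protein consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefx)
```

# Scope and model of the data

`splicefx` starts where event-based alternative-splicing detection tools
stop. Its inputs are (a) an event-level table — for each local splicing
event, the exon coordinates of its two mutually exclusive isoform
structures — and (b) a sample-level table of read counts supporting each
isoform, plus a genome FASTA, a gene annotation, known protein sequences
per gene, and a protein-domain table. Alignment, event detection and
quantification are upstream concerns; any tool that can emit the two
tables can feed the pipeline.

The quantity modelled throughout is the percent-spliced-in (PSI) of
isoform 2 of each event: `psi = reads_iso2 / (reads_iso1 + reads_iso2)`,
set to missing when the denominator is below `min_coverage` (default 10
reads) because ratio estimates at lower support are unstable. Isoform
labels are normalized first so PSI has a consistent direction: the
exon-richer structure is isoform 2 for (multiple) exon skips, the
nucleotide-longer structure for alternative 3'/5' splice sites, the
merged (intron-retaining) structure for intron retention — so PSI is the
retention level — and for mutually exclusive exons, where neither length
rule is well defined, isoform 1 carries the exclusive exon with the
smaller genomic start. When normalization swaps labels the swap is
recorded and applied to the count columns before any statistics.

# Pre-test filtering

Three filters run before any hypothesis test, for statistical rather
than computational reasons: every event tested enlarges the
multiple-testing family, so events that cannot yield a meaningful result
should not enter it.

* **Protein-coding restriction** (default on): events in non-coding
  genes are removed; downstream translation is meaningless for them, and
  non-coding RNA splices promiscuously without reading-frame
  constraints. Genes absent from the annotation are treated as
  non-coding with a warning rather than an error, so partial annotations
  remain usable.
* **Missingness** (default: ≥ 10 samples with valid PSI *per group*):
  a few missing samples are tolerated — low coverage happens for
  technical reasons — but a test on 3 valid samples per group is noise.
* **PSI variability** (default: pooled sample SD ≥ 0.05): the SD is
  taken over all valid PSI values of both groups together, which is
  agnostic about whether variability arises within or between groups.
  The n−1 (sample) denominator is used; with fewer than two valid
  values the SD is undefined and the event is dropped.

Set membership is independent of filter order; the logged funnel
reports the order coding → missingness → variability.

# The beta-binomial test of differential PSI

For one event, let sample *i* contribute `y_i` reads for isoform 2 out
of `n_i` total. A binomial model of `y_i ~ Bin(n_i, psi)` understates
the variance: biological replicates scatter more than sampling noise
alone. The model therefore lets each sample's success probability be
drawn from a beta distribution with mean

`logit(p_i) = beta0 + beta1 * I[case_i]`

and overdispersion `phi_g` specific to the sample's group (two beta
distributions, one per group), giving the beta-binomial mass with shape
parameters `a_i = p_i (1 − phi_g) / phi_g`, `b_i = (1 − p_i)(1 −
phi_g)/phi_g`. Under this parameterization `Var(p) = p(1−p)phi`, and the
likelihood converges to the binomial as `phi → 0`. Modelling the PSI
ratio rather than the counts makes the test invariant to gene-level
expression changes: doubling both isoform counts moves no PSI.

`fit_betabin()` maximizes the likelihood with bounded quasi-Newton
(L-BFGS-B) over `(beta0, beta1, logit(phi_case), logit(phi_control))`;
the logit transform of phi enforces `[0, 1)` without constrained
optimization. The initial point uses the empirical logits of the two
group mean PSIs with `phi = 0.05`; jittered restarts (up to 4) are taken
only when an attempt fails to converge or yields a non-invertible
Hessian — with the informed start, routinely running multiple restarts
costs five times the compute of the large calibration simulations for no
measurable change in the optimum. Convergence tolerance is `factr =
1e4` (≈ 1e−12 relative); events that still fail are flagged, excluded
from the multiple-testing family, and reported with missing p-values.

**Test statistic.** The group effect can be tested by a Wald z on
`beta1` (standard error from the inverse observed Hessian) or by a
likelihood-ratio test against the `beta1 = 0` submodel. The default is
the **likelihood-ratio test**: in simulation at the cohort sizes this
package targets (10–15 samples per group, coverage 20–300, phi 0.05)
the Wald test rejects a true null at 0.085–0.093 when the nominal level
is 0.05, because maximum likelihood underestimates phi in small
samples and the Wald standard error inherits that bias; the LRT
measures ≈ 0.06 under the identical design. Both are exposed through
`test =`. P-values are adjusted by Benjamini–Hochberg step-up, and
significance is called at adjusted p < 0.01 (strict inequality). BH
controls the false-discovery *rate* in expectation — individual runs
can and do contain an occasional false positive among many true
discoveries; the reported effect size, delta average PSI (case −
control group means over valid samples), is the screen for biological
relevance.

# Reading-frame prediction

Translating a whole isoform blindly fails: event-based tools report
3–4 exons mid-transcript, annotation is incomplete, and novel isoforms
have no annotated frame. The pipeline instead anchors on the **first
5' exon of the event**, which both isoforms share, because a single
exon is short enough that a wrong frame usually reveals itself. Two
methods run on its strand-aware DNA:

1. **Single open reading frame**: translate in all three frames; a
   frame is "open" if its translation contains at least one codon and
   no stop. Exactly one open frame is an unambiguous call. No start
   codon is required — the exon is usually internal. Frames yielding
   zero complete codons are not considered open (they carry no
   evidence).
2. **Peptide matching**: translate in all three frames, truncate each
   peptide at its first stop, and count known proteins of the gene that
   contain the peptide as an exact substring. A call requires exactly
   one frame with a positive count and zero in the other two. Queries
   shorter than `min_match_len` (default 7 residues) are skipped —
   short peptides match by chance; queries containing `X` (ambiguous
   codons) are skipped as well, which is conservative in both
   directions.

Agreement between the two methods, or a call by exactly one, resolves
the frame. Genuine disagreement is resolved to `X` with a loud warning
— preferring either method would be arbitrary, and in practice the two
methods are expected never to conflict. When both are ambiguous, a
**fallback** counts internal stop codons of the full assembled
isoform-2 DNA in each frame (a single terminal stop does not count as
internal); a unique stop-free frame is accepted. The fallback uses
isoform 2 — the longer structure, hence the stricter constraint — by
default; a flag additionally requires isoform 1 to be clean.

# Protein-level differences

With a frame in hand, both isoforms' exon chains are translated from
that frame. Translation deliberately does **not** stop at stop codons:
the full residue string, `*` included, is kept so the decomposition
below can show what an escaped or truncated product would look like;
the first-stop position is reported separately, both as a residue index
and as the genomic coordinate of its codon's first base (walked
through the exon structure, strand-aware). Consumers wanting the
biological product cut at the reported stop.

The two peptides are decomposed into four segments: longest common
prefix (`same_start_aa`), isoform-specific middles (either may be
empty), and the longest common suffix *of the post-prefix remainders*
(`same_end_aa`). Taking the suffix of the remainders, not of the full
strings, guarantees the segments partition each peptide exactly and
never overlap; ties favor the prefix. A frameshift is flagged when the
isoforms' total exonic lengths differ by a non-multiple of three
(shared flanks cancel, so this is the middle-segment difference; for
intron retention the "middle" is the retained intron).

# Visualizations

Three figure types are produced per event, each driven by a plain
coordinate table that is exposed for testing — the pixel layout is not
part of the contract, the coordinates are. The zoomed-in event view
colors exons light blue when every residue they contribute lies in the
shared prefix/suffix and light green otherwise, marks first stops in
red, and pairs with a per-sample PSI jitter panel. The zoomed-out view
places the event alongside the best-matching transcript, ranked by
exact boundary matches of the event's flanking exons (both exact > one
exact > overlap > none; ties to the longer transcript, then lexicographic
ID). The domain view collapses the transcript's exons end-to-end
(introns removed) and aligns protein domains on the same axis via
`nt = 5'UTR_offset + 3*(aa−1) + 1`; records sharing an accession are
merged by interval union first, since domain databases report the same
domain with slightly different boundaries, and domains running past
the transcript are clipped with a warning.

# The synthetic fixture

`generate_fixture()` builds a complete six-input dataset with known
ground truth. Genes are constructed codon-by-codon, not as random DNA:
each gene is an ORF (5'UTR, ATG, stop-free codons, terminal stop,
3'UTR) sliced into exons, with the planted event's first shared exon
rejection-sampled until its two off-frames contain stop codons and no
off-frame peptide of ≥ 7 residues occurs in the gene's protein — so the
true frame is discoverable by construction, by either method. A third
of genes sit on the minus strand, all six event types are planted on
both strands, and every second stored event row (and its count columns)
is deliberately written label-swapped to exercise normalization.
Counts are drawn from the same beta-binomial model the test assumes.

Defaults mirror a realistic autoimmune-cohort design: 14 case and 13
control samples, coverage 100–300 reads per event and sample,
differential events at PSI 0.7 vs 0.3, null events at 0.5/0.5, phi =
0.02, half the events null, plus two non-coding genes to exercise the
coding filter.

What the fixture does *not* emulate: alignment artefacts, coverage
that varies along the gene, correlated events within a gene, annotation
errors, or overdispersion heterogeneity across events. Passing the
end-to-end recovery test therefore demonstrates the internal
consistency and correctness of every pipeline stage on data obeying the
model's assumptions, not robustness to the ways real libraries violate
them.

# Numerical and design choices

* Coordinates are 1-based inclusive throughout (Ensembl-style);
  conversion to 0-based half-open happens only inside FASTA substring
  extraction.
* Codons containing `N` translate to `X`, which counts as neither stop
  nor match — conservative for both frame methods.
* The beta-binomial mass is computed on the log scale via `lchoose` +
  `lbeta`; `phi = 0` switches exactly to the binomial mass rather than
  approaching it.
* `adjust_bh()` implements the step-up rule directly (sorted cumulative
  minima of `p * m / rank`, capped at 1, original order restored); the
  test suite checks it against `stats::p.adjust(method = "BH")` to
  1e−12 on random vectors. Non-converged fits are excluded before
  adjustment so `m` counts only tested events.
* Problem sizes used by the checks: 2000 simulated null events for
  type-I calibration, 200 differential events for recovery/power, 500
  random exons and 200 exon-protein pairs for the frame-method oracles,
  and a 74-event fixture (all six types, both strands) end-to-end.
  These sizes give Monte-Carlo standard errors comfortably below the
  asserted bounds while keeping a full run in minutes.

# Known limitations

* The frame is predicted from the first shared exon; an event whose
  isoforms share no 5' boundary (possible with unusual upstream
  structures) is reported as frame `X` rather than guessed.
* Peptide matching depends on the supplied protein set; with no
  proteins for a gene the method abstains. Whether to supply canonical
  or all isoform proteins per gene is the caller's choice.
* The per-event model treats samples as independent; paired or batch
  designs are not modelled.
* Nonsense-mediated decay, signal peptides and structural consequences
  are out of scope; the output states where the protein changes, not
  what the cell does about it.

# A minimal run

```{r example, eval = FALSE}
fx <- generate_fixture(fixture_spec(seed = 1), dir = tempdir())
res <- run_pipeline(fx$paths$events, fx$paths$counts, fx$paths$genome,
                    fx$paths$annotation, fx$paths$proteins,
                    fx$paths$domains, out_dir = file.path(tempdir(), "out"),
                    translate_all = TRUE, figures_top = 5)
head(res$results)
res$agreement       # 4x4 ORF-method vs peptide-method matrix
```
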