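---
title: "Calling large structural variants from linked-read split molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling large structural variants from linked-read split molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitmol)
```

## The signal: split molecules

Linked-read sequencing barcodes large DNA molecules (tens of kbp) in pools
of roughly 2--30 molecules and sequences each pool shallowly (~0.1x per
molecule), so reads sharing a barcode trace the footprint of a handful of
long molecules. A molecule that spans a rearrangement breakpoint maps to the
reference as two disjoint intervals. `splitmol` exploits exactly this: it
reconstructs the molecules *in silico* ("submolecules"), finds pairs of
same-barcode submolecules that look like the two mapped halves of one broken
molecule ("candidate splits"), and asks whether candidate splits from
*different* pools agree on the breakpoints of one event ("split molecule
pairs"). Agreeing pairs are clustered on a graph, and clusters become calls
for five event types: deletions (> 100 kbp), inversions (80 kbp--7 Mbp),
interspersed segmental duplications in direct or inverted orientation
(40 kbp--7 Mbp, copied > 80 kbp away), and non-reciprocal translocations
(> 100 kbp).

The pipeline is a chain of tibble-in/tibble-out stages:

```{r pipeline, eval = FALSE}
truth <- withr::with_seed(1, random_svs(c(chr1 = 30e6), n_inv = 20))
sim <- simulate_linked_reads(sim_config(genome = c(chr1 = 30e6),
                                        svs = truth, seed = 1))
fit <- call_svs(sim)
tidy(fit)              # PASS calls
glance(fit)            # per-stage record counts
evaluate_calls(sim$truth, pass_calls(fit))
```

## Molecule recovery

Concordantly mapped FR pairs (insert within mean +/- 4 sd, estimated from
the data) become *fragments* spanning the full pair. Within each
(barcode, chromosome) group, fragments sorted by start are scanned once: a
fragment joins the open submolecule iff its gap to the submolecule's current
right end is at most `T`, or its start is within `Q` of the submolecule's
leftmost fragment. Defaults are `T = mu/4` and `Q = 2*mu` with `mu` the mean
molecule size; submolecules shorter than 3 kbp are discarded (a relative
mode, 10% of `mu`, is also available). The gap is measured from the running
right end — the only reading consistent with a single left-to-right sliding
window; the `Q` clause then extends long, sparsely sequenced molecules.

Because `mu` is only known after recovery, `recover_molecules()` runs two
passes: the first with a configurable prior (45 kbp), the second with
`T`/`Q` derived from the sizes the first pass recovered. One refinement is
deterministic and, on data with the assumed structure, lands within a few
percent of the truth; iterating to convergence buys nothing measurable.

A consequence worth knowing: an event of size below ~`Q` can fail to split
the molecules that cross it (both halves stay within `Q` of the anchor and
merge back together). With 50 kbp molecules this affects events near the
80--110 kbp floor, which is an intrinsic property of this parameterization,
not an implementation accident.

## Candidate splits and split-molecule pairs

All same-barcode, same-chromosome submolecule pairs whose spans sum to at
most `mu + 3*sigma` are candidate splits (a longer pair cannot be one
molecule). Cross-chromosome pairing is never done exhaustively: for
translocations, inter-chromosomal discordant read pairs act as anchors and
same-barcode submolecules within one molecule length of each anchor end are
attached. Candidate splits with no discordant read pair landing near both
halves are dropped before the quadratic pairing step; the windows for this
are padded by the concordant insert bound *plus* the breakpoint window,
because a recovered submolecule edge sits up to a fragment gap away from the
true junction.

Pairing across barcodes is geometric. Each split constrains breakpoints via
its submolecule edges; for example a deletion requires both splits to gap
over the same interval, while an inversion pairs one split whose submolecule
*ends* sit at the two breakpoints with one whose submolecule *starts* do.
Edges constrain the truth one-sidedly (a gap start is a lower bound for the
breakpoint), so each breakpoint interval is built from the tightest bound
plus a window `w` (default `T`). Two estimates of the same breakpoint must
agree within `w`. A non-reciprocal translocation has three candidate-split
shapes — one at each insertion junction (inter-chromosomal) and one over the
deleted source (deletion-like, intra-chromosomal) — and any cross-barcode
combination of two of them that agrees on the breakpoints is accepted.

Discordant-pair support then applies, with orientation classes per type:
FR pairs with an oversized span for deletions; FF at the left and RR at the
right breakpoint for inversions; RF (everted) plus far-FR junction pairs for
direct duplications; FF/RR junction pairs for inverted duplications;
inter-chromosomal pairs for translocations. An event needs at least 3
supporting pairs in total; additionally every junction of a 3-breakpoint
event needs at least one pair of its own, and a translocation's source must
show the deletion-type far-pair junction. Without the per-junction rule, a
single well-supported junction can carry a chimeric pairing of one real and
one coincidental split to a call; requiring each junction to be bridged is
the cheap and faithful fix, since every junction of a real event produces
discordant pairs.

## Clustering and calling

Split-molecule pairs are vertices; an edge joins two pairs of the same type
whose corresponding breakpoint intervals all overlap (>= 1 bp — the
intervals are already molecule-gap-sized, so a reciprocal criterion would
only fragment true clusters). Within each connected component we repeatedly
extract a dense vertex set: remove the minimum-degree vertex until the
induced edge count reaches `gamma * choose(|V|, 2)` (`gamma = 0.6`), then
add back removed vertices that keep the bound, report the set if it has at
least `min_support` vertices spanning `min_support` distinct barcodes
(4 by default, 2 in haploid mode), remove it, and repeat. Vertex order is
fixed by (chromosome, breakpoint, id), ties on removal prefer keeping the
smaller leftmost coordinate, so output is deterministic. The heuristic is a
standard densest-subgraph peel; on graphs small enough to enumerate it stays
within one vertex of the exhaustive optimum (asserted in the test suite).

A clique becomes a call whose breakpoint intervals are the intersection of
the members' intervals when non-empty, otherwise the median endpoints.
Support is re-annotated against the call's own intervals. Same-type PASS
calls overlapping > 50% reciprocally (with agreeing insertion loci) are
merged at reporting, so one event yields one call.

## Molecule-depth filtering

Molecule depth — submolecules per position, binned at 10 kbp — is the
physical analogue of read depth, and copy-number-changing events must move
it. With genome-wide mean and sd over unmasked bins, calls are kept iff:

| type | keep condition on source-interval depth |
|------|------------------------------------------|
| DUP  | `depth >= mu_depth + sigma_depth` |
| DEL  | `depth <= 0.5*mu_depth + 0.5*sigma_depth` |
| TRA  | `mu_depth - 1.5*sigma_depth <= depth <= mu_depth + 1.5*sigma_depth` |
| INV  | always (copy-neutral) |

The discard conditions are strict inequalities, so boundary values are
kept. The translocation band deserves a note: a non-reciprocally moved
segment keeps its copy number — its reads still map to the source
coordinates — so true translocations show *normal* source depth, a gain
there indicates a duplication, and a plain loss a deletion. The "source"
interval is taken between the midpoints of breakpoint intervals 1 and 2, and
depth over it is the length-weighted bin mean (grid-phase independent).

## What the simulator emulates — and what it does not

`simulate_linked_reads()` samples molecules (lognormal sizes, sdlog 0.7 —
long right tail with many short molecules; exponential is available) on
donor haplotypes built by applying the planted variants to the reference
coordinate space, partitions them into pools of uniformly 2--30 molecules,
places read pairs at ~0.1x per-molecule coverage (150 bp reads, 500 bp mean
insert), and maps every read back through the piecewise donor-to-reference
map. Reads on SV-spanning molecules therefore produce split mappings and
discordant orientations exactly as a mapper would report them. Positional
noise is a small Gaussian jitter plus a configurable fraction (1% by
default) of pairs whose second mate is relocated uniformly — enough to
exercise the support and depth filters.

Default study conditions: 30 Mbp single-chromosome genomes (2 x 20 Mbp for
translocations), 20 planted events per replicate (10 translocations),
50x physical coverage, event sizes log-uniform within each class's
detection window (deletions 120--400 kbp, inversions 100--600 kbp,
duplications 50--300 kbp, translocations 120--400 kbp — the upper ends are
bounded by what 20 non-overlapping events fit on a 30 Mbp genome, not by
the caller's 7 Mbp cap). Variants are planted homozygous by default. That
choice comes from a power calculation, not convenience: at ~50x physical
and ~0.1x per-molecule coverage the aggregate sequence coverage is ~5x,
which puts a *heterozygous* junction at an expectation of about 4
discordant pairs against the method's fixed >= 3-pair threshold — roughly a
fifth of het events would then fail on Poisson noise alone, an artifact of
desk-scale coverage rather than a property of the algorithm. Homozygous
planting preserves the signal-to-threshold ratio of the full-scale setting;
`het` and `mixed` zygosity modes are implemented for studying exactly that
degradation.

What passing these simulations does **not** show: robustness to mapping
ambiguity in repeats (reads are placed exactly, mismapping is uniform
noise), barcode errors or collisions, sequencing errors, reference bias, or
chimeric library artifacts — the main false-positive sources in real data.
Accuracy on real linked-read libraries will be lower than on these
fixtures, which is the usual relation between a generative test bed and
biological data.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; conversion happens only in
  the VCF writer (1-based, interval midpoints, `CIPOS`/`CIEND`).
* Breakpoint windows use `w = T = mu/4` by default; support windows pad by
  the concordant insert bound.
* Interval intersections that come up empty fall back to median endpoints;
  degenerate zero-width intervals are widened to 1 bp.
* Empty inputs yield an empty call set with zeroed stage counts; fewer than
  two submolecules is a fatal error for size estimation; a call whose source
  interval leaves the depth profile is flagged `no_depth` and excluded from
  PASS.
* Per-barcode candidate splits are capped (128, largest spans first) to
  bound the quadratic pairing step; the cap is far above anything the
  default conditions produce.
* The evaluation protocol is strict: reciprocal overlap must *exceed* 50%
  (an exact 50/50 split is no match), insertion loci must agree within
  `mu/2`, matching is one-to-one greedy by overlap so one broad call cannot
  absorb several truths, and undefined ratios are reported `NA`, never 0.

## Known limitations

* Reciprocal and inverted translocations are not modelled; a reciprocal
  event would surface as two non-reciprocal candidates sharing breakpoints.
* Translocation discovery is inter-chromosomal only; an intra-chromosomal
  distant move surfaces as a deletion plus duplication signature instead.
* Events within ~2 molecule lengths of a class's size floor lose split
  molecules to the `Q`-merge described above.
* The depth filter assumes fairly uniform coverage; on real data with
  mappability structure the genome-wide sd widens and the deletion band
  loosens accordingly.
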