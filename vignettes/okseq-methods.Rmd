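---
title: "Models and methods: origin efficiency, fork progression and polymerase usage from nascent-strand reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okseqr)
```

This vignette is the package's own account of its science: the model
behind each statistic, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator emulates (and what it
does not — hence what a green test does and does not establish), the
numerical conventions, and known limitations.  It states no empirical
result that the test suite does not itself compute.

## 1. The measurement model

In a ligase-depleted cell, Okazaki fragments accumulate on the nascent
lagging strand and can be sequenced strand-specifically.  A rightward
moving fork synthesizes its lagging strand on the Crick strand, a
leftward fork on the Watson strand, so the strand of a fragment reports
the direction of the fork that made it.  Around an origin that fired in a
given cell, forks diverge: Watson fragments to the left, Crick to the
right.  In cells where the origin did *not* fire, the locus is replicated
passively by a fork from a neighboring origin, which contributes the
opposite (convergent) pattern on one flank.

The **origin efficiency metric** aggregates this over a population.  With
Watson/Crick counts $W_L, C_L, W_R, C_R$ in the $\pm f$ flanks of the
origin midpoint ($f = 10$ kb by default),

$$\mathrm{OEM} \;=\; \frac{W_L}{W_L + C_L} \;-\; \frac{W_R}{W_R + C_R}
  \;\in\; [-1, 1].$$

OEM estimates the fraction of cells with *productive* firing — firing
that synthesized appreciable lagging-strand DNA.  Abortive initiation
without synthesis is invisible, and an origin whose flanks carry no reads
has an undefined OEM, which the package reports as `NA` and excludes from
summaries (never imputing 0).

Two conventions are deliberate and covered by tests:

* **Midpoint assignment.**  A fragment belongs to the bin or flank that
  contains its midpoint.  This keeps count conservation exact (each
  fragment counted exactly once) and avoids double-counting across
  window boundaries; OEM and the bias profiles are read-count fractions,
  not per-base depth, so midpoint assignment is the natural estimator.
  Whether per-base overlap coverage would change the fork-progression
  metaprofiles materially is an open sensitivity question; midpoint
  counting is the package-wide rule.
* **Half-open flanks.**  Left flank $[m - f, m)$, right flank
  $[m, m + f)$: a fragment whose midpoint falls exactly on the origin
  midpoint counts right.  Flanks running past a chromosome end are
  truncated, not dropped.

Because passive replication erodes OEM as S phase progresses, conditions
whose S phases run at different speeds must be compared at **matched
replicated-fraction checkpoints**.  For sequencing data the package
matches timepoints by coverage similarity (`match_timepoints()`: 1 −
Spearman correlation of depth-normalized binned total coverage; an L1
alternative is available).  Spearman was chosen because it is invariant
to sequencing depth and to any monotone distortion of coverage, which is
exactly the family of nuisances a loading difference introduces.  For
simulations the matching is analytic (`time_at_replicated_fraction()`).

## 2. The S-phase simulator

`sphase_model()` states a generative world; `simulate_cell()` realizes
one cell from it:

1. Each origin $i$ fires with probability $p_i$ (its *competence*),
   independently per cell, at a time $T_i \sim$ Normal$(\mu_i, \sigma_i)$
   truncated at 0.  Competence and time are independent; there is no
   re-licensing.
2. A fired origin launches two forks at speed $v$ bp/min.  A locus $x$ is
   replicated when the first fork arrives:
   $\min_i [T_i + |x - x_i| / v] \le t$.  Its direction is that of the
   arg-min origin (rightward if that origin lies at or left of $x$); ties
   between convergent forks resolve toward the leftmost source, and
   termination happens exactly at the meeting point — no termination
   zones, no stalling, no checkpoint feedback.
3. Okazaki fragments are emitted at `frag_rate` per replicated
   lagging-strand kb, with lengths from Normal(`frag_len_mean`,
   `frag_len_sd`), strand Crick behind rightward forks and Watson behind
   leftward forks.
4. Ribonucleotide 5′-end reads are emitted per polymerase: Pol ε on the
   nascent leading strand at `r_pole`/kb, Pol δ uniformly on the lagging
   strand at `r_pold`/kb, Pol α near Okazaki-fragment 5′ ends at
   `r_pola`/kb (exponential offset, mean 15 bp, from the 5′ edge of
   fragment-sized tiles).  The read strand is the strand of the nascent
   strand holding the ribonucleotide.
5. SbfI loading-control reads are Poisson(`depth`) per configured site.
6. A depletion condition `deplete(model, d)` multiplies every competence
   and the fork speed by $d \in (0, 1]$; flags can decouple the two,
   since reduced firing and slower progression are distinct observables.
   An optional `reroute` fraction moves that share of lagging-strand
   synthesis from Pol δ to Pol ε — the "alternative polymerase takes
   over" scenario the HydEn-seq comparison is designed to detect.

Randomness is one base seed with per-cell substreams derived
deterministically from (seed, cell index), so any cell can be regenerated
in isolation and pooled runs are byte-reproducible.

### Parameter defaults and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `fork_speed` | 1500 | bp/min | the order measured for budding-yeast forks |
| `frag_len_mean` | 165 | bp | nucleosome-periodic Okazaki fragment size |
| `frag_len_sd` | 30 | bp | moderate spread around the periodicity |
| `t_mean`, `t_sd` | 15, 5 | min | mid-S firing with realistic dispersion |
| `competence` | 0.6 | — | a moderately efficient origin |
| `frag_rate` | 0.05 | frags/kb/cell | sequencing-depth knob; default gives a few hundred reads per origin flank from 1000 cells |
| `r_pole` | 2 | events/kb | a ribonucleotide-hypersensitive Pol ε variant dominates incorporation |
| `r_pold`, `r_pola` | 0.1, 0.05 | events/kb | background incorporation by wild-type Pol δ / Pol α |

The `r_pole`-dominated defaults emulate the strain in which Pol ε usage
is traced; with them, the ribonucleotide strand bias is a mirrored,
slightly attenuated copy of the Okazaki bias (attenuation
$(1 - 2\beta)$ where $\beta$ is the lagging share of ribonucleotide
events).  That attenuation is what makes the take-over criterion
(section 4) conservative in the no-rerouting case.

### One emission detail

The specification of fragment emission as "length clipped to the
replicated interval" was changed to *midpoint-uniform* placement with
spans clipped only at chromosome ends.  Clipping spans at
direction-boundary points compresses the midpoints of boundary-straddling
fragments into the last half-length of every interval, doubling the
midpoint density there; the artifact bin then becomes the normalization
constant of every max-normalized metaprofile.  Midpoint-uniform placement
keeps the midpoint density exactly uniform — which is the quantity all
downstream statistics consume — at the cost of letting a fragment's span
protrude past the termination point it physically could not cross.  Since
no analysis in the package reads spans except through midpoints, the
trade is safe.

## 3. The independent OEM oracle

`expected_oem_oracle()` computes expected OEM without simulating reads.
For a position $x$, the best rightward arrival time $A$ is the minimum of
$T_i + (x - x_i)/v$ over origins at or left of $x$, and similarly $B$
leftward.  Origins are independent, so on a discretized time grid
$P(A > t) = \prod_i \bigl(1 - p_i F_i(t - d_i/v)\bigr)$ — a product of
survival functions that is mathematically identical to the exhaustive
enumeration of fire/not-fire patterns weighted by competences, without
the $2^k$ cost.  Then

$$P(\text{replicated rightward by } t_s)
  = \sum_{g \le t_s} P(A \in \text{cell } g)\, P(B \ge g),$$

with the tie ($A = B$ within a grid cell) awarded to the rightward side,
matching the simulator's leftmost-source tie-break.  Expected flank
masses are integrals of these probabilities over the flanks (every
replicated base contributes equal lagging-strand read mass), combined by
the OEM formula.  Defaults: time grid 0.2 min, spatial stride 50 bp;
the residual discretization bias is ~0.005 on closed-form cases, an
order below the Monte-Carlo tolerances the tests use.  A guard refuses
more than 64 origins per chromosome and instructs chromosome-wise
chunking.

The closure test (acceptance criterion 2) compares pipeline OEM from
5000 pooled cells against the oracle within 3 Monte-Carlo standard
errors.  Fragments from one cell share that cell's fork-direction
pattern, so the SE uses the *cell* as the effective sampling unit: a
binomial flank SE inflated by the mean number of fragments per
contributing cell (`oem_se()`), which is conservative (it assumes full
within-cell correlation).

## 4. Design choices in the analyses

* **Pooled, not averaged, profiles.**  `strand_bias_profile()` computes
  fractions on counts pooled across origins; per-origin averaging exists
  behind `per_origin_mean = TRUE` but is not the default, because pooled
  fractions are what deeply-sequenced population data estimate.
* **Early-origin selection** is an explicit criterion on the earliest
  timepoint's OEM table (threshold, default 0.4, or top-N), because at an
  early timepoint only early efficient origins carry strand-bias signal.
  The underlying definition in the source analyses is ambiguous, so the
  criterion is a named, configurable parameter rather than a buried
  constant.
* **Stranded metaprofile gating** uses the printed ranges exactly:
  Watson in $[-20, -1]$ kb, Crick in $[+1, +20]$ kb, with the 1 kb
  exclusion zones around the origin; normalization is by the single
  global maximum of the raw profile, not per-arm maxima.
  `front_position()` (level 0.5, linear interpolation between bin
  centers) is a reporting convention, recorded in output metadata.
* **Paired t-test** for condition comparison, exactly as the experiment
  demands (one global comparison, no multiple-testing correction);
  degenerate inputs (all differences numerically equal) are reported
  directly rather than passed to `t.test()`.
* **HydEn-seq conventions.**  A ribonucleotide location is the single 5′
  base; site-read removal uses half-open membership; the SbfI denominator
  comes from the same library (an external site-read file is accepted);
  the chrXII exclusion is a configurable default, not hard-coded, and the
  end-mapping strand orientation has an inversion flag because upstream
  protocol dialects differ.
* **Polarity-matched take-over criterion.**  The Okazaki delta is
  re-expressed on Watson fractions when compared against a leading-strand
  tracer (`flip_okazaki_strand`) or kept on Crick fractions for a
  lagging-strand tracer (`same`); the summary asks whether the
  ribonucleotide change is smaller in magnitude than the Okazaki change.

## 5. What the generator emulates — and what it does not

The simulator reproduces: stochastic firing with per-origin competence
and timing, passive replication and its erosion of OEM, fork-speed
effects on metaprofiles, depth-independent SbfI normalization,
polymerase-specific ribonucleotide strands, and a global depletion
condition.  It does **not** emulate replication-timing chromatin domains,
fork stalling or collapse, checkpoint feedback, termination zones,
sequence composition, mappability, or copy-number artifacts (the rDNA
exclusion exists precisely because real chromosome XII violates the
uniform-mappability idealization).  A green parameter-recovery test
therefore establishes the correctness of the *computations* under the
stated stochastic model — not robustness to every artifact of real
libraries.

Two model properties discovered while building the acceptance suite are
worth stating plainly:

* **OEM ranks firing fractions cleanly only in comparable passive
  contexts.**  With origins on a regular grid, the Spearman correlation
  between late-S OEM and the true fired fraction exceeds 0.95; with
  irregular spacing it degrades (≈0.89 in our prototypes), because
  passive replication pressure differs per origin.  This is a property of
  the metric, not a bug, and real origin lists are irregular — rank
  comparisons of OEM across origins should be read with that caveat.
* **Very early matched checkpoints cannot see depletion.**  At a matched
  replicated fraction of ~0.25, halving every competence leaves OEM
  essentially unchanged (slightly higher, if anything): with negligible
  passive replication, the flanks of a fired origin look fully divergent
  regardless of how many cells fired.  The depletion signature appears
  once passive forks contribute; the acceptance comparison therefore uses
  a mid-S checkpoint (replicated fraction ≈ 0.56), where every origin
  falls below the identity line.

## 6. Numerical conventions and degenerate inputs

* All coordinates are 0-based half-open (BED convention); output headers
  state this.
* The replication boundary base at exactly $v\,t$ from its origin is
  replicated (the arrival condition is $\le$).
* Duplicate removal is exact (chrom, start, end, strand) equality — no
  UMIs; chromosome names match exactly, with no implicit "chr" stripping.
* BEDPE fragments are the outer span of the pair; the strand comes from
  mate 1 by default (`mate_strand` parameter, since mate orientation is
  protocol-dependent).
* Zero-count degenerate cases are explicit: empty flank → `NA` OEM;
  all-zero metaprofile → error (normalization undefined); zero SbfI
  denominator → density `NA` with status `"undefined"`; empty early-origin
  selection → error.
* Seeds are kept below $2^{31}$; per-cell substream seeds are derived by
  a fixed integer recurrence.

## 7. Known limitations

Beyond the emulation gaps above: the simulator models speed, not
stalling (the two are not distinguishable in this readout anyway); OEM
cannot count abortive initiations; `match_timepoints()` assumes the two
conditions share binning and genome; and the oracle's discretization,
while far below Monte-Carlo noise at defaults, is not exact — closed-form
tests use a 0.01 absolute tolerance for it.
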