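---
title: "Damage-aware consensus reconstruction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damage-aware consensus reconstruction: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
```

## The damage process and what the caller assumes

Post-mortem hydrolytic deamination converts cytosine to uracil, sequenced as
thymine. Single-stranded library preparation preserves the original molecule
strand, so the substitution appears as C→T on forward-mapping reads and as
G→A on reverse-mapping reads, and it is strongly concentrated at fragment
termini where single-stranded overhangs are exposed. The caller assumes:

* reads are already mapped, adapter-trimmed and deduplicated (upstream
  pipeline territory); this package consumes SAM/BAM and a reference FASTA;
* libraries are non-UDG single-stranded, i.e. both ends carry C→T damage in
  molecule coordinates — which is why profile lookups anchor to the *nearer*
  alignment end by default;
* the consensus is defined on reference coordinates: inserted read bases are
  ignored and deleted reference positions simply receive no entry, because
  the method is per-position base calling, not an assembler;
* base qualities are not used in calling; the damage model replaces them.

## Calling model

For a reference position with informative pileup entries (entries whose base
is `N` are never counted anywhere), let the per-base tallies be
$n_A, n_C, n_G, n_T$. A base is called when

* coverage ≥ `min_cov` (default 3), and
* support = max tally / total tally ≥ `min_support` (default 0.65),

both inclusive; otherwise the position is the non-informative base `N`. A
2-of-3 column (66.7%) is therefore callable at the defaults. With
`min_support > 0.5` an argmax tie always has support ≤ 0.5 and yields `N`,
so no tie-break rule is needed (asserted by a property test).

The four modes differ only in how tallies and coverage are formed:

* **none** — raw counts; coverage gate on the raw entry count.
* **pol_silence** — positions where the reference base is C and any forward
  read shows T are flagged (mirror: reference G, reverse-read A); at flagged
  positions the matching damage-pattern bases are treated as `N`. The
  coverage gate applies to the *post-silencing* count by default
  (`cov_basis = "effective"`): a silenced base has been declared
  uninformative, so it should not attest coverage either. The alternative
  (`"raw"`) is available because this choice directly drives the N counts
  and the literature does not fix it.
* **free_silence** — same silencing, but a position is flagged from the read
  stack alone: (1) at least one forward-read T and (2) a C observed in any
  read, regardless of orientation (mirror for G/A). The observed C witnesses
  the undamaged allele, so flagging requires actual variation rather than
  disagreement with a possibly distant reference.
* **free_weight** — every entry contributes a weight to its base's tally:
  forward T gets $1-d$, forward C gets $1+d$, reverse A gets $1-d$, reverse
  G gets $1+d$, everything else 1, where $d$ is the entry's position-specific
  damage frequency. A balanced T/C pair at one end distance keeps total mass
  $(1-d)+(1+d)=2$, equal to its raw count. The coverage gate uses the
  *unweighted* entry count by default (`weight_cov = "raw"`): weights encode
  base-identity confidence, not molecule existence; `"weighted"` is
  available. Damage flags are still computed (polarization-free variant) and
  reported, but never alter weighted calls. In mode `none` flags are likewise
  computed for reporting parity only.

Reported per sample: the number of flagged ("potentially damaged")
positions — the union of the C→T and G→A flags — the total and percentage
of `N` calls, and how many `N`s fall at flagged positions.

## Damage-profile estimation

`estimate_profile()` measures, per distance $i$ from each alignment end
within a window of $W=25$ read positions, the frequency of T among forward
entries over reference C (`ct5`, `ct3`) and of A among reverse entries over
reference G (`ga5`, `ga3`). Estimation is deliberately reference-polarized
even when calling is polarization-free: the profile characterizes the
sample's damage chemistry, where reference comparison is the standard
instrument; only the per-position calling decision avoids the reference.
Choices:

* $W=25$ covers the conventional display range of misincorporation plots and
  keeps the tail cells, where damage has decayed, out of the weights.
* The baseline applied beyond the window is the pooled rate over the
  innermost five window cells of the corresponding curves; cells with zero
  denominator inherit the baseline rather than 0, avoiding spuriously
  certain weights at rarely covered distances.
* Lookups use the nearer alignment end (`anchor = "nearer"`), appropriate
  for both-end single-stranded damage; a `"five_prime"` anchor is available
  for comparison with tools that tabulate a single curve. Whether the
  orientation-specific curves should be pooled is not settled usage; the
  package keeps them separate (forward entries read the C→T curves, reverse
  entries the G→A curves) and records the anchor in the profile metadata.
* Profiles serialize to a TSV plus JSON sidecar, so profiles from external
  damage tools can be imported.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere except the human-readable
  call log (1-based), stated once to avoid off-by-one drift.
* The support threshold is applied with $10^{-9}$ slack: weighted tallies
  can land one ulp below an exactly attained boundary (e.g. $2.47/3.8$
  versus $0.65$) depending on summation order, and the boundary is defined
  as inclusive.
* Weights are clamped to a $10^{-9}$ floor so a sparse profile cell
  estimated at $d=1$ cannot zero out an entry entirely.
* An empty pileup region yields `N` (coverage 0); an empty pileup cannot be
  profiled (error); a read overhanging a *linear* reference end is an error,
  since it signals that upstream mapping was not circular-aware. On circular
  references the pileup wraps coordinates modulo the genome length, and the
  simulator writes origin-spanning reads as single SAM records whose
  alignment extends past the stated reference length — a convention the
  reader reverses exactly.
* A mapping-quality filter is *not* re-applied at consensus time by default
  (upstream mappers filter at alignment time); `min_mapq` is exposed for
  parity.

## The simulator: what it emulates and what it does not

The generator emulates shotgun data from deep-time single-stranded
libraries. Defaults are the study conditions the package is validated
under:

| parameter | default | meaning |
|---|---|---|
| `frag_mean` | 34 bp | mean fragment length after truncation |
| `min_len` | 30 bp | shortest retained fragment (trimming convention) |
| `frag_shape` | 0.25 | lognormal sdlog of the length distribution |
| `damage_amp5` | 0.72 | terminal 5′ C→T amplitude (molecule coordinates) |
| `damage_amp3` | 0.40 | terminal 3′ amplitude — a package choice, freely configurable |
| `damage_decay` | 3.0 | exponential decay scale, read positions |
| `damage_baseline` | 0.02 | interior residual deamination |
| `seq_error` | 0.001 | uniform, strand-symmetric sequencing error |
| `p_forward` | 0.5 | forward-orientation probability |

Fragment lengths are lognormal truncated at `min_len`, with the meanlog
solved numerically so the *truncated* mean equals `frag_mean` — matching the
right-skewed ~34 bp post-filter means typical of such data while staying a
two-parameter model. Each molecule-strand C at distances $i$ (5′) and $j$
(3′) deaminates with probability
$\min(1,\ a_5 e^{-i/\lambda} + a_3 e^{-j/\lambda} + b)$. Note the realized
terminal rate is therefore $a_5 + b$ (0.74 at the defaults), and that is
the quantity the profile estimator recovers; recovery tests compare against
this model-implied rate. Damage is asymmetric by construction (C→T in
molecule coordinates only), while sequencing error is symmetric — which is
exactly what lets tests distinguish the two channels. Every damage event is
logged, making the simulator its own oracle.

Not modeled: PCR duplicates, contamination mixtures, bacterial background,
capture bias, realistic per-cycle sequencer error profiles, UDG-treated
libraries, indels. Passing tests therefore demonstrate correctness of the
calling logic under the stated damage chemistry and coverage, not robustness
to every artifact of real capture data; coverage in the simulator is near
uniform, whereas real enrichment data can be very uneven, which mainly
inflates the `N` fraction through low-coverage tails.

## Sex inference

The length-normalized X:autosome read-density ratio is ~0.5 in males (one X)
and ~1 in females. The classification bands — male [0.35, 0.65], female
[0.8, 1.2], undetermined otherwise, at least 100 total reads — are package
policy chosen symmetric and non-overlapping around the two expectations, and
fully configurable. Degenerate inputs (zero autosome reads, empty tables)
return an explicit `undetermined` with a reason rather than failing.

## Validation problem sizes

The shipped tests validate the methods on simulated genomes of 300–16,660 bp
at 3–40× coverage; the deepest checks use a 16,660 bp circular genome — a
typical mammalian mitogenome length — at 10× with terminal amplitude 0.7 and
100 true variants, and ~20,000 reads for profile recovery. The exhaustive
caller-versus-oracle comparison enumerates every base-by-orientation column
of up to four entries and samples 100,000 larger ones. These sizes were
chosen to make sampling error small relative to the effects under test while
keeping the suite quick to run.

## Known limitations

* The consensus is haploid by construction; heteroplasmy and nuclear
  mitochondrial insertions are outside the model (support below threshold
  simply yields `N`).
* Silencing modes can erase genuine variation: a true T over a reference C
  with few reverse reads is indistinguishable from damage to the polarized
  method — this is the motivating failure mode the weighting mode addresses,
  and it is demonstrated directly in the test suite.
* Damage weights are estimated against the chosen reference; a grossly wrong
  reference biases the profile itself, not just polarized flagging.
* CRAM input and quality rescaling of output BAMs are not provided.
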