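# paleomito

Damage-aware mitochondrial consensus reconstruction for ancient DNA.

## The problem

DNA surviving in very old bones is fragmented into pieces of roughly 30–40 bp
and chemically altered: hydrolytic deamination converts cytosine to uracil,
which sequencers read as thymine. In single-stranded library preparations the
original molecule strand is preserved, so this damage shows up with a
characteristic asymmetry — C→T substitutions on forward-mapping reads and
G→A on reverse-mapping reads — concentrated at fragment ends, where terminal
rates can exceed 70%. For low-coverage mitochondrial data this creates a
dilemma: calling a consensus without correction risks miscalls from damage,
while masking every damage-looking base throws away real sequence, including
genuine C→T variants that distinguish the ancient individual from the modern
reference.

`paleomito` implements four consensus-calling modes spanning that trade-off,
for anyone reconstructing mitogenomes (or other small circular genomes) from
heavily damaged reads:

* **none** — plain coverage/frequency calling, no damage handling.
* **pol_silence** (polarization-based damage silencing) — where the reference
  has a C, forward-read Ts are converted to N before calling (reverse-read As
  where the reference has a G). Classical, but unreliable when the sample is
  evolutionarily distant from the reference.
* **free_silence** (polarization-free damage silencing) — a position is
  flagged from the read stack alone: at least one forward-read T *and* a C
  observed in any read (plus the G/A mirror). Flagged damage-pattern bases
  are silenced; the reference is never consulted.
* **free_weight** (polarization-free damage weighting) — no base is
  discarded. Using the sample's estimated damage profile, a damage-prone base
  with position-specific damage frequency *d* is down-weighted to 1 − *d* and
  its undamaged counterpart up-weighted to 1 + *d* (forward T/C and reverse
  A/G pairs), keeping the total mass of a balanced pair at 2. Weighted tallies
  then feed the usual thresholds.

In every mode, a position is called only with coverage ≥ 3 and support for
the most frequent base ≥ 65% (both inclusive, both configurable); anything
else becomes `N`. The damage profile is estimated from the alignment itself
(per-end, per-orientation mismatch curves over the 25 terminal read
positions), and the pileup engine is circular-aware, so reads spanning the
mitochondrial origin wrap correctly.

The package also includes genetic sex inference from length-normalized
X-vs-autosome read counts (density ratio ≈ 0.5 male, ≈ 1 female), and a
single-stranded-library read simulator with known truth — fragment lengths,
positional deamination, sequencing error, circular coordinates — so every
mode can be validated end to end without any external data.

## Worked example

Simulate a deep-time-like sample — 16,660 bp circular genome, 10× coverage,
72% terminal deamination, 100 true variants — then estimate its damage
profile and reconstruct the consensus:

```r
library(paleomito)
set.seed(99)
ref <- new_reference("mt_demo",
                     paste(sample(c("A","C","G","T"), 16660, TRUE), collapse = ""))

cfg   <- simulation_config(seed = 99, target_cov = 10,
                           damage_amp5 = 0.72, n_variants = 100)
truth <- mutate_reference(ref, cfg$n_variants, cfg$seed)
sim   <- simulate_reads(truth, cfg)
pile  <- build_pileup(sim$reads, ref)
prof  <- estimate_profile(pile)
print(prof)
#> <damage_profile> window 25, anchor 'nearer'
#>   5' C>T terminal: 0.748   3' G>A terminal: 0.713
#>   baselines: C>T 0.0472, G>A 0.0500

res_w <- reconstruct(pile, ref, calling_params("free_weight"), prof)
res_s <- reconstruct(pile, ref, calling_params("free_silence"))
print(summary(res_w))
#> mode: free_weight
#> mean coverage: 10.00x (99.9% of positions at >=3x)
#> N calls: 26 (0.16%)
#> damaged positions: 4174, of which called N: 10
print(res_s)
#> <consensus_result> mt_demo (16660 bp), mode 'free_silence'
#>   non-informative: 37 (0.2%); flagged damaged positions: 4174 (21 called N)

cmp <- compare_to_truth(res_w, truth)
cat(sprintf("miscalls: %d of %d called positions\n", cmp$n_miscall, cmp$n_called))
#> miscalls: 1 of 16634 called positions
```

The terminal 5′ C→T estimate (0.748) recovers the simulated deamination
chemistry (amplitude 0.72 plus the 0.02 interior baseline). Weighting calls
N at 10 of 4,174 flagged positions versus 21 for polarization-free
silencing — the same qualitative reduction seen on real deep-time samples —
while keeping the miscall rate at the 10⁻⁴ level and recovering the
introduced variants.

Results are written with `write_consensus()` (FASTA), `write_call_log()`
(per-base TSV audit) and `write_summary_json()`. The same workflows are
available from a shell via the CLI wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "paleomito", package = "paleomito"))')
Rscript $CLI call --bam reads.sam --ref mt.fasta --mode free-weight \
    --estimate-profile --out cons.fasta --log calls.tsv --summary summary.json
Rscript $CLI simulate --ref mt.fasta --seed 7 --coverage 10 --out-dir sim/
Rscript $CLI sexdet --idxstats idx.tsv --x-name chrX --autosome-name chr3
```

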