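# diskfret

Lifetime-based Förster resonance energy transfer (FRET) analysis for
covalently coupled protein-disk chromophore arrays.

## The problem

Ring-shaped pigment assemblies — the LH1/LH2 antenna complexes of
photosynthetic bacteria — funnel excitation energy between circular
chromophore arrays. A synthetic mimic can be built from circularly permuted
tobacco mosaic virus coat protein (cpTMV): each double disk carries 34
attachment sites in two stacked 17-site rings, one disk fully labelled with
a donor dye and a second with an acceptor dye, the two joined covalently at
their peripheries. Energy transfer from the donor disk to the acceptor disk
shows up as a shortening of the donor fluorescence lifetime, measured by
time-correlated single photon counting (TCSPC).

`diskfret` implements the full downstream analysis of such an experiment,
plus the synthetic data needed to validate it:

* **Simulation** — TCSPC decay histograms from a known multiexponential
  truth, convolved with a Gaussian instrument response (default FWHM
  150 ps) with multinomial or Poisson counting noise
  (`decay_components()`, `gaussian_irf()`, `simulate_histogram()`).
* **Fitting** — mono/biexponential iterative reconvolution by weighted
  Levenberg–Marquardt, with asymptotic standard errors, amplitude
  fractions and reduced χ² (`reconvolution_fit()`, `compare_models()`).
* **FRET inference** — from the donor lifetime without (τ_D) and with
  (τ_DA) coupled acceptors:

  1/τ_T = 1/τ_DA − 1/τ_D,  k_T = 1/τ_T,  E = 1 − τ_DA/τ_D

  (`transfer_timescale()`, `transfer_rate()`, `fret_efficiency()`,
  `fret_estimate()`).
* **Geometry** — an idealised model of two coupled ring-array disks,
  calibrated so the closest donor–acceptor pair sits at a stated distance,
  and the distance-only pathway weights p_i = R_i⁻⁶ / Σ R_j⁻⁶ that show
  transfer is distributed over many pairs (`couple_disks()`,
  `pathway_table()`).

## Worked example

The packaged table of fitted lifetime components
(`lifetime_table_path()`) describes seven samples; sample 3 is the
donor-only disk and sample 7 the coupled donor–acceptor assembly.
Running the one-command reproduction:

```r
library(diskfret)
run_reproduction()
```

prints

```
Coupled-disk energy-transfer reproduction
  tau_D = 3.933 ns (sample 3, amplitude-weighted); tau_DA = 3.126 ns (sample 7, amplitude-weighted)
                              quantity  computed reported reference                tolerance pass
              transfer rate k_T (1/ns)  0.065688    0.066     0.066    rounded to 3 decimals TRUE
         transfer timescale tau_T (ns) 15.224000       15        15      rounded to whole ns TRUE
                      efficiency E (%) 20.531000       21        21 rounded to whole percent TRUE
 furthest donor-acceptor distance (nm) 28.719000       29        29      rounded to whole nm TRUE
   max single-pathway contribution (%)  2.572300     2.57     <= 12              upper bound TRUE
         modifications/assembly at 31% 10.540000     10.5      10.5     rounded to 1 decimal TRUE
         modifications/assembly at 91% 30.940000       31        31  rounded to whole number TRUE
```

Reading the rows: collapsing each biexponential donor decay to its
amplitude-weighted mean lifetime and applying the FRET expressions gives a
donor-to-acceptor transfer timescale of ~15 ns (rate 0.066 ns⁻¹) at 21%
efficiency. In the idealised coupled-disk geometry (closest pair calibrated
to 7.5 nm) the farthest donor–acceptor pair lies ~29 nm away, and no single
pair carries more than ~2.6% of the total 1/R⁶ weight — transfer is a
many-pathway process. The last two rows are labelling stoichiometry: 31%
and 91% modification of a 34-monomer assembly correspond to ~10.5 and ~31
modified monomers.

The choice of averaging scheme and donor reference is not arbitrary:
`averaging_scheme_search()` enumerates short/long/amplitude/intensity
weighting against each candidate reference sample and shows the
amplitude-weighted mean with the donor-only disk (sample 3) is the unique
combination reproducing all three transfer quantities at once.

A full simulate → fit → infer round trip with known truth:

```r
run_synthetic_validation(seed = 1)   # deterministic given the seed
```

simulates donor-only and coupled histograms (10⁶ photons each) at the
table's component values, refits them by biexponential reconvolution, and
reports every recovered parameter with its z-score against truth.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/diskfret-pipeline.R` (subcommands `reproduce`, `validate`,
`geometry`).

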