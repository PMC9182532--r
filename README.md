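# coinspec

Analysis of two-colour **confocal coincidence spectroscopy (CCS)** records
of amyloid assemblies, together with **limited-proteolysis core mapping**
of the protected amyloid scaffold.

## The problem

RHIM-containing signalling proteins (TRIF, RIPK1, RIPK3) form amyloid
fibrils whose homo- and hetero-assembly drives necroptosis signalling.
Two questions recur when characterising such systems in vitro:

1. **Do two labelled proteins co-assemble?** In CCS, two fluorescent
   fusion proteins diffuse through a ~1 fL confocal volume while photon
   counts are recorded in two spectral channels at 1 ms resolution over
   minutes. Monomer gives a flat Poisson baseline; an assembly transiting
   the volume gives a transient burst. Bursts coincident in both channels
   indicate heteromeric complexes. The degree of co-assembly is quantified
   by the directional *colourQ* statistic

   ```
   colourQ = (# Colour A peaks aligned with Colour B peaks) / (total # Colour A peaks)
   ```

   with *RedQ* = the proportion of green peaks aligned with red peaks, and
   *GreenQ* the converse. Peak-intensity distributions (photon-counting
   histograms, PCH) additionally report on complex size.

2. **Which residues form the amyloid core?** Digesting fibrils with a
   non-specific protease leaves the hydrogen-bonded cross-β scaffold
   intact; LC–MS of the resistant fragments yields peptide reads that map
   back onto the parent sequence. The per-residue *prevalence* (fraction
   of reads covering each position) delineates the protected core as the
   contiguous high-prevalence run containing the motif's core tetrad.

`coinspec` implements both analyses as composable, tested stages, plus a
simulator that generates dual-channel traces and synthetic digests with
known ground truth, so every stage can be validated without instrument
data.

## Worked example

Simulate a 60 s co-incubation in which 40% of the green-visible
assemblies are dual-labelled, then recover that fraction as RedQ:

```r
library(coinspec)

cfg <- trace_config(duration_s = 60, seed = 42)
tr  <- simulate_mixture(hetero_fraction = 0.4, n_events_target = 500, cfg)
res <- run_ccs(tr)
res
#> <ccs_result>
#>   peaks: 333 green, 297 red
#>   aligned: 128 green, 128 red (128 pairs)
#>   RedQ   = 0.384
#>   GreenQ = 0.431
#>   chance-coincidence rate = 0.004971
```

The trace's ground truth carries a realised dual fraction of 0.383, so
RedQ = 0.384 recovers it to the third decimal; the chance-coincidence
diagnostic (~0.005) shows how little of that could arise from random
co-occupancy of the record. The peak-intensity distribution:

```r
build_pch(res$green_peaks, bin_width = 25, max_intensity = 300)
#> <pch> 333 peaks (green channel, max intensity), 12 bins of 25
#>   [75, 100): 10
#>   [100, 125): 187
#>   [125, 150): 135
#>   [150, 175): 1
```

Map a synthetic protease digest (70% of reads spanning the protected
core, tetrad present in every read) onto the bundled synthetic
112-residue RHIM construct:

```r
d    <- simulate_digest(digest_config(seed = 42))
prof <- build_profile(d, trif_rhim_synthetic(), trif_tetrad())
prof$core_interval <- delineate_core(prof, threshold = 0.7)
prof
#> <protection_profile> positions 601-712, 200 mapped reads (count weighting)
#>   tetrad 663-666 prevalence: 1.000
#>   protected core: 654-709
```

The delineated core 654–709 is exactly the interval the generator
encoded: 44 residues of protected flank around the VQLG tetrad, covered
by at least 70% of reads.

A command-line front end (`exec/ccstool`) exposes the same stages as
`simulate`, `ccs`, `pch`, `coremap` and an all-in-one `demo` verb; every
output directory includes a YAML manifest from which the run can be
reproduced byte-for-byte.

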