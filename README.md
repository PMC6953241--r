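# grasskit

Comparative- and population-genomic computations for forage-grass genome
projects, packaged as reusable, tested R functions:

* **LTR insertion dating** — a retrotransposon's two long terminal repeats
  are identical at insertion; their divergence λ (mismatch proportion after
  exact global alignment) is corrected for multiple hits with the
  Jukes–Cantor transform *K* = −0.75 ln(1 − 4λ/3) and converted to an age
  *T* = *K*/2*r* at a molecular clock rate *r* (default 1.3 × 10⁻⁸
  substitutions/site/year).
* **Ks-based WGD dating** — synonymous sites and differences for duplicate
  CDS pairs by Nei–Gojobori (1986) counting with pathway averaging, the
  same JC correction giving *ks*, and the distribution peak dated as
  *ks*/2*r* (default *r* = 6.96 × 10⁻⁹ synonymous substitutions/site/year).
* **BSA / QTL-seq scan** — informative SNPs (homozygous × heterozygous
  parents), per-pool SNP index polarized by the homozygous parent's allele,
  sliding-window Δ(SNP index) (1-Mb windows, 10-kb steps), the
  SNP-density-weighted *transformed* Δ, quantile-threshold candidate-region
  calling, QTL-marker overlap and expression-filtered candidate genes.
* **Windowed popgen statistics** — the diploid-mixed and autotetraploid
  population SNP filter presets, windowed nucleotide diversity π, Hudson
  FST (ratio of sums) and composite LD r² by distance bin.
* **Simulators with truth channels** for all of the above: JC-evolved LTR
  pairs, synonymous-only CDS divergence, an F1 biparental pool-seq cross
  with one causal flowering locus and Haldane crossovers, and
  Balding–Nichols two-population panels.

The intended audience is genome-project analysts who want these steps
scripted, deterministic and testable rather than buried in one-off
pipelines.

## Worked example

Simulate a cross with a causal flowering locus at 5.0 Mb on a 10-Mb
chromosome, scan it, and test the called regions against a QTL marker:

```r
library(grasskit)

sim  <- simulate_bsa_cross(chrom_length = 1e7, n_snps = 2000,
                           causal_pos = 5e6, pool_size = 30,
                           read_depth = 50, seed = 1)
scan <- bsa_scan(sim$sites, chrom_lengths = c(chr1 = 1e7))
scan
#> BSA scan: 2000 informative SNPs, 1000 windows, 1 candidate region(s)
#> threshold |transformed delta| >= 0.446
#>   chrom   start     end peak_abs_transformed_delta n_windows_merged
#> 1  chr1 4370001 5540000                     0.4506                5
```

The single called region (4.37–5.54 Mb) contains the true locus; its peak
|transformed Δ| of 0.45 is close to the theoretical causal-site Δ of 0.5
(late pool = alternate-allele carriers, each contributing one alternate
chromosome of two). Marker overlap reporting, here with the two intervals
of a real chromosome-6 flowering-time scan and the linked QTL marker at
157.639 Mb:

```r
regions <- data.frame(chrom = "chr6",
                      start = c(154344001, 157050001),
                      end   = c(156231000, 159599000))
overlap_marker(regions, "chr6", 157639000)
#>   chrom     start       end length_mb overlaps_marker
#> 1  chr6 154344001 156231000      1.89           FALSE
#> 2  chr6 157050001 159599000      2.55            TRUE
```

LTR dating end to end, recovering a known 0.5-Myr insertion age:

```r
sim  <- simulate_ltr_pairs(1000, 1000, true_age_years = 5e5,
                           clock_rate = 1.3e-8, seed = 42)
ages <- ltr_age(sim$sequences)
summary(ages)
#> 1000 LTR elements (0 saturated); mean age 5.022e+05 yr, median 5.044e+05 yr
age_distribution(ages, bin_width_years = 0.25e6)
#> Age histogram: 1000 estimates in 4 bins of 2.5e+05 yr; mode 6.25e+05 yr (0 saturated excluded)
```

The mean recovers the true age within 0.5%; the histogram mode sits in the
bin adjacent to the 0.5-Myr boundary, within one bin width of truth.

A command-line wrapper is installed as `exec/grasskit` inside the package
library; `run_pipeline()` exposes the same subcommands
(`simulate-ltr`, `simulate-wgd`, `simulate-bsa`, `simulate-panel`,
`ltr-age`, `ks`, `bsa-scan`, `popgen`) from R.

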