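---
title: "Models and methods behind grasskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grasskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasskit)
```

grasskit bundles four analyses that recur in forage-grass genome projects —
dating LTR-retrotransposon insertions, dating whole-genome duplications from
synonymous distances, a bulked-segregant (QTL-seq) scan for a flowering-time
locus, and windowed population-genetic summaries — together with simulators
that generate inputs with known truth for each of them. This vignette
explains the models, the defaults and the numerical choices, and what the
simulators do and do not capture.

## LTR insertion dating

The two long terminal repeats of a retrotransposon are identical when the
element inserts; they then diverge neutrally. Dating inverts that process in
three steps:

1. **Alignment.** Each 5′/3′ pair is aligned globally by Needleman–Wunsch
   with match +1, mismatch −1 and a linear gap penalty of −2. The traceback
   breaks ties deterministically (diagonal, then a gap in the 3′ sequence,
   then a gap in the 5′ sequence), so the same input always yields the same
   alignment. For kilobase-scale LTR pairs at the low divergences of
   interest the optimal alignment is essentially unique, which is why an
   exact, dependency-free aligner is preferable here to a heuristic
   multiple-alignment tool. Columns containing a gap or an `N` are excluded
   from both the mismatch numerator and the site denominator: the
   substitution model below has nothing to say about indels, so they are not
   allowed to contaminate λ. A `pre_aligned = TRUE` mode accepts externally
   aligned pairs.
2. **Divergence.** λ is the mismatch proportion over usable columns, and the
   Jukes–Cantor correction `K = -0.75 ln(1 - 4λ/3)` converts it to
   substitutions per site. λ ≥ 0.75 is outside the model's image; such
   pairs are flagged saturated and excluded from summaries rather than
   extrapolated.
3. **Age.** The two LTRs diverge along two branches, so `T = K / (2r)` with
   the clock rate `r` defaulting to 1.3 × 10⁻⁸ substitutions/site/year, the
   standard grass intergenic rate. It is a plain argument, never hard-wired.

Age distributions are summarized as histograms with left-closed, right-open
bins anchored at zero (default width 0.25 Myr — fine enough to resolve
sub-Myr amplification waves, coarse enough that kb-scale pairs do not
scatter one element per bin). The mode is the midpoint of the fullest bin,
ties resolved toward the younger bin. Note that when the true age sits
exactly on a bin boundary, the mode legitimately lands in either adjacent
bin depending on sampling noise; it remains within one bin width of truth.

The simulator draws a uniform-composition ancestral sequence per element and
evolves the two copies independently by exact per-site sampling from the JC
transition matrix: a site stays with probability `1/4 + 3/4 e^{-4rt/3}` and
otherwise lands uniformly on the other three bases. The tip-to-tip mismatch
probability is therefore exactly `0.75(1 - e^{-8rT/3})`, the quantity the
estimator inverts. The simulator produces no indels and no within-element
rate variation, so the alignment step is exercised only lightly by it; the
aligner is validated separately against brute-force enumeration.

## Ks-based WGD dating

For a duplicate or orthologous CDS pair, synonymous sites and differences
are counted by the Nei–Gojobori (1986) method: per codon, the fraction of
the three possible changes at each position that are synonymous (averaged
over the two sequences) gives fractional site counts `S` and `N`; codons
differing at several positions are resolved by averaging the synonymous /
nonsynonymous step counts over all minimal mutational pathways, excluding
pathways that pass through a stop codon (if every pathway is blocked, all
are used). Changes *to* stop codons are counted as nonsynonymous in the
site fractions, keeping the denominator at three changes per position.
`ps = Sd/S` is corrected for multiple hits with the same Jukes–Cantor
transform used for LTRs, giving ks; `ps ≥ 0.75` is reported saturated.
Codons containing `N` in either sequence are skipped, not imputed.

The implementation is validated against an independent pathway-enumeration
oracle over all 61 × 61 sense-codon pairs. Which counting scheme an upstream
synteny pipeline used is often undocumented; NG86 with JC correction was
chosen because it is fully specified, auditable by enumeration, and
consistent with the LTR correction. Gene-pair selection (reciprocal best
hits, synteny blocks) is upstream of this package: the module consumes
explicit pair lists.

The ks distribution peak is a histogram mode with bins *centred* on
multiples of the bin width (default 0.05), ties toward smaller ks, so a
peak at 0.5 is reported as 0.5 rather than an off-centre bin midpoint.
Duplication time is `ks / (2r)` with `r = 6.96 × 10⁻⁹` synonymous
substitutions/site/year by default.

The paired-CDS simulator samples sense codons uniformly, then places
substitutions only at single-step synonymous positions, with the
per-position hit probability scaled by the position's synonymous-site
fraction so that the expected NG86 `ps` equals the JC mismatch probability
at the requested true ks — hence the JC-corrected estimate is centred on
truth. `true_ks ≥ 2` is refused: beyond that the observable proportion is
too close to its 0.75 asymptote for the exercise to be meaningful.

## The BSA / QTL-seq scan

The design assumes an F1 mapping population from a cross where informative
SNPs are homozygous in one parent and heterozygous in the other, and two
pools of phenotypically extreme individuals are sequenced. The scan:

* keeps sites with one homozygous and one heterozygous parent, neither
  missing, and both pool depths ≥ 6 (the same depth cutoff as the
  population-scale SNP filter, since no separate BSA cutoff is standard);
* computes the **SNP index** per pool as the fraction of reads carrying the
  allele *different from the homozygous parent's allele* — polarity follows
  the cross design, not the reference base;
* averages indices in sliding windows (1 Mb window, 10 kb step by default;
  1 kb steps are available but are ~10× more windows for no extra
  information at pool-seq depths), takes
  `Δ = mean(index_late) - mean(index_early)`, and multiplies by the window
  SNP count normalized by the chromosome-wise maximum window count to give
  the **transformed Δ**. The normalizer bounds the density factor in [0, 1]
  so transformed Δ stays on the Δ scale and sparse, noisy windows are
  down-weighted. Empty windows report 0 with an `empty` flag instead of
  being dropped, preserving genome-wide coordinates;
* calls candidate regions by thresholding |transformed Δ| at a quantile of
  the non-empty windows (default 0.995) and merging selected windows that
  overlap or touch; a fixed absolute threshold is available. The signed Δ
  convention (late minus early) and the use of |Δ| for calling are explicit
  choices; with alt alleles driving lateness, Δ is positive at the locus;
* reports marker overlap on closed intervals with lengths in Mb (two
  decimals), and filters genes in a region by requiring expression above a
  threshold (default: any nonzero value) in at least one of the five stages
  prevernalization, vernalization, postvernalization, preheading, heading.

The cross simulator makes the P1 gametes non-recombinant carriers of the
reference allele and builds P2 gametes with Haldane (Poisson,
no-interference) crossovers over two haplotypes, one carrying the alternate
allele everywhere. The phenotype is carrier status at the causal SNP
(dominant; an additive mode scores half-dosage) plus Gaussian noise, pools
are the phenotypic extremes, and read counts are binomial at the pool
allele frequency. Under zero noise the late pool consists exactly of
carriers, so the causal-site expectation is an index of 0.5 in the late
pool and 0 in the early pool (each carrier contributes one alternate
chromosome of two). The default crossover density is 0.1 crossovers/Mb
(10 cM/Mb): on the 10-Mb test chromosome that is about one obligate
crossover per meiosis, a realistic linkage-group figure; much larger values
would unlink everything, much smaller ones flatten the scan into a single
plateau. The simulator does not model genotyping error, segregation
distortion, or mapping bias; recovery rates measured on it are therefore an
upper bound on real-data performance. The F1 population size from which
pools are drawn defaults to 200 individuals, in the range of practical
mapping populations.

## Windowed population statistics

Site filters reproduce the two resequencing presets: `diploid-mixed`
(depth ≥ 6, RMS mapping quality ≥ 20, minor-allele frequency ≥ 0.01,
missingness ≤ 0.2) and `autotetraploid` (depth ≥ 15, MQ ≥ 20, maf ≥ 0.05,
no missing genotypes). "Depth" defaults to the per-site mean of per-sample
allele-depth sums; `depth_source = "dp"` switches to the site's INFO `DP`
when the caller provides it. Every explicit cutoff overrides its preset
value, and per-criterion rejection counts are attached to the result.

π is computed per SNP site as the average pairwise difference among sampled
alleles, `2 n_alt n_ref / (n(n-1))`, summed over a window and divided by
the window length in bp — the resequencing convention that treats
unreported sites as monomorphic. FST uses the Hudson estimator in the
Bhatia et al. form, accumulated as a ratio of sums across windows, because
it is robust to unequal sample sizes and needs no iterative fitting;
windows whose denominator sum is zero are reported `NA`. LD is the
composite r² of genotype dosages (no phasing is assumed anywhere), binned
by pair distance; pairs involving a monomorphic site are skipped. Dosages
come from diploid genotypes; tetraploid dosage models are out of scope.

The two-population simulator is Balding–Nichols: ancestral frequencies
uniform on (0.05, 0.95), population frequencies Beta-distributed with
concentration `(1-F)/F`, genotypes binomial. Its `F` parameter is the
expectation the Hudson ratio-of-averages estimator targets, which the test
suite verifies at `F = 0.2` within ±0.03.

## Problem sizes and determinism

All simulators consume a single integer seed and are byte-reproducible.
The shipped checks run at moderated sizes chosen to exercise the estimators
well inside their asymptotic regimes: 1000 LTR pairs of 1 kb for clock
recovery, 300 CDS pairs of 300 codons for ks recovery, 20 crosses of 2000
SNPs on a 10-Mb chromosome with pools of 30 at 50× for peak recovery, and
a 5000-SNP, 50 + 50-sample panel for FST recovery. These sizes keep each
property readable as a statistical statement (Monte-Carlo error well below
the tolerance being asserted) without gratuitous computation.

## Known limitations

* The aligner is exact but O(nm) in time and memory; it is intended for
  LTR-sized (≤ a few kb) pairs, not chromosome alignment.
* NG86 assumes equal base frequencies and no transition/transversion bias;
  ks from strongly biased genes will be biased accordingly.
* The BSA scan offers no analytic significance band for Δ; the quantile
  threshold is a ranking device, and confidence assessment should come from
  permutation or simulation if needed.
* Pool "genotypes" in simulated VCFs are placeholders; only their allele
  depths matter.
* π/FST/LD are descriptive summaries; no selection test is implied.
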