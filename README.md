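# loopover

Comparative analysis of how transposable elements (TEs) supply and turn
over CTCF chromatin-loop anchor sites between two genomes.

CTCF-anchored loops are strongly conserved between mammalian genomes even
where the underlying sequence is not. TEs carry (or acquire) CTCF motifs
and can replace a decayed ancestral anchor with a nearby younger binding
site while the loop persists — *binding-site turnover* at the level of 3D
genome structure. `loopover` is for genomicists who have loop calls, CTCF
ChIP peaks, RepeatMasker annotations, a liftOver chain, contact maps and
WGBS tracks for a pair of genomes (or who want a fully synthetic pair with
implanted ground truth) and want to:

* annotate the repeat origin of anchor CTCF sites (≥10 bp core-motif
  overlap rule) and compute class/family enrichment against the
  length-weighted genomic repeat background,
* call orthologous loops by reciprocal chain lifting, with the `minMatch`
  gate chosen by a shuffle sweep and the vicinity window
  `w = min(loop length / 2, vicinity)` calibrated to `FDR < 0.1`,
* detect turnover events — a conserved loop whose species-A anchor motif
  lies in a species-specific TE while the matched anchor in species B is
  the putative ancestral, non-TE site — and test the convergent-motif
  orientation bias with a 2×2 Pearson chi-square (no continuity
  correction): χ² = N(ad − bc)²/(r₁r₂c₁c₂),
* quantify anchor-deletion phenotypes in contact maps: fixed-depth
  subsampling without replacement, VC‑sqrt balancing
  (N<sub>ij</sub> = C<sub>ij</sub>/√(s<sub>i</sub>s<sub>j</sub>)), virtual
  4C profiles, cross-domain percentage
  (inter × 100 / (intra + inter)) and Welch's unequal-variance t test,
* profile TE substitution spectra against the consensus (12 directional
  categories; methylation-associated rate = mean of C→T and G→A) with a
  subfamily-stratified permutation background and a left-tailed z test for
  the CpG-deamination signature of hypomethylation, plus Jukes–Cantor /
  Kimura distances and TE age = divergence / neutral rate.

## Worked example

Everything below runs on the packaged synthetic two-genome dataset; no
downloads are needed.

```r
library(loopover)

sim <- simulate_dataset(simulation_config(seed = 1))

loops_a <- classify_loops(annotate_loops(sim$loops_a, sim$repeats_a))
loops_b <- classify_loops(annotate_loops(sim$loops_b, sim$repeats_b))
table(loops_a$class)
#>     non_RE RE_derived
#>         18         15

calls  <- loop_orthology(loops_a, loops_b, sim$chain_ab, sim$chain_ba,
                         min_match = 0.1, vicinity = 50000)
nrow(calls)   # 26 orthologous loop pairs among 33 A-genome loops

events <- detect_turnover(calls, loops_a, loops_b,
                          sim$repeats_a, sim$repeats_b, sim$chain_ab)
ot <- orientation_table(events)
ot$counts
#>            side
#> orientation left right
#>           +    6     0
#>           -    0     4
ot$p
#> [1] 0.001565402
```

All ten implanted turnover events are recovered (left-anchor events carry
`+` motifs, right-anchor events `-` motifs — the convergent-orientation
bias the chi-square quantifies), with no false calls. The mutational
signature of the turnover cohort:

```r
profiles <- substitution_profiles(sim$aligns_a)
cohort <- sim$ground_truth$tes$cohort[
  match(profiles$element_id, sim$ground_truth$tes$element_id)]
st <- substitution_test(profiles[cohort == "turnover", ],
                        profiles[cohort == "background", ],
                        n_perms = 200, seed = 8)
st[st$statistic %in% c("meth_rate", "nonmeth_rate"),
   c("statistic", "observed", "perm_mean", "z", "p_left")]
#>       statistic observed perm_mean     z   p_left
#>       meth_rate   0.0130    0.0233 -4.77 9.34e-07
#>    nonmeth_rate   0.0131    0.0106  4.04 1.00e+00
```

Turnover TEs carry significantly fewer methylation-associated (C→T/G→A)
substitutions than an identically subfamily-stratified background — the
fossil record of an unmethylated history — while the other ten
substitution categories show no depletion. The desk-scale statistics work
the same way on published tables: `pearson_chi2(matrix(c(53, 8, 18, 45), 2))`
gives p = 5.3e-11.

A single call runs every stage (simulate → annotate → orthology →
turnover → contacts → evolve → methylation) and writes per-stage outputs
plus a manifest:

```r
res <- run_pipeline(list(seed = 1, outdir = "run1"))
```

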