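# isofoodweb

Stable-isotope food-web and community analysis for paired-site field
comparisons — for instance a reference seagrass bed versus a naturally
CO2-enriched one. The package is aimed at trophic ecologists who have (a)
replicated quadrat counts of motile invertebrates with trophic-group
assignments and (b) bulk δ¹³C/δ¹⁵N measurements of basal organic-matter
sources and consumers, and who want to quantify how diversity, isotopic
niche width, trophic position and diet composition differ between sites.

## What it computes

**Community structure.** Shannon diversity *H′* = −Σ pᵢ log₂ pᵢ and Pielou
evenness *J′* = *H′*/log₂ *R* per replicate quadrat, with between-site
Student/Welch t tests; Sorensen similarity *S* = 2a/(2a + b + c) of the
per-site taxon lists; per-taxon densities (ind. m⁻²) and trophic-group
composition as percentages of individuals.

**Isotopic niche.** Trophic position TL = (δ¹⁵N_c − δ¹⁵N_b)/Δₙ + λ against
a lowest-δ¹⁵N primary-consumer baseline (defaults Δₙ = 2.5‰, λ = 2); the
five Layman community-wide metrics (NR, CR, CD, NND, SDNND) on species mean
signatures; maximum-likelihood standard ellipse areas SEA = π√det Σ̂ with
small-sample correction SEAc = SEA·(n−1)/(n−2), exact conjugate
(normal–inverse-Wishart) posterior draws of the ellipse area, and the
overlap area between two sites' SEAc ellipses.

**Diet mixing.** A Bayesian stable-isotope mixing model in the SIAR family:
each consumer specimen's signature is normal with mean Σₖ pₖ(μₖ + μ_TEF)
and variance Σₖ pₖ²(σₖ² + σ_TEF²) + τ², diet proportions p ~ Dirichlet(1),
residual SDs τ ~ half-normal. Ecologically related source species are pooled
a priori when a Kruskal–Wallis test (Dunn/Bonferroni post hoc) finds no
isotopic difference. Sampling is by adaptive Metropolis-within-Gibbs on
log-ratio coordinates; marginals are reported as mean, KDE mode and 95%
highest-density interval, with split-chain R̂ convergence diagnostics.

**Synthetic studies.** `vent_survey_config()` + `generate_study()` build a
complete two-site study — abundances, sources, consumers — with known
ground truth (consumers are drawn from the mixing likelihood itself), so
every stage of the pipeline can be tested end to end.

## Worked example

```r
library(isofoodweb)

# Sorensen similarity of two sites sharing 11 of 32 and 23 taxa
sorensen_index(sprintf("c%02d", 1:32),
               c(sprintf("c%02d", 1:11), sprintf("v%02d", 1:12)))
#> [1] 0.4

# a synthetic two-site study with known ground truth
iso <- generate_isotopes(vent_survey_config(seed = 1))
niche_summary(iso$records, "control", n_draws = 2000, seed = 2)
#> Isotopic niche summary - site 'control' (60 specimens, 6 species)
#>   Layman: NR=2.51 CR=5.68 CD=1.61 NND=1.09 SDNND=0.79 (permil)
#>   SEA=9.742 permil^2, SEAc=9.910 permil^2, posterior median SEAc=9.606

# pool source species into ecological groups, then fit one consumer's diet
src <- subset(as.data.frame(iso$records),
              entity_class == "source" & site == "control")
grp <- aggregate_sources(data.frame(species = src$entity, group = src$group,
                                    d13C = src$d13C, d15N = src$d15N))
cons <- subset(as.data.frame(iso$records),
               entity_class == "consumer" & site == "control" &
               entity == "Dexaminidae")
fit <- fit_mixing_model(cons[, c("d13C", "d15N")], grp,
                        mcmc = mcmc_control(seed = 1))
fit$summary[, c("source", "mean", "mode", "ci_low", "ci_high", "rhat")]
#>       source  mean  mode  ci_low ci_high rhat
#> 1 seagrasses 0.068 0.000 5.6e-06    0.17    1
#> 2      algae 0.169 0.094 1.8e-04    0.38    1
#> 3  epiphytes 0.137 0.085 3.6e-05    0.31    1
#> 4        SOM 0.626 0.630 4.8e-01    0.76    1
```

The generator's true diet for this species is (0.05, 0.10, 0.15, 0.70) over
(seagrasses, algae, epiphytes, SOM): the posterior means recover the
SOM-dominated diet, and the near-zero lower credible bounds for the minor
sources are the expected behaviour when sources are close relative to their
variability. The Layman NR here (2.51‰) is the δ¹⁵N spread of the six
species means; SEAc is the corrected ellipse area over all 60 specimens.

`run_full_pipeline(vent_survey_config(seed = 1), out_dir = "out")` executes
all three stages for both sites and writes CSV summaries, posterior-draw
files, a `truth.json` ground-truth ledger and a `manifest.json` recording
seeds and configuration. A thin command-line wrapper with subcommands
`simulate | community | niche | mix | run` is installed at
`inst/scripts/isofoodweb.R`.

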