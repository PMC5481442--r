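test_that("generation is fully deterministic given the config", {
  cfg <- vent_survey_config(seed = 5)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$abundances, s2$abundances)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(vent_survey_config(seed = 6))
  expect_false(identical(s1$records$d13C, s3$records$d13C))
})

test_that("Poisson-limit abundances reproduce the configured mean density", {
  taxa <- data.frame(taxon = "t1", trophic_group = "herbivore",
                     density_control = 100, density_vent = 0,
                     dispersion = Inf)
  sources <- data.frame(species = "s", group = "SOM", mean_d13C = -20,
                        sd_d13C = 0.5, mean_d15N = 1, sd_d15N = 0.3, n = 3)
  consumers <- data.frame(species = "c", n = 3, residual_sd = 0.1,
                          primary_consumer = TRUE, p_SOM = 1)
  cfg <- study_config(seed = 2, taxa = taxa, sources = sources,
                      consumers = consumers, n_replicates = 1000,
                      quadrat_area = 0.09)
  ab <- generate_abundances(cfg)
  ctl <- ab[ab$site == "control", ]
  # mean count per quadrat converges to density * area = 9
  expect_equal(mean(ctl$count), 9, tolerance = 0.1)
  # zero-density taxon gives all-zero counts at the vent
  expect_true(all(ab$count[ab$site == "vent"] == 0))
})

test_that("vent-site source means are shifted by exactly the configured amounts", {
  cfg <- vent_survey_config(seed = 3)
  cfg$sources$sd_d13C <- 0
  cfg$sources$sd_d15N <- 0
  iso <- generate_isotopes(cfg)
  src <- iso$records[iso$records$entity_class == "source", ]
  for (sp in unique(src$entity)) {
    ctl <- src[src$entity == sp & src$site == "control", ]
    vnt <- src[src$entity == sp & src$site == "vent", ]
    expect_equal(mean(vnt$d13C) - mean(ctl$d13C), -3, tolerance = 1e-12)
    expect_equal(mean(vnt$d15N) - mean(ctl$d15N), -1.5, tolerance = 1e-12)
  }
})

test_that("a pure-diet consumer with zero variances sits at source mean + TEF", {
  sources <- data.frame(species = c("s1", "s2"),
                        group = c("SOM", "algae"),
                        mean_d13C = c(-22, -16), sd_d13C = 0,
                        mean_d15N = c(0.8, 2), sd_d15N = 0, n = 3)
  consumers <- data.frame(species = "c", n = 5, residual_sd = 0,
                          primary_consumer = TRUE, p_SOM = 1, p_algae = 0)
  taxa <- data.frame(taxon = "t", trophic_group = "herbivore",
                     density_control = 10, density_vent = 10, dispersion = 5)
  tef <- tef_defaults(sd_d15N = 0, sd_d13C = 0)
  cfg <- study_config(seed = 4, taxa = taxa, sources = sources,
                      consumers = consumers, tef = tef)
  iso <- generate_isotopes(cfg)
  cons <- iso$records[iso$records$entity_class == "consumer" &
                        iso$records$site == "control", ]
  expect_true(all(abs(cons$d13C - (-22 + tef$mean_d13C)) < 1e-12))
  expect_true(all(abs(cons$d15N - (0.8 + tef$mean_d15N)) < 1e-12))
})

test_that("the designated lowest-d15N primary consumer is recovered as baseline", {
  for (s in c(1, 2, 3)) {
    iso <- generate_isotopes(vent_survey_config(seed = s))
    for (site in c("control", "vent")) {
      expect_equal(select_baseline(iso$records, iso$truth$primary_consumers,
                                   site),
                   iso$truth$baseline_entity)
    }
  }
})

test_that("generated abundances recover configured trophic-group percentages", {
  cfg <- vent_survey_config(seed = 8)
  # expected percentages implied by the configured densities
  exp_pct <- function(dens) {
    p <- tapply(dens, cfg$taxa$trophic_group, sum)
    100 * p / sum(p)
  }
  ab <- generate_abundances(cfg)
  for (site in c("control", "vent")) {
    dens <- if (site == "control") cfg$taxa$density_control else cfg$taxa$density_vent
    want <- exp_pct(dens)
    got <- trophic_group_composition(ab, site)
    tot <- sum(ab$count[ab$site == site])
    for (g in names(want)[want > 0]) {
      # binomial sampling error on a proportion from `tot` individuals
      se <- 100 * sqrt(want[[g]] / 100 * (1 - want[[g]] / 100) / tot)
      got_g <- if (g %in% names(got)) got[[g]] else 0
      expect_lt(abs(got_g - want[[g]]), max(4 * se, 1.5))
    }
  }
})

test_that("diet proportions stated in truth are recoverable by the mixing model", {
  cfg <- vent_survey_config(seed = 12)
  iso <- generate_isotopes(cfg)
  gp <- iso$truth$group_params[["control"]]
  sub <- iso$records[iso$records$entity_class == "consumer" &
                       iso$records$site == "control" &
                       iso$records$entity == "Dexaminidae", ]
  f <- fit_mixing_model(sub[, c("d13C", "d15N")],
                        data.frame(name = gp$name, mean_d13C = gp$mean_d13C,
                                   sd_d13C = gp$sd_d13C,
                                   mean_d15N = gp$mean_d15N,
                                   sd_d15N = gp$sd_d15N),
                        tef = cfg$tef,
                        mcmc = mcmc_control(chains = 2, iterations = 4000,
                                            burn_in = 2000, thin = 2,
                                            seed = 12))
  truth <- iso$truth$diet_proportions["Dexaminidae", f$summary$source]
  # four partially collinear sources at n = 10: loose recovery only
  expect_lt(mean(abs(f$summary$mean - truth)), 0.2)
})

test_that("invalid configurations are rejected", {
  taxa <- data.frame(taxon = "t", trophic_group = "herbivore",
                     density_control = 10, density_vent = 10, dispersion = 5)
  sources <- data.frame(species = "s", group = "SOM", mean_d13C = -20,
                        sd_d13C = 0.5, mean_d15N = 1, sd_d15N = 0.3, n = 3)
  ok_cons <- data.frame(species = "c", n = 3, residual_sd = 0.1,
                        primary_consumer = TRUE, p_SOM = 1)
  bad_cons <- ok_cons; bad_cons$p_SOM <- 0.8
  expect_error(study_config(seed = 1, taxa = taxa, sources = sources,
                            consumers = bad_cons),
               class = "isofw_domain_error")
  bad_taxa <- taxa; bad_taxa$density_vent <- -1
  expect_error(study_config(seed = 1, taxa = bad_taxa, sources = sources,
                            consumers = ok_cons),
               class = "isofw_domain_error")
})
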