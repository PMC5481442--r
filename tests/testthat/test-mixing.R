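quick_mcmc <- function(seed) {
  mcmc_control(chains = 2, iterations = 4000, burn_in = 2000, thin = 2,
               seed = seed)
}

make_sources <- function(names = c("A", "B"),
                         d13C = c(-20, -10), d15N = c(1, 6),
                         sd = 0.5) {
  data.frame(name = names, mean_d13C = d13C, sd_d13C = sd,
             mean_d15N = d15N, sd_d15N = sd, stringsAsFactors = FALSE)
}

# consumers drawn from the mixing likelihood itself
draw_consumers <- function(n, p, sources, tef, residual_sd = 0.3, seed = 1) {
  set.seed(seed)
  mu <- c(sum(p * (sources$mean_d13C + tef$mean_d13C)),
          sum(p * (sources$mean_d15N + tef$mean_d15N)))
  v <- c(sum(p^2 * (sources$sd_d13C^2 + tef$sd_d13C^2)),
         sum(p^2 * (sources$sd_d15N^2 + tef$sd_d15N^2))) + residual_sd^2
  cbind(rnorm(n, mu[1], sqrt(v[1])), rnorm(n, mu[2], sqrt(v[2])))
}

test_that("HDR summary: degenerate, uniform and boundary-concentrated draws", {
  h0 <- summarize_hdr(rep(0.4, 1500))
  expect_equal(unname(h0), rep(0.4, 4))

  set.seed(41)
  u <- runif(20000)
  hu <- summarize_hdr(u)
  # a 95% shortest window of a uniform sample has width ~0.95 and sits
  # somewhere inside [0, 1]; location is arbitrary up to the 0.05 slack
  expect_equal(unname(hu["high"] - hu["low"]), 0.95, tolerance = 0.01)
  expect_gte(unname(hu["low"]), 0)
  expect_lte(unname(hu["high"]), 1)
  expect_equal(unname(hu["mean"]), 0.5, tolerance = 0.02)

  b <- rbeta(20000, 1, 20)
  hb <- summarize_hdr(b)
  expect_lt(unname(hb["low"]), 0.005)   # lower bound collapses to ~0
  expect_lt(unname(hb["mode"]), 0.05)   # mode at the boundary, not pushed in
  expect_error(summarize_hdr(runif(100)), class = "isofw_insufficient_data")
  expect_error(summarize_hdr(runif(1500) + 1), class = "isofw_domain_error")
})

test_that("source aggregation pools homogeneous groups and splits distinct ones", {
  set.seed(42)
  v <- rnorm(10)
  same <- data.frame(species = rep(c("s1", "s2"), each = 10),
                     group = "seagrasses",
                     d13C = c(v, v), d15N = c(v + 2, v + 2))
  g <- aggregate_sources(same)
  expect_equal(nrow(g), 1)
  expect_equal(g$name, "seagrasses")
  expect_equal(g$n, 20)

  apart <- data.frame(species = rep(c("s1", "s2"), each = 10),
                      group = "algae",
                      d13C = c(1:10, 21:30), d15N = rep(rnorm(10), 2))
  expect_warning(g2 <- aggregate_sources(apart), "heterogeneous")
  expect_equal(sort(g2$name), c("s1", "s2"))

  single <- data.frame(species = "only", group = "SOM",
                       d13C = rnorm(5, -20), d15N = rnorm(5, 1))
  g3 <- aggregate_sources(single)
  expect_equal(g3$name, "SOM")
  expect_equal(g3$mean_d13C, mean(single$d13C))
})

test_that("posterior draws live on the simplex and the fit is seed-deterministic", {
  src <- make_sources()
  x <- draw_consumers(20, c(0.6, 0.4), src, tef_defaults(), seed = 2)
  f1 <- fit_mixing_model(x, src, mcmc = quick_mcmc(9))
  f2 <- fit_mixing_model(x, src, mcmc = quick_mcmc(9))
  expect_identical(f1$draws, f2$draws)
  expect_true(all(abs(rowSums(f1$draws) - 1) < 1e-9))
  expect_true(all(f1$draws >= 0))
  expect_true(all(f1$summary$mean >= 0 & f1$summary$mean <= 1))
  expect_true(all(f1$summary$ci_low <= f1$summary$ci_high))
})

test_that("relabelling sources permutes the posterior exactly", {
  src <- make_sources(c("algae", "seagrass", "SOM"),
                      d13C = c(-18, -10, -24), d15N = c(2, 3, 0.5))
  x <- draw_consumers(15, c(0.5, 0.3, 0.2), src, tef_defaults(), seed = 3)
  f_fwd <- fit_mixing_model(x, src, mcmc = quick_mcmc(4))
  f_rev <- fit_mixing_model(x, src[c(3, 1, 2), ], mcmc = quick_mcmc(4))
  expect_identical(f_fwd$draws[, f_rev$sources], f_rev$draws)
  expect_equal(f_fwd$summary[match(f_rev$sources, f_fwd$sources), "mean"],
               f_rev$summary$mean)
})

test_that("two symmetric sources around the consumer mean give p = (0.5, 0.5)", {
  src <- make_sources(d13C = c(-20, -10), d15N = c(1, 5), sd = 0.3)
  tef <- tef_defaults(sd_d15N = 0.3, sd_d13C = 0.3)
  mid <- c(mean(src$mean_d13C) + tef$mean_d13C,
           mean(src$mean_d15N) + tef$mean_d15N)
  set.seed(44)
  x <- cbind(rnorm(50, mid[1], 0.2), rnorm(50, mid[2], 0.2))
  f <- fit_mixing_model(x, src, tef = tef, mcmc = quick_mcmc(5))
  expect_equal(f$summary$mean, c(0.5, 0.5), tolerance = 0.05)
})

test_that("a consumer at one source's TEF-corrected mean loads on that source", {
  src <- make_sources(c("near", "far"), d13C = c(-20, -8), d15N = c(1, 6),
                      sd = 0.2)
  tef <- tef_defaults(sd_d15N = 0.2, sd_d13C = 0.2)
  x <- matrix(rep(c(src$mean_d13C[1] + tef$mean_d13C,
                    src$mean_d15N[1] + tef$mean_d15N), each = 5), 5, 2)
  x <- x + matrix(rnorm(10, 0, 0.05), 5, 2)
  f <- fit_mixing_model(x, src, tef = tef,
                        mcmc = mcmc_control(chains = 2, iterations = 7000,
                                            burn_in = 2000, thin = 2, seed = 6))
  expect_gt(f$summary$mean[f$summary$source == "near"],
            f$summary$mean[f$summary$source == "far"])
  expect_gt(f$summary$mean[f$summary$source == "near"], 0.8)
})

test_that("posterior means recover known diet proportions", {
  src <- make_sources()
  tef <- tef_defaults()
  x <- draw_consumers(30, c(0.7, 0.3), src, tef, seed = 7)
  f <- fit_mixing_model(x, src, tef = tef, mcmc = quick_mcmc(8))
  expect_equal(f$summary$mean, c(0.7, 0.3), tolerance = 0.1)
})

test_that("posterior means agree with a simplex-grid importance-sampling oracle", {
  src <- make_sources(sd = 0.4)
  tef <- tef_defaults(sd_d15N = 0.4, sd_d13C = 0.4)
  x <- draw_consumers(25, c(0.65, 0.35), src, tef, residual_sd = 0.2, seed = 9)
  f <- fit_mixing_model(x, src, tef = tef, mcmc = quick_mcmc(10))
  om <- oracle_mixing_posterior_mean(x, src, tef, step = 0.01)
  expect_equal(f$summary$mean, unname(om), tolerance = 0.05)
})

test_that("degenerate inputs are refused", {
  src <- make_sources()
  x <- draw_consumers(10, c(0.5, 0.5), src, tef_defaults())
  expect_error(fit_mixing_model(x[1:2, ], src, mcmc = quick_mcmc(1)),
               class = "isofw_insufficient_data")
  expect_error(fit_mixing_model(x, src[1, ], mcmc = quick_mcmc(1)),
               class = "isofw_domain_error")
  expect_error(mcmc_control(chains = 1, iterations = 100, burn_in = 50,
                            thin = 1, seed = 1),
               class = "isofw_domain_error")
  expect_error(mcmc_control(chains = 2, iterations = 2000, burn_in = 1000,
                            thin = 1), class = "isofw_domain_error")
})
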