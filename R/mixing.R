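# Bayesian stable-isotope mixing model (SIAR-family likelihood) with a
# Dirichlet prior on diet proportions, sampled by adaptive
# Metropolis-within-Gibbs on additive-log-ratio coordinates.

#' Trophic enrichment factors for herbivorous consumers
#'
#' Default per-trophic-step enrichment between diet and consumer tissue:
#' 2.5 +/- 2.5 permil for delta15N and 0.47 +/- 1.23 permil for delta13C,
#' the standard herbivore values for aquatic invertebrates.
#'
#' @param mean_d15N,sd_d15N,mean_d13C,sd_d13C TEF means and SDs in permil.
#' @return List of class `tef` with the four components.
#' @export
tef_defaults <- function(mean_d15N = 2.5, sd_d15N = 2.5,
                         mean_d13C = 0.47, sd_d13C = 1.23) {
  .assert(sd_d15N >= 0 && sd_d13C >= 0, "TEF SDs must be non-negative",
          "isofw_domain_error")
  structure(list(mean_d15N = mean_d15N, sd_d15N = sd_d15N,
                 mean_d13C = mean_d13C, sd_d13C = sd_d13C),
            class = "tef")
}

#' MCMC settings for the mixing model
#'
#' @param chains Number of independent chains.
#' @param iterations Iterations per chain (including burn-in).
#' @param burn_in Iterations discarded per chain; step sizes adapt only here.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed (mandatory); chain c uses `seed + c - 1`.
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iterations = 20000, burn_in = 10000,
                         thin = 10, seed) {
  .assert(!missing(seed), "`seed` is mandatory for the mixing model",
          "isofw_domain_error")
  .assert(chains >= 1 && iterations > burn_in && burn_in >= 0 && thin >= 1,
          "invalid MCMC settings: need iterations > burn_in >= 0, thin >= 1",
          "isofw_domain_error")
  n_keep <- floor((iterations - burn_in) / thin) * chains
  .assert(n_keep >= 1000,
          sprintf("settings retain only %d draws; at least 1000 are needed", n_keep),
          "isofw_domain_error")
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Aggregate ecologically related source species into pooled source groups
#'
#' Species sharing a named ecological group (e.g. two seagrasses) are pooled
#' into one source when a Kruskal-Wallis comparison across the member species
#' finds no significant difference at `alpha` on *both* isotopes; otherwise
#' the group is split back into its member species and a warning is emitted.
#' Pooling fewer, broader sources yields better-constrained mixing solutions
#' than many near-collinear species-level sources.
#'
#' @param sources Data frame of source specimens with columns `species`,
#'   `group`, `d13C`, `d15N`.
#' @param alpha Significance level for the pooling test.
#' @return Data frame of class `source_groups` with columns `name`,
#'   `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N`, `n`.
#' @export
aggregate_sources <- function(sources, alpha = 0.05) {
  .assert(is.data.frame(sources) && nrow(sources) > 0,
          "`sources` must be a non-empty data frame", "isofw_domain_error")
  needed <- c("species", "group", "d13C", "d15N")
  .assert(all(needed %in% names(sources)),
          paste0("`sources` needs columns: ", paste(needed, collapse = ", ")),
          "isofw_parse_error")
  one_group <- function(df, name) {
    data.frame(name = name,
               mean_d13C = mean(df$d13C), sd_d13C = if (nrow(df) > 1) stats::sd(df$d13C) else 0,
               mean_d15N = mean(df$d15N), sd_d15N = if (nrow(df) > 1) stats::sd(df$d15N) else 0,
               n = nrow(df), stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in unique(sources$group)) {
    sub <- sources[sources$group == g, , drop = FALSE]
    spp <- unique(sub$species)
    if (length(spp) < 2) {
      out[[length(out) + 1]] <- one_group(sub, g)
      next
    }
    by_sp <- split(sub, sub$species)
    ok_c <- kruskal_wallis_posthoc(lapply(by_sp, `[[`, "d13C"), alpha)$merge_all
    ok_n <- kruskal_wallis_posthoc(lapply(by_sp, `[[`, "d15N"), alpha)$merge_all
    if (ok_c && ok_n) {
      out[[length(out) + 1]] <- one_group(sub, g)
    } else {
      warning(sprintf(
        "source group '%s' is isotopically heterogeneous at alpha = %g; keeping member species separate",
        g, alpha))
      for (sp in spp) out[[length(out) + 1]] <- one_group(by_sp[[sp]], sp)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("source_groups", "data.frame")
  res
}

# log posterior density (up to a constant) on the working scale
# z: K-1 additive-log-ratio coords; ltau: log residual SDs (2)
#' @keywords internal
.mix_logpost <- function(z, ltau, st) {
  ez <- exp(c(z, 0))
  p <- ez / sum(ez)
  # Dirichlet(alpha) prior density * ALR Jacobian prod(p) => sum(alpha*log p)
  lp <- sum(st$alpha * log(p))
  tau <- exp(ltau)
  lp <- lp - sum(tau^2) / (2 * st$tau_prior_sd^2) + sum(ltau) # half-normal + Jacobian
  p2 <- p * p
  for (j in 1:2) {
    mu <- sum(p * st$mu[, j])
    v <- sum(p2 * st$s2[, j]) + tau[j]^2
    lp <- lp - st$n / 2 * log(v) -
      (st$SS[j] - 2 * mu * st$S[j] + st$n * mu * mu) / (2 * v)
  }
  lp
}

#' @keywords internal
.mix_chain <- function(st, iterations, burn_in, thin, seed) {
  K <- nrow(st$mu)
  .with_seed(seed, {
    z <- numeric(K - 1)
    ltau <- c(0, 0)
    lp <- .mix_logpost(z, ltau, st)
    step_z <- 0.5
    step_t <- 0.5
    acc_z <- acc_t <- 0L
    batch <- 50L
    n_keep <- floor((iterations - burn_in) / thin)
    draws_p <- matrix(NA_real_, n_keep, K)
    draws_tau <- matrix(NA_real_, n_keep, 2)
    kept <- 0L
    for (it in seq_len(iterations)) {
      z_new <- z + step_z * stats::rnorm(K - 1)
      lp_new <- .mix_logpost(z_new, ltau, st)
      if (log(stats::runif(1)) < lp_new - lp) {
        z <- z_new; lp <- lp_new; acc_z <- acc_z + 1L
      }
      lt_new <- ltau + step_t * stats::rnorm(2)
      lp_new <- .mix_logpost(z, lt_new, st)
      if (log(stats::runif(1)) < lp_new - lp) {
        ltau <- lt_new; lp <- lp_new; acc_t <- acc_t + 1L
      }
      if (it <= burn_in && it %% batch == 0L) {
        # Robbins-Monro style adaptation toward ~30% acceptance
        step_z <- min(5, max(1e-3, step_z * exp((acc_z / batch - 0.3))))
        step_t <- min(5, max(1e-3, step_t * exp((acc_t / batch - 0.3))))
        acc_z <- acc_t <- 0L
      }
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        ez <- exp(c(z, 0))
        draws_p[kept, ] <- ez / sum(ez)
        draws_tau[kept, ] <- exp(ltau)
      }
    }
    list(p = draws_p, tau = draws_tau)
  })
}

# split-chain potential scale reduction factor for one scalar quantity;
# x is a matrix of draws with one column per chain
#' @keywords internal
.split_rhat <- function(x) {
  half <- floor(nrow(x) / 2)
  seqs <- cbind(x[seq_len(half), , drop = FALSE],
                x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(seqs); nn <- nrow(seqs)
  mu_j <- colMeans(seqs)
  s2_j <- apply(seqs, 2, stats::var)
  W <- mean(s2_j)
  B <- nn * stats::var(mu_j)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit the Bayesian stable-isotope mixing model for one consumer species
#'
#' Models each consumer specimen's `(d13C, d15N)` as a normal whose mean is
#' the proportion-weighted combination of TEF-corrected source means and whose
#' variance is `sum(p_k^2 * (sd_source^2 + sd_TEF^2)) + tau^2` per isotope,
#' with diet proportions `p ~ Dirichlet(prior_alpha)` and per-isotope residual
#' SDs `tau_j ~ half-normal(0, tau_prior_sd)`. Sampling is by adaptive
#' random-walk Metropolis-within-Gibbs on additive-log-ratio coordinates;
#' results are deterministic given the seed in `mcmc`.
#'
#' @param consumers Matrix or data frame of `(d13C, d15N)` specimens for one
#'   species (n >= 3).
#' @param sources A [aggregate_sources()] table (2-4 rows) or a data frame
#'   with columns `name`, `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N`.
#' @param tef Trophic enrichment factors, see [tef_defaults()].
#' @param prior_alpha Dirichlet concentration, scalar or per-source vector;
#'   the default 1 is uniform on the simplex.
#' @param tau_prior_sd Scale of the half-normal prior on the residual SDs
#'   (permil).
#' @param mcmc An [mcmc_control()]; its seed is mandatory.
#' @param hdr_mass Posterior mass of the reported highest-density interval.
#' @return Object of class `mixing_result`: list with `sources` (names),
#'   `summary` (data frame: source, mean, mode, ci_low, ci_high, q_low,
#'   q_high, rhat), `draws` (matrix, one column per source), `tau_draws`,
#'   `converged` (all rhat <= 1.1) and `mcmc`.
#' @export
fit_mixing_model <- function(consumers, sources, tef = tef_defaults(),
                             prior_alpha = 1, tau_prior_sd = 5,
                             mcmc = mcmc_control(seed = 1), hdr_mass = 0.95) {
  x <- .as_points(consumers, min_n = 3L, what = "consumers")
  .assert(is.data.frame(sources) && nrow(sources) >= 2,
          "need at least two sources", "isofw_domain_error")
  needed <- c("name", "mean_d13C", "sd_d13C", "mean_d15N", "sd_d15N")
  .assert(all(needed %in% names(sources)),
          paste0("`sources` needs columns: ", paste(needed, collapse = ", ")),
          "isofw_parse_error")
  .assert(!anyDuplicated(sources$name), "source names must be unique",
          "isofw_domain_error")
  .assert(inherits(mcmc, "mcmc_control"), "`mcmc` must be an mcmc_control()",
          "isofw_domain_error")
  K <- nrow(sources)
  if (length(prior_alpha) == 1) prior_alpha <- rep(prior_alpha, K)
  .assert(length(prior_alpha) == K && all(prior_alpha > 0),
          "`prior_alpha` must be positive, one value per source",
          "isofw_domain_error")
  # canonical internal source order (sorted by name) so that permuting the
  # rows of `sources` permutes the result exactly, given the same seed
  ord <- order(sources$name)
  inv <- order(ord)
  src <- sources[ord, , drop = FALSE]
  st <- list(
    n = nrow(x),
    S = colSums(x),
    SS = colSums(x * x),
    mu = cbind(src$mean_d13C + tef$mean_d13C, src$mean_d15N + tef$mean_d15N),
    s2 = cbind(src$sd_d13C^2 + tef$sd_d13C^2, src$sd_d15N^2 + tef$sd_d15N^2),
    alpha = prior_alpha[ord],
    tau_prior_sd = tau_prior_sd
  )
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    .mix_chain(st, mcmc$iterations, mcmc$burn_in, mcmc$thin,
               seed = mcmc$seed + ch - 1L)
  })
  p_all <- do.call(rbind, lapply(chains, `[[`, "p"))
  tau_all <- do.call(rbind, lapply(chains, `[[`, "tau"))
  rhat <- vapply(seq_len(K), function(k) {
    .split_rhat(sapply(chains, function(ch) ch$p[, k]))
  }, numeric(1))
  summ <- lapply(seq_len(K), function(k) {
    h <- summarize_hdr(p_all[, k], mass = hdr_mass)
    data.frame(source = src$name[k], mean = h["mean"], mode = h["mode"],
               ci_low = h["low"], ci_high = h["high"],
               q_low = unname(stats::quantile(p_all[, k], (1 - hdr_mass) / 2)),
               q_high = unname(stats::quantile(p_all[, k], 1 - (1 - hdr_mass) / 2)),
               rhat = rhat[k], stringsAsFactors = FALSE, row.names = NULL)
  })
  summ <- do.call(rbind, summ)[inv, , drop = FALSE]
  rownames(summ) <- NULL
  p_all <- p_all[, inv, drop = FALSE]
  colnames(p_all) <- summ$source
  colnames(tau_all) <- c("tau_d13C", "tau_d15N")
  converged <- all(summ$rhat <= 1.1)
  if (!converged) {
    warning(sprintf("possible non-convergence: max split-chain Rhat = %.3f",
                    max(summ$rhat)))
  }
  structure(list(sources = summ$source, summary = summ, draws = p_all,
                 tau_draws = tau_all, converged = converged, mcmc = mcmc,
                 hdr_mass = hdr_mass),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("Bayesian mixing model: %d sources, %d posterior draws%s\n",
              length(x$sources), nrow(x$draws),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(cbind(x$summary[, c("source")], round(x$summary[, -1], 3)))
  invisible(x)
}

#' Posterior summary: mean, mode and highest-density interval
#'
#' Summarises a vector of posterior proportion draws by its arithmetic mean,
#' the mode of a boundary-reflected kernel density estimate on `[0, 1]`
#' (Silverman bandwidth), and the shortest interval containing `mass` of the
#' draws (highest-density region). Genuine ties between equally short
#' intervals are broken by centring (midpoint closest to the sample median).
#'
#' @param draws Numeric vector of at least 1000 draws in `[0, 1]`.
#' @param mass Probability mass of the interval (default 0.95).
#' @return Named numeric vector `c(mean, mode, low, high)`.
#' @export
summarize_hdr <- function(draws, mass = 0.95) {
  .assert(is.numeric(draws) && length(draws) >= 1000,
          "at least 1000 draws are required", "isofw_insufficient_data")
  .assert(all(is.finite(draws)) && all(draws >= 0) && all(draws <= 1),
          "draws must lie in [0, 1]", "isofw_domain_error")
  .assert(mass > 0 && mass < 1, "`mass` must be in (0, 1)", "isofw_domain_error")
  n <- length(draws)
  if (stats::sd(draws) == 0) {
    v <- draws[1]
    return(c(mean = v, mode = v, low = v, high = v))
  }
  # mode from a KDE with reflection at 0 and 1 (corrects boundary bias)
  bw <- stats::bw.nrd0(draws)
  aug <- c(draws, -draws, 2 - draws)
  d <- stats::density(aug, bw = bw, from = 0, to = 1, n = 1024)
  mode <- d$x[which.max(d$y)]
  # shortest interval containing ceil(mass * n) order statistics
  xs <- sort(draws)
  nkeep <- ceiling(mass * n)
  i_max <- n - nkeep + 1
  widths <- xs[nkeep:n] - xs[seq_len(i_max)]
  wmin <- min(widths)
  tied <- which(widths <= wmin + 1e-12)
  if (length(tied) > 1) {
    med <- stats::median(xs)
    mid <- (xs[tied] + xs[tied + nkeep - 1]) / 2
    tied <- tied[which.min(abs(mid - med))]
  }
  i <- tied[1]
  c(mean = mean(draws), mode = mode, low = xs[i], high = xs[i + nkeep - 1])
}
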