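# Readers/writers, the run manifest and the end-to-end pipeline.

#' Read a community abundance table from CSV
#'
#' Expects long format with columns `site`, `replicate`, `taxon`, `count` and
#' optionally `trophic_group`. Rows with negative counts and duplicate
#' (site, replicate, taxon) combinations are rejected with the offending row
#' numbers.
#'
#' @param path Path to a CSV file.
#' @param quadrat_area Quadrat area in m^2 (not stored in the file).
#' @return A [community_table()].
#' @export
read_abundance_table <- function(path, quadrat_area = 0.09) {
  .assert(file.exists(path), sprintf("file not found: %s", path),
          "isofw_parse_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  community_table(df, quadrat_area = quadrat_area)
}

#' Read per-specimen isotope records from CSV
#'
#' Expects columns `entity`, `entity_class` (`source`/`consumer`), `site`,
#' `d13C`, `d15N`; extra columns (e.g. `group` for sources) are kept.
#'
#' @param path Path to a CSV file.
#' @return An [isotope_records()] data frame.
#' @export
read_isotope_table <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path),
          "isofw_parse_error")
  isotope_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a data frame to CSV (UTF-8, header, "." decimal separator)
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build and write a run manifest
#'
#' Records the configuration snapshot, all seeds, the package version, input
#' file digests and a timestamp. The manifest is written before any results so
#' a run is reproducible even if it aborts midway.
#'
#' @param out_dir Output directory.
#' @param seed Master seed of the run.
#' @param config_snapshot List describing the run configuration.
#' @param input_files Character vector of input paths to digest (may be empty).
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
write_manifest <- function(out_dir, seed, config_snapshot = list(),
                           input_files = character(0)) {
  digests <- if (length(input_files)) {
    as.list(tools::md5sum(input_files))
  } else {
    NULL
  }
  manifest <- list(
    package = "isofoodweb",
    version = as.character(utils::packageVersion("isofoodweb")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    input_digests = digests,
    config = config_snapshot
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(manifest)
}

#' Run the full two-site analysis pipeline
#'
#' Executes, for a synthetic study or user-supplied tables: (1) community
#' metrics — per-replicate Shannon/Pielou indices with a between-site t test,
#' Sorensen similarity of the pooled taxon sets, per-taxon densities and
#' trophic-group composition; (2) isotopic niche — baseline selection,
#' trophic levels, Layman metrics, SEA/SEAc with posterior draws, and the
#' between-site ellipse overlap; (3) diet mixing — source aggregation and a
#' Bayesian mixing fit per consumer species and site. All outputs are written
#' as CSV under `out_dir` together with a JSON manifest (and `truth.json`
#' when simulating).
#'
#' @param config A [study_config()]; its data are simulated unless both
#'   `abundances` and `records` are supplied.
#' @param out_dir Output directory (created if needed); `NULL` disables file
#'   output.
#' @param stages Subset of `c("community", "niche", "mixing")`.
#' @param abundances,records Optional pre-loaded [community_table()] and
#'   [isotope_records()] overriding simulation.
#' @param mcmc [mcmc_control()] used for every mixing fit.
#' @param n_draws,alpha,delta_n,lambda,resolution Stage parameters; see the
#'   stage functions.
#' @param primary_consumers Baseline candidates; defaults to the config's
#'   flagged primary consumers.
#' @return List of class `pipeline_result` with elements per executed stage
#'   plus the manifest.
#' @export
run_full_pipeline <- function(config, out_dir = NULL,
                              stages = c("community", "niche", "mixing"),
                              abundances = NULL, records = NULL,
                              mcmc = mcmc_control(seed = config$seed),
                              n_draws = 4000, alpha = 0.05,
                              delta_n = 2.5, lambda = 2, resolution = 1000,
                              primary_consumers = NULL) {
  .assert(inherits(config, "study_config"), "`config` must be a study_config",
          "isofw_domain_error")
  stages <- match.arg(stages, several.ok = TRUE)
  stage_fail <- function(stage, e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_table(x, file.path(out_dir, name))
  }

  simulated <- is.null(abundances) || is.null(records)
  truth <- NULL
  if (simulated) {
    message("[simulate] generating synthetic study (seed ", config$seed, ")")
    study <- generate_study(config)
    if (is.null(abundances)) abundances <- study$abundances
    if (is.null(records)) records <- study$records
    truth <- study$truth
  }
  if (is.null(primary_consumers)) {
    primary_consumers <- config$consumers$species[config$consumers$primary_consumer]
  }
  sites <- config$sites

  if (!is.null(out_dir)) {
    write_manifest(out_dir, seed = config$seed,
                   config_snapshot = list(
                     sites = sites, n_replicates = config$n_replicates,
                     quadrat_area = config$quadrat_area,
                     simulated = simulated, stages = stages,
                     mcmc = unclass(mcmc), n_draws = n_draws, alpha = alpha,
                     delta_n = delta_n, lambda = lambda,
                     resolution = resolution))
    if (simulated) {
      tr <- truth
      tr$diet_proportions <- as.data.frame(tr$diet_proportions)
      jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
    }
    emit(as.data.frame(abundances), "abundances.csv")
    emit(as.data.frame(records), "isotopes.csv")
  }

  result <- list(config = config, truth = truth, sites = sites)

  if ("community" %in% stages) {
    res <- tryCatch({
      div <- replicate_diversity(abundances)
      tt_H <- two_sample_t_test(div$shannon_H[div$site == sites[1]],
                                div$shannon_H[div$site == sites[2]])
      tt_J <- two_sample_t_test(div$pielou_J[div$site == sites[1]],
                                div$pielou_J[div$site == sites[2]])
      taxa_present <- function(s) {
        sub <- abundances[abundances$site == s, ]
        unique(sub$taxon[sub$count > 0])
      }
      sor <- sorensen_index(taxa_present(sites[1]), taxa_present(sites[2]))
      comp <- lapply(sites, function(s) trophic_group_composition(abundances, s))
      names(comp) <- sites
      dens <- stats::aggregate(count ~ site + taxon, data = abundances, sum)
      dens$density_m2 <- density_per_m2(
        dens$count, config$quadrat_area * config$n_replicates)
      list(diversity = div, t_test_shannon = tt_H, t_test_pielou = tt_J,
           sorensen = sor, composition = comp, density = dens)
    }, error = function(e) stage_fail("community", e))
    emit(res$diversity, "diversity.csv")
    emit(res$density, "density.csv")
    result$community <- res
    message(sprintf("[community] Sorensen = %.2f; Shannon t-test p = %.3g",
                    res$sorensen, res$t_test_shannon$p_value))
  }

  if ("niche" %in% stages) {
    res <- tryCatch({
      niches <- lapply(seq_along(sites), function(i) {
        niche_summary(records, sites[i], n_draws = n_draws,
                      seed = config$seed + 10L + i)
      })
      names(niches) <- sites
      tls <- lapply(sites, function(s) {
        trophic_level_table(records, primary_consumers = primary_consumers,
                            site = s, delta_n = delta_n, lambda = lambda)
      })
      tl <- do.call(rbind, tls)
      cons_pts <- function(s) {
        sub <- records[records$entity_class == "consumer" & records$site == s, ]
        as.matrix(sub[, c("d13C", "d15N")])
      }
      overlap <- ellipse_overlap(cons_pts(sites[1]), cons_pts(sites[2]),
                                 resolution = resolution)
      list(niches = niches, trophic_levels = tl, overlap = overlap)
    }, error = function(e) stage_fail("niche", e))
    emit(res$trophic_levels, "trophic_levels.csv")
    niche_df <- do.call(rbind, lapply(res$niches, function(ns) {
      data.frame(site = ns$site, t(ns$layman), SEA = ns$SEA, SEAc = ns$SEAc,
                 SEAc_posterior_median = stats::median(ns$SEA_posterior),
                 n_points = ns$n_points, n_species = ns$n_species)
    }))
    emit(niche_df, "niche_summary.csv")
    if (!is.null(out_dir)) {
      for (s in sites) {
        write_table(data.frame(SEA_draw = res$niches[[s]]$SEA_posterior),
                    file.path(out_dir, paste0("sea_posterior_", s, ".csv")))
      }
    }
    result$niche <- res
    message(sprintf("[niche] SEAc %s = %.2f, %s = %.2f, overlap = %.3f permil^2",
                    sites[1], res$niches[[1]]$SEAc,
                    sites[2], res$niches[[2]]$SEAc, res$overlap))
  }

  if ("mixing" %in% stages) {
    res <- tryCatch({
      fits <- list()
      rows <- list()
      for (s in sites) {
        src_recs <- records[records$entity_class == "source" & records$site == s, ]
        .assert(nrow(src_recs) > 0, sprintf("no source records at site '%s'", s),
                "isofw_insufficient_data")
        src_df <- data.frame(species = src_recs$entity, group = src_recs$group,
                             d13C = src_recs$d13C, d15N = src_recs$d15N)
        grp <- aggregate_sources(src_df, alpha = alpha)
        for (sp in unique(records$entity[records$entity_class == "consumer"])) {
          sub <- records[records$entity_class == "consumer" &
                           records$site == s & records$entity == sp, ]
          if (nrow(sub) < 3) next
          fit <- fit_mixing_model(sub[, c("d13C", "d15N")], grp,
                                  tef = config$tef, mcmc = mcmc)
          fits[[paste(s, sp, sep = ":")]] <- fit
          rows[[length(rows) + 1]] <- cbind(site = s, species = sp, fit$summary)
        }
      }
      list(fits = fits, summary = do.call(rbind, rows))
    }, error = function(e) stage_fail("mixing", e))
    emit(res$summary, "mixing_summary.csv")
    result$mixing <- res
    message(sprintf("[mixing] fitted %d consumer x site models", length(res$fits)))
  }

  class(result) <- "pipeline_result"
  result
}
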