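# Community structure and biodiversity metrics for replicated quadrat samples.

#' Sorensen similarity index between two taxon sets
#'
#' Computes `S = 2a / (2a + b + c)` where `a` is the number of taxa shared by
#' both communities, `b` the number unique to the first and `c` the number
#' unique to the second. Symmetric in its arguments; 1 for identical non-empty
#' sets, 0 for disjoint sets.
#'
#' @param taxa_a,taxa_b Character vectors of taxon labels (duplicates ignored).
#' @return A single numeric value in `[0, 1]`.
#' @examples
#' # two sites sharing 11 of 32 and 23 taxa
#' a <- paste0("t", 1:32)
#' b <- paste0("t", c(1:11, 33:44))
#' sorensen_index(a, b) # 0.40
#' @export
sorensen_index <- function(taxa_a, taxa_b) {
  taxa_a <- unique(as.character(taxa_a))
  taxa_b <- unique(as.character(taxa_b))
  .assert(length(taxa_a) > 0 || length(taxa_b) > 0,
          "both taxon sets are empty; Sorensen index is undefined",
          "isofw_undefined_input")
  a <- length(intersect(taxa_a, taxa_b))
  b <- length(setdiff(taxa_a, taxa_b))
  cc <- length(setdiff(taxa_b, taxa_a))
  2 * a / (2 * a + b + cc)
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over taxa with non-zero counts, with
#' `p_i = count_i / sum(counts)`. The default base-2 logarithm gives bits per
#' individual; zero-count taxa contribute nothing.
#'
#' @param counts Non-negative numeric vector of per-taxon counts.
#' @param log_base Base of the logarithm (default 2).
#' @return Shannon index, a non-negative scalar bounded by `log(richness)`.
#' @export
shannon_index <- function(counts, log_base = 2) {
  .assert(is.numeric(counts) && all(is.finite(counts)) && all(counts >= 0),
          "`counts` must be finite and non-negative", "isofw_domain_error")
  .assert(any(counts > 0), "all counts are zero; Shannon index is undefined",
          "isofw_undefined_input")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = log_base))
}

#' Pielou evenness index
#'
#' `J' = H' / H'_max` with `H'_max = log(richness)` in the same base as the
#' Shannon index; 1 means all observed taxa are equally abundant.
#'
#' @inheritParams shannon_index
#' @return Evenness in `[0, 1]`.
#' @export
pielou_evenness <- function(counts, log_base = 2) {
  .assert(is.numeric(counts) && all(is.finite(counts)) && all(counts >= 0),
          "`counts` must be finite and non-negative", "isofw_domain_error")
  richness <- sum(counts > 0)
  .assert(richness >= 2,
          "Pielou evenness needs at least two taxa with non-zero counts",
          "isofw_undefined_input")
  shannon_index(counts, log_base) / log(richness, base = log_base)
}

#' Density of individuals per square metre
#'
#' @param count Number of individuals counted (non-negative).
#' @param quadrat_area Sampled area in square metres (> 0); the default is a
#'   30 x 30 cm quadrat.
#' @return Individuals per square metre.
#' @export
density_per_m2 <- function(count, quadrat_area = 0.09) {
  .assert(is.numeric(count) && all(count >= 0),
          "`count` must be non-negative", "isofw_domain_error")
  .assert(is.numeric(quadrat_area) && length(quadrat_area) == 1 && quadrat_area > 0,
          "`quadrat_area` must be a single positive number (m^2)",
          "isofw_domain_error")
  count / quadrat_area
}

#' Construct a validated community abundance table
#'
#' A community table is a long-format data frame with one row per
#' (site, replicate, taxon) and columns `site`, `replicate`, `taxon`,
#' `count` and `trophic_group`, carrying the quadrat area as an attribute.
#' Taxa with positive counts but no trophic-group assignment are labelled
#' `"unassigned"` rather than dropped.
#'
#' @param data Data frame with columns `site`, `replicate`, `taxon`, `count`
#'   and optionally `trophic_group`.
#' @param quadrat_area Area of one replicate quadrat in m^2 (> 0).
#' @return An object of class `community_table` (a data frame).
#' @export
community_table <- function(data, quadrat_area = 0.09) {
  .assert(is.data.frame(data), "`data` must be a data frame", "isofw_parse_error")
  needed <- c("site", "replicate", "taxon", "count")
  missing_cols <- setdiff(needed, names(data))
  .assert(length(missing_cols) == 0,
          paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          "isofw_parse_error")
  .assert(is.numeric(data$count), "`count` must be numeric", "isofw_parse_error")
  bad <- which(!is.finite(data$count) | data$count < 0 | data$count != round(data$count))
  .assert(length(bad) == 0,
          paste0("negative, non-finite or non-integer count in row(s): ",
                 paste(bad, collapse = ", ")),
          "isofw_parse_error")
  key <- paste(data$site, data$replicate, data$taxon, sep = "\r")
  dup <- which(duplicated(key))
  .assert(length(dup) == 0,
          paste0("duplicate (site, replicate, taxon) row(s): ",
                 paste(dup, collapse = ", ")),
          "isofw_parse_error")
  .assert(is.numeric(quadrat_area) && length(quadrat_area) == 1 && quadrat_area > 0,
          "`quadrat_area` must be a single positive number (m^2)",
          "isofw_domain_error")
  if (is.null(data$trophic_group)) data$trophic_group <- NA_character_
  data$trophic_group <- as.character(data$trophic_group)
  data$trophic_group[is.na(data$trophic_group) | data$trophic_group == ""] <- "unassigned"
  known <- c(.trophic_groups, "unassigned")
  unknown <- setdiff(unique(data$trophic_group), known)
  if (length(unknown) > 0) {
    warning(sprintf("unknown trophic group(s): %s (kept as given)",
                    paste(unknown, collapse = ", ")))
  }
  data <- data[, c("site", "replicate", "taxon", "count", "trophic_group")]
  attr(data, "quadrat_area") <- quadrat_area
  class(data) <- c("community_table", "data.frame")
  data
}

# trophic guilds used for motile invertebrates in seagrass/macroalgal beds
.trophic_groups <- c("herbivore", "herbivore/detritivore", "carnivore",
                     "omnivore/detritivore", "filter-feeder")

#' Trophic-group composition as percentages of individuals
#'
#' Percentage of all counted individuals (not taxa) in each trophic group,
#' pooled over replicates. Unassigned taxa appear under their own
#' `"unassigned"` key; percentages sum to 100.
#'
#' @param table A [community_table()] (optionally pre-filtered to one site).
#' @param site Optional site label to subset to before tabulating.
#' @return Named numeric vector of percentages, sorted decreasing.
#' @export
trophic_group_composition <- function(table, site = NULL) {
  .assert(inherits(table, "community_table") ||
            (is.data.frame(table) && all(c("count", "trophic_group") %in% names(table))),
          "`table` must be a community_table", "isofw_domain_error")
  if (!is.null(site)) table <- table[table$site %in% site, , drop = FALSE]
  .assert(sum(table$count) > 0,
          "no individuals counted; composition is undefined",
          "isofw_undefined_input")
  tot <- tapply(table$count, table$trophic_group, sum)
  pct <- 100 * tot / sum(tot)
  sort(pct, decreasing = TRUE)
}

#' Per-replicate diversity summaries for a community table
#'
#' Computes richness, total individuals, Shannon `H'` and Pielou `J'` for each
#' (site, replicate). Taxa absent from a replicate contribute zero counts and
#' are ignored by the indices; `J'` is `NA` when a replicate holds a single
#' taxon.
#'
#' @inheritParams trophic_group_composition
#' @param log_base Logarithm base passed to [shannon_index()].
#' @return Data frame with columns `site`, `replicate`, `richness`,
#'   `total_individuals`, `shannon_H`, `pielou_J`.
#' @export
replicate_diversity <- function(table, log_base = 2) {
  .assert(is.data.frame(table) &&
            all(c("site", "replicate", "count") %in% names(table)),
          "`table` must be a community_table", "isofw_domain_error")
  keys <- unique(table[, c("site", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$site == keys$site[i] & table$replicate == keys$replicate[i], ]
    counts <- sub$count
    richness <- sum(counts > 0)
    data.frame(site = keys$site[i], replicate = keys$replicate[i],
               richness = richness,
               total_individuals = sum(counts),
               shannon_H = if (richness >= 1) shannon_index(counts, log_base) else NA_real_,
               pielou_J = if (richness >= 2) pielou_evenness(counts, log_base) else NA_real_)
  })
  do.call(rbind, out)
}

#' Two-sample t test (Student or Welch)
#'
#' Two-sided comparison of two groups of measurements, defaulting to the
#' classical Student test with pooled variance; the Welch variant relaxes the
#' equal-variance assumption.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `variant`.
#' @export
two_sample_t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  .assert(is.numeric(x) && is.numeric(y), "inputs must be numeric",
          "isofw_domain_error")
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  .assert(length(x) >= 2 && length(y) >= 2,
          "each group needs at least two finite observations",
          "isofw_insufficient_data")
  .assert(stats::var(x) > 0 || stats::var(y) > 0,
          "zero variance in both groups; t test is degenerate",
          "isofw_degenerate_input")
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y),
       variant = variant)
}

#' Kruskal-Wallis test with Dunn-type post-hoc comparisons
#'
#' Rank-based global comparison of two or more groups with tie correction,
#' followed (when the global test is significant at `alpha`) by Dunn z
#' comparisons of mean ranks with Bonferroni correction. Pairs whose adjusted
#' post-hoc p value exceeds `alpha` — or all pairs, when the global test is
#' not significant — are flagged as mergeable; this drives a-priori pooling
#' of ecologically related isotope sources.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, total n >= 3).
#' @param alpha Significance level for both the global and post-hoc decisions.
#' @return List with `H`, `df`, `p_value`, `merge_all` (logical), and
#'   `pairwise`, a data frame with columns `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adjusted`, `mergeable`.
#' @export
kruskal_wallis_posthoc <- function(groups, alpha = 0.05) {
  .assert(is.list(groups) && length(groups) >= 2,
          "`groups` must be a list of at least two numeric vectors",
          "isofw_domain_error")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  lens <- vapply(groups, length, integer(1))
  .assert(all(lens >= 1) && sum(lens) >= 3,
          "each group needs n >= 1 and total n >= 3", "isofw_insufficient_data")
  x <- unlist(groups, use.names = FALSE)
  .assert(all(is.finite(x)), "groups contain non-finite values",
          "isofw_domain_error")
  g <- factor(rep(names(groups), lens), levels = names(groups))
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)

  if (length(unique(x)) == 1) {
    # all observations tied: H is 0 by construction, no division by zero
    pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                           z = 0, p_raw = 1, p_adjusted = 1, mergeable = TRUE,
                           stringsAsFactors = FALSE)
    return(list(H = 0, df = k - 1, p_value = 1, merge_all = TRUE,
                pairwise = pairwise))
  }

  kt <- stats::kruskal.test(x, g)
  global_p <- kt$p.value
  H <- unname(kt$statistic)

  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term

  z <- p_raw <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(v0 * (1 / lens[[a]] + 1 / lens[[b]]))
    z[i] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p_raw[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  merge_all <- global_p > alpha
  pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                         z = z, p_raw = p_raw, p_adjusted = p_adj,
                         mergeable = merge_all | p_adj > alpha,
                         stringsAsFactors = FALSE)
  list(H = H, df = k - 1, p_value = global_p, merge_all = merge_all,
       pairwise = pairwise)
}
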