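# internal helpers shared across modules

#' @keywords internal
.assert <- function(cond, msg, class = "isofw_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls do not disturb user RNG.
#' @keywords internal
.with_seed <- function(seed, expr) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "`seed` must be a single finite integer", "isofw_domain_error")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' @keywords internal
.as_points <- function(points, min_n = 2L, what = "points") {
  if (is.data.frame(points)) points <- as.matrix(points)
  .assert(is.matrix(points) && ncol(points) == 2 && is.numeric(points),
          sprintf("`%s` must be a numeric matrix or data frame with two columns (d13C, d15N)", what),
          "isofw_domain_error")
  .assert(all(is.finite(points)),
          sprintf("`%s` contains non-finite values", what), "isofw_domain_error")
  .assert(nrow(points) >= min_n,
          sprintf("`%s` needs at least %d rows, got %d", what, min_n, nrow(points)),
          "isofw_insufficient_data")
  unname(points)
}
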