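#' Fixation fraction for one quenched fitness configuration
#'
#' Runs `n_iters` independent absorption runs against a fixed (quenched)
#' fitness field. Each run starts from an all-resident lattice, replaces one
#' uniformly chosen site by a mutant, and applies death-birth updates until
#' fixation or extinction. Uses the current R random stream.
#'
#' @param field A [fitness_field()], held fixed across all iterations.
#' @param motility A [motility_params()].
#' @param lattice A [build_lattice()] object.
#' @param n_iters Number of absorption runs.
#' @param max_updates,cascade_cap Passed to the engine; see
#'   [run_to_absorption()].
#' @return The fixation fraction (fixed runs / `n_iters`), with the integer
#'   count attached as attribute `"n_fixed"`.
#' @examples
#' set.seed(2)
#' lat <- build_lattice(5, 5)
#' f <- fitness_field(rep(1, 25), rep(2, 25))
#' estimate_fixation_single_config(f, motility_params(), lat, n_iters = 200)
#' @export
estimate_fixation_single_config <- function(field, motility, lattice, n_iters,
                                            max_updates = 100 * lattice$n_sites^2,
                                            cascade_cap = 1e6) {
  stopifnot(inherits(field, "fitness_field"),
            inherits(motility, "motility_params"),
            inherits(lattice, "moran_lattice"))
  if (n_iters < 1) abort("`n_iters` must be at least 1.")
  if (all(field$r_B <= 0) && motility$m_B == 0) {
    # mutants can never reproduce anywhere: short-circuit, fraction is 0
    out <- 0
    attr(out, "n_fixed") <- 0L
    return(out)
  }
  starts <- sample.int(lattice$n_sites, n_iters, replace = TRUE) - 1L
  use_migration <- motility$m_A > 0 || motility$m_B > 0
  res <- cpp_estimate_runs(lattice$nbr_mat, lattice$degree,
                           field$r_A, field$r_B,
                           motility$m_A, motility$m_B,
                           starts, max_updates, cascade_cap, use_migration)
  n_fixed <- sum(res$fixed)
  out <- n_fixed / n_iters
  attr(out, "n_fixed") <- as.integer(n_fixed)
  out
}

#' Invasion probability averaged over quenched fitness configurations
#'
#' The full estimation protocol: draw `n_configs` independent quenched fitness
#' fields from the given distributions, estimate the fixation fraction of a
#' uniformly placed single mutant for each (over `n_iters` runs), and average.
#' The reported uncertainty (`spread`) is the standard deviation of the
#' per-configuration fractions; each configuration's binomial standard error
#' is also recorded so the two sources of uncertainty — stochastic trajectories
#' within a configuration and randomness of the field between configurations —
#' remain decomposable.
#'
#' @param spec_B,spec_A [fitness_spec] objects for mutants and residents.
#' @param motility A [motility_params()].
#' @param lattice A [build_lattice()] object.
#' @param n_configs Number of independent fitness configurations.
#' @param n_iters Absorption runs per configuration.
#' @param seed Optional master seed; per-configuration child seeds are derived
#'   from it, so identical seeds give bit-identical estimates.
#' @param max_updates,cascade_cap Passed to the engine.
#' @return An object of class `fixation_estimate`; see [tidy.fixation_estimate()]
#'   and [glance.fixation_estimate()].
#' @examples
#' est <- estimate_fixation(fitness_uniform(1.5, 0.5), fitness_constant(1),
#'                          motility_params(), build_lattice(5, 5),
#'                          n_configs = 3, n_iters = 100, seed = 1)
#' glance(est)
#' @export
estimate_fixation <- function(spec_B, spec_A, motility, lattice,
                              n_configs = 10, n_iters = 10000, seed = NULL,
                              max_updates = 100 * lattice$n_sites^2,
                              cascade_cap = 1e6) {
  stopifnot(inherits(spec_B, "fitness_spec"), inherits(spec_A, "fitness_spec"))
  if (n_configs < 1) abort("`n_configs` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  config_seeds <- sample.int(.Machine$integer.max - 1L, n_configs)
  frac <- numeric(n_configs)
  n_fixed <- integer(n_configs)
  for (k in seq_len(n_configs)) {
    set.seed(config_seeds[k])
    field <- sample_field_pair(lattice, spec_A, spec_B)
    f <- estimate_fixation_single_config(field, motility, lattice, n_iters,
                                         max_updates = max_updates,
                                         cascade_cap = cascade_cap)
    frac[k] <- as.numeric(f)
    n_fixed[k] <- attr(f, "n_fixed")
  }
  per_config <- tibble::tibble(
    config = seq_len(n_configs),
    seed = config_seeds,
    n_fixed = n_fixed,
    fraction = frac,
    se_binomial = sqrt(frac * (1 - frac) / n_iters)
  )
  structure(
    list(per_config = per_config,
         rho = mean(frac),
         spread = if (n_configs > 1) sd(frac) else 0,
         n_iters = n_iters, n_configs = n_configs, seed = seed,
         spec_B = spec_B, spec_A = spec_A, motility = motility,
         lattice_dims = c(lattice$rows, lattice$cols)),
    class = "fixation_estimate"
  )
}

#' Combined standard error of a fixation estimate
#'
#' Standard error of the pooled invasion probability, combining the
#' between-configuration spread (scaled by `sqrt(n_configs)`) and the pooled
#' binomial sampling error in quadrature.
#'
#' @param est A [estimate_fixation()] result.
#' @return A single non-negative number.
#' @export
combined_se <- function(est) {
  stopifnot(inherits(est, "fixation_estimate"))
  se_bin <- sqrt(est$rho * (1 - est$rho) / (est$n_iters * est$n_configs))
  sqrt(est$spread^2 / est$n_configs + se_bin^2)
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf(
    "<fixation_estimate> rho = %.5f (spread %.5f over %d configs x %d iters)\n",
    x$rho, x$spread, x$n_configs, x$n_iters))
  invisible(x)
}

#' Tidy a fixation estimate into per-configuration rows
#'
#' @param x A [estimate_fixation()] result.
#' @param ... Unused.
#' @return A tibble with one row per quenched fitness configuration.
#' @export
tidy.fixation_estimate <- function(x, ...) {
  x$per_config
}

#' One-row summary of a fixation estimate
#'
#' @param x A [estimate_fixation()] result.
#' @param ... Unused.
#' @return A tibble with columns `rho`, `spread`, `se_combined`, `n_configs`,
#'   `n_iters`.
#' @export
glance.fixation_estimate <- function(x, ...) {
  tibble::tibble(rho = x$rho, spread = x$spread, se_combined = combined_se(x),
                 n_configs = x$n_configs, n_iters = x$n_iters)
}

#' Sweep the invasion probability over a parameter grid
#'
#' Repeats the full estimation protocol at each value of one swept parameter:
#' the half-width `delta` of a uniform mutant-fitness distribution, the
#' advantaged-site fraction `x` of a bimodal distribution, the mutant motility
#' `m_B`, or the uniform-distribution mean `r_B_mean`.
#'
#' @param variable One of `"delta"`, `"x"`, `"m_B"`, `"r_B_mean"`.
#' @param values Numeric grid (non-empty); rows are returned in this order.
#' @param lattice A [build_lattice()] object.
#' @param spec_B Mutant fitness spec; must be `uniform` when sweeping `delta`
#'   or `r_B_mean` and `bimodal` when sweeping `x`.
#' @param spec_A Resident fitness spec.
#' @param motility Baseline motility (replaced when sweeping `m_B`).
#' @param n_configs,n_iters,seed,max_updates,cascade_cap As in
#'   [estimate_fixation()]; each grid point gets its own child seed derived
#'   from `seed`.
#' @param verbose Print one progress line per grid point.
#' @return A tibble of class `fixation_sweep` with one row per grid value:
#'   the swept `variable`, `value`, `rho`, `spread`, `se_combined`, and a
#'   `per_config` list-column of per-configuration tables.
#' @examples
#' sw <- sweep_fixation("delta", c(0, 0.5), build_lattice(5, 5),
#'                      spec_B = fitness_uniform(1.5, 0),
#'                      n_configs = 2, n_iters = 100, seed = 1)
#' sw
#' @export
sweep_fixation <- function(variable = c("delta", "x", "m_B", "r_B_mean"),
                           values, lattice,
                           spec_B, spec_A = fitness_constant(1),
                           motility = motility_params(),
                           n_configs = 10, n_iters = 10000, seed = NULL,
                           max_updates = 100 * lattice$n_sites^2,
                           cascade_cap = 1e6, verbose = FALSE) {
  variable <- match.arg(variable)
  if (length(values) == 0) abort("`values` must be a non-empty numeric grid.")
  if (variable %in% c("delta", "r_B_mean") && spec_B$kind != "uniform") {
    abort(sprintf("sweeping `%s` requires a uniform mutant spec.", variable))
  }
  if (variable == "x" && spec_B$kind != "bimodal") {
    abort("sweeping `x` requires a bimodal mutant spec.")
  }
  if (!is.null(seed)) set.seed(seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, length(values))
  rows <- purrr::map2(values, point_seeds, function(v, s) {
    sb <- spec_B
    mot <- motility
    switch(variable,
      delta = { sb <- fitness_uniform(spec_B$mean, v) },
      x = { sb <- fitness_bimodal(spec_B$r1, spec_B$r2, v) },
      m_B = { mot <- motility_params(motility$m_A, v) },
      r_B_mean = { sb <- fitness_uniform(v, spec_B$width) }
    )
    est <- estimate_fixation(sb, spec_A, mot, lattice,
                             n_configs = n_configs, n_iters = n_iters,
                             seed = s, max_updates = max_updates,
                             cascade_cap = cascade_cap)
    if (verbose) {
      message(sprintf("  %s = %g: rho = %.5f (+/- %.5f)",
                      variable, v, est$rho, est$spread))
    }
    tibble::tibble(variable = variable, value = v,
                   rho = est$rho, spread = est$spread,
                   se_combined = combined_se(est),
                   n_configs = n_configs, n_iters = n_iters,
                   per_config = list(est$per_config))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fixation_sweep", class(out))
  out
}

#' Plot a fixation sweep
#'
#' Point-and-error-bar plot of the invasion probability against the swept
#' parameter; error bars are the standard deviation of per-configuration
#' fractions.
#'
#' @param object A [sweep_fixation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fixation_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$rho)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$rho - .data$spread),
                                          ymax = pmin(1, .data$rho + .data$spread))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$variable[1], y = "invasion probability ρ")
}
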