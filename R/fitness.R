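#' Fitness distribution specifications
#'
#' A `fitness_spec` describes how the quenched per-site fitness of one
#' phenotype is generated. Fitness is a property of position — a value is drawn
#' (or assigned) once per site and then held fixed for a whole simulation
#' batch, modelling micro-environmental heterogeneity that varies in space but
#' is effectively constant on the selection time scale.
#'
#' * `fitness_constant(mean)` — every site gets `mean`.
#' * `fitness_uniform(mean, width)` — i.i.d. uniform on
#'   `[mean - width, mean + width]`; requires `mean - width >= 0` so fitness is
#'   never negative.
#' * `fitness_triangular(lower, upper, mode)` — i.i.d. from the triangular
#'   density on `[lower, upper]` with the given mode. Skew makes the mean
#'   (`(lower + mode + upper) / 3`) differ from the mode, which is how a
#'   nominally neutral mutant can be pushed towards advantage or disadvantage.
#' * `fitness_bimodal(r1, r2, x)` — a two-valued field: exactly
#'   `round(x * n_sites)` sites (round half up) chosen uniformly without
#'   replacement get `r2`, the rest `r1`. The fraction `x` is a composition
#'   statement about the system, not a per-site coin flip, so the count is
#'   exact in every realisation.
#' * `fitness_checkerboard(r_low, r_high)` — deterministic alternating
#'   pattern: site (i, j) gets `r_high` when `i + j` is even. This is the
#'   ideal evenly-mixed arrangement of advantaged sites.
#'
#' Zero fitness is allowed (such a cell can die but never reproduce); negative
#' fitness is an error.
#'
#' @param mean,width,lower,upper,mode,r1,r2,x,r_low,r_high Numeric scalars, see
#'   above.
#' @return An object of class `fitness_spec`.
#' @examples
#' fitness_uniform(1.5, 1.5)
#' fitness_bimodal(0.5, 1.5, x = 0.5)
#' @name fitness_spec
NULL

new_fitness_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "fitness_spec")
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name),
          class = "moranfield_spec_error")
  }
  invisible(x)
}

#' @rdname fitness_spec
#' @export
fitness_constant <- function(mean) {
  check_nonneg(mean, "mean")
  new_fitness_spec("constant", mean = mean)
}

#' @rdname fitness_spec
#' @export
fitness_uniform <- function(mean, width) {
  check_nonneg(mean, "mean")
  check_nonneg(width, "width")
  if (mean - width < 0) {
    abort("uniform fitness support dips below zero: need `mean - width >= 0`.",
          class = "moranfield_spec_error")
  }
  new_fitness_spec("uniform", mean = mean, width = width)
}

#' @rdname fitness_spec
#' @export
fitness_triangular <- function(lower, upper, mode = 1) {
  check_nonneg(lower, "lower")
  check_nonneg(upper, "upper")
  check_nonneg(mode, "mode")
  if (!(lower <= mode && mode <= upper)) {
    abort("triangular spec needs `lower <= mode <= upper`.",
          class = "moranfield_spec_error")
  }
  if (lower == upper) {
    abort("triangular spec needs `lower < upper` (use fitness_constant for a point mass).",
          class = "moranfield_spec_error")
  }
  new_fitness_spec("triangular", lower = lower, mode = mode, upper = upper)
}

#' @rdname fitness_spec
#' @export
fitness_bimodal <- function(r1, r2, x) {
  check_nonneg(r1, "r1")
  check_nonneg(r2, "r2")
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort("`x` must be a fraction in [0, 1].", class = "moranfield_spec_error")
  }
  new_fitness_spec("bimodal", r1 = r1, r2 = r2, x = x)
}

#' @rdname fitness_spec
#' @export
fitness_checkerboard <- function(r_low, r_high) {
  check_nonneg(r_low, "r_low")
  check_nonneg(r_high, "r_high")
  new_fitness_spec("checkerboard", r_low = r_low, r_high = r_high)
}

#' @export
print.fitness_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf("<fitness_spec: %s> %s\n", x$kind,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Sample a quenched per-site fitness vector
#'
#' Draws one realisation of the fitness field described by a [fitness_spec].
#' Random kinds use the current R random number stream, so `set.seed()` gives
#' reproducible fields. The checkerboard kind is deterministic and needs the
#' lattice to know site coordinates.
#'
#' @param spec A [fitness_spec].
#' @param n_sites Number of lattice sites (ignored for `checkerboard`, taken
#'   from `lattice`).
#' @param lattice Required for `kind = "checkerboard"`.
#' @return A numeric vector of length `n_sites`, all entries `>= 0`.
#' @examples
#' set.seed(1)
#' r <- sample_fitness_field(fitness_uniform(1.5, 0.5), 441)
#' range(r)
#' @export
sample_fitness_field <- function(spec, n_sites, lattice = NULL) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (spec$kind == "checkerboard") {
    if (is.null(lattice)) {
      abort("checkerboard fields need `lattice` to resolve site coordinates.")
    }
    return(checkerboard_field(spec$r_low, spec$r_high, lattice))
  }
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 2) {
    abort("`n_sites` must be a single integer >= 2.")
  }
  n_sites <- as.integer(n_sites)
  switch(spec$kind,
    constant = rep(spec$mean, n_sites),
    uniform = runif(n_sites, spec$mean - spec$width, spec$mean + spec$width),
    triangular = rtriangular(n_sites, spec$lower, spec$mode, spec$upper),
    bimodal = {
      n_high <- as.integer(floor(spec$x * n_sites + 0.5))  # round half up
      field <- rep(spec$r1, n_sites)
      field[sample.int(n_sites, n_high)] <- spec$r2
      field
    },
    abort(sprintf("unknown fitness kind '%s'", spec$kind))
  )
}

# Inverse-CDF sampler for the triangular density on [a, b] with mode c.
rtriangular <- function(n, a, c, b) {
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Deterministic checkerboard fitness field
#'
#' Site (i, j) gets `r_high` when `i + j` is even and `r_low` otherwise — the
#' evenly distributed arrangement of advantaged and disadvantaged sites in
#' which every advantaged site is exactly one lattice step from the next. On an
#' odd-by-odd lattice the high sites outnumber the low sites by one.
#'
#' @param r_low,r_high Non-negative fitness values.
#' @param lattice A [build_lattice()] object.
#' @return Numeric vector of length `lattice$n_sites`.
#' @examples
#' matrix(checkerboard_field(0.5, 1.5, build_lattice(2, 2)), 2, byrow = TRUE)
#' @export
checkerboard_field <- function(r_low, r_high, lattice) {
  stopifnot(inherits(lattice, "moran_lattice"))
  check_nonneg(r_low, "r_low")
  check_nonneg(r_high, "r_high")
  co <- site_coords(lattice)
  ifelse((co$row + co$col) %% 2L == 0L, r_high, r_low)
}

#' Pair of quenched fitness vectors for the two phenotypes
#'
#' Bundles the per-site fitness of residents (`r_A`) and mutants (`r_B`) into
#' one immutable field object used by the dynamics. Both vectors must have one
#' entry per lattice site and no negative entries.
#'
#' @param r_A,r_B Numeric vectors of equal length, entries `>= 0`.
#' @return An object of class `fitness_field` with elements `r_A`, `r_B`,
#'   `n_sites`.
#' @examples
#' fitness_field(rep(1, 9), rep(1.5, 9))
#' @export
fitness_field <- function(r_A, r_B) {
  if (!is.numeric(r_A) || !is.numeric(r_B) || length(r_A) != length(r_B)) {
    abort("`r_A` and `r_B` must be numeric vectors of equal length.")
  }
  if (anyNA(r_A) || anyNA(r_B) || any(r_A < 0) || any(r_B < 0)) {
    abort("fitness values must be non-negative and non-missing.",
          class = "moranfield_spec_error")
  }
  structure(list(r_A = as.numeric(r_A), r_B = as.numeric(r_B),
                 n_sites = length(r_A)),
            class = "fitness_field")
}

#' @export
print.fitness_field <- function(x, ...) {
  cat(sprintf("<fitness_field> %d sites; r_A in [%.3g, %.3g], r_B in [%.3g, %.3g]\n",
              x$n_sites, min(x$r_A), max(x$r_A), min(x$r_B), max(x$r_B)))
  invisible(x)
}

#' Draw a fitness field for both phenotypes on a lattice
#'
#' Convenience wrapper: samples one quenched realisation of `spec_A` and
#' `spec_B` on the given lattice and returns the [fitness_field()].
#'
#' @param lattice A [build_lattice()] object.
#' @param spec_A,spec_B [fitness_spec] objects for residents and mutants.
#' @return A `fitness_field`.
#' @examples
#' set.seed(7)
#' sample_field_pair(build_lattice(5, 5), fitness_constant(1), fitness_uniform(1.5, 0.5))
#' @export
sample_field_pair <- function(lattice, spec_A, spec_B) {
  stopifnot(inherits(lattice, "moran_lattice"))
  fitness_field(
    sample_fitness_field(spec_A, lattice$n_sites, lattice),
    sample_fitness_field(spec_B, lattice$n_sites, lattice)
  )
}

#' Plot a per-site fitness vector as a lattice heat map
#'
#' @param field Numeric vector of per-site values (row-major site order).
#' @param lattice The lattice the vector lives on.
#' @return A ggplot object.
#' @export
plot_fitness_field <- function(field, lattice) {
  stopifnot(inherits(lattice, "moran_lattice"), length(field) == lattice$n_sites)
  df <- site_coords(lattice)
  df$fitness <- field
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fitness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "fitness")
}
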