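#' Motility parameters for the two phenotypes
#'
#' Cellular motility enters the update rule as a fitness-independent rate of
#' migration into a vacancy: after a death, each occupied neighbour of the
#' empty site can either divide into it (at rate proportional to its site
#' fitness) or migrate into it (at rate `m_A` or `m_B` by type). A migration
#' relocates the vacancy and the elementary-event draw repeats until a
#' division finally refills the system. Motility is uniform over the lattice.
#'
#' @param m_A,m_B Non-negative motility rates of residents and mutants.
#' @return An object of class `motility_params`.
#' @examples
#' motility_params(m_B = 5)
#' @export
motility_params <- function(m_A = 0, m_B = 0) {
  check_nonneg(m_A, "m_A")
  check_nonneg(m_B, "m_B")
  structure(list(m_A = m_A, m_B = m_B), class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat(sprintf("<motility_params> m_A = %g, m_B = %g\n", x$m_A, x$m_B))
  invisible(x)
}

#' Initial occupancy with a single mutant
#'
#' Occupancy vectors code residents (type A) as 0 and mutants (type B) as 1;
#' every site is occupied between updates (the population is constant at N).
#'
#' @param lattice A [build_lattice()] object.
#' @param mutant_site Site index for the initial mutant; by default a site is
#'   chosen uniformly at random, which is how invasion probabilities averaged
#'   over initial placements are defined.
#' @return Integer vector of length `n_sites` with exactly one 1.
#' @examples
#' initial_state(build_lattice(3, 3), mutant_site = 5)
#' @export
initial_state <- function(lattice, mutant_site = NULL) {
  stopifnot(inherits(lattice, "moran_lattice"))
  if (is.null(mutant_site)) {
    mutant_site <- sample.int(lattice$n_sites, 1L)
  }
  if (mutant_site < 1L || mutant_site > lattice$n_sites) {
    abort("`mutant_site` out of range.")
  }
  occ <- integer(lattice$n_sites)
  occ[mutant_site] <- 1L
  occ
}

#' Elementary-event distribution at a vacancy
#'
#' Given a configuration with one vacant site, returns the probabilities of
#' the four kinds of elementary event over the occupied neighbours of the
#' vacancy: an A or B neighbour divides into it, or an A or B neighbour
#' migrates into it. A neighbour `j` of type `T` divides with probability
#' `w * r_T[j] / N_r` and migrates with probability `w * m_T / N_r`, where
#' `N_r = sum_k w * (r_T(k)[k] + m_T(k))` runs over the occupied neighbours.
#' The edge weight `w` is the same for every term, so the distribution is
#' invariant to the convention used for `w` (constant 1/4 versus 1/degree).
#'
#' @param occupancy Integer vector, 0 = A, 1 = B, `NA` at the vacant site.
#' @param field A [fitness_field()].
#' @param motility A [motility_params()].
#' @param lattice A [build_lattice()] object.
#' @param vacancy Site index of the vacancy; `occupancy[vacancy]` must be `NA`.
#' @param w Edge weight; defaults to the lattice's constant 1/4.
#' @return A tibble with columns `site`, `type` ("A"/"B"), `event`
#'   ("divide"/"migrate") and `prob`, with the normalisation `N_r` attached as
#'   attribute `"normalization"`. Probabilities sum to 1.
#' @examples
#' lat <- build_lattice(3, 3)
#' occ <- rep(0L, 9); occ[5] <- NA
#' f <- fitness_field(rep(1, 9), rep(1.5, 9))
#' event_distribution(occ, f, motility_params(), lat, vacancy = 5)
#' @export
event_distribution <- function(occupancy, field, motility, lattice, vacancy,
                               w = lattice$w) {
  stopifnot(inherits(lattice, "moran_lattice"),
            inherits(field, "fitness_field"),
            inherits(motility, "motility_params"))
  if (length(occupancy) != lattice$n_sites) {
    abort("`occupancy` must have one entry per lattice site.")
  }
  if (!is.na(occupancy[vacancy])) {
    abort("`vacancy` is occupied; the event distribution is defined at an empty site.",
          class = "moranfield_logic_error")
  }
  nbs <- lattice$neighbors[[vacancy]]
  occ_nbs <- nbs[!is.na(occupancy[nbs])]
  if (length(occ_nbs) == 0L) {
    abort("all neighbours of the vacancy are vacant; no elementary event is possible.",
          class = "moranfield_logic_error")
  }
  type <- occupancy[occ_nbs]
  r_div <- ifelse(type == 1L, field$r_B[occ_nbs], field$r_A[occ_nbs])
  r_mig <- ifelse(type == 1L, motility$m_B, motility$m_A)
  n_r <- sum(w * (r_div + r_mig))
  if (n_r <= 0) {
    abort("normalisation N_r is zero: no occupied neighbour can divide or migrate.",
          class = "moranfield_logic_error")
  }
  out <- tibble::tibble(
    site = rep(occ_nbs, each = 2L),
    type = rep(ifelse(type == 1L, "B", "A"), each = 2L),
    event = rep(c("divide", "migrate"), length(occ_nbs)),
    prob = as.vector(rbind(w * r_div, w * r_mig)) / n_r
  )
  attr(out, "normalization") <- n_r
  out
}

#' One death-birth (optionally death-birth/migration) update
#'
#' Pure-R reference implementation of a single update: a site is chosen
#' uniformly at random to die (probability 1/N each), then elementary events
#' are drawn at the vacancy until a division refills it. A migration event
#' moves the chosen neighbour into the vacancy and relocates the vacancy to
#' that neighbour's old site; the event distribution is then recomputed there.
#' An offspring takes the type of its parent and the fitness of the site it
#' lands on (fitness is bound to position, not carried by the cell).
#'
#' If no neighbour of a fresh vacancy can divide or migrate (all have zero
#' fitness and zero motility), the update is a null update: the dead cell is
#' restored and the configuration is unchanged.
#'
#' This implementation consumes uniform draws in exactly the same order as the
#' compiled engine, so with the same seed the two produce identical
#' trajectories; it exists for transparency and as a cross-check, not speed.
#'
#' @inheritParams event_distribution
#' @param occupancy Integer 0/1 vector, fully occupied (no `NA`).
#' @param cascade_cap Maximum elementary events within one update before a
#'   runtime error is raised (guards pathological motility regimes).
#' @param kernel `"migration"` (the general four-event kernel, default) or
#'   `"plain"` (division only; requires `m_A = m_B = 0`). With zero motility
#'   both kernels are event-for-event identical.
#' @return The updated occupancy vector with attribute `"n_elementary"`, the
#'   number of elementary events drawn (0 for a null update).
#' @examples
#' set.seed(1)
#' lat <- build_lattice(2, 2)
#' f <- fitness_field(rep(1, 4), rep(1, 4))
#' death_birth_update(initial_state(lat, 1), f, motility_params(), lat)
#' @export
death_birth_update <- function(occupancy, field, motility, lattice,
                               cascade_cap = 1e6,
                               kernel = c("migration", "plain")) {
  kernel <- match.arg(kernel)
  n <- lattice$n_sites
  if (kernel == "plain" && (motility$m_A > 0 || motility$m_B > 0)) {
    abort("`kernel = \"plain\"` requires zero motility.")
  }
  d <- min(floor(n * runif(1)) + 1, n)
  orig <- occupancy[d]
  if (kernel == "plain") {
    nbs <- lattice$neighbors[[d]]
    wts <- ifelse(occupancy[nbs] == 1L, field$r_B[nbs], field$r_A[nbs])
    tot <- sum(wts)
    if (tot <= 0) {
      attr(occupancy, "n_elementary") <- 0
      return(occupancy)
    }
    u <- tot * runif(1)
    pick <- which(u <= cumsum(wts))[1]
    occupancy[d] <- occupancy[nbs[pick]]
    attr(occupancy, "n_elementary") <- 1
    return(occupancy)
  }
  vac <- d
  events <- 0
  repeat {
    nbs <- lattice$neighbors[[vac]]
    type <- occupancy[nbs]
    r_div <- ifelse(type == 1L, field$r_B[nbs], field$r_A[nbs])
    r_mig <- ifelse(type == 1L, motility$m_B, motility$m_A)
    wts <- as.vector(rbind(r_div, r_mig))  # divide/migrate interleaved
    tot <- sum(wts)
    if (tot <= 0) {
      if (vac == d) {
        occupancy[d] <- orig
        attr(occupancy, "n_elementary") <- 0
        return(occupancy)
      }
      abort("vacancy cascade is stuck: every neighbour has zero fitness and zero motility.",
            class = "moranfield_logic_error")
    }
    u <- tot * runif(1)
    events <- events + 1
    if (events > cascade_cap) {
      abort(sprintf("elementary-event cap (%g) exceeded within a single update.",
                    cascade_cap),
            class = "moranfield_cascade_error")
    }
    pick <- which(u <= cumsum(wts))[1]
    j <- nbs[ceiling(pick / 2)]
    if (pick %% 2L == 1L) {  # division: vacancy filled, update complete
      occupancy[vac] <- occupancy[j]
      attr(occupancy, "n_elementary") <- events
      return(occupancy)
    }
    occupancy[vac] <- occupancy[j]  # migration: vacancy relocates to j
    vac <- j
  }
}

#' Run the process to an absorbing state
#'
#' Applies death-birth updates until the lattice is monomorphic: all mutants
#' (fixation) or all residents (extinction). Uses the compiled engine by
#' default; `engine = "reference"` replays the identical trajectory in pure R.
#'
#' @inheritParams death_birth_update
#' @param max_updates Cap on updates before a `moranfield_max_updates` error
#'   (carrying the partial state in its condition data) is raised. Default
#'   `100 * N^2`, generous relative to observed absorption times.
#' @param engine `"compiled"` or `"reference"`.
#' @param kernel `"auto"` picks the plain kernel when both motilities are zero
#'   (provably equivalent) and the migration kernel otherwise; either can be
#'   forced.
#' @return An object of class `moran_absorption`: list with `fixed` (TRUE if
#'   the all-mutant state was reached), `n_updates`, `n_elementary`, and the
#'   final `occupancy`.
#' @examples
#' set.seed(42)
#' lat <- build_lattice(4, 4)
#' f <- fitness_field(rep(1, 16), rep(2, 16))
#' run_to_absorption(initial_state(lat), f, motility_params(), lat)
#' @export
run_to_absorption <- function(occupancy, field, motility, lattice,
                              max_updates = 100 * lattice$n_sites^2,
                              cascade_cap = 1e6,
                              engine = c("compiled", "reference"),
                              kernel = c("auto", "migration", "plain")) {
  engine <- match.arg(engine)
  kernel <- match.arg(kernel)
  stopifnot(inherits(lattice, "moran_lattice"),
            inherits(field, "fitness_field"),
            inherits(motility, "motility_params"))
  if (length(occupancy) != lattice$n_sites || anyNA(occupancy)) {
    abort("`occupancy` must be a complete 0/1 vector over all sites.")
  }
  if (max_updates < 1) abort("`max_updates` must be at least 1.")
  use_migration <- switch(kernel,
    auto = motility$m_A > 0 || motility$m_B > 0,
    migration = TRUE,
    plain = FALSE
  )
  if (!use_migration && (motility$m_A > 0 || motility$m_B > 0)) {
    abort("`kernel = \"plain\"` requires zero motility.")
  }
  if (engine == "compiled") {
    res <- cpp_run_to_absorption(lattice$nbr_mat, lattice$degree,
                                 field$r_A, field$r_B,
                                 motility$m_A, motility$m_B,
                                 as.integer(occupancy),
                                 max_updates, cascade_cap, use_migration)
    if (!res$absorbed) {
      abort(sprintf("no absorption within max_updates = %g.", max_updates),
            class = "moranfield_max_updates",
            occupancy = res$occupancy, n_updates = res$n_updates)
    }
    out <- list(fixed = res$fixed, n_updates = res$n_updates,
                n_elementary = res$n_elementary, occupancy = res$occupancy)
  } else {
    count_b <- sum(occupancy)
    n_updates <- 0
    n_elem <- 0
    rkernel <- if (use_migration) "migration" else "plain"
    while (count_b > 0 && count_b < lattice$n_sites) {
      if (n_updates >= max_updates) {
        abort(sprintf("no absorption within max_updates = %g.", max_updates),
              class = "moranfield_max_updates",
              occupancy = occupancy, n_updates = n_updates)
      }
      occupancy <- death_birth_update(occupancy, field, motility, lattice,
                                      cascade_cap = cascade_cap,
                                      kernel = rkernel)
      n_elem <- n_elem + attr(occupancy, "n_elementary")
      attr(occupancy, "n_elementary") <- NULL
      count_b <- sum(occupancy)
      n_updates <- n_updates + 1
    }
    out <- list(fixed = count_b == lattice$n_sites, n_updates = n_updates,
                n_elementary = n_elem, occupancy = occupancy)
  }
  structure(out, class = "moran_absorption")
}

#' @export
print.moran_absorption <- function(x, ...) {
  cat(sprintf("<moran_absorption> %s after %g updates (%g elementary events)\n",
              if (x$fixed) "mutant fixation" else "mutant extinction",
              x$n_updates, x$n_elementary))
  invisible(x)
}
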