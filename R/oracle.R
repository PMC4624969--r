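#' Exact fixation probabilities on a small lattice
#'
#' Ground truth for the no-motility dynamics: enumerates all `2^N` occupancy
#' configurations, builds the exact one-update transition matrix (a uniformly
#' chosen site dies, an occupied neighbour wins the vacancy with probability
#' proportional to its site fitness), and solves the absorbing-chain linear
#' system for the probability of ending in the all-mutant state. Used to
#' validate the stochastic engine; limited to `N <= 14` sites because the
#' state space grows as `2^N`.
#'
#' A death site whose neighbours all have zero fitness cannot be refilled by
#' reproduction; consistent with the simulator, that death is a null update
#' (a self-loop in the chain).
#'
#' @param lattice A [build_lattice()] object with at most 14 sites.
#' @param field A [fitness_field()] on that lattice.
#' @param motility A [motility_params()]; must be zero — the oracle does not
#'   cover the migration cascade (each update would itself be an absorbing
#'   sub-chain over vacancy positions).
#' @return A list with `per_site` (fixation probability starting from a single
#'   mutant at each site), `average` (their mean, the invasion probability of
#'   a uniformly placed mutant), and `n_sites`.
#' @examples
#' lat <- build_lattice(1, 3)
#' f <- fitness_field(rep(1, 3), rep(1, 3))
#' exact_fixation_probability(lat, f)$average  # neutrality forces 1/N
#' @export
exact_fixation_probability <- function(lattice, field,
                                       motility = motility_params()) {
  stopifnot(inherits(lattice, "moran_lattice"), inherits(field, "fitness_field"))
  if (motility$m_A > 0 || motility$m_B > 0) {
    abort("the exact oracle covers only zero motility (m_A = m_B = 0).")
  }
  n <- lattice$n_sites
  if (n > 14L) {
    abort("exact oracle is limited to lattices with at most 14 sites (2^N states).")
  }
  if (field$n_sites != n) abort("`field` does not match the lattice size.")

  n_states <- 2L^n
  states <- 0:(n_states - 1L)
  bit <- 2L^(0:(n - 1L))
  # occ[s, i] = 1 iff site i holds a mutant in state s
  occ <- sapply(seq_len(n), function(i) bitwAnd(states, bit[i]) > 0L)
  full <- n_states - 1L

  trans_mask <- states != 0L & states != full
  trans_states <- states[trans_mask]
  trans_id <- integer(n_states)
  trans_id[trans_states + 1L] <- seq_along(trans_states)

  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  for (d in seq_len(n)) {
    nbs <- lattice$neighbors[[d]]
    # per-state weight of each neighbour of the death site d
    w <- matrix(sapply(nbs, function(j) ifelse(occ[, j], field$r_B[j], field$r_A[j])),
                nrow = n_states)
    tot <- rowSums(w)
    zero <- tot <= 0
    # null update: dead cell restored, state unchanged
    if (any(zero & trans_mask)) {
      s <- states[zero & trans_mask]
      push(trans_id[s + 1L], s, rep(1 / n, length(s)))
    }
    ok <- !zero & trans_mask
    s_ok <- states[ok]
    for (t in seq_along(nbs)) {
      j <- nbs[t]
      p <- (1 / n) * w[ok, t] / tot[ok]
      # site d takes the type of neighbour j
      new_s <- ifelse(occ[s_ok + 1L, j],
                      bitwOr(s_ok, bit[d]),
                      bitwAnd(s_ok, bitwNot(bit[d])))
      keep <- p > 0
      push(trans_id[s_ok + 1L][keep], new_s[keep], p[keep])
    }
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)

  n_trans <- length(trans_states)
  # split destinations: transient block Q, absorption into all-B column b
  to_full <- jj == full
  to_empty <- jj == 0L
  to_trans <- !to_full & !to_empty
  Q <- Matrix::sparseMatrix(i = ii[to_trans], j = trans_id[jj[to_trans] + 1L],
                            x = xx[to_trans], dims = c(n_trans, n_trans))
  b <- numeric(n_trans)
  if (any(to_full)) {
    add <- tapply(xx[to_full], ii[to_full], sum)
    b[as.integer(names(add))] <- add
  }
  A <- Matrix::Diagonal(n_trans) - Q
  h <- as.numeric(Matrix::solve(A, b))

  per_site <- h[trans_id[bit + 1L]]
  list(per_site = per_site, average = mean(per_site), n_sites = n)
}
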