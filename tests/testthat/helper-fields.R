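# Small fixtures used across test files.

homogeneous_field <- function(n, r_A = 1, r_B = 1) {
  fitness_field(rep(r_A, n), rep(r_B, n))
}

# breadth-first search reachability, used to check lattice connectivity
reachable_sites <- function(lattice, from = 1L) {
  seen <- logical(lattice$n_sites)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    s <- queue[1]
    queue <- queue[-1]
    for (j in lattice$neighbors[[s]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  sum(seen)
}
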