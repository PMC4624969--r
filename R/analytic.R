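#' Well-mixed Moran fixation probability
#'
#' Closed-form probability that a single mutant of constant relative fitness
#' `r` fixes in a well-mixed (space-free) population of size `N`:
#' `(1 - 1/r) / (1 - r^-N)`, with the neutral limit `1/N` at `r = 1`. The
#' expression is evaluated through `log`/`expm1`, which is numerically stable
#' arbitrarily close to `r = 1` (both numerator and denominator vanish
#' linearly there).
#'
#' @param r Positive relative fitness (vectorised).
#' @param N Population size, integer `>= 2`.
#' @return Fixation probabilities in `[0, 1]`.
#' @examples
#' moran_fixation(1, 441)    # 1/441, the space-free neutral value
#' moran_fixation(1.5, 441)  # approx 1 - 1/1.5
#' @export
moran_fixation <- function(r, N) {
  if (any(!is.numeric(r)) || any(is.na(r)) || any(r <= 0)) {
    abort("`r` must be positive.")
  }
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != floor(N)) {
    abort("`N` must be a single integer >= 2.")
  }
  lr <- log(r)
  out <- ifelse(r == 1, 1 / N, -expm1(-lr) / -expm1(-N * lr))
  # r -> Inf gives num 1, den 1; r -> 0+ gives 0
  as.numeric(out)
}

#' Well-mixed approximation for a bimodal fitness field
#'
#' For a mutant whose site fitness takes the value `r2` on a fraction `x` of
#' sites and `r1` elsewhere, the weak-selection / weak-heterogeneity
#' approximation replaces the field by its mean and uses the large-`N` Moran
#' result: `rho ~= 1 - 1 / (r2 * x + r1 * (1 - x))`, clamped at 0 (the
#' formula goes negative when the mean fitness is below 1, where a probability
#' must vanish instead). The approximation is expected to break down for
#' strong heterogeneity (widely separated `r1`, `r2`), where spatial
#' localisation of advantaged sites dominates.
#'
#' @param r1,r2 Non-negative site fitness values (vectorised with `x`).
#' @param x Fraction of sites carrying `r2`, in `[0, 1]`.
#' @return Approximate fixation probabilities in `[0, 1)`.
#' @examples
#' bimodal_moran_approx(0.5, 1.5, 0.5)  # mean 1: exactly 0
#' bimodal_moran_approx(0.8, 1.2, 1.0)  # 1 - 1/1.2
#' @export
bimodal_moran_approx <- function(r1, r2, x) {
  if (any(r1 < 0) || any(r2 < 0)) abort("fitness values must be non-negative.")
  if (any(x < 0 | x > 1)) abort("`x` must lie in [0, 1].")
  mean_r <- r2 * x + r1 * (1 - x)
  if (any(mean_r <= 0)) abort("mean fitness must be positive.")
  pmax(0, 1 - 1 / mean_r)
}
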