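## Closed-form asymptotic utilities: local power of chi-square tests near
## the null and Pitman asymptotic efficiencies (PAE) of the symmetry tests.

#' Local power of a chi-square test near the null
#'
#' First-order approximation, in the noncentrality parameter lambda, of the
#' power of an upper-tail chi-square test with `nu` df at level `alpha`:
#' `beta ~= alpha + lambda * (-alpha/2 + (1 - F_{nu+2}(q)) / 2)` where `q`
#' is the central chi-square critical value with `nu` df and `F_{nu+2}` the
#' central chi-square cdf with `nu + 2` df. Valid for small lambda; at
#' lambda = 0 it returns `alpha` exactly.
#'
#' @param lambda noncentrality parameter, `>= 0` and small.
#' @param nu degrees of freedom, `>= 1`.
#' @param alpha level in (0, 1).
#' @return Approximate power (may exceed (0, 1) for large lambda, where the
#'   approximation no longer applies).
#' @examples
#' local_power(0, 2, 0.05)       # exactly 0.05
#' local_power(0.5, 2, 0.05)
#' @export
local_power <- function(lambda, nu, alpha) {
  if (any(lambda < 0))
    stop("'lambda' must be nonnegative")
  stopifnot(nu >= 1, alpha > 0, alpha < 1)
  q <- stats::qchisq(1 - alpha, nu)
  alpha + lambda * (-alpha / 2 +
                      (1 - stats::pchisq(q, nu + 2)) / 2)
}

#' Pitman asymptotic efficiency of Dixon's symmetry test
#'
#' `PAE(Z_D) = 1 / (nu1 (1 - nu1) p_q)`, where `nu1` is the class-1
#' proportion and `p_q` the probability of a point being a shared NN
#' (around 0.63 under CSR on the plane). Efficiency grows as the class
#' proportions become unbalanced and is minimized at `nu1 = 1/2`.
#'
#' @param nu1 class-1 proportion, strictly inside (0, 1).
#' @param p_q shared-NN probability in (0, 1].
#' @return The PAE value.
#' @examples
#' pae_dixon(0.5, 0.63)    # about 6.35
#' @export
pae_dixon <- function(nu1, p_q) {
  if (any(nu1 <= 0) || any(nu1 >= 1))
    stop("'nu1' must be strictly inside (0, 1) (efficiency is infinite at the boundary)")
  if (any(p_q <= 0) || any(p_q > 1))
    stop("'p_q' must be in (0, 1]")
  1 / (nu1 * (1 - nu1) * p_q)
}

#' Large-n variance and covariance approximations for the NNCT off-diagonals
#'
#' Per-n scaled approximations used in the PAE derivation for Dixon's test:
#' `Var[N_ij]/n ~= nu_i nu_j (1 + p_q nu_i - (3 + p_q - p_r) nu_i nu_j)` and
#' `Cov[N_12, N_21]/n ~= nu_1 nu_2 (p_r + (1 - p_r)(nu_1 + nu_2) -
#' (3 + p_q - p_r) nu_1 nu_2)`, with `p_r` the probability of a pair being
#' reflexive (around 0.62 under CSR). Their combination gives
#' `Var[N_12 - N_21]/n ~= nu_1 nu_2 p_q`, the reciprocal of
#' [pae_dixon()] times `nu_1 nu_2 / (nu_1 (1 - nu_1))`.
#'
#' @param nu1 class-1 proportion in (0, 1); `nu2 = 1 - nu1`.
#' @param p_q shared-NN probability.
#' @param p_r reflexive-pair probability.
#' @return List with `var12`, `var21`, `cov`, and `var_diff`
#'   (= `var12 + var21 - 2 cov` = `nu1 nu2 p_q`).
#' @export
dixon_large_n_moments <- function(nu1, p_q, p_r) {
  stopifnot(nu1 > 0, nu1 < 1, p_q >= 0, p_q <= 1, p_r >= 0, p_r <= 1)
  nu2 <- 1 - nu1
  a <- 3 + p_q - p_r
  var12 <- nu1 * nu2 * (1 + p_q * nu1 - a * nu1 * nu2)
  var21 <- nu1 * nu2 * (1 + p_q * nu2 - a * nu1 * nu2)
  cv <- nu1 * nu2 * (p_r + (1 - p_r) * (nu1 + nu2) - a * nu1 * nu2)
  list(var12 = var12, var21 = var21, cov = cv,
       var_diff = var12 + var21 - 2 * cv)
}

#' Pitman asymptotic efficiency of Pielou's first symmetry test
#'
#' For the binomial parameterization of the alternative (success probability
#' `1/2 + eps`), the scaled proportion statistic has drift derivative 1 at
#' the null and variance `1/(4 nt)`, giving the constant efficiency 4,
#' independent of `nt`.
#'
#' @return List with `pae = 4` and the derivation quantities `mu_prime`
#'   (drift derivative at the null) and `sigma2_n` (variance times `nt`).
#' @export
pae_pielou <- function() {
  list(pae = 4, mu_prime = 1, sigma2_n = 1 / 4)
}
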