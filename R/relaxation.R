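#' Exponential integral E1
#'
#' Computes \eqn{E_1(x) = \int_x^\infty e^{-m}/m \, dm} for positive `x`,
#' the building block of the continuous-spectrum reduced relaxation
#' function. A power series is used for `x <= 1` and a modified-Lentz
#' continued fraction for `x > 1`; both are iterated to near machine
#' precision.
#'
#' @param x Positive numeric vector.
#' @return \eqn{E_1(x)}, same length as `x`.
#' @examples
#' exp_integral_e1(1) # 0.2193839...
#' @export
exp_integral_e1 <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  if (any(!is.finite(x) | x <= 0)) abort("`x` must be positive and finite")
  out <- numeric(length(x))
  small <- x <= 1

  if (any(small)) {
    xs <- x[small]
    # E1(x) = -gamma - log(x) + sum_{k>=1} (-1)^{k+1} x^k / (k k!)
    term <- xs # k = 1 term
    s <- term
    for (k in 2:30) {
      term <- term * (-xs) * (k - 1) / (k * k)
      s <- s + term
      if (max(abs(term)) < 1e-17 * max(abs(s))) break
    }
    out[small] <- -0.57721566490153286061 - log(xs) + s
  }

  if (any(!small)) {
    xl <- x[!small]
    # continued fraction e^{-x}/(x + 1 - 1/(x + 3 - 4/(x + 5 - ...)))
    # evaluated with the modified Lentz algorithm
    tiny <- 1e-300
    b <- xl + 1
    c <- 1 / tiny
    d <- 1 / b
    h <- d
    for (k in 1:200) {
      a <- -k^2
      b <- b + 2
      d <- 1 / (a * d + b)
      c <- b + a / c
      delta <- c * d
      h <- h * delta
      if (max(abs(delta - 1)) < 1e-15) break
    }
    out[!small] <- exp(-xl) * h
  }
  out
}

#' Continuous-spectrum reduced relaxation function
#'
#' Fung's reduced relaxation function with a box spectrum of relaxation
#' times between `tau1` and `tau2`:
#' \deqn{Q(t) = \frac{1 + \nu\,[E_1(t/\tau_2) - E_1(t/\tau_1)]}
#'                   {1 + \nu \ln(\tau_2/\tau_1)},}
#' which decays from \eqn{Q(0) = 1} (handled analytically) to the plateau
#' \eqn{Q(\infty) = [1 + \nu\ln(\tau_2/\tau_1)]^{-1}} and yields a nearly
#' frequency-flat damping for loading frequencies between \eqn{1/\tau_2}
#' and \eqn{1/\tau_1}.
#'
#' @param t Time since the step change, s (vectorised, `>= 0`).
#' @param nu Spectrum magnitude (dimensionless, `>= 0`).
#' @param tau1,tau2 Short and long time constants, s (`tau1 < tau2` when
#'   `nu > 0`).
#' @return \eqn{Q(t)}, same length as `t`.
#' @examples
#' reduced_relaxation(c(0, 1, 1e4), nu = 0.059, tau1 = 1e-3, tau2 = 59.3)
#' @export
reduced_relaxation <- function(t, nu, tau1 = 1e-3, tau2) {
  if (any(t < 0)) abort("`t` must be non-negative")
  if (nu == 0) return(rep(1, length(t)))
  if (!(tau1 > 0 && tau2 > tau1)) abort("need 0 < tau1 < tau2")
  out <- rep(1, length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    num <- 1 + nu * (exp_integral_e1(tp / tau2) - exp_integral_e1(tp / tau1))
    out[pos] <- num / (1 + nu * log(tau2 / tau1))
  }
  out
}

#' Long-time plateau of the reduced relaxation function
#'
#' @inheritParams reduced_relaxation
#' @return A one-row tibble with `q_inf` \eqn{= [1 +
#'   \nu\ln(\tau_2/\tau_1)]^{-1}} and `relaxation_pct` \eqn{= 100(1 -
#'   q_\infty)}, the percent stress relaxation after a step deformation.
#' @examples
#' q_infinity(nu = 0.059, tau1 = 1e-3, tau2 = 59.3)
#' @export
q_infinity <- function(nu, tau1 = 1e-3, tau2 = 100) {
  n <- max(length(nu), length(tau1), length(tau2))
  nu <- rep_len(nu, n); tau1 <- rep_len(tau1, n); tau2 <- rep_len(tau2, n)
  q <- ifelse(nu == 0, 1, 1 / (1 + nu * log(tau2 / tau1)))
  tibble(q_inf = q, relaxation_pct = 100 * (1 - q))
}

## kernel weights for the midpoint discretisation of the hereditary
## integral: Q evaluated at lags (m - 1/2) dt, m = 1..n
.q_kernel <- function(n, dt, nu, tau1, tau2) {
  if (n < 1L) return(numeric(0))
  reduced_relaxation((seq_len(n) - 0.5) * dt, nu, tau1, tau2)
}
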