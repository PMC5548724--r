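#' BDI rate set
#'
#' Bundles the four rates of the Birth-Death-cis-Innovation (BDI) process:
#' per-element birth (duplication) rate `lambda`, per-element death rate
#' `delta`, per-element cis-innovation rate `mu` (an element mutates and
#' founds a new size-1 family, conserving the total element count), and the
#' global de-novo innovation rate `nu` (a brand-new size-1 family appears).
#' The derived redundancy parameter is `theta = lambda / (delta + mu)`.
#'
#' @param lambda per-element birth rate (>= 0).
#' @param delta per-element death rate (>= 0).
#' @param mu per-element cis-innovation rate (>= 0).
#' @param nu de-novo innovation rate (>= 0), defaults to 0: in the regime the
#'   model targets (late metazoan TF evolution) creation of genuinely new
#'   families is negligible.
#' @return An object of class `bdi_rates` with fields `lambda`, `delta`,
#'   `mu`, `nu` and the derived `theta`.
#' @examples
#' bdi_rates(lambda = 1, delta = 1, mu = 1 / 0.74 - 1) # theta = 0.74
#' @export
bdi_rates <- function(lambda, delta, mu, nu = 0) {
  for (r in list(lambda = lambda, delta = delta, mu = mu, nu = nu)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
      stop("all BDI rates must be single non-negative numbers", call. = FALSE)
    }
  }
  if (delta + mu <= 0) stop("delta + mu must be positive", call. = FALSE)
  structure(
    list(lambda = lambda, delta = delta, mu = mu, nu = nu,
         theta = lambda / (delta + mu)),
    class = "bdi_rates"
  )
}

#' @export
print.bdi_rates <- function(x, ...) {
  cat(sprintf(
    "BDI rates: lambda=%g delta=%g mu=%g nu=%g  (theta = %.4f)\n",
    x$lambda, x$delta, x$mu, x$nu, x$theta))
  invisible(x)
}

#' Rates with unit birth rate for a target redundancy theta
#'
#' Convenience constructor for the balanced regime `lambda = delta` used
#' throughout the analysis: given `theta`, returns
#' `bdi_rates(lambda, lambda, mu)` with `mu = lambda * (1/theta - 1)` so that
#' `lambda / (delta + mu) = theta` and the element count is a critical random
#' walk (`N(delta - lambda) = nu = 0` at steady state).
#'
#' @param theta redundancy parameter in (0, 1).
#' @param lambda birth (= death) rate, default 1 (sets the time unit).
#' @return A `bdi_rates` object.
#' @export
bdi_rates_balanced <- function(theta, lambda = 1) {
  check_theta(theta)
  bdi_rates(lambda, lambda, lambda * (1 / theta - 1), nu = 0)
}

#' Check the mean-field steady-state constraint
#'
#' At stationarity with constant mean element count the rates must satisfy
#' `N * (delta - lambda) = nu`. The constraint is reported, not enforced, so
#' off-balance regimes can be explored deliberately.
#'
#' @param rates a [bdi_rates()] object.
#' @param N total element count the constraint refers to.
#' @param tol relative tolerance.
#' @return `TRUE`/`FALSE` invisibly; warns when the constraint is violated.
#' @export
check_balance <- function(rates, N, tol = 1e-8) {
  stopifnot(inherits(rates, "bdi_rates"))
  lhs <- N * (rates$delta - rates$lambda)
  ok <- abs(lhs - rates$nu) <= tol * max(1, abs(rates$nu), N * rates$lambda)
  if (!ok) {
    warning(sprintf(
      "steady-state constraint N(delta - lambda) = nu violated: %g != %g",
      lhs, rates$nu), call. = FALSE)
  }
  invisible(ok)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    stop("theta must be a single number strictly inside (0, 1)",
         call. = FALSE)
  }
  invisible(theta)
}

check_M <- function(M) {
  if (length(M) != 1L || is.na(M) || M < 1 ||
      (is.finite(M) && M != floor(M))) {
    stop("M must be a positive integer or Inf", call. = FALSE)
  }
  invisible(M)
}

#' Normalization constant of the truncated logarithmic series
#'
#' `C_M = 1 / sum_{i=1}^{M} theta^i / i`; for `M = Inf` the closed form
#' `1 / (-log(1 - theta))` is used.
#'
#' @param theta redundancy parameter in (0, 1).
#' @param M truncation size (positive integer) or `Inf`.
#' @return The scalar normalization constant.
#' @export
bdi_norm_const <- function(theta, M = Inf) {
  check_theta(theta); check_M(M)
  if (is.infinite(M)) return(1 / (-log1p(-theta)))
  i <- seq_len(M)
  1 / sum(theta^i / i)
}

#' Stationary family-size probability law of the BDI model
#'
#' The stationary size distribution is the (optionally truncated)
#' logarithmic series `p_i = C_M * theta^i / i`, `i = 1..M`. Successive
#' probabilities satisfy `p_i / p_{i+1} = (i + 1) / (i * theta)`.
#'
#' @param i vector of family sizes (positive integers).
#' @param theta redundancy parameter in (0, 1).
#' @param M truncation size or `Inf` (default).
#' @return `p_i` for each requested size; 0 beyond the truncation.
#' @examples
#' bdi_pmf(1, 0.5)            # 0.5 / log(2) ~= 0.7213
#' sum(bdi_pmf(1:50, 0.5, M = 50)) # exactly 1
#' @export
bdi_pmf <- function(i, theta, M = Inf) {
  check_theta(theta); check_M(M)
  stopifnot(is.numeric(i), all(i >= 1), all(i == floor(i)))
  p <- bdi_norm_const(theta, M) * theta^i / i
  p[i > M] <- 0
  p
}

#' Cumulative distribution of the stationary size law
#'
#' @inheritParams bdi_pmf
#' @return `P(size <= i)` for each requested size.
#' @export
bdi_cdf <- function(i, theta, M = Inf) {
  check_theta(theta); check_M(M)
  stopifnot(is.numeric(i), all(i >= 1), all(i == floor(i)))
  imax <- max(i)
  upto <- if (is.finite(M)) min(imax, M) else imax
  cs <- cumsum(bdi_pmf(seq_len(upto), theta, M))
  out <- cs[pmin(i, upto)]
  if (is.finite(M)) out[i >= M] <- 1
  out
}

#' Expected number of families per size class
#'
#' In the negligible-de-novo regime (`nu -> 0`) the expected count of
#' families of size `i` among `N` elements is
#' `f_i = N * (1 - theta) * theta^(i-1) / i`, so that `sum_i i * f_i = N`
#' as the truncation grows.
#'
#' @param theta redundancy parameter in (0, 1).
#' @param N total number of elements (TFs).
#' @param imax largest size class to report.
#' @return Numeric vector `f_1 .. f_imax`.
#' @examples
#' bdi_family_counts(0.5, 100, 3) # 50, 12.5, 4.1667
#' @export
bdi_family_counts <- function(theta, N, imax = 100L) {
  check_theta(theta)
  stopifnot(N > 0, imax >= 1)
  i <- seq_len(imax)
  N * (1 - theta) * theta^(i - 1) / i
}

#' Expected stationary family counts for explicit rates
#'
#' General stationary solution `f_i = ((nu + mu * N) / lambda) * theta^i / i`
#' of the BDI master equation, without the `nu -> 0` simplification.
#'
#' @param rates a [bdi_rates()] object.
#' @param N total number of elements.
#' @param imax largest size class to report.
#' @return Numeric vector `f_1 .. f_imax`.
#' @export
bdi_stationary_counts <- function(rates, N, imax = 100L) {
  stopifnot(inherits(rates, "bdi_rates"), N > 0, imax >= 1)
  i <- seq_len(imax)
  (rates$nu + rates$mu * N) / rates$lambda * rates$theta^i / i
}

#' Mean family size under the stationary law
#'
#' For `M = Inf` the closed form is
#' `kbar = -theta / ((1 - theta) * log(1 - theta))`; for finite truncation
#' the geometric partial sum `C_M * theta * (1 - theta^M) / (1 - theta)`.
#'
#' @inheritParams bdi_norm_const
#' @return The expected family size (>= 1).
#' @examples
#' bdi_mean_size(0.5) # 1 / log(2) ~= 1.4427
#' @export
bdi_mean_size <- function(theta, M = Inf) {
  check_theta(theta); check_M(M)
  if (is.infinite(M)) return(-theta / ((1 - theta) * log1p(-theta)))
  bdi_norm_const(theta, M) * theta * (1 - theta^M) / (1 - theta)
}

#' Neutral expectation for the families-per-element ratio F/N
#'
#' `F/N = ((1 - theta)/theta) * sum_{i<=M} theta^i / i`, which for
#' `M = Inf` is `((1 - theta)/theta) * (-log(1 - theta))` — the reciprocal
#' of the mean family size. Decreasing in theta; tends to 1 as theta -> 0
#' (every element its own family) and to 0 as theta -> 1.
#'
#' @inheritParams bdi_norm_const
#' @return Ratio in (0, 1].
#' @examples
#' bdi_expected_fn(0.74) # ~= 0.4733
#' @export
bdi_expected_fn <- function(theta, M = Inf) {
  check_theta(theta); check_M(M)
  1 / bdi_mean_size(theta, M)
}

#' Sample family sizes from the stationary law
#'
#' Draws i.i.d. sizes from the truncated logarithmic series by inverse-CDF
#' lookup on a precomputed table, so results are exactly reproducible across
#' platforms for a given RNG state. Seed the R RNG with [set.seed()] before
#' calling (all higher-level routines in this package do so explicitly).
#'
#' @param n number of families to draw.
#' @param theta redundancy parameter in (0, 1).
#' @param M finite truncation of the support (sampling needs finite
#'   support; default 10000 is effectively untruncated for theta <= 0.99).
#' @return Integer vector of `n` sizes in `1..M`.
#' @export
bdi_sample_sizes <- function(n, theta, M = 10000L) {
  check_theta(theta); check_M(M)
  if (!is.finite(M)) stop("sampling requires a finite truncation M",
                          call. = FALSE)
  stopifnot(n >= 1)
  p <- bdi_pmf(seq_len(M), theta, M)
  # findInterval on the CDF == inverse-CDF sampling; robust to tiny tail mass
  cdf <- pmin(cumsum(p), 1)
  cdf[M] <- 1
  findInterval(stats::runif(n), cdf, left.open = TRUE) + 1L
}

#' Right-hand side of the BDI master equation
#'
#' Evaluates the time derivative of the class counts `f_i` (number of
#' families of size `i`) under the BDI dynamics:
#' \deqn{df_1/dt = -(\lambda+\delta+\mu) f_1 + 2(\delta+\mu) f_2 + \mu N + \nu}
#' \deqn{df_i/dt = (i-1)\lambda f_{i-1} - i(\lambda+\delta+\mu) f_i +
#'   (i+1)(\delta+\mu) f_{i+1}}
#' \deqn{df_M/dt = (M-1)\lambda f_{M-1} - M(\delta+\mu) f_M}
#' where `N` is the mean-field total element count (a parameter of the
#' equation, not recomputed from `f`).
#'
#' @param f numeric vector of class counts, `f[i]` = families of size `i`;
#'   its length sets the truncation `M`.
#' @param rates a [bdi_rates()] object.
#' @param N mean-field element count entering the cis-innovation inflow. If
#'   it differs from `sum(i * f_i)` by more than 1e-6 relative a warning is
#'   emitted (exploring off-consistency states is allowed).
#' @return Numeric vector `df_i/dt` of the same length as `f`.
#' @export
bdi_master_rhs <- function(f, rates, N) {
  stopifnot(inherits(rates, "bdi_rates"), is.numeric(f), length(f) >= 2,
            is.numeric(N), length(N) == 1L, N >= 0)
  M <- length(f)
  i <- seq_len(M)
  Nf <- sum(i * f)
  if (abs(Nf - N) > 1e-6 * max(1, N)) {
    warning(sprintf(
      "mean-field N = %g differs from sum(i * f_i) = %g", N, Nf),
      call. = FALSE)
  }
  lam <- rates$lambda; dm <- rates$delta + rates$mu
  up   <- c(0, (i[-M] ) * lam * f[-M])          # inflow from class i-1
  down <- c((i[-1]) * dm * f[-1], 0)            # inflow from class i+1
  out  <- i * (lam + dm) * f                    # outflow
  out[M] <- M * dm * f[M]                       # no birth out of the cap
  rhs <- up + down - out
  rhs[1] <- rhs[1] + rates$mu * N + rates$nu
  rhs
}
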