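# Circular statistics: von Mises density, sampling, weighted ML fitting, and
# angle arithmetic. All angles are radians internally; degrees appear only at
# I/O boundaries.

# Concentration cap keeping besselI and the density finite in double precision.
KAPPA_MAX <- 700

#' Wrap angles to [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles congruent to `x` modulo 2*pi, in `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% can return 2*pi for inputs just below -pi due to rounding
  y[y >= pi] <- -pi
  y
}

#' Signed minimal difference between two angles
#'
#' Returns the signed difference `a - b` folded to `(-pi, pi]`, i.e. the
#' shortest rotation taking `b` onto `a`.
#'
#' @param a,b angles in radians (recycled to common length).
#' @return signed difference in `(-pi, pi]`.
#' @examples
#' angle_diff(175 * pi / 180, -179 * pi / 180) * 180 / pi  # -6 degrees
#' @export
angle_diff <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  d <- (a - b) %% (2 * pi)   # in [0, 2*pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# log I0(kappa), stable for kappa in [0, KAPPA_MAX] via the scaled Bessel.
log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

check_vm_params <- function(mu, kappa) {
  if (any(!is.finite(mu)) || any(!is.finite(kappa))) {
    stop("von Mises parameters must be finite", call. = FALSE)
  }
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
}

#' Von Mises density
#'
#' Density of the von Mises distribution, the circular analogue of the
#' Gaussian: `f(x) = exp(kappa * cos(x - mu)) / (2 * pi * I0(kappa))`.
#'
#' @param x angles in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0` (capped at 700).
#' @param log if `TRUE`, return the log-density (nats per radian).
#' @return density (or log-density) values, invariant to adding multiples of
#'   `2*pi` to `x`.
#' @examples
#' dvm(0, 0, 0)            # 1 / (2*pi), the circular uniform
#' dvm(0.3, 0, 5, log = TRUE)
#' @export
dvm <- function(x, mu, kappa, log = FALSE) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  check_vm_params(mu, kappa)
  kappa <- pmin(kappa, KAPPA_MAX)
  ll <- kappa * cos(x - mu) - log(2 * pi) - log_bessel_i0(kappa)
  if (log) ll else exp(ll)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampling (wrapped-Cauchy envelope). Uses R's global
#' RNG stream unless `seed` is given, in which case the draw is made under a
#' local seed and the caller's RNG state is left untouched.
#'
#' @param n number of draws (`>= 1`).
#' @param mu mean direction in radians.
#' @param kappa concentration, `>= 0`.
#' @param seed optional integer seed for a reproducible, state-independent
#'   draw.
#' @return `n` angles in `[-pi, pi)`.
#' @export
rvm <- function(n, mu, kappa, seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  check_vm_params(mu, kappa)
  kappa <- min(kappa, KAPPA_MAX)
  with_seed(seed, {
    if (kappa < 1e-10) {
      wrap_angle(stats::runif(n, -pi, pi))
    } else {
      tau <- 1 + sqrt(1 + 4 * kappa^2)
      rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
      r <- (1 + rho^2) / (2 * rho)
      out <- numeric(0)
      while (length(out) < n) {
        m <- max(n - length(out), 16L)
        m <- ceiling(m / 0.65)  # acceptance rate is >= ~65% for all kappa
        u1 <- stats::runif(m)
        u2 <- stats::runif(m)
        u3 <- stats::runif(m)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
        theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
        out <- c(out, theta[ok])
      }
      wrap_angle(mu + out[seq_len(n)])
    }
  })
}

# A(kappa) = I1(kappa)/I0(kappa), the mean resultant length of vM(mu, kappa).
vm_A <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Invert A(kappa) = R: Fisher's closed-form start, then Newton refinement.
# A'(kappa) = 1 - A/kappa - A^2.
vm_kappa_from_R <- function(R, tol = 1e-10, max_iter = 50) {
  if (R <= 0) return(0)
  if (R >= vm_A(KAPPA_MAX)) return(KAPPA_MAX)
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  k <- min(max(k, 1e-8), KAPPA_MAX)
  for (i in seq_len(max_iter)) {
    A <- vm_A(k)
    if (abs(A - R) < tol) break
    dA <- 1 - A / k - A^2
    k_new <- k - (A - R) / dA
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    k <- min(k_new, KAPPA_MAX)
  }
  k
}

#' Weighted maximum-likelihood fit of a von Mises distribution
#'
#' The mean direction is the direction of the weighted resultant vector; the
#' concentration solves `A(kappa) = I1(kappa)/I0(kappa) = R` (the weighted
#' mean resultant length), inverted by a closed-form approximation followed by
#' Newton refinement to `|A(kappa) - R| < 1e-10`.
#'
#' @param x angles in radians.
#' @param w non-negative weights (default: unit weights). At least one weight
#'   must be positive.
#' @return a list with components `mu` (in `[-pi, pi)`) and `kappa`
#'   (capped at 700).
#' @export
fit_vm <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) stop("weights length mismatch", call. = FALSE)
  if (any(w < 0) || any(!is.finite(w))) {
    stop("weights must be non-negative and finite", call. = FALSE)
  }
  sw <- sum(w)
  if (sw <= 0) stop("all weights are zero: degenerate fit", call. = FALSE)
  S <- sum(w * sin(x))
  C <- sum(w * cos(x))
  mu <- atan2(S, C)
  R <- sqrt(S^2 + C^2) / sw
  list(mu = wrap_angle(mu), kappa = vm_kappa_from_R(min(R, 1)))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialization so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
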