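#' Distribution of pairwise differences under divergence models
#'
#' Probability mass function of the number of nucleotide differences `S`
#' between two haplotypes sampled one per species, under each of four
#' demographic models: strict isolation (SI), isolation with migration (IM),
#' isolation with initial migration (IIM), and a secondary-contact admixture
#' pulse (SC). Conditional on the pairwise coalescence time `T = t` (in units
#' of 2*Ne generations), `S ~ Poisson(theta * t)`; each model determines the
#' law of `T`.
#'
#' All four laws share the same structure backwards in time: an optional
#' phase before `T0` in which the coalescence-time density is a mixture of
#' exponential pieces (migration and/or pulse dynamics), and a panmictic
#' ancestral phase after `T0` in which the residual lineage pair coalesces at
#' rate 1. The mass function is computed exactly from this decomposition via
#' incomplete-gamma integrals for the pieces and a Poisson-geometric
#' convolution for the ancestral tail.
#'
#' @param params Model parameters from [model_params()] (or a named list).
#'   Each model reads only its active subset; see [active_params()].
#' @param kmax Largest difference class to compute. If `NULL` (default), uses
#'   `max(40, smallest k with cumulative mass > 1 - 1e-10)`. If given, the
#'   residual tail mass beyond `kmax` must not exceed `tail_tol`.
#' @param tail_tol Maximum tolerated tail mass beyond `kmax` (default `1e-6`).
#'
#' @return A tibble of class `div_pmf` with columns `k` (0..kmax) and `prob`,
#'   and attributes `model`, `params`, `kmax` and `tail` (residual mass beyond
#'   `kmax`; `sum(prob) + tail == 1`).
#'
#' @details
#' * **SI**: `T = T0 + Exp(1)`, so the pmf is the convolution of
#'   `Poisson(theta * T0)` with the geometric law
#'   `P[j] = theta^j / (1 + theta)^(j + 1)`.
#' * **IM**: before `T0` the lineage pair follows the structured coalescent
#'   with two demes and symmetric migration: apart -> together at rate `M`,
#'   together -> apart at rate `M`, together -> coalesced at rate 1.
#' * **IIM**: strict isolation on `(0, T1)` (no coalescence possible), IM
#'   dynamics on `(T1, T0)`; equivalently the IM law time-shifted by `T1`.
#' * **SC**: each lineage independently switches demes with probability `f`
#'   at `T1`; with probability `2 f (1 - f)` the pair is then in one deme and
#'   coalesces at rate 1 on `(T1, T0)`.
#'
#' @examples
#' pmf_si(model_params(theta = 1, T0 = 0.5))
#' pmf_im(model_params(theta = 1.5, T0 = 1, M = 0.5), kmax = 40)
#' @name pmf_models
NULL

# Piecewise-exponential representation of the coalescence-time density before
# T0: each piece contributes coef * exp(-s * (t - t0)) on (a, b). `w` is the
# probability the pair is still uncoalesced at T0 (panmictic tail T0 + Exp(1)).
# Pieces are parallel vectors (hot path: no data frames).
coal_pieces <- function(model, params) {
  p <- as_div_params(params)
  model <- match.arg(model, div_models)
  empty <- list(coef = numeric(), s = numeric(), t0 = numeric(),
                a = numeric(), b = numeric())
  if (model == "SI" || p$T0 == 0) {
    return(list(pieces = empty, w = 1, T0 = p$T0))
  }
  if (model == "SC") {
    q <- 2 * p$f * (1 - p$f)
    if (q == 0 || p$T1 == p$T0) {
      return(list(pieces = empty, w = 1, T0 = p$T0))
    }
    pieces <- list(coef = q, s = 1, t0 = p$T1, a = p$T1, b = p$T0)
    w <- 1 - q * (1 - exp(-(p$T0 - p$T1)))
    return(list(pieces = pieces, w = w, T0 = p$T0))
  }
  # IM / IIM: three-state ancestral chain on (t1, T0), started "apart".
  t1 <- if (model == "IIM") p$T1 else 0
  M <- p$M
  if (t1 >= p$T0 || M == 0) {   # zero-length migration window, or no migration
    return(list(pieces = empty, w = 1, T0 = p$T0))
  }
  # Generator on transient states (1 = apart, 2 = together):
  # A = [[-M, M], [M, -(M+1)]]; coalescence density f(t) = P_12(t - t1).
  # Closed-form eigendecomposition: lambda = (-(2M+1) +- sqrt(4M^2+1)) / 2,
  # giving P_12(u) = M / sqrt(4M^2+1) * (exp(lambda1 u) - exp(lambda2 u)).
  disc <- sqrt(4 * M^2 + 1)
  lam1 <- (-(2 * M + 1) + disc) / 2
  lam2 <- (-(2 * M + 1) - disc) / 2
  cc <- M / disc
  pieces <- list(coef = c(cc, -cc), s = -c(lam1, lam2),
                 t0 = c(t1, t1), a = c(t1, t1), b = c(p$T0, p$T0))
  # survival at T0: P_11 + P_12 with a_i = (M + lambda_i) / M
  u <- p$T0 - t1
  a1 <- (M + lam1) / M; a2 <- (M + lam2) / M
  w <- ((a2 - 1) * exp(lam1 * u) + (1 - a1) * exp(lam2 * u)) / (a2 - a1)
  list(pieces = pieces, w = w, T0 = p$T0)
}

# log(exp(la) - exp(lb)) for la >= lb, -Inf-safe
logspace_sub <- function(la, lb) {
  d <- lb - la
  out <- la + log1p(-exp(d))
  out[la == -Inf] <- -Inf
  out
}

# Contribution of one exponential density piece to P[S = k], k = 0..kmax:
# integral over (a,b) of dpois(k, theta*t) * coef * exp(-s*(t - t0)) dt.
piece_pmf <- function(coef, s, t0, a, b, theta, kmax) {
  r <- theta + s
  kk <- 0:kmax
  lga <- stats::pgamma(a, shape = kk + 1, rate = r, lower.tail = FALSE, log.p = TRUE)
  lgb <- stats::pgamma(b, shape = kk + 1, rate = r, lower.tail = FALSE, log.p = TRUE)
  ldiff <- logspace_sub(lga, lgb)
  lmag <- log(abs(coef)) + s * t0 + kk * log(theta / r) - log(r) + ldiff
  if (theta == 0) lmag[-1] <- -Inf   # (theta/r)^k = 0 for k > 0
  sign(coef) * exp(lmag)
}

# pmf of S for the panmictic tail: pair uncoalesced at T0 (weight w) has
# T = T0 + Exp(1); S is Poisson(theta*T0) + geometric(theta/(1+theta)).
# The geometric factor turns the convolution into the exact linear
# recursion t[k] = rho * t[k-1] + w * dpois(k) / (1 + theta).
tail_pmf <- function(w, theta, T0, kmax) {
  if (theta == 0) return(c(w, numeric(kmax)))
  kk <- 0:kmax
  if (T0 == 0) {
    return(w * exp(kk * log(theta / (1 + theta)) - log(1 + theta)))
  }
  dp <- stats::dpois(kk, theta * T0)
  rho <- theta / (1 + theta)
  as.numeric(stats::filter(w * dp / (1 + theta), rho, method = "recursive"))
}

pmf_at <- function(model, params, kmax) {
  p <- as_div_params(params)
  cp <- coal_pieces(model, p)
  probs <- tail_pmf(cp$w, p$theta, cp$T0, kmax)
  pc <- cp$pieces
  n_pieces <- length(pc$coef)
  if (n_pieces > 0 && p$theta > 0) {
    for (i in seq_len(n_pieces)) {
      probs <- probs + piece_pmf(pc$coef[i], pc$s[i], pc$t0[i], pc$a[i], pc$b[i],
                                 p$theta, kmax)
    }
  } else if (n_pieces > 0 && p$theta == 0) {
    # no mutation: all pre-T0 coalescences also yield S = 0
    mass <- sum(pc$coef / pc$s *
                  (exp(-pc$s * (pc$a - pc$t0)) - exp(-pc$s * (pc$b - pc$t0))))
    probs[1] <- probs[1] + mass
  }
  pmax(probs, 0)
}

new_div_pmf <- function(probs, model, params, tail) {
  out <- tibble::tibble(k = seq_along(probs) - 1L, prob = probs)
  class(out) <- c("div_pmf", class(out))
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "kmax") <- length(probs) - 1L
  attr(out, "tail") <- tail
  out
}

div_pmf <- function(model, params, kmax = NULL, tail_tol = 1e-6) {
  p <- as_div_params(params)
  model <- match.arg(model, div_models)
  if (is.null(kmax)) {
    cap <- 64L
    repeat {
      probs <- pmf_at(model, p, cap)
      cum <- cumsum(probs)
      if (cum[length(cum)] > 1 - 1e-10 || cap >= 8192L) break
      cap <- cap * 2L
    }
    if (cum[length(cum)] <= 1 - 1e-10) {
      stop("pmf tail does not vanish below k = 8192; parameters out of supported range",
           call. = FALSE)
    }
    kmax <- max(40L, which(cum > 1 - 1e-10)[1] - 1L)
    probs <- probs[1:(kmax + 1)]
  } else {
    kmax <- as.integer(kmax)
    if (kmax < 0) stop("kmax must be >= 0", call. = FALSE)
    probs <- pmf_at(model, p, kmax)
  }
  tail <- max(0, 1 - sum(probs))
  if (tail > tail_tol) {
    stop(sprintf("truncation error: tail mass %.3g beyond kmax = %d exceeds tolerance %.1g",
                 tail, kmax, tail_tol), call. = FALSE)
  }
  new_div_pmf(probs, model, p, tail)
}

#' @rdname pmf_models
#' @export
pmf_si <- function(params, kmax = NULL, tail_tol = 1e-6) {
  div_pmf("SI", params, kmax, tail_tol)
}

#' @rdname pmf_models
#' @export
pmf_im <- function(params, kmax = NULL, tail_tol = 1e-6) {
  div_pmf("IM", params, kmax, tail_tol)
}

#' @rdname pmf_models
#' @export
pmf_iim <- function(params, kmax = NULL, tail_tol = 1e-6) {
  div_pmf("IIM", params, kmax, tail_tol)
}

#' @rdname pmf_models
#' @export
pmf_sc <- function(params, kmax = NULL, tail_tol = 1e-6) {
  div_pmf("SC", params, kmax, tail_tol)
}

#' @export
print.div_pmf <- function(x, ...) {
  cat(sprintf("<div_pmf> model %s, kmax = %d, tail = %.3g\n",
              attr(x, "model"), attr(x, "kmax"), attr(x, "tail")))
  NextMethod()
}
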