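#' Blockwise log-likelihood of a divergence model
#'
#' The log-likelihood of an S-distribution is the weighted sum over
#' difference classes, `sum_k n_k * ln P[S = k]`, with `P[S = k]` given by
#' the model's pairwise-difference pmf. In conditioned mode the monomorphic
#' class is excluded and each class probability is renormalised by
#' `1 - P[S = 0]`, i.e. `sum_{k>=1} n_k * ln( P[S=k] / (1 - P[S=0]) )`;
#' this makes the fit robust to an unreliable count of monomorphic blocks.
#'
#' @param model One of `"SI"`, `"IM"`, `"IIM"`, `"SC"`.
#' @param params Model parameters ([model_params()] or named list).
#' @param sdist An `sdist` object from [build_sdist()] (fractional weights
#'   allowed).
#' @param conditioned Logical; exclude the `S = 0` class and renormalise.
#' @return The log-likelihood (scalar). Observed classes with analytic
#'   probability zero (e.g. `theta = 0` with `S > 0` observed) yield `-Inf`.
#' @examples
#' sd1 <- new_sdist_from_counts(c(0, 1))  # one block with S = 1
#' loglik("SI", model_params(theta = 1, T0 = 0), sd1)  # log(0.25)
#' @export
loglik <- function(model, params, sdist, conditioned = FALSE) {
  stopifnot(inherits(sdist, "sdist"))
  kobs <- max(sdist$k)
  probs <- pmf_at(match.arg(model, div_models), as_div_params(params), kobs)
  n <- sdist$count
  if (conditioned) {
    p0 <- probs[1]
    n <- n[-1]
    probs <- probs[-1] / (1 - p0)
  }
  use <- n > 0
  if (any(use & probs <= 0)) return(-Inf)
  sum(n[use] * log(probs[use]))
}

# construct an sdist directly from a numeric count vector over k = 0..len-1
# (exported convenience for simulated or externally tallied histograms)

#' Make an S-distribution from raw class counts
#'
#' @param counts Numeric vector of (possibly fractional) weights for
#'   `S = 0, 1, 2, ...`.
#' @param pair_id Optional identifier.
#' @return An `sdist` object; `n_blocks` is `sum(counts)`.
#' @export
new_sdist_from_counts <- function(counts, pair_id = NA_character_) {
  stopifnot(is.numeric(counts), length(counts) >= 1, all(counts >= 0))
  new_sdist(counts, n_blocks = sum(counts), norm_total = NULL, pair_id = pair_id)
}

#' Default optimisation bounds for the demographic parameters
#'
#' The migration-rate ceiling encodes the identifiability limit of
#' pairwise-difference data: long-term rates of gene flow are only
#' distinguishable from panmixia when they are sufficiently low (M < 10).
#' `T1` is bounded by `T0` through an internal fractional reparameterisation.
#'
#' @return A named list of `c(lower, upper)` bounds for `theta`, `T0`, `M`
#'   and `f`.
#' @export
default_bounds <- function() {
  list(theta = c(1e-4, 50), T0 = c(1e-4, 20), M = c(0, 10), f = c(0, 1))
}

# Internal transformed parameterisation per model: theta and T0 on log scale,
# T1 = u * T0 with u in [0,1], M and f linear.
fit_space <- function(model, bounds) {
  dims <- switch(model,
    SI  = c("ltheta", "lT0"),
    IM  = c("ltheta", "lT0", "M"),
    IIM = c("ltheta", "lT0", "u", "M"),
    SC  = c("ltheta", "lT0", "u", "f")
  )
  lower <- c(ltheta = log(bounds$theta[1]), lT0 = log(bounds$T0[1]),
             u = 0, M = bounds$M[1], f = bounds$f[1])[dims]
  upper <- c(ltheta = log(bounds$theta[2]), lT0 = log(bounds$T0[2]),
             u = 1, M = bounds$M[2], f = bounds$f[2])[dims]
  list(dims = dims, lower = lower, upper = upper)
}

space_to_params <- function(x, dims) {
  v <- stats::setNames(as.numeric(x), dims)
  theta <- exp(v[["ltheta"]])
  T0 <- exp(v[["lT0"]])
  model_params(theta = theta, T0 = T0,
               T1 = if ("u" %in% dims) v[["u"]] * T0 else 0,
               M = if ("M" %in% dims) v[["M"]] else 0,
               f = if ("f" %in% dims) v[["f"]] else 0)
}

params_to_space <- function(params, dims, bounds) {
  p <- as_div_params(params)
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  v <- c(ltheta = log(clamp(p$theta, bounds$theta)),
         lT0 = log(clamp(p$T0, bounds$T0)),
         u = if (p$T0 > 0) clamp(p$T1 / p$T0, c(0, 1)) else 0,
         M = clamp(p$M, bounds$M),
         f = clamp(p$f, bounds$f))
  v[dims]
}

#' Fit one divergence model to an S-distribution
#'
#' Multi-start bounded maximisation of the blockwise log-likelihood. Starting
#' points are a Latin-hypercube sample of the transformed parameter box
#' (`theta`, `T0` on log scale; `T1/T0` and `f` as fractions), optionally
#' augmented with user-supplied starts (e.g. the optimum of a nested model).
#' Results are deterministic given `seed`.
#'
#' @inheritParams loglik
#' @param bounds Parameter bounds, as from [default_bounds()].
#' @param n_starts Number of Latin-hypercube starting points.
#' @param seed Integer seed for the start sample.
#' @param extra_starts Optional list of `div_params` used as additional
#'   starting points.
#' @return A `div_fit` object: a list with `model`, `params` (MLEs), `lnL`,
#'   `converged`, `n_starts`, `at_boundary` (names of parameters whose MLE is
#'   within relative tolerance 1e-3 of a search bound) and `conditioned`.
#' @examples
#' sd <- sdist_from_pmf(pmf_si(model_params(theta = 1, T0 = 0.5)), total = 1000)
#' fit_model("SI", sd, seed = 1)
#' @export
fit_model <- function(model, sdist, bounds = default_bounds(), n_starts = 8,
                      seed = 1, conditioned = FALSE, extra_starts = NULL) {
  model <- match.arg(model, div_models)
  stopifnot(inherits(sdist, "sdist"))
  sp <- fit_space(model, bounds)
  d <- length(sp$dims)

  negll <- function(x) {
    p <- space_to_params(x, sp$dims)
    ll <- loglik(model, p, sdist, conditioned)
    if (!is.finite(ll)) 1e12 else -ll
  }

  starts <- with_seed(seed, {
    u01 <- lhs::randomLHS(n_starts, d)
    sweep(sweep(u01, 2, sp$upper - sp$lower, "*"), 2, sp$lower, "+")
  })
  if (!is.null(extra_starts)) {
    extra <- t(vapply(extra_starts,
                      function(p) params_to_space(p, sp$dims, bounds),
                      numeric(d)))
    starts <- rbind(starts, extra)
  }

  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                   lower = sp$lower, upper = sp$upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }

  if (is.null(best)) {
    return(structure(list(model = model, params = NULL, lnL = NA_real_,
                          converged = FALSE, n_starts = nrow(starts),
                          at_boundary = character(), conditioned = conditioned,
                          pair_id = attr(sdist, "pair_id")),
                     class = "div_fit"))
  }

  mle <- space_to_params(best$par, sp$dims)
  at_b <- boundary_params(best$par, sp, model)
  structure(list(model = model, params = mle, lnL = -best$value,
                 converged = n_ok > 0L, n_starts = nrow(starts),
                 at_boundary = at_b, conditioned = conditioned,
                 pair_id = attr(sdist, "pair_id")),
            class = "div_fit")
}

# parameters whose MLE sits within relative tolerance of a search bound,
# reported under their natural names
boundary_params <- function(x, sp, model, rel_tol = 1e-3) {
  nat <- c(ltheta = "theta", lT0 = "T0", u = "T1", M = "M", f = "f")
  hit <- character()
  for (i in seq_along(sp$dims)) {
    span <- sp$upper[i] - sp$lower[i]
    tol <- rel_tol * max(span, 1)
    if (x[i] <= sp$lower[i] + tol || x[i] >= sp$upper[i] - tol) {
      hit <- c(hit, nat[[sp$dims[i]]])
    }
  }
  hit
}

#' Expected S-distribution under a model pmf
#'
#' Scale a pmf to a target total weight, giving the noise-free expected
#' histogram of `total` blocks. Useful for oracle tests and power
#' calculations.
#'
#' @param pmf A `div_pmf` object.
#' @param total Total weight (number of blocks).
#' @return An `sdist` object.
#' @export
sdist_from_pmf <- function(pmf, total = 500) {
  stopifnot(inherits(pmf, "div_pmf"))
  new_sdist(pmf$prob * total, n_blocks = total, norm_total = NULL)
}

#' Likelihood-ratio comparison of two nested fits
#'
#' @param null_fit,alt_fit `div_fit` objects on the same S-distribution with
#'   the same conditioning; `null_fit`'s model must nest within `alt_fit`'s.
#' @param df Degrees of freedom (difference in number of free parameters).
#' @param alpha Test level (default 0.05; the chi-square 0.95 quantiles are
#'   3.841 at 1 d.f. and 5.99 at 2 d.f.).
#' @return A list with `two_delta` (`2 * (lnL_alt - lnL_null)`, clipped below
#'   at zero), `df`, `threshold` and `significant`.
#' @examples
#' # thresholds used throughout model selection:
#' qchisq(0.95, df = 1)  # 3.841
#' qchisq(0.95, df = 2)  # 5.991
#' @export
compare_lrt <- function(null_fit, alt_fit, df, alpha = 0.05) {
  stopifnot(inherits(null_fit, "div_fit"), inherits(alt_fit, "div_fit"))
  if (!identical(null_fit$conditioned, alt_fit$conditioned)) {
    stop("fits differ in conditioning; refit with matching `conditioned`",
         call. = FALSE)
  }
  two_delta <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  threshold <- stats::qchisq(1 - alpha, df = df)
  list(two_delta = two_delta, df = df, threshold = threshold,
       significant = two_delta > threshold)
}

#' Chi-square thresholds for hierarchical model selection
#'
#' @param alpha Test level.
#' @return Named list with the 1-d.f. and 2-d.f. upper-`alpha` chi-square
#'   quantiles (3.841 and 5.99 at `alpha = 0.05`, to printed precision).
#' @export
select_thresholds <- function(alpha = 0.05) {
  list(df1 = stats::qchisq(1 - alpha, 1), df2 = stats::qchisq(1 - alpha, 2),
       alpha = alpha)
}

#' Hierarchical selection of the best minimally complex model
#'
#' Applies the decision tree used for per-pair model choice:
#' the strict-isolation model is retained unless isolation-with-migration
#' improves on it at the 1-d.f. threshold (2dlnL > 3.841) or secondary
#' contact improves on it at the 2-d.f. threshold (2dlnL > 5.99). Secondary
#' contact replaces isolation-with-migration only when its additional
#' parameter is justified at the 1-d.f. threshold. The initial-migration
#' model is compared against isolation-with-migration at 1 d.f. and against
#' secondary contact by raw log-likelihood (the two have equally many
#' parameters). Ties at exactly a threshold resolve to the simpler model.
#'
#' @param fits A named list of `div_fit` objects with elements `SI`, `IM`,
#'   `IIM`, `SC` fitted to the same S-distribution (e.g. from
#'   [fit_all_models()]).
#' @param thresholds From [select_thresholds()].
#' @param m_limit Migration-rate identifiability limit used by
#'   [flag_nonidentifiable()].
#' @return A one-row tibble of class `div_selection`: `pair_id`,
#'   `best_model`, the four `2dlnL` statistics, `nonidentifiable` and `tie`
#'   flags.
#' @export
select_best <- function(fits, thresholds = select_thresholds(), m_limit = 10) {
  need <- div_models
  if (!all(need %in% names(fits))) {
    stop("`fits` must contain elements ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ln <- vapply(fits[need], function(f) f$lnL, numeric(1))
  if (any(!is.finite(ln))) {
    stop("all four fits must have finite log-likelihood", call. = FALSE)
  }
  td <- function(alt, null) max(0, 2 * (ln[[alt]] - ln[[null]]))
  two_delta <- c(si_im = td("IM", "SI"), si_sc = td("SC", "SI"),
                 im_sc = td("SC", "IM"), im_iim = td("IIM", "IM"))

  # strict exceedance with a numerical guard: a statistic exactly at the
  # threshold keeps the simpler model
  exceeds <- function(stat, thr) stat - thr > 1e-9
  im_sig <- exceeds(two_delta[["si_im"]], thresholds$df1)
  sc_sig <- exceeds(two_delta[["si_sc"]], thresholds$df2)
  best <- "SI"
  if (im_sig || sc_sig) {
    best <- if (sc_sig && exceeds(two_delta[["im_sc"]], thresholds$df1)) "SC"
            else if (im_sig) "IM"
            else "SC"
    # IIM: one extra parameter over IM; same complexity as SC
    if (exceeds(two_delta[["im_iim"]], thresholds$df1) && ln[["IIM"]] > ln[["SC"]]) {
      best <- "IIM"
    }
  }

  tie <- any(abs(c(two_delta[["si_im"]] - thresholds$df1,
                   two_delta[["si_sc"]] - thresholds$df2,
                   two_delta[["im_sc"]] - thresholds$df1)) <= 1e-9)
  nonid <- flag_nonidentifiable(fits[[best]], m_limit = m_limit)
  out <- tibble::tibble(
    pair_id = fits[["SI"]]$pair_id %||% NA_character_,
    best_model = best,
    two_delta_si_im = two_delta[["si_im"]],
    two_delta_si_sc = two_delta[["si_sc"]],
    two_delta_im_sc = two_delta[["im_sc"]],
    two_delta_im_iim = two_delta[["im_iim"]],
    nonidentifiable = nonid,
    tie = tie
  )
  class(out) <- c("div_selection", class(out))
  out
}

#' Flag a fit whose parameters are not identifiable
#'
#' Arbitrarily high estimates of the migration rate or the divergence time
#' indicate poor fit or non-identifiability; such fits are excluded from
#' downstream parameter summaries. A fit is flagged when the migration-rate
#' or divergence-time estimate sits at a search bound, or when the estimated
#' migration rate reaches the identifiability ceiling (`M >= 10` by default,
#' the regime indistinguishable from panmixia).
#'
#' @param fit A `div_fit`.
#' @param m_limit Migration-rate ceiling.
#' @return Logical.
#' @export
flag_nonidentifiable <- function(fit, m_limit = 10) {
  stopifnot(inherits(fit, "div_fit"))
  if (!fit$converged || is.null(fit$params)) return(TRUE)
  any(c("M", "T0") %in% fit$at_boundary) || fit$params$M >= m_limit
}

#' Fit all four divergence models
#'
#' Fits SI, IM, IIM and SC in nesting order, feeding each null model's
#' optimum in as an extra starting point for the models that contain it, so
#' that the fitted log-likelihoods respect the nesting hierarchy.
#'
#' @inheritParams fit_model
#' @return Named list of `div_fit` objects (`SI`, `IM`, `IIM`, `SC`).
#' @export
fit_all_models <- function(sdist, bounds = default_bounds(), n_starts = 8,
                           seed = 1, conditioned = FALSE) {
  si <- fit_model("SI", sdist, bounds, n_starts, seed, conditioned)
  im <- fit_model("IM", sdist, bounds, n_starts, seed + 1L, conditioned,
                  extra_starts = list(si$params))
  iim <- fit_model("IIM", sdist, bounds, n_starts, seed + 2L, conditioned,
                   extra_starts = list(im$params, si$params))
  sc <- fit_model("SC", sdist, bounds, n_starts, seed + 3L, conditioned,
                  extra_starts = list(si$params))
  list(SI = si, IM = im, IIM = iim, SC = sc)
}

#' @export
print.div_fit <- function(x, ...) {
  cat(sprintf("<div_fit> %s: lnL = %.4f, converged = %s%s\n", x$model,
              x$lnL, x$converged,
              if (length(x$at_boundary)) paste0(", at boundary: ",
                                                paste(x$at_boundary, collapse = ","))
              else ""))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Tidy a fitted divergence model
#'
#' @param x A `div_fit` object.
#' @param ... Unused.
#' @return One row per active parameter: `term`, `estimate`, `at_boundary`.
#' @importFrom generics tidy
#' @export
tidy.div_fit <- function(x, ...) {
  act <- active_params(x$model)
  tibble::tibble(
    term = act,
    estimate = vapply(act, function(nm) x$params[[nm]], numeric(1)),
    at_boundary = act %in% x$at_boundary
  )
}

#' One-row summary of a fitted divergence model
#'
#' @param x A `div_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `logLik`, `converged`, `n_starts`,
#'   `conditioned`, `nonidentifiable`.
#' @importFrom generics glance
#' @export
glance.div_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$lnL, converged = x$converged,
                 n_starts = x$n_starts, conditioned = x$conditioned,
                 nonidentifiable = flag_nonidentifiable(x))
}

#' @importFrom rlang %||%
NULL
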