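#' Demographic model parameters
#'
#' Bundle and validate the scaled parameters shared by the four divergence
#' models. Times are measured in units of 2*Ne generations and the mutation
#' rate is scaled per block, so that a pair of lineages with coalescence time
#' `t` carries `Poisson(theta * t)` pairwise differences.
#'
#' @param theta Scaled per-block mutation rate, `4 * Ne * mu_block` (>= 0).
#' @param T0 Species divergence time in units of `2 * Ne` generations (>= 0).
#' @param T1 Secondary event time, same units: the time gene flow stops under
#'   the initial-migration model, or the admixture-pulse time under the
#'   secondary-contact model. Must satisfy `0 <= T1 <= T0`.
#' @param M Scaled symmetric migration rate, `4 * Ne * m` migrants per
#'   generation (>= 0).
#' @param f Admixture fraction of the secondary-contact pulse, in `[0, 1]`:
#'   each lineage independently relocates to the other deme with probability
#'   `f` at `T1`.
#'
#' @return A named list of class `div_params` with elements `theta`, `T0`,
#'   `T1`, `M`, `f`.
#'
#' @details Each model consumes only its active subset: strict isolation (SI)
#'   uses `theta, T0`; isolation-with-migration (IM) adds `M`;
#'   isolation-with-initial-migration (IIM) adds `T1`; the secondary-contact
#'   pulse (SC) uses `theta, T0, T1, f`.
#'
#' @examples
#' model_params(theta = 1.5, T0 = 1, M = 0.5)
#' @export
model_params <- function(theta, T0 = 0, T1 = 0, M = 0, f = 0) {
  p <- list(theta = as.numeric(theta), T0 = as.numeric(T0),
            T1 = as.numeric(T1), M = as.numeric(M), f = as.numeric(f))
  bad <- vapply(p, function(x) length(x) != 1L || !is.finite(x), logical(1))
  if (any(bad)) {
    stop("model parameters must be single finite numbers: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  if (p$theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (p$T0 < 0) stop("T0 must be >= 0", call. = FALSE)
  if (p$T1 < 0 || p$T1 > p$T0) stop("T1 must satisfy 0 <= T1 <= T0", call. = FALSE)
  if (p$M < 0) stop("M must be >= 0", call. = FALSE)
  if (p$f < 0 || p$f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  structure(p, class = "div_params")
}

#' @export
print.div_params <- function(x, ...) {
  cat("<div_params> ",
      paste(sprintf("%s = %g", names(unclass(x)), unlist(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

div_models <- c("SI", "IM", "IIM", "SC")

#' Active parameters of each divergence model
#'
#' @param model One of `"SI"`, `"IM"`, `"IIM"`, `"SC"`.
#' @return Character vector of parameter names the model actually uses.
#' @examples
#' active_params("IM")
#' @export
active_params <- function(model) {
  switch(match.arg(model, div_models),
    SI  = c("theta", "T0"),
    IM  = c("theta", "T0", "M"),
    IIM = c("theta", "T0", "T1", "M"),
    SC  = c("theta", "T0", "T1", "f")
  )
}

as_div_params <- function(params) {
  if (inherits(params, "div_params")) return(params)
  if (is.numeric(params) && !is.null(names(params))) params <- as.list(params)
  if (is.list(params)) return(do.call(model_params, params))
  stop("`params` must be a div_params object or a named list/vector", call. = FALSE)
}
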