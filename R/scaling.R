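#' Mutation-rate model for natural-unit scaling
#'
#' Bundles the spontaneous per-base per-generation mutation rate (with its
#' 95% confidence bounds) and the block length, used to convert scaled
#' parameter estimates into individuals and generations. The defaults are
#' the direct estimate for *D. melanogaster*, `3.32e-9` per base and
#' generation (95% CI `2.52e-9`–`4.30e-9`).
#'
#' @param mu_per_base Point estimate of the per-base per-generation mutation
#'   rate.
#' @param mu_ci_low,mu_ci_high Confidence bounds, `0 < low <= mu <= high`.
#' @param block_length Bases per block (> 0).
#' @return A list of class `mutation_model`.
#' @examples
#' mutation_model()
#' @export
mutation_model <- function(mu_per_base = 3.32e-9, mu_ci_low = 2.52e-9,
                           mu_ci_high = 4.30e-9, block_length = 100) {
  if (!(mu_ci_low > 0 && mu_ci_low <= mu_per_base && mu_per_base <= mu_ci_high)) {
    stop("need 0 < mu_ci_low <= mu_per_base <= mu_ci_high", call. = FALSE)
  }
  if (block_length <= 0) stop("block_length must be > 0", call. = FALSE)
  structure(list(mu_per_base = mu_per_base, mu_ci_low = mu_ci_low,
                 mu_ci_high = mu_ci_high, block_length = block_length),
            class = "mutation_model")
}

#' Per-lineage probability of gene flow
#'
#' Under continuous symmetric migration at scaled rate `M` over a gene-flow
#' period of length `T0` (in units of 2*Ne generations), the probability that
#' the ancestry of a random haplotype is affected by migration is
#' `1 - exp(-T0 * M / 2)`. This converts the scaled effective rate of gene
#' flow into a probability directly comparable with the discrete
#' secondary-contact pulse (see [sc_gene_flow_probability()]).
#'
#' @param T0 Duration of the gene-flow period, in `2 * Ne` generations.
#' @param M Scaled migration rate `4 * Ne * m`.
#' @return Probability in `[0, 1)`.
#' @examples
#' gene_flow_probability(T0 = 2, M = 1)  # 1 - exp(-1)
#' @export
gene_flow_probability <- function(T0, M) {
  if (any(T0 < 0) || any(M < 0)) {
    stop("T0 and M must be >= 0", call. = FALSE)
  }
  -expm1(-T0 * M / 2)
}

#' Gene-flow probability of a secondary-contact pulse
#'
#' Under the pulse convention used here, each lineage independently
#' relocates with probability `f`, so `f` itself is the per-lineage
#' probability that ancestry is affected by the pulse. The alternative
#' convention `2 f (1 - f)` (probability the sampled pair is brought into
#' one deme) is available via `convention = "pair"`.
#'
#' @param f Admixture fraction in `[0, 1]`.
#' @param convention `"lineage"` (default, returns `f`) or `"pair"`
#'   (returns `2 f (1 - f)`).
#' @return Probability in `[0, 1]`.
#' @export
sc_gene_flow_probability <- function(f, convention = c("lineage", "pair")) {
  if (any(f < 0) || any(f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  switch(match.arg(convention), lineage = f, pair = 2 * f * (1 - f))
}

#' Convert scaled estimates to natural units
#'
#' Maps the scaled parameter vector of a fitted model to the ancestral
#' effective population size `Ne = theta / (4 * mu * L)`, the divergence
#' time in generations `T0 * 2 * Ne`, and the per-lineage gene-flow
#' probability, with low/high variants evaluated at the mutation-rate
#' confidence bounds (a larger mutation rate implies a smaller `Ne`, so the
#' `_lo` column uses `mu_ci_high` and vice versa).
#'
#' The gene-flow probability uses the duration of the migration epoch for
#' the migration models (`T0` for IM, `T0 - T1` for IIM), `f` for the
#' secondary-contact pulse, and 0 for strict isolation.
#'
#' @param params Fitted [model_params()] (or a `div_fit`).
#' @param mm A [mutation_model()].
#' @param model Model the parameters belong to (taken from the fit when
#'   `params` is a `div_fit`).
#' @return A one-row tibble: `Ne`, `Ne_lo`, `Ne_hi`, `T0_gen`, `T0_gen_lo`,
#'   `T0_gen_hi`, `p_geneflow`.
#' @examples
#' to_natural_units(model_params(theta = 1.2, T0 = 1, M = 0.5),
#'                  mutation_model(), model = "IM")
#' @export
to_natural_units <- function(params, mm = mutation_model(), model = "SI") {
  if (inherits(params, "div_fit")) {
    model <- params$model
    params <- params$params
  }
  p <- as_div_params(params)
  model <- match.arg(model, div_models)
  if (p$theta <= 0) stop("theta must be > 0 for natural-unit scaling", call. = FALSE)
  ne <- function(mu) p$theta / (4 * mu * mm$block_length)
  Ne <- ne(mm$mu_per_base)
  Ne_lo <- ne(mm$mu_ci_high)
  Ne_hi <- ne(mm$mu_ci_low)
  pgf <- switch(model,
    SI  = 0,
    IM  = gene_flow_probability(p$T0, p$M),
    IIM = gene_flow_probability(p$T0 - p$T1, p$M),
    SC  = sc_gene_flow_probability(p$f)
  )
  tibble::tibble(
    Ne = Ne, Ne_lo = Ne_lo, Ne_hi = Ne_hi,
    T0_gen = p$T0 * 2 * Ne, T0_gen_lo = p$T0 * 2 * Ne_lo,
    T0_gen_hi = p$T0 * 2 * Ne_hi,
    p_geneflow = pgf
  )
}
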