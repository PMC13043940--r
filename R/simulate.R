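#' Simulation configuration
#'
#' Collects everything a block simulation needs: the demographic model and
#' its parameters, the number of blocks, the per-base mutation and
#' recombination rates used to anchor the scaled parameters to physical
#' units, the within-species mutation rate driving heterozygous sites, and a
#' seed.
#'
#' @param model One of `"SI"`, `"IM"`, `"IIM"`, `"SC"`.
#' @param params [model_params()] for the model.
#' @param n_blocks Number of blocks to simulate (> 0).
#' @param block_length Bases per block.
#' @param mu_per_base Per-base per-generation mutation rate (used with
#'   `theta` to recover `Ne` when recombination is simulated).
#' @param r_per_base Per-base per-generation crossover rate; 0 disables
#'   recombination. The conventional conversion is
#'   `1.03 cM/Mb = 1.03e-8` per base and generation.
#' @param theta_within Within-species scaled mutation rate generating
#'   heterozygous sites (`h ~ Poisson(theta_within)` per block); 0 disables.
#' @param seed Integer seed; fixed seed gives reproducible output.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config("SI", model_params(theta = 1, T0 = 1), n_blocks = 1000)
#' @export
sim_config <- function(model, params, n_blocks, block_length = 100,
                       mu_per_base = 3.32e-9, r_per_base = 0,
                       theta_within = 0, seed = 1) {
  model <- match.arg(model, div_models)
  params <- as_div_params(params)
  stopifnot(n_blocks > 0, block_length > 0, mu_per_base > 0,
            r_per_base >= 0, theta_within >= 0)
  structure(list(model = model, params = params,
                 n_blocks = as.integer(n_blocks),
                 block_length = as.integer(block_length),
                 mu_per_base = mu_per_base, r_per_base = r_per_base,
                 theta_within = theta_within, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw pairwise coalescence times under a divergence model
#'
#' Samples from the model's law of the coalescence time `T` of two lineages
#' sampled one per species (in units of 2*Ne generations): `T0 + Exp(1)`
#' under strict isolation; an event-driven simulation of the three-state
#' ancestral chain (apart/together/coalesced) for the migration models; and
#' Bernoulli(`f`) deme relocation at `T1` followed by piecewise-exponential
#' coalescence for the secondary-contact pulse.
#'
#' @inheritParams loglik
#' @param n Number of draws.
#' @return Numeric vector of `n` coalescence times.
#' @examples
#' mean(sample_coal_time("SI", model_params(theta = 1, T0 = 2), n = 1e4))  # ~ 3
#' @export
sample_coal_time <- function(model, params, n = 1) {
  p <- as_div_params(params)
  model <- match.arg(model, div_models)
  switch(model,
    SI = p$T0 + stats::rexp(n),
    IM = coal_time_im(n, p$T0, p$M),
    IIM = p$T1 + coal_time_im(n, p$T0 - p$T1, p$M),
    SC = coal_time_sc(n, p$T0, p$T1, p$f)
  )
}

# Event-driven three-state chain before T0 (apart <-> together at rate M,
# together -> coalesced at rate 1), panmictic Exp(1) after T0; vectorised
# over draws by iterating events on the still-active subset.
coal_time_im <- function(n, T0, M) {
  t_out <- numeric(n)
  if (M == 0 || T0 == 0) return(T0 + stats::rexp(n))
  now <- numeric(n)
  together <- rep(FALSE, n)
  active <- rep(TRUE, n)
  while (any(active)) {
    i <- which(active)
    rate <- ifelse(together[i], M + 1, M)
    wait <- stats::rexp(length(i), rate)
    nxt <- now[i] + wait
    crossed <- nxt >= T0
    # uncoalesced at T0: panmictic ancestor
    hit <- i[crossed]
    t_out[hit] <- T0 + stats::rexp(length(hit))
    active[hit] <- FALSE
    j <- i[!crossed]
    if (length(j)) {
      now[j] <- nxt[!crossed]
      coal <- together[j] & stats::runif(length(j)) < 1 / (M + 1)
      t_out[j[coal]] <- now[j[coal]]
      active[j[coal]] <- FALSE
      sw <- j[!coal]
      together[sw] <- !together[sw]
    }
  }
  t_out
}

coal_time_sc <- function(n, T0, T1, f) {
  # each lineage relocates independently w.p. f at T1; pair in same deme
  # (prob 2 f (1-f)) may coalesce at rate 1 on (T1, T0)
  same <- stats::runif(n) < 2 * f * (1 - f)
  e <- stats::rexp(n)
  t <- ifelse(same & T1 + e < T0, T1 + e, T0 + stats::rexp(n))
  t
}

#' Simulate block records under a divergence model
#'
#' Per block, draws a pairwise coalescence time `t` from the model, the
#' inter-specific difference count `S ~ Poisson(theta * t)` (emitted as
#' fixed differences `d`), and optionally a heterozygous-site count
#' `h ~ Poisson(theta_within)`, so that the binomially phased S-distribution
#' of the output follows the model pmf convolved with
#' `Poisson(theta_within / 2)`. Blocks are non-recombining
#' (`r_per_base` must be 0 here; see [simulate_si_recomb()]).
#'
#' @param config A [sim_config()].
#' @return A tibble of block records (`block_id`, `length`, `d`, `h`).
#' @examples
#' cfg <- sim_config("IM", model_params(theta = 1.5, T0 = 1, M = 0.5),
#'                   n_blocks = 100, seed = 7)
#' simulate_blocks(cfg)
#' @export
simulate_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$r_per_base != 0) {
    stop("simulate_blocks() generates non-recombining blocks; use simulate_si_recomb() for r_per_base > 0",
         call. = FALSE)
  }
  with_seed(config$seed, {
    t <- sample_coal_time(config$model, config$params, config$n_blocks)
    d <- stats::rpois(config$n_blocks, config$params$theta * t)
    h <- if (config$theta_within > 0) {
      stats::rpois(config$n_blocks, config$theta_within)
    } else {
      integer(config$n_blocks)
    }
    if (any(d + h > config$block_length)) {
      stop("simulated site counts exceed block_length; increase block_length",
           call. = FALSE)
    }
    tibble::tibble(
      block_id = sprintf("b%06d", seq_len(config$n_blocks)),
      length = config$block_length,
      d = as.integer(d), h = as.integer(h)
    )
  })
}

#' Simulate the strict-isolation null with intra-block recombination
#'
#' Runs a two-sample ancestral-recombination simulation under strict
#' isolation: within each block, crossovers split the lineages' ancestral
#' material into segments whose coalescence times (all `>= T0`) are
#' positively correlated but not identical, and the block's difference count
#' is `Poisson(theta * mean marginal coalescence time)`. Recombination
#' leaves the mean of `S` unchanged but shrinks its variance relative to
#' non-recombining blocks, which is what inflates apparent support for gene
#' flow when blocks are assumed non-recombining.
#'
#' The scaled per-block crossover rate is recovered from the physical rates:
#' `Ne = theta / (4 mu L)` and `rho = 4 Ne r L`.
#'
#' @param config A [sim_config()] with `model = "SI"`.
#' @return An `sdist` with the simulated S histogram (one count per block).
#' @export
simulate_si_recomb <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$model != "SI") {
    stop("recombination is implemented for the SI null only", call. = FALSE)
  }
  p <- config$params
  L <- config$block_length
  Ne <- p$theta / (4 * config$mu_per_base * L)
  rho <- 4 * Ne * config$r_per_base * L
  with_seed(config$seed, {
    if (rho == 0) {
      tbar <- p$T0 + stats::rexp(config$n_blocks)
    } else {
      tbar <- vapply(seq_len(config$n_blocks),
                     function(i) arg_mean_coal_time(p$T0, rho), numeric(1))
    }
    s <- stats::rpois(config$n_blocks, p$theta * tbar)
    counts <- tabulate(s + 1L, nbins = max(s) + 1L)
    new_sdist(counts, n_blocks = config$n_blocks, norm_total = NULL)
  })
}

# --- two-sample ancestral-recombination simulation under strict isolation ---
# A lineage is a matrix of half-open segments [l, r) of ancestral material on
# [0, 1] with a bitmask label (1 = sample A, 2 = sample B) and a deme. Before
# T0 lineages coalesce only within their own deme (rejoining material split
# by recombination); after T0 all lineages form one pool. When a merge
# produces label 3 over an interval, that interval has reached the MRCA of
# the two samples and its coalescence time is recorded.
arg_mean_coal_time <- function(T0, rho) {
  lineages <- list(
    list(segs = matrix(c(0, 1, 1), 1, 3), deme = 1L),
    list(segs = matrix(c(0, 1, 2), 1, 3), deme = 2L)
  )
  t <- 0
  tbar <- 0
  open <- 1          # measure of positions not yet at their MRCA
  repeat {
    spans <- vapply(lineages, function(ln) max(ln$segs[, 2]) - min(ln$segs[, 1]),
                    numeric(1))
    rec_rates <- rho / 2 * spans
    demes <- vapply(lineages, `[[`, integer(1), "deme")
    if (t < T0) {
      nA <- sum(demes == 1L); nB <- sum(demes == 2L)
      coal_rate <- nA * (nA - 1) / 2 + nB * (nB - 1) / 2
    } else {
      k <- length(lineages)
      coal_rate <- k * (k - 1) / 2
    }
    total <- coal_rate + sum(rec_rates)
    if (total == 0) {        # waiting for the phase switch at T0
      t <- T0
      next
    }
    wait <- stats::rexp(1, total)
    if (t < T0 && t + wait > T0) {
      t <- T0
      next
    }
    t <- t + wait
    if (stats::runif(1) * total < coal_rate) {
      # coalescence: uniform pair (within deme before T0)
      if (t < T0) {
        dm <- if (stats::runif(1) * coal_rate < sum(demes == 1L) * (sum(demes == 1L) - 1) / 2) 1L else 2L
        pool <- which(demes == dm)
      } else {
        pool <- seq_along(lineages)
      }
      pair <- sample(pool, 2)
      mg <- merge_lineages(lineages[[pair[1]]], lineages[[pair[2]]], t)
      tbar <- tbar + mg$tbar
      open <- open - mg$resolved
      lineages <- lineages[-pair]
      if (!is.null(mg$lineage)) lineages <- c(lineages, list(mg$lineage))
      if (open <= 1e-12 || length(lineages) == 0) break
    } else {
      # recombination: lineage chosen proportional to span, uniform breakpoint
      i <- sample.int(length(lineages), 1, prob = rec_rates)
      ln <- lineages[[i]]
      lo <- min(ln$segs[, 1]); hi <- max(ln$segs[, 2])
      u <- stats::runif(1, lo, hi)
      left <- split_segs(ln$segs, u, "left")
      right <- split_segs(ln$segs, u, "right")
      if (is.null(left) || is.null(right)) next   # breakpoint at a boundary
      lineages[[i]] <- list(segs = left, deme = ln$deme)
      lineages <- c(lineages, list(list(segs = right, deme = ln$deme)))
    }
  }
  tbar
}

split_segs <- function(segs, u, side) {
  if (side == "left") {
    keep <- segs[segs[, 1] < u, , drop = FALSE]
    keep[keep[, 2] > u, 2] <- u
  } else {
    keep <- segs[segs[, 2] > u, , drop = FALSE]
    keep[keep[, 1] < u, 1] <- u
  }
  if (nrow(keep) == 0) NULL else keep
}

merge_lineages <- function(ln1, ln2, t) {
  s1 <- ln1$segs; s2 <- ln2$segs
  bp <- sort(unique(c(s1[, 1], s1[, 2], s2[, 1], s2[, 2])))
  l <- bp[-length(bp)]; r <- bp[-1]
  mid <- (l + r) / 2
  lab <- bitwOr(interval_label(s1, mid), interval_label(s2, mid))
  done <- lab == 3L
  resolved <- sum((r - l)[done])
  keep <- lab == 1L | lab == 2L
  segs <- cbind(l[keep], r[keep], lab[keep])
  # fuse adjacent segments with identical labels
  if (nrow(segs) > 1) {
    fuse <- which(segs[-1, 1] == segs[-nrow(segs), 2] &
                  segs[-1, 3] == segs[-nrow(segs), 3])
    for (i in rev(fuse)) {
      segs[i, 2] <- segs[i + 1, 2]
      segs <- segs[-(i + 1), , drop = FALSE]
    }
  }
  list(
    tbar = t * resolved,
    resolved = resolved,
    lineage = if (nrow(segs) > 0) list(segs = segs, deme = ln1$deme) else NULL
  )
}

interval_label <- function(segs, x) {
  out <- integer(length(x))
  for (i in seq_len(nrow(segs))) {
    inside <- x >= segs[i, 1] & x < segs[i, 2]
    out[inside] <- as.integer(segs[i, 3])
  }
  out
}

#' False-positive rate of the gene-flow test under a strict-isolation null
#'
#' For each replicate, simulates an S-distribution under the null
#' configuration (non-recombining blocks via [simulate_blocks()], or the
#' ancestral-recombination simulator when `r_per_base > 0`), fits the SI and
#' IM models, and records the likelihood-ratio statistic
#' `2 (lnL_IM - lnL_SI)`. Returns per-replicate statistics plus the rate at
#' which each threshold is exceeded, with a binomial confidence interval.
#'
#' @param null_config A [sim_config()] with `model = "SI"`.
#' @param n_replicates Number of simulated datasets.
#' @param thresholds Numeric vector of decision thresholds for the LRT
#'   statistic (default the 1-d.f. chi-square 0.95 quantile, 3.841).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param n_starts Starting points per fit (the SI/IM likelihoods here are
#'   low-dimensional and smooth, so a small multi-start suffices).
#' @param bounds Optimisation bounds.
#' @return A tibble with columns `replicate`, `two_delta` and one logical
#'   `exceeds_<threshold>` column per threshold, with attributes `rates`
#'   (tibble of threshold, false-positive rate and 95% binomial CI).
#' @export
power_analysis <- function(null_config, n_replicates = 100,
                           thresholds = stats::qchisq(0.95, 1), seed = 1,
                           n_starts = 4, bounds = default_bounds()) {
  stopifnot(inherits(null_config, "sim_config"))
  if (null_config$model != "SI") {
    stop("the calibration experiment simulates under the SI null", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_replicates)
  two_delta <- vapply(seq_len(n_replicates), function(i) {
    cfg <- null_config
    cfg$seed <- seeds[i]
    sd <- if (cfg$r_per_base > 0) {
      simulate_si_recomb(cfg)
    } else {
      build_sdist(simulate_blocks(cfg), normalize_total = NULL)
    }
    si <- fit_model("SI", sd, bounds, n_starts, seed = seeds[i])
    im <- fit_model("IM", sd, bounds, n_starts, seed = seeds[i] %% 1000000L + 1L,
                    extra_starts = list(si$params))
    max(0, 2 * (im$lnL - si$lnL))
  }, numeric(1))

  out <- tibble::tibble(replicate = seq_len(n_replicates), two_delta = two_delta)
  for (thr in thresholds) {
    out[[sprintf("exceeds_%g", thr)]] <- two_delta > thr
  }
  rates <- purrr::map_dfr(thresholds, function(thr) {
    x <- sum(two_delta > thr)
    ci <- stats::binom.test(x, n_replicates)$conf.int
    tibble::tibble(threshold = thr, rate = x / n_replicates,
                   ci_low = ci[1], ci_high = ci[2])
  })
  attr(out, "rates") <- rates
  out
}
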