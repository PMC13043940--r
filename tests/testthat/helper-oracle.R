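# Independent Monte-Carlo oracles for the pairwise-difference distributions.
# These re-derive each model's coalescence-time law directly from its
# description (scalar per-draw logic, no shared code with the analytic pmf
# route or with the package's vectorised samplers).

oracle_draw_T <- function(model, theta, T0 = 0, T1 = 0, M = 0, f = 0) {
  if (model == "SI") return(T0 + rexp(1))
  if (model == "SC") {
    move1 <- runif(1) < f
    move2 <- runif(1) < f
    same_deme <- xor(move1, move2)
    if (same_deme) {
      e <- rexp(1)
      if (T1 + e < T0) return(T1 + e)
    }
    return(T0 + rexp(1))
  }
  # IM / IIM: explicit event walk of the three-state chain
  t <- if (model == "IIM") T1 else 0
  state <- "apart"
  while (t < T0) {
    if (M == 0) {
      t <- T0
      break
    }
    rate <- if (state == "apart") M else M + 1
    t_next <- t + rexp(1, rate)
    if (t_next >= T0) {
      t <- T0
      break
    }
    t <- t_next
    if (state == "apart") {
      state <- "together"
    } else if (runif(1) < 1 / (M + 1)) {
      return(t)                       # coalesced before T0
    } else {
      state <- "apart"
    }
  }
  T0 + rexp(1)
}

oracle_draw_S <- function(n, model, theta, T0 = 0, T1 = 0, M = 0, f = 0) {
  tt <- vapply(seq_len(n), function(i) oracle_draw_T(model, theta, T0, T1, M, f),
               numeric(1))
  rpois(n, theta * tt)
}

# empirical frequencies of draws over classes 0..kmax (draws beyond kmax pooled)
empirical_pmf <- function(s, kmax) {
  tabulate(pmin(s, kmax) + 1L, nbins = kmax + 1L) / length(s)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# chi-square goodness of fit of counts against probabilities, pooling
# classes with small expectation
gof_pvalue <- function(counts, probs, min_expected = 5) {
  n <- sum(counts)
  expected <- probs * n
  ord <- seq_along(counts)
  grp <- integer(length(counts))
  g <- 1L
  acc <- 0
  for (i in ord) {
    grp[i] <- g
    acc <- acc + expected[i]
    if (acc >= min_expected && i < length(counts)) {
      g <- g + 1L
      acc <- 0
    }
  }
  obs <- tapply(counts, grp, sum)
  exp <- tapply(expected, grp, sum)
  keep <- exp > 0
  stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  df <- max(1L, sum(keep) - 1L)
  pchisq(stat, df = df, lower.tail = FALSE)
}

expect_pmf_valid <- function(pmf, tol = 1e-8) {
  expect_true(all(pmf$prob >= 0))
  expect_lt(abs(sum(pmf$prob) + attr(pmf, "tail") - 1), tol)
}

# small deterministic block table used by the I/O tests
make_block_tbl <- function() {
  tibble::tibble(
    block_id = c("g1.i2", "g2.i1", "g3.i1"),
    length = c(100L, 120L, 80L),
    d = c(2L, 0L, 1L),
    h = c(1L, 0L, 3L)
  )
}
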