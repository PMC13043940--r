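# Analytic pairwise-difference distributions: closed forms, limiting cases,
# reductions between nested models, and agreement with an independent
# Monte-Carlo oracle.

test_that("strict isolation reduces to the geometric law at T0 = 0", {
  pm <- pmf_si(model_params(theta = 1, T0 = 0), kmax = 10, tail_tol = 1e-2)
  expect_equal(pm$prob[1:3], c(0.5, 0.25, 0.125), tolerance = 1e-12)
  # general geometric: theta^k / (1 + theta)^(k+1)
  th <- 2.5
  pm2 <- pmf_si(model_params(theta = th, T0 = 0), kmax = 30, tail_tol = 1e-2)
  expect_equal(pm2$prob, th^(0:30) / (1 + th)^(1:31), tolerance = 1e-12)
})

test_that("zero mutation rate puts all mass on S = 0 for every model", {
  for (m in c("SI", "IM", "IIM", "SC")) {
    pm <- pairdiv:::div_pmf(m, model_params(theta = 0, T0 = 5, T1 = 1,
                                            M = 2, f = 0.3), kmax = 5)
    expect_equal(pm$prob[1], 1)
    expect_equal(sum(pm$prob), 1)
  }
})

test_that("pmfs are normalised on a parameter grid", {
  grid <- expand.grid(theta = c(0.1, 1, 5), T0 = c(0, 0.5, 2),
                      M = c(0, 0.5, 5), t1f = c(0, 0.5, 1), f = c(0, 0.3, 1))
  # thin the full factorial to keep the loop quick but representative
  grid <- grid[seq(1, nrow(grid), by = 7), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- model_params(theta = g$theta, T0 = g$T0, T1 = g$t1f * g$T0,
                      M = g$M, f = g$f)
    for (m in c("SI", "IM", "IIM", "SC")) {
      expect_pmf_valid(pairdiv:::div_pmf(m, p), tol = 1e-8)
    }
  }
})

test_that("nested models reduce to their special cases within 1e-10", {
  cases <- list(
    list(a = pmf_im(model_params(theta = 1.5, T0 = 1, M = 0), kmax = 40),
         b = pmf_si(model_params(theta = 1.5, T0 = 1), kmax = 40)),
    list(a = pmf_im(model_params(theta = 1, T0 = 0, M = 7), kmax = 40, tail_tol = 1e-2),
         b = pmf_si(model_params(theta = 1, T0 = 0), kmax = 40, tail_tol = 1e-2)),
    list(a = pmf_iim(model_params(theta = 2, T0 = 1.5, T1 = 0, M = 1), kmax = 40),
         b = pmf_im(model_params(theta = 2, T0 = 1.5, M = 1), kmax = 40)),
    list(a = pmf_iim(model_params(theta = 2, T0 = 1.5, T1 = 1.5, M = 1), kmax = 40),
         b = pmf_si(model_params(theta = 2, T0 = 1.5), kmax = 40)),
    list(a = pmf_sc(model_params(theta = 1, T0 = 2, T1 = 0.5, f = 0), kmax = 40),
         b = pmf_si(model_params(theta = 1, T0 = 2), kmax = 40)),
    list(a = pmf_sc(model_params(theta = 1, T0 = 2, T1 = 0.5, f = 1), kmax = 40),
         b = pmf_si(model_params(theta = 1, T0 = 2), kmax = 40))
  )
  for (cs in cases) {
    expect_lt(max(abs(cs$a$prob - cs$b$prob)), 1e-10)
  }
})

test_that("analytic pmfs match the Monte-Carlo oracle", {
  withr::local_seed(424243)
  n <- 2e5
  cases <- list(
    list(model = "SI", theta = 2, T0 = 1),
    list(model = "IM", theta = 1.5, T0 = 1, M = 0.5),
    list(model = "IIM", theta = 1, T0 = 2, T1 = 0.5, M = 1),
    list(model = "SC", theta = 1, T0 = 2, T1 = 0.2, f = 0.3)
  )
  for (cs in cases) {
    s <- do.call(oracle_draw_S, c(list(n = n), cs))
    kmax <- max(40, max(s))
    pm <- pairdiv:::div_pmf(cs$model,
                            do.call(model_params, cs[-1]),
                            kmax = kmax, tail_tol = 1)
    emp <- empirical_pmf(s, kmax)
    expect_lt(total_variation(emp, pm$prob), 0.005)
    counts <- tabulate(pmin(s, kmax) + 1L, nbins = kmax + 1L)
    expect_gt(gof_pvalue(counts, pm$prob / sum(pm$prob)), 0.01)
  }
})

test_that("pmf mean equals theta * E[T]", {
  # SI exactly: E[S] = theta * (T0 + 1)
  pm <- pmf_si(model_params(theta = 2, T0 = 1.5))
  expect_equal(sum(pm$k * pm$prob), 2 * 2.5, tolerance = 1e-8)
  # IM against the oracle mean within 3 standard errors
  withr::local_seed(99)
  n <- 2e5
  tt <- vapply(seq_len(n), function(i) oracle_draw_T("IM", 1.5, T0 = 1, M = 0.5),
               numeric(1))
  pm <- pmf_im(model_params(theta = 1.5, T0 = 1, M = 0.5))
  mu_hat <- 1.5 * mean(tt)
  se <- 1.5 * sd(tt) / sqrt(n)
  expect_lt(abs(sum(pm$k * pm$prob) - mu_hat), 3 * se)
})

test_that("P[S = 0] under strict isolation decreases in theta and T0", {
  p0 <- function(theta, T0) pmf_si(model_params(theta, T0))$prob[1]
  thetas <- c(0.1, 0.5, 1, 2, 5)
  expect_true(all(diff(vapply(thetas, p0, numeric(1), T0 = 1)) < 0))
  t0s <- c(0, 0.5, 1, 2, 5)
  expect_true(all(diff(vapply(t0s, function(t) p0(1, t), numeric(1))) < 0))
})

test_that("invalid parameters and excessive truncation raise errors", {
  expect_error(model_params(theta = -1), "theta")
  expect_error(model_params(theta = 1, T0 = 1, T1 = 2), "T1")
  expect_error(model_params(theta = 1, M = -0.5), "M")
  expect_error(model_params(theta = 1, f = 1.2), "f")
  # heavy tail beyond a small explicit kmax must be reported
  expect_error(pmf_si(model_params(theta = 5, T0 = 2), kmax = 5), "truncation")
})

test_that("default kmax policy covers the distribution to 1e-10", {
  pm <- pmf_si(model_params(theta = 5, T0 = 2))
  expect_gte(attr(pm, "kmax"), 40)
  expect_lt(attr(pm, "tail"), 1e-10)
})
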