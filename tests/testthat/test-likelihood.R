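# Blockwise likelihood, multi-start fitting, LRT comparison and the
# hierarchical model-selection rules.

test_that("loglik matches the geometric closed form on a single block", {
  sd1 <- new_sdist_from_counts(c(0, 1))   # one block with S = 1
  expect_equal(loglik("SI", model_params(theta = 1, T0 = 0), sd1), log(0.25))
})

test_that("conditioned likelihood renormalises by 1 - P[S = 0]", {
  p <- model_params(theta = 1.5, T0 = 1, M = 0.5)
  sd1 <- new_sdist_from_counts(c(0, 0, 1))  # one block at S = 2
  full <- loglik("IM", p, sd1)
  cond <- loglik("IM", p, sd1, conditioned = TRUE)
  probs <- pairdiv:::pmf_at("IM", p, 2)
  expect_equal(cond, log(probs[3] / (1 - probs[1])), tolerance = 1e-12)
  expect_gte(cond, full)  # renormalisation can only increase the class probability
})

test_that("conditioned and full likelihood differ by the monomorphic correction", {
  # on data with no monomorphic blocks, conditioned = full - sum n_k log(1 - P0)
  withr::local_seed(21)
  cfg <- sim_config("IM", model_params(theta = 1.5, T0 = 1, M = 0.5),
                    n_blocks = 2000, seed = 5)
  sd <- build_sdist(simulate_blocks(cfg), normalize_total = NULL)
  counts <- sd$count
  counts[1] <- 0
  sd0 <- new_sdist_from_counts(counts)
  p <- model_params(theta = 1.4, T0 = 0.9, M = 0.6)
  p0 <- pairdiv:::pmf_at("IM", p, max(sd0$k))[1]
  expect_equal(loglik("IM", p, sd0, conditioned = TRUE),
               loglik("IM", p, sd0) - sum(counts) * log(1 - p0),
               tolerance = 1e-9)
})

test_that("an observed class with zero probability yields -Inf, not an error", {
  sd1 <- new_sdist_from_counts(c(0, 1))
  expect_identical(loglik("SI", model_params(theta = 0, T0 = 2), sd1), -Inf)
})

test_that("fitting noise-free expected counts recovers the truth within 1%", {
  truth <- model_params(theta = 1.2, T0 = 0.8)
  sd <- sdist_from_pmf(pmf_si(truth), total = 1e5)
  fit <- fit_model("SI", sd, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$theta - truth$theta) / truth$theta, 0.01)
  expect_lt(abs(fit$params$T0 - truth$T0) / truth$T0, 0.01)

  truth_im <- model_params(theta = 1.5, T0 = 1, M = 0.5)
  sd_im <- sdist_from_pmf(pmf_im(truth_im), total = 1e5)
  fit_im <- fit_model("IM", sd_im, seed = 1)
  for (nm in c("theta", "T0", "M")) {
    expect_lt(abs(fit_im$params[[nm]] - truth_im[[nm]]) / truth_im[[nm]], 0.01)
  }
})

test_that("the fitted optimum matches a coarse grid scan", {
  withr::local_seed(31)
  cfg <- sim_config("IM", model_params(theta = 1.5, T0 = 1, M = 0.5),
                    n_blocks = 10000, seed = 13)
  sd <- build_sdist(simulate_blocks(cfg), normalize_total = NULL)
  grid <- expand.grid(theta = seq(0.8, 2.2, by = 0.1),
                      T0 = seq(0.4, 1.8, by = 0.1),
                      M = seq(0, 1.5, by = 0.1))
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    loglik("IM", model_params(theta = grid$theta[i], T0 = grid$T0[i],
                              M = grid$M[i]), sd)
  }, numeric(1))
  best_grid <- grid[which.max(ll), ]
  fit <- fit_model("IM", sd, seed = 2)
  # optimiser must do at least as well as the grid, with nearby estimates
  expect_gte(fit$lnL, max(ll) - 1e-6)
  expect_lt(abs(fit$params$theta - best_grid$theta), 0.11)
  expect_lt(abs(fit$params$T0 - best_grid$T0), 0.11)
  expect_lt(abs(fit$params$M - best_grid$M), 0.11)
})

test_that("fits are deterministic given the seed", {
  cfg <- sim_config("IM", model_params(theta = 1.5, T0 = 1, M = 0.5),
                    n_blocks = 3000, seed = 17)
  sd <- build_sdist(simulate_blocks(cfg), normalize_total = NULL)
  f1 <- fit_model("IM", sd, seed = 42)
  f2 <- fit_model("IM", sd, seed = 42)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$lnL, f2$lnL)
})

test_that("log-likelihoods respect the nesting hierarchy", {
  for (sim_seed in c(3, 19)) {
    cfg <- sim_config("IM", model_params(theta = 1.2, T0 = 0.8, M = 1),
                      n_blocks = 2000, seed = sim_seed)
    sd <- build_sdist(simulate_blocks(cfg), normalize_total = NULL)
    fits <- fit_all_models(sd, n_starts = 4, seed = 1)
    expect_gte(fits$IM$lnL, fits$SI$lnL - 1e-6)
    expect_gte(fits$IIM$lnL, fits$IM$lnL - 1e-6)
    expect_gte(fits$SC$lnL, fits$SI$lnL - 1e-6)
  }
})

test_that("near-panmictic data drives the migration estimate to its bound", {
  withr::local_seed(5)
  # very high true M: lineages effectively panmictic before T0
  cfg <- sim_config("IM", model_params(theta = 1, T0 = 2, M = 100),
                    n_blocks = 5000, seed = 23)
  sd <- build_sdist(simulate_blocks(cfg), normalize_total = NULL)
  fit <- fit_model("IM", sd, seed = 3)
  expect_true("M" %in% fit$at_boundary || fit$params$M >= 10 * (1 - 1e-3))
  expect_true(flag_nonidentifiable(fit))
})

test_that("identifiability flag follows the migration ceiling and boundaries", {
  fit <- structure(list(model = "IM",
                        params = model_params(theta = 1, T0 = 1, M = 10),
                        lnL = -10, converged = TRUE, n_starts = 8,
                        at_boundary = "M", conditioned = FALSE),
                   class = "div_fit")
  expect_true(flag_nonidentifiable(fit))
  fit$params <- model_params(theta = 1, T0 = 1, M = 0.3)
  fit$at_boundary <- character()
  expect_false(flag_nonidentifiable(fit))
})

test_that("LRT comparison clips at zero and uses chi-square thresholds", {
  mkfit <- function(lnL, model = "SI") {
    structure(list(model = model, params = model_params(1, 1), lnL = lnL,
                   converged = TRUE, n_starts = 1, at_boundary = character(),
                   conditioned = FALSE), class = "div_fit")
  }
  eq <- compare_lrt(mkfit(-100), mkfit(-100, "IM"), df = 1)
  expect_equal(eq$two_delta, 0)
  expect_false(eq$significant)
  expect_equal(round(select_thresholds()$df1, 3), 3.841)
  expect_equal(round(select_thresholds()$df2, 2), 5.99)
  cond <- mkfit(-90, "IM")
  cond$conditioned <- TRUE
  expect_error(compare_lrt(mkfit(-100), cond, df = 1), "conditioning")
})

test_that("hierarchical selection applies the decision-tree rules", {
  mkfits <- function(si, im, iim, sc) {
    mk <- function(lnL, model) {
      structure(list(model = model,
                     params = model_params(theta = 1, T0 = 1, M = 0.5, f = 0.2,
                                           T1 = 0.2),
                     lnL = lnL, converged = TRUE, n_starts = 1,
                     at_boundary = character(), conditioned = FALSE,
                     pair_id = "p"), class = "div_fit")
    }
    list(SI = mk(si, "SI"), IM = mk(im, "IM"), IIM = mk(iim, "IIM"),
         SC = mk(sc, "SC"))
  }
  # equal likelihoods: parsimony keeps SI
  expect_equal(select_best(mkfits(-100, -100, -100, -100))$best_model, "SI")
  # IM strongly better, SC barely better than IM: IM wins
  expect_equal(select_best(mkfits(-110, -100, -100, -99.9))$best_model, "IM")
  # SC beats IM by 2d = 6 > 3.841 and SI by > 5.99: SC wins
  expect_equal(select_best(mkfits(-110, -103, -103, -100))$best_model, "SC")
  # IIM justified over IM at 1 d.f. and better than SC: IIM wins
  expect_equal(select_best(mkfits(-110, -100, -97, -99))$best_model, "IIM")
  # ties exactly at the threshold resolve to the simpler model
  thr <- select_thresholds()
  expect_equal(select_best(mkfits(-100 - thr$df1 / 2, -100,
                                  -100, -100))$best_model, "SI")
  expect_error(select_best(list(SI = mkfits(-1, -1, -1, -1)$SI)), "must contain")
})

test_that("tidy and glance summarise fits in broom style", {
  sd <- sdist_from_pmf(pmf_si(model_params(theta = 1, T0 = 0.5)), total = 1e4)
  fit <- fit_model("SI", sd, seed = 1)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("theta", "T0"))
  expect_type(td$estimate, "double")
  gl <- generics::glance(fit)
  expect_equal(gl$model, "SI")
  expect_true(gl$converged)
})
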