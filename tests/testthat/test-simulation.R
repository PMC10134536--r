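test_that("the generator is deterministic and honours its design", {
  des <- sim_design(n = 20, p = 50, relation = "linear", seed = 5)
  s1 <- simulate_dataset(des, 2)
  s2 <- simulate_dataset(des, 2)
  expect_identical(s1, s2)
  s3 <- simulate_dataset(des, 3)
  expect_false(identical(s1$train$y, s3$train$y))

  # constant relation with c = 0: coefficients exactly zero, pure noise
  des0 <- sim_design(n = 15, p = 30, relation = "constant",
                     params = list(c = 0), seed = 1)
  s0 <- simulate_dataset(des0, 1)
  expect_identical(s0$beta0, rep(0, 30))

  expect_error(sim_design(relation = "linear", params = list(b = -1)),
               "non-negative")
  expect_error(sim_design(sparse_frac = 1), "sparse_frac")
})

test_that("true variance relations have their stated shapes", {
  z <- seq(0, 1, length.out = 11)
  dl <- sim_design(relation = "linear")
  expect_equal(true_variance(dl, z), 0.01 + 0.1 * z)
  dc <- sim_design(relation = "convex")
  expect_equal(true_variance(dc, z), 0.01 + 0.2 * z^2)
  dm <- sim_design(relation = "monotone_step")
  expect_equal(true_variance(dm, c(0.2, 0.8)), c(0.01, 0.1))
})

test_that("coefficient variance increases with the co-data under the linear relation", {
  des <- sim_design(n = 10, p = 5000, relation = "linear",
                    params = list(a = 0, b = 0.1), seed = 9)
  s <- simulate_dataset(des, 1)
  hi <- s$beta0[s$z > 0.9]
  lo <- s$beta0[s$z <= 0.1]
  expect_lt(var.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("empirical coefficient variances track the true relation per co-data bin", {
  des <- sim_design(n = 10, p = 8000, relation = "convex", seed = 13)
  s <- simulate_dataset(des, 1)
  bins <- cut(s$z, seq(0, 1, 0.2))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    mid <- mean(s$z[idx])
    v_emp <- var(s$beta0[idx])
    v_tr <- true_variance(des, mid)
    se <- v_tr * sqrt(2 / (length(idx) - 1))   # var-of-variance, normal
    expect_lt(abs(v_emp - v_tr), 3 * se + 0.1 * v_tr)
  }
})

test_that("random co-data is the permuted informative co-data", {
  des_i <- sim_design(n = 10, p = 200, relation = "linear", seed = 21)
  des_r <- sim_design(n = 10, p = 200, relation = "linear",
                      codata_kind = "random", seed = 21)
  si <- simulate_dataset(des_i, 1)
  sr <- simulate_dataset(des_r, 1)
  expect_identical(si$beta0, sr$beta0)
  expect_identical(sort(si$z), sort(sr$z))
  expect_false(identical(si$z, sr$z))
})

test_that("model comparison harness returns deterministic tables with curves", {
  des <- sim_design(n = 40, p = 80, relation = "linear", seed = 25,
                    n_replicates = 2)
  r1 <- run_codata_model_comparison(des, models = c("linear",
                                                    "agnostic_ridge"),
                                    grid_size = 11)
  r2 <- run_codata_model_comparison(des, models = c("linear",
                                                    "agnostic_ridge"),
                                    grid_size = 11)
  expect_identical(r1$metrics$metric, r2$metrics$metric)
  expect_equal(nrow(r1$metrics), 4L)
  expect_false(any(r1$metrics$failed))
  sm <- summarise_curves(r1$curves)
  expect_true(all(c("median", "q25", "q95") %in% names(sm)))
  expect_true(all(sm$q25 <= sm$median & sm$median <= sm$q75))
})

test_that("selection metrics have their boundary identities", {
  sp <- codapen:::sens_prec(c(1, 3), truth_nonzero = c(1, 2, 3))
  expect_equal(sp$sensitivity, 2 / 3)
  expect_equal(sp$precision, 1)
  exact <- codapen:::sens_prec(1:4, 1:4)
  expect_equal(exact$sensitivity, 1)
  expect_equal(exact$precision, 1)
  none <- codapen:::sens_prec(integer(0), 1:4)
  expect_true(is.na(none$precision))
  expect_error(run_selection_comparison(sim_design(sparse_frac = 0)),
               "sparse")
})

test_that("selection comparison runs at small scale and matches set sizes", {
  des <- sim_design(n = 60, p = 150, relation = "monotone_step",
                    sparse_frac = 0.8, seed = 33, n_replicates = 2)
  res <- suppressWarnings(
    run_selection_comparison(des, alpha = 0.5, n_replicates = 2,
                             n_splits = 3))
  expect_equal(nrow(res), 4L)
  a <- res[res$method == "adaptive_en", ]
  u <- res[res$method == "uniform_en", ]
  expect_true(all(abs(a$selected - u$selected) <=
                    pmax(3, 0.2 * a$selected)))
  expect_true(all(res$sensitivity >= 0 & res$sensitivity <= 1,
                  na.rm = TRUE))
})
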