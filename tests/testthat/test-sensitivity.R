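test_that("Latin hypercube samples occupy every stratum exactly once", {
  rng <- sensitivity_ranges()
  for (n in c(5L, 50L, 100L)) {
    s <- lhs_sample(rng, n, seed = 101)
    expect_identical(dim(s), c(n, 6L))
    for (j in seq_len(nrow(rng))) {
      x <- s[[rng$name[j]]]
      expect_true(all(x >= rng$min[j] & x <= rng$max[j]))
      expect_identical(stratum_counts(x, rng$min[j], rng$max[j], n),
                       rep(1L, n))
    }
  }
})

test_that("sampling is deterministic for a fixed seed", {
  rng <- sensitivity_ranges()
  expect_identical(lhs_sample(rng, 100, seed = 5),
                   lhs_sample(rng, 100, seed = 5))
  expect_false(identical(lhs_sample(rng, 100, seed = 5),
                         lhs_sample(rng, 100, seed = 6)))
})

test_that("a degenerate range collapses to its single value", {
  rng <- tibble::tibble(name = "k1", min = 0.004, max = 0.004)
  s <- lhs_sample(rng, 10, seed = 1)
  expect_equal(s$k1, rep(0.004, 10))
})

test_that("unknown range names are rejected with the valid list", {
  rng <- tibble::tibble(name = "theta", min = 0, max = 1)
  expect_error(lhs_sample(rng, 5), "Valid names")
  expect_error(lhs_sample(tibble::tibble(name = "k1", min = 1, max = 0), 5),
               "min.*max")
})

test_that("an empty variation collapses the envelope onto the baseline", {
  env <- sensitivity_envelope(ref$params, ref$schedule,
                              ranges = sensitivity_ranges()[0, ],
                              n_samples = 1, t_end = 50)
  base <- attr(env, "baseline")
  expect_equal(env$min, base)
  expect_equal(env$max, base)
  expect_equal(env$median, base)
})

test_that("envelope bands are ordered pointwise under joint PK variation", {
  rng <- dplyr::filter(sensitivity_ranges(), name %in% c("k1", "k2", "h"))
  env <- sensitivity_envelope(ref$params, ref$schedule, rng,
                              n_samples = 100, seed = 2, t_end = 500)
  expect_true(all(env$min <= env$q05))
  expect_true(all(env$q05 <= env$median))
  expect_true(all(env$median <= env$q95))
  expect_true(all(env$q95 <= env$max))
  expect_identical(attr(env, "n_failed"), 0L)
})

test_that("the max band widens with the sample size (order statistics)", {
  rng <- dplyr::filter(sensitivity_ranges(), name %in% c("k1", "k2", "h"))
  env_small <- sensitivity_envelope(ref$params, ref$schedule, rng,
                                    n_samples = 50, seed = 31, t_end = 500)
  env_big <- sensitivity_envelope(ref$params, ref$schedule, rng,
                                  n_samples = 200, seed = 32, t_end = 500)
  frac <- mean(env_big$max[-1] >= env_small$max[-1])
  expect_gte(frac, 0.95)
})

test_that("concentration ranking puts every PK parameter above the decoupled ones", {
  rk <- rank_parameters(ref$params, ref$schedule, sensitivity_ranges(),
                        n_samples = 100, seed = 13)
  scores <- setNames(rk$score, rk$parameter)
  expect_gt(min(scores[c("k1", "k2", "h")]),
            max(scores[c("hill_k", "A", "B")]))
  # c(t) does not depend on A, B or the Hill exponent at all
  expect_lt(max(abs(scores[c("hill_k", "A", "B")])), 1e-9)
  expect_identical(rk$rank, 1:6)
})

test_that("a degenerate range scores zero and the k1 score is Monte-Carlo stable", {
  rng0 <- tibble::tibble(name = "k1", min = 0.005, max = 0.005)
  rk0 <- rank_parameters(ref$params, ref$schedule, rng0, n_samples = 10,
                         t_end = 100)
  expect_identical(rk0$score, 0)
  rng <- dplyr::filter(sensitivity_ranges(), name == "k1")
  s100 <- rank_parameters(ref$params, ref$schedule, rng, n_samples = 100,
                          seed = 41)$score
  s200 <- rank_parameters(ref$params, ref$schedule, rng, n_samples = 200,
                          seed = 42)$score
  expect_lt(abs(s200 - s100) / s100, 0.2)
})

test_that("cell-count and objective outputs do feel the tumor parameters", {
  rng <- dplyr::filter(sensitivity_ranges(), name == "A")
  rk_n <- rank_parameters(ref$params, ref$schedule, rng, n_samples = 20,
                          seed = 9, t_end = 200, output = "N")
  expect_gt(rk_n$score, 0)
  rk_j <- rank_parameters(ref$params, ref$schedule, rng, n_samples = 20,
                          seed = 9, t_end = 200, output = "J")
  expect_gt(rk_j$score, 0)
})

test_that("failed draws are excluded and counted rather than fatal", {
  # strongly negative k2 draws blow up; mildly negative ones survive
  rng <- tibble::tibble(name = "k2", min = -0.02, max = 0)
  env <- NULL
  msgs <- capture_warnings(
    env <- sensitivity_envelope(ref$params, ref$schedule, rng,
                                n_samples = 5, seed = 3, t_end = 500))
  expect_true(any(grepl("excluded", msgs)))
  expect_gt(attr(env, "n_failed"), 0)
  expect_lt(attr(env, "n_failed"), 5)
  expect_true(all(is.finite(env$max)))
})

test_that("envelope and score tables export with their documented headers", {
  rng <- dplyr::filter(sensitivity_ranges(), name == "h")
  env <- sensitivity_envelope(ref$params, ref$schedule, rng,
                              n_samples = 10, t_end = 50)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_envelope(env, p1)
  expect_identical(readLines(p1, n = 1), "time,min,q05,mean,median,q95,max")
  rk <- rank_parameters(ref$params, ref$schedule, rng, n_samples = 10,
                        t_end = 50)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_scores(rk, p2)
  expect_identical(readLines(p2, n = 1), "parameter,score,rank")
})
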