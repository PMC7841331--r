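test_that("effect function reproduces hand-computed values", {
  pd <- pd_params(e0 = 0, emax = 100, ec50 = 15)
  expect_identical(drug_effect(0, pd), 0)
  expect_identical(drug_effect(15, pd), 50)
  expect_identical(drug_effect(15, pd_params(0, 100, 15, 3L), "sigmoid"), 50)
  expect_equal(drug_effect(30, pd), 100 * 30 / 45)
  # baseline shifts the whole curve
  expect_equal(drug_effect(0, pd_params(e0 = 5, emax = 100, ec50 = 15)), 5)
  expect_error(drug_effect(-1, pd), "non-negative")
})

test_that("effect is monotone and bounded for varied parameter draws", {
  set.seed(42)
  grid <- seq(0, 200, length.out = 400)
  for (i in 1:20) {
    pd <- pd_params(e0 = runif(1, 0, 10), emax = runif(1, 1, 200),
                    ec50 = runif(1, 0.5, 50), hill_k = sample(1:5, 1))
    for (model in c("emax", "sigmoid")) {
      s <- drug_effect(grid, pd, model)
      expect_true(all(diff(s) >= 0))
      expect_true(all(s >= pd$e0 & s < pd$e0 + pd$emax))
    }
  }
})

test_that("sigmoid with unit Hill exponent equals the hyperbolic model exactly", {
  grid <- seq(0, 100, length.out = 1000)
  pd <- pd_params(e0 = 0, emax = 100, ec50 = 15, hill_k = 1L)
  expect_identical(drug_effect(grid, pd, "sigmoid"),
                   drug_effect(grid, pd, "emax"))
})

test_that("PK right-hand side matches closed-form evaluations", {
  pk <- pk_params(0.005, 0.0004, 0.001)
  expect_identical(pk_rate(0, 0, pk), 0)
  # fixed point c_ss = h u / (k1 + k2 u)
  expect_equal(pk_rate(0.01 / 0.009, 10, pk), 0)
  expect_equal(pk_rate(1, 10, pk_params(0.005, -0.0004, 0.001)), 0.009)
})

test_that("PK right-hand side is affine in dose and in concentration", {
  pk <- pk_params(0.007, 0.002, 0.003)
  for (cc in c(0, 0.5, 2)) {
    u <- c(0, 1, 2, 5)
    r <- pk_rate(cc, u, pk)
    slopes <- diff(r) / diff(u)
    expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
  }
  for (u in c(0, 3, 10)) {
    cs <- c(0, 1, 2, 4)
    r <- pk_rate(cs, u, pk)
    slopes <- diff(r) / diff(cs)
    expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
  }
})

test_that("tumor right-hand side applies the bilinear coupling", {
  tum <- tumor_params(matrix(0.001), matrix(0.001))
  expect_equal(tumor_rate(1, 0, tum), 0.001)
  expect_equal(tumor_rate(1, 50, tum), 0.051)
  tum2 <- tumor_params(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(tumor_rate(c(3, 7), 0, tum2), c(0, 0))
  expect_error(tumor_rate(c(1, 2), 0, tum), "length")
})

test_that("tumor right-hand side is linear in the cell-count vector", {
  set.seed(7)
  a <- matrix(rnorm(9, sd = 0.01), 3)
  b <- matrix(rnorm(9, sd = 0.01), 3)
  tum <- tumor_params(a, b)
  for (s in c(0, 12.5, 80)) {
    x <- runif(3); y <- runif(3)
    expect_equal(tumor_rate(2 * x + 3 * y, s, tum),
                 2 * tumor_rate(x, s, tum) + 3 * tumor_rate(y, s, tum))
  }
})

test_that("constructors enforce the domain invariants", {
  expect_error(pd_params(ec50 = 0), "positive")
  expect_error(pd_params(hill_k = 0.5), "integer")
  expect_error(pk_params(k1 = 0), "positive")
  expect_no_error(pk_params(k2 = -1))  # k2 sign is unrestricted
  expect_error(tumor_params(matrix(1, 2, 3), matrix(1, 2, 3)), "square")
  expect_error(tumor_params(matrix(1), matrix(1, 2, 2)), "identical")
  expect_error(model_params(tumor_params(matrix(1), matrix(1)),
                            pk_params(), pd_params(), n0 = c(1, 2)),
               "compartment")
  expect_error(model_params(tumor_params(matrix(1), matrix(1)),
                            pk_params(), pd_params(), n0 = 0),
               "positive")
  expect_error(objective_weights(p = -1), "non-negative")
  expect_error(objective_weights(p = 0, q = 0, b = 0), "zero")
})

test_that("dose schedules evaluate their parametric forms and reject negatives", {
  cosine <- dose_schedule("cosine", amplitude = 10, frequency = 0.1,
                          offset = 10)
  expect_equal(eval_dose(cosine, 0), 20)
  expect_equal(eval_dose(cosine, pi / 0.1), 0)
  const <- dose_schedule("constant", level = 3)
  expect_equal(eval_dose(const, c(0, 50)), c(3, 3))
  pw <- dose_schedule("piecewise_constant", breakpoints = c(10, 20),
                      levels = c(1, 5, 0))
  expect_equal(eval_dose(pw, c(0, 10, 15, 25)), c(1, 5, 5, 0))
  expect_error(dose_schedule("constant", level = -1), "non-negative")
  expect_error(dose_schedule("cosine", amplitude = 1, frequency = 0,
                             offset = 1), "positive")
  expect_error(dose_schedule("piecewise_constant", breakpoints = c(2, 1),
                             levels = c(1, 1, 1)), "increasing")
})

test_that("parameter bundles round-trip exactly through JSON", {
  params <- one_comp_params(k1 = 1 / 3, k2 = -0.07, hill_k = 4L,
                            effect_model = "sigmoid")
  json <- params_to_json(params, ref$schedule, ref$weights)
  back <- params_from_json(json)
  expect_identical(back$params, params)
  expect_identical(back$schedule, ref$schedule)
  expect_identical(back$weights, ref$weights)
  # and via a file, including a multi-compartment bundle
  p2 <- model_params(tumor_params(matrix(c(0.01, 0.2, 1 / 7, 0), 2),
                                  diag(2) * -0.5),
                     pk_params(), pd_params(), n0 = c(2, exp(1)))
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p2, path = path)
  expect_identical(params_from_json(path)$params, p2)
})
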