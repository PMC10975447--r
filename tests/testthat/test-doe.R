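# Design construction, response-surface regression, model reduction and
# correlation analysis on the packaged 24-run study.

test_that("factor coding maps the study levels correctly", {
  expect_equal(code_factor(1100, 725, 375), 1)
  expect_equal(code_factor(350, 725, 375), -1)
  expect_equal(code_factor(0.6, 2, 1), -1.4)
  expect_equal(code_factor(194.7, 725, 375), -1.4141, tolerance = 1e-4)
  expect_error(code_factor(1, 0, 0), "nonzero")
})

test_that("the constructed CCD is balanced and matches the study layout", {
  d <- build_ccd()
  expect_identical(nrow(d), 24L)
  expect_identical(as.integer(table(d$x4)), c(12L, 12L))
  for (col in c("x1", "x2", "x3", "x4")) {
    expect_equal(sum(d[[col]]), 0)
  }
  # the categorical factor is orthogonal to every other model column
  X <- cbind(d$x1, d$x2, d$x3, d$x1 * d$x2, d$x1 * d$x3, d$x2 * d$x3,
             d$x1^2, d$x2^2, d$x3^2, 1)
  expect_equal(unname(as.numeric(crossprod(X, d$x4))), rep(0, 10))
  # actual axial particle sizes round to the study's printed levels
  expect_equal(sort(unique(round(d$particle_size, 1))),
               c(194.7, 350, 725, 1100, 1255.3))
  expect_error(build_ccd(axial = 0.9), "exceed 1")
})

test_that("packaged tables load, validate and agree internally", {
  d <- study_data()
  expect_identical(nrow(d), 24L)
  expect_true(all(c("x1", "x2", "x3", "x4", "saor_deg", "ft_s",
                    "amplitude_px", "wavelength_frames", "count",
                    "a", "b", "c", "a_plus_b", "aufc") %in% names(d)))
  # Table-consistency: the a_plus_b column restates a + b (to rounding)
  expect_lte(max(abs(d$a + d$b - d$a_plus_b)), 0.011)
  expect_identical(as.integer(table(d$x4)), c(12L, 12L))
  # coded design columns come from the published actual levels
  expect_equal(sort(unique(d$x1)), c(-1.41413333333333, -1, 0, 1,
                                     1.41413333333333), tolerance = 1e-10)
  expect_error(read_response_table("saor_ft",
                                   path = flowcone_example(
                                     "table1_design.csv")),
               "columns")
})

test_that("response-surface fits reproduce the reported study slopes", {
  d <- study_data()
  saor <- fit_response_surface(d, d$saor_deg, form = "2FI")
  expect_equal(unname(coef(saor)["x4"]), -2.46, tolerance = 0.005)
  aufc <- fit_response_surface(d, d$aufc, terms = c("x1", "x4", "I(x1^2)"))
  expect_equal(unname(coef(aufc)["x4"]), 805.76, tolerance = 1e-5)
  # noiseless synthetic response: exact recovery
  truth <- c("(Intercept)" = 34.41, x1 = 1.45, x4 = -2.46, "x3:x4" = -0.91)
  y <- simulate_design_responses(d, truth)
  fit <- fit_response_surface(d, y, terms = names(truth)[-1])
  expect_equal(coef(fit)[names(truth)], truth, tolerance = 1e-10)
})

test_that("the x4 slope equals half the pellet-granule mean difference", {
  d <- study_data()
  responses <- c("saor_deg", "ft_s", "amplitude_px", "wavelength_frames",
                 "count", "a", "b", "c", "a_plus_b", "aufc")
  for (resp in responses) {
    y <- d[[resp]]
    oracle <- (mean(y[d$x4 == 1]) - mean(y[d$x4 == -1])) / 2
    for (form in c("linear", "2FI", "quadratic")) {
      fit <- fit_response_surface(d, y, form = form)
      expect_equal(unname(coef(fit)["x4"]), oracle, tolerance = 1e-10)
    }
  }
})

test_that("model statistics match the reference linear-model machinery", {
  d <- study_data()
  fit <- fit_response_surface(d, d$ft_s, form = "quadratic")
  ref <- lm(ft_s ~ x1 + x2 + x3 + x4 + x1:x2 + x1:x3 + x1:x4 + x2:x3 +
              x2:x4 + x3:x4 + I(x1^2) + I(x2^2) + I(x3^2), data = d)
  sref <- summary(ref)
  expect_equal(unname(coef(fit)[c("x1", "x4", "I(x1^2)")]),
               unname(coef(ref)[c("x1", "x4", "I(x1^2)")]),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, sref$r.squared, tolerance = 1e-10)
  expect_equal(fit$coefficients["x4", "Pr(>|t|)"],
               sref$coefficients["x4", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(fit$f_pvalue,
               unname(pf(sref$fstatistic[1], sref$fstatistic[2],
                         sref$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-10)
  # PRESS against an explicit leave-one-out loop
  loo <- vapply(1:24, function(i) {
    m <- lm(ft_s ~ x1 + x2 + x3 + x4, data = d[-i, ])
    d$ft_s[i] - predict(m, newdata = d[i, ])
  }, numeric(1))
  lin <- fit_response_surface(d, d$ft_s, form = "linear")
  expect_equal(lin$press, sum(loo^2), tolerance = 1e-10)
})

test_that("predicted R-squared can go negative where the mean wins", {
  d <- study_data()
  m_a <- fit_response_surface(d, d$a, form = "quadratic")
  expect_lt(m_a$pred_r_squared, 0)
  expect_lte(m_a$pred_r_squared, m_a$r_squared)
})

test_that("hierarchical reduction keeps only the sphericity factor", {
  d <- study_data()
  wav <- reduce_model(fit_response_surface(d, d$wavelength_frames,
                                           form = "linear"))
  expect_identical(wav$terms, "x4")
  expect_equal(unname(coef(wav)["x4"]), -1.82, tolerance = 0.005)
  cnt <- reduce_model(fit_response_surface(d, d$count, form = "linear"))
  expect_identical(cnt$terms, "x4")
  expect_equal(unname(coef(cnt)["x4"]), 2.71, tolerance = 0.005)
  # a model whose terms are all significant is left unchanged
  y <- simulate_design_responses(d, c("(Intercept)" = 1, x1 = 5, x4 = -5),
                                 sigma = 0.2, seed = 12)
  m <- fit_response_surface(d, y, terms = c("x1", "x4"))
  expect_identical(reduce_model(m)$terms, m$terms)
})

test_that("reduction preserves hierarchy under interactions", {
  d <- study_data()
  # x1 main effect is null but its interaction is strong: x1 must stay
  y <- simulate_design_responses(d, c("(Intercept)" = 0, "x1:x4" = 4,
                                      x1 = 0.001, x4 = 0.001),
                                 sigma = 0.3, seed = 77)
  red <- reduce_model(fit_response_surface(d, y, form = "2FI"))
  expect_true(all(c("x1", "x4", "x1:x4") %in% red$terms))
})

test_that("rank-deficient models fail loudly naming the aliased term", {
  d <- study_data()
  # factorial + center runs only: there the half-fraction's defining
  # relation x1:x2 = -x3 makes the interaction a perfect alias
  sub <- d[d$x1 %in% c(-1, 0, 1) & abs(d$x2) != 1.4 & abs(d$x3) != 1.4, ]
  expect_error(fit_response_surface(sub, sub$saor_deg,
                                    terms = c("x1", "x2", "x3", "x1:x2")),
               "aliased.*x1:x2")
})

test_that("the correlation matrix matches direct computation", {
  d <- study_data()
  vars <- c("a", "b", "c", "aufc", "a_plus_b", "wavelength_frames",
            "amplitude_px", "count", "saor_deg", "ft_s")
  cm <- pearson_matrix(d[, vars])
  expect_identical(cm$n, 24L)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 10))
  expect_true(all(abs(cm$r) <= 1))
  expect_equal(cm$r, cor(as.matrix(d[, vars])), tolerance = 1e-12)
  # p-values against cor.test
  ct <- cor.test(d$b, d$c)
  expect_equal(cm$r["b", "c"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["b", "c"], ct$p.value, tolerance = 1e-10)
  # the study's strongest reported pairing
  expect_equal(cm$r["b", "c"], -0.970, tolerance = 0.005)
  expect_error(pearson_matrix(d[1:2, vars]), "3 complete rows")
  d$flat <- 1
  expect_warning(cz <- pearson_matrix(d[, c("a", "b", "flat")]),
                 "zero-variance")
  expect_true(is.na(cz$r["a", "flat"]))
})
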