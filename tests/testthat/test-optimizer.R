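small_ctl <- function(...) clgbo_control(pop_size = 20L, max_iter = 100L, ...)

test_that("the optimizer solves a low-dimensional convex bowl easily", {
  fit <- clgbo("sphere", lower = rep(-100, 2), upper = rep(100, 2),
               control = small_ctl(), seed = 31)
  expect_lt(fit$value, 1e-6)
  expect_length(fit$best, 2L)
  expect_true(all(fit$best >= -100 & fit$best <= 100))
})

test_that("convergence curves are monotone non-increasing with final = best", {
  for (s in c(32, 33, 34)) {
    fit <- clgbo("rastrigin", rep(-5.12, 10), rep(5.12, 10),
                 control = small_ctl(), seed = s)
    expect_true(all(diff(fit$curve) <= 0))
    expect_identical(fit$curve[length(fit$curve)], fit$value)
  }
})

test_that("runs are bit-identical under a fixed seed", {
  a <- clgbo("ackley", rep(-32, 5), rep(32, 5), control = small_ctl(), seed = 35)
  b <- clgbo("ackley", rep(-32, 5), rep(32, 5), control = small_ctl(), seed = 35)
  expect_identical(a$best, b$best)
  expect_identical(a$curve, b$curve)
  expect_identical(a$evaluations, b$evaluations)
})

test_that("pr = 0 never enters the local escape operator", {
  fit <- clgbo("sphere", rep(-10, 4), rep(10, 4),
               control = small_ctl(pr = 0), seed = 36)
  expect_identical(fit$leo_entries, 0)
  fit2 <- clgbo("sphere", rep(-10, 4), rep(10, 4),
                control = small_ctl(pr = 1), seed = 36)
  expect_identical(fit2$leo_entries, fit2$iterations * 20)
})

test_that("arbitrary R objectives are supported and non-finite values abort", {
  fit <- clgbo(function(x) sum((x - 3)^2), lower = 0, upper = rep(10, 3),
               control = small_ctl(), seed = 37)
  expect_lt(fit$value, 1e-4)
  expect_equal(fit$best, rep(3, 3), tolerance = 1e-2)
  expect_error(
    clgbo(function(x) NaN, lower = -1, upper = 1,
          control = clgbo_control(pop_size = 5, max_iter = 5), seed = 1),
    "non-finite.*position")
})

test_that("both mutations together do not hurt the sphere average at equal budget", {
  vals <- sapply(1:10, function(s) {
    both <- clgbo("sphere", rep(-100, 10), rep(100, 10),
                  control = small_ctl(mutation = "both"), seed = 1000 + s)$value
    none <- clgbo("sphere", rep(-100, 10), rep(100, 10),
                  control = small_ctl(mutation = "none"), seed = 1000 + s)$value
    c(both = both, none = none)
  })
  expect_lte(mean(vals["both", ]), mean(vals["none", ]))
})

test_that("early stopping truncates the run once the target is reached", {
  fit <- clgbo("sphere", rep(-100, 5), rep(100, 5),
               control = small_ctl(stop_at = 1e-3), seed = 38)
  expect_lte(fit$value, 1e-3)
  expect_lt(fit$iterations, 100)
})

test_that("control validation rejects out-of-range settings", {
  expect_error(clgbo_control(pop_size = 1), "pop_size")
  expect_error(clgbo_control(max_iter = 0), "max_iter")
  expect_error(clgbo_control(levy_beta = 3), "levy_beta")
})

test_that("clgbo objects expose coef/print/plot methods", {
  fit <- clgbo("sphere", rep(-5, 3), rep(5, 3), control = small_ctl(), seed = 39)
  expect_identical(coef(fit), fit$best)
  expect_output(print(fit), "best fitness")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
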