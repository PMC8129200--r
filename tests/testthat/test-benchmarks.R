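test_that("every benchmark reproduces its known minimum at the optimizer", {
  suite <- benchmark_suite()
  expect_identical(nrow(suite), 14L)
  expect_identical(sum(suite$kind == "unimodal"), 6L)
  origin_min <- c("sphere", "schwefel222", "schwefel12", "schwefel221",
                  "step", "rastrigin", "griewank", "schaffer", "sumpowers")
  for (nm in origin_min) {
    b <- benchmark_function(nm)
    expect_equal(benchmark_evaluate(nm, rep(0, b$dim)), 0, info = nm)
  }
  expect_equal(benchmark_evaluate("rosenbrock", rep(1, 30)), 0)
  expect_equal(benchmark_evaluate("penalized1", rep(-1, 30)), 0, tolerance = 1e-30)
  expect_equal(benchmark_evaluate("penalized2", rep(1, 30)), 0, tolerance = 1e-30)
  # Ackley's origin value is the floating-point floor, not exactly zero
  f0 <- benchmark_evaluate("ackley", rep(0, 30))
  expect_gte(f0, 0)
  expect_lte(f0, 8.9e-16)
  # Kowalik's known optimum (fixed dimension 4)
  f9 <- benchmark_evaluate("kowalik", c(0.1928, 0.1908, 0.1231, 0.1358))
  expect_lt(f9, 3.2e-4)
})

test_that("R reference and compiled implementations agree on random points", {
  set.seed(41)
  for (id in 1:14) {
    b <- benchmark_function(id)
    for (rep in 1:10) {
      x <- runif(b$dim, b$lower, b$upper)
      expect_equal(benchmark_evaluate(id, x, engine = "r"),
                   benchmark_evaluate(id, x, engine = "cpp"),
                   tolerance = 1e-12, info = b$name)
    }
  }
})

test_that("fixed-dimension functions reject other dimensions", {
  expect_error(benchmark_evaluate("kowalik", rep(0, 5)), "dimension")
  expect_error(benchmark_evaluate("schaffer", rep(0, 3)), "dimension")
})

test_that("run_experiment statistics behave at the edges", {
  ctl <- clgbo_control(pop_size = 10, max_iter = 20)
  one <- run_experiment("sphere", control = ctl, repeats = 1, seed = 42, dim = 5)
  expect_identical(one$best, one$avg)
  expect_identical(one$sd, 0)
  few <- run_experiment("sphere", control = ctl, repeats = 4, seed = 42, dim = 5)
  vals <- attr(few, "values")
  expect_lte(few$best, few$avg)
  expect_equal(few$sd, sd(vals))
  # regeneration with the same master seed is bit-identical
  again <- run_experiment("sphere", control = ctl, repeats = 4, seed = 42, dim = 5)
  expect_identical(vals, attr(again, "values"))
})

test_that("benchmark_table compares variants under shared conditions", {
  ctl <- clgbo_control(pop_size = 10, max_iter = 20)
  tab <- benchmark_table("sphere", mutations = c("both", "none"),
                         control = ctl, repeats = 2, seed = 43)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$mutation, c("both", "none"))
})

test_that("rank-sum comparison handles separation, symmetry and degeneracy", {
  # complete separation at n = 3: exact two-sided p = 2/choose(6,3) = 0.1
  p <- rank_sum_compare(c(1, 2, 3), c(101, 102, 103))
  expect_equal(p, 0.1)
  expect_lt(p, 0.2)
  expect_equal(rank_sum_compare(c(101, 102, 103), c(1, 2, 3)), p)
  # all-identical pooled values are not comparable
  expect_true(is.na(rank_sum_compare(rep(0, 5), rep(0, 5))))
})
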