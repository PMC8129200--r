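# Benchmark function harness: 6 unimodal (F1-F6) + 8 multimodal (F7-F14)
# classical test functions, repeated-run statistics, and rank-sum comparison.

.BENCHMARKS <- list(
  list(id = 1L,  name = "sphere",       kind = "unimodal",   dim = 30L, lower = -100,  upper = 100,  fmin = 0),
  list(id = 2L,  name = "schwefel222",  kind = "unimodal",   dim = 30L, lower = -10,   upper = 10,   fmin = 0),
  list(id = 3L,  name = "schwefel12",   kind = "unimodal",   dim = 30L, lower = -100,  upper = 100,  fmin = 0),
  list(id = 4L,  name = "rosenbrock",   kind = "unimodal",   dim = 30L, lower = -30,   upper = 30,   fmin = 0),
  list(id = 5L,  name = "schwefel221",  kind = "unimodal",   dim = 30L, lower = -100,  upper = 100,  fmin = 0),
  list(id = 6L,  name = "step",         kind = "unimodal",   dim = 30L, lower = -100,  upper = 100,  fmin = 0),
  list(id = 7L,  name = "rastrigin",    kind = "multimodal", dim = 30L, lower = -5.12, upper = 5.12, fmin = 0),
  list(id = 8L,  name = "griewank",     kind = "multimodal", dim = 30L, lower = -600,  upper = 600,  fmin = 0),
  list(id = 9L,  name = "kowalik",      kind = "multimodal", dim = 4L,  lower = -5,    upper = 5,    fmin = 3.0748e-4),
  list(id = 10L, name = "ackley",       kind = "multimodal", dim = 30L, lower = -32,   upper = 32,   fmin = 0),
  list(id = 11L, name = "penalized1",   kind = "multimodal", dim = 30L, lower = -50,   upper = 50,   fmin = 0),
  list(id = 12L, name = "penalized2",   kind = "multimodal", dim = 30L, lower = -50,   upper = 50,   fmin = 0),
  list(id = 13L, name = "schaffer",     kind = "multimodal", dim = 2L,  lower = -100,  upper = 100,  fmin = 0),
  list(id = 14L, name = "sumpowers",    kind = "multimodal", dim = 30L, lower = -1,    upper = 1,    fmin = 0)
)

#' The benchmark function suite
#'
#' Fourteen classical continuous test functions used to evaluate the
#' optimizer: six unimodal (sphere, Schwefel 2.22, Schwefel 1.2, Rosenbrock,
#' Schwefel 2.21, Step) probing exploitation, and eight multimodal
#' (Rastrigin, Griewank, Kowalik, Ackley, two penalized functions, Schaffer,
#' sum of increasing powers) probing exploration. All are minimization
#' problems; `fmin` is the known global minimum value.
#'
#' @return A data frame with columns `id`, `name`, `kind`, `dim`, `lower`,
#'   `upper`, `fmin`.
#' @export
benchmark_suite <- function() {
  do.call(rbind, lapply(.BENCHMARKS, function(b)
    data.frame(b, stringsAsFactors = FALSE)))
}

benchmark_id <- function(f) {
  if (is.numeric(f)) {
    id <- as.integer(f)
  } else {
    id <- match(f, vapply(.BENCHMARKS, `[[`, "", "name"))
  }
  if (is.na(id) || id < 1L || id > length(.BENCHMARKS))
    stop("unknown benchmark function: ", f, call. = FALSE)
  id
}

#' Look up a benchmark function descriptor
#'
#' @param f Benchmark id (1-14) or name (e.g. `"ackley"`).
#' @return A list with fields `id`, `name`, `kind`, `dim`, `lower`, `upper`,
#'   `fmin`, and `fn` (the R closure evaluating the function).
#' @export
benchmark_function <- function(f) {
  b <- .BENCHMARKS[[benchmark_id(f)]]
  b$fn <- function(x) benchmark_evaluate(b$id, x)
  b
}

# R reference implementations; the C++ twins drive the optimizer hot loop and
# are tested for agreement with these.
.bench_r <- list(
  function(x) sum(x^2),
  function(x) sum(abs(x)) + prod(abs(x)),
  function(x) sum(cumsum(x)^2),
  function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 + (x[-length(x)] - 1)^2),
  function(x) max(abs(x)),
  function(x) sum(floor(x + 0.5)^2),
  function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
  function(x) sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1,
  function(x) {
    a <- c(0.1957, 0.1947, 0.1735, 0.16, 0.0844, 0.0627, 0.0456, 0.0342,
           0.0323, 0.0235, 0.0246)
    b <- c(4, 2, 1, 0.5, 0.25, 1/6, 0.125, 0.1, 1/12, 1/14, 0.0625)
    sum((a - x[1] * (b^2 + b * x[2]) / (b^2 + b * x[3] + x[4]))^2)
  },
  function(x) {
    d <- length(x)
    -20 * exp(-0.2 * sqrt(sum(x^2) / d)) - exp(sum(cos(2 * pi * x)) / d) +
      20 + exp(1)
  },
  function(x) {
    d <- length(x)
    y <- 1 + (x + 1) / 4
    u <- .bench_u(x, 10)
    pi / d * (10 * sin(pi * y[1])^2 +
                sum((y[-d] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                (y[d] - 1)^2) + sum(u)
  },
  function(x) {
    d <- length(x)
    u <- .bench_u(x, 5)
    0.1 * (sin(3 * pi * x[1])^2 +
             sum((x[-d] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
             (x[d] - 1)^2 * (1 + sin(2 * pi * x[d])^2)) + sum(u)
  },
  function(x) {
    r2 <- sum(x[1:2]^2)
    0.5 + (sin(sqrt(r2))^2 - 0.5) / (1 + 0.001 * r2)^2
  },
  function(x) sum(abs(x)^(seq_along(x) + 1))
)

.bench_u <- function(x, a, k = 100, m = 4) {
  ifelse(x > a, k * (x - a)^m, ifelse(x < -a, k * (-x - a)^m, 0))
}

#' Evaluate a benchmark function
#'
#' @param f Benchmark id or name.
#' @param x Numeric vector of the function's dimension.
#' @param engine `"r"` (reference implementation) or `"cpp"` (the compiled
#'   twin used inside the optimizer).
#' @return Scalar function value.
#' @export
benchmark_evaluate <- function(f, x, engine = c("r", "cpp")) {
  engine <- match.arg(engine)
  id <- benchmark_id(f)
  b <- .BENCHMARKS[[id]]
  if (length(x) != b$dim && b$dim %in% c(2L, 4L))
    stop(sprintf("%s is fixed at dimension %d (got %d)", b$name, b$dim,
                 length(x)), call. = FALSE)
  if (engine == "r") .bench_r[[id]](as.numeric(x))
  else .bench_eval_cpp(id, as.numeric(x))
}

#' Repeated-run statistics for an optimizer variant on a benchmark function
#'
#' Runs the optimizer `repeats` times with distinct seeds derived from
#' `seed` and reports the best, average and sample standard deviation
#' (divisor `repeats - 1`) of the final best-fitness values, mirroring the
#' usual 30-repeat evaluation protocol.
#'
#' @param f Benchmark id or name.
#' @param control A [clgbo_control()]; set `mutation` to compare CLGBO
#'   (`"both"`), CGBO, LGBO and plain GBO.
#' @param repeats Number of independent runs (default 30).
#' @param seed Master seed from which per-run seeds are drawn.
#' @param dim Optional dimension override for scalable functions.
#' @return A data frame row with columns `function`, `mutation`, `repeats`,
#'   `best`, `avg`, `sd`, plus the vector of final values in attribute
#'   `"values"`.
#' @export
run_experiment <- function(f, control = clgbo_control(), repeats = 30L,
                           seed = NULL, dim = NULL) {
  b <- .BENCHMARKS[[benchmark_id(f)]]
  d <- if (is.null(dim)) b$dim else as.integer(dim)
  repeats <- as.integer(repeats)
  stopifnot(repeats >= 1L)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  vals <- vapply(run_seeds, function(s) {
    clgbo(b$name, lower = rep(b$lower, d), upper = rep(b$upper, d),
          control = control, seed = s)$value
  }, numeric(1))
  out <- data.frame(
    `function` = b$name, mutation = control$mutation, repeats = repeats,
    best = min(vals), avg = mean(vals),
    sd = if (repeats > 1L) sd(vals) else 0,
    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "values") <- vals
  out
}

#' Benchmark table across functions and optimizer variants
#'
#' @param functions Vector of benchmark ids or names.
#' @param mutations Character vector of mutation modes to compare.
#' @param control Base [clgbo_control()] (its `mutation` entry is overridden
#'   per variant).
#' @param repeats,seed Passed to [run_experiment()]; the same master seed is
#'   reused per (function, variant) cell so comparisons share conditions.
#' @return A data frame with one row per (function, variant).
#' @export
benchmark_table <- function(functions = benchmark_suite()$name,
                            mutations = c("both", "none"),
                            control = clgbo_control(), repeats = 30L,
                            seed = NULL) {
  rows <- list()
  for (f in functions) {
    for (m in mutations) {
      ctl <- control
      ctl$mutation <- m
      rows[[length(rows) + 1L]] <-
        run_experiment(f, control = ctl, repeats = repeats, seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Two-sided Wilcoxon rank-sum comparison of two result samples
#'
#' Delegates to [stats::wilcox.test()]. When the pooled sample is constant
#' the statistic is undefined; `NA` is returned for that degenerate case
#' (reported as "N/A" in tabulated output).
#'
#' @param a,b Numeric vectors of final fitness values from two algorithms.
#' @return The two-sided p-value, or `NA` if the pooled values are all equal.
#' @export
rank_sum_compare <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(NA_real_)
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
}
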