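#' Standard Cauchy deviate from a uniform draw
#'
#' Inverse-CDF transform `gamma = tan(pi * (u - 1/2))` of the standard Cauchy
#' distribution (median 0, heavy tails). This is the random number behind the
#' Cauchy mutation operator: its heavy tails let an agent occasionally jump
#' far from its current position, which combats premature convergence.
#'
#' @param u Numeric vector of values strictly inside (0, 1).
#' @return Numeric vector of Cauchy deviates.
#' @examples
#' cauchy_random(0.5)   # 0
#' cauchy_random(0.75)  # 1
#' @export
cauchy_random <- function(u) {
  if (any(u <= 0 | u >= 1))
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  tan(pi * (u - 0.5))
}

#' Cauchy mutation of a position vector
#'
#' Multiplicative perturbation `x_new = x + x * C` with `C` standard Cauchy.
#' The origin is a fixed point: coordinates that are exactly zero stay zero,
#' which is what lets runs on benchmark functions with the optimum at the
#' origin underflow all the way to an exact 0 objective.
#'
#' @param x Numeric position vector.
#' @param u Uniform draws in (0, 1), one per coordinate (default freshly
#'   drawn). Supply explicitly for reproducible single steps.
#' @param lower,upper Optional box bounds; the candidate is clamped.
#' @return Mutated position vector.
#' @export
cauchy_mutate <- function(x, u = runif(length(x)), lower = NULL, upper = NULL) {
  stopifnot(length(u) == length(x) || length(u) == 1L)
  out <- x + x * cauchy_random(u)
  if (!is.null(lower)) out <- pmax(out, lower)
  if (!is.null(upper)) out <- pmin(out, upper)
  out
}

#' Mantegna scale factor for Levy steps
#'
#' `phi = [Gamma(1+beta) sin(pi beta/2) / (Gamma((1+beta)/2) beta
#' 2^((beta-1)/2))]^(1/beta)`; about 0.6966 at the customary `beta = 1.5`.
#'
#' @param beta Stability index, `0 < beta <= 2`.
#' @return Scalar scale factor.
#' @export
levy_scale <- function(beta) {
  if (!(beta > 0 && beta <= 2))
    stop("beta must lie in (0, 2]", call. = FALSE)
  (gamma(1 + beta) * sin(pi * beta / 2) /
      (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Levy-distributed step via the Mantegna algorithm
#'
#' Draws `phi * mu / |nu|^(1/beta)` with `mu`, `nu` standard normal. The
#' resulting steps mix frequent short moves with rare long flights, the
#' exploration pattern the Levy mutation operator exploits.
#'
#' @param n Number of draws.
#' @param beta Stability index, `0 < beta <= 2` (default 1.5).
#' @return Numeric vector of `n` Levy steps.
#' @export
levy_step <- function(n = 1L, beta = 1.5) {
  phi <- levy_scale(beta)
  phi * rnorm(n) / abs(rnorm(n))^(1 / beta)
}

#' Levy mutation of a position vector
#'
#' Multiplicative perturbation `x_new = x + x * L(beta)` analogous to
#' [cauchy_mutate()], with Levy steps in place of Cauchy deviates. Shares the
#' origin fixed-point property.
#'
#' @param x Numeric position vector.
#' @param beta Stability index (default 1.5).
#' @param step Optional pre-drawn Levy steps (one per coordinate or scalar).
#' @param lower,upper Optional box bounds; the candidate is clamped.
#' @return Mutated position vector.
#' @export
levy_mutate <- function(x, beta = 1.5, step = levy_step(length(x), beta),
                        lower = NULL, upper = NULL) {
  stopifnot(length(step) == length(x) || length(step) == 1L)
  out <- x + x * step
  if (!is.null(lower)) out <- pmax(out, lower)
  if (!is.null(upper)) out <- pmin(out, upper)
  out
}

#' Control parameters for the CLGBO optimizer
#'
#' Defaults are the study settings: population 50, 500 iterations, local
#' escape probability 0.5, Levy index 1.5, GBO step-control parameter swept
#' over `[0.2, 1.2]`.
#'
#' @param pop_size Number of agents (>= 2).
#' @param max_iter Maximum iterations (>= 1).
#' @param pr Probability of entering the local escape operator per agent and
#'   iteration, in `[0, 1]`.
#' @param levy_beta Stability index of the Levy mutation, in (0, 2].
#' @param beta_range Length-2 numeric range of the GBO control parameter that
#'   is annealed over the run.
#' @param mutation Which mutation operators to apply after each GBO update:
#'   `"both"` (CLGBO), `"cauchy"` (CGBO), `"levy"` (LGBO) or `"none"` (plain
#'   GBO).
#' @param per_coordinate Draw one mutation deviate per coordinate instead of
#'   a single scalar per agent. The default (`FALSE`) follows the update
#'   formula's per-individual indexing: one draw rescales the whole
#'   position, which preserves the direction of a converged agent and lets
#'   runs on origin-centred problems decay all the way to an exact 0.
#' @param mutation_anchor Position the mutants are generated from: `"best"`
#'   (default) mutates around the incumbent best individual, concentrating
#'   search effort near the current optimum, while each mutant still
#'   competes greedily with its own parent; `"agent"` mutates each agent's
#'   own position.
#' @param stop_at Early-stop threshold: the run ends once the best fitness is
#'   `<= stop_at` (default `-Inf`, never).
#' @return A list of class `clgbo_control`.
#' @export
clgbo_control <- function(pop_size = 50L, max_iter = 500L, pr = 0.5,
                          levy_beta = 1.5, beta_range = c(0.2, 1.2),
                          mutation = c("both", "cauchy", "levy", "none"),
                          per_coordinate = FALSE,
                          mutation_anchor = c("best", "agent"),
                          stop_at = -Inf) {
  mutation <- match.arg(mutation)
  mutation_anchor <- match.arg(mutation_anchor)
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  stopifnot(pop_size >= 2L, max_iter >= 1L, pr >= 0, pr <= 1,
            levy_beta > 0, levy_beta <= 2, length(beta_range) == 2L,
            beta_range[1] <= beta_range[2])
  structure(list(pop_size = pop_size, max_iter = max_iter, pr = pr,
                 levy_beta = levy_beta, beta_range = as.numeric(beta_range),
                 mutation = mutation, per_coordinate = isTRUE(per_coordinate),
                 mutation_anchor = mutation_anchor, stop_at = stop_at),
            class = "clgbo_control")
}

.mutation_code <- function(mutation) {
  switch(mutation, none = 0L, cauchy = 1L, levy = 2L, both = 3L)
}

# shared driver: objective is an R function, a builtin benchmark id, or the
# codeset penalty (obj_id 100 with data list)
.clgbo_run <- function(obj_id, obj_fun, obj_data, lower, upper, control) {
  .clgbo_core(obj_id,
              if (is.null(obj_fun)) function(x) NA_real_ else obj_fun,
              if (is.null(obj_data)) list() else obj_data,
              as.numeric(lower), as.numeric(upper),
              control$pop_size, control$max_iter, control$pr,
              control$levy_beta, control$beta_range[1], control$beta_range[2],
              .mutation_code(control$mutation), control$per_coordinate,
              identical(control$mutation_anchor, "best"), control$stop_at)
}

#' Minimize an objective with the CLGBO metaheuristic
#'
#' Population-based minimization over a box. Each iteration applies the GBO
#' update (gradient search rule blending the agent, the incumbent best and
#' random peers, plus a local escape operator entered with probability `pr`)
#' followed, per agent, by a Cauchy mutant and a Levy mutant with greedy
#' survivor selection: a candidate replaces the agent only if its fitness is
#' strictly better, so the best-so-far fitness is non-increasing.
#'
#' @param objective An R function mapping a numeric vector to a finite scalar,
#'   or the name of a built-in benchmark function (see [benchmark_suite()]).
#' @param lower,upper Numeric box bounds (recycled to a common length).
#' @param control A [clgbo_control()] list.
#' @param seed Optional integer seed; when supplied the run is bit
#'   reproducible.
#' @return An object of class `clgbo` with elements `best` (position),
#'   `value` (best fitness), `curve` (best-so-far fitness per iteration,
#'   non-increasing), `evaluations`, `iterations`, `leo_entries`, `control`
#'   and `seed`.
#' @examples
#' fit <- clgbo("sphere", lower = rep(-100, 5), upper = rep(100, 5),
#'              control = clgbo_control(pop_size = 20, max_iter = 50),
#'              seed = 1)
#' fit$value
#' @export
clgbo <- function(objective, lower, upper, control = clgbo_control(),
                  seed = NULL) {
  stopifnot(inherits(control, "clgbo_control"))
  k <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), k)
  upper <- rep_len(as.numeric(upper), k)
  if (!is.null(seed)) set.seed(seed)
  obj_name <- NULL
  if (is.character(objective)) {
    obj_name <- match.arg(objective, benchmark_suite()$name)
    id <- benchmark_id(obj_name)
    res <- .clgbo_run(id, NULL, NULL, lower, upper, control)
  } else {
    stopifnot(is.function(objective))
    res <- .clgbo_run(0L, objective, NULL, lower, upper, control)
  }
  structure(c(res, list(control = control, seed = seed,
                        objective = if (is.null(obj_name)) "user function"
                                    else obj_name,
                        lower = lower, upper = upper)),
            class = "clgbo")
}

#' @export
print.clgbo <- function(x, ...) {
  cat("CLGBO run on", x$objective, "\n")
  cat(sprintf("  dimensions: %d, population: %d, iterations: %d (max %d)\n",
              length(x$best), x$control$pop_size, x$iterations,
              x$control$max_iter))
  cat(sprintf("  mutation mode: %s, evaluations: %d\n",
              x$control$mutation, as.integer(x$evaluations)))
  cat(sprintf("  best fitness: %.6g\n", x$value))
  invisible(x)
}

#' @export
summary.clgbo <- function(object, ...) {
  cat("CLGBO run summary\n")
  print(object)
  cv <- object$curve
  show <- unique(pmin(length(cv), c(1, 10, 50, 100, 250, length(cv))))
  cat("  best-so-far fitness:\n")
  for (i in show)
    cat(sprintf("    iteration %4d: %.6g\n", i, cv[i]))
  invisible(object)
}

#' @export
coef.clgbo <- function(object, ...) object$best

#' Plot the convergence curve of a CLGBO run
#'
#' @param x A `clgbo` object.
#' @param log Use a log10 fitness axis where possible (default TRUE; zero or
#'   negative fitness values fall back to a linear axis).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.clgbo <- function(x, log = TRUE, ...) {
  cv <- x$curve
  use_log <- log && all(cv > 0)
  graphics::plot(seq_along(cv), cv, type = "l",
                 log = if (use_log) "y" else "",
                 xlab = "iteration", ylab = "best fitness",
                 main = paste("CLGBO convergence:", x$objective), ...)
  invisible(x)
}
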