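#' Build a schedule-optimization problem
#'
#' Packages the decision-variable encoding (bounds, lattices), the
#' evaluator and the objective into a single problem object consumed by
#' [optimize_ga()], [optimize_de()] and [exhaustive_search()].
#'
#' Bounds follow the dosing conventions: the smallest inter-dose interval
#' is 90 minutes, dose sizes lie in `[0, max_dose]` mg on the `dose_step`
#' lattice (the maintenance dose may carry its own upper bound in the
#' benchmark setting), and intake times fit within the patient's day. A
#' decoded candidate whose doses spill past the end of the day receives a
#' large distance-scaled penalty instead of a hard failure so that
#' population-based optimizers can recover.
#'
#' @param evaluator schedule evaluator (see [pkpd_evaluator()]).
#' @param target a [target_spec()].
#' @param constraints a [constraint_set()].
#' @param n_doses number of doses per day (fixed per run).
#' @param day_length minutes awake.
#' @param dose_step dose lattice (mg), e.g. 5 or 50.
#' @param max_dose upper dose bound (mg).
#' @param maint_max optional maintenance-dose upper bound (mg) under
#'   constraint 3 (the comparison benchmark uses 300).
#' @param min_interval smallest inter-dose interval (minutes).
#' @param obj an [objective_spec()].
#' @param grid_step trace sampling step (minutes).
#' @param fill_day with constraints 2-4 active, let the number of doses
#'   follow from the interval (doses repeat until the day ends, the
#'   comparison-benchmark convention) instead of being fixed.
#' @return An object of class `schedule_problem`.
#' @export
make_problem <- function(evaluator, target, constraints, n_doses,
                         day_length, dose_step = 50, max_dose = 400,
                         maint_max = NULL, min_interval = 90,
                         obj = objective_spec(), grid_step = 10,
                         fill_day = FALSE) {
  if (fill_day && !(constraints$c2 && constraints$c3 && constraints$c4))
    stop("fill_day requires constraints 2, 3 and 4 to be active")
  n <- if (fill_day) 2L else n_doses
  dim <- encoding_dim(constraints, n)
  lower <- numeric(dim); upper <- numeric(dim)
  lattice <- numeric(dim)  # 0 = continuous
  nm <- character(dim)
  i <- 1
  last_grid_time <- day_length - grid_step
  max_interval <- if (fill_day) last_grid_time / 2
  else if (n > 1) last_grid_time / (n - 1) else last_grid_time
  if (!constraints$c2) {
    lower[i] <- 0; upper[i] <- last_grid_time
    lattice[i] <- if (constraints$c1) constraints$time_step else 0
    nm[i] <- "t1"; i <- i + 1
  }
  n_int <- if (constraints$c4) 1L else n - 1L
  # free intervals are bounded individually by the day length minus the
  # minimum room for the other gaps; the joint day-length constraint is
  # enforced through the decode-overflow penalty
  free_upper <- if (n > 2) last_grid_time - min_interval * (n - 2)
  else last_grid_time
  for (j in seq_len(n_int)) {
    lower[i] <- min_interval
    upper[i] <- max(min_interval,
                    if (constraints$c4) max_interval else free_upper)
    lattice[i] <- if (constraints$c1) constraints$time_step else 0
    nm[i] <- if (constraints$c4) "dt" else paste0("dt", j + 1)
    i <- i + 1
  }
  n_sizes <- if (constraints$c3) 2L else n
  for (j in seq_len(n_sizes)) {
    lower[i] <- 0
    upper[i] <- if (constraints$c3 && j == 2 && !is.null(maint_max))
      maint_max else max_dose
    lattice[i] <- dose_step
    nm[i] <- if (constraints$c3) c("d_mor", "d_main")[j] else paste0("d", j)
    i <- i + 1
  }
  # floor lattice-variable upper bounds onto the lattice so every
  # admissible value is exactly enumerable
  for (j in seq_len(dim)) {
    if (lattice[j] > 0)
      upper[j] <- lower[j] + floor((upper[j] - lower[j]) / lattice[j]) *
        lattice[j]
  }
  snap <- function(v) {
    for (j in seq_len(dim)) {
      if (lattice[j] > 0)
        v[j] <- lower[j] + round((v[j] - lower[j]) / lattice[j]) * lattice[j]
      v[j] <- min(max(v[j], lower[j]), upper[j])
    }
    v
  }
  decode <- function(vec) {
    nn <- if (fill_day) {
      dt <- vec[1]
      max(1L, floor(last_grid_time / dt) + 1L)
    } else n
    decode_schedule(if (fill_day) c(vec[1], vec[2], vec[3]) else vec,
                    constraints, nn)
  }
  objective <- function(vec) {
    sch <- decode(vec)
    if (length(sch$times) && max(sch$times) > last_grid_time + 1e-9)
      return(1e6 + (max(sch$times) - last_grid_time))
    combined_objective(sch, evaluator, obj, target)
  }
  structure(list(dim = dim, lower = lower, upper = upper,
                 lattice = lattice, names = nm, snap = snap,
                 objective = objective, decode = decode,
                 constraints = constraints,
                 n_doses = n, fill_day = fill_day,
                 day_length = day_length,
                 dose_step = dose_step, evaluator = evaluator,
                 target = target, obj = obj, grid_step = grid_step),
            class = "schedule_problem")
}

random_individual <- function(problem) {
  problem$snap(stats::runif(problem$dim, problem$lower, problem$upper))
}

#' Genetic-algorithm schedule optimization
#'
#' A generational GA over the encoded decision space: tournament
#' selection, two-point crossover (probability `cxpb`), and per-variable
#' mutation (each individual mutates with probability `mutpb`, each of
#' its variables with probability `indpb`) — gaussian perturbation
#' clipped to the bounds for continuous variables, uniform resampling on
#' the admissible lattice for discrete ones. Fitness is the negative
#' objective; the best individual ever seen is returned.
#'
#' @param problem a [make_problem()] object.
#' @param pop_size population size (kept at or below 200).
#' @param generations number of generations (kept at or below 100).
#' @param cxpb crossover probability.
#' @param mutpb per-individual mutation probability.
#' @param indpb per-variable mutation probability.
#' @param tourn_k tournament size.
#' @param sigma gaussian mutation sd per variable; defaults to 10% of
#'   each variable's range.
#' @param seed integer seed.
#' @param restarts number of independent multi-start runs; the best
#'   result is returned. Hard-constrained landscapes with large
#'   infeasible plateaus occasionally trap a single run, and multi-start
#'   is the standard remedy.
#' @return List with `schedule`, `score`, `vector`, `evaluations`.
#' @export
optimize_ga <- function(problem, pop_size = 100, generations = 50,
                        cxpb = 0.5, mutpb = 0.2, indpb = 0.1,
                        tourn_k = 3, sigma = NULL, seed = 1,
                        restarts = 1) {
  if (restarts > 1) {
    runs <- lapply(seq_len(restarts), function(r)
      optimize_ga(problem, pop_size, generations, cxpb, mutpb, indpb,
                  tourn_k, sigma, seed = seed + 7919L * (r - 1L)))
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "score"))]]
    best$evaluations <- sum(vapply(runs, `[[`, numeric(1), "evaluations"))
    return(best)
  }
  if (pop_size <= 2) stop("population size must exceed 2")
  set.seed(seed)
  if (is.null(sigma)) sigma <- 0.1 * (problem$upper - problem$lower)
  pop <- t(vapply(seq_len(pop_size), function(i) random_individual(problem),
                  numeric(problem$dim)))
  fit <- apply(pop, 1, problem$objective)
  evals <- pop_size
  best <- list(vec = pop[which.min(fit), ], score = min(fit))
  mutate <- function(v) {
    for (j in seq_len(problem$dim)) {
      if (stats::runif(1) < indpb) {
        if (problem$lattice[j] > 0) {
          vals <- seq(problem$lower[j], problem$upper[j],
                      by = problem$lattice[j])
          v[j] <- if (length(vals) == 1) vals else sample(vals, 1)
        } else {
          v[j] <- v[j] + stats::rnorm(1, 0, sigma[j])
          v[j] <- min(max(v[j], problem$lower[j]), problem$upper[j])
        }
      }
    }
    v
  }
  for (g in seq_len(generations)) {
    sel <- vapply(seq_len(pop_size), function(i) {
      cand <- sample(pop_size, tourn_k, replace = TRUE)
      cand[which.min(fit[cand])]
    }, integer(1))
    pop <- pop[sel, , drop = FALSE]
    fit <- fit[sel]
    changed <- rep(FALSE, pop_size)
    if (problem$dim >= 2) {
      for (i in seq_len(floor(pop_size / 2))) {
        if (stats::runif(1) < cxpb) {
          a <- 2 * i - 1; b <- 2 * i
          pts <- sort(sample(problem$dim, 2))
          seg <- pts[1]:pts[2]
          tmp <- pop[a, seg]
          pop[a, seg] <- pop[b, seg]
          pop[b, seg] <- tmp
          changed[c(a, b)] <- TRUE
        }
      }
    }
    for (i in seq_len(pop_size)) {
      if (stats::runif(1) < mutpb) {
        pop[i, ] <- problem$snap(mutate(pop[i, ]))
        changed[i] <- TRUE
      }
    }
    if (any(changed)) {
      fit[changed] <- apply(pop[changed, , drop = FALSE], 1,
                            problem$objective)
      evals <- evals + sum(changed)
    }
    if (min(fit) < best$score) {
      best <- list(vec = pop[which.min(fit), ], score = min(fit))
    }
  }
  list(schedule = problem$decode(best$vec),
       score = best$score, vector = best$vec, evaluations = evals)
}

#' Differential-evolution schedule optimization
#'
#' Classic rand/1/bin differential evolution: for each target vector a
#' trial is built from three distinct other individuals as
#' `v[i] = a[i] + F (b[i] - c[i])` under the crossover probability, and
#' it replaces the target when its objective is no worse. The population
#' is kept continuous; integrality is handled as in the reference
#' implementation by clipping to the bounds and rounding to the
#' admissible lattice at evaluation time only, which preserves the
#' differential diversity on discrete variables.
#'
#' @inheritParams optimize_ga
#' @param cxpb crossover probability.
#' @param F differential weight.
#' @param init optional matrix of decision vectors (one per row) placed
#'   into the initial population, e.g. to warm-start from a previously
#'   found schedule.
#' @param polish refine the best individual after the evolution loop by
#'   coordinate descent on the admissible lattice (the reference
#'   implementation likewise finishes with a local polish phase).
#' @export
optimize_de <- function(problem, pop_size = 40, generations = 60,
                        cxpb = 0.7, F = 0.8, seed = 1, init = NULL,
                        polish = TRUE) {
  if (pop_size <= 2) stop("population size must exceed 2")
  set.seed(seed)
  pop <- t(vapply(seq_len(pop_size), function(i)
    stats::runif(problem$dim, problem$lower, problem$upper),
    numeric(problem$dim)))
  if (!is.null(init)) {
    init <- matrix(init, ncol = problem$dim)
    for (r in seq_len(min(nrow(init), pop_size))) pop[r, ] <- init[r, ]
  }
  fit <- apply(pop, 1, function(v) problem$objective(problem$snap(v)))
  evals <- pop_size
  for (g in seq_len(generations)) {
    for (j in seq_len(pop_size)) {
      abc <- sample(setdiff(seq_len(pop_size), j), 3)
      a <- pop[abc[1], ]; b <- pop[abc[2], ]; cc <- pop[abc[3], ]
      cross <- stats::runif(problem$dim) < cxpb
      v <- pop[j, ]
      v[cross] <- a[cross] + F * (b[cross] - cc[cross])
      v <- pmin(pmax(v, problem$lower), problem$upper)
      fv <- problem$objective(problem$snap(v))
      evals <- evals + 1
      if (fv <= fit[j]) {
        pop[j, ] <- v
        fit[j] <- fv
      }
    }
  }
  i <- which.min(fit)
  best <- problem$snap(pop[i, ])
  fbest <- fit[i]
  if (polish) {
    pol <- lattice_polish(problem, best, fbest)
    best <- pol$vector; fbest <- pol$score
    evals <- evals + pol$evaluations
  }
  list(schedule = problem$decode(best),
       score = fbest, vector = best, evaluations = evals)
}

# coordinate descent over +-1..3 lattice steps (continuous variables move
# on the trace grid step); runs until no single-coordinate move improves
lattice_polish <- function(problem, v, f0, max_passes = 50) {
  evals <- 0L
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (j in seq_len(problem$dim)) {
      step <- if (problem$lattice[j] > 0) problem$lattice[j]
      else problem$grid_step
      for (s in c(-3, -2, -1, 1, 2, 3)) {
        w <- v
        w[j] <- w[j] + s * step
        w <- problem$snap(w)
        if (identical(w, v)) next
        fw <- problem$objective(w)
        evals <- evals + 1L
        if (fw < f0 - 1e-9) {
          v <- w; f0 <- fw; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(vector = v, score = f0, evaluations = evals)
}

#' Exhaustive-search benchmark
#'
#' The comparison method: with all four constraints active (first dose at
#' wake, equal maintenance doses at equal lattice intervals) it
#' enumerates every candidate on the given grids and returns the
#' minimizer of the area outside the target range among candidates that
#' satisfy the threshold condition after the first dose. Ties are broken
#' by smaller total dose, then smaller interval.
#'
#' @param evaluator schedule evaluator.
#' @param target a [target_spec()].
#' @param day_length minutes awake.
#' @param n_doses number of doses; `NULL` (default) repeats the
#'   maintenance dose until the day ends (doses fill the day).
#' @param dose_step dose grid (mg).
#' @param interval_step interval grid (minutes).
#' @param morning_max,maint_max dose bounds (mg).
#' @param min_interval smallest interval (minutes).
#' @param squared squared-excursion reading of the objective.
#' @param grid_step trace sampling step (minutes).
#' @return List with `schedule`, `score`, `feasible` (FALSE with an empty
#'   feasible grid, reported explicitly), `n_evaluated`.
#' @export
exhaustive_search <- function(evaluator, target, day_length, n_doses = NULL,
                              dose_step = 50, interval_step = 30,
                              morning_max = 400, maint_max = 300,
                              min_interval = 90, squared = TRUE,
                              grid_step = 10) {
  last_grid_time <- day_length - grid_step
  max_interval <- if (is.null(n_doses)) last_grid_time / 2
  else if (n_doses > 1) last_grid_time / (n_doses - 1) else last_grid_time
  intervals <- seq(min_interval, max(min_interval, max_interval),
                   by = interval_step)
  if (!is.null(n_doses))
    intervals <- intervals[intervals * (n_doses - 1) <= last_grid_time]
  mor <- seq(0, morning_max, by = dose_step)
  mnt <- seq(0, maint_max, by = dose_step)
  best <- NULL
  n_eval <- 0L
  for (dt in intervals) {
    nd <- if (is.null(n_doses)) max(1L, floor(last_grid_time / dt) + 1L)
    else n_doses
    for (dm in mor) {
      for (dn in mnt) {
        sch <- schedule_from_intervals(0, rep(dt, nd - 1),
                                       c(dm, rep(dn, nd - 1)))
        trace <- evaluator(sch)
        n_eval <- n_eval + 1L
        if (!threshold_ok(trace, target, 0)) next
        score <- objective_outside_range(trace, target, squared)
        cand <- list(schedule = sch, score = score,
                     total = dm + (nd - 1) * dn, interval = dt)
        if (is.null(best) ||
            score < best$score - 1e-12 ||
            (abs(score - best$score) <= 1e-12 &&
             (cand$total < best$total ||
              (cand$total == best$total && dt < best$interval)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    warning("exhaustive search found no schedule satisfying the threshold condition")
    return(list(schedule = NULL, score = Inf, feasible = FALSE,
                n_evaluated = n_eval))
  }
  list(schedule = best$schedule, score = best$score, feasible = TRUE,
       n_evaluated = n_eval)
}
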