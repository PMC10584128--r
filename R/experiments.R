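#' General + patient-specific transfer experiment
#'
#' The core modelling pipeline: generate a synthetic cohort (40 general +
#' 10 individual patients by default, 3 days each on a 10-minute grid),
#' train the general response model by whole-day rollout, then
#' transfer-fit each individual patient on 2 days with the third day held
#' out for validation, and report per-patient validation metrics.
#'
#' @param pop a [population_model()].
#' @param n_general,n_individual cohort split.
#' @param n_days days per patient.
#' @param model_cfg response-model architecture (default the impulse
#'   model with 8 LSTM units and two 64-neuron dense layers).
#' @param general_cfg,patient_cfg training configurations.
#' @param day_cfg a [day_gen_config()].
#' @param seed global experiment seed.
#' @param n_general_restarts,n_transfer_restarts number of training
#'   repetitions with different weight-initialization/shuffling seeds;
#'   the run with the lowest validation loss is kept (the
#'   repeat-and-select protocol used for the model-selection tables,
#'   scaled down from 10 repetitions).
#' @return List with `general` (fit), `patients` (data frame of
#'   per-patient validation metrics), `models` (patient models),
#'   `cohort`.
#' @export
transfer_experiment <- function(pop = default_population(),
                                n_general = 40, n_individual = 10,
                                n_days = 3,
                                model_cfg = impulse_model_config(8, c(64, 64)),
                                general_cfg = train_config(),
                                patient_cfg = transfer_config(batch_size = 1),
                                day_cfg = day_gen_config(),
                                seed = 1,
                                n_general_restarts = 1,
                                n_transfer_restarts = 3) {
  cohort <- generate_cohort(pop, n_general + n_individual, n_days,
                            day_cfg, seed = seed)
  gen_days <- Filter(function(d) d$patient_id <= n_general, cohort$days)
  general <- NULL
  for (r in seq_len(n_general_restarts)) {
    general_cfg$seed <- seed + 101L * r
    fit <- train_general(gen_days, model_cfg, general_cfg)
    if (is.null(general) || fit$best_val_loss < general$best_val_loss)
      general <- fit
  }
  res <- data.frame()
  models <- list()
  for (pid in (n_general + 1):(n_general + n_individual)) {
    pdays <- Filter(function(d) d$patient_id == pid, cohort$days)
    best <- NULL
    for (r in seq_len(n_transfer_restarts)) {
      pcfg <- patient_cfg
      pcfg$seed <- seed + 1000L * r + pid
      fit <- transfer_fit(general$model, pdays, pcfg)
      if (is.null(best) || fit$best_val_loss < best$best_val_loss)
        best <- fit
    }
    ev_before <- evaluate_model(general$model, pdays[3])
    ev_after <- evaluate_model(best$model, pdays[3])
    models[[as.character(pid)]] <- best$model
    res <- rbind(res, data.frame(
      patient_id = pid,
      mse_before = ev_before$mse, r2_before = ev_before$r2,
      mse = ev_after$mse, mae = ev_after$mae, r2 = ev_after$r2,
      epochs = nrow(best$history)))
  }
  list(general = general, patients = res, models = models, cohort = cohort)
}

#' Constraint-relaxation experiment
#'
#' For each patient, optimizes the daily schedule with differential
#' evolution under the full constraint set (discrete times, first dose at
#' wake, morning + equal maintenance doses at equal intervals, repeated
#' until the day ends) and under only the discretization and
#' first-dose-at-wake constraints, then reports the relative decrease of
#' the optimized objective (area outside the target range plus the
#' below-threshold penalty). The relaxed search keeps the dose count of
#' the constrained optimum (so its feasible region is a superset) and is
#' warm-started from it.
#'
#' @param patients list of [patient_params()].
#' @param day_length minutes awake.
#' @param dose_step dose lattice (mg).
#' @param obj an [objective_spec()].
#' @param seed integer seed.
#' @param de_con,de_rel DE settings (lists with `pop_size`,
#'   `generations`) for the constrained and relaxed runs.
#' @return List with `results` (per-patient data frame) and
#'   `mean_decrease` (mean relative decrease, as a percentage).
#' @export
relaxation_experiment <- function(patients, day_length = 960,
                                  dose_step = 50,
                                  obj = objective_spec(w_range = 1,
                                                       w_threshold = 10),
                                  seed = 1,
                                  de_con = list(pop_size = 30,
                                                generations = 60),
                                  de_rel = list(pop_size = 60,
                                                generations = 150)) {
  res <- data.frame()
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    ev <- pkpd_evaluator(p, day_length)
    tg <- target_from_patient(p)
    con <- optimize_de(
      make_problem(ev, tg, constraints_from_numbers(1:4), NULL, day_length,
                   dose_step = dose_step, fill_day = TRUE, obj = obj),
      pop_size = de_con$pop_size, generations = de_con$generations,
      seed = seed + 31L * i)
    nstar <- n_doses(con$schedule)
    prob <- make_problem(ev, tg, constraints_from_numbers(1:2), nstar,
                         day_length, dose_step = dose_step, obj = obj)
    sv <- encode_schedule(con$schedule, constraints_from_numbers(1:2))
    set.seed(seed + 97L * i)
    scale <- 1.5 * ifelse(prob$lattice > 0, prob$lattice, prob$grid_step)
    cloud <- t(vapply(seq_len(de_rel$pop_size), function(r)
      pmin(pmax(sv + stats::rnorm(prob$dim, 0, scale), prob$lower),
           prob$upper), numeric(prob$dim)))
    cloud[1, ] <- sv
    relx <- optimize_de(prob, pop_size = de_rel$pop_size,
                        generations = de_rel$generations,
                        seed = seed + 53L * i, init = cloud)
    res <- rbind(res, data.frame(
      patient = i, n_doses = nstar,
      score_constrained = con$score, score_relaxed = relx$score,
      decrease_pct = 100 * (con$score - relx$score) / con$score))
  }
  list(results = res, mean_decrease = mean(res$decrease_pct))
}
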