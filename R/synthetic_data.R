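# Synthetic longitudinal EHR cohorts with known structure.
#
# Each patient carries a latent health-state trajectory z_t following a
# stationary AR(1) process; the three discrete views (diagnosis, medication,
# abnormal-lab indicators) are conditionally independent Bernoulli draws whose
# logits load on the shared z_t, which is what gives encounters their
# cross-view correlation. Mortality is Bernoulli in the final latent state,
# and a set of "marker" codes per view receives an additional logit shift in
# patients who die — a planted, unambiguous attribution ground truth.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror a scaled-down version of a multi-encounter ICU cohort:
#' 2000 patients with 2–8 encounters, vocabularies of 200/150/100 codes, and a
#' mortality prevalence calibrated to 38%.
#'
#' @param n_patients number of patients.
#' @param encounter_range integer (min, max) encounters per patient; min >= 2
#'   so every patient survives the cohort rule.
#' @param latent_dim dimension k of the latent health state.
#' @param vocab_sizes named integer vector: codes per view.
#' @param loading_scale standard deviation of the per-code logit contribution
#'   of the latent state; 0 makes the views independent.
#' @param trajectory_persistence AR(1) coefficient rho in [0, 1); innovations
#'   have variance 1 - rho^2 so the latent state is stationary with unit
#'   variance.
#' @param mortality_coefficients beta, length `latent_dim`: log-odds of death
#'   per unit of final latent state.
#' @param intercept gamma, the mortality intercept; `NULL` calibrates it to
#'   `target_prevalence` via [prevalence_calibrate()].
#' @param target_prevalence mortality prevalence used when `intercept` is NULL.
#' @param n_marker_features_per_view number of marker codes planted per view.
#' @param marker_effect logit shift added to each marker code's documentation
#'   probability in patients who die.
#' @param baseline_rates named per-view marginal documentation rates, chosen
#'   to give realistic per-encounter code counts (about 8 diagnoses, 10
#'   medications, 8 abnormal labs).
#' @param normal_lab_rate probability that a lab code is additionally measured
#'   *normal* in an encounter (these events are dropped in abnormal-only mode).
#' @param seed integer seed; cohorts are byte-identical for a fixed seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 2000L,
                             encounter_range = c(2L, 8L),
                             latent_dim = 8L,
                             vocab_sizes = c(diagnosis = 200L,
                                             medication = 150L, lab = 100L),
                             loading_scale = 1,
                             trajectory_persistence = 0.7,
                             mortality_coefficients = rep(0.3, latent_dim),
                             intercept = NULL,
                             target_prevalence = 0.38,
                             n_marker_features_per_view = 40L,
                             marker_effect = 2,
                             baseline_rates = c(diagnosis = 0.04,
                                                medication = 0.067, lab = 0.08),
                             normal_lab_rate = 0.1,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              encounter_range = as.integer(encounter_range),
              latent_dim = as.integer(latent_dim),
              vocab_sizes = vocab_sizes,
              loading_scale = loading_scale,
              trajectory_persistence = trajectory_persistence,
              mortality_coefficients = mortality_coefficients,
              intercept = intercept,
              target_prevalence = target_prevalence,
              n_marker_features_per_view = as.integer(n_marker_features_per_view),
              marker_effect = marker_effect,
              baseline_rates = baseline_rates,
              normal_lab_rate = normal_lab_rate,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  check <- function(ok, field) {
    if (!ok) stop("invalid generator config field: ", field)
  }
  check(cfg$n_patients >= 1, "n_patients")
  check(length(cfg$encounter_range) == 2 && cfg$encounter_range[1] >= 2 &&
          cfg$encounter_range[2] >= cfg$encounter_range[1], "encounter_range")
  check(cfg$latent_dim >= 1, "latent_dim")
  check(length(cfg$vocab_sizes) == 3 && all(cfg$vocab_sizes >= 1) &&
          setequal(names(cfg$vocab_sizes), .views), "vocab_sizes")
  check(cfg$loading_scale >= 0, "loading_scale")
  check(cfg$trajectory_persistence >= 0 && cfg$trajectory_persistence < 1,
        "trajectory_persistence")
  check(length(cfg$mortality_coefficients) == cfg$latent_dim,
        "mortality_coefficients")
  check(cfg$n_marker_features_per_view >= 0 &&
          all(cfg$vocab_sizes >= cfg$n_marker_features_per_view),
        "n_marker_features_per_view")
  check(cfg$marker_effect >= 0, "marker_effect")
  check(cfg$normal_lab_rate >= 0 && cfg$normal_lab_rate < 1, "normal_lab_rate")
  invisible(cfg)
}

# simulate final-encounter latent states only (for prevalence calibration)
simulate_final_latents <- function(cfg, n) {
  rho <- cfg$trajectory_persistence
  k <- cfg$latent_dim
  lens <- sample(seq(cfg$encounter_range[1], cfg$encounter_range[2]), n,
                 replace = TRUE)
  # stationary AR(1): z_1 ~ N(0, I); marginal variance is 1 at every step,
  # so the final state is N(0, I) regardless of length -- draw directly
  z <- matrix(rnorm(n * k), n, k)
  list(z_final = z, lens = lens)
}

#' Calibrate the mortality intercept to a target prevalence
#'
#' Bisects the intercept gamma until the Monte-Carlo mortality prevalence
#' under the generator's latent model is within `tol` of `target`.
#'
#' @param config a [generator_config()].
#' @param target target prevalence in (0, 1).
#' @param n_calibrate Monte-Carlo sample size.
#' @param tol admissible |prevalence - target|.
#' @param bounds search interval for gamma; must bracket the target.
#' @return the calibrated intercept (numeric scalar).
#' @export
prevalence_calibrate <- function(config, target = config$target_prevalence,
                                 n_calibrate = 20000L, tol = 0.01,
                                 bounds = c(-15, 15)) {
  stopifnot(target > 0, target < 1)
  beta <- config$mortality_coefficients
  eta <- withr::with_seed(derive_seed(config$seed, "prevalence_calibrate"), {
    sim <- simulate_final_latents(config, n_calibrate)
    drop(sim$z_final %*% beta)
  })
  prev <- function(gamma) mean(stats::plogis(eta + gamma))
  lo <- bounds[1]; hi <- bounds[2]
  if (prev(lo) > target || prev(hi) < target) {
    stop("calibration bounds do not bracket the target prevalence")
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (prev(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  gamma <- (lo + hi) / 2
  if (abs(prev(gamma) - target) > tol) {
    stop("prevalence calibration failed to reach the target within tolerance")
  }
  gamma
}

#' Generate a synthetic cohort with planted risk markers
#'
#' @param config a [generator_config()].
#' @return a list with elements
#'   \describe{
#'     \item{cohort}{an `ehr_cohort` of patient timelines (abnormal-only mode);}
#'     \item{events}{the full event table (including normal-lab measurement
#'       rows) in the dialect [load_event_table()] reads;}
#'     \item{truth}{a `clout_ground_truth` object: per-view loading matrices,
#'       marker indices, per-feature planted effect sizes, per-patient latent
#'       trajectories, and the intercept actually used.}
#'   }
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  gamma <- config$intercept
  if (is.null(gamma)) gamma <- prevalence_calibrate(config)
  withr::with_seed(derive_seed(config$seed, "generate_cohort"), {
    k <- config$latent_dim
    rho <- config$trajectory_persistence
    inno_sd <- sqrt(1 - rho^2)
    sizes <- config$vocab_sizes[.views]
    codes <- list(
      diagnosis = sprintf("D%04d", seq_len(sizes[["diagnosis"]])),
      medication = sprintf("M%04d", seq_len(sizes[["medication"]])),
      lab = sprintf("L%04d", seq_len(sizes[["lab"]]))
    )
    loadings <- lapply(.views, function(v) {
      matrix(rnorm(sizes[[v]] * k, sd = config$loading_scale / sqrt(k)),
             sizes[[v]], k, dimnames = list(codes[[v]], NULL))
    })
    names(loadings) <- .views
    baselines <- lapply(.views, function(v) {
      stats::setNames(qlogis(config$baseline_rates[[v]]) + rnorm(sizes[[v]], sd = 0.5),
                      codes[[v]])
    })
    names(baselines) <- .views
    markers <- lapply(.views, function(v) {
      sort(sample(sizes[[v]], config$n_marker_features_per_view))
    })
    names(markers) <- .views
    effects <- lapply(.views, function(v) {
      e <- stats::setNames(numeric(sizes[[v]]), codes[[v]])
      e[markers[[v]]] <- config$marker_effect
      e
    })
    names(effects) <- .views

    lens <- sample(seq(config$encounter_range[1], config$encounter_range[2]),
                   config$n_patients, replace = TRUE)
    pids <- sprintf("P%05d", seq_len(config$n_patients))
    trajectories <- vector("list", config$n_patients)
    names(trajectories) <- pids
    event_rows <- vector("list", config$n_patients)
    mortality <- integer(config$n_patients)

    for (i in seq_len(config$n_patients)) {
      ti <- lens[i]
      z <- matrix(0, ti, k)
      z[1, ] <- rnorm(k)
      if (ti > 1) {
        for (t in 2:ti) z[t, ] <- rho * z[t - 1, ] + rnorm(k, sd = inno_sd)
      }
      y <- rbinom(1, 1, plogis(sum(config$mortality_coefficients * z[ti, ]) + gamma))
      mortality[i] <- y
      trajectories[[i]] <- z
      # encounter dates: first at day 0, gaps 1-120 days
      dates <- as.Date("2010-01-01") + cumsum(c(0, sample(1:120, ti - 1,
                                                          replace = TRUE)))
      rows <- vector("list", ti)
      for (t in seq_len(ti)) {
        view_rows <- lapply(.views, function(v) {
          logit <- drop(loadings[[v]] %*% z[t, ]) + baselines[[v]] +
            effects[[v]] * y
          present <- runif(sizes[[v]]) < plogis(logit)
          if (v == "lab") {
            normal <- !present & runif(sizes[[v]]) < config$normal_lab_rate
            idx <- which(present | normal)
            if (length(idx) == 0) return(NULL)
            data.frame(view = v, code = codes[[v]][idx],
                       abnormal_flag = present[idx], stringsAsFactors = FALSE)
          } else {
            idx <- which(present)
            if (length(idx) == 0) return(NULL)
            data.frame(view = v, code = codes[[v]][idx],
                       abnormal_flag = NA, stringsAsFactors = FALSE)
          }
        })
        vr <- do.call(rbind, view_rows)
        if (is.null(vr)) {
          # an encounter must document something to exist in an event table;
          # empty draws are vanishingly rare at the default rates
          vr <- data.frame(view = "diagnosis",
                           code = codes$diagnosis[sample(sizes[["diagnosis"]], 1)],
                           abnormal_flag = NA, stringsAsFactors = FALSE)
        }
        vr$patient_id <- pids[i]
        vr$encounter_id <- sprintf("%s_E%02d", pids[i], t)
        vr$timestamp <- dates[t]
        rows[[t]] <- vr
      }
      event_rows[[i]] <- do.call(rbind, rows)
    }
    events <- do.call(rbind, event_rows)
    events$mortality <- mortality[match(events$patient_id, pids)]
    events <- events[, c("patient_id", "encounter_id", "timestamp", "view",
                         "code", "abnormal_flag", "mortality")]
    rownames(events) <- NULL
    cohort <- build_cohort(events, abnormal_only = TRUE)
    truth <- structure(
      list(loadings = loadings, baselines = baselines,
           marker_index = markers, effects = effects,
           trajectories = trajectories, intercept = gamma,
           config = config),
      class = "clout_ground_truth")
    list(cohort = cohort, events = events, truth = truth)
  })
}

#' Planted effect sizes as a long data frame
#'
#' @param truth a `clout_ground_truth`.
#' @return data frame with columns `view`, `code`, `effect`.
#' @export
ground_truth_effects <- function(truth) {
  do.call(rbind, lapply(.views, function(v) {
    data.frame(view = v, code = names(truth$effects[[v]]),
               effect = unname(truth$effects[[v]]), stringsAsFactors = FALSE)
  }))
}

#' Write the ground-truth sidecar as JSON
#'
#' @param truth a `clout_ground_truth`.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(intercept = truth$intercept,
         marker_index = truth$marker_index,
         effects = lapply(truth$effects, as.list),
         seed = truth$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
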