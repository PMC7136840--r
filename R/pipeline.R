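# End-to-end experiment pipeline.
#
# One YAML run configuration drives: simulate (or ingest) -> split -> pretrain
# (correlational network / autoencoder) -> train classifier variant(s) across
# seeds -> evaluate -> attribute -> sample features for review. Every stage
# writes its artifacts into the run directory and is skipped on rerun when its
# outputs already exist (resume). All randomness derives from one master seed
# via stage-name hashing (see derive_seed()).

#' Assemble (and validate) a run configuration
#'
#' @param out_dir run output directory.
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"` (read
#'   `events_path`).
#' @param events_path event table path (ingest mode).
#' @param dialect an [event_dialect()].
#' @param generator a [generator_config()] (simulate mode).
#' @param encoder an [encoder_config()]; its variant is overridden per entry
#'   of `variants`.
#' @param classifier a [clout_config()].
#' @param corrnet a [corrnet_config()].
#' @param variants character vector of encounter-vector variants to train.
#' @param n_seeds number of training replicate seeds per variant (for the
#'   mean/SD metric report).
#' @param master_seed master seed from which all stage seeds derive.
#' @param ratios train/validation/test split ratios.
#' @param abnormal_only lab handling for cohort construction.
#' @param logistic_l2 ridge penalty of the logistic baseline.
#' @param attribution_split which split to attribute over.
#' @param patient_plan a [sampling_plan()] for the patient-level review draw
#'   (default 4 features from each of the rank bins 1–20 / 21–50 / 51+).
#' @param population_plan a [sampling_plan()] applied to each per-view
#'   population ranking (default 2 per bin per view, 18 in total).
#' @return a validated `run_config`.
#' @export
run_config <- function(out_dir,
                       mode = c("simulate", "ingest"),
                       events_path = NULL,
                       dialect = event_dialect(),
                       generator = generator_config(),
                       encoder = encoder_config(),
                       classifier = clout_config(),
                       corrnet = corrnet_config(),
                       variants = c("simple_concat", "latent_concat"),
                       n_seeds = 1L,
                       master_seed = 1L,
                       ratios = c(0.7, 0.1, 0.2),
                       abnormal_only = TRUE,
                       logistic_l2 = 1e-2,
                       attribution_split = c("test", "validation", "train"),
                       patient_plan = sampling_plan(),
                       population_plan = sampling_plan(draws = c(2L, 2L, 2L))) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(events_path)) {
    stop("ingest mode requires events_path")
  }
  ok_variants <- c("simple_concat", "ae_only", "latent_only", "ae_concat",
                   "latent_concat")
  stopifnot(all(variants %in% ok_variants), n_seeds >= 1)
  structure(list(out_dir = out_dir, mode = mode, events_path = events_path,
                 dialect = dialect, generator = generator, encoder = encoder,
                 classifier = classifier, corrnet = corrnet,
                 variants = variants, n_seeds = as.integer(n_seeds),
                 master_seed = as.integer(master_seed), ratios = ratios,
                 abnormal_only = abnormal_only, logistic_l2 = logistic_l2,
                 attribution_split = match.arg(attribution_split),
                 patient_plan = patient_plan,
                 population_plan = population_plan),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()]; nested
#' blocks `generator`, `encoder`, `classifier` and `corrnet` override the
#' corresponding constructor defaults field by field.
#'
#' @param path YAML file.
#' @param out_dir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) {
    if (is.null(block)) return(ctor())
    do.call(ctor, block)
  }
  args <- list(
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    mode = y$mode %||% "simulate",
    events_path = y$events_path,
    generator = build(generator_config, y$generator),
    encoder = build(encoder_config, y$encoder),
    classifier = build(clout_config, y$classifier),
    corrnet = build(corrnet_config, y$corrnet)
  )
  for (k in c("variants", "n_seeds", "master_seed", "ratios", "abnormal_only",
              "logistic_l2", "attribution_split")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(dir, stage, seed, t0) {
  line <- jsonlite::toJSON(list(stage = stage, seed = seed,
                                wall_time = round(as.numeric(Sys.time()) -
                                                    t0, 3),
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(dir, "log.jsonl"), append = TRUE)
}

# training data must never include test patients
assert_no_leakage <- function(object, splits, what) {
  fit_ids <- attr(object, "fit_ids")
  if (is.null(fit_ids)) return(invisible(TRUE))
  if (length(intersect(fit_ids, splits$test)) > 0) {
    stop("leakage: ", what, " was fitted on test-split patients")
  }
  invisible(TRUE)
}

#' Run the full experiment pipeline
#'
#' @param config a `run_config`.
#' @param stages `"all"` or a subset of `c("data", "split", "pretrain",
#'   "train", "evaluate", "attribute", "sample_factors")`; earlier stages must
#'   have run (their artifacts are reloaded from disk).
#' @param resume skip stages whose outputs already exist.
#' @return the run directory path (invisibly). On stage failure a `FAILED`
#'   marker naming the stage is written before the error propagates.
#' @export
run_experiment <- function(config, stages = "all", resume = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("data", "split", "pretrain", "train", "evaluate",
                  "attribute", "sample_factors")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  env <- new.env(parent = emptyenv())
  for (stage in all_stages) {
    needed <- stage %in% stages
    t0 <- as.numeric(Sys.time())
    seed <- derive_seed(config$master_seed, stage)
    tryCatch(
      run_stage(stage, config, env, seed, execute = needed, resume = resume),
      error = function(e) {
        writeLines(paste0("FAILED at stage: ", stage, " -- ",
                          conditionMessage(e)),
                   file.path(config$out_dir, "FAILED"))
        stop(e)
      })
    if (needed) log_stage(config$out_dir, stage, seed, t0)
  }
  invisible(config$out_dir)
}

run_stage <- function(stage, config, env, seed, execute, resume) {
  dir <- config$out_dir
  path <- function(...) file.path(dir, ...)
  switch(stage,
    data = {
      if (config$mode == "simulate") {
        ev_path <- path("events.csv")
        if (execute && !(resume && file.exists(ev_path))) {
          gen_cfg <- config$generator
          gen_cfg$seed <- seed
          sim <- generate_cohort(gen_cfg)
          write_event_table(sim$events, ev_path)
          write_ground_truth(sim$truth, path("ground_truth.json"))
          env$truth <- sim$truth
        }
        events <- load_event_table(ev_path, config$dialect)
      } else {
        events <- load_event_table(config$events_path, config$dialect)
      }
      env$cohort <- build_cohort(events, abnormal_only = config$abnormal_only)
    },
    split = {
      man <- path("splits.json")
      if (execute && !(resume && file.exists(man))) {
        splits <- split_cohort(names(env$cohort), config$ratios, seed = seed)
        write_split_manifest(splits, man)
      }
      env$splits <- read_split_manifest(man)
      env$prepared <- prepare_cohort(env$cohort)
      train_cohort <- cohort_subset(env$prepared, env$splits$train)
      env$vocabs <- build_vocabularies(train_cohort)
      assert_no_leakage(env$vocabs, env$splits, "vocabulary")
    },
    pretrain = {
      train_cohort <- cohort_subset(env$prepared, env$splits$train)
      if (any(vapply(config$variants, uses_latent, logical(1)))) {
        ck <- path("corrnet.rds")
        if (execute && !(resume && file.exists(ck))) {
          cn_cfg <- config$corrnet
          cn_cfg$seed <- seed
          net <- train_corrnet(train_cohort, env$vocabs, cn_cfg)
          saveRDS(net, ck)
          jsonlite::write_json(
            list(latent_dim = net$latent_dim, lambda = net$lambda,
                 seed = cn_cfg$seed, epochs = cn_cfg$epochs,
                 final_loss = tail(attr(net, "trace")$loss, 1)),
            path("corrnet_meta.json"), auto_unbox = TRUE, digits = NA)
        }
        env$corrnet <- readRDS(ck)
        assert_no_leakage(env$corrnet, env$splits, "correlational network")
      }
      if (any(vapply(config$variants, uses_autoencoder, logical(1)))) {
        ak <- path("autoencoder.rds")
        if (execute && !(resume && file.exists(ak))) {
          ae <- train_autoencoder(train_cohort, env$vocabs,
                                  hidden = config$encoder$autoencoder_hidden,
                                  seed = seed)
          saveRDS(ae, ak)
        }
        env$autoencoder <- readRDS(ak)
        assert_no_leakage(env$autoencoder, env$splits, "autoencoder")
      }
    },
    train = {
      env$models <- list()
      preds <- list()
      for (variant in config$variants) {
        enc_cfg <- config$encoder
        enc_cfg$variant <- variant
        for (s in seq_len(config$n_seeds)) {
          tag <- sprintf("%s_seed%d", variant, s)
          ck <- path(paste0("model_", tag, ".rds"))
          if (execute && !(resume && file.exists(ck))) {
            cl_cfg <- config$classifier
            cl_cfg$seed <- derive_seed(seed, tag)
            fit <- train_clout(env$cohort, env$splits, enc_cfg, cl_cfg,
                               corrnet = env$corrnet,
                               autoencoder = env$autoencoder)
            saveRDS(fit, ck)
          }
          fit <- readRDS(ck)
          assert_no_leakage(fit$model, env$splits, tag)
          env$models[[tag]] <- fit
          for (split in c("validation", "test")) {
            tls <- unclass(env$prepared)[intersect(env$splits[[split]],
                                                   names(env$prepared))]
            p <- predict_cohort(fit$model, tls)
            preds[[paste(tag, split)]] <- data.frame(
              patient_id = names(p), probability = unname(p),
              label = vapply(tls, `[[`, integer(1), "mortality"),
              split = split, variant = variant, seed = s,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (execute) {
        utils::write.csv(do.call(rbind, preds), path("predictions.csv"),
                         row.names = FALSE)
      }
      env$predictions <- do.call(rbind, preds)
    },
    evaluate = {
      pr <- env$predictions
      test <- pr[pr$split == "test", ]
      per_variant <- lapply(config$variants, function(v) {
        sub <- test[test$variant == v, ]
        aucs <- vapply(unique(sub$seed), function(s) {
          w <- sub[sub$seed == s, ]
          auroc(w$probability, w$label)
        }, numeric(1))
        first <- sub[sub$seed == unique(sub$seed)[1], ]
        prf <- confusion_and_prf(as.integer(first$probability >= 0.5),
                                 first$label)
        list(variant = v, auroc_mean = mean(aucs),
             auroc_sd = if (length(aucs) > 1) stats::sd(aucs) else NA,
             auroc_by_seed = aucs, counts = as.list(prf$counts),
             prf = cbind(class = rownames(prf$metrics), prf$metrics))
      })
      names(per_variant) <- config$variants
      report <- list(metrics = per_variant)
      if (length(config$variants) > 1 && config$n_seeds > 1) {
        a <- per_variant[[config$variants[1]]]$auroc_by_seed
        b <- per_variant[[config$variants[2]]]$auroc_by_seed
        report$variant_t_test <- two_sample_t_test(a, b)
      }
      if (execute) {
        jsonlite::write_json(report, path("metrics.json"), auto_unbox = TRUE,
                             digits = NA)
      }
      env$report <- report
    },
    attribute = {
      tag <- sprintf("%s_seed1", tail(config$variants, 1))
      model <- env$models[[tag]]$model
      ids <- env$splits[[config$attribution_split]]
      tls <- unclass(env$prepared)[intersect(ids, names(env$prepared))]
      if (execute && !(resume && file.exists(path("attribution.csv")))) {
        pop <- population_risk_factors(model, tls)
        # the review patient is drawn among patients documenting enough
        # distinct features to satisfy every bin of the patient plan
        plan <- config$patient_plan
        n_feat <- vapply(tls, function(tl) {
          nrow(documented_features(tl, model$vocabs))
        }, integer(1))
        feasible <- vapply(n_feat, function(n) {
          all(vapply(seq_along(plan$bins), function(b) {
            lo <- plan$bins[[b]][1]
            hi <- min(plan$bins[[b]][2], n)
            hi - lo + 1 >= plan$draws[b]
          }, logical(1)))
        }, logical(1))
        if (!any(feasible)) {
          stop("no patient in the ", config$attribution_split,
               " split documents enough features for the patient sampling plan")
        }
        sample_patient <- withr::with_seed(seed,
                                           sample(names(tls)[feasible], 1))
        pat <- patient_risk_factors(model, tls[[sample_patient]])
        pat$support <- NA_integer_
        pat$scope <- "patient"
        pop_df <- pop$pooled
        pop_df$scope <- "population"
        out <- rbind(pat[, c("scope", "view", "code", "weight", "support",
                             "rank")],
                     pop_df[, c("scope", "view", "code", "weight", "support",
                                "rank")])
        utils::write.csv(out, path("attribution.csv"), row.names = FALSE)
        saveRDS(list(patient = pat, population = pop,
                     patient_id = sample_patient), path("attribution.rds"))
      }
      env$attribution <- readRDS(path("attribution.rds"))
    },
    sample_factors = {
      if (execute && !(resume && file.exists(path("review_features.csv")))) {
        sel <- stratified_sample_features(
          env$attribution$patient, env$attribution$population$per_view,
          patient_plan = config$patient_plan,
          population_plan = config$population_plan,
          seed = seed)
        utils::write.csv(sel, path("review_features.csv"), row.names = FALSE)
        prov <- attr(sel, "provenance")
        jsonlite::write_json(list(seed = seed, provenance = prov),
                             path("review_sidecar.json"), auto_unbox = TRUE,
                             digits = NA)
      }
    })
  invisible(NULL)
}
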