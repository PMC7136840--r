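# Attention pooling, sequence classifier, training loop, logistic baseline.

test_that("attention weights: singleton, symmetry, simplex, scalar oracle", {
  pars <- attn_params()
  h1 <- matrix(rnorm(3), 1, 3)
  out1 <- attention_pool(h1, pars)
  expect_equal(out1$weights, 1)
  expect_equal(out1$context, drop(h1))
  h2 <- rbind(h1, h1)
  out2 <- attention_pool(h2, pars)
  expect_equal(out2$weights, c(0.5, 0.5))
  set.seed(2)
  for (rep in 1:20) {
    h <- matrix(rnorm(15), 5, 3)
    out <- attention_pool(h, pars)
    expect_equal(sum(out$weights), 1, tolerance = 1e-6)
    expect_true(all(out$weights >= 0))
    # independent scalar computation
    s <- vapply(1:5, function(i) {
      sum(tanh(colSums(h[i, ] * pars$W) + pars$b) * pars$u)
    }, numeric(1))
    a <- exp(s) / sum(exp(s))
    expect_equal(out$weights, a, tolerance = 1e-10)
    expect_equal(out$context, colSums(a * h), tolerance = 1e-10)
  }
})

test_that("zeroed output layer predicts exactly 1/2 for any patient", {
  vocabs <- vocabs_from_codes(diagnosis = c("A", "B"), medication = "M",
                              lab = "L")
  model <- surrogate_clout(vocabs)
  model$params$wo[] <- 0
  model$params$bo <- 0
  tl <- make_timeline("p", list(list(diagnosis = "A"),
                                list(diagnosis = "B", medication = "M")))
  expect_equal(predict_mortality(model, tl), 0.5)
})

test_that("predictions are invariant to trailing padding and code storage order", {
  vocabs <- vocabs_from_codes(diagnosis = c("A", "B", "C"), medication = "M",
                              lab = "L")
  model <- surrogate_clout(vocabs)
  short <- make_timeline("s", list(list(diagnosis = c("A", "C")),
                                   list(medication = "M")))
  long <- make_timeline("l", replicate(5, list(list(diagnosis = "B")),
                                       simplify = FALSE))
  p_alone <- predict_mortality(model, short)
  # batching with a longer patient forces padded positions for `short`
  p_batch <- predict_cohort(model, list(s = short, l = long))
  expect_equal(unname(p_batch["s"]), p_alone, tolerance = 1e-7)
  expect_equal(unname(p_batch["l"]), predict_mortality(model, long),
               tolerance = 1e-7)
  # storage order of codes within an encounter is immaterial
  shuffled <- short
  shuffled$encounters[[1]]$codes$diagnosis <- c("C", "A")
  expect_equal(predict_mortality(model, shuffled), p_alone)
  empty <- short
  empty$encounters <- list()
  expect_error(predict_mortality(model, empty), "empty")
})

test_that("the forward pass matches a step-by-step scalar oracle", {
  vocabs <- vocabs_from_codes(diagnosis = c("A", "B"), medication = c("M1", "M2"),
                              lab = "L")
  sizes <- sapply(vocabs, `[[`, "size")
  cn <- corrnet_init(sizes, corrnet_config(latent_dim = 2, seed = 9))
  for (variant in c("simple_concat", "latent_concat")) {
    model <- surrogate_clout(vocabs, variant = variant,
                             time_feature = "since_first",
                             corrnet = if (variant == "latent_concat") cn)
    tl1 <- make_timeline("p", list(list(diagnosis = "A", lab = "L")))
    expect_equal(predict_mortality(model, tl1), oracle_clout_predict(model, tl1),
                 tolerance = 1e-8)
    tl3 <- make_timeline("q", list(list(diagnosis = c("A", "B")),
                                   list(medication = "M2"),
                                   list(diagnosis = "B", medication = "M1",
                                        lab = "L")))
    expect_equal(predict_mortality(model, tl3), oracle_clout_predict(model, tl3),
                 tolerance = 1e-8)
  }
})

test_that("classifier gradients agree with finite differences", {
  vocabs <- vocabs_from_codes(diagnosis = c("A", "B", "C"),
                              medication = c("M1", "M2"), lab = "L")
  sizes <- sapply(vocabs, `[[`, "size")
  cn <- corrnet_init(sizes, corrnet_config(latent_dim = 2, seed = 4))
  ec <- encoder_config(variant = "latent_concat",
                       embedding_dims = c(diagnosis = 2, medication = 2, lab = 1),
                       time_feature = "since_first", seed = 4)
  cc <- clout_config(hidden_dim = 3, attention_dim = 2, seed = 4)
  tls <- list(
    a = make_timeline("a", list(list(diagnosis = "A"), list(medication = "M1"))),
    b = make_timeline("b", list(list(diagnosis = c("B", "C"), lab = "L"))),
    c = make_timeline("c", list(list(medication = "M2"), list(diagnosis = "A"),
                                list(lab = "L")), mortality = 0L))
  data <- clout:::prepare_tensors(tls, vocabs, ec, corrnet = cn)
  idim <- encounter_vector_length(ec, latent_dim = 2)
  pars <- clout:::clout_init_params(idim, vocabs, ec, cc)
  set.seed(40)  # keep every rectifier input off its kink
  pars <- lapply(pars, function(p) p + rnorm(length(p), sd = 0.1))
  out <- clout:::clout_batch(pars, data, ec, y = data$y, want_grad = TRUE)
  eps <- 1e-6
  for (nm in names(pars)) {
    probe <- seq_len(min(length(pars[[nm]]), 5))
    for (i in probe) {
      p2 <- pars
      p2[[nm]][i] <- pars[[nm]][i] + eps
      lp <- clout:::clout_batch(p2, data, ec, y = data$y, want_grad = TRUE)$loss
      p2[[nm]][i] <- pars[[nm]][i] - eps
      lm <- clout:::clout_batch(p2, data, ec, y = data$y, want_grad = TRUE)$loss
      expect_equal(out$grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("training is reproducible and learns the planted signal", {
  sim <- generate_cohort(small_gen_config(seed = 81, n_patients = 200))
  splits <- split_cohort(names(sim$cohort), seed = 2)
  ec <- encoder_config(variant = "simple_concat",
                       embedding_dims = c(diagnosis = 8, medication = 8, lab = 4))
  cc <- clout_config(hidden_dim = 16, attention_dim = 8, epochs = 40,
                     batch_size = 32, seed = 6)
  fit1 <- train_clout(sim$cohort, splits, ec, cc)
  fit2 <- train_clout(sim$cohort, splits, ec, cc)
  expect_identical(fit1$report, fit2$report)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(fit1$report$selected_epoch, which.max(fit1$report$val_auroc))
  prep <- clout:::prepare_cohort(sim$cohort)
  test_tl <- unclass(prep)[intersect(splits$test, names(prep))]
  p <- predict_cohort(fit1$model, test_tl)
  expect_gt(auroc(p, vapply(test_tl, `[[`, integer(1), "mortality")), 0.7)
})

test_that("retraining on the merged split uses the selected epoch budget", {
  sim <- generate_cohort(small_gen_config(seed = 82, n_patients = 120))
  splits <- split_cohort(names(sim$cohort), seed = 3)
  ec <- encoder_config(variant = "simple_concat",
                       embedding_dims = c(diagnosis = 4, medication = 4, lab = 2))
  cc <- clout_config(hidden_dim = 8, attention_dim = 4, epochs = 4,
                     batch_size = 64, retrain_on_merged = TRUE, seed = 7)
  fit <- train_clout(sim$cohort, splits, ec, cc)
  expect_true(fit$report$retrained_on_merged)
  expect_setequal(attr(fit$model, "fit_ids"),
                  intersect(merge_train_validation(splits), names(sim$cohort)))
})

test_that("training fails fast without a validation split or required encoders", {
  sim <- generate_cohort(small_gen_config(seed = 83, n_patients = 60))
  splits <- split_cohort(names(sim$cohort), seed = 4)
  splits$validation <- character(0)
  expect_error(train_clout(sim$cohort, splits, encoder_config("simple_concat"),
                           clout_config(epochs = 1)),
               "validation")
  splits2 <- split_cohort(names(sim$cohort), seed = 4)
  expect_error(train_clout(sim$cohort, splits2, encoder_config("latent_concat"),
                           clout_config(epochs = 1)),
               "corrnet")
  expect_error(train_clout(sim$cohort, splits2, encoder_config("ae_only"),
                           clout_config(epochs = 1)),
               "autoencoder")
})

test_that("patient feature aggregation is the elementwise OR of encounters", {
  vocabs <- vocabs_from_codes(diagnosis = c("A", "B"), medication = c("M1", "M2"),
                              lab = "L")
  one <- make_timeline("p", list(list(diagnosis = "A", lab = "L")))
  x1 <- aggregate_patient_features(one, vocabs)
  mh <- encode_encounter(one$encounters[[1]], vocabs)
  expect_equal(x1, unlist(mh[views3], use.names = FALSE))
  two <- make_timeline("q", list(list(diagnosis = "A"),
                                 list(medication = "M2")))
  x2 <- aggregate_patient_features(two, vocabs)
  expect_equal(x2, c(1, 0, 0, 1, 0))
  # popcount of the union dominates any single encounter
  for (enc in two$encounters) {
    expect_gte(sum(x2), sum(unlist(encode_encounter(enc, vocabs)[views3])))
  }
})

test_that("ridge baseline: shrinkage limit, separating sign, determinism", {
  vocabs <- vocabs_from_codes(diagnosis = c("RISK", "NOISE"),
                              medication = character(), lab = character())
  tls <- list(
    a = make_timeline("a", list(list(diagnosis = "RISK"),
                                list(diagnosis = "RISK")), mortality = 1L),
    b = make_timeline("b", list(list(diagnosis = c("RISK", "NOISE")),
                                list(diagnosis = "RISK")), mortality = 1L),
    c = make_timeline("c", list(list(diagnosis = "NOISE"), list()), mortality = 0L),
    d = make_timeline("d", list(list(), list()), mortality = 0L))
  cohort <- structure(tls, class = "ehr_cohort")
  risk_col <- vocab_index(vocabs$diagnosis, "RISK")
  m_small <- suppressWarnings(
    train_logistic_baseline(cohort, names(tls), vocabs, l2 = 1e-3))
  expect_gt(m_small$weights[risk_col], 0)   # RISK separates the classes
  m_big <- suppressWarnings(
    train_logistic_baseline(cohort, names(tls), vocabs, l2 = 1e4))
  expect_lt(max(abs(m_big$weights)), 1e-3)
  expect_equal(predict_mortality(m_big, clout:::prepare_cohort(cohort)$a),
               0.5, tolerance = 0.01)  # prevalence logit at w ~ 0
  m2 <- suppressWarnings(
    train_logistic_baseline(cohort, names(tls), vocabs, l2 = 1e-3))
  expect_identical(m_small$weights, m2$weights)
  # degenerate single-class training set
  mono <- cohort
  for (i in seq_along(mono)) mono[[i]]$mortality <- 1L
  expect_error(train_logistic_baseline(mono, names(mono), vocabs),
               "single outcome class")
})
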