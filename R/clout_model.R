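# Attention-pooled LSTM mortality classifier.
#
# Encounter vectors e_1..e_n (built per the configured variant) are run
# through a single-layer LSTM; the hidden states h_1..h_n are pooled by
# additive attention, H = a_1 h_1 + ... + a_n h_n with softmax weights
# a_i over the real (unmasked) encounters; a linear layer plus sigmoid turns
# H into the predicted probability of death. Training minimises mean binary
# cross-entropy with Adam; embeddings are trained jointly with the classifier
# while the correlational network / autoencoder stay frozen. All gradients are
# hand-derived and checked against finite differences in the test suite.

#' Classifier configuration
#'
#' @param hidden_dim LSTM hidden state size.
#' @param attention_dim size of the attention scoring layer.
#' @param dropout dropout probability applied to the encounter vectors during
#'   training (0 disables it).
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size (patients).
#' @param learning_rate Adam step size.
#' @param early_stopping_patience stop after this many epochs without
#'   improvement in validation AUROC.
#' @param retrain_on_merged after selecting the epoch budget on the validation
#'   split, retrain for that budget on the combined train+validation set.
#' @param seed integer seed (initialisation, shuffling, dropout).
#' @return a `clout_config` list.
#' @export
clout_config <- function(hidden_dim = 128L, attention_dim = 64L, dropout = 0,
                         epochs = 100L, batch_size = 128L,
                         learning_rate = 1e-3, early_stopping_patience = 5L,
                         retrain_on_merged = FALSE, seed = 1L) {
  stopifnot(hidden_dim >= 1, attention_dim >= 1, dropout >= 0, dropout < 1,
            epochs >= 1, batch_size >= 1, early_stopping_patience >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 attention_dim = as.integer(attention_dim), dropout = dropout,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 retrain_on_merged = isTRUE(retrain_on_merged),
                 seed = as.integer(seed)),
            class = "clout_config")
}

# ---- parameter initialisation ------------------------------------------------

clout_init_params <- function(input_dim, vocabs, enc_config, clout_config) {
  H <- clout_config$hidden_dim
  A <- clout_config$attention_dim
  withr::with_seed(derive_seed(clout_config$seed, "clout_init"), {
    pars <- list(
      Wx = matrix(rnorm(input_dim * 4 * H, sd = 1 / sqrt(input_dim)),
                  input_dim, 4 * H),
      Wh = matrix(rnorm(H * 4 * H, sd = 1 / sqrt(H)), H, 4 * H),
      b = c(numeric(H), rep(1, H), numeric(2 * H)),  # forget-gate bias 1
      Wa = matrix(rnorm(H * A, sd = 1 / sqrt(H)), H, A),
      ba = numeric(A),
      u = rnorm(A, sd = 1 / sqrt(A)),
      wo = matrix(rnorm(H, sd = 1 / sqrt(H)), H, 1),
      bo = 0
    )
    if (uses_embeddings(enc_config$variant)) {
      emb <- init_embedding_params(vocabs, enc_config)
      for (v in .views) {
        pars[[paste0("E_", v)]] <- emb[[v]]$E
        pars[[paste0("bE_", v)]] <- emb[[v]]$b
      }
    }
    pars
  })
}

# ---- batched tensors ---------------------------------------------------------

# Stack prepared timelines into time-major tensors: row (t-1)*B + b holds
# patient b at encounter t. Frozen features (corrnet latent / autoencoder
# hidden) are precomputed here once.
prepare_tensors <- function(timelines, vocabs, enc_config, corrnet = NULL,
                            autoencoder = NULL) {
  B <- length(timelines)
  stopifnot(B >= 1)
  lens <- vapply(timelines, function(tl) length(tl$encounters), integer(1))
  stopifnot(all(lens >= 1))
  Tm <- max(lens)
  X <- lapply(.views, function(v) matrix(0, B * Tm, vocabs[[v]]$size))
  names(X) <- .views
  mask <- matrix(0, B, Tm)
  timev <- numeric(B * Tm)
  y <- vapply(timelines, `[[`, integer(1), "mortality")
  for (b in seq_len(B)) {
    tl <- timelines[[b]]
    for (t in seq_len(lens[b])) {
      row <- (t - 1) * B + b
      enc <- tl$encounters[[t]]
      for (v in .views) {
        idx <- vocab_index(vocabs[[v]], enc$codes[[v]])
        idx <- idx[!is.na(idx)]
        if (length(idx)) X[[v]][row, idx] <- 1
      }
      mask[b, t] <- 1
      timev[row] <- switch(enc_config$time_feature,
                           none = 0,
                           since_first = enc$elapsed_first,
                           since_previous = enc$elapsed_prev) / 365
    }
  }
  frozen <- NULL
  if (uses_latent(enc_config$variant)) {
    stopifnot(!is.null(corrnet))
    frozen <- corrnet_encode(X, corrnet)
  } else if (uses_autoencoder(enc_config$variant)) {
    stopifnot(!is.null(autoencoder))
    frozen <- autoencoder_hidden(do.call(cbind, X), autoencoder)
  }
  list(X = X, mask = mask, time = timev, frozen = frozen, y = y,
       ids = names(timelines), B = B, Tm = Tm, lens = lens)
}

# extract a patient subset from time-major tensors
tensor_subset <- function(data, sel) {
  B <- data$B
  rows <- rep((seq_len(data$Tm) - 1) * B, each = length(sel)) + sel
  list(X = lapply(data$X, function(m) m[rows, , drop = FALSE]),
       mask = data$mask[sel, , drop = FALSE],
       time = data$time[rows],
       frozen = if (is.null(data$frozen)) NULL else
         data$frozen[rows, , drop = FALSE],
       y = data$y[sel], ids = data$ids[sel],
       B = length(sel), Tm = data$Tm, lens = data$lens[sel])
}

# ---- forward / backward ------------------------------------------------------

# One pass over a batch. Returns predictions; with want_grad also the mean-BCE
# loss and gradients for every trainable parameter. dropout_mask, if given,
# multiplies the encounter vectors (inverted dropout, precomputed by caller).
clout_batch <- function(pars, data, enc_config, y = NULL, want_grad = FALSE,
                        dropout_mask = NULL) {
  B <- data$B; Tm <- data$Tm
  H <- nrow(pars$Wh)
  use_ec <- uses_embeddings(enc_config$variant)
  use_time <- enc_config$time_feature != "none"
  dims <- enc_config$embedding_dims

  parts <- list()
  if (!is.null(data$frozen)) parts$frozen <- data$frozen
  Ec <- NULL
  if (use_ec) {
    pre <- do.call(cbind, lapply(.views, function(v) {
      add_bias(data$X[[v]] %*% pars[[paste0("E_", v)]], pars[[paste0("bE_", v)]])
    }))
    Ec <- relu(pre)
    parts$e_c <- Ec
  }
  if (use_time) parts$time <- matrix(data$time, ncol = 1)
  e <- do.call(cbind, parts)
  if (!is.null(dropout_mask)) e <- e * dropout_mask
  fz_width <- if (is.null(data$frozen)) 0L else ncol(data$frozen)

  # LSTM forward (time-major blocks of B rows)
  Zx <- e %*% pars$Wx
  hprev <- cprev <- matrix(0, B, H)
  I <- Fg <- O <- G <- tC <- Hs <- Hprev <- Cprev <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    idx <- ((t - 1) * B + 1):(t * B)
    Z <- add_bias(Zx[idx, , drop = FALSE] + hprev %*% pars$Wh, pars$b)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, H + 1:H, drop = FALSE])
    o <- sigmoid(Z[, 2 * H + 1:H, drop = FALSE])
    g <- tanh(Z[, 3 * H + 1:H, drop = FALSE])
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[[t]] <- i; Fg[[t]] <- f; O[[t]] <- o; G[[t]] <- g; tC[[t]] <- tc
    Hprev[[t]] <- hprev; Cprev[[t]] <- cprev
    Hs[[t]] <- h
    hprev <- h; cprev <- cc
  }

  # additive attention over unmasked positions
  S <- matrix(-Inf, B, Tm)
  Ms <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    M <- tanh(add_bias(Hs[[t]] %*% pars$Wa, pars$ba))
    Ms[[t]] <- M
    S[, t] <- drop(M %*% pars$u)
  }
  S[data$mask == 0] <- -Inf
  smax <- S[, 1]
  if (Tm > 1) for (t in 2:Tm) smax <- pmax(smax, S[, t])
  A <- exp(S - smax)
  A[data$mask == 0] <- 0
  A <- A / rowSums(A)
  Hc <- matrix(0, B, H)
  for (t in seq_len(Tm)) Hc <- Hc + A[, t] * Hs[[t]]

  logit <- drop(Hc %*% pars$wo) + pars$bo
  p <- sigmoid(logit)

  if (!want_grad) {
    return(list(p = p, attention = A))
  }
  stopifnot(!is.null(y))
  loss <- -mean(y * safe_log(p) + (1 - y) * safe_log(1 - p))

  grads <- lapply(pars, function(x) x * 0)
  dlogit <- (p - y) / B
  grads$wo <- crossprod(Hc, dlogit)
  grads$bo <- sum(dlogit)
  dHc <- outer(dlogit, drop(pars$wo))

  dA <- matrix(0, B, Tm)
  for (t in seq_len(Tm)) dA[, t] <- rowSums(dHc * Hs[[t]])
  dS <- A * (dA - rowSums(A * dA))
  dH_att <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    dM <- outer(dS[, t], pars$u)
    dpre <- dM * (1 - Ms[[t]]^2)
    grads$Wa <- grads$Wa + crossprod(Hs[[t]], dpre)
    grads$ba <- grads$ba + colSums(dpre)
    grads$u <- grads$u + drop(crossprod(Ms[[t]], dS[, t]))
    dH_att[[t]] <- A[, t] * dHc + tcrossprod(dpre, pars$Wa)
  }

  dZ_all <- matrix(0, B * Tm, 4 * H)
  dh_rec <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tm))) {
    m <- data$mask[, t]
    dh <- (dH_att[[t]] + dh_rec) * m
    dc <- dc_next + dh * O[[t]] * (1 - tC[[t]]^2)
    do_ <- dh * tC[[t]]
    di <- dc * G[[t]]
    dg <- dc * I[[t]]
    df <- dc * Cprev[[t]]
    dc_next <- dc * Fg[[t]]
    dZ <- cbind(di * I[[t]] * (1 - I[[t]]),
                df * Fg[[t]] * (1 - Fg[[t]]),
                do_ * O[[t]] * (1 - O[[t]]),
                dg * (1 - G[[t]]^2)) * m
    idx <- ((t - 1) * B + 1):(t * B)
    dZ_all[idx, ] <- dZ
    grads$Wh <- grads$Wh + crossprod(Hprev[[t]], dZ)
    dh_rec <- tcrossprod(dZ, pars$Wh)
  }
  grads$Wx <- crossprod(e, dZ_all)
  grads$b <- colSums(dZ_all)

  if (use_ec) {
    dE <- tcrossprod(dZ_all, pars$Wx)
    if (!is.null(dropout_mask)) dE <- dE * dropout_mask
    dEc <- dE[, fz_width + seq_len(sum(dims)), drop = FALSE] * (Ec > 0)
    off <- 0L
    for (v in .views) {
      cols <- off + seq_len(dims[[v]])
      grads[[paste0("E_", v)]] <- crossprod(data$X[[v]],
                                            dEc[, cols, drop = FALSE])
      grads[[paste0("bE_", v)]] <- colSums(dEc[, cols, drop = FALSE])
      off <- off + dims[[v]]
    }
  }
  list(p = p, attention = A, loss = loss, grads = grads)
}

# ---- public ops --------------------------------------------------------------

#' Attention pooling of a sequence of hidden vectors
#'
#' Scores `s_i = u . tanh(W h_i + b)`, weights `a = softmax(s)`, pooled
#' context `H = sum_i a_i h_i`.
#'
#' @param h an `n x hidden_dim` matrix, one row per encounter.
#' @param params list with `W` (`hidden_dim x attention_dim`), `b`
#'   (`attention_dim`) and `u` (`attention_dim`).
#' @return list with `weights` (length n, nonnegative, summing to 1) and
#'   `context` (length `hidden_dim`).
#' @export
attention_pool <- function(h, params) {
  stopifnot(is.matrix(h), nrow(h) >= 1)
  s <- drop(tanh(add_bias(h %*% params$W, params$b)) %*% params$u)
  a <- exp(s - max(s))
  a <- a / sum(a)
  list(weights = a, context = drop(crossprod(h, a)))
}

#' Predict the probability of death for a patient
#'
#' @param model a trained `clout_model` or `logistic_baseline`.
#' @param timeline a `patient_timeline` that has already been passed through
#'   [prepare_model_input()].
#' @param ... unused.
#' @return the predicted probability `p` in (0, 1).
#' @export
predict_mortality <- function(model, timeline, ...) {
  UseMethod("predict_mortality")
}

#' @export
predict_mortality.clout_model <- function(model, timeline, ...) {
  if (length(timeline$encounters) < 1) stop("empty encounter sequence")
  predict_cohort(model, list(tl = timeline))[[1]]
}

#' Predict probabilities for many prepared timelines at once
#'
#' @param model a trained `clout_model` or `logistic_baseline`.
#' @param timelines list of prepared `patient_timeline`s.
#' @return named numeric vector of probabilities.
#' @export
predict_cohort <- function(model, timelines) {
  UseMethod("predict_cohort")
}

#' @export
predict_cohort.clout_model <- function(model, timelines) {
  data <- prepare_tensors(timelines, model$vocabs, model$encoder_config,
                          corrnet = model$corrnet,
                          autoencoder = model$autoencoder)
  out <- clout_batch(model$params, data, model$encoder_config)
  stats::setNames(out$p, data$ids)
}

#' Train the attention-pooled LSTM classifier
#'
#' Minimises mean binary cross-entropy with Adam, evaluating AUROC on the
#' validation split after every epoch; training stops early after
#' `early_stopping_patience` epochs without improvement and the parameters of
#' the best validation epoch are kept. With `retrain_on_merged = TRUE` the
#' selected epoch budget is then used to retrain from scratch on the combined
#' train+validation set (the protocol used after hyperparameter selection).
#'
#' @param cohort an `ehr_cohort` (full timelines; the final encounter of every
#'   patient is removed internally before training).
#' @param splits a `cohort_splits`.
#' @param enc_config an [encoder_config()].
#' @param config a [clout_config()].
#' @param corrnet a trained [corrnet] (required by latent variants; frozen).
#' @param autoencoder a [clout_autoencoder] (required by autoencoder variants;
#'   frozen).
#' @param vocabs vocabularies; built from the training split when `NULL`.
#' @return list with `model` (a `clout_model`) and `report` (per-epoch
#'   training loss and validation AUROC, the selected epoch, and the seed).
#' @export
train_clout <- function(cohort, splits, enc_config = encoder_config(),
                        config = clout_config(), corrnet = NULL,
                        autoencoder = NULL, vocabs = NULL) {
  prepared <- prepare_cohort(cohort)
  train_tl <- unclass(prepared)[intersect(splits$train, names(prepared))]
  val_tl <- unclass(prepared)[intersect(splits$validation, names(prepared))]
  if (length(train_tl) == 0) stop("empty training split")
  if (length(val_tl) == 0) {
    stop("validation split is empty but early stopping is requested")
  }
  if (is.null(vocabs)) {
    vocabs <- build_vocabularies(cohort_subset(prepared, splits$train))
  }
  if (uses_latent(enc_config$variant) && is.null(corrnet)) {
    stop("variant '", enc_config$variant, "' requires trained corrnet parameters")
  }
  if (uses_autoencoder(enc_config$variant) && is.null(autoencoder)) {
    stop("variant '", enc_config$variant,
         "' requires trained autoencoder parameters")
  }

  input_dim <- encounter_vector_length(
    enc_config, latent_dim = if (!is.null(corrnet)) corrnet$latent_dim)
  data_train <- prepare_tensors(train_tl, vocabs, enc_config, corrnet,
                                autoencoder)
  data_val <- prepare_tensors(val_tl, vocabs, enc_config, corrnet, autoencoder)

  fit <- clout_fit_loop(data_train, data_val, input_dim, vocabs, enc_config,
                        config)
  report <- fit$report
  params <- fit$best_params

  if (config$retrain_on_merged) {
    merged_ids <- intersect(merge_train_validation(splits), names(prepared))
    data_merged <- prepare_tensors(unclass(prepared)[merged_ids], vocabs,
                                   enc_config, corrnet, autoencoder)
    refit <- clout_fit_loop(data_merged, NULL, input_dim, vocabs, enc_config,
                            config, fixed_epochs = report$selected_epoch)
    params <- refit$best_params
    report$retrained_on_merged <- TRUE
    fit_ids <- merged_ids
  } else {
    fit_ids <- names(train_tl)
  }

  model <- structure(
    list(variant = enc_config$variant, params = params,
         encoder_config = enc_config, clout_config = config, vocabs = vocabs,
         corrnet = corrnet, autoencoder = autoencoder, input_dim = input_dim),
    class = "clout_model")
  attr(model, "fit_ids") <- sort(fit_ids)
  list(model = model, report = report)
}

# core epoch loop; data_val = NULL disables early stopping (fixed_epochs used)
clout_fit_loop <- function(data_train, data_val, input_dim, vocabs, enc_config,
                           config, fixed_epochs = NULL) {
  pars <- clout_init_params(input_dim, vocabs, enc_config, config)
  state <- adam_init(pars)
  n <- data_train$B
  max_epochs <- if (is.null(fixed_epochs)) config$epochs else fixed_epochs
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best_params <- pars
  best_auroc <- -Inf
  stale <- 0L
  withr::with_seed(derive_seed(config$seed, "clout_train"), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(n)
      tot <- 0; nb <- 0L
      for (s in seq(1, n, by = config$batch_size)) {
        sel <- ord[s:min(s + config$batch_size - 1, n)]
        batch <- tensor_subset(data_train, sel)
        dmask <- NULL
        if (config$dropout > 0) {
          dmask <- matrix(rbinom(batch$B * batch$Tm * input_dim, 1,
                                 1 - config$dropout) / (1 - config$dropout),
                          batch$B * batch$Tm, input_dim)
        }
        out <- clout_batch(pars, batch, enc_config, y = batch$y,
                           want_grad = TRUE, dropout_mask = dmask)
        if (!is.finite(out$loss)) stop("non-finite training loss at epoch ", epoch)
        upd <- adam_step(pars, out$grads, state, lr = config$learning_rate)
        pars <- upd$params; state <- upd$state
        tot <- tot + out$loss; nb <- nb + 1L
      }
      loss_trace[epoch] <- tot / nb
      if (!is.null(data_val)) {
        pv <- clout_batch(pars, data_val, enc_config)$p
        val_trace[epoch] <- auroc(pv, data_val$y)
        if (val_trace[epoch] > best_auroc) {
          best_auroc <- val_trace[epoch]
          best_params <- pars
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$early_stopping_patience) break
        }
      } else {
        best_params <- pars
      }
    }
  })
  selected <- if (length(val_trace)) which.max(val_trace) else max_epochs
  list(best_params = best_params,
       report = list(loss = loss_trace, val_auroc = val_trace,
                     selected_epoch = selected, seed = config$seed))
}

#' @export
print.clout_model <- function(x, ...) {
  cat(sprintf("<clout_model> variant=%s input_dim=%d hidden=%d\n",
              x$variant, x$input_dim, x$clout_config$hidden_dim))
  invisible(x)
}

# ---- logistic-regression baseline -------------------------------------------

#' Aggregate a timeline into one multi-hot patient vector
#'
#' Elementwise OR of every encounter's concatenated (diagnosis, medication,
#' lab) indicator vectors — the bag-of-features input of the logistic
#' baseline, which cannot use temporal structure.
#'
#' @param timeline a prepared `patient_timeline`.
#' @param vocabs vocabularies.
#' @return 0/1 numeric vector of length `sum of vocabulary sizes`.
#' @export
aggregate_patient_features <- function(timeline, vocabs) {
  out <- unlist(lapply(.views, function(v) {
    x <- numeric(vocabs[[v]]$size)
    for (enc in timeline$encounters) {
      idx <- vocab_index(vocabs[[v]], enc$codes[[v]])
      idx <- idx[!is.na(idx)]
      if (length(idx)) x[idx] <- 1
    }
    x
  }), use.names = FALSE)
  out
}

#' Construct a logistic baseline model from explicit coefficients
#'
#' @param weights numeric vector over the concatenated
#'   (diagnosis, medication, lab) feature space.
#' @param intercept scalar intercept.
#' @param vocabs vocabularies defining the feature space.
#' @return a `logistic_baseline`.
#' @export
logistic_baseline <- function(weights, intercept, vocabs) {
  total <- sum(vapply(vocabs[.views], `[[`, integer(1), "size"))
  stopifnot(length(weights) == total)
  structure(list(weights = as.numeric(weights), intercept = intercept,
                 vocabs = vocabs),
            class = "logistic_baseline")
}

#' Train the l2-penalised logistic-regression baseline
#'
#' Ridge-penalised maximum likelihood (via glmnet) on aggregated per-patient
#' feature vectors.
#'
#' @param cohort an `ehr_cohort` (full timelines; last encounters are removed
#'   internally).
#' @param ids patient ids to train on (e.g. `splits$train` or the merged
#'   train+validation set).
#' @param vocabs vocabularies (built from the same training data).
#' @param l2 ridge penalty (glmnet `lambda` with `alpha = 0`).
#' @return a `logistic_baseline`.
#' @export
train_logistic_baseline <- function(cohort, ids, vocabs, l2 = 1e-2) {
  prepared <- prepare_cohort(cohort_subset(cohort, ids))
  y <- vapply(prepared, `[[`, integer(1), "mortality")
  if (length(unique(y)) < 2) {
    stop("training set contains a single outcome class")
  }
  X <- do.call(rbind, lapply(prepared, aggregate_patient_features,
                             vocabs = vocabs))
  fit <- glmnet::glmnet(Matrix::Matrix(X, sparse = TRUE), factor(y),
                        family = "binomial", alpha = 0, lambda = l2,
                        standardize = FALSE, thresh = 1e-10)
  beta <- as.numeric(fit$beta)
  model <- logistic_baseline(beta, as.numeric(fit$a0), vocabs)
  attr(model, "fit_ids") <- sort(names(prepared))
  model
}

#' @export
predict_mortality.logistic_baseline <- function(model, timeline, ...) {
  x <- aggregate_patient_features(timeline, model$vocabs)
  sigmoid(sum(model$weights * x) + model$intercept)
}

#' @export
predict_cohort.logistic_baseline <- function(model, timelines) {
  vapply(timelines, function(tl) predict_mortality(model, tl), numeric(1))
}
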