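# Three-view correlational network.
#
# A multi-view autoencoder over the per-encounter indicator vectors
# (v_d, v_m, v_lab) whose training objective adds, to the usual reconstruction
# terms, a reward for correlation between the latent encodings computed from
# each single view. The resulting shared latent space is the encounter-level
# "patient condition" summary that the classifier concatenates with the
# embedded views. Encoders are sigmoid with a shared latent bias; decoders are
# linear with mean-squared-error reconstruction (inputs are 0/1 indicators);
# a cross-entropy decoder is available behind `decoder = "logistic"`.

#' Correlational network configuration
#'
#' @param latent_dim dimension of the shared latent space.
#' @param lambda nonnegative weight of the cross-view correlation reward.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size (correlations are computed per minibatch).
#' @param decoder `"linear"` (mean-squared error, default) or `"logistic"`
#'   (sigmoid output with cross-entropy loss).
#' @param seed integer seed for initialisation and batch shuffling.
#' @return a `corrnet_config` list.
#' @export
corrnet_config <- function(latent_dim = 64L, lambda = 1, learning_rate = 1e-3,
                           epochs = 50L, batch_size = 128L,
                           decoder = c("linear", "logistic"), seed = 1L) {
  stopifnot(latent_dim >= 1, lambda >= 0, epochs >= 1, batch_size >= 2)
  structure(list(latent_dim = as.integer(latent_dim), lambda = lambda,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 decoder = match.arg(decoder), seed = as.integer(seed)),
            class = "corrnet_config")
}

#' Initialise correlational network parameters
#'
#' @param vocab_sizes named integer vector of per-view input dimensions.
#' @param config a [corrnet_config()].
#' @return a `corrnet` parameter object (untrained).
#' @export
corrnet_init <- function(vocab_sizes, config = corrnet_config()) {
  k <- config$latent_dim
  withr::with_seed(derive_seed(config$seed, "corrnet_init"), {
    params <- list(b = numeric(k))
    for (v in .views) {
      d <- vocab_sizes[[v]]
      params[[paste0("W_", v)]] <- matrix(rnorm(d * k, sd = 1 / sqrt(d)), d, k)
      params[[paste0("D_", v)]] <- matrix(rnorm(k * d, sd = 1 / sqrt(k)), k, d)
      params[[paste0("c_", v)]] <- numeric(d)
    }
    structure(list(params = params, latent_dim = k, lambda = config$lambda,
                   vocab_sizes = vocab_sizes, decoder = config$decoder,
                   config = config),
              class = "corrnet")
  })
}

# coerce a batch (list of multi_hot_views, or list of 3 matrices) to a named
# list of B x V_v matrices
as_view_matrices <- function(batch, vocab_sizes = NULL) {
  if (is.list(batch) && all(.views %in% names(batch)) &&
      is.matrix(batch[[1]])) {
    return(batch[.views])
  }
  stopifnot(length(batch) >= 1)
  out <- lapply(.views, function(v) {
    do.call(rbind, lapply(batch, function(mh) mh[[v]]))
  })
  stats::setNames(out, .views)
}

#' Project encounter views into the shared latent space
#'
#' Computes `l = sigmoid(sum_v W_v' x_v + b)` over the active views. With a
#' subset of views active, the inactive views simply contribute nothing to the
#' pre-activation (they are treated as all-zero).
#'
#' @param views a `multi_hot_views` (or named list of indicator vectors).
#' @param net a `corrnet`.
#' @param active character subset of views to include; defaults to all three.
#' @return numeric latent vector of length `latent_dim`.
#' @export
encode_views <- function(views, net, active = .views) {
  if (length(active) == 0) stop("encode_views: empty active view set")
  stopifnot(all(active %in% .views))
  pre <- net$params$b
  for (v in active) {
    pre <- pre + drop(crossprod(net$params[[paste0("W_", v)]], views[[v]]))
  }
  sigmoid(pre)
}

# batched single- or multi-view encoding: X is a named list of B x V_v
corrnet_encode <- function(X, net, active = .views) {
  if (length(active) == 0) stop("empty active view set")
  pre <- matrix(rep(net$params$b, each = nrow(X[[active[1]]])),
                nrow(X[[active[1]]]), net$latent_dim)
  for (v in active) pre <- pre + X[[v]] %*% net$params[[paste0("W_", v)]]
  sigmoid(pre)
}

# loss + gradients for one minibatch. Returns list(total, reconstruction,
# correlation, pairwise, grads?, n_degenerate).
corrnet_batch <- function(X, net, lambda = net$lambda, want_grad = FALSE) {
  p <- net$params
  B <- nrow(X[[1]])
  if (B < 2) stop("corrnet loss needs a batch of size >= 2")
  k <- net$latent_dim
  logistic_dec <- identical(net$decoder, "logistic")

  P <- lapply(.views, function(v) X[[v]] %*% p[[paste0("W_", v)]])
  names(P) <- .views
  h <- stats::setNames(lapply(.views, function(v) {
    sigmoid(add_bias(P[[v]], p$b))
  }), .views)
  h_all <- sigmoid(add_bias(P$diagnosis + P$medication + P$lab, p$b))
  encodings <- c(list(all = h_all), h)

  grads <- if (want_grad) lapply(p, function(x) x * 0) else NULL
  recon <- 0
  dH <- lapply(encodings, function(e) if (want_grad) e * 0 else NULL)
  for (enc_name in names(encodings)) {
    he <- encodings[[enc_name]]
    for (v in .views) {
      R <- add_bias(he %*% p[[paste0("D_", v)]], p[[paste0("c_", v)]])
      nv <- ncol(R)
      if (logistic_dec) {
        S <- sigmoid(R)
        recon <- recon + mean(-(X[[v]] * safe_log(S) +
                                  (1 - X[[v]]) * safe_log(1 - S)))
        if (want_grad) dR <- (S - X[[v]]) / (B * nv)
      } else {
        diff <- R - X[[v]]
        recon <- recon + mean(diff * diff)
        if (want_grad) dR <- 2 * diff / (B * nv)
      }
      if (want_grad) {
        grads[[paste0("D_", v)]] <- grads[[paste0("D_", v)]] + crossprod(he, dR)
        grads[[paste0("c_", v)]] <- grads[[paste0("c_", v)]] + colSums(dR)
        dH[[enc_name]] <- dH[[enc_name]] + tcrossprod(dR, p[[paste0("D_", v)]])
      }
    }
  }

  pairs <- list(c("diagnosis", "medication"), c("diagnosis", "lab"),
                c("medication", "lab"))
  pairwise <- numeric(3)
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = "_")
  n_degenerate <- 0L
  for (j in seq_along(pairs)) {
    u <- pairs[[j]][1]; w <- pairs[[j]][2]
    cc <- col_corr(h[[u]], h[[w]], grad = want_grad && lambda > 0)
    pairwise[j] <- mean(cc$r)
    n_degenerate <- n_degenerate + sum(!cc$ok)
    if (want_grad && lambda > 0) {
      dH[[u]] <- dH[[u]] - (lambda / k) * cc$da
      dH[[w]] <- dH[[w]] - (lambda / k) * cc$db
    }
  }
  correlation <- sum(pairwise)
  total <- recon - lambda * correlation

  if (want_grad) {
    for (enc_name in names(encodings)) {
      he <- encodings[[enc_name]]
      dPre <- dH[[enc_name]] * he * (1 - he)
      grads$b <- grads$b + colSums(dPre)
      active <- if (enc_name == "all") .views else enc_name
      for (v in active) {
        grads[[paste0("W_", v)]] <- grads[[paste0("W_", v)]] +
          crossprod(X[[v]], dPre)
      }
    }
  }
  list(total = total, reconstruction = recon, correlation = correlation,
       pairwise = pairwise, grads = grads, n_degenerate = n_degenerate)
}

#' Correlational network objective on a batch of encounters
#'
#' The loss is the sum of reconstruction errors (the all-views encoding
#' decoded to each view, plus each single-view encoding decoded to all three
#' views) minus `lambda` times the sum over the three view pairs of the mean
#' per-dimension sample correlation between single-view latent encodings.
#' Latent dimensions with (near) zero variance in the batch contribute a
#' correlation of 0 (guarded; counted in `n_degenerate`).
#'
#' @param batch a list of `multi_hot_views`, or a named list of three
#'   `B x vocab_size` indicator matrices; `B >= 2`.
#' @param net a `corrnet`.
#' @param lambda correlation weight; defaults to the network's own.
#' @return list with `total`, `reconstruction`, `correlation`,
#'   `pairwise` (named length-3 vector) and `n_degenerate`.
#' @export
corrnet_loss <- function(batch, net, lambda = net$lambda) {
  X <- as_view_matrices(batch)
  out <- corrnet_batch(X, net, lambda = lambda, want_grad = FALSE)
  out[c("total", "reconstruction", "correlation", "pairwise", "n_degenerate")]
}

#' Mean per-dimension correlation between single-view encodings
#'
#' Diagnostic for the correlation objective: for each of the three view pairs,
#' the mean over latent dimensions of the Pearson correlation between the two
#' single-view encodings across the batch.
#'
#' @inheritParams corrnet_loss
#' @return named numeric vector of length 3 in [-1, 1].
#' @export
pairwise_latent_correlation <- function(batch, net) {
  X <- as_view_matrices(batch)
  if (nrow(X[[1]]) < 2) stop("need a batch of size >= 2")
  h <- lapply(.views, function(v) corrnet_encode(X, net, active = v))
  names(h) <- .views
  pairs <- list(c("diagnosis", "medication"), c("diagnosis", "lab"),
                c("medication", "lab"))
  out <- vapply(pairs, function(pr) mean(col_corr(h[[pr[1]]], h[[pr[2]]])$r),
                numeric(1))
  stats::setNames(out, vapply(pairs, paste, character(1), collapse = "_"))
}

# stack every encounter of a (prepared) cohort into view matrices
cohort_view_matrices <- function(cohort, vocabs) {
  encs <- unlist(lapply(cohort, `[[`, "encounters"), recursive = FALSE)
  X <- lapply(.views, function(v) {
    m <- matrix(0, length(encs), vocabs[[v]]$size)
    for (i in seq_along(encs)) {
      idx <- vocab_index(vocabs[[v]], encs[[i]]$codes[[v]])
      idx <- idx[!is.na(idx)]
      if (length(idx)) m[i, idx] <- 1
    }
    m
  })
  stats::setNames(X, .views)
}

#' Train the correlational network
#'
#' Unsupervised minimisation of [corrnet_loss()] by Adam on minibatches of
#' training-split encounters. The network is trained once and then frozen; the
#' classifier only projects through it.
#'
#' @param cohort an `ehr_cohort` (training split, after last-encounter
#'   removal), or a named list of three indicator matrices.
#' @param vocabs vocabularies from [build_vocabularies()] (ignored when
#'   matrices are supplied).
#' @param config a [corrnet_config()].
#' @return a trained `corrnet` with attribute `trace`, a data frame of
#'   per-epoch mean loss components.
#' @export
train_corrnet <- function(cohort, vocabs = NULL, config = corrnet_config()) {
  X <- if (is.list(cohort) && all(.views %in% names(cohort)) &&
           is.matrix(cohort[[1]])) {
    cohort[.views]
  } else {
    stopifnot(!is.null(vocabs))
    cohort_view_matrices(cohort, vocabs)
  }
  n <- nrow(X[[1]])
  if (n < 2) stop("train_corrnet needs at least 2 encounters")
  sizes <- stats::setNames(vapply(X, ncol, integer(1)), .views)
  net <- corrnet_init(sizes, config)
  state <- adam_init(net$params)
  trace <- vector("list", config$epochs)
  withr::with_seed(derive_seed(config$seed, "train_corrnet"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      tot <- rec <- corr <- 0
      nb <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        if (length(idx) < 2) next  # correlation needs variance
        Xb <- lapply(X, function(m) m[idx, , drop = FALSE])
        out <- corrnet_batch(Xb, net, want_grad = TRUE)
        if (!is.finite(out$total)) {
          stop("non-finite correlational network loss at epoch ", epoch)
        }
        upd <- adam_step(net$params, out$grads, state,
                         lr = config$learning_rate)
        net$params <- upd$params
        state <- upd$state
        tot <- tot + out$total; rec <- rec + out$reconstruction
        corr <- corr + out$correlation; nb <- nb + 1L
      }
      trace[[epoch]] <- data.frame(epoch = epoch, loss = tot / nb,
                                   reconstruction = rec / nb,
                                   correlation = corr / nb)
    }
  })
  if (!is.null(names(cohort)) && inherits(cohort, "ehr_cohort")) {
    attr(net, "fit_ids") <- sort(names(cohort))
  }
  attr(net, "trace") <- do.call(rbind, trace)
  net
}

#' @export
print.corrnet <- function(x, ...) {
  tr <- attr(x, "trace")
  cat(sprintf("<corrnet> latent_dim=%d lambda=%g views=(%s)%s\n",
              x$latent_dim, x$lambda,
              paste(x$vocab_sizes, collapse = ","),
              if (is.null(tr)) " [untrained]" else
                sprintf(" final loss %.4f", tail(tr$loss, 1))))
  invisible(x)
}
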