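# Per-encounter dense representations.
#
# Five variants of the encounter vector e fed to the recurrent classifier:
#   simple_concat : e_c = relu(concat of per-view linear embeddings)
#   ae_only       : the hidden representation f of a plain autoencoder on the
#                   raw concatenated indicator vectors
#   latent_only   : the correlational-network latent projection l
#   ae_concat     : concat(f, e_c)
#   latent_concat : concat(l, e_c)   (the best-performing fusion)
# An optional elapsed-time feature (scaled to years) is appended at the end.

#' Encounter encoder configuration
#'
#' @param variant one of `"latent_concat"`, `"simple_concat"`, `"ae_only"`,
#'   `"latent_only"`, `"ae_concat"`.
#' @param embedding_dims named integer vector: per-view linear embedding
#'   dimensions used by the concatenation variants.
#' @param time_feature `"none"`, `"since_first"` or `"since_previous"`; when
#'   set, elapsed days divided by 365 are appended as one scalar.
#' @param autoencoder_hidden hidden dimension of the plain autoencoder (must
#'   be smaller than the total input dimension).
#' @param seed integer seed for embedding initialisation.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(variant = c("latent_concat", "simple_concat",
                                       "ae_only", "latent_only", "ae_concat"),
                           embedding_dims = c(diagnosis = 64L, medication = 64L,
                                              lab = 32L),
                           time_feature = c("none", "since_first",
                                            "since_previous"),
                           autoencoder_hidden = 64L,
                           seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(embedding_dims) == 3, all(embedding_dims >= 1),
            setequal(names(embedding_dims), .views))
  structure(list(variant = variant,
                 embedding_dims = embedding_dims,
                 time_feature = match.arg(time_feature),
                 autoencoder_hidden = as.integer(autoencoder_hidden),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

uses_embeddings <- function(variant) {
  variant %in% c("simple_concat", "latent_concat", "ae_concat")
}
uses_latent <- function(variant) variant %in% c("latent_only", "latent_concat")
uses_autoencoder <- function(variant) variant %in% c("ae_only", "ae_concat")

#' Initialise per-view linear embedding parameters
#'
#' @param vocabs vocabularies from [build_vocabularies()].
#' @param config an [encoder_config()].
#' @return named list per view with elements `E` (vocab x dim) and `b` (dim).
#' @export
init_embedding_params <- function(vocabs, config = encoder_config()) {
  withr::with_seed(derive_seed(config$seed, "init_embeddings"), {
    emb <- lapply(.views, function(v) {
      d <- vocabs[[v]]$size
      m <- config$embedding_dims[[v]]
      list(E = matrix(rnorm(d * m, sd = 1 / sqrt(d)), d, m), b = numeric(m))
    })
    stats::setNames(emb, .views)
  })
}

#' The simple-concatenation encounter vector
#'
#' `e_c = relu(concat(E_d' v_d + b_d, E_m' v_m + b_m, E_l' v_l + b_l))`.
#'
#' @param views a `multi_hot_views`.
#' @param emb embedding parameters from [init_embedding_params()].
#' @return numeric vector of length `sum(embedding_dims)`, entries >= 0.
#' @export
simple_concat_vector <- function(views, emb) {
  parts <- lapply(.views, function(v) {
    if (length(views[[v]]) != nrow(emb[[v]]$E)) {
      stop("dimension mismatch between view '", v, "' and its embedding")
    }
    drop(crossprod(emb[[v]]$E, views[[v]])) + emb[[v]]$b
  })
  relu(unlist(parts, use.names = FALSE))
}

#' Train the plain (non-correlational) autoencoder
#'
#' One sigmoid hidden layer `f` and one linear output layer `g`, trained to
#' reconstruct the raw concatenated indicator vectors under mean squared
#' error. The hidden dimension must be smaller than the input dimension
#' (compression).
#'
#' @param cohort an `ehr_cohort` (training split, prepared), or a single
#'   `N x V` indicator matrix.
#' @param vocabs vocabularies (ignored when a matrix is supplied).
#' @param hidden hidden dimension.
#' @param learning_rate,epochs,batch_size,seed optimiser settings.
#' @return a `clout_autoencoder` with weights `W1`, `b1` (input -> hidden) and
#'   `W2`, `b2` (hidden -> input), plus a per-epoch loss `trace` attribute.
#' @export
train_autoencoder <- function(cohort, vocabs = NULL, hidden = 64L,
                              learning_rate = 1e-3, epochs = 30L,
                              batch_size = 128L, seed = 1L) {
  X <- if (is.matrix(cohort)) cohort else {
    do.call(cbind, cohort_view_matrices(cohort, vocabs))
  }
  n <- nrow(X); d <- ncol(X)
  if (hidden >= d) {
    stop("autoencoder hidden dimension (", hidden,
         ") must be smaller than the input dimension (", d, ")")
  }
  if (n < 1) stop("train_autoencoder needs at least one encounter")
  params <- withr::with_seed(derive_seed(seed, "ae_init"), {
    list(W1 = matrix(rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden),
         b1 = numeric(hidden),
         W2 = matrix(rnorm(hidden * d, sd = 1 / sqrt(hidden)), hidden, d),
         b2 = numeric(d))
  })
  state <- adam_init(params)
  trace <- numeric(epochs)
  withr::with_seed(derive_seed(seed, "ae_train"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample(n)
      tot <- 0; nb <- 0L
      for (s in seq(1, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        f <- sigmoid(add_bias(Xb %*% params$W1, params$b1))
        g <- add_bias(f %*% params$W2, params$b2)
        diff <- g - Xb
        loss <- mean(diff * diff)
        if (!is.finite(loss)) stop("non-finite autoencoder loss")
        dG <- 2 * diff / length(diff)
        dF <- tcrossprod(dG, params$W2) * f * (1 - f)
        grads <- list(W1 = crossprod(Xb, dF), b1 = colSums(dF),
                      W2 = crossprod(f, dG), b2 = colSums(dG))
        upd <- adam_step(params, grads, state, lr = learning_rate)
        params <- upd$params; state <- upd$state
        tot <- tot + loss; nb <- nb + 1L
      }
      trace[epoch] <- tot / nb
    }
  })
  out <- structure(c(params, list(hidden = as.integer(hidden))),
                   class = "clout_autoencoder")
  if (inherits(cohort, "ehr_cohort")) attr(out, "fit_ids") <- sort(names(cohort))
  attr(out, "trace") <- trace
  out
}

#' Hidden representation of the plain autoencoder
#'
#' @param views a `multi_hot_views` or an `N x V` matrix of concatenated
#'   indicators.
#' @param ae a `clout_autoencoder`.
#' @return hidden representation `f` (vector, or matrix for matrix input).
#' @export
autoencoder_hidden <- function(views, ae) {
  x <- if (is.matrix(views)) views else
    matrix(unlist(views[.views], use.names = FALSE), nrow = 1)
  f <- sigmoid(add_bias(x %*% ae$W1, ae$b1))
  if (is.matrix(views)) f else drop(f)
}

#' Build one encounter vector under a variant
#'
#' Dispatches on the configured variant and concatenates the required
#' components; the optional time feature (elapsed days / 365) is appended
#' last. Components not required by the variant may be omitted; a required
#' missing component is an error naming the dependency.
#'
#' @param views a `multi_hot_views`.
#' @param config an [encoder_config()].
#' @param emb embedding parameters (concatenation variants).
#' @param corrnet a trained [corrnet] (latent variants).
#' @param autoencoder a [clout_autoencoder] (autoencoder variants).
#' @param elapsed_first,elapsed_prev elapsed days since the first/previous
#'   encounter (used when `time_feature` is set).
#' @return numeric encounter vector with attribute `slices`, a named list of
#'   index ranges for each component.
#' @export
build_encounter_vector <- function(views, config, emb = NULL, corrnet = NULL,
                                   autoencoder = NULL, elapsed_first = 0,
                                   elapsed_prev = 0) {
  variant <- config$variant
  parts <- list()
  if (uses_latent(variant)) {
    if (is.null(corrnet)) {
      stop("variant '", variant, "' requires trained corrnet parameters")
    }
    parts$latent <- encode_views(views, corrnet)
  }
  if (uses_autoencoder(variant)) {
    if (is.null(autoencoder)) {
      stop("variant '", variant, "' requires trained autoencoder parameters")
    }
    parts$ae <- autoencoder_hidden(views, autoencoder)
  }
  if (uses_embeddings(variant)) {
    if (is.null(emb)) {
      stop("variant '", variant, "' requires embedding parameters")
    }
    parts$e_c <- simple_concat_vector(views, emb)
  }
  if (config$time_feature != "none") {
    days <- switch(config$time_feature,
                   since_first = elapsed_first,
                   since_previous = elapsed_prev)
    parts$time <- days / 365
  }
  lens <- lengths(parts)
  ends <- cumsum(lens)
  slices <- Map(function(a, b) a:b, ends - lens + 1, ends)
  structure(unlist(parts, use.names = FALSE), slices = slices)
}

#' Length of the encounter vector implied by a configuration
#'
#' @param config an [encoder_config()].
#' @param latent_dim latent dimension of the correlational network (latent
#'   variants).
#' @return integer vector length.
#' @export
encounter_vector_length <- function(config, latent_dim = NULL) {
  n <- 0L
  if (uses_embeddings(config$variant)) n <- n + sum(config$embedding_dims)
  if (uses_latent(config$variant)) {
    stopifnot(!is.null(latent_dim))
    n <- n + latent_dim
  }
  if (uses_autoencoder(config$variant)) n <- n + config$autoencoder_hidden
  if (config$time_feature != "none") n <- n + 1L
  as.integer(n)
}
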