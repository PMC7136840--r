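# Fixtures and independent oracle implementations used across the suite.
# Oracles are deliberately written as explicit scalar loops so they share no
# code path with the vectorised package implementations they check.

views3 <- c("diagnosis", "medication", "lab")

# ---- tiny hand-written event table -------------------------------------------

tiny_events <- function() {
  data.frame(
    patient_id   = c("p1","p1","p1","p1","p2","p2","p2","p3"),
    encounter_id = c("e1","e1","e2","e2","e3","e4","e4","e5"),
    timestamp    = as.Date(c("2011-01-01","2011-01-01","2011-03-01","2011-03-01",
                             "2012-05-02","2012-01-10","2012-01-10","2013-02-02")),
    view         = c("diagnosis","medication","diagnosis","lab",
                     "diagnosis","lab","medication","diagnosis"),
    code         = c("C10","MA","A01","LX","B20","LY","MB","A01"),
    abnormal_flag = c(NA, NA, NA, TRUE, NA, FALSE, NA, NA),
    mortality    = c(1L,1L,1L,1L,0L,0L,0L,1L),
    stringsAsFactors = FALSE)
}

write_tiny_csv <- function(events, path = tempfile(fileext = ".csv")) {
  out <- events
  out$timestamp <- format(out$timestamp, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}

# small synthetic cohort for model-level tests (fast to generate and train)
small_gen_config <- function(seed = 1, n_patients = 150, ...) {
  generator_config(n_patients = n_patients, encounter_range = c(2, 4),
                   latent_dim = 3,
                   vocab_sizes = c(diagnosis = 12, medication = 10, lab = 8),
                   mortality_coefficients = rep(0.3, 3),
                   n_marker_features_per_view = 3, seed = seed, ...)
}

# ---- O(n^2) pair-counting AUROC oracle ----------------------------------------

auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# ---- scalar-loop oracles for the networks --------------------------------------

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# shared-latent projection l = sigmoid(sum_v W_v' x_v + b), element by element
oracle_encode_views <- function(views, net, active = views3) {
  k <- net$latent_dim
  l <- numeric(k)
  for (j in seq_len(k)) {
    s <- net$params$b[j]
    for (v in active) {
      W <- net$params[[paste0("W_", v)]]
      x <- views[[v]]
      for (i in seq_along(x)) s <- s + W[i, j] * x[i]
    }
    l[j] <- oracle_sigmoid(s)
  }
  l
}

# full correlational objective by brute force on a list of per-view matrices
oracle_corrnet_loss <- function(X, net, lambda) {
  p <- net$params
  B <- nrow(X[[1]])
  k <- net$latent_dim
  enc <- function(active) {
    h <- matrix(0, B, k)
    for (r in seq_len(B)) {
      h[r, ] <- oracle_encode_views(lapply(X, function(m) m[r, ]), net, active)
    }
    h
  }
  encodings <- list(all = enc(views3), diagnosis = enc("diagnosis"),
                    medication = enc("medication"), lab = enc("lab"))
  recon <- 0
  for (he in encodings) {
    for (v in views3) {
      D <- p[[paste0("D_", v)]]; cv <- p[[paste0("c_", v)]]
      sse <- 0
      for (r in seq_len(B)) {
        for (i in seq_len(ncol(X[[v]]))) {
          pred <- cv[i]
          for (j in seq_len(k)) pred <- pred + he[r, j] * D[j, i]
          sse <- sse + (pred - X[[v]][r, i])^2
        }
      }
      recon <- recon + sse / (B * ncol(X[[v]]))
    }
  }
  corr <- 0
  pairs <- list(c("diagnosis","medication"), c("diagnosis","lab"),
                c("medication","lab"))
  for (pr in pairs) {
    rsum <- 0
    for (j in seq_len(k)) {
      a <- encodings[[pr[1]]][, j]; b <- encodings[[pr[2]]][, j]
      va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
      rsum <- rsum + if (va > 1e-8 && vb > 1e-8) {
        sum((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
      } else 0
    }
    corr <- corr + rsum / k
  }
  list(total = recon - lambda * corr, reconstruction = recon,
       correlation = corr)
}

# e_c = relu of per-view linear embeddings, scalar loops
oracle_simple_concat <- function(views, emb) {
  out <- c()
  for (v in views3) {
    E <- emb[[v]]$E; b <- emb[[v]]$b; x <- views[[v]]
    for (j in seq_len(ncol(E))) {
      s <- b[j]
      for (i in seq_along(x)) s <- s + E[i, j] * x[i]
      out <- c(out, max(0, s))
    }
  }
  out
}

# full classifier forward for one prepared timeline, scalar loops throughout
oracle_clout_predict <- function(model, timeline) {
  pars <- model$params
  ec_cfg <- model$encoder_config
  H <- nrow(pars$Wh)
  n <- length(timeline$encounters)
  emb <- lapply(views3, function(v) list(E = pars[[paste0("E_", v)]],
                                         b = pars[[paste0("bE_", v)]]))
  names(emb) <- views3
  hs <- matrix(0, n, H)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(n)) {
    enc <- timeline$encounters[[t]]
    mh <- encode_encounter(enc, model$vocabs)
    e <- c()
    if (model$variant %in% c("latent_only", "latent_concat")) {
      e <- c(e, oracle_encode_views(mh, model$corrnet))
    }
    if (model$variant %in% c("simple_concat", "latent_concat", "ae_concat")) {
      e <- c(e, oracle_simple_concat(mh, emb))
    }
    if (ec_cfg$time_feature != "none") {
      d <- if (ec_cfg$time_feature == "since_first") enc$elapsed_first else
        enc$elapsed_prev
      e <- c(e, d / 365)
    }
    z <- numeric(4 * H)
    for (j in seq_len(4 * H)) {
      s <- pars$b[j]
      for (i in seq_along(e)) s <- s + e[i] * pars$Wx[i, j]
      for (i in seq_len(H)) s <- s + h[i] * pars$Wh[i, j]
      z[j] <- s
    }
    i_g <- oracle_sigmoid(z[1:H])
    f_g <- oracle_sigmoid(z[H + 1:H])
    o_g <- oracle_sigmoid(z[2 * H + 1:H])
    g_g <- tanh(z[3 * H + 1:H])
    cc <- f_g * cc + i_g * g_g
    h <- o_g * tanh(cc)
    hs[t, ] <- h
  }
  s <- numeric(n)
  for (t in seq_len(n)) {
    m <- numeric(length(pars$ba))
    for (j in seq_along(pars$ba)) {
      acc <- pars$ba[j]
      for (i in seq_len(H)) acc <- acc + hs[t, i] * pars$Wa[i, j]
      m[j] <- tanh(acc)
    }
    s[t] <- sum(m * pars$u)
  }
  a <- exp(s - max(s)); a <- a / sum(a)
  ctx <- numeric(H)
  for (t in seq_len(n)) ctx <- ctx + a[t] * hs[t, ]
  oracle_sigmoid(sum(ctx * drop(pars$wo)) + pars$bo)
}

# hand-set miniature clout model over given vocabularies (no training)
surrogate_clout <- function(vocabs, variant = "simple_concat",
                            time_feature = "none", hidden = 2, attn = 2,
                            seed = 5, corrnet = NULL) {
  ec <- encoder_config(variant = variant,
                       embedding_dims = c(diagnosis = 2, medication = 2, lab = 1),
                       time_feature = time_feature, seed = seed)
  cc <- clout_config(hidden_dim = hidden, attention_dim = attn, seed = seed)
  idim <- encounter_vector_length(ec, latent_dim =
                                    if (!is.null(corrnet)) corrnet$latent_dim)
  pars <- clout:::clout_init_params(idim, vocabs, ec, cc)
  set.seed(seed + 1)
  pars <- lapply(pars, function(p) p + rnorm(length(p), sd = 0.3))
  structure(list(variant = variant, params = pars, encoder_config = ec,
                 clout_config = cc, vocabs = vocabs, corrnet = corrnet,
                 autoencoder = NULL, input_dim = idim),
            class = "clout_model")
}

attn_params <- function(hidden = 3, attn = 2, seed = 1) {
  set.seed(seed)
  list(W = matrix(rnorm(hidden * attn), hidden, attn), b = rnorm(attn),
       u = rnorm(attn))
}

# vocabularies over explicit code sets
vocabs_from_codes <- function(diagnosis, medication, lab) {
  v <- lapply(list(diagnosis = diagnosis, medication = medication, lab = lab),
              sort)
  out <- lapply(views3, function(nm) {
    structure(list(view = nm, codes = v[[nm]], size = length(v[[nm]])),
              class = "code_vocabulary")
  })
  stats::setNames(out, views3)
}

# build a patient_timeline by hand from per-encounter code lists
make_timeline <- function(pid, codes_by_enc, mortality = 1L, start = "2015-01-01",
                          gap_days = 30) {
  dates <- as.Date(start) + gap_days * (seq_along(codes_by_enc) - 1)
  encs <- lapply(seq_along(codes_by_enc), function(i) {
    cl <- codes_by_enc[[i]]
    list(encounter_id = sprintf("%s_e%d", pid, i), timestamp = dates[i],
         codes = list(diagnosis = sort(cl$diagnosis %||% character()),
                      medication = sort(cl$medication %||% character()),
                      lab = sort(cl$lab %||% character())),
         elapsed_first = as.numeric(dates[i] - dates[1]),
         elapsed_prev = if (i == 1) 0 else as.numeric(dates[i] - dates[i - 1]))
  })
  structure(list(patient_id = pid, mortality = as.integer(mortality),
                 encounters = encs), class = "patient_timeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
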