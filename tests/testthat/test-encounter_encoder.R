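# Encounter-vector construction: embeddings, autoencoder, variant dispatch.

small_vocabs <- function() {
  vocabs_from_codes(diagnosis = c("A", "B", "C", "D"),
                    medication = c("M1", "M2", "M3"), lab = c("L1", "L2"))
}

test_that("simple concatenation: zero propagation and rectification", {
  vocabs <- small_vocabs()
  emb <- init_embedding_params(vocabs, encoder_config(
    variant = "simple_concat",
    embedding_dims = c(diagnosis = 2, medication = 2, lab = 1)))
  for (v in views3) emb[[v]]$b <- numeric(length(emb[[v]]$b))
  zero_views <- list(diagnosis = numeric(4), medication = numeric(3),
                     lab = numeric(2))
  expect_equal(simple_concat_vector(zero_views, emb), numeric(5))
  # force a negative pre-activation: rectifier clamps it to zero
  emb$diagnosis$E[] <- -1
  views <- list(diagnosis = c(1, 0, 0, 0), medication = numeric(3),
                lab = numeric(2))
  out <- simple_concat_vector(views, emb)
  expect_equal(out[1:2], c(0, 0))
  expect_true(all(out >= 0))
})

test_that("simple_concat_vector matches the scalar oracle and is size-checked", {
  vocabs <- small_vocabs()
  cfg <- encoder_config(variant = "simple_concat",
                        embedding_dims = c(diagnosis = 3, medication = 2, lab = 2),
                        seed = 4)
  emb <- init_embedding_params(vocabs, cfg)
  set.seed(5)
  views <- list(diagnosis = rbinom(4, 1, 0.5), medication = rbinom(3, 1, 0.5),
                lab = rbinom(2, 1, 0.5))
  expect_equal(simple_concat_vector(views, emb),
               oracle_simple_concat(views, emb), tolerance = 1e-12)
  bad <- views
  bad$diagnosis <- numeric(9)
  expect_error(simple_concat_vector(bad, emb), "mismatch")
})

test_that("embedding relabeling equivariance: permuting codes and rows is a no-op", {
  vocabs <- small_vocabs()
  cfg <- encoder_config(variant = "simple_concat",
                        embedding_dims = c(diagnosis = 3, medication = 2, lab = 2),
                        seed = 6)
  emb <- init_embedding_params(vocabs, cfg)
  set.seed(7)
  for (rep in 1:10) {
    views <- list(diagnosis = rbinom(4, 1, 0.5), medication = rbinom(3, 1, 0.5),
                  lab = rbinom(2, 1, 0.5))
    perm <- sample(4)
    emb2 <- emb
    emb2$diagnosis$E <- emb$diagnosis$E[perm, , drop = FALSE]
    views2 <- views
    views2$diagnosis <- views$diagnosis[perm]
    expect_equal(simple_concat_vector(views2, emb2),
                 simple_concat_vector(views, emb))
  }
})

test_that("autoencoder training descends, compresses, and is reproducible", {
  set.seed(8)
  X <- matrix(rbinom(600, 1, 0.3), 60, 10)
  ae <- train_autoencoder(X, hidden = 4, epochs = 10, seed = 2)
  tr <- attr(ae, "trace")
  expect_lte(tail(tr, 1), tr[1])
  ae2 <- train_autoencoder(X, hidden = 4, epochs = 10, seed = 2)
  expect_identical(ae$W1, ae2$W1)
  expect_error(train_autoencoder(X, hidden = 10), "smaller than")
  f <- autoencoder_hidden(X, ae)
  expect_equal(dim(f), c(60, 4))
  expect_true(all(f > 0 & f < 1))
})

test_that("variant dispatch assembles the right components in order", {
  vocabs <- small_vocabs()
  sizes <- sapply(vocabs, `[[`, "size")
  cn <- corrnet_init(sizes, corrnet_config(latent_dim = 3, seed = 3))
  set.seed(9)
  X <- matrix(rbinom(180, 1, 0.3), 20, 9)
  ae <- train_autoencoder(X, hidden = 4, epochs = 2, seed = 4)
  cfg <- function(variant, time = "none") {
    encoder_config(variant = variant,
                   embedding_dims = c(diagnosis = 3, medication = 2, lab = 2),
                   time_feature = time, seed = 5)
  }
  emb <- init_embedding_params(vocabs, cfg("simple_concat"))
  views <- list(diagnosis = c(1, 0, 1, 0), medication = c(0, 1, 0),
                lab = c(1, 0))

  e_lc <- build_encounter_vector(views, cfg("latent_concat"), emb = emb,
                                 corrnet = cn)
  expect_length(e_lc, 3 + 7)
  sl <- attr(e_lc, "slices")
  expect_equal(e_lc[sl$latent], encode_views(views, cn))
  expect_equal(e_lc[sl$e_c], simple_concat_vector(views, emb))
  expect_equal(e_lc[sl$latent],
               build_encounter_vector(views, cfg("latent_only"), corrnet = cn)[1:3])

  e_ae <- build_encounter_vector(views, cfg("ae_concat"), emb = emb,
                                 autoencoder = ae)
  expect_length(e_ae, 4 + 7)
  expect_equal(e_ae[attr(e_ae, "slices")$ae],
               drop(autoencoder_hidden(matrix(unlist(views), 1), ae)))

  # time feature: 730 elapsed days appends the scalar 2.0
  e_t <- build_encounter_vector(views, cfg("simple_concat", "since_first"),
                                emb = emb, elapsed_first = 730)
  expect_length(e_t, 8)
  expect_equal(unname(e_t[8]), 2.0)
})

test_that("missing required parameters fail naming the dependency", {
  views <- list(diagnosis = numeric(4), medication = numeric(3),
                lab = numeric(2))
  expect_error(build_encounter_vector(views, encoder_config("latent_concat")),
               "corrnet")
  expect_error(build_encounter_vector(views, encoder_config("ae_only")),
               "autoencoder")
  expect_error(build_encounter_vector(views, encoder_config("simple_concat")),
               "embedding")
})

test_that("output length is a pure function of the configuration", {
  vocabs <- small_vocabs()
  sizes <- sapply(vocabs, `[[`, "size")
  set.seed(10)
  X <- matrix(rbinom(180, 1, 0.3), 20, 9)
  variants <- c("simple_concat", "ae_only", "latent_only", "ae_concat",
                "latent_concat")
  for (rep in 1:100) {
    variant <- sample(variants, 1)
    dims <- c(diagnosis = sample(1:5, 1), medication = sample(1:5, 1),
              lab = sample(1:5, 1))
    time <- sample(c("none", "since_first", "since_previous"), 1)
    k <- sample(1:4, 1)
    hid <- sample(1:8, 1)
    cfg <- encoder_config(variant = variant, embedding_dims = dims,
                          time_feature = time, autoencoder_hidden = hid,
                          seed = rep)
    cn <- corrnet_init(sizes, corrnet_config(latent_dim = k, seed = rep))
    ae <- train_autoencoder(X, hidden = hid, epochs = 1, seed = rep)
    emb <- init_embedding_params(vocabs, cfg)
    views <- list(diagnosis = rbinom(4, 1, 0.5), medication = rbinom(3, 1, 0.5),
                  lab = rbinom(2, 1, 0.5))
    e <- build_encounter_vector(views, cfg, emb = emb, corrnet = cn,
                                autoencoder = ae, elapsed_first = 10,
                                elapsed_prev = 5)
    expect_length(e, encounter_vector_length(cfg, latent_dim = k))
    expect_true(all(is.finite(e)))
    if (variant == "simple_concat" && time == "none") expect_true(all(e >= 0))
  }
})
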