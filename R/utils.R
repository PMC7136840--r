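# Internal numerical helpers shared by the network modules.

sigmoid <- function(x) stats::plogis(x)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# add a bias (row) vector to every row of a matrix without sweep() overhead
add_bias <- function(m, b) m + rep(b, each = nrow(m))

# numerically safe log for Bernoulli likelihoods
safe_log <- function(p, eps = 1e-12) log(pmax(p, eps))

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; per-stage seeds
#' are derived deterministically from the stage name so that re-running a
#' stage in isolation reproduces its randomness.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1013904223
  as.integer(((master %% 1013904223) * 69069 + h) %% 2147483647)
}

# ---- Adam optimiser over a flat named list of numeric arrays ----------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise accumulate grads (b into a), both flat named lists
acc_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# Pearson correlation per column pair with a variance floor; returns the
# per-dimension r vector plus (optionally) gradients w.r.t. both matrices.
# Columns whose centred sum of squares falls below `floor` contribute r = 0
# and zero gradient (degenerate, guarded).
col_corr <- function(a, b, floor = 1e-8, grad = FALSE) {
  ac <- add_bias(a, -colMeans(a))
  bc <- add_bias(b, -colMeans(b))
  s2a <- colSums(ac * ac)
  s2b <- colSums(bc * bc)
  sab <- colSums(ac * bc)
  ok <- s2a > floor & s2b > floor
  r <- numeric(ncol(a))
  denom <- sqrt(s2a * s2b)
  r[ok] <- sab[ok] / denom[ok]
  if (!grad) return(list(r = r, ok = ok))
  da <- a * 0
  db <- b * 0
  if (any(ok)) {
    # d r_j / d a_ij = bc_ij/(sa sb) - r_j ac_ij / sa^2 (centering projection
    # vanishes because both terms are already mean-zero over i)
    da[, ok] <- bc[, ok, drop = FALSE] *
      rep(1 / denom[ok], each = nrow(a)) -
      ac[, ok, drop = FALSE] * rep(r[ok] / s2a[ok], each = nrow(a))
    db[, ok] <- ac[, ok, drop = FALSE] *
      rep(1 / denom[ok], each = nrow(b)) -
      bc[, ok, drop = FALSE] * rep(r[ok] / s2b[ok], each = nrow(b))
  }
  list(r = r, ok = ok, da = da, db = db)
}
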