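# Explainability: a variational autoencoder over flattened median beats
# (fully connected encoder/decoder, Gaussian likelihood, beta = 1 by
# default), latent ranking by regression t-value, latent traversal, and
# extreme-prediction waveform averaging.

#' Flatten median beats into a matrix
#'
#' @param beats list of `median_beat` objects (or a numeric matrix, returned
#'   as is).
#' @param leads lead names to keep (default all leads of the first beat).
#' @return numeric matrix, one row per beat; the beat shape is attached as
#'   attribute `beat_dim` (leads x samples) for un-flattening.
#' @export
beats_matrix <- function(beats, leads = NULL) {
  if (is.matrix(beats)) return(beats)
  stopifnot(length(beats) > 0, inherits(beats[[1]], "median_beat"))
  leads <- leads %||% rownames(beats[[1]]$samples)
  rows <- lapply(beats, function(b) as.numeric(t(b$samples[leads, , drop = FALSE])))
  X <- do.call(rbind, rows)
  attr(X, "beat_dim") <- c(length(leads), ncol(beats[[1]]$samples))
  attr(X, "leads") <- leads
  rownames(X) <- vapply(beats, function(b) b$ecg_id, "")
  X
}

#' Gaussian KL divergence to the standard normal prior
#'
#' `KL(N(mu, exp(logvar)) || N(0, 1))`, summed over latent coordinates per
#' row; zero exactly when the posterior equals the prior.
#'
#' @param mu,logvar matrices (rows = observations).
#' @return numeric vector of per-row KL values.
#' @export
vae_kl <- function(mu, logvar) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  rowSums(-0.5 * (1 + logvar - mu^2 - exp(logvar)))
}

#' Train a variational autoencoder on median beats
#'
#' Fully connected encoder and decoder with one tanh hidden layer each,
#' diagonal Gaussian posterior, linear Gaussian likelihood on features
#' standardized internally. Minimizes reconstruction error plus
#' `beta` times the KL term by mini-batch Adam; training is deterministic
#' under `seed`.
#'
#' @param X matrix of flattened beats (rows = beats) from [beats_matrix()].
#' @param latent_dim latent dimension (default 8).
#' @param hidden hidden width (default 64).
#' @param epochs,batch_size,lr optimizer settings.
#' @param beta KL weight.
#' @param seed integer seed.
#' @param verbose print loss every 25 epochs.
#' @return object of class `vae`: weights, feature standardization, the
#'   per-epoch `loss` trace, and posterior-mean summary statistics
#'   (`mu_center`, `mu_sd`) used by [traverse_latent()].
#' @export
train_vae <- function(X, latent_dim = 8, hidden = 64, epochs = 200,
                      batch_size = 64, lr = 1e-3, beta = 1, seed = 1,
                      verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 100) stopf("need at least 100 beats to train a VAE (got %d)", n)
  sds <- apply(X, 2, sd)
  if (all(sds < 1e-10)) stopf("degenerate (constant) inputs")
  ctr <- colMeans(X)
  scl <- pmax(sds, 1e-6)
  XS <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  D <- latent_dim; H <- hidden
  with_seed(seed, {
    init <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(1 / nr)), nr, nc)
    par <- list(W1 = init(d, H), b1 = rep(0, H),
                Wmu = init(H, D), bmu = rep(0, D),
                Wlv = init(H, D), blv = rep(0, D),
                W2 = init(D, H), b2 = rep(0, H),
                W3 = init(H, d), b3 = rep(0, d))
    mns <- lapply(par, function(p) p * 0)
    vns <- lapply(par, function(p) p * 0)
    b1m <- 0.9; b2m <- 0.999; epsa <- 1e-8; step <- 0
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- XS[idx, , drop = FALSE]
        nb <- nrow(xb)
        H1 <- tanh(xb %*% par$W1 + rep(par$b1, each = nb))
        mu <- H1 %*% par$Wmu + rep(par$bmu, each = nb)
        lv <- H1 %*% par$Wlv + rep(par$blv, each = nb)
        eps <- matrix(rnorm(nb * D), nb, D)
        z <- mu + eps * exp(0.5 * lv)
        H2 <- tanh(z %*% par$W2 + rep(par$b2, each = nb))
        xhat <- H2 %*% par$W3 + rep(par$b3, each = nb)
        recon <- 0.5 * sum((xhat - xb)^2)
        kl <- sum(vae_kl(mu, lv))
        ep_loss <- ep_loss + recon + beta * kl
        # backprop (all gradients divided by batch size)
        dxhat <- (xhat - xb) / nb
        g <- list()
        g$W3 <- t(H2) %*% dxhat; g$b3 <- colSums(dxhat)
        dH2 <- dxhat %*% t(par$W3) * (1 - H2^2)
        g$W2 <- t(z) %*% dH2; g$b2 <- colSums(dH2)
        dz <- dH2 %*% t(par$W2)
        dmu <- dz + beta * mu / nb
        dlv <- dz * eps * 0.5 * exp(0.5 * lv) +
          beta * 0.5 * (exp(lv) - 1) / nb
        g$Wmu <- t(H1) %*% dmu; g$bmu <- colSums(dmu)
        g$Wlv <- t(H1) %*% dlv; g$blv <- colSums(dlv)
        dH1 <- (dmu %*% t(par$Wmu) + dlv %*% t(par$Wlv)) * (1 - H1^2)
        g$W1 <- t(xb) %*% dH1; g$b1 <- colSums(dH1)
        step <- step + 1
        corr <- lr * sqrt(1 - b2m^step) / (1 - b1m^step)
        for (pn in names(par)) {
          mns[[pn]] <- b1m * mns[[pn]] + (1 - b1m) * g[[pn]]
          vns[[pn]] <- b2m * vns[[pn]] + (1 - b2m) * g[[pn]]^2
          par[[pn]] <- par[[pn]] - corr * mns[[pn]] / (sqrt(vns[[pn]]) + epsa)
        }
      }
      losses[ep] <- ep_loss / n
      if (verbose && ep %% 25 == 0)
        message(sprintf("vae epoch %d loss %.4f", ep, losses[ep]))
    }
    enc <- .vae_encode_par(par, XS)
    structure(list(par = par, center = ctr, scale = scl, latent_dim = D,
                   hidden = H, beta = beta, loss = losses,
                   mu_center = colMeans(enc$mu),
                   mu_sd = apply(enc$mu, 2, sd),
                   beat_dim = attr(X, "beat_dim"),
                   leads = attr(X, "leads")),
              class = "vae")
  })
}

.vae_encode_par <- function(par, XS) {
  nb <- nrow(XS)
  H1 <- tanh(XS %*% par$W1 + rep(par$b1, each = nb))
  list(mu = H1 %*% par$Wmu + rep(par$bmu, each = nb),
       logvar = H1 %*% par$Wlv + rep(par$blv, each = nb))
}

#' Encode beats to the latent posterior
#' @param vae a fitted [train_vae()] object.
#' @param X beat matrix on the original (mV) scale.
#' @return list `mu`, `logvar` (rows = beats).
#' @export
vae_encode <- function(vae, X) {
  X <- as.matrix(X)
  XS <- sweep(sweep(X, 2, vae$center), 2, vae$scale, "/")
  .vae_encode_par(vae$par, XS)
}

#' Decode latent codes to beats
#' @param vae a fitted [train_vae()] object.
#' @param Z latent matrix (rows = codes).
#' @return decoded beat matrix on the original (mV) scale.
#' @export
vae_decode <- function(vae, Z) {
  Z <- matrix(Z, ncol = vae$latent_dim)
  nb <- nrow(Z)
  H2 <- tanh(Z %*% vae$par$W2 + rep(vae$par$b2, each = nb))
  XS <- H2 %*% vae$par$W3 + rep(vae$par$b3, each = nb)
  sweep(sweep(XS, 2, vae$scale, "*"), 2, vae$center, "+")
}

#' Rank latent features by association with model predictions
#'
#' Multiple linear regression of the prediction on all posterior means;
#' latents are ranked by absolute t-value and the top `top` returned.
#' Aliased (collinear) latents get a rank-deficiency warning and t = 0.
#'
#' @param vae fitted VAE.
#' @param X beat matrix matched to `predictions`.
#' @param predictions model risk predictions, one per beat.
#' @param top how many latents to return (default 3).
#' @return data frame `latent`, `t`, ordered by decreasing `|t|`, plus the
#'   full ranking as attribute `"all"`.
#' @export
rank_latents <- function(vae, X, predictions, top = 3) {
  mu <- vae_encode(vae, X)$mu
  colnames(mu) <- paste0("z", seq_len(ncol(mu)))
  fit <- lm(predictions ~ mu)
  sm <- summary(fit)$coefficients
  tv <- setNames(rep(0, ncol(mu)), colnames(mu))
  got <- sub("^mu", "", rownames(sm)[-1])
  tv[got] <- sm[-1, "t value"]
  if (anyNA(coef(fit))) warnf("rank-deficient latent regression; aliased latents get t = 0")
  tv[is.na(tv)] <- 0
  tv <- pmin(pmax(tv, -1e12), 1e12)  # perfect fits capped, not infinite
  ord <- order(abs(tv), decreasing = TRUE)
  out <- data.frame(latent = ord, t = tv[ord], row.names = NULL)
  attr(out, "all") <- out
  head(out, top)
}

#' Latent traversal panel
#'
#' Decodes the cohort's central latent code while sweeping one coordinate
#' symmetrically from `-span_sd` to `+span_sd` posterior-mean standard
#' deviations in `steps` steps, all other coordinates fixed. The centre
#' step decodes the unperturbed code.
#'
#' @param vae fitted VAE.
#' @param latent_index coordinate to sweep (1-based).
#' @param span_sd sweep half-width in SD units.
#' @param steps number of panel positions (odd keeps the exact centre).
#' @return object of class `traversal_panel`: `offsets` (in SD units) and
#'   `beats` (decoded matrix, one row per position).
#' @export
traverse_latent <- function(vae, latent_index, span_sd = 3, steps = 7) {
  if (latent_index < 1 || latent_index > vae$latent_dim)
    stopf("latent index %d out of range 1..%d", latent_index, vae$latent_dim)
  offs <- seq(-span_sd, span_sd, length.out = steps)
  Z <- matrix(rep(vae$mu_center, each = steps), steps)
  Z[, latent_index] <- Z[, latent_index] + offs * vae$mu_sd[latent_index]
  structure(list(latent_index = latent_index, offsets = offs,
                 beats = vae_decode(vae, Z), beat_dim = vae$beat_dim,
                 leads = vae$leads),
            class = "traversal_panel")
}

#' Average waveforms of the extreme prediction groups
#'
#' Ranks beats by the model prediction and averages the `n_extreme` highest
#' and lowest; per-sample mean and standard deviation per group, for
#' shaded-band plotting.
#'
#' @param X beat matrix (rows = beats).
#' @param predictions one prediction per beat.
#' @param n_extreme group size; shrunk to `floor(n/2)` with a warning when
#'   the cohort is too small.
#' @return list `high` and `low`, each with `mean` and `sd` vectors, plus
#'   `n_extreme`.
#' @export
extreme_group_waveforms <- function(X, predictions, n_extreme = 10000) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stopf("empty input")
  stopifnot(length(predictions) == n)
  if (n_extreme > floor(n / 2)) {
    warnf("n_extreme = %d exceeds half the cohort; shrunk to %d",
          n_extreme, floor(n / 2))
    n_extreme <- floor(n / 2)
  }
  ord <- order(predictions)
  lo <- ord[seq_len(n_extreme)]
  hi <- ord[seq(n - n_extreme + 1, n)]
  grp <- function(idx) list(mean = colMeans(X[idx, , drop = FALSE]),
                            sd = apply(X[idx, , drop = FALSE], 2, sd))
  list(high = grp(hi), low = grp(lo), n_extreme = n_extreme,
       beat_dim = attr(X, "beat_dim"), leads = attr(X, "leads"))
}

#' Width of the QRS complex of a (mean) beat
#'
#' Measures the contiguous span around the largest absolute deflection where
#' the beat exceeds `frac` of that deflection; a simple morphology read-out
#' used to compare extreme-group averages.
#'
#' @param beat numeric vector (one lead of a beat).
#' @param fs sampling rate.
#' @param frac threshold fraction of the peak.
#' @return width in milliseconds.
#' @export
qrs_width_of <- function(beat, fs, frac = 0.2) {
  a <- abs(beat - median(beat))
  pk <- which.max(a)
  thr <- frac * a[pk]
  lo <- pk
  while (lo > 1 && a[lo - 1] > thr) lo <- lo - 1
  hi <- pk
  while (hi < length(a) && a[hi + 1] > thr) hi <- hi + 1
  (hi - lo + 1) / fs * 1000
}
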