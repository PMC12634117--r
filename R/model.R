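# Model core: residual 1-D CNN backbone with interchangeable heads.
# The network itself (forward, backprop, Adam loop) lives in src/net.cpp;
# this file holds configuration, the loss functions at the hazard scale,
# risk read-outs, and the user-facing training interface.

#' Backbone configuration
#'
#' The backbone is a 1-D residual CNN: a strided stem convolution followed
#' by residual blocks (two convolutions plus a strided 1x1 projection skip),
#' global average pooling, and a linear head with one logit per discrete
#' time interval (survival head) or a single logit (classification head).
#'
#' Two profiles are provided: `"default"` is a faithful small-scale
#' rendition of the residual ECG architecture (4 blocks, channels
#' 64/128/196/256, kernel 17, stride-4 downsampling, dropout 0.2, 4096
#' samples in); `"tiny"` (2 blocks, 1000 samples in) is sized for CPU
#' training.
#'
#' @param profile `"tiny"` or `"default"`.
#' @param n_leads input leads.
#' @param n_out number of output logits (set from the label grid by
#'   [train_risk_model()]).
#' @param input_len,channels,strides,kernel,dropout overrides.
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(profile = c("tiny", "default"), n_leads = 12,
                            n_out = 7, input_len = NULL, channels = NULL,
                            strides = NULL, kernel = NULL, dropout = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "tiny") {
    list(input_len = 1000, channels = c(16L, 24L, 32L),
         strides = c(2L, 4L, 4L), kernel = 9L, dropout = 0.1)
  } else {
    list(input_len = 4096, channels = c(32L, 64L, 128L, 196L, 256L),
         strides = c(2L, 4L, 4L, 4L, 4L), kernel = 17L, dropout = 0.2)
  }
  cfg <- list(
    profile = profile, n_leads = as.integer(n_leads), n_out = as.integer(n_out),
    input_len = as.integer(input_len %||% def$input_len),
    channels = as.integer(channels %||% def$channels),
    strides = as.integer(strides %||% def$strides),
    kernel = as.integer(kernel %||% def$kernel),
    dropout = dropout %||% def$dropout
  )
  stopifnot(length(cfg$channels) == length(cfg$strides),
            all(cfg$channels > 0), cfg$kernel %% 2 == 1)
  structure(cfg, class = c("backbone_config", "list"))
}

#' Discrete-time survival loss
#'
#' Negative log-likelihood of a per-interval Bernoulli hazard model:
#' `sum over observed intervals of -[y log h + (1 - y) log(1 - h)]`.
#' Masked intervals contribute exactly zero to the value and the gradient.
#' Hazards outside (0, 1) are clamped at `1e-7` with a warning.
#'
#' @param hazards numeric vector or matrix (rows = subjects) of per-interval
#'   hazards in (0, 1).
#' @param y event indicators, same shape.
#' @param mask observation mask (1 observed, 0 masked), same shape.
#' @param gradient also return `d loss / d hazards`.
#' @return the loss (summed over subjects and intervals); with
#'   `gradient = TRUE`, a list `value`, `gradient`.
#' @export
survival_loss <- function(hazards, y, mask = NULL, gradient = FALSE) {
  h <- as.matrix(hazards)
  y <- as.matrix(y)
  m <- if (is.null(mask)) matrix(1, nrow(h), ncol(h)) else as.matrix(mask)
  stopifnot(all(dim(h) == dim(y)), all(dim(h) == dim(m)))
  eps <- 1e-7
  if (any(m == 1 & (h <= 0 | h >= 1))) {
    warnf("hazards outside (0,1) clamped at %g", eps)
    h <- pmin(pmax(h, eps), 1 - eps)
  }
  term <- -(y * log(h) + (1 - y) * log(1 - h)) * m
  val <- sum(term)
  if (!gradient) return(val)
  grad <- (-y / h + (1 - y) / (1 - h)) * m
  list(value = val, gradient = grad)
}

#' Binary cross-entropy classification loss
#'
#' @param score predicted probability in (0, 1).
#' @param label binary label.
#' @return summed binary cross-entropy.
#' @export
classification_loss <- function(score, label) {
  stopifnot(all(label %in% c(0, 1)))
  survival_loss(score, label)
}

#' Risk read-outs from per-interval hazards
#'
#' The first timepoint's hazard is the diagnosis score (probability of
#' prevalent disease in the baseline window); the 5-year risk is
#' `1 - prod(1 - h_k)` over the post-baseline intervals ending at or before
#' 5 years. The baseline hazard is excluded from the 5-year risk: prediction
#' is conditional on no prevalent disease, matching the evaluation-time
#' exclusion of prevalent cases.
#'
#' @param hazards matrix (subjects x intervals) of hazards.
#' @param edges interval edges in years.
#' @param horizon prediction horizon in years.
#' @return data frame `diagnosis_score`, `risk` (cumulative risk at the
#'   horizon); the hazards are attached as an attribute.
#' @export
risk_from_hazards <- function(hazards, edges = default_interval_edges(),
                              horizon = 5) {
  h <- as.matrix(hazards)
  stopifnot(ncol(h) == length(edges) - 1)
  ks <- which(edges[-1] <= horizon)
  ks <- ks[ks >= 2]
  surv <- apply(1 - h[, ks, drop = FALSE], 1, prod)
  out <- data.frame(diagnosis_score = h[, 1], risk = 1 - surv)
  attr(out, "hazards") <- h
  out
}

# Internal: cfg list for the C++ routines.
.cpp_cfg <- function(cfg) {
  list(n_leads = cfg$n_leads, input_len = cfg$input_len, kernel = cfg$kernel,
       n_out = cfg$n_out, channels = cfg$channels, strides = cfg$strides,
       dropout = cfg$dropout)
}

#' Prepare model input tensors from ECGs
#'
#' Runs the pre-processing chain on each ECG and assembles the fixed-shape
#' input array. For the `tiny` profile the 400 Hz / 4096-sample output is
#' further low-pass filtered (40 Hz), decimated by 4 to 100 Hz and centre
#' cropped to 1000 samples.
#'
#' @param ecgs list of `ecg_signal`.
#' @param config a [backbone_config()].
#' @param verbose print progress every 500 ECGs.
#' @return numeric array `leads x input_len x n`; dimnames carry ecg ids.
#' @export
prepare_model_input <- function(ecgs, config, verbose = FALSE) {
  n <- length(ecgs)
  X <- array(0, c(config$n_leads, config$input_len, n))
  ids <- character(n)
  lp <- NULL
  for (i in seq_len(n)) {
    e <- preprocess_ecg(ecgs[[i]])
    sm <- e$samples
    if (config$input_len < 4096) {
      if (is.null(lp)) {
        f <- signal::butter(4, 40 / 200, type = "low")
        lp <- list(b = f$b, a = f$a)
      }
      dec <- t(apply(sm, 1, function(x) zp_filter(lp, x)[seq(1, 4096, 4)]))
      start <- floor((ncol(dec) - config$input_len) / 2) + 1
      sm <- dec[, start:(start + config$input_len - 1), drop = FALSE]
    }
    X[, , i] <- sm[seq_len(config$n_leads), , drop = FALSE]
    ids[i] <- ecgs[[i]]$ecg_id
    if (verbose && i %% 500 == 0) message("prepared ", i, "/", n, " ECGs")
  }
  dimnames(X) <- list(NULL, NULL, ids)
  X
}

#' Train a risk model
#'
#' Trains the residual CNN by mini-batch Adam on the masked discrete-time
#' survival likelihood (survival head) or binary cross-entropy against the
#' prevalent-disease label (classification head). Model selection is by
#' tuning-set loss with early stopping and learning-rate reduction on
#' plateau. Training is deterministic under `seed`.
#'
#' @param X input array from [prepare_model_input()].
#' @param labels `survival_labels` aligned with `X` (same pair order).
#' @param split data frame from [split_cohort()].
#' @param head `"survival"` or `"classification"`.
#' @param config [backbone_config()]; `n_out` is set from the label grid.
#' @param epochs,batch_size,lr,patience,lr_patience,lr_factor optimizer
#'   settings (Adam; early stopping on tuning loss).
#' @param seed integer seed for initialization, shuffling, and dropout.
#' @param verbose print per-epoch losses.
#' @return object of class `valvecg_model`.
#' @export
train_risk_model <- function(X, labels, split, head = c("survival", "classification"),
                             config = backbone_config("tiny"),
                             epochs = 20, batch_size = 64, lr = 1e-3,
                             patience = 5, lr_patience = 2, lr_factor = 0.5,
                             seed = 1, verbose = FALSE) {
  head <- match.arg(head)
  n <- dim(X)[3]
  stopifnot(nrow(labels$y) == n)
  if (n == 0) stopf("empty dataset")
  if (head == "survival") {
    Y <- labels$y
    M <- labels$mask
  } else {
    # classification uses baseline pairs only (|interval| <= 60 d): the
    # binary label is prevalent significant disease at the paired echo
    Y <- matrix(as.numeric(labels$prevalent), ncol = 1)
    iv <- labels$pairs$interval_days
    M <- matrix(as.numeric(!is.na(iv) & abs(iv) <= 60), ncol = 1)
  }
  config$n_out <- ncol(Y)
  sp <- setNames(as.character(split$split), split$patient_id)
  grp <- sp[labels$pairs$patient_id]
  train_idx <- which(grp == "train" & rowSums(M) > 0) - 1L
  tune_idx <- which(grp == "tune" & rowSums(M) > 0) - 1L
  if (!length(train_idx)) stopf("empty training set")
  fit <- cpp_net_train(X, Y, M, .cpp_cfg(config), train_idx, tune_idx,
                       epochs, batch_size, lr, seed, patience, lr_patience,
                       lr_factor, verbose)
  structure(list(weights = fit$weights, config = config, head = head,
                 edges = labels$edges, valve = labels$valve,
                 log = data.frame(epoch = seq_along(fit$train_loss),
                                  train_loss = fit$train_loss,
                                  tune_loss = fit$tune_loss, lr = fit$lr),
                 best_epoch = fit$best_epoch,
                 best_tune_loss = fit$best_tune_loss, seed = seed),
            class = "valvecg_model")
}

#' @export
print.valvecg_model <- function(x, ...) {
  cat(sprintf("<valvecg_model %s head, %s profile, valve %s: %d epochs (best %d, tune loss %.4f)>\n",
              x$head, x$config$profile, x$valve %||% "?", nrow(x$log),
              x$best_epoch, x$best_tune_loss))
  invisible(x)
}

#' Predict risk outputs for new ECGs
#'
#' @param object a `valvecg_model`.
#' @param X input array (`leads x input_len x n`).
#' @param horizon horizon in years for the cumulative risk read-out.
#' @param ... unused.
#' @return for the survival head, a data frame with `diagnosis_score`
#'   (first-timepoint hazard) and `risk` (cumulative risk at the horizon,
#'   baseline interval excluded), hazards attached as an attribute; for the
#'   classification head, a data frame with `score`.
#' @export
predict.valvecg_model <- function(object, X, horizon = 5, ...) {
  logits <- cpp_net_predict(object$weights, .cpp_cfg(object$config), X)
  probs <- plogis(logits)
  ids <- dimnames(X)[[3]]
  if (object$head == "classification") {
    out <- data.frame(score = probs[, 1])
    if (!is.null(ids)) out$ecg_id <- ids
    return(out)
  }
  out <- risk_from_hazards(probs, object$edges, horizon)
  if (!is.null(ids)) out$ecg_id <- ids
  out
}
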