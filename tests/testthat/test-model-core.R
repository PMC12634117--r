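# Model core: losses (closed forms, masking, gradients), risk read-outs,
# network forward contracts, and learning sanity on a controlled problem.

tiny_cfg <- function(n_out = 3) {
  list(n_leads = 2L, input_len = 40L, kernel = 5L, n_out = as.integer(n_out),
       channels = c(4L, 6L), strides = c(2L, 2L), dropout = 0)
}

test_that("survival loss matches the closed-form Bernoulli sum", {
  expect_equal(survival_loss(0.5, 1), -log(0.5), tolerance = 1e-12)
  expect_equal(survival_loss(c(0.1, 0.1), c(0, 0)), -2 * log(0.9),
               tolerance = 1e-12)
  # worked values
  expect_equal(round(survival_loss(0.5, 1), 4), 0.6931)
  expect_equal(round(survival_loss(c(0.1, 0.1), c(0, 0)), 4), 0.2107)
  # fully masked label contributes exactly zero
  expect_identical(survival_loss(c(0.3, 0.9), c(1, 0), mask = c(0, 0)), 0)
})

test_that("masked intervals contribute zero to value and gradient", {
  h <- matrix(c(0.2, 0.7, 0.9), 1)
  y <- matrix(c(0, 1, 0), 1)
  m <- matrix(c(1, 1, 0), 1)
  base <- survival_loss(h, y, m, gradient = TRUE)
  expect_equal(base$gradient[1, 3], 0)
  h2 <- h; h2[1, 3] <- 0.01
  expect_equal(survival_loss(h2, y, m), base$value, tolerance = 1e-15)
})

test_that("survival loss gradient matches central finite differences", {
  set.seed(30)
  for (r in 1:20) {
    K <- sample(2:8, 1)
    h <- matrix(runif(K, 0.05, 0.95), 1)
    y <- matrix(rbinom(K, 1, 0.3), 1)
    m <- matrix(rbinom(K, 1, 0.7), 1)
    g <- survival_loss(h, y, m, gradient = TRUE)$gradient
    eps <- 1e-6
    for (k in seq_len(K)) {
      hp <- h; hp[k] <- h[k] + eps
      hm <- h; hm[k] <- h[k] - eps
      fd <- (survival_loss(hp, y, m) - survival_loss(hm, y, m)) / (2 * eps)
      denom <- max(1e-8, abs(fd) + abs(g[k]))
      expect_lt(abs(fd - g[k]) / denom, 1e-5)
    }
  }
})

test_that("hazards outside (0,1) are clamped with a warning", {
  expect_warning(v <- survival_loss(c(0, 1), c(0, 1)), "clamped")
  expect_true(is.finite(v))
})

test_that("classification loss covers the worked values and limits", {
  expect_equal(round(classification_loss(0.5, 1), 4), 0.6931)
  expect_equal(classification_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  expect_lt(classification_loss(1 - 1e-9, 1), 1e-6)
  expect_error(classification_loss(0.5, 2), "label")
})

test_that("risk read-outs follow the product-limit identity", {
  edges <- default_interval_edges()
  # all logits zero -> h = 0.5 everywhere; risk over 2 post-baseline
  # intervals is 1 - 0.25
  h <- matrix(0.5, 1, 7)
  r2 <- risk_from_hazards(h, edges, horizon = 2)
  expect_equal(r2$diagnosis_score, 0.5)
  expect_equal(r2$risk, 0.75)
  # vanishing hazards -> vanishing risk
  expect_lt(risk_from_hazards(matrix(1e-9, 1, 7), edges)$risk, 1e-6)
  # random hazards vs brute-force product oracle, all horizons
  set.seed(31)
  for (r in 1:50) {
    hv <- matrix(runif(7), 1)
    for (hz in c(1, 3, 5)) {
      ks <- which(edges[-1] <= hz & seq_len(7) >= 2)
      oracle <- 1 - prod(1 - hv[ks])
      expect_equal(risk_from_hazards(hv, edges, hz)$risk, oracle,
                   tolerance = 1e-12)
    }
  }
  # monotone non-decreasing in every hazard
  hv <- matrix(runif(7, 0.1, 0.5), 1)
  base <- risk_from_hazards(hv, edges)$risk
  for (k in 2:6) {
    hv2 <- hv; hv2[k] <- hv[k] + 0.2
    expect_gte(risk_from_hazards(hv2, edges)$risk, base)
  }
})

test_that("network forward is deterministic and shape-checked", {
  cfg <- tiny_cfg()
  w <- valvecg:::cpp_net_init(cfg, 5)
  X <- withr::with_seed(6, array(rnorm(2 * 40 * 4), c(2, 40, 4)))
  p1 <- valvecg:::cpp_net_predict(w, cfg, X)
  p2 <- valvecg:::cpp_net_predict(w, cfg, X)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(4, 3))
})

test_that("full-network analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  set.seed(41)
  X <- array(rnorm(2 * 40 * 3), c(2, 40, 3))
  Y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  M <- matrix(rbinom(9, 1, 0.8), 3, 3)
  w <- valvecg:::cpp_net_init(cfg, 7)
  # head starts at zero; nudge so its gradient path is exercised
  w[[length(w) - 1]][] <- rnorm(length(w[[length(w) - 1]]), 0, 0.1)
  g <- valvecg:::cpp_net_grad(w, cfg, X, Y, M)
  h <- 1e-5
  for (p in seq_along(w)) {
    for (rep in 1:3) {
      i <- sample(length(w[[p]]), 1)
      wp <- w; wp[[p]][i] <- wp[[p]][i] + h
      wm <- w; wm[[p]][i] <- wm[[p]][i] - h
      fd <- (valvecg:::cpp_net_loss(wp, cfg, X, Y, M) -
               valvecg:::cpp_net_loss(wm, cfg, X, Y, M)) / (2 * h)
      denom <- max(1e-6, abs(fd) + abs(g[[p]][i]))
      expect_lt(abs(fd - g[[p]][i]) / denom, 1e-5)
    }
  }
})

test_that("perturbing hazards in masked intervals never changes the net loss", {
  cfg <- tiny_cfg()
  set.seed(43)
  X <- array(rnorm(2 * 40 * 2), c(2, 40, 2))
  Y <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3)
  M <- matrix(c(1, 1, 1, 0, 0, 1), 2, 3)  # interval 2 masked for row 1 etc.
  w <- valvecg:::cpp_net_init(cfg, 9)
  g <- valvecg:::cpp_net_grad(w, cfg, X, Y, M)
  # gradient wrt the head row of a fully masked interval is zero
  head_w <- length(w) - 1
  masked_k <- which(colSums(M) == 0)
  if (length(masked_k))
    expect_true(all(g[[head_w]][masked_k, ] == 0))
  l1 <- valvecg:::cpp_net_loss(w, cfg, X, Y, M)
  Y2 <- Y; Y2[M == 0] <- 1 - Y2[M == 0]  # flip labels under the mask
  expect_identical(l1, valvecg:::cpp_net_loss(w, cfg, X, Y2, M))
})

test_that("training learns a planted signal and respects determinism", {
  set.seed(50)
  n <- 240
  X <- array(rnorm(2 * 40 * n), c(2, 40, n))
  sig <- rnorm(n)
  for (i in seq_len(n)) X[1, , i] <- X[1, , i] + sig[i]
  Y <- matrix(as.numeric(runif(n) < plogis(2 * sig)), ncol = 1)
  M <- matrix(1, n, 1)
  cfg <- tiny_cfg(1)
  fit <- valvecg:::cpp_net_train(X, Y, M, cfg, 0:179, 180:219, 12, 32,
                                 1e-3, 7, 12, 3, 0.5, FALSE)
  expect_lt(min(fit$tune_loss), fit$tune_loss[1])
  pr <- valvecg:::cpp_net_predict(fit$weights, cfg, X)
  expect_gt(auroc(pr[221:240], Y[221:240]), 0.7)
  fit2 <- valvecg:::cpp_net_train(X, Y, M, cfg, 0:179, 180:219, 12, 32,
                                  1e-3, 7, 12, 3, 0.5, FALSE)
  expect_identical(fit$weights, fit2$weights)
})

test_that("train_risk_model rejects an empty dataset", {
  lab <- structure(list(y = matrix(0, 0, 7), mask = matrix(0, 0, 7),
                        edges = default_interval_edges(),
                        pairs = data.frame(patient_id = character(),
                                           interval_days = numeric()),
                        prevalent = logical(0)),
                   class = "survival_labels")
  X <- array(0, c(2, 40, 0))
  sp <- data.frame(patient_id = character(), split = character())
  expect_error(train_risk_model(X, lab, sp, config = backbone_config("tiny", n_leads = 2)),
               "empty")
})
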