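test_that("attention reduces correctly in degenerate cases and matches its oracle", {
  set.seed(1)
  v <- matrix(rnorm(4), 1, 4)
  expect_equal(attention(v, v, v), v, tolerance = 1e-12)

  # identical keys: uniform weights, output = mean of V rows, independent of Q
  K <- matrix(rep(rnorm(4), 3), 3, 4, byrow = TRUE)
  V <- matrix(rnorm(12), 3, 4)
  Q1 <- matrix(rnorm(8), 2, 4)
  Q2 <- matrix(rnorm(8), 2, 4)
  m <- matrix(colMeans(V), 2, 4, byrow = TRUE)
  expect_equal(attention(Q1, K, V), m, tolerance = 1e-12)
  expect_equal(attention(Q2, K, V), m, tolerance = 1e-12)

  Q <- matrix(rnorm(9), 3, 3); K <- matrix(rnorm(9), 3, 3)
  V <- matrix(rnorm(9), 3, 3)
  expect_equal(attention(Q, K, V), oracle_attention(Q, K, V),
               tolerance = 1e-6)
  expect_error(attention(matrix(1, 1, 2), K, V), "widths differ")
})

test_that("multi_head reduces to attention for h = 1 with identity projections", {
  set.seed(2)
  d <- 4
  p <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
  Q <- matrix(rnorm(2 * d), 2, d); K <- matrix(rnorm(3 * d), 3, d)
  V <- matrix(rnorm(3 * d), 3, d)
  expect_equal(multi_head(Q, K, V, p, h = 1), attention(Q, K, V),
               tolerance = 1e-12)

  p0 <- p; p0$Wo <- matrix(0, d, d)
  expect_true(all(multi_head(Q, K, V, p0, h = 1) == 0))

  # h = 2: per-head manual computation on the projected column blocks
  set.seed(3)
  p2 <- lapply(list(Wq = 1, Wk = 1, Wv = 1, Wo = 1),
               function(i) glorot_test(d, d))
  Qp <- Q %*% p2$Wq; Kp <- K %*% p2$Wk; Vp <- V %*% p2$Wv
  manual <- cbind(oracle_attention(Qp[, 1:2], Kp[, 1:2], Vp[, 1:2]),
                  oracle_attention(Qp[, 3:4], Kp[, 3:4], Vp[, 3:4])) %*% p2$Wo
  expect_equal(multi_head(Q, K, V, p2, h = 2), manual, tolerance = 1e-8)
  expect_error(multi_head(Q, K, V, p2, h = 3), "divisible")
})

test_that("encoder keeps shape, is permutation-equivariant, and normalizes", {
  set.seed(4)
  d <- 8
  params <- init_encoder_params(d, 16)
  for (n in 1:10) {
    X <- matrix(rnorm(n * d), n, d)
    expect_equal(dim(encoder(X, params, h = 2)), c(n, d))
  }
  X <- matrix(rnorm(6 * d), 6, d)
  out <- encoder(X, params, h = 2)
  perm <- sample(6)
  expect_equal(encoder(X[perm, ], params, h = 2), out[perm, ],
               tolerance = 1e-12)
  expect_error(encoder(matrix(0, 0, d), params, h = 2), "empty")

  # layer-norm rows: mean 0, unit variance before the affine map
  ln <- visitrx:::layernorm_fwd(matrix(rnorm(5 * d, 3, 2), 5, d),
                                g = rep(1, d), b = numeric(d))
  expect_equal(rowMeans(ln$out), numeric(5), tolerance = 1e-10)
  expect_equal(apply(ln$out, 1, function(r) mean(r^2)), rep(1, 5),
               tolerance = 1e-4)
})

test_that("pool_set averages rows and ignores order", {
  expect_equal(pool_set(matrix(c(1, 5), 1, 2)), c(1, 5))
  expect_equal(pool_set(rbind(c(1, 3), c(3, 1))), c(2, 2))
  set.seed(5)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(pool_set(X[sample(5), ]), pool_set(X))
  expect_error(pool_set(matrix(0, 0, 3)), "zero rows")
})

test_that("ca_mhsa matches its compositional oracle", {
  set.seed(6)
  d <- 6
  p <- init_mh_params(2 * d)
  Q <- matrix(rnorm(4 * d), 4, d)
  D <- matrix(rnorm(3 * d), 3, d)
  P <- matrix(rnorm(2 * d), 2, d)
  out <- ca_mhsa(Q, D, P, p, h = 2)
  expect_length(out, 2 * d)
  CA <- cbind(oracle_attention(Q, D, D), oracle_attention(Q, P, P))
  expect_equal(out, colMeans(multi_head(CA, CA, CA, p, h = 2)),
               tolerance = 1e-8)

  # single query row: just the self-attended concat, no pooling effect
  q1 <- ca_mhsa(Q[1, , drop = FALSE], D, P, p, h = 2)
  expect_length(q1, 2 * d)

  # constant keys/values: output ignores the query content
  Dc <- matrix(rep(rnorm(d), 3), 3, d, byrow = TRUE)
  Pc <- matrix(rep(rnorm(d), 2), 2, d, byrow = TRUE)
  expect_equal(ca_mhsa(Q, Dc, Pc, p, h = 2),
               ca_mhsa(Q * 5 + 1, Dc, Pc, p, h = 2), tolerance = 1e-10)
  expect_error(ca_mhsa(Q, matrix(0, 0, d), P, p, h = 2), "empty")
})

test_that("fuse_predict thresholds strictly and monotonically", {
  b <- fuse_predict(numeric(5), numeric(5), numeric(5), delta = 0.4)
  expect_equal(b$o_hat, rep(0.5, 5))
  expect_equal(b$m_hat, rep(1L, 5))

  logits <- stats::qlogis(c(0.39, 0.40, 0.41))
  b2 <- fuse_predict(logits, numeric(3), numeric(3), delta = 0.4)
  expect_equal(b2$m_hat, c(0L, 0L, 1L))

  set.seed(7)
  o <- fuse_predict(rnorm(20), rnorm(20), rnorm(20), 0.5)
  prev <- rep(1L, 20)
  for (delta in seq(0.05, 0.95, by = 0.05)) {
    cur <- as.integer(o$o_hat > delta)
    expect_true(all(cur <= prev))
    prev <- cur
  }
  expect_error(fuse_predict(numeric(3), numeric(2), numeric(3)), "length")
})

test_that("bce_loss matches its closed forms and loop oracle", {
  expect_lt(bce_loss(c(1, 0), c(1 - 1e-12, 1e-12)), 1e-9)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), 2 * log(2))
  # clipping keeps impossible probabilities finite
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  set.seed(8)
  for (i in 1:20) {
    m <- rbinom(15, 1, 0.4)
    o <- runif(15)
    expect_equal(bce_loss(m, o), oracle_bce(m, o), tolerance = 1e-10)
  }
  # batch form averages per-visit sums
  M <- rbind(c(1, 0), c(0, 1))
  O <- rbind(c(0.5, 0.5), c(0.25, 0.25))
  expect_equal(bce_loss(M, O),
               mean(c(oracle_bce(M[1, ], O[1, ]), oracle_bce(M[2, ], O[2, ]))))
  expect_error(bce_loss(c(1, 0), c(0.5)), "mismatch")
})

test_that("ddi_loss is the full quadratic form", {
  D <- matrix(0, 3, 3); D[2, 3] <- D[3, 2] <- 1
  expect_equal(ddi_loss(c(1, 1, 0), matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3)), 2)
  expect_equal(ddi_loss(c(0.5, 0.5, 0), matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3)),
               0.5)
  set.seed(9)
  for (i in 1:20) {
    o <- runif(10)
    Dm <- matrix(rbinom(100, 1, 0.2), 10)
    Dm <- 1 * ((Dm + t(Dm)) > 0); diag(Dm) <- 0
    expect_equal(ddi_loss(o, Dm), oracle_ddi_loss(o, Dm), tolerance = 1e-10)
  }
  expect_error(ddi_loss(c(1, 0), matrix(0, 3, 3)), "shape")
})

test_that("total_loss combines linearly and honours the ablation flag", {
  expect_equal(total_loss(1, 2, alpha = 0)$total, 1)
  expect_equal(total_loss(1, 2, alpha = 0.5)$total, 2)
  expect_equal(total_loss(1, 2, alpha = 0.5, use_ddi_loss = FALSE)$total, 1)
  for (a in seq(0, 2, by = 0.25))
    expect_equal(total_loss(1.5, 3, a)$total, 1.5 + a * 3)
  expect_error(total_loss(Inf, 1, 0.5), "non-finite")
})

test_that("model_config validates its invariants", {
  expect_error(model_config(dim = 10, heads = 4), "divisible")
  expect_error(model_config(delta = 1.2), "delta")
  expect_error(model_config(alpha = -1), "alpha")
})

test_that("branch entry points honour shapes, ablations and cold start", {
  s <- tiny_setup(dim = 16, heads = 2, ffn = 32)
  model <- s$model
  E <- build_substructure_table(s$lib, model$params$gin)$matrix
  v <- s$cohort$patients[[1]]$visits[[1]]
  m_c <- visit_forward(model, v$diagnoses, v$procedures, E)
  expect_length(m_c, 20)
  expect_true(all(is.finite(m_c)))
  expect_error(visit_forward(model, character(0), v$procedures, E), "empty")

  # ablation: block 1 off changes the logits but keeps the shape
  m_ab <- model
  m_ab$config$use_block1 <- FALSE
  m_c0 <- visit_forward(m_ab, v$diagnoses, v$procedures, E)
  expect_length(m_c0, 20)
  expect_false(isTRUE(all.equal(m_c, m_c0)))

  # cold start: both history branches are exactly zero
  expect_equal(history_rnn_forward(model, list()), numeric(20))
  expect_equal(effectiveness_forward(model, NULL), numeric(20))

  # empty procedure set runs through the learned no-procedure token
  expect_silent(visit_forward(model, v$diagnoses, character(0), E))
})

test_that("history branch matches a hand-rolled GRU recurrence", {
  s <- tiny_setup(dim = 8, heads = 2, ffn = 16)
  model <- s$model
  vocab <- model$vocab
  hist <- list(c("RX001", "RX002"), c("RX003"), c("RX002", "RX004"))
  m_h <- history_rnn_forward(model, hist)
  expect_length(m_h, 20)

  # independent recurrence with the same convention:
  # h = (1 - z) h_prev + z tanh(Wh x + Uh (r h_prev) + bh)
  p <- model$params$gru
  sig <- function(x) 1 / (1 + exp(-x))
  h <- numeric(8)
  for (codes in hist) {
    x <- colMeans(model$params$emb_m[code_index(vocab, codes, "medication"), ,
                                     drop = FALSE])
    z <- sig(drop(x %*% p$Wz) + drop(h %*% p$Uz) + p$bz)
    r <- sig(drop(x %*% p$Wr) + drop(h %*% p$Ur) + p$br)
    hc <- tanh(drop(x %*% p$Wh) + drop((r * h) %*% p$Uh) + p$bh)
    h <- (1 - z) * h + z * hc
  }
  expected <- drop(h %*% model$params$proj_W) + model$params$proj_b
  expect_equal(m_h, expected, tolerance = 1e-6)

  # single historical visit: one GRU step then projection
  one <- history_rnn_forward(model, hist[1])
  expect_length(one, 20)
  expect_false(isTRUE(all.equal(one, m_h)))
})

test_that("effectiveness branch matches its compositional oracle", {
  s <- tiny_setup(dim = 8, heads = 2, ffn = 16)
  model <- s$model
  prev <- s$cohort$patients[[1]]$visits[[1]]
  m_p <- effectiveness_forward(model, prev)
  expect_length(m_p, 20)

  vocab <- model$vocab
  p <- model$params
  Mrows <- p$emb_m[code_index(vocab, prev$medications, "medication"), ,
                   drop = FALSE]
  Dp <- encoder(p$emb_d[code_index(vocab, prev$diagnoses, "diagnosis"), ,
                        drop = FALSE], p$enc_d_prev, 2)
  pidx <- code_index(vocab, prev$procedures, "procedure")
  if (length(pidx) == 0) pidx <- nrow(p$emb_p)
  Pp <- encoder(p$emb_p[pidx, , drop = FALSE], p$enc_p_prev, 2)
  E2 <- ca_mhsa(Mrows, Dp, Pp, p$ca2, 2)
  expected <- drop(crossprod(p$ff2_W, c(E2, colMeans(Mrows)))) + p$ff2_b
  expect_equal(m_p, expected, tolerance = 1e-10)
})

test_that("predictions are invariant to code order within a visit", {
  s <- tiny_setup(dim = 16, heads = 2, ffn = 32)
  model <- s$model
  E <- build_substructure_table(s$lib, model$params$gin)$matrix
  pat <- Filter(function(p) length(p$visits) >= 2, s$cohort$patients)[[1]]
  v <- pat$visits[[2]]
  set.seed(10)
  base <- visit_forward(model, v$diagnoses, v$procedures, E)
  for (i in 1:5) {
    shuf <- visit_forward(model, sample(v$diagnoses), sample(v$procedures), E)
    expect_lt(max(abs(shuf - base)), 1e-5)
  }
  hist <- list(pat$visits[[1]]$medications)
  m_h <- history_rnn_forward(model, hist)
  m_h_s <- history_rnn_forward(model, list(sample(hist[[1]])))
  expect_lt(max(abs(m_h - m_h_s)), 1e-5)
})

test_that("cold start uses only the current visit; ablated model still runs", {
  s <- tiny_setup(dim = 16, heads = 2, ffn = 32)
  model <- s$model
  pat <- s$cohort$patients[[1]]
  ex <- visitrx:::make_example(pat, 1L, model$vocab)
  E <- build_substructure_table(s$lib, model$params$gin)$matrix
  fwd <- visitrx:::example_forward(model$params, model$config, ex, E)
  expect_equal(fwd$m_h, numeric(20))
  expect_equal(fwd$m_p, numeric(20))
  expect_equal(fwd$o_hat, visitrx:::sigmoid(fwd$m_c))

  bare <- model
  bare$config$use_block1 <- FALSE
  bare$config$use_block2 <- FALSE
  bare$config$use_rnn <- FALSE
  preds <- predict_cohort(bare, s$cohort)
  for (p in preds[1:5]) {
    expect_true(all(p$o_hat > 0 & p$o_hat < 1))
    expect_true(all(is.finite(p$o_hat)))
  }
})

test_that("checkpoints round trip the whole model", {
  s <- tiny_setup(dim = 8, heads = 2, ffn = 16)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(s$model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, s$model$params)
  expect_identical(back$vocab_hash, s$model$vocab_hash)
  p1 <- predict_cohort(s$model, s$cohort)[[1]]
  p2 <- predict_cohort(back, s$cohort)[[1]]
  expect_identical(p1$o_hat, p2$o_hat)
})
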