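# Independent brute-force oracles used across test files. These deliberately
# avoid the package's vectorised implementations: metrics are computed with
# explicit loops over set elements and ranks, attention with a two-loop
# softmax-weighted sum.

oracle_jaccard <- function(preds) {
  vals <- numeric(length(preds))
  for (i in seq_along(preds)) {
    a <- preds[[i]]$truth; b <- preds[[i]]$predicted
    u <- unique(c(a, b))
    if (length(u) == 0) { vals[i] <- 1; next }
    inter <- 0
    for (x in a) if (x %in% b) inter <- inter + 1
    vals[i] <- inter / length(u)
  }
  mean(vals)
}

oracle_f1 <- function(preds) {
  vals <- numeric(length(preds))
  for (i in seq_along(preds)) {
    a <- preds[[i]]$truth; b <- preds[[i]]$predicted
    inter <- 0
    for (x in a) if (x %in% b) inter <- inter + 1
    prec <- if (length(b) == 0) 0 else inter / length(b)
    rec <- if (length(a) == 0) 0 else inter / length(a)
    vals[i] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  mean(vals)
}

oracle_ddi_rate <- function(preds, D) {
  vals <- numeric(length(preds))
  for (i in seq_along(preds)) {
    s <- preds[[i]]$predicted
    if (length(s) < 2) { vals[i] <- 0; next }
    hits <- 0; tot <- 0
    for (a in seq_along(s)) for (b in seq_along(s)) {
      if (b <= a) next
      tot <- tot + 1
      if (D[s[a], s[b]] == 1) hits <- hits + 1
    }
    vals[i] <- hits / tot
  }
  mean(vals)
}

# Eq.-22-style step sum: walk the ranked list, accumulate Precision(k) *
# (Recall(k) - Recall(k-1)).
oracle_prauc <- function(preds) {
  vals <- c()
  for (p in preds) {
    npos <- length(p$truth)
    if (npos == 0) next
    y <- numeric(length(p$o_hat)); y[p$truth] <- 1
    ord <- order(p$o_hat, decreasing = TRUE)
    tp <- 0; rec_prev <- 0; auc <- 0
    for (k in seq_along(ord)) {
      if (y[ord[k]] == 1) tp <- tp + 1
      prec_k <- tp / k
      rec_k <- tp / npos
      auc <- auc + prec_k * (rec_k - rec_prev)
      rec_prev <- rec_k
    }
    vals <- c(vals, auc)
  }
  if (length(vals)) mean(vals) else 0
}

oracle_attention <- function(Q, K, V) {
  out <- matrix(0, nrow(Q), ncol(V))
  scale <- sqrt(ncol(K))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / scale
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

oracle_bce <- function(m, o) {
  o <- pmin(pmax(o, 1e-12), 1 - 1e-12)
  tot <- 0
  for (i in seq_along(m))
    tot <- tot - (m[i] * log(o[i]) + (1 - m[i]) * log(1 - o[i]))
  tot
}

oracle_ddi_loss <- function(o, D) {
  tot <- 0
  for (i in seq_along(o)) for (j in seq_along(o))
    tot <- tot + D[i, j] * o[i] * o[j]
  tot
}

random_predictions <- function(n, n_drugs, seed, with_scores = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    truth <- which(runif(n_drugs) < 0.3)
    predicted <- which(runif(n_drugs) < 0.3)
    visit_prediction(truth, predicted,
                     if (with_scores) runif(n_drugs) else numeric(n_drugs),
                     sprintf("PT%03d", i), 1L)
  })
}

# small fully wired setup shared by model / training / cli tests
tiny_setup <- function(seed = 42, n_patients = 20, dim = 32, heads = 4,
                       ffn = 64, ...) {
  cfg <- generator_config(n_patients = n_patients, n_diagnoses = 30,
                          n_procedures = 10, n_medications = 20,
                          fragment_pool_size = 15, seed = seed)
  gen <- generate_cohort(cfg)
  lib <- generate_fragment_library(cfg)
  ddi <- generate_ddi(cfg)
  mcfg <- model_config(dim = dim, heads = heads, ffn_size = ffn, seed = 1, ...)
  model <- init_model(mcfg, gen$cohort$vocabulary, lib)
  list(cfg = cfg, cohort = gen$cohort, truth = gen$truth, lib = lib,
       ddi = ddi, model = model)
}

# per-diagnosis frequency baseline: score(drug) = max over the visit's
# diagnoses of the training-set conditional frequency P(drug | diagnosis);
# recommend drugs with score > delta
freq_baseline_predict <- function(train_cohort, test_cohort, delta = 0.4) {
  vocab <- train_cohort$vocabulary
  nD <- vocab_size(vocab, "diagnosis")
  nM <- vocab_size(vocab, "medication")
  cnt_d <- numeric(nD)
  cnt_dm <- matrix(0, nD, nM)
  for (p in train_cohort$patients) for (v in p$visits) {
    di <- code_index(vocab, v$diagnoses, "diagnosis")
    mi <- code_index(vocab, v$medications, "medication")
    cnt_d[di] <- cnt_d[di] + 1
    cnt_dm[di, mi] <- cnt_dm[di, mi] + 1
  }
  freq <- cnt_dm / pmax(cnt_d, 1)
  out <- list()
  for (p in test_cohort$patients) for (t in seq_along(p$visits)) {
    v <- p$visits[[t]]
    di <- code_index(vocab, v$diagnoses, "diagnosis")
    sc <- apply(freq[di, , drop = FALSE], 2, max)
    out[[length(out) + 1L]] <- visit_prediction(
      code_index(vocab, v$medications, "medication"),
      which(sc > delta), sc, p$patient_id, t)
  }
  out
}

cohort_signature <- function(cohort) {
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_cohort(cohort, path)
  paste(readLines(path), collapse = "\n")
}

glorot_test <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.3), nr, nc)

init_gin_params_test <- function(feature_dim, dim, seed) {
  set.seed(seed)
  make <- function(d_in) list(W1 = glorot_test(d_in, dim), b1 = rnorm(dim, sd = 0.1),
                              W2 = glorot_test(dim, dim), b2 = rnorm(dim, sd = 0.1),
                              eps = runif(1, -0.1, 0.3))
  list(make(feature_dim), make(dim), make(dim))
}
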