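#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size visits per optimisation step.
#' @param epochs maximum number of epochs.
#' @param seed master seed for shuffling (one derived stream per epoch).
#' @param patience early-stopping patience on validation Jaccard; ignored
#'   when no validation cohort is supplied.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 16L,
                         epochs = 50L, seed = 1023L, patience = 10L,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L, patience >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 patience = as.integer(patience), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build a visit-level training sequence
#'
#' Produces one example per visit, globally shuffled across patients while
#' preserving each patient's internal chronological order. The interleaving
#' is sampled uniformly: a random permutation of per-visit patient labels is
#' drawn, then each patient's visits fill their label positions in
#' chronological order.
#'
#' @param cohort an `ehr_cohort`.
#' @param seed integer seed.
#' @return list of visit examples: `patient_id`, `t`, `visit` (the
#'   `ehr_visit`), `history` (list of that patient's earlier visits,
#'   chronological).
#' @export
build_visit_sequence <- function(cohort, seed = 1L) {
  if (length(cohort$patients) == 0L) stop("empty cohort")
  counts <- vapply(cohort$patients, function(p) length(p$visits), integer(1))
  labels <- rep(seq_along(cohort$patients), counts)
  perm <- local_rng(seed, sample(labels))
  next_t <- integer(length(cohort$patients))
  out <- vector("list", length(perm))
  for (i in seq_along(perm)) {
    pi <- perm[i]
    next_t[pi] <- next_t[pi] + 1L
    t <- next_t[pi]
    patient <- cohort$patients[[pi]]
    out[[i]] <- list(patient_id = patient$patient_id, t = t,
                     visit = patient$visits[[t]],
                     history = if (t > 1L) patient$visits[seq_len(t - 1L)]
                               else list())
  }
  out
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params)
  list(m = grad_zero_like(params), v = grad_zero_like(params), t = 0L)

# recursive Adam step; entries missing from `grads` are left untouched
adam_walk <- function(p, g, m, v, lr_t, b1, b2, eps) {
  if (is.list(p)) {
    for (nm in names(p)) {
      if (is.null(g[[nm]])) next
      r <- adam_walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr_t, b1, b2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  list(p = p - lr_t * m / (sqrt(v) + eps), m = m, v = v)
}

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  r <- adam_walk(params, grads, state$m, state$v, lr_t, b1, b2, eps)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

## ---- training loop -------------------------------------------------------

# gradient of the batch-averaged total loss at the fused logits
loss_logit_grad <- function(o_hat, y, D, alpha, use_ddi, batch_size) {
  g <- o_hat - y
  if (use_ddi) g <- g + alpha * 2 * drop(D %*% o_hat) * o_hat * (1 - o_hat)
  g / batch_size
}

#' Train a model visit-by-visit
#'
#' Each epoch draws a fresh globally shuffled visit sequence (per-patient
#' chronology preserved), batches the examples, computes the combined BCE +
#' DDI loss and takes an Adam step. The substructure table is recomputed each
#' batch so gradients flow end-to-end into the GIN. When a validation cohort
#' is given, the checkpoint with the best validation Jaccard is kept and
#' training early-stops after `patience` non-improving epochs.
#'
#' @param model a `visitrx_model`.
#' @param train_cohort,validation_cohort `ehr_cohort`s sharing the model's
#'   vocabulary (`validation_cohort` may be `NULL`).
#' @param ddi binary symmetric `|M| x |M|` DDI matrix.
#' @param config a [train_config()].
#' @return list with `model` (best parameters) and `log` (a data.frame of
#'   per-epoch loss and validation metrics).
#' @export
train <- function(model, train_cohort, ddi, config = train_config(),
                  validation_cohort = NULL) {
  stopifnot(inherits(model, "visitrx_model"), inherits(config, "train_config"))
  if (!identical(vocab_hash(train_cohort$vocabulary), model$vocab_hash))
    stop("training cohort vocabulary does not match the model")
  if (!is.null(validation_cohort) &&
      !identical(vocab_hash(validation_cohort$vocabulary), model$vocab_hash))
    stop("validation cohort vocabulary does not match the model")
  nM <- vocab_size(model$vocab, "medication")
  if (!all(dim(ddi) == c(nM, nM))) stop("DDI matrix shape mismatch")
  D <- unclass(ddi)
  storage.mode(D) <- "double"
  mcfg <- model$config
  params <- model$params
  state <- adam_init(params)
  use_gin <- mcfg$use_block1

  # index-form examples, fixed; only their order changes per epoch
  idx_examples <- list()
  for (patient in train_cohort$patients)
    for (t in seq_along(patient$visits))
      idx_examples[[paste(patient$patient_id, t)]] <-
        make_example(patient, t, model$vocab)
  counts <- vapply(train_cohort$patients, function(p) length(p$visits),
                   integer(1))
  keys_by_patient <- lapply(seq_along(train_cohort$patients), function(pi)
    paste(train_cohort$patients[[pi]]$patient_id, seq_len(counts[pi])))

  log <- list()
  best_val <- -Inf
  best_params <- params
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    ep_seed <- (config$seed + epoch * 10007L) %% 2147483647L
    labels <- rep(seq_along(counts), counts)
    perm <- local_rng(ep_seed, sample(labels))
    next_t <- integer(length(counts))
    keys <- character(length(perm))
    for (i in seq_along(perm)) {
      next_t[perm[i]] <- next_t[perm[i]] + 1L
      keys[i] <- keys_by_patient[[perm[i]]][next_t[perm[i]]]
    }

    ep_loss <- 0; ep_bce <- 0; ep_ddi <- 0; n_seen <- 0L
    batch_starts <- seq.int(1L, length(keys), by = config$batch_size)
    for (bs in batch_starts) {
      bkeys <- keys[bs:min(bs + config$batch_size - 1L, length(keys))]
      B <- length(bkeys)
      tab <- if (use_gin) substructure_table_fwd(model$library, params$gin)
             else NULL
      E <- if (use_gin) tab$table$matrix else matrix(0, 1L, mcfg$dim)
      dE <- if (use_gin) matrix(0, nrow(E), ncol(E)) else NULL
      grads <- NULL
      for (key in bkeys) {
        ex <- idx_examples[[key]]
        fwd <- example_forward(params, mcfg, ex, E)
        y <- numeric(nM); y[ex$rx] <- 1
        ep_bce <- ep_bce + bce_loss(y, fwd$o_hat)
        ep_ddi <- ep_ddi + ddi_loss(fwd$o_hat, D)
        dlog <- loss_logit_grad(fwd$o_hat, y, D, mcfg$alpha,
                                mcfg$use_ddi_loss, B)
        bwd <- example_backward(params, mcfg, ex, fwd, dlog)
        grads <- if (is.null(grads)) bwd$grads else grad_add(grads, bwd$grads)
        if (use_gin && !is.null(bwd$dE_drug)) dE <- dE + bwd$dE_drug
      }
      if (use_gin) grads$gin <- substructure_table_bwd(dE, tab$caches, params$gin)
      st <- adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
      n_seen <- n_seen + B
    }
    ep_bce <- ep_bce / n_seen; ep_ddi <- ep_ddi / n_seen
    ep_loss <- if (mcfg$use_ddi_loss) ep_bce + mcfg$alpha * ep_ddi else ep_bce
    if (!is.finite(ep_loss))
      stop("training diverged at epoch ", epoch, " (non-finite loss ",
           "bce=", ep_bce, " ddi=", ep_ddi, ")")

    val_j <- NA_real_
    if (!is.null(validation_cohort)) {
      tmp <- model; tmp$params <- params
      val_j <- jaccard(predict_cohort(tmp, validation_cohort))
      if (val_j > best_val) {
        best_val <- val_j; best_params <- params; stale <- 0L
      } else stale <- stale + 1L
    } else best_params <- params
    log[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss, bce = ep_bce,
                               ddi = ep_ddi, val_jaccard = val_j)
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  bce %.4f  ddi %.4f  val_jac %s",
                      epoch, ep_loss, ep_bce, ep_ddi,
                      ifelse(is.na(val_j), "-", sprintf("%.4f", val_j))))
    if (!is.null(validation_cohort) && stale >= config$patience) break
  }
  model$params <- best_params
  list(model = model, log = do.call(rbind, log))
}
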