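#' Model configuration
#'
#' Hyper-parameters of the visit-level recommender. `dim` is decoupled from
#' `|M|` (the prediction heads always project to `|M|`); set `dim` to the
#' medication vocabulary size to mirror the original formulation exactly.
#'
#' @param dim embedding width; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param ffn_size inner width `s` of the encoder feed-forward sub-layer.
#' @param delta decision threshold on the fused probabilities (strict `>`).
#' @param alpha trade-off weight of the DDI loss.
#' @param use_block1 keep the substructure-aware CA-MHSA block (ablation
#'   switch; when off, its output is replaced by zeros with head input width
#'   unchanged).
#' @param use_block2 keep the effectiveness-aware CA-MHSA block.
#' @param use_rnn keep the GRU over historical prescriptions.
#' @param use_ddi_loss keep the DDI term in the training loss.
#' @param share_prev_encoders reuse the current-visit diagnosis/procedure
#'   encoders for the previous-visit pathway instead of separate parameters.
#' @param seed seed for parameter initialisation.
#' @return object of class `model_config`.
#' @export
model_config <- function(dim = 64L, heads = 4L, ffn_size = 2048L,
                         delta = 0.4, alpha = 0.5,
                         use_block1 = TRUE, use_block2 = TRUE,
                         use_rnn = TRUE, use_ddi_loss = TRUE,
                         share_prev_encoders = FALSE, seed = 1L) {
  dim <- as.integer(dim); heads <- as.integer(heads)
  if (dim %% heads != 0L) stop("dim must be divisible by heads")
  if ((2L * dim) %% heads != 0L) stop("2*dim must be divisible by heads")
  if (!(delta > 0 && delta < 1)) stop("delta must lie in (0,1)")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(dim = dim, heads = heads, ffn_size = as.integer(ffn_size),
                 delta = delta, alpha = alpha,
                 use_block1 = isTRUE(use_block1),
                 use_block2 = isTRUE(use_block2),
                 use_rnn = isTRUE(use_rnn),
                 use_ddi_loss = isTRUE(use_ddi_loss),
                 share_prev_encoders = isTRUE(share_prev_encoders),
                 seed = as.integer(seed)),
            class = "model_config")
}

vocab_hash <- function(vocab) {
  digest::digest(list(vocab$diagnosis, vocab$procedure, vocab$medication),
                 algo = "sha256")
}

#' Initialise a visit-level recommendation model
#'
#' Creates all learnable parameters: the three code embedding tables (the
#' procedure table carries one extra learned "no procedure" token used when a
#' visit has an empty procedure set), the current- and previous-visit
#' transformer set encoders, the three-layer GIN, the two CA-MHSA blocks, the
#' two feed-forward heads, and the GRU with its output projection.
#'
#' @param config a [model_config()].
#' @param vocab a `medical_vocabulary`.
#' @param library a `fragment_library` (drives the GIN input width).
#' @return object of class `visitrx_model`.
#' @export
init_model <- function(config, vocab, library) {
  stopifnot(inherits(config, "model_config"),
            inherits(vocab, "medical_vocabulary"),
            inherits(library, "fragment_library"))
  d <- config$dim
  nD <- vocab_size(vocab, "diagnosis")
  nP <- vocab_size(vocab, "procedure")
  nM <- vocab_size(vocab, "medication")
  params <- local_rng(config$seed, {
    p <- list(
      emb_d = glorot(nD, d),
      emb_p = glorot(nP + 1L, d),   # last row: no-procedure token
      emb_m = glorot(nM, d),
      enc_d = init_encoder_params(d, config$ffn_size),
      enc_p = init_encoder_params(d, config$ffn_size),
      gin = init_gin_params(library$feature_dim, d),
      ca1 = init_mh_params(2L * d),
      ca2 = init_mh_params(2L * d),
      ff1_W = glorot(4L * d, nM), ff1_b = numeric(nM),
      ff2_W = glorot(3L * d, nM), ff2_b = numeric(nM),
      gru = init_gru_params(d),
      proj_W = glorot(d, nM), proj_b = numeric(nM))
    if (!config$share_prev_encoders) {
      p$enc_d_prev <- init_encoder_params(d, config$ffn_size)
      p$enc_p_prev <- init_encoder_params(d, config$ffn_size)
    }
    p
  })
  structure(list(config = config, params = params, vocab = vocab,
                 library = library, vocab_hash = vocab_hash(vocab)),
            class = "visitrx_model")
}

#' @export
print.visitrx_model <- function(x, ...) {
  cat(sprintf("<visitrx_model> dim=%d heads=%d |D|=%d |P|=%d |M|=%d\n",
              x$config$dim, x$config$heads,
              length(x$vocab$diagnosis), length(x$vocab$procedure),
              length(x$vocab$medication)))
  invisible(x)
}

# rows of the procedure table for a (possibly empty) procedure index set;
# empty sets fall back to the learned no-procedure token (last row)
proc_rows_idx <- function(px_idx, emb_p) {
  if (length(px_idx) == 0L) nrow(emb_p) else px_idx
}

## ---- per-example forward ------------------------------------------------

# ex: list(t, dx, px, rx (target indices), history (list of rx index
#     vectors for visits 1..t-1), prev (list(dx, px, rx) for visit t-1 or NULL))
# E_drug: S x dim substructure matrix for this forward pass.
example_forward <- function(params, config, ex, E_drug) {
  h <- config$heads
  d <- config$dim
  nM <- length(params$ff1_b)

  Drows <- params$emb_d[ex$dx, , drop = FALSE]
  pidx <- proc_rows_idx(ex$px, params$emb_p)
  Prows <- params$emb_p[pidx, , drop = FALSE]
  encd <- encoder_fwd(Drows, params$enc_d, h)
  encp <- encoder_fwd(Prows, params$enc_p, h)
  Dp <- encd$out; Pp <- encp$out
  ca1 <- NULL
  Et <- if (config$use_block1) {
    ca1 <- ca_mhsa_fwd(E_drug, Dp, Pp, params$ca1, h)
    ca1$out
  } else numeric(2L * d)
  x1 <- c(Et, colMeans(Dp), colMeans(Pp))
  m_c <- drop(crossprod(params$ff1_W, x1)) + params$ff1_b

  # history branch: GRU over pooled medication embeddings of visits 1..t-1
  gru <- NULL; Xseq <- NULL
  m_h <- numeric(nM)
  if (config$use_rnn && length(ex$history) > 0L) {
    Xseq <- do.call(rbind, lapply(ex$history, function(ix)
      colMeans(params$emb_m[ix, , drop = FALSE])))
    gru <- gru_fwd(Xseq, params$gru)
    m_h <- drop(crossprod(params$proj_W, gru$out)) + params$proj_b
  }

  # effectiveness branch: previous prescriptions as queries over the
  # previous visit's encoded diagnoses/procedures
  ca2 <- NULL; encd2 <- NULL; encp2 <- NULL; Mrows <- NULL; x2 <- NULL
  pidx2 <- NULL
  m_p <- numeric(nM)
  if (!is.null(ex$prev) && length(ex$prev$rx) > 0L) {
    Mrows <- params$emb_m[ex$prev$rx, , drop = FALSE]
    enc_d_prev <- if (config$share_prev_encoders) params$enc_d else params$enc_d_prev
    enc_p_prev <- if (config$share_prev_encoders) params$enc_p else params$enc_p_prev
    Dprev <- params$emb_d[ex$prev$dx, , drop = FALSE]
    pidx2 <- proc_rows_idx(ex$prev$px, params$emb_p)
    Pprev <- params$emb_p[pidx2, , drop = FALSE]
    encd2 <- encoder_fwd(Dprev, enc_d_prev, h)
    encp2 <- encoder_fwd(Pprev, enc_p_prev, h)
    E2 <- if (config$use_block2) {
      ca2 <- ca_mhsa_fwd(Mrows, encd2$out, encp2$out, params$ca2, h)
      ca2$out
    } else numeric(2L * d)
    x2 <- c(E2, colMeans(Mrows))
    m_p <- drop(crossprod(params$ff2_W, x2)) + params$ff2_b
  }

  o_hat <- sigmoid(m_c + m_h + m_p)
  list(m_c = m_c, m_h = m_h, m_p = m_p, o_hat = o_hat,
       cache = list(encd = encd, encp = encp, ca1 = ca1, x1 = x1,
                    pidx = pidx, gru = gru, Xseq = Xseq,
                    ca2 = ca2, encd2 = encd2, encp2 = encp2,
                    Mrows = Mrows, x2 = x2, pidx2 = pidx2))
}

# dlogits: gradient of the (batch-averaged) loss w.r.t. the fused logits.
# Returns a partial gradient tree plus the dE_drug contribution.
example_backward <- function(params, config, ex, fwd, dlogits) {
  h <- config$heads
  d <- config$dim
  cc <- fwd$cache
  g <- list()
  dE_drug <- NULL
  demb_d <- NULL; demb_p <- NULL; demb_m <- NULL
  add_rows <- function(mat, idx, rows) {
    # accumulate `rows` into `mat[idx, ]`, handling repeated indices
    for (k in seq_along(idx)) mat[idx[k], ] <- mat[idx[k], ] + rows[k, ]
    mat
  }

  ## current-visit branch
  g$ff1_W <- outer(cc$x1, dlogits)
  g$ff1_b <- dlogits
  dx1 <- drop(params$ff1_W %*% dlogits)
  dEt <- dx1[seq_len(2L * d)]
  dDpool <- dx1[2L * d + seq_len(d)]
  dPpool <- dx1[3L * d + seq_len(d)]
  nDr <- nrow(cc$encd$out); nPr <- nrow(cc$encp$out)
  dDp <- matrix(dDpool / nDr, nDr, d, byrow = TRUE)
  dPp <- matrix(dPpool / nPr, nPr, d, byrow = TRUE)
  if (config$use_block1) {
    cb <- ca_mhsa_bwd(dEt, cc$ca1$cache, params$ca1)
    dE_drug <- cb$dQ
    dDp <- dDp + cb$dD
    dPp <- dPp + cb$dP
    g$ca1 <- cb$grads
  }
  eb <- encoder_bwd(dDp, cc$encd$cache, params$enc_d)
  g$enc_d <- eb$grads
  demb_d <- matrix(0, nrow(params$emb_d), d)
  demb_d <- add_rows(demb_d, ex$dx, eb$dX)
  eb <- encoder_bwd(dPp, cc$encp$cache, params$enc_p)
  g$enc_p <- eb$grads
  demb_p <- matrix(0, nrow(params$emb_p), d)
  demb_p <- add_rows(demb_p, cc$pidx, eb$dX)

  ## history branch
  if (!is.null(cc$gru)) {
    g$proj_W <- outer(cc$gru$out, dlogits)
    g$proj_b <- dlogits
    dh_final <- drop(params$proj_W %*% dlogits)
    gb <- gru_bwd(dh_final, cc$gru$cache, params$gru)
    g$gru <- gb$grads
    demb_m <- matrix(0, nrow(params$emb_m), d)
    for (j in seq_along(ex$history)) {
      ix <- ex$history[[j]]
      demb_m <- add_rows(demb_m, ix,
                         matrix(gb$dX[j, ] / length(ix), length(ix), d,
                                byrow = TRUE))
    }
  }

  ## effectiveness branch
  if (!is.null(cc$x2)) {
    g$ff2_W <- outer(cc$x2, dlogits)
    g$ff2_b <- dlogits
    dx2 <- drop(params$ff2_W %*% dlogits)
    dE2 <- dx2[seq_len(2L * d)]
    dMpool <- dx2[2L * d + seq_len(d)]
    nMr <- nrow(cc$Mrows)
    dMrows <- matrix(dMpool / nMr, nMr, d, byrow = TRUE)
    nD2 <- nrow(cc$encd2$out); nP2 <- nrow(cc$encp2$out)
    dDp2 <- matrix(0, nD2, d); dPp2 <- matrix(0, nP2, d)
    if (config$use_block2) {
      cb <- ca_mhsa_bwd(dE2, cc$ca2$cache, params$ca2)
      dMrows <- dMrows + cb$dQ
      dDp2 <- dDp2 + cb$dD
      dPp2 <- dPp2 + cb$dP
      g$ca2 <- cb$grads
    }
    enc_d_prev_nm <- if (config$share_prev_encoders) "enc_d" else "enc_d_prev"
    enc_p_prev_nm <- if (config$share_prev_encoders) "enc_p" else "enc_p_prev"
    eb <- encoder_bwd(dDp2, cc$encd2$cache, params[[enc_d_prev_nm]])
    g[[enc_d_prev_nm]] <- grad_add(g[[enc_d_prev_nm]] %||% grad_zero_like(eb$grads),
                                   eb$grads)
    demb_d <- add_rows(demb_d, ex$prev$dx, eb$dX)
    eb <- encoder_bwd(dPp2, cc$encp2$cache, params[[enc_p_prev_nm]])
    g[[enc_p_prev_nm]] <- grad_add(g[[enc_p_prev_nm]] %||% grad_zero_like(eb$grads),
                                   eb$grads)
    demb_p <- add_rows(demb_p, cc$pidx2, eb$dX)
    if (is.null(demb_m)) demb_m <- matrix(0, nrow(params$emb_m), d)
    demb_m <- add_rows(demb_m, ex$prev$rx, dMrows)
  }

  g$emb_d <- demb_d
  g$emb_p <- demb_p
  if (!is.null(demb_m)) g$emb_m <- demb_m
  list(grads = g, dE_drug = dE_drug)
}

## ---- fusion, thresholding, losses ---------------------------------------

#' Fuse the three recommendation branches and threshold
#'
#' `o_hat = sigmoid(m_c + m_h + m_p)`; the recommended combination is the set
#' of drugs with probability strictly greater than `delta`.
#'
#' @param m_c,m_h,m_p logit vectors of equal length `|M|`.
#' @param delta decision threshold in (0,1).
#' @return object of class `prediction_bundle` with fields `m_c`, `m_h`,
#'   `m_p`, `o_hat`, `m_hat`.
#' @export
fuse_predict <- function(m_c, m_h, m_p, delta = 0.4) {
  if (length(m_h) != length(m_c) || length(m_p) != length(m_c))
    stop("fuse_predict: logit vectors have different lengths")
  o_hat <- sigmoid(m_c + m_h + m_p)
  structure(list(m_c = m_c, m_h = m_h, m_p = m_p, o_hat = o_hat,
                 m_hat = as.integer(o_hat > delta)),
            class = "prediction_bundle")
}

#' Multi-label binary cross-entropy loss
#'
#' Sum over the medication vocabulary of `-m log(o) - (1-m) log(1-o)`,
#' averaged over the batch when given matrices (one visit per row).
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param m ground-truth multi-hot vector (or matrix, visits in rows).
#' @param o_hat predicted probabilities, same shape.
#' @return scalar loss.
#' @export
bce_loss <- function(m, o_hat) {
  if (length(m) != length(o_hat)) stop("bce_loss: length mismatch")
  o <- pmin(pmax(o_hat, 1e-12), 1 - 1e-12)
  ll <- -(m * log(o) + (1 - m) * log(1 - o))
  if (is.matrix(m)) mean(rowSums(ll)) else sum(ll)
}

#' DDI loss
#'
#' The quadratic form `sum_ij D_ij o_i o_j` over the full symmetric
#' interaction matrix (each unordered pair counted twice), averaged over the
#' batch when given a probability matrix.
#'
#' @param o_hat probability vector (or matrix, visits in rows).
#' @param D binary symmetric `|M| x |M|` DDI matrix.
#' @return scalar loss.
#' @export
ddi_loss <- function(o_hat, D) {
  if (is.matrix(o_hat)) {
    if (ncol(o_hat) != nrow(D)) stop("ddi_loss: shape mismatch")
    return(mean(rowSums((o_hat %*% D) * o_hat)))
  }
  if (length(o_hat) != nrow(D)) stop("ddi_loss: shape mismatch")
  drop(o_hat %*% D %*% o_hat)
}

#' Combined training loss
#'
#' `total = bce + alpha * ddi`; with `use_ddi_loss = FALSE` the DDI term is
#' dropped (ablation), i.e. `total = bce`.
#'
#' @param bce,ddi scalar loss components.
#' @param alpha trade-off weight.
#' @param use_ddi_loss include the DDI term?
#' @return object of class `loss_report` with fields `bce`, `ddi`, `total`.
#' @export
total_loss <- function(bce, ddi, alpha, use_ddi_loss = TRUE) {
  if (!is.finite(bce) || !is.finite(ddi)) stop("non-finite loss component")
  total <- if (use_ddi_loss) bce + alpha * ddi else bce
  structure(list(bce = bce, ddi = ddi, total = total), class = "loss_report")
}

## ---- inference over cohorts ---------------------------------------------

# convert a visit to index form against the model vocabulary
visit_indices <- function(visit, vocab) {
  list(dx = code_index(vocab, visit$diagnoses, "diagnosis"),
       px = code_index(vocab, visit$procedures, "procedure"),
       rx = code_index(vocab, visit$medications, "medication"))
}

# build the index-form example for patient p at visit t (history from ground truth)
make_example <- function(patient, t, vocab) {
  cur <- visit_indices(patient$visits[[t]], vocab)
  history <- if (t >= 2L)
    lapply(patient$visits[seq_len(t - 1L)],
           function(v) code_index(vocab, v$medications, "medication"))
  else list()
  prev <- if (t >= 2L) visit_indices(patient$visits[[t - 1L]], vocab) else NULL
  list(patient_id = patient$patient_id, t = t,
       dx = cur$dx, px = cur$px, rx = cur$rx,
       history = history, prev = prev)
}

#' Predict medication combinations for every visit of a cohort
#'
#' Runs the model on each visit with the patient's ground-truth history
#' (teacher forcing, the standard evaluation protocol for this task).
#'
#' @param model a `visitrx_model`.
#' @param cohort an `ehr_cohort` sharing the model's vocabulary.
#' @return list of `visit_prediction` objects: ground-truth set, predicted
#'   set, probability vector, `patient_id`, `t`.
#' @export
predict_cohort <- function(model, cohort) {
  if (!identical(vocab_hash(cohort$vocabulary), model$vocab_hash))
    stop("cohort vocabulary does not match the model's vocabulary")
  E <- build_substructure_table(model$library, model$params$gin)
  out <- list()
  for (patient in cohort$patients) {
    for (t in seq_along(patient$visits)) {
      ex <- make_example(patient, t, model$vocab)
      fwd <- example_forward(model$params, model$config, ex, E$matrix)
      bundle <- fuse_predict(fwd$m_c, fwd$m_h, fwd$m_p, model$config$delta)
      out[[length(out) + 1L]] <- structure(list(
        truth = ex$rx, predicted = which(bundle$m_hat == 1L),
        o_hat = bundle$o_hat, patient_id = patient$patient_id, t = t),
        class = "visit_prediction")
    }
  }
  out
}

## ---- checkpointing ------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the parameters, the
#' configuration, the vocabulary and its hash, and the fragment library.
#'
#' @param model a `visitrx_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `visitrx_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "visitrx_checkpoint", version = 1L,
               config = model$config, params = model$params,
               vocab = model$vocab, vocab_hash = model$vocab_hash,
               library = model$library), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "visitrx_checkpoint"))
    stop(path, " is not a visitrx checkpoint")
  structure(list(config = obj$config, params = obj$params, vocab = obj$vocab,
                 library = obj$library, vocab_hash = obj$vocab_hash),
            class = "visitrx_model")
}

## ---- named branch entry points ------------------------------------------

#' Current-visit recommendation branch
#'
#' Encodes the visit's diagnosis and procedure codes, queries the
#' substructure table through the first CA-MHSA block, concatenates
#' `[E_t', pool(D_t'), pool(P_t')]` and applies the first feed-forward head.
#'
#' @param model a `visitrx_model`.
#' @param diagnoses,procedures character code vectors of the current visit
#'   (diagnoses must be non-empty; an empty procedure set uses the learned
#'   no-procedure token).
#' @param E_drug optional precomputed `S x dim` substructure matrix; rebuilt
#'   from the model's library when omitted.
#' @return logit vector `m_c` of length `|M|`.
#' @export
visit_forward <- function(model, diagnoses, procedures, E_drug = NULL) {
  if (length(diagnoses) == 0L) stop("visit_forward: empty diagnosis set")
  if (is.null(E_drug))
    E_drug <- build_substructure_table(model$library, model$params$gin)$matrix
  ex <- list(t = 1L,
             dx = code_index(model$vocab, diagnoses, "diagnosis"),
             px = code_index(model$vocab, procedures, "procedure"),
             rx = integer(0), history = list(), prev = NULL)
  example_forward(model$params, model$config, ex, E_drug)$m_c
}

#' Historical-prescription branch
#'
#' GRU over per-visit pooled medication embeddings in chronological order;
#' the final hidden state is projected to `|M|` logits. With no history
#' (cold start) the branch returns the zero vector.
#'
#' @param model a `visitrx_model`.
#' @param history list of character medication-code vectors for visits
#'   `1..t-1` (chronological); may be empty.
#' @return logit vector `m_h` of length `|M|`.
#' @export
history_rnn_forward <- function(model, history) {
  nM <- length(model$params$proj_b)
  if (length(history) == 0L || !model$config$use_rnn) return(numeric(nM))
  Xseq <- do.call(rbind, lapply(history, function(codes) {
    ix <- code_index(model$vocab, codes, "medication")
    colMeans(model$params$emb_m[ix, , drop = FALSE])
  }))
  h <- gru_fwd(Xseq, model$params$gru)$out
  drop(crossprod(model$params$proj_W, h)) + model$params$proj_b
}

#' Effectiveness-aware branch over the previous visit
#'
#' The previous visit's medication embeddings act as queries over its encoded
#' diagnoses and procedures through the second CA-MHSA block; the result is
#' concatenated with the pooled medication embedding and mapped by the second
#' feed-forward head. With no previous visit (cold start) the branch returns
#' the zero vector.
#'
#' @param model a `visitrx_model`.
#' @param prev_visit an `ehr_visit` (visit t-1) or `NULL`.
#' @return logit vector `m_p` of length `|M|`.
#' @export
effectiveness_forward <- function(model, prev_visit) {
  nM <- length(model$params$ff2_b)
  if (is.null(prev_visit) || length(prev_visit$medications) == 0L)
    return(numeric(nM))
  ex <- list(t = 2L, dx = 1L, px = integer(0), rx = integer(0),
             history = list(),
             prev = visit_indices(prev_visit, model$vocab))
  # reuse the full forward with a dummy current visit; only m_p is taken
  E_dummy <- matrix(0, 1L, model$config$dim)
  cfg <- model$config
  cfg$use_block1 <- FALSE
  cfg$use_rnn <- FALSE
  example_forward(model$params, cfg, ex, E_dummy)$m_p
}
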