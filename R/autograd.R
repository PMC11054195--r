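# Reverse-mode gradients for the full model. The forward pass is
# model_forward_batch(); this file walks it backwards: softmax/CE ->
# linear head -> similarity -> distance -> (regularizers join here) ->
# attention pooling -> stacked (bi)directional LSTM.

# flat named list of every trainable array, in a fixed order
param_list <- function(model) {
  out <- list()
  for (l in seq_len(model$encoder$num_layers)) {
    for (dir in c("fwd", "bwd")) {
      cell <- model$encoder$layers[[l]][[dir]]
      if (is.null(cell)) next
      for (nm in c("Wx", "Wh", "b"))
        out[[sprintf("enc_l%d_%s_%s", l, dir, nm)]] <- cell[[nm]]
    }
  }
  out$att_W <- model$attention$W
  out$att_b <- model$attention$b
  out$att_V <- model$attention$V
  out$prototypes <- model$prototypes
  out$head_W <- model$W
  out
}

set_param_list <- function(model, params) {
  for (l in seq_len(model$encoder$num_layers)) {
    for (dir in c("fwd", "bwd")) {
      if (is.null(model$encoder$layers[[l]][[dir]])) next
      for (nm in c("Wx", "Wh", "b"))
        model$encoder$layers[[l]][[dir]][[nm]] <-
          params[[sprintf("enc_l%d_%s_%s", l, dir, nm)]]
    }
  }
  model$attention$W <- params$att_W
  model$attention$b <- params$att_b
  model$attention$V <- params$att_V
  model$prototypes <- params$prototypes
  model$W <- params$head_W
  model
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# backprop through one LSTM direction; dH is a list (by original time
# index) of gradients flowing into that direction's per-step states
bptt_direction <- function(frames, cell, run, dH, reverse) {
  T_ <- length(frames)
  B <- nrow(frames[[1L]])
  u <- nrow(cell$Wh)
  ca <- run$cache
  dWx <- cell$Wx * 0; dWh <- cell$Wh * 0; db <- cell$b * 0
  dInput <- vector("list", T_)
  dh_next <- matrix(0, B, u)
  dc_next <- matrix(0, B, u)
  proc <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (idx in rev(seq_along(proc))) {
    t <- proc[idx]
    h_prev <- if (idx > 1L) run$H[[proc[idx - 1L]]] else matrix(0, B, u)
    c_prev <- if (idx > 1L) ca$c[[proc[idx - 1L]]] else matrix(0, B, u)
    dh <- dH[[t]] + dh_next
    o <- ca$o[[t]]; tc <- ca$tc[[t]]
    i <- ca$i[[t]]; f <- ca$f[[t]]; g <- ca$g[[t]]
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    dA <- cbind(dc * g * i * (1 - i),          # input gate pre-activation
                dc * c_prev * f * (1 - f),     # forget gate
                dc * i * (1 - g^2),            # candidate
                do_ * o * (1 - o))             # output gate
    dWx <- dWx + crossprod(frames[[t]], dA)
    dWh <- dWh + crossprod(h_prev, dA)
    db <- db + colSums(dA)
    dInput[[t]] <- tcrossprod(dA, cell$Wx)
    dh_next <- tcrossprod(dA, cell$Wh)
    dc_next <- dc * f
  }
  list(Wx = dWx, Wh = dWh, b = db, dInput = dInput)
}

# loss + gradients for one mini-batch. X: B x L raw beats, y: zero-based
# labels. reg_E: optional embeddings to use for R1/R2 instead of the
# batch's own (full-training-set recomputation mode).
model_loss_grads <- function(model, X, y, weights = loss_weights(),
                             dropout_mask = NULL, reg_E = NULL) {
  cf <- model$config
  fwd <- model_forward_batch(model, X, keep_cache = TRUE,
                             dropout_mask = dropout_mask)
  B <- nrow(fwd$e)
  K <- cf$K
  P <- model$prototypes
  E <- fwd$e

  ce <- cross_entropy(y, fwd$probs)
  dZ <- fwd$probs
  dZ[cbind(seq_len(B), as.integer(y) + 1L)] <-
    dZ[cbind(seq_len(B), as.integer(y) + 1L)] - 1

  grads <- zero_like(param_list(model))
  grads$head_W <- crossprod(dZ, fwd$s)          # C x K
  dS <- dZ %*% model$W                          # B x K
  dD <- -fwd$s * dS                             # s = exp(-d)

  # distance layer -> embeddings and prototypes
  if (cf$dist_squared) {
    G <- dD
    dE <- 2 * (rowSums(G) * E - G %*% P)
    dP <- 2 * (colSums(G) * P - crossprod(G, E))
  } else {
    G <- dD / pmax(fwd$d, 1e-12)
    dE <- rowSums(G) * E - G %*% P
    dP <- colSums(G) * P - crossprod(G, E)
  }

  # regularizers (computed on the same embedding node as the CE path)
  Ereg <- if (is.null(reg_E)) E else reg_E
  D2 <- prototype_distances(P, Ereg, squared = TRUE)  # K x N
  jmin <- apply(D2, 1L, which.min)
  r1 <- sum(D2[cbind(seq_len(K), jmin)])
  kmin <- apply(D2, 2L, which.min)
  r2 <- sum(D2[cbind(kmin, seq_len(ncol(D2)))])
  if (weights$lambda1 > 0) {
    diff1 <- P - Ereg[jmin, , drop = FALSE]
    dP <- dP + weights$lambda1 * 2 * diff1
    if (is.null(reg_E))
      for (k in seq_len(K))
        dE[jmin[k], ] <- dE[jmin[k], ] - weights$lambda1 * 2 * diff1[k, ]
  }
  if (weights$lambda2 > 0) {
    diff2 <- Ereg - P[kmin, , drop = FALSE]
    dPk <- rowsum(-weights$lambda2 * 2 * diff2, kmin)
    rows <- as.integer(rownames(dPk))
    dP[rows, ] <- dP[rows, , drop = FALSE] + dPk
    if (is.null(reg_E))
      dE <- dE + weights$lambda2 * 2 * diff2
  }

  r_div <- 0
  if (K >= 2L) {
    pd <- as.matrix(stats::dist(P))^2
    diag(pd) <- Inf
    m <- min(pd)
    ij <- which(pd == m, arr.ind = TRUE)[1L, ]
    r_div <- sigmoid(weights$diversity_threshold - m)
    if (weights$lambda > 0) {
      slope <- r_div * (1 - r_div)
      dpair <- -slope * 2 * (P[ij[1L], ] - P[ij[2L], ])
      dP[ij[1L], ] <- dP[ij[1L], ] + weights$lambda * dpair
      dP[ij[2L], ] <- dP[ij[2L], ] - weights$lambda * dpair
    }
  }
  grads$prototypes <- dP

  # dropout backward
  if (!is.null(dropout_mask)) dE <- dE * dropout_mask

  # attention backward
  att <- model$attention
  H <- fwd$enc_out$H
  T_ <- length(H)
  alpha <- fwd$alpha
  dAlpha <- matrix(0, B, T_)
  for (t in seq_len(T_)) dAlpha[, t] <- rowSums(dE * H[[t]])
  dScores <- alpha * (dAlpha - rowSums(alpha * dAlpha))
  dH <- vector("list", T_)
  dW_a <- att$W * 0; db_a <- att$b * 0; dV_a <- att$V * 0
  for (t in seq_len(T_)) {
    ds <- dScores[, t]
    Pt <- fwd$att_out$pre[[t]]           # B x Da (post-tanh if enabled)
    dV_a <- dV_a + as.vector(crossprod(Pt, ds))
    dPre <- outer(ds, att$V)
    if (att$score_tanh) dPre <- dPre * (1 - Pt^2)
    dW_a <- dW_a + crossprod(H[[t]], dPre)
    db_a <- db_a + colSums(dPre)
    dH[[t]] <- alpha[, t] * dE + tcrossprod(dPre, att$W)
  }
  grads$att_W <- dW_a; grads$att_b <- db_a; grads$att_V <- dV_a

  # stacked LSTM backward, top layer down
  enc <- model$encoder
  u1 <- enc$hidden_size
  for (l in rev(seq_len(enc$num_layers))) {
    lc <- fwd$enc_out$caches[[l]]
    if (enc$bidirectional) {
      dHf <- lapply(dH, function(m) m[, 1:u1, drop = FALSE])
      dHb <- lapply(dH, function(m) m[, (u1 + 1):(2 * u1), drop = FALSE])
      gf <- bptt_direction(lc$input, enc$layers[[l]]$fwd, lc$fwd, dHf, FALSE)
      gb <- bptt_direction(lc$input, enc$layers[[l]]$bwd, lc$bwd, dHb, TRUE)
      dH <- lapply(seq_len(T_), function(t) gf$dInput[[t]] + gb$dInput[[t]])
      for (nm in c("Wx", "Wh", "b")) {
        grads[[sprintf("enc_l%d_fwd_%s", l, nm)]] <- gf[[nm]]
        grads[[sprintf("enc_l%d_bwd_%s", l, nm)]] <- gb[[nm]]
      }
    } else {
      gf <- bptt_direction(lc$input, enc$layers[[l]]$fwd, lc$fwd, dH, FALSE)
      dH <- gf$dInput
      for (nm in c("Wx", "Wh", "b"))
        grads[[sprintf("enc_l%d_fwd_%s", l, nm)]] <- gf[[nm]]
    }
  }

  list(breakdown = total_loss(ce, r_div, r1, r2, weights), grads = grads,
       forward = fwd)
}
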