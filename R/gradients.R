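# Exact analytic gradients of the per-example cross-entropy loss with
# respect to every trainable parameter, mirroring the forward caches in
# model.R. Verified against finite differences in the test suite.

zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

add_grads <- function(a, b) {
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

scale_grads <- function(a, k) rapply(a, function(x) x * k, how = "replace")

# accumulate the encoder backward pass: v = W_enc %*% mean(E[ids, ]) + b_enc
enc_bwd <- function(grads, params, dv, ids, m) {
  grads$W_enc <- grads$W_enc + outer(dv, m)
  grads$b_enc <- grads$b_enc + dv
  L <- length(ids)
  if (L > 0) {
    dm <- drop(crossprod(params$W_enc, dv))
    uid <- unique(ids)
    cnt <- tabulate(match(ids, uid), nbins = length(uid))
    grads$E[uid, ] <- grads$E[uid, , drop = FALSE] + outer(cnt / L, dm)
  }
  grads
}

backward_example <- function(ex, fwd, model) {
  params <- model$params
  cfg <- model$config
  grads <- zero_grads(params)

  dlogits <- fwd$probs
  dlogits[ex$label] <- dlogits[ex$label] - 1
  grads$Wc <- grads$Wc + outer(dlogits, fwd$z)
  grads$bc <- grads$bc + dlogits
  dz <- drop(crossprod(params$Wc, dlogits))

  kdim <- if (fwd$use_gat || fwd$use_linear) cfg$d1 else 0L
  dk <- if (kdim) dz[seq_len(kdim)] else NULL
  dtext <- if (length(dz) > kdim) dz[(kdim + 1L):length(dz)] else NULL

  dS <- NULL
  dC <- NULL
  ds <- if (fwd$use_gat) dk else NULL
  if (fwd$text_kind == "attention") {
    ab <- att_bwd(dtext, fwd$att, params, fwd$s, fwd$S_e$v, fwd$C_e$v)
    grads$W1 <- grads$W1 + ab$dW1
    grads$W2 <- grads$W2 + ab$dW2
    grads$v <- grads$v + ab$dv
    dS <- ab$dh1
    dC <- ab$dh2
    ds <- ds + ab$ds
  } else if (fwd$text_kind == "sre") {
    dS <- dtext
  } else if (fwd$text_kind == "de") {
    dC <- dtext
  }

  if (fwd$use_gat) {
    n_nodes <- nrow(ex$jg$nodes)
    dH <- matrix(rep(ds / n_nodes, each = n_nodes), n_nodes, cfg$d1)
    for (l in rev(seq_len(cfg$n_layers))) {
      bw <- gat_layer_bwd(dH, fwd$layers[[l]], params$gat[[l]], ex$adj,
                          cfg$leaky_slope)
      grads$gat[[l]] <- add_grads(grads$gat[[l]], bw$grads)
      dH <- bw$dH
    }
    # node features: row 1 is the projected dialogue encoding, the rest are
    # projected entity-name encodings
    ent_idx <- which(ex$jg$nodes$type != "dialog")
    d_dlg <- dH[1, ]
    grads$W_proj <- grads$W_proj + outer(d_dlg, fwd$C_e$v)
    grads$b_proj <- grads$b_proj + d_dlg
    dC <- (dC %||% numeric(cfg$d2)) + drop(crossprod(params$W_proj, d_dlg))
    for (j in seq_along(ent_idx)) {
      dhj <- dH[ent_idx[j], ]
      e <- fwd$ent_enc[[j]]
      grads$W_proj <- grads$W_proj + outer(dhj, e$v)
      grads$b_proj <- grads$b_proj + dhj
      denc <- drop(crossprod(params$W_proj, dhj))
      grads <- enc_bwd(grads, params, denc, ex$node_ids[[ent_idx[j]]], e$m)
    }
  } else if (fwd$use_linear) {
    ent_idx <- which(ex$jg$nodes$type != "dialog")
    ne <- length(ent_idx)
    if (ne > 0) {
      dfeat <- dk / ne
      for (j in seq_len(ne)) {
        e <- fwd$ent_enc[[j]]
        grads$W_proj <- grads$W_proj + outer(dfeat, e$v)
        grads$b_proj <- grads$b_proj + dfeat
        denc <- drop(crossprod(params$W_proj, dfeat))
        grads <- enc_bwd(grads, params, denc, ex$node_ids[[ent_idx[j]]], e$m)
      }
    }
  }

  if (!is.null(dS)) grads <- enc_bwd(grads, params, dS, ex$sr_ids, fwd$S_e$m)
  if (!is.null(dC)) grads <- enc_bwd(grads, params, dC, ex$dlg_ids, fwd$C_e$m)
  grads
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
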