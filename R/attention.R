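# Multi-head self-attention with the double projection used throughout the
# model: the sequence is first mapped to q, k, v by F2 x F2 matrices, then
# each head applies its own F2 x Dh map; scaled dot-product attention
# (scale 1/sqrt(Dh)) runs per head, head outputs are concatenated and mapped
# back to F2 by a trainable output projection.  An attention site owns one
# such parameter set plus the layer-norm scale/shift of its pre-norm
# residual wrapper  z + MSA(LN(z)).

attn_params_init <- function(F2, Dh, h) {
  list(
    ln_gamma = rep(1, F2), ln_beta = rep(0, F2),
    Wq = glorot_uniform(F2, F2), Wk = glorot_uniform(F2, F2),
    Wv = glorot_uniform(F2, F2),
    Whq = glorot_uniform(F2, Dh, c(F2, Dh, h)),
    Whk = glorot_uniform(F2, Dh, c(F2, Dh, h)),
    Whv = glorot_uniform(F2, Dh, c(F2, Dh, h)),
    Wo = glorot_uniform(h * Dh, F2)
  )
}

# z3: (B, Wn, F2) batch of sequences; returns out (B, Wn, F2) and cache.
# keep_attn stores the pre-dropout attention rows for inspection.
msa_fwd <- function(z3, p, Dh, h, drop_rate = 0, training = FALSE,
                    keep_attn = FALSE) {
  d <- dim(z3); B <- d[1]; Wn <- d[2]; F2 <- d[3]
  zm <- matrix(z3, B * Wn, F2)
  if (!all(is.finite(zm))) {
    stop("non-finite values entering self-attention", call. = FALSE)
  }
  q <- zm %*% p$Wq; k <- zm %*% p$Wk; v <- zm %*% p$Wv
  qh <- array(0, c(B * Wn, Dh, h)); kh <- qh; vh <- qh
  for (i in seq_len(h)) {
    qh[, , i] <- q %*% p$Whq[, , i]
    kh[, , i] <- k %*% p$Whk[, , i]
    vh[, , i] <- v %*% p$Whv[, , i]
  }
  sc <- 1 / sqrt(Dh)
  A <- matrix(0, B * Wn, h * Dh)
  P_all <- array(0, c(Wn, Wn, h, B))
  mask_all <- if (training && drop_rate > 0) array(0, c(Wn, Wn, h, B)) else NULL
  for (b in seq_len(B)) {
    idx <- seq.int(b, by = B, length.out = Wn)
    for (i in seq_len(h)) {
      Q <- matrix(qh[idx, , i], Wn, Dh)
      K <- matrix(kh[idx, , i], Wn, Dh)
      V <- matrix(vh[idx, , i], Wn, Dh)
      S <- tcrossprod(Q, K) * sc
      P <- softmax_rows(S)
      P_all[, , i, b] <- P
      if (!is.null(mask_all)) {
        m <- matrix((stats::runif(Wn * Wn) >= drop_rate) / (1 - drop_rate),
                    Wn, Wn)
        mask_all[, , i, b] <- m
        Pd <- P * m
      } else Pd <- P
      A[idx, ((i - 1L) * Dh + 1L):(i * Dh)] <- Pd %*% V
    }
  }
  out <- A %*% p$Wo
  cache <- list(zm = zm, q = q, k = k, v = v, qh = qh, kh = kh, vh = vh,
                P = P_all, mask = mask_all, A = A, B = B, Wn = Wn, F2 = F2,
                Dh = Dh, h = h, sc = sc)
  list(out = array(out, c(B, Wn, F2)),
       attn = if (keep_attn) P_all else NULL,
       cache = cache)
}

msa_bwd <- function(d_out, cache, p) {
  B <- cache$B; Wn <- cache$Wn; F2 <- cache$F2
  Dh <- cache$Dh; h <- cache$h; sc <- cache$sc
  dom <- matrix(d_out, B * Wn, F2)
  dA <- dom %*% t(p$Wo)
  dWo <- crossprod(cache$A, dom)
  dqh <- array(0, c(B * Wn, Dh, h)); dkh <- dqh; dvh <- dqh
  for (b in seq_len(B)) {
    idx <- seq.int(b, by = B, length.out = Wn)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * Dh + 1L):(i * Dh)
      Q <- matrix(cache$qh[idx, , i], Wn, Dh)
      K <- matrix(cache$kh[idx, , i], Wn, Dh)
      V <- matrix(cache$vh[idx, , i], Wn, Dh)
      P <- cache$P[, , i, b]
      m <- if (!is.null(cache$mask)) cache$mask[, , i, b] else NULL
      Pd <- if (is.null(m)) P else P * m
      dAb <- matrix(dA[idx, cols], Wn, Dh)
      dV <- crossprod(Pd, dAb)
      dPd <- tcrossprod(dAb, V)
      dP <- if (is.null(m)) dPd else dPd * m
      dS <- P * (dP - rowSums(dP * P))
      dqh[idx, , i] <- (dS %*% K) * sc
      dkh[idx, , i] <- (crossprod(dS, Q)) * sc
      dvh[idx, , i] <- dV
    }
  }
  dq <- matrix(0, B * Wn, F2); dk <- dq; dv <- dq
  dWhq <- array(0, dim(p$Whq)); dWhk <- dWhq; dWhv <- dWhq
  for (i in seq_len(h)) {
    dq <- dq + dqh[, , i] %*% t(p$Whq[, , i])
    dk <- dk + dkh[, , i] %*% t(p$Whk[, , i])
    dv <- dv + dvh[, , i] %*% t(p$Whv[, , i])
    dWhq[, , i] <- crossprod(cache$q, dqh[, , i])
    dWhk[, , i] <- crossprod(cache$k, dkh[, , i])
    dWhv[, , i] <- crossprod(cache$v, dvh[, , i])
  }
  dzm <- dq %*% t(p$Wq) + dk %*% t(p$Wk) + dv %*% t(p$Wv)
  list(dx = array(dzm, c(B, Wn, F2)),
       grads = list(Wq = crossprod(cache$zm, dq),
                    Wk = crossprod(cache$zm, dk),
                    Wv = crossprod(cache$zm, dv),
                    Whq = dWhq, Whk = dWhk, Whv = dWhv, Wo = dWo))
}

# pre-norm residual attention site: z + MSA(LN(z))
attn_block_fwd <- function(z3, p, Dh, h, drop_rate = 0, training = FALSE,
                           keep_attn = FALSE) {
  d <- dim(z3); B <- d[1]; Wn <- d[2]; F2 <- d[3]
  zm <- matrix(z3, B * Wn, F2)
  ln <- ln_fwd(zm, p$ln_gamma, p$ln_beta)
  ms <- msa_fwd(array(ln$out, c(B, Wn, F2)), p, Dh, h, drop_rate, training,
                keep_attn)
  list(out = z3 + ms$out, attn = ms$attn,
       cache = list(ln = ln$cache, msa = ms$cache, B = B, Wn = Wn, F2 = F2))
}

attn_block_bwd <- function(d_out, cache, p) {
  mb <- msa_bwd(d_out, cache$msa, p)
  lb <- ln_bwd(matrix(mb$dx, cache$B * cache$Wn, cache$F2), cache$ln)
  dz <- d_out + array(lb$dx, c(cache$B, cache$Wn, cache$F2))
  g <- mb$grads
  g$ln_gamma <- lb$dgamma
  g$ln_beta <- lb$dbeta
  list(dx = dz, grads = g)
}

#' Multi-head self-attention over a token sequence
#'
#' User-facing wrapper around the internal attention engine: applies
#' multi-head scaled dot-product self-attention (without the residual
#' wrapper) to one sequence or a batch of sequences.  Each row of every
#' head's attention matrix is a probability distribution over the
#' sequence positions.
#'
#' @param z A `n_tokens x F2` matrix or a `B x n_tokens x F2` array.
#' @param params Attention parameters as produced inside the model
#'   (elements `Wq`, `Wk`, `Wv`, `Whq`, `Whk`, `Whv`, `Wo`).
#' @param head_dim Per-head dimension `Dh`.
#' @param n_heads Number of heads `h`.
#' @return Same shape as `z`; the attention probabilities are attached as
#'   attribute `"attention"` (array `n_tokens x n_tokens x h x B`).
#' @export
self_attention <- function(z, params, head_dim, n_heads) {
  single <- is.matrix(z)
  if (single) z <- array(z, c(1L, dim(z)))
  ms <- msa_fwd(z, params, head_dim, n_heads, drop_rate = 0,
                training = FALSE, keep_attn = TRUE)
  out <- ms$out
  if (single) out <- matrix(out, dim(z)[2], dim(z)[3])
  attr(out, "attention") <- ms$attn
  out
}
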