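#' Sliding-window token index map
#'
#' Enumerates which token positions of a `Tz`-token sequence enter each
#' sliding window.  Continuous windows are overlapping stride-2 blocks of
#' `floor(Tz/2)` consecutive tokens: window `i` (for `i = 1 .. floor(Tz/4)`)
#' covers positions `2i - 1, 2i, ..., 2i + floor(Tz/2) - 2`.  The two
#' dilated windows take the odd-position and the even-position tokens,
#' each truncated to its first `floor(Tz/2)` members so that every window
#' shares one length (for odd `Tz` the trailing token is unused).
#'
#' @param tz Token count (`>= 4`).
#' @return A list with elements `continuous` (list of integer vectors) and
#'   `dilated` (list of two integer vectors); all indices are 1-based.
#' @examples
#' window_index_map(20)$continuous[[1]]  # 1..10
#' window_index_map(11)$dilated[[1]]     # 1 3 5 7 9
#' @export
window_index_map <- function(tz) {
  tz <- as.integer(tz)
  if (tz < 4L) stop("tz must be >= 4 to build a continuous window", call. = FALSE)
  wl <- tz %/% 2L
  n_cont <- tz %/% 4L
  continuous <- lapply(seq_len(n_cont), function(i) {
    idx <- seq.int(2L * i - 1L, length.out = wl)
    if (max(idx) > tz) stop("continuous window index exceeds Tz", call. = FALSE)
    idx
  })
  dilated <- list(
    seq.int(1L, by = 2L, length.out = wl),
    seq.int(2L, by = 2L, length.out = wl)
  )
  if (max(unlist(dilated)) > tz) stop("dilated window index exceeds Tz", call. = FALSE)
  list(continuous = continuous, dilated = dilated)
}

#' Build sliding windows from a token sequence
#'
#' Gathers the tokens of each trial into the continuous and dilated
#' windows of [window_index_map()], optionally prepending the trainable
#' window-type token (`type_tokens$et1` for continuous windows,
#' `type_tokens$et2` for dilated) as slot 1 of every window.
#'
#' @param tokens Numeric array `n_trials x Tz x F2` (a single `Tz x F2`
#'   matrix is also accepted).
#' @param type_tokens `NULL`, or a list with numeric vectors `et1`, `et2`
#'   of length `F2`.
#' @return A list of class `mi_windows`: `windows` (array
#'   `n x L x W x F2`), `kinds` (character, `"continuous"`/`"dilated"`),
#'   `index_map` (per-window source indices, `0` marking the type-token
#'   slot).
#' @examples
#' toks <- array(rnorm(2 * 8 * 4), c(2, 8, 4))
#' w <- build_windows(toks)
#' dim(w$windows)  # 2 trials, 4 windows, 4 tokens each
#' @export
build_windows <- function(tokens, type_tokens = NULL) {
  if (is.matrix(tokens)) tokens <- array(tokens, c(1L, dim(tokens)))
  d <- dim(tokens); n <- d[1]; tz <- d[2]; F2 <- d[3]
  im <- window_index_map(tz)
  idx_all <- c(im$continuous, im$dilated)
  kinds <- c(rep("continuous", length(im$continuous)), rep("dilated", 2L))
  L <- length(idx_all)
  wl <- tz %/% 2L
  has_type <- !is.null(type_tokens)
  W <- wl + if (has_type) 1L else 0L
  zw <- array(0, c(n, L, W, F2))
  index_map <- vector("list", L)
  for (l in seq_len(L)) {
    idx <- idx_all[[l]]
    if (has_type) {
      et <- if (kinds[l] == "continuous") type_tokens$et1 else type_tokens$et2
      zw[, l, 1L, ] <- matrix(et, n, F2, byrow = TRUE)
      zw[, l, 1L + seq_along(idx), ] <- tokens[, idx, , drop = FALSE]
      index_map[[l]] <- c(0L, idx)
    } else {
      zw[, l, seq_along(idx), ] <- tokens[, idx, , drop = FALSE]
      index_map[[l]] <- idx
    }
  }
  structure(list(windows = zw, kinds = kinds, index_map = index_map,
                 tz = tz, has_type = has_type),
            class = "mi_windows")
}

# gradient of build_windows: scatter window grads back onto tokens and the
# two type tokens (which are shared, so their grads accumulate over windows
# and trials)
windows_bwd <- function(d_windows, ws) {
  d <- dim(d_windows); n <- d[1]; L <- d[2]; F2 <- d[4]
  dtok <- array(0, c(n, ws$tz, F2))
  det1 <- rep(0, F2); det2 <- rep(0, F2)
  for (l in seq_len(L)) {
    idx <- ws$index_map[[l]]
    src <- idx[idx > 0L]
    slots <- which(idx > 0L)
    dtok[, src, ] <- dtok[, src, , drop = FALSE] +
      array(d_windows[, l, slots, , drop = FALSE], c(n, length(src), F2))
    if (ws$has_type) {
      g <- colSums(matrix(d_windows[, l, 1L, ], n, F2))
      if (ws$kinds[l] == "continuous") det1 <- det1 + g else det2 <- det2 + g
    }
  }
  list(dtokens = dtok, det1 = det1, det2 = det2)
}

#' Concatenate windows into one token sequence
#'
#' Flattens an `n x L x W x F2` window array into the `n x (L*W) x F2`
#' sequence fed to the global attention stage, preserving window order and
#' within-window token order (type-token slots included).
#'
#' @param windows An `mi_windows` object or a bare `n x L x W x F2` array.
#' @return Numeric array `n x (L*W) x F2`.
#' @export
concatenate_windows <- function(windows) {
  zw <- if (inherits(windows, "mi_windows")) windows$windows else windows
  d <- dim(zw)
  stopifnot(length(d) == 4L)
  array(aperm(zw, c(1, 3, 2, 4)), c(d[1], d[2] * d[3], d[4]))
}

# inverse reshape for the backward pass
concat_bwd <- function(d_seq, L, W) {
  d <- dim(d_seq)
  aperm(array(d_seq, c(d[1], W, L, d[3])), c(1, 3, 2, 4))
}
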