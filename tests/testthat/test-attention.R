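test_that("multi-head attention matches the loop-based oracle on small toys", {
  for (case in list(list(n = 2, F2 = 2, Dh = 1, h = 2),
                    list(n = 3, F2 = 4, Dh = 2, h = 2),
                    list(n = 4, F2 = 4, Dh = 1, h = 4))) {
    p <- small_attn_params(case$F2, case$Dh, case$h, seed = case$n)
    set.seed(case$n + 10)
    z <- matrix(rnorm(case$n * case$F2), case$n, case$F2)
    got <- self_attention(z, p, case$Dh, case$h)
    want <- oracle_msa(z, p, case$Dh, case$h)
    expect_equal(unclass(got), want, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("attention rows are probability distributions", {
  p <- small_attn_params(4, 2, 2)
  set.seed(1)
  z <- matrix(rnorm(4 * 4), 4, 4)
  out <- self_attention(z, p, 2, 2)
  attn <- attr(out, "attention")      # n x n x h x B
  sums <- apply(attn, c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("a single token attends to itself with weight exactly 1", {
  p <- small_attn_params(4, 2, 2)
  z <- matrix(rnorm(4), 1, 4)
  out <- self_attention(z, p, 2, 2)
  attn <- attr(out, "attention")
  expect_equal(as.numeric(attn), rep(1, 2))
})

test_that("identical tokens yield uniform attention in every head", {
  p <- small_attn_params(4, 2, 2)
  z <- matrix(rep(rnorm(4), each = 5), 5, 4)
  out <- self_attention(z, p, 2, 2)
  attn <- attr(out, "attention")
  expect_true(all(abs(attn - 1 / 5) < 1e-6))
})

test_that("zeroed projections make the residual attention site an identity", {
  F2 <- 4; Dh <- 2; h <- 2
  p <- small_attn_params(F2, Dh, h)
  p$Wo <- p$Wo * 0
  set.seed(2)
  z3 <- array(rnorm(3 * 5 * F2), c(3, 5, F2))
  out <- attnmi:::attn_block_fwd(z3, p, Dh, h)$out
  expect_identical(out, z3)
})

test_that("residual attention sites match the oracle composition", {
  # local / global stage: z + MSA(LN(z)), checked on a single 3-token window
  F2 <- 4; Dh <- 2; h <- 2
  p <- small_attn_params(F2, Dh, h, seed = 7)
  set.seed(8)
  z <- matrix(rnorm(3 * F2), 3, F2)
  got <- attnmi:::attn_block_fwd(array(z, c(1, 3, F2)), p, Dh, h)$out
  want <- z + oracle_msa(oracle_layernorm(z, p$ln_gamma, p$ln_beta), p, Dh, h)
  expect_equal(array(want, c(1, 3, F2)), got, tolerance = 1e-5)
})

test_that("attention gradients agree with finite differences", {
  F2 <- 4; Dh <- 2; h <- 2; B <- 2; Wn <- 3
  p <- small_attn_params(F2, Dh, h, seed = 9)
  set.seed(10)
  z3 <- array(rnorm(B * Wn * F2), c(B, Wn, F2))
  loss <- function(pp, zz) sum(sin(attnmi:::attn_block_fwd(zz, pp, Dh, h)$out))
  fw <- attnmi:::attn_block_fwd(z3, p, Dh, h)
  gr <- attnmi:::attn_block_bwd(array(cos(fw$out), dim(fw$out)), fw$cache, p)
  eps <- 1e-6
  # probe a few entries of each parameter and of the input
  for (nm in c("Wq", "Whk", "Wo", "ln_gamma")) {
    for (k in 1:2) {
      pp <- p; pp[[nm]][k] <- pp[[nm]][k] + eps; up <- loss(pp, z3)
      pp[[nm]][k] <- pp[[nm]][k] - 2 * eps; dn <- loss(pp, z3)
      expect_equal(gr$grads[[nm]][k], (up - dn) / (2 * eps), tolerance = 1e-4,
                   info = nm)
    }
  }
  for (k in c(1, 7, 20)) {
    zz <- z3; zz[k] <- zz[k] + eps; up <- loss(p, zz)
    zz[k] <- zz[k] - 2 * eps; dn <- loss(p, zz)
    expect_equal(gr$dx[k], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("non-finite inputs are rejected before the softmax", {
  p <- small_attn_params(4, 2, 2)
  z <- matrix(rnorm(8), 2, 4)
  z[1, 1] <- NaN
  expect_error(self_attention(z, p, 2, 2), "non-finite")
})
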