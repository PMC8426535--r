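make_scores <- function(sub, n_valid = 10, heads = 3, len = 40) {
  A <- matrix(0, heads, len)
  A[, seq_len(n_valid)] <- 1 / n_valid
  structure(list(sub = sub, org = apply(sub, 2, max), A = A,
                 n_valid = n_valid, accession = "x"),
            class = "loc_scores")
}

test_that("forward output has the configured geometry and masked attention", {
  m <- toy_model()
  s <- random_sequence(16, seed = 21)
  enc <- encode(s, blosum_fallback(s), encode_len = m$cfg$encode_len)
  sc <- forward(enc, m$cfg, m$params, m$hierarchy)
  expect_equal(dim(sc$sub), c(8L, 3L))
  expect_equal(length(sc$org), 3L)
  expect_equal(dim(sc$A), c(3L, 40L))
  expect_equal(sc$n_valid, 16L)
  expect_true(all(sc$A[, 17:40] == 0))
  expect_true(all(sc$sub > 0 & sc$sub < 1))
  expect_equal(unname(sc$org), unname(apply(sc$sub, 2, max)))
})

test_that("attention rows are a masked softmax over valid positions", {
  cfg <- tiny_config()
  for (seed in 1:5) {
    cfg$seed <- seed
    params <- attnloc:::init_params(cfg)
    s <- random_sequence(sample(5:40, 1), seed = seed + 100)
    enc <- encode(s, blosum_fallback(s), encode_len = cfg$encode_len)
    sc <- forward(enc, cfg, params)
    sums <- rowSums(sc$A)
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_true(all(sc$A >= 0))
  }
})

test_that("C++ attention agrees with direct evaluation of the formula", {
  cfg <- tiny_config(seed = 13)
  params <- attnloc:::init_params(cfg)
  s <- random_sequence(20, seed = 13)
  enc <- encode(s, blosum_fallback(s), encode_len = cfg$encode_len)
  out <- attnloc:::cpp_forward(params, attnloc:::enc_to_x(enc), cfg$n_org)
  H <- out$H                                   # n x 2u
  S <- params$Ws2 %*% tanh(params$Ws1 %*% t(H))
  A_ref <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(out$A, A_ref, tolerance = 1e-10)
  expect_equal(out$M, A_ref %*% H, tolerance = 1e-10)
  expect_equal(length(out$M), cfg$flatten_len)
})

test_that("attention math is permutation-covariant given permuted embeddings", {
  # the attention block in isolation: permuting H's rows permutes A's columns
  set.seed(42)
  att <- function(H, Ws1, Ws2) {
    S <- Ws2 %*% tanh(Ws1 %*% t(H))
    t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  }
  H <- matrix(rnorm(15 * 8), 15, 8)
  Ws1 <- matrix(rnorm(6 * 8), 6, 8)
  Ws2 <- matrix(rnorm(3 * 6), 3, 6)
  A <- att(H, Ws1, Ws2)
  for (i in 1:5) {
    perm <- sample(15)
    expect_equal(att(H[perm, ], Ws1, Ws2), A[, perm], tolerance = 1e-12)
  }
})

test_that("all-masked input is rejected", {
  m <- toy_model()
  enc <- encode("MK", blosum_fallback("MK"), encode_len = m$cfg$encode_len)
  enc$mask[] <- 0
  expect_error(forward(enc, m$cfg, m$params), "masked")
})

test_that("attention penalty has its closed-form values", {
  expect_equal(attention_penalty(diag(3)), 0)
  A2 <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_equal(attention_penalty(A2), 2)
  A41 <- matrix(0, 41, 100)
  A41[, 1] <- 1
  # direct matrix computation oracle
  oracle <- sum((A41 %*% t(A41) - diag(41))^2)
  expect_equal(attention_penalty(A41), oracle)
  expect_equal(oracle, 41^2 - 41)
})

test_that("penalty decreases along its negative gradient from rank-one A", {
  A <- matrix(1 / 20, nrow = 4, ncol = 20)   # identical rows
  grad <- 4 * (A %*% t(A) - diag(4)) %*% A
  # finite-difference agreement
  eps <- 1e-6
  Ap <- A; Ap[2, 3] <- Ap[2, 3] + eps
  num <- (attention_penalty(Ap) - attention_penalty(A)) / eps
  expect_equal(num, grad[2, 3], tolerance = 1e-4)
  step <- A - 1e-3 * grad
  expect_lt(attention_penalty(step), attention_penalty(A))
})

test_that("two-level loss matches hand-computed cross-entropies", {
  h <- toy_hierarchy()
  cfg <- tiny_config()
  # uniform 0.5 scores: both terms are ln 2 regardless of the target
  sub <- matrix(0.5, 8, 3)
  sc <- make_scores(sub)
  tg <- labels_to_matrix("alpha", "a1", h)
  pen <- attention_penalty(sc$A[, 1:10])
  expect_equal(loss_lv2(sc, tg, cfg),
               log(2) + log(2) + cfg$attention_reg_weight * pen)
  # hand-set 2-organelle toy on the organelle term
  sub2 <- matrix(1e-4, 8, 3)
  sub2[1, 1] <- 0.9; sub2[1, 2] <- 0.1; sub2[1, 3] <- 1e-4
  sc2 <- make_scores(sub2)
  tg2 <- labels_to_matrix("alpha", character(0), h)
  lv1 <- loss_lv1(sc2, tg2, cfg)
  hand <- -(log(0.9) + log(0.9) + log(1 - 1e-4)) / 3
  expect_equal(lv1, hand + cfg$attention_reg_weight * pen, tolerance = 1e-9)
  expect_equal(-(log(0.9) + log(0.9)) / 2, 0.1054, tolerance = 1e-3)
})

test_that("lv2 minus the cell term equals lv1 on identical predictions", {
  h <- toy_hierarchy()
  cfg <- tiny_config()
  set.seed(8)
  sub <- matrix(runif(24, 0.05, 0.95), 8, 3)
  sc <- make_scores(sub)
  tg <- labels_to_matrix(c("alpha", "beta"), c("a2", "b1"), h)
  cell_term <- mean(attnloc:::.bce(as.numeric(sc$sub),
                                   as.numeric(tg$matrix)))
  expect_equal(loss_lv2(sc, tg, cfg) - cell_term, loss_lv1(sc, tg, cfg),
               tolerance = 1e-12)
})

test_that("R and C++ losses agree on forward outputs", {
  cfg <- tiny_config(seed = 3)
  params <- attnloc:::init_params(cfg)
  h <- toy_hierarchy()
  s <- random_sequence(18, seed = 3)
  enc <- encode(s, blosum_fallback(s), encode_len = cfg$encode_len)
  sc <- forward(enc, cfg, params, h)
  tg <- labels_to_matrix("alpha", "a1", h)
  cmask <- rep(1, cfg$dense_out)
  for (lv1 in c(FALSE, TRUE)) {
    r_loss <- if (lv1) loss_lv1(sc, tg, cfg) else loss_lv2(sc, tg, cfg, h)
    c_loss <- attnloc:::cpp_sample_loss(params, attnloc:::enc_to_x(enc),
                                        as.numeric(tg$matrix),
                                        as.numeric(tg$org), lv1, cmask,
                                        cfg$attention_reg_weight, cfg$n_org)
    expect_equal(r_loss, c_loss, tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config(seed = 11)
  cfg$attention_reg_weight <- 1e-2
  params <- attnloc:::init_params(cfg)
  h <- toy_hierarchy()
  s <- random_sequence(15, seed = 11)
  enc <- encode(s, blosum_fallback(s), encode_len = cfg$encode_len)
  X <- attnloc:::enc_to_x(enc)
  tg <- labels_to_matrix(c("alpha", "beta"), c("a1", "b1"), h)
  tm <- as.numeric(tg$matrix); to <- as.numeric(tg$org)
  cmask <- rep(1, cfg$dense_out)
  g <- attnloc:::cpp_grad(params, X, tm, to, FALSE, cmask,
                          cfg$attention_reg_weight, cfg$n_org)
  eps <- 1e-5
  set.seed(1)
  for (nm in c("l1f.W", "l2b.U", "Ws1", "Ws2", "Wd", "bd", "l1b.b")) {
    P <- params
    for (i in sample(length(P[[nm]]), 3)) {
      P[[nm]][i] <- params[[nm]][i] + eps
      lp <- attnloc:::cpp_sample_loss(P, X, tm, to, FALSE, cmask,
                                      cfg$attention_reg_weight, cfg$n_org)
      P[[nm]][i] <- params[[nm]][i] - eps
      lm <- attnloc:::cpp_sample_loss(P, X, tm, to, FALSE, cmask,
                                      cfg$attention_reg_weight, cfg$n_org)
      P[[nm]][i] <- params[[nm]][i]
      num <- (lp - lm) / (2 * eps)
      expect_equal(g$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("categorical cross-entropy variant matches direct evaluation", {
  expect_equal(loss_variant(rep(0, 10), c(1, rep(0, 9))), log(10))
  expect_equal(loss_variant(c(2, rep(0, 9)), c(1, rep(0, 9))),
               -log(exp(2) / (exp(2) + 9)), tolerance = 1e-12)
  big <- c(50, rep(0, 9))
  expect_lt(loss_variant(big, c(1, rep(0, 9))), 1e-10)
  expect_error(loss_variant(rep(0, 10), rep(0, 10)), "one-hot")
})
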