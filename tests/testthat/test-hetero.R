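# Heterogeneous GCN predictor module.

test_that("fused_similarity matches a hand-computed kernel", {
  Z <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  # pairwise distances: 0, 5, 5; median off-diagonal distance h = 5
  s <- fused_similarity(Z)
  expect_equal(s$values["a", "b"], exp(-25 / (2 * 25)), tolerance = 1e-12)
  expect_equal(s$values["a", "c"], 1, tolerance = 1e-12)
  expect_equal(diag(s$values), rep(1, 3), ignore_attr = TRUE)
  # explicit bandwidth, 3-point oracle
  s2 <- fused_similarity(Z, bandwidth = 2)
  expect_equal(s2$values["b", "c"], exp(-25 / 8), tolerance = 1e-12)
  set.seed(1)
  r <- fused_similarity(matrix(rnorm(40), 8, 5))
  expect_lt(max(abs(r$values - t(r$values))), 1e-12)
  expect_warning(fused_similarity(matrix(1, 4, 2)), "bandwidth")
})

test_that("knn_graph keeps topk neighbours with deterministic ties", {
  S <- random_similarity(5, seed = 13)$values
  A <- knn_graph(S, 2)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, 5), ignore_attr = TRUE)
  # sort-based oracle for the pre-symmetrization neighbour sets
  for (i in 1:5) {
    s <- S[i, ]; s[i] <- -Inf
    nb <- order(-s, seq_len(5))[1:2]
    expect_true(all(A[i, nb] > 0 | A[nb, i] > 0))
  }
  # topk = N-1 -> full matrix minus diagonal
  full <- knn_graph(S, 4)
  expect_equal(full, S - diag(diag(S)), tolerance = 1e-12, ignore_attr = TRUE)
  # tie at the boundary resolved toward the smaller index
  T2 <- matrix(0.5, 4, 4); diag(T2) <- 1
  At <- knn_graph(T2, 1)
  expect_equal(which(At[3, ] > 0), 1L)
  expect_error(knn_graph(S, 5), "topk")
})

test_that("init_state builds the block-diagonal embedding", {
  st <- toy_gcn_setup()
  H0 <- init_state(st$S_r, st$S_d)
  expect_identical(dim(H0), c(9L, 9L))
  expect_equal(H0[1:5, 1:5], st$S_r, ignore_attr = TRUE)
  expect_equal(H0[1:5, 6:9], matrix(0, 5, 4))
  expect_equal(H0[6:9, 6:9], st$S_d, ignore_attr = TRUE)
})

test_that("normalized_gcn matches its hand-normalized oracle", {
  expect_equal(normalized_gcn(diag(3), diag(3), diag(3)), diag(3))
  set.seed(3)
  A <- matrix(runif(9), 3); A <- A + t(A); diag(A) <- 0
  H <- matrix(rnorm(6), 3, 2)
  W <- matrix(rnorm(4), 2, 2)
  d <- rowSums(A)
  oracle <- diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d)) %*% H %*% W
  oracle[oracle < 0] <- 0
  expect_equal(normalized_gcn(A, H, W), oracle, tolerance = 1e-12)
  expect_true(all(normalized_gcn(A, H, W) >= 0))
  # zero-degree row falls back to degree 1 without NaN
  A0 <- A; A0[1, ] <- 0; A0[, 1] <- 0
  expect_true(all(is.finite(normalized_gcn(A0, H, W))))
})

test_that("intra_domain_step separates domains and composes normalized_gcn", {
  st <- toy_gcn_setup()
  set.seed(5)
  H_r <- matrix(rnorm(st$N * st$k), st$N)
  H_d <- matrix(rnorm(st$M * st$k), st$M)
  W_r <- matrix(rnorm(st$k^2), st$k)
  W_d <- matrix(rnorm(st$k^2), st$k)
  out <- intra_domain_step(H_r, H_d, st$A_r, st$A_d, W_r, W_d)
  expect_equal(out$H_r, normalized_gcn(st$A_r, H_r, W_r), tolerance = 1e-12)
  expect_equal(out$H_d, normalized_gcn(st$A_d, H_d, W_d), tolerance = 1e-12)
  # drug block is independent of disease inputs
  out2 <- intra_domain_step(H_r, H_d + 5, st$A_r, st$A_d, W_r, W_d)
  expect_equal(out2$H_r, out$H_r)
})

test_that("inter_domain_step matches a double-loop oracle", {
  set.seed(7)
  N <- 3; M <- 2; k <- 2
  A <- rbind(c(1, 0), c(1, 1), c(0, 0))     # includes a zero-degree drug
  H_r <- matrix(rnorm(N * k), N)
  H_d <- matrix(rnorm(M * k), M)
  W <- matrix(rnorm(k * k), k)
  for (alpha in c(0, 0.5, 1)) {
    out <- inter_domain_step(H_r, H_d, A, W, alpha)
    for (i in 1:N) {
      ba <- rep(0, k); mn <- rep(0, k)
      for (j in 1:M) {
        ba <- ba + (H_d[j, ] %*% W) * (H_r[i, ] %*% W) * A[i, j]
        mn <- mn + (H_d[j, ] %*% W) * A[i, j]
      }
      pre <- alpha * ba / (sum(A[i, ]) + 1) +
        (1 - alpha) * mn / max(sum(A[i, ]), 1)
      expect_equal(out$H_r[i, ], drop(1 / (1 + exp(-pre))), tolerance = 1e-12)
    }
    for (j in 1:M) {
      ba <- rep(0, k); mn <- rep(0, k)
      for (i in 1:N) {
        ba <- ba + (H_r[i, ] %*% W) * (H_d[j, ] %*% W) * A[i, j]
        mn <- mn + (H_r[i, ] %*% W) * A[i, j]
      }
      pre <- alpha * ba / (sum(A[, j]) + 1) +
        (1 - alpha) * mn / max(sum(A[, j]), 1)
      expect_equal(out$H_d[j, ], drop(1 / (1 + exp(-pre))), tolerance = 1e-12)
    }
  }
})

test_that("merge_step and layer_attention_combine are exact sums", {
  a <- matrix(1:6, 2); b <- matrix(rnorm(6), 2); c0 <- matrix(runif(6), 2)
  expect_equal(merge_step(a, b, c0), a + b + c0)
  expect_equal(merge_step(a, b, c0), merge_step(b, a, c0))
  expect_equal(merge_step(a * 0, b * 0, c0), c0)
  H1 <- matrix(rnorm(12), 4); H2 <- matrix(rnorm(12), 4)
  comb <- layer_attention_combine(list(H1, H2), c(0.5, 0.5), N = 3)
  expect_equal(rbind(comb$H_R, comb$H_D), (H1 + H2) / 2)
  expect_identical(nrow(comb$H_R), 3L)
  expect_identical(nrow(comb$H_D), 1L)
  one <- layer_attention_combine(list(H1), 1, N = 2)
  expect_equal(rbind(one$H_R, one$H_D), H1)
  expect_error(layer_attention_combine(list(H1), c(1, 2), N = 2), "length")
})

test_that("decode_scores is the logistic bilinear decoder", {
  H_R <- matrix(0, 3, 2); H_D <- matrix(rnorm(4), 2, 2)
  expect_equal(decode_scores(H_R, H_D), matrix(0.5, 3, 2))
  # 2x2 closed form
  H_R <- rbind(c(1, 0), c(0, 2)); H_D <- rbind(c(1, 1), c(-1, 0))
  expect_equal(decode_scores(H_R, H_D),
               1 / (1 + exp(-tcrossprod(H_R, H_D))), tolerance = 1e-12)
  # monotone in the inner product
  x <- seq(-3, 3, by = 0.5)
  s <- decode_scores(matrix(x, ncol = 1), matrix(1))
  expect_true(all(diff(drop(s)) > 0))
  expect_error(decode_scores(matrix(0, 2, 2), matrix(0, 2, 3)), "width")
})

test_that("weighted_bce_loss counts the balance factor and closed form", {
  A <- matrix(0, 3, 4); A[1, 1] <- A[2, 3] <- 1
  # gamma = (12 - 2) / 2 = 5 via the counting oracle
  p_half <- matrix(0.5, 3, 4)
  expected <- -(5 * 2 * log(0.5) + 10 * log(0.5)) / 12
  expect_equal(weighted_bce_loss(p_half, A), expected, tolerance = 1e-12)
  good <- matrix(0.001, 3, 4); good[A == 1] <- 0.999
  expect_lt(weighted_bce_loss(good, A), weighted_bce_loss(p_half, A))
  expect_error(weighted_bce_loss(p_half, A * 0), "positive")
})

test_that("analytic GCN gradients match finite differences", {
  st <- toy_gcn_setup()
  H0 <- init_state(st$S_r, st$S_d)
  An_r <- kgrdr:::sym_normalize(st$A_r)
  An_d <- kgrdr:::sym_normalize(st$A_d)
  params <- kgrdr:::gcn_init(st$N, st$M, st$k, st$L, seed = 7)
  mask <- matrix(1, st$N, st$M)
  lossfun <- function(p) {
    fw <- kgrdr:::gcn_forward(p, H0, An_r, An_d, st$A, st$N, st$M)
    weighted_bce_loss(fw$scores, st$A, mask)
  }
  fw <- kgrdr:::gcn_forward(params, H0, An_r, An_d, st$A, st$N, st$M,
                            keep = TRUE)
  gr <- kgrdr:::gcn_backward(params, fw, H0, An_r, An_d, st$A, mask,
                             st$N, st$M)
  eps <- 1e-4
  num_for <- function(set_get) {
    x <- set_get$get(params)
    g <- x * 0
    for (i in seq_along(x)) {
      p1 <- set_get$set(params, `[<-`(x, i, x[i] + eps))
      p2 <- set_get$set(params, `[<-`(x, i, x[i] - eps))
      g[i] <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    }
    g
  }
  cases <- list(
    P = list(get = function(p) p$P, set = function(p, x) { p$P <- x; p }),
    beta = list(get = function(p) p$beta,
                set = function(p, x) { p$beta <- x; p }),
    W_r1 = list(get = function(p) p$layers[[1]]$W_r,
                set = function(p, x) { p$layers[[1]]$W_r <- x; p }),
    W2 = list(get = function(p) p$layers[[2]]$W,
              set = function(p, x) { p$layers[[2]]$W <- x; p }),
    alpha1 = list(get = function(p) p$layers[[1]]$alpha,
                  set = function(p, x) { p$layers[[1]]$alpha <- x; p })
  )
  analytic <- list(P = gr$P, beta = gr$beta, W_r1 = gr$layers[[1]]$W_r,
                   W2 = gr$layers[[2]]$W, alpha1 = gr$layers[[1]]$alpha)
  for (nm in names(cases)) {
    n <- num_for(cases[[nm]])
    expect_lt(max(abs(analytic[[nm]] - n)) / max(max(abs(n)), 1e-8), 2e-3)
  }
})

test_that("train_predictor descends and emits probabilities", {
  st <- toy_gcn_setup(N = 8, M = 6)
  net <- build_hetero_network(st$A, S_r = st$S_r, S_d = st$S_d, topk = 3)
  model <- train_predictor(net, k = 4, L = 2, epochs = 60, lr = 0.05,
                           dropout = 0.2, edge_dropout = 0.1, seed = 1)
  expect_true(all(model$scores > 0 & model$scores < 1))
  expect_lt(model$loss_trace[60], model$loss_trace[1])
  # determinism
  model2 <- train_predictor(net, k = 4, L = 2, epochs = 60, lr = 0.05,
                            dropout = 0.2, edge_dropout = 0.1, seed = 1)
  expect_equal(model$scores, model2$scores, tolerance = 1e-12)
})

test_that("auroc and aupr match rank-based oracles", {
  set.seed(17)
  scores <- rnorm(20)
  labels <- rbinom(20, 1, 0.5)
  labels[1] <- 1; labels[2] <- 0
  # pair-counting oracle for AUROC
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cnt <- 0
  for (p in pos) for (n in neg) cnt <- cnt + (p > n) + 0.5 * (p == n)
  expect_equal(auroc(scores, labels), cnt / (length(pos) * length(neg)),
               tolerance = 1e-12)
  # cumulative precision oracle for AUPR
  ord <- order(-scores)
  lab <- labels[ord]
  ap <- 0; tp <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  expect_equal(aupr(scores, labels), ap / sum(labels), tolerance = 1e-12)
  # random scores on a balanced 200-pair set stay near 0.5
  set.seed(23)
  r <- replicate(20, auroc(rnorm(200), rbinom(200, 1, 0.5)))
  expect_lt(abs(mean(r) - 0.5), 0.05)
})

test_that("evaluate_cv partitions pairs into disjoint covering folds", {
  st <- toy_gcn_setup(N = 10, M = 8)
  set.seed(2)
  A <- matrix(rbinom(80, 1, 0.3), 10, 8)
  A[1, 1] <- 1
  net <- build_hetero_network(A, S_r = random_similarity(10, 1)$values,
                              S_d = random_similarity(8, 2)$values, topk = 3)
  cv <- evaluate_cv(net, folds = 5, seed = 3, k = 4, L = 1, epochs = 15,
                    dropout = 0, edge_dropout = 0)
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(is.finite(cv$folds$auroc)))
  expect_true(cv$mean_auroc >= 0 && cv$mean_auroc <= 1)
  expect_error(evaluate_cv(net, folds = 1000), "folds")
})

test_that("zero-information limit yields near-constant scores", {
  # identical features and an empty association matrix: with no training
  # signal (the class-balanced loss is undefined without positives) the
  # decoded scores must not distinguish pairs
  N <- 8; M <- 6
  Z <- matrix(1, N, 3)
  rownames(Z) <- paste0("d", 1:N)
  Zd <- matrix(1, M, 3)
  rownames(Zd) <- paste0("i", 1:M)
  A <- matrix(0, N, M)
  suppressWarnings(
    net <- build_hetero_network(A, Z_r = Z, Z_d = Zd, topk = 2))
  model <- train_predictor(net, k = 3, L = 1, epochs = 0, dropout = 0,
                           edge_dropout = 0, seed = 4)
  # kNN tie-breaking on the all-equal similarity leaves slightly unequal
  # degrees, so "near-constant", not bitwise-constant
  expect_lt(stats::sd(model$scores), 0.01)
  # and training with positives is refused outright on an empty matrix
  expect_error(weighted_bce_loss(matrix(0.5, N, M), A), "positive")
})
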