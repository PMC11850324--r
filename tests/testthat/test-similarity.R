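# Multi-similarity integration module.

test_that("gip_similarity matches a scalar-loop oracle and its contracts", {
  interactions <- random_interactions(6, 5, seed = 3)
  sim <- gip_similarity(interactions, "drugs")
  # independent scalar-loop oracle
  P <- interactions$values
  gamma_n <- nrow(P) / sum(P^2)
  oracle <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    oracle[a, b] <- exp(-gamma_n * sum((P[a, ] - P[b, ])^2))
  }
  expect_equal(unname(sim$values), oracle, tolerance = 1e-12)
  expect_equal(diag(sim$values), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(sim$values > 0 & sim$values <= 1))
  # identical profiles -> similarity 1
  A <- interaction_matrix(rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(gip_similarity(A, "drugs")$values[1, 2], 1)
  # hand-evaluated 2x2 toy: profiles (1,0) and (0,1); gamma_n = 1*2/2 = 1,
  # off-diagonal similarity exp(-1 * 2) = e^-2 (oracle-verified)
  toy <- interaction_matrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(gip_similarity(toy, "drugs")$values[1, 2], exp(-2),
               tolerance = 1e-12)
  # disease axis uses column profiles
  simd <- gip_similarity(interactions, "diseases")
  expect_identical(dim(simd$values), c(5L, 5L))
  expect_error(gip_similarity(interaction_matrix(matrix(0, 2, 2)), "drugs"),
               "all-zero")
  expect_error(gip_similarity(interactions, "drugs", gamma_prime = -1),
               "positive")
})

test_that("gip_similarity is equivariant under entity permutation", {
  interactions <- random_interactions(7, 5, seed = 9)
  sim <- gip_similarity(interactions, "drugs")$values
  perm <- c(3, 1, 7, 2, 6, 5, 4)
  permuted <- interaction_matrix(interactions$values[perm, ],
                                 interactions$drug_ids[perm],
                                 interactions$disease_ids)
  expect_equal(unname(gip_similarity(permuted, "drugs")$values),
               unname(sim[perm, perm]), tolerance = 1e-12)
})

test_that("average_entropy handles point masses, uniform rows and mixtures", {
  expect_equal(average_entropy(similarity_matrix(diag(4))), 0)
  ones <- similarity_matrix(matrix(1, 4, 4))
  expect_equal(average_entropy(ones), log(4))
  mixed <- similarity_matrix(rbind(c(1, 1), c(1, 0)))
  expect_equal(average_entropy(mixed), log(2) / 2)
  # zero row warns and contributes 0
  z <- matrix(0, 3, 3); z[1, 2] <- z[2, 1] <- 1
  expect_warning(e <- average_entropy(similarity_matrix(z)), "zero row")
  expect_equal(e, 0)
  expect_error(average_entropy(similarity_matrix(matrix(1, 1, 1))),
               "at least 2")
})

test_that("select_similarities drops uninformative and redundant views", {
  expect_length(select_similarities(list(random_similarity(5))), 1)
  # duplicate is removed at redundancy_threshold 0.99
  s1 <- random_similarity(6, seed = 1)
  dup <- s1; dup$source_name <- "dup"
  kept <- select_similarities(list(s1, dup), entropy_quantile = 1,
                              redundancy_threshold = 0.99)
  expect_length(kept, 1)
  # 4-matrix case: two noisy copies of a latent structure, one uniform
  # (max entropy), one exact duplicate -> uniform and duplicate go
  spec <- tiny_spec(seed = 5)
  stack <- make_similarity_stack(spec, "drugs")   # v1, v2, dup(v1), noise
  names(stack) <- vapply(stack, `[[`, "", "source_name")
  kept <- select_similarities(stack, entropy_quantile = 0.75,
                              redundancy_threshold = 0.8)
  kept_names <- vapply(kept, `[[`, "", "source_name")
  expect_false("drugs_noise" %in% kept_names)
  expect_false(all(c("drugs_view1", "drugs_dup1") %in% kept_names))
  # exhaustive pairwise-check oracle: no surviving pair above threshold
  for (i in seq_along(kept)) for (j in seq_len(i - 1)) {
    ut <- upper.tri(kept[[i]]$values)
    expect_lte(stats::cor(kept[[i]]$values[ut], kept[[j]]$values[ut]), 0.8)
  }
  # mismatched id orders rejected
  other <- random_similarity(6, seed = 2, ids = sprintf("x%02d", 1:6))
  expect_error(select_similarities(list(s1, other)), "id ordering")
})

test_that("denoise matches its power-series oracle and spectral form", {
  sim <- random_similarity(10, seed = 4)
  dn <- denoise(sim, alpha = 0.5)
  # power-series oracle of the closed form: (1-a) sum_t a^t S^(2t+1)
  rs <- rowSums(sim$values)
  Sn <- sim$values * tcrossprod(1 / sqrt(rs))
  Sn <- (Sn + t(Sn)) / 2
  acc <- matrix(0, 10, 10)
  P <- Sn
  S2 <- Sn %*% Sn
  for (t in 0:200) {
    acc <- acc + 0.5^t * P
    P <- P %*% S2
  }
  expect_equal(dn$values, 0.5 * acc, tolerance = 1e-6, ignore_attr = TRUE)
  # eigenvalues transform as (1-a)l/(1-a l^2)
  lam <- dn$eigvals
  expect_equal(sort(eigen(dn$values, symmetric = TRUE)$values),
               sort((1 - 0.5) * lam / (1 - 0.5 * lam^2)), tolerance = 1e-8)
  # symmetry for several alphas; identity in the alpha -> 0 limit
  for (a in c(0.2, 0.8, 0.99)) {
    expect_lt(max(abs(denoise(sim, a)$values - t(denoise(sim, a)$values))),
              1e-10)
  }
  expect_equal(denoise(sim, 1e-9)$values, Sn, tolerance = 1e-6,
               ignore_attr = TRUE)
  # identity input is a fixed point for any alpha
  expect_equal(denoise(similarity_matrix(diag(5)), 0.7)$values, diag(5),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(denoise(sim, 1), "alpha")
  expect_error(denoise(sim, 0), "alpha")
})

test_that("denoise adds self-loops to isolated entities", {
  S <- diag(4); S[1, 2] <- S[2, 1] <- 0.5
  S[3, 3] <- S[4, 4] <- 0                 # isolated, zero rows
  expect_message(dn <- denoise(similarity_matrix(S), 0.5), "self-loop")
  expect_true(all(is.finite(dn$values)))
})

test_that("reconstruct is row-stochastic and matches closed forms", {
  set.seed(8)
  X <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(15), 5, 3)
  R <- reconstruct(X, W)
  expect_equal(rowSums(R), rep(1, 4), tolerance = 1e-12)
  expect_equal(reconstruct(matrix(0, 3, 2), matrix(rnorm(8), 4, 2)),
               matrix(1 / 4, 3, 4), tolerance = 1e-12)
  # 2x2 logits (1, 0) -> (e/(e+1), 1/(e+1))
  X1 <- matrix(c(1, 0), 1, 2)
  W1 <- rbind(c(1, 0), c(0, 0))
  expect_equal(drop(reconstruct(X1, W1)),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # overflow safety
  expect_true(all(is.finite(reconstruct(matrix(1e4, 2, 2),
                                        matrix(1e4, 3, 2)))))
})

test_that("joint_loss components satisfy their identities", {
  set.seed(11)
  n <- 6; D <- 3
  S <- random_similarity(n, seed = 12)$values
  X <- matrix(rnorm(n * D), n, D)
  W <- matrix(rnorm(n * D), n, D)
  # Laplacian trace identity vs double-loop pairwise sum (factor 1/2)
  l <- joint_loss(list(S), X, list(W), lambda_reg = 1)
  brute <- 0
  for (i in 1:n) for (j in 1:n) {
    brute <- brute + sum((X[i, ] - X[j, ])^2) * S[i, j]
  }
  expect_equal(l$L_reg, brute / 2, tolerance = 1e-9)
  # identical entity feature vectors -> zero regularizer
  Xc <- matrix(rep(rnorm(D), each = n), n, D)
  expect_equal(joint_loss(list(S), Xc, list(W), 1)$L_reg, 0,
               tolerance = 1e-9)
  # perfect reconstruction -> L_appr = 0: build W so softmax(XW') equals the
  # row-normalized target is hard analytically; instead check KL >= 0 and
  # the exact zero when the target equals the reconstruction
  Q <- reconstruct(X, W)
  lz <- joint_loss(list(Q), X, list(W), 0)
  expect_equal(lz$L_appr, 0, tolerance = 1e-9)
  expect_gte(l$L_appr, 0)
})

test_that("fit_joint_decomposition descends, reconstructs and is bit-stable", {
  spec <- tiny_spec(seed = 2)
  den <- lapply(make_similarity_stack(spec, "drugs")[1:2], denoise, 0.8)
  fit <- suppressWarnings(
    fit_joint_decomposition(den, dim_D = 6, lambda_reg = 0.1,
                            max_iter = 150, seed = 7))
  tr <- fit$loss_trace
  expect_true(all(diff(tr$L) <= 1e-9))
  # improves on the uniform-reconstruction init baseline
  base <- joint_loss(den, fit$X * 0, lapply(fit$W_list, function(w) w * 0),
                     0.1)
  expect_lt(tr$L_appr[nrow(tr)], base$L_appr)
  # reconstructions are row-stochastic
  for (W in fit$W_list) {
    expect_equal(unname(rowSums(reconstruct(fit$X, W))),
                 rep(1, nrow(fit$X)), tolerance = 1e-8)
  }
  # repeated runs with one seed agree to machine precision
  fit2 <- suppressWarnings(
    fit_joint_decomposition(den, dim_D = 6, lambda_reg = 0.1,
                            max_iter = 150, seed = 7))
  expect_lt(abs(tr$L[nrow(tr)] -
                fit2$loss_trace$L[nrow(fit2$loss_trace)]), 1e-12)
  expect_error(fit_joint_decomposition(den, dim_D = 100), "dim_D")
})

test_that("analytic decomposition gradient matches finite differences", {
  set.seed(21)
  S <- random_similarity(5, seed = 22)$values
  X <- matrix(rnorm(10, sd = 0.3), 5, 2)
  W <- matrix(rnorm(10, sd = 0.3), 5, 2)
  g <- kgrdr:::joint_loss_grad(list(S), X, list(W), lambda_reg = 0.5)
  eps <- 1e-5
  numX <- X * 0
  for (i in seq_along(X)) {
    X1 <- X; X1[i] <- X[i] + eps
    X2 <- X; X2[i] <- X[i] - eps
    numX[i] <- (joint_loss(list(S), X1, list(W), 0.5)$L -
                joint_loss(list(S), X2, list(W), 0.5)$L) / (2 * eps)
  }
  expect_equal(g$gX, numX, tolerance = 1e-5, ignore_attr = TRUE)
  numW <- W * 0
  for (i in seq_along(W)) {
    W1 <- W; W1[i] <- W[i] + eps
    W2 <- W; W2[i] <- W[i] - eps
    numW[i] <- (joint_loss(list(S), X, list(W1), 0.5)$L -
                joint_loss(list(S), X, list(W2), 0.5)$L) / (2 * eps)
  }
  expect_equal(g$gW[[1]], numW, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("noisier views degrade latent recovery monotonically", {
  rec <- vapply(c(0.05, 0.3, 0.8), function(sig) {
    spec <- fixture_spec(n_drugs = 20, n_diseases = 20, latent_rank = 3,
                         density = 0.1, n_views_drug = 2, n_views_disease = 2,
                         noise_sigma = sig, redundancy_copies = 0,
                         noise_view = FALSE, seed = 1)
    den <- lapply(make_similarity_stack(spec, "drugs"), denoise, 0.8)
    fit <- suppressWarnings(
      fit_joint_decomposition(den, dim_D = 8, lambda_reg = 10, seed = 1))
    mean(stats::cancor(fit$X, kgrdr:::planted_factors(spec)$U)$cor)
  }, numeric(1))
  expect_gt(rec[1], rec[3])
})
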