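# Shared in-code fixtures for the test suite.  Everything is generated
# deterministically; nothing is read from disk except files the tests
# themselves write to tempdir().

# small random symmetric similarity matrix in [0, 1] with unit diagonal
random_similarity <- function(n, seed = 1, ids = sprintf("e%02d", seq_len(n))) {
  set.seed(seed)
  S <- matrix(stats::runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  similarity_matrix(S, ids = ids, source_name = paste0("rand", seed))
}

# small random binary interaction matrix guaranteed to have both classes
random_interactions <- function(n = 6, m = 5, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(stats::rbinom(n * m, 1, p), n, m)
    if (any(A == 1) && any(A == 0) && all(rowSums(A) > 0)) break
  }
  interaction_matrix(A)
}

# tiny fixture spec for fast end-to-end tests; ... overrides any default
tiny_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_drugs = 16, n_diseases = 12, latent_rank = 2, density = 0.15,
         n_views_drug = 2, n_views_disease = 2, noise_sigma = 0.05,
         redundancy_copies = 1, noise_view = TRUE, kg_extra_relations = 1,
         seed = seed),
    list(...))
  do.call(fixture_spec, args)
}

# small trained-free GCN setup shared by predictor tests
toy_gcn_setup <- function(seed = 42, N = 5, M = 4, k = 3, L = 2) {
  set.seed(seed)
  S_r <- crossprod(matrix(stats::runif(N * N), N)); S_r <- S_r / max(S_r)
  diag(S_r) <- 1
  S_d <- crossprod(matrix(stats::runif(M * M), M)); S_d <- S_d / max(S_d)
  diag(S_d) <- 1
  A <- matrix(stats::rbinom(N * M, 1, 0.4), N, M)
  if (all(A == 0)) A[1, 1] <- 1
  if (all(A == 1)) A[N, M] <- 0
  list(S_r = S_r, S_d = S_d, A = A,
       A_r = knn_graph(S_r, 2), A_d = knn_graph(S_d, 2),
       N = N, M = M, k = k, L = L)
}
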