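# Multi-similarity integration: profile-kernel similarity, entropy-based
# selection, spectral denoising, and KL joint decomposition with graph
# Laplacian regularization.

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes the Gaussian interaction profile kernel over the rows (drugs) or
#' columns (diseases) of a binary interaction matrix:
#' `K(a, b) = exp(-gamma_n * ||p_a - p_b||^2)` with the bandwidth normalized
#' by the mean squared profile norm, `gamma_n = gamma_prime * n / sum_i
#' ||p_i||^2`.
#'
#' @param interactions a [interaction_matrix()] object.
#' @param axis `"drugs"` (row profiles) or `"diseases"` (column profiles).
#' @param gamma_prime positive bandwidth multiplier; 1 by convention.
#' @return a [similarity_matrix()] with unit diagonal.
#' @export
gip_similarity <- function(interactions, axis = c("drugs", "diseases"),
                           gamma_prime = 1) {
  axis <- match.arg(axis)
  if (!inherits(interactions, "kgrdr_interactions")) {
    stop_invalid("interactions must be a kgrdr_interactions object")
  }
  if (!is.numeric(gamma_prime) || length(gamma_prime) != 1 || gamma_prime <= 0) {
    stop_invalid("gamma_prime must be a positive scalar")
  }
  P <- if (axis == "drugs") interactions$values else t(interactions$values)
  ids <- if (axis == "drugs") interactions$drug_ids else interactions$disease_ids
  sq <- rowSums(P^2)
  total <- sum(sq)
  if (total == 0) {
    stop_invalid("all-zero interaction matrix: GIP bandwidth undefined")
  }
  gamma_n <- gamma_prime * nrow(P) / total
  # squared Euclidean distances via the Gram matrix
  G <- tcrossprod(P)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  K <- exp(-gamma_n * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  similarity_matrix(K, ids = ids, source_name = paste0("GIP_", axis))
}

#' Average row entropy of a similarity matrix
#'
#' Each row is normalized to a probability distribution and its Shannon
#' entropy (natural log, `0 log 0 := 0`) computed; rows summing to zero get
#' entropy 0 with a warning.  The mean over rows lies in `[0, log N]`.
#'
#' @param sim a [similarity_matrix()] object.
#' @return scalar average entropy.
#' @export
average_entropy <- function(sim) {
  S <- sim$values
  if (nrow(S) < 2) stop_invalid("average_entropy needs at least 2 entities")
  rs <- rowSums(S)
  zero <- rs == 0
  if (any(zero)) {
    warning(sprintf("%d zero row(s) in '%s': entropy of those rows set to 0",
                    sum(zero), sim$source_name))
  }
  ent <- vapply(seq_len(nrow(S)), function(i) {
    if (zero[i]) return(0)
    p <- S[i, ] / rs[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(ent)
}

# correlation of the upper-triangular entries of two same-shaped matrices;
# zero-variance vectors are compared for near-equality instead.
uppertri_cor <- function(A, B) {
  ut <- upper.tri(A)
  a <- A[ut]; b <- B[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(if (max(abs(a - b)) < 1e-12) 1 else 0)
  }
  stats::cor(a, b)
}

#' Select an informative, low-redundancy subset of similarity matrices
#'
#' Four steps: (1) average entropy per matrix; (2) rank ascending (lower
#' entropy = more informative); (3) drop matrices whose entropy exceeds the
#' `entropy_quantile` of the entropy distribution; (4) among survivors,
#' whenever a pair has Pearson correlation of upper-triangular entries above
#' `redundancy_threshold`, drop the higher-entropy member.  The returned
#' subset preserves the input order and is never empty.
#'
#' @param stack list of [similarity_matrix()] objects sharing one id order.
#' @param entropy_quantile quantile in (0, 1\] above which matrices are
#'   discarded as uninformative.
#' @param redundancy_threshold correlation in (0, 1\] above which the
#'   higher-entropy member of a pair is discarded.
#' @return sub-list of `stack`.
#' @export
select_similarities <- function(stack, entropy_quantile = 0.75,
                                redundancy_threshold = 0.8) {
  if (length(stack) == 0) stop_invalid("empty similarity stack")
  ids <- stack[[1]]$ids
  for (s in stack) {
    if (!identical(s$ids, ids)) {
      stop_invalid("all similarity matrices must share the same id ordering")
    }
  }
  if (length(stack) == 1) return(stack)
  ent <- vapply(stack, average_entropy, numeric(1))
  keep <- which(ent <= stats::quantile(ent, entropy_quantile))
  # redundancy pruning: visit survivors from most to least informative and
  # greedily retain those not redundant with an already-retained matrix
  ord <- keep[order(ent[keep])]
  retained <- integer(0)
  for (i in ord) {
    redundant <- any(vapply(retained, function(j) {
      uppertri_cor(stack[[i]]$values, stack[[j]]$values) > redundancy_threshold
    }, logical(1)))
    if (!redundant) retained <- c(retained, i)
  }
  stack[sort(retained)]
}

#' Spectral denoising diffusion of a similarity matrix
#'
#' Symmetrically normalizes the input (`D^-1/2 S D^-1/2`, adding a unit
#' self-loop to isolated entities) so that eigenvalues lie in \[-1, 1\],
#' then damps noisy eigen-components:
#' `S_tilde = (1 - alpha) U Sigma (I - alpha Sigma^2)^-1 U'`.
#' Equivalently each eigenvalue `lambda` maps to
#' `(1 - alpha) lambda / (1 - alpha lambda^2)`.
#'
#' @param sim a [similarity_matrix()] object.
#' @param alpha diffusion strength in (0, 1); larger values boost
#'   self-similarity and damp small eigen-components more.
#' @return object of class `kgrdr_denoised` with fields `values`, `alpha`,
#'   `eigvecs`, `eigvals` (spectrum of the normalized input), `ids`.
#' @export
denoise <- function(sim, alpha = 0.8) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_invalid("alpha must lie strictly in (0, 1)")
  }
  S <- sim$values
  check_square_symmetric(S, what = "similarity")
  rs <- rowSums(S)
  if (any(rs == 0)) {
    iso <- which(rs == 0)
    message(sprintf("denoise: adding self-loops to %d isolated entit(ies)",
                    length(iso)))
    S[cbind(iso, iso)] <- 1
    rs <- rowSums(S)
  }
  d <- 1 / sqrt(rs)
  Sn <- S * tcrossprod(d)          # D^-1/2 S D^-1/2
  Sn <- (Sn + t(Sn)) / 2
  eg <- eigen(Sn, symmetric = TRUE)
  lam <- eg$values
  lam_new <- (1 - alpha) * lam / (1 - alpha * lam^2)
  out <- eg$vectors %*% (lam_new * t(eg$vectors))
  out <- (out + t(out)) / 2
  structure(list(values = out, alpha = alpha, eigvecs = eg$vectors,
                 eigvals = lam, ids = sim$ids,
                 source_name = sim$source_name),
            class = "kgrdr_denoised")
}

#' Softmax reconstruction of a similarity matrix from factors
#'
#' Entry `(i, j)` is `exp(<x_i, w_j>) / sum_j' exp(<x_i, w_j'>)` where `x_i`
#' and `w_j` are the i-th row of `X` and j-th row of `W`; every row of the
#' result sums to one.
#'
#' @param X common feature matrix, entities x D (rows are `x_i`).
#' @param W view-specific feature matrix, entities x D (rows are `w_j`).
#' @return row-stochastic reconstruction matrix.
#' @export
reconstruct <- function(X, W) {
  if (ncol(X) != ncol(W)) stop_invalid("X and W must have the same width")
  row_softmax(tcrossprod(X, W))
}

# row-normalize a denoised matrix to per-entity probability rows; zero rows
# become uniform (logged).
normalize_target <- function(S) {
  rs <- rowSums(S)
  bad <- rs <= 0
  if (any(bad)) {
    message(sprintf("joint_loss: %d nonpositive target row(s) set to uniform",
                    sum(bad)))
    S[bad, ] <- 1
    rs[bad] <- ncol(S)
  }
  S / rs
}

#' Joint decomposition loss
#'
#' `L = L_appr + lambda_reg * L_reg` where
#' `L_appr = (1/N) sum_v sum_i KL(s_i^(v) || shat_i^(v))` over row-normalized
#' denoised targets and softmax reconstructions, and
#' `L_reg = sum_v Tr(X' L_v X)` with `L_v = D_v - S_v` the graph Laplacian
#' of the v-th denoised matrix.
#'
#' @param denoised list of `kgrdr_denoised` objects (or plain matrices).
#' @param X common feature matrix (entities x D).
#' @param W_list list of view-specific matrices, same shape as `X`.
#' @param lambda_reg regularization weight, `>= 0`.
#' @return list with elements `L`, `L_appr`, `L_reg`.
#' @export
joint_loss <- function(denoised, X, W_list, lambda_reg) {
  N <- nrow(X)
  L_appr <- 0
  L_reg <- 0
  for (v in seq_along(denoised)) {
    S <- if (is.list(denoised[[v]])) denoised[[v]]$values else denoised[[v]]
    P <- normalize_target(S)
    Q <- reconstruct(X, W_list[[v]])
    PlogP <- ifelse(P > 0, P * log(P), 0)
    L_appr <- L_appr + sum(PlogP - P * log(pmax(Q, .Machine$double.xmin))) / N
    LX <- rowSums(S) * X - S %*% X          # L_v X  with L_v = D_v - S_v
    L_reg <- L_reg + sum(X * LX)
  }
  list(L = L_appr + lambda_reg * L_reg, L_appr = L_appr, L_reg = L_reg)
}

# analytic gradient of joint_loss wrt X and each W
joint_loss_grad <- function(denoised, X, W_list, lambda_reg) {
  N <- nrow(X)
  gX <- matrix(0, nrow(X), ncol(X))
  gW <- vector("list", length(denoised))
  for (v in seq_along(denoised)) {
    S <- if (is.list(denoised[[v]])) denoised[[v]]$values else denoised[[v]]
    P <- normalize_target(S)
    Q <- reconstruct(X, W_list[[v]])
    Dq <- (Q - P) / N                     # d L_appr / d logits
    gX <- gX + Dq %*% W_list[[v]]
    gW[[v]] <- crossprod(Dq, X)
    LX <- rowSums(S) * X - S %*% X
    gX <- gX + lambda_reg * 2 * LX
  }
  list(gX = gX, gW = gW)
}

#' Fit the graph-regularized joint decomposition
#'
#' Minimizes [joint_loss()] over the common feature matrix `X` and the
#' view-specific matrices `W^(v)` by full-batch gradient descent with
#' backtracking step-halving, which guarantees a non-increasing loss trace.
#'
#' @param denoised list of `kgrdr_denoised` objects sharing one entity set.
#' @param dim_D feature dimension (`<=` number of entities).
#' @param lambda_reg Laplacian regularization weight (`>= 0`).
#' @param max_iter iteration cap.
#' @param tol relative loss-change convergence tolerance.
#' @param seed initialization seed (`X, W ~ N(0, 0.01)`).
#' @return object of class `kgrdr_decomposition` with fields `X` (entities x
#'   `dim_D`, rownames = ids), `W_list`, `lambda_reg`, `loss_trace`
#'   (data.frame of `L`, `L_appr`, `L_reg` per accepted iterate) and
#'   `converged`.
#' @export
fit_joint_decomposition <- function(denoised, dim_D, lambda_reg = 10,
                                    max_iter = 500, tol = 1e-6, seed = 1) {
  if (length(denoised) == 0) stop_invalid("no denoised views supplied")
  N <- nrow(if (is.list(denoised[[1]])) denoised[[1]]$values else denoised[[1]])
  if (dim_D > N) stop_invalid("dim_D must not exceed the number of entities")
  if (lambda_reg < 0) stop_invalid("lambda_reg must be >= 0")
  ids <- if (is.list(denoised[[1]])) denoised[[1]]$ids else
    paste0("e", seq_len(N))
  V <- length(denoised)
  init <- with_seed(seed, {
    list(X = matrix(stats::rnorm(N * dim_D, sd = 0.1), N, dim_D),
         W = replicate(V, matrix(stats::rnorm(N * dim_D, sd = 0.1), N, dim_D),
                       simplify = FALSE))
  })
  X <- init$X
  W_list <- init$W
  cur <- joint_loss(denoised, X, W_list, lambda_reg)
  trace <- list(cur)
  step <- 1
  converged <- FALSE
  small_steps <- 0L
  for (it in seq_len(max_iter)) {
    g <- joint_loss_grad(denoised, X, W_list, lambda_reg)
    step <- min(step * 4, 1)          # re-open the step after halvings
    accepted <- FALSE
    for (h in 1:40) {
      Xn <- X - step * g$gX
      Wn <- lapply(seq_len(V), function(v) W_list[[v]] - step * g$gW[[v]])
      cand <- joint_loss(denoised, Xn, Wn, lambda_reg)
      if (is.finite(cand$L) && cand$L <= cur$L + 1e-12) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (cur$L - cand$L) / max(abs(cur$L), 1e-12)
    X <- Xn; W_list <- Wn; cur <- cand
    trace[[length(trace) + 1L]] <- cur
    # declare convergence only after sustained stalling, so a single
    # backtracked micro-step cannot masquerade as a minimum
    small_steps <- if (rel < tol) small_steps + 1L else 0L
    if (small_steps >= 3L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fit_joint_decomposition: max_iter reached without convergence")
  }
  rownames(X) <- ids
  loss_trace <- do.call(rbind, lapply(trace, function(z) {
    data.frame(L = z$L, L_appr = z$L_appr, L_reg = z$L_reg)
  }))
  structure(list(X = X, W_list = W_list, lambda_reg = lambda_reg,
                 loss_trace = loss_trace, converged = converged),
            class = "kgrdr_decomposition")
}
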