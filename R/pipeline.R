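# Pipeline orchestration: configuration, stage composition with caching
# and an I/O audit, ablation variants, cross-validation and candidate
# ranking.

config_defaults <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  base <- list(
    # predictor
    epoch = 2000, embedding_dim = 32, learning_rate = 0.05, layer_num = 2,
    topk = 15, dropout = 0.4, edge_dropout = 0.2, optimizer = "adam",
    # integration
    GR_dim = 32, alpha = 0.8, lambda_reg = 10, K_neighbors = 20,
    entropy_quantile = 0.75, redundancy_threshold = 0.8,
    gr_max_iter = 500, gr_tol = 1e-6,
    # knowledge graph
    KG_dim = 32, KG_lr = 0.1, KG_regularization = 0.1,
    kg_epochs = 200, n_neg = 10, kg_batch = 512,
    dd_relation = "Compound:Disease",
    # fusion
    channels = 16, ratio = 4,
    # run
    variant = "full", folds = 10, seed = 1, profile = profile
  )
  if (profile == "paper") {
    base[c("epoch", "embedding_dim", "GR_dim", "KG_dim",
           "KG_regularization", "n_neg")] <-
      list(4096, 128, 500, 500, 1e-7, 2)
  }
  base
}

#' Build a resolved run configuration
#'
#' Starts from the profile defaults (`"desk"` scales the published
#' hyperparameters down for laptop-sized runs; `"paper"` keeps them:
#' 4,096 epochs, feature dimension 500) and applies overrides.  Unknown
#' keys are rejected.
#'
#' @param ... named overrides of configuration keys.
#' @param profile `"desk"` or `"paper"`.
#' @return named list of class `kgrdr_config`.
#' @export
run_config <- function(..., profile = "desk") {
  cfg <- config_defaults(profile)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_invalid("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  if (!cfg$variant %in% c("full", "no_kg", "no_gri", "no_kg_gri")) {
    stop_invalid("variant must be one of full, no_kg, no_gri, no_kg_gri")
  }
  structure(cfg, class = "kgrdr_config")
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are
#' converted to numbers where possible.  Unknown keys are rejected.
#'
#' @param path file path.
#' @param profile base profile for unset keys.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(path, profile = "desk") {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop_invalid("malformed config line %d", bad[1])
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(run_config, c(vals, list(profile = profile)))
}

#' Write the resolved configuration as JSON next to the run outputs
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# content hash of input files plus a configuration subset, for stage caching
stage_hash <- function(files, cfg_subset) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg_subset), collapse = ""), tmp)
  h <- unname(tools::md5sum(c(files, tmp)))
  writeLines(h, tmp)                      # hash of hashes -> one 32-char key
  unname(tools::md5sum(tmp))
}

# ---- stages ---------------------------------------------------------------

#' Similarity-integration stage
#'
#' Appends the interaction-profile kernel similarity to the similarity
#' stack, selects an informative low-redundancy subset, denoises each
#' survivor and fits the graph-regularized joint decomposition.
#'
#' @param stack list of [similarity_matrix()] objects for one side.
#' @param interactions a [interaction_matrix()].
#' @param side `"drugs"` or `"diseases"`.
#' @param config a [run_config()].
#' @return the integrated feature matrix `X` (entities x `GR_dim`).
#' @export
integrate_stage <- function(stack, interactions, side, config) {
  gip <- gip_similarity(interactions, axis = side)
  stack <- c(stack, list(gip))
  sel <- select_similarities(stack, config$entropy_quantile,
                             config$redundancy_threshold)
  den <- lapply(sel, denoise, alpha = config$alpha)
  fit <- fit_joint_decomposition(den, dim_D = min(config$GR_dim,
                                                  length(stack[[1]]$ids)),
                                 lambda_reg = config$lambda_reg,
                                 max_iter = config$gr_max_iter,
                                 tol = config$gr_tol, seed = config$seed)
  fit$X
}

#' Knowledge-graph embedding stage
#'
#' Aligns the graph's drug-disease edges with the benchmark interactions,
#' trains ComplEx embeddings and extracts `[Re || Im]` features for the
#' benchmark drugs and diseases (width `KG_dim = 2k`).
#'
#' @param kg a [triple_store()].
#' @param interactions a [interaction_matrix()].
#' @param config a [run_config()].
#' @return list with `Y_r` (drugs x KG_dim), `Y_d`, and the fitted `emb`.
#' @export
embed_stage <- function(kg, interactions, config) {
  aligned <- align_benchmark(kg, interactions, config$dd_relation)
  k <- max(1L, as.integer(config$KG_dim / 2))
  emb <- fit_complex(aligned, k = k, lr = config$KG_lr,
                     reg_lambda = config$KG_regularization,
                     epochs = config$kg_epochs, n_neg = config$n_neg,
                     batch_size = config$kg_batch, seed = config$seed)
  list(Y_r = extract_features(emb, interactions$drug_ids),
       Y_d = extract_features(emb, interactions$disease_ids),
       emb = emb)
}

#' Attention-fusion stage
#'
#' Fuses the attribute features `X` and topological features `Y` of one
#' side by iterative attentional feature fusion; requires equal widths.
#'
#' @param X,Y feature matrices (entities x D).
#' @param config a [run_config()].
#' @return fused matrix `Z`.
#' @export
fuse_stage <- function(X, Y, config) {
  if (!all(dim(X) == dim(Y))) {
    stop_invalid(paste0("fusion requires equal feature dimensions ",
                        "(GR_dim must equal KG_dim); got %dx%d vs %dx%d"),
                 nrow(X), ncol(X), nrow(Y), ncol(Y))
  }
  params <- fusion_params(fusion_config(config$channels, config$ratio,
                                        seed = config$seed))
  iaff(X, Y, params)
}

# ---- end-to-end orchestration ---------------------------------------------

#' Run the full pipeline on file inputs
#'
#' Executes integrate -> embed -> fuse -> train (or cross-validate)
#' according to the configured ablation variant, writing every artifact
#' (features, scores, metrics, resolved config, I/O audit log) under
#' `out_dir`.  Variants: `full` fuses both feature sets; `no_kg` feeds the
#' integrated features alone; `no_gri` feeds the knowledge-graph features
#' alone; `no_kg_gri` feeds the first raw similarity of each side straight
#' to the predictor.  Integration and embedding results are cached by a
#' content hash of their inputs and configuration.
#'
#' @param config a [run_config()].
#' @param inputs list with paths: `interactions`, `drug_sims` (vector),
#'   `disease_sims` (vector), `kg`.
#' @param out_dir run directory (created).
#' @param action `"train"` (fit once, write scores) or `"cv"` (10-fold
#'   cross-validation, write metrics).
#' @return list with the run artifacts (`scores`, `metrics`, `audit`,
#'   paths).
#' @export
run_pipeline <- function(config, inputs, out_dir, action = c("train", "cv")) {
  action <- match.arg(action)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  audit <- character(0)
  note_read <- function(stage, path) {
    audit <<- c(audit, sprintf("%s\t%s", stage, path))
  }
  need <- function(key) {
    if (is.null(inputs[[key]])) stop_invalid("missing pipeline input: %s", key)
    inputs[[key]]
  }
  variant <- config$variant

  note_read("load", need("interactions"))
  interactions <- read_interactions_tsv(inputs$interactions)

  Z_r <- Z_d <- NULL
  S_r <- S_d <- NULL

  read_stack <- function(key, stage) {
    lapply(need(key), function(p) {
      note_read(stage, p)
      read_similarity_tsv(p)
    })
  }

  if (variant %in% c("full", "no_kg")) {
    h <- stage_hash(c(inputs$interactions, inputs$drug_sims,
                      inputs$disease_sims),
                    config[c("GR_dim", "alpha", "lambda_reg",
                             "entropy_quantile", "redundancy_threshold",
                             "gr_max_iter", "gr_tol", "seed")])
    cache_xr <- file.path(cache_dir, paste0("X_r_", h, ".tsv"))
    cache_xd <- file.path(cache_dir, paste0("X_d_", h, ".tsv"))
    if (file.exists(cache_xr) && file.exists(cache_xd)) {
      note_read("integrate(cache)", cache_xr)
      X_r <- read_features_tsv(cache_xr)
      X_d <- read_features_tsv(cache_xd)
    } else {
      X_r <- integrate_stage(read_stack("drug_sims", "integrate"),
                             interactions, "drugs", config)
      X_d <- integrate_stage(read_stack("disease_sims", "integrate"),
                             interactions, "diseases", config)
      write_features_tsv(X_r, cache_xr)
      write_features_tsv(X_d, cache_xd)
    }
    write_features_tsv(X_r, file.path(out_dir, "X_drugs.tsv"))
    write_features_tsv(X_d, file.path(out_dir, "X_diseases.tsv"))
  }

  if (variant %in% c("full", "no_gri")) {
    note_read("embed", need("kg"))
    h <- stage_hash(c(inputs$kg, inputs$interactions),
                    config[c("KG_dim", "KG_lr", "KG_regularization",
                             "kg_epochs", "n_neg", "kg_batch", "dd_relation",
                             "seed")])
    cache_yr <- file.path(cache_dir, paste0("Y_r_", h, ".tsv"))
    cache_yd <- file.path(cache_dir, paste0("Y_d_", h, ".tsv"))
    if (file.exists(cache_yr) && file.exists(cache_yd)) {
      note_read("embed(cache)", cache_yr)
      Y_r <- read_features_tsv(cache_yr)
      Y_d <- read_features_tsv(cache_yd)
    } else {
      kg <- read_triples(inputs$kg)
      emb <- embed_stage(kg, interactions, config)
      Y_r <- emb$Y_r; Y_d <- emb$Y_d
      write_features_tsv(Y_r, cache_yr)
      write_features_tsv(Y_d, cache_yd)
    }
    write_features_tsv(Y_r, file.path(out_dir, "Y_drugs.tsv"))
    write_features_tsv(Y_d, file.path(out_dir, "Y_diseases.tsv"))
  }

  if (variant == "full") {
    Z_r <- fuse_stage(X_r, Y_r, config)
    Z_d <- fuse_stage(X_d, Y_d, config)
  } else if (variant == "no_kg") {
    Z_r <- X_r; Z_d <- X_d
  } else if (variant == "no_gri") {
    Z_r <- Y_r; Z_d <- Y_d
  } else {                                   # no_kg_gri: first raw similarity
    S_r <- read_stack("drug_sims", "raw_similarity")[[1]]
    S_d <- read_stack("disease_sims", "raw_similarity")[[1]]
    S_r <- S_r$values; S_d <- S_d$values
  }
  if (!is.null(Z_r)) {
    write_features_tsv(Z_r, file.path(out_dir, "Z_drugs.tsv"))
    write_features_tsv(Z_d, file.path(out_dir, "Z_diseases.tsv"))
  }

  network <- build_hetero_network(interactions$values, Z_r = Z_r, Z_d = Z_d,
                                  S_r = S_r, S_d = S_d, topk = config$topk)
  result <- list(audit = audit, out_dir = out_dir)
  if (action == "train") {
    model <- train_predictor(network, k = config$embedding_dim,
                             L = config$layer_num, lr = config$learning_rate,
                             epochs = config$epoch, dropout = config$dropout,
                             edge_dropout = config$edge_dropout,
                             seed = config$seed)
    write_features_tsv(model$scores, file.path(out_dir, "scores.tsv"))
    utils::write.csv(data.frame(epoch = seq_along(model$loss_trace),
                                loss = model$loss_trace),
                     file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
    result$scores <- model$scores
    result$model <- model
  } else {
    cv <- evaluate_cv(network, folds = config$folds, seed = config$seed,
                      k = config$embedding_dim, L = config$layer_num,
                      lr = config$learning_rate, epochs = config$epoch,
                      dropout = config$dropout,
                      edge_dropout = config$edge_dropout)
    metrics <- list(variant = variant, seed = config$seed,
                    folds = cv$folds[, c("auroc", "aupr")],
                    mean_auroc = cv$mean_auroc, sd_auroc = cv$sd_auroc,
                    mean_aupr = cv$mean_aupr, sd_aupr = cv$sd_aupr)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    result$metrics <- metrics
  }
  write_run_config(config, file.path(out_dir, "config.json"))
  writeLines(audit, file.path(out_dir, "audit.log"))
  result
}

#' Rank candidate drugs for a disease
#'
#' Unknown pairs only (`A_ij = 0`), sorted by predicted score descending
#' with ties broken by drug identifier.
#'
#' @param scores N x M probability matrix with drug rownames and disease
#'   colnames.
#' @param interactions a [interaction_matrix()].
#' @param disease_id target disease identifier.
#' @param top_n maximum number of candidates.
#' @return data.frame with columns `disease_id`, `drug_id`, `score`,
#'   `rank`.
#' @export
rank_candidates <- function(scores, interactions, disease_id, top_n = 10) {
  if (!disease_id %in% interactions$disease_ids) {
    stop_invalid("unknown disease id: %s", disease_id)
  }
  j <- match(disease_id, interactions$disease_ids)
  unknown <- which(interactions$values[, j] == 0)
  if (length(unknown) == 0) {
    return(data.frame(disease_id = character(0), drug_id = character(0),
                      score = numeric(0), rank = integer(0)))
  }
  drugs <- interactions$drug_ids[unknown]
  s <- scores[cbind(match(drugs, rownames(scores)),
                    match(disease_id, colnames(scores)))]
  ord <- order(-s, drugs)
  n <- min(top_n, length(ord))
  data.frame(disease_id = disease_id, drug_id = drugs[ord[seq_len(n)]],
             score = s[ord[seq_len(n)]], rank = seq_len(n),
             row.names = NULL)
}
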