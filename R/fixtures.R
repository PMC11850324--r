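# Seeded synthetic inputs with the statistical structure the method
# assumes: a planted low-rank binary association matrix, stacks of noisy
# partially redundant similarity views sharing that latent structure, and a
# multi-relation knowledge graph whose drug-disease edges match the
# associations.  Pure functions of (spec, seed): byte-identical re-runs.

#' Specification of a synthetic benchmark fixture
#'
#' Defaults mirror the shape of the public SND benchmark at roughly 1/15
#' scale (58 drugs, 54 diseases, 10 drug views, 14 disease views) while
#' preserving its sparsity regime (association density 0.0125).
#'
#' @param n_drugs,n_diseases entity counts.
#' @param latent_rank planted factor dimension.
#' @param density association density in (0, 1).
#' @param n_views_drug,n_views_disease base similarity views per side
#'   (before duplicates and the optional noise view).
#' @param noise_sigma view noise standard deviation.
#' @param redundancy_copies exact duplicates of view 1 appended per side.
#' @param noise_view append one pure-noise view per side.
#' @param kg_extra_relations non-drug-disease relation types in the KG.
#' @param seed master seed.
#' @return object of class `kgrdr_fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 58, n_diseases = 54, latent_rank = 3,
                         density = 0.0125, n_views_drug = 10,
                         n_views_disease = 14, noise_sigma = 0.05,
                         redundancy_copies = 1, noise_view = TRUE,
                         kg_extra_relations = 2, seed = 1) {
  if (density <= 0 || density >= 1) stop_invalid("density must be in (0, 1)")
  if (latent_rank > min(n_drugs, n_diseases)) {
    stop_invalid("latent_rank must not exceed min(n_drugs, n_diseases)")
  }
  structure(as.list(environment()), class = "kgrdr_fixture_spec")
}

# planted factors shared by all generators; regenerated identically from
# the spec's master seed
planted_factors <- function(spec) {
  with_seed(spec$seed, {
    list(U = matrix(stats::rnorm(spec$n_drugs * spec$latent_rank),
                    spec$n_drugs, spec$latent_rank),
         V = matrix(stats::rnorm(spec$n_diseases * spec$latent_rank),
                    spec$n_diseases, spec$latent_rank))
  })
}

#' Planted low-rank binary interaction matrix
#'
#' Thresholds the top `density` fraction of `U V'` (standard-normal
#' factors) to 1; exactly `round(density * n_drugs * n_diseases)` known
#' pairs.
#'
#' @param spec a [fixture_spec()].
#' @return a [interaction_matrix()].
#' @export
make_interactions <- function(spec) {
  f <- planted_factors(spec)
  S <- tcrossprod(f$U, f$V)
  k <- round(spec$density * length(S))
  if (k < 1) stop_invalid("density yields zero positive pairs")
  A <- matrix(0, nrow(S), ncol(S))
  A[order(-S)[seq_len(k)]] <- 1
  interaction_matrix(A,
                     drug_ids = sprintf("DR%03d", seq_len(spec$n_drugs)),
                     disease_ids = sprintf("DI%03d", seq_len(spec$n_diseases)))
}

gaussian_kernel_sim <- function(F) {
  sq <- rowSums(F^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(F)
  D2[D2 < 0] <- 0
  h <- stats::median(sqrt(D2[upper.tri(D2)]))
  S <- exp(-D2 / (2 * h^2))
  diag(S) <- 1
  S
}

#' Stack of noisy similarity views sharing the planted structure
#'
#' The base similarity is a Gaussian kernel on the planted factors of the
#' requested side; each view adds symmetric `N(0, sigma^2)` noise, clipped
#' to \[0, 1\] with unit diagonal restored.  `redundancy_copies` exact
#' duplicates of view 1 and (optionally) one pure-noise view are appended.
#'
#' @param spec a [fixture_spec()].
#' @param side `"drugs"` or `"diseases"`.
#' @return list of [similarity_matrix()] objects.
#' @export
make_similarity_stack <- function(spec, side = c("drugs", "diseases")) {
  side <- match.arg(side)
  f <- planted_factors(spec)
  F <- if (side == "drugs") f$U else f$V
  ids <- if (side == "drugs") sprintf("DR%03d", seq_len(spec$n_drugs)) else
    sprintf("DI%03d", seq_len(spec$n_diseases))
  base <- gaussian_kernel_sim(F)
  n_views <- if (side == "drugs") spec$n_views_drug else spec$n_views_disease
  n <- nrow(base)
  with_seed(spec$seed + if (side == "drugs") 101 else 202, {
    views <- lapply(seq_len(n_views), function(v) {
      E <- matrix(0, n, n)
      E[upper.tri(E)] <- stats::rnorm(n * (n - 1) / 2, sd = spec$noise_sigma)
      E <- E + t(E)
      S <- pmin(pmax(base + E, 0), 1)
      diag(S) <- 1
      similarity_matrix(S, ids = ids,
                        source_name = sprintf("%s_view%d", side, v))
    })
    if (spec$redundancy_copies > 0) {
      for (ccc in seq_len(spec$redundancy_copies)) {
        dup <- views[[1]]
        dup$source_name <- sprintf("%s_dup%d", side, ccc)
        views[[length(views) + 1L]] <- dup
      }
    }
    if (isTRUE(spec$noise_view)) {
      # a flat, uninformative view: near-constant similarity, maximal row
      # entropy, so the selection step has something to discard
      S <- matrix(0.5, n, n)
      S[upper.tri(S)] <- 0.5 + stats::rnorm(n * (n - 1) / 2, sd = 0.01)
      S[lower.tri(S)] <- t(S)[lower.tri(S)]
      S <- pmin(pmax(S, 0), 1)
      diag(S) <- 1
      views[[length(views) + 1L]] <-
        similarity_matrix(S, ids = ids,
                          source_name = paste0(side, "_noise"))
    }
    views
  })
}

#' Multi-relation knowledge graph consistent with the interactions
#'
#' Drug-disease triples are exactly the known interactions (relation
#' `"Compound:Disease"`).  Each extra relation links drugs and diseases to
#' auxiliary gene-like entities whose latent affinity with them falls in
#' the top decile.
#'
#' @param spec a [fixture_spec()].
#' @param interactions the matching [make_interactions()] output.
#' @return a [triple_store()].
#' @export
make_kg <- function(spec, interactions) {
  pos <- which(interactions$values == 1, arr.ind = TRUE)
  dd <- data.frame(head = interactions$drug_ids[pos[, 1]],
                   relation = "Compound:Disease",
                   tail = interactions$disease_ids[pos[, 2]],
                   stringsAsFactors = FALSE)
  extra <- NULL
  if (spec$kg_extra_relations > 0) {
    f <- planted_factors(spec)
    # real drug-repurposing graphs carry an order of magnitude more triples
    # than entities; one gene-like hub per benchmark entity keeps that regime
    n_aux <- max(2L, spec$n_drugs + spec$n_diseases)
    aux_ids <- sprintf("GE%03d", seq_len(n_aux))
    extra <- with_seed(spec$seed + 303, {
      G <- matrix(stats::rnorm(n_aux * spec$latent_rank), n_aux,
                  spec$latent_rank)
      rows <- list()
      for (rel in seq_len(spec$kg_extra_relations)) {
        # affinity of each drug/disease to each auxiliary entity
        for (side in c("drug", "disease")) {
          F <- if (side == "drug") f$U else f$V
          ids <- if (side == "drug") interactions$drug_ids else
            interactions$disease_ids
          aff <- tcrossprod(F, G) +
            matrix(stats::rnorm(nrow(F) * n_aux, sd = 0.3), nrow(F), n_aux)
          thr <- stats::quantile(aff, 0.9)
          hit <- which(aff >= thr, arr.ind = TRUE)
          if (nrow(hit)) {
            rows[[length(rows) + 1L]] <- data.frame(
              head = ids[hit[, 1]],
              relation = sprintf("%s:Gene%d",
                                 if (side == "drug") "Compound" else "Disease",
                                 rel),
              tail = aux_ids[hit[, 2]],
              stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    })
  }
  triple_store(rbind(dd, extra),
               extra_entities = c(interactions$drug_ids,
                                  interactions$disease_ids))
}

#' Sparsity of an interaction matrix
#'
#' `1 - (number of known pairs) / (n_drugs * n_diseases)`.
#'
#' @param interactions a [interaction_matrix()].
#' @return scalar in \[0, 1\].
#' @export
sparsity <- function(interactions) {
  1 - sum(interactions$values) / length(interactions$values)
}

#' Write a complete synthetic input set to disk
#'
#' Emits the similarity stacks, the interaction matrix and the knowledge
#' graph in the plain-text formats the pipeline readers consume.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list of written paths.
#' @export
write_fixture <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  interactions <- make_interactions(spec)
  paths <- list(interactions = file.path(out_dir, "interactions.tsv"),
                kg = file.path(out_dir, "kg_triples.tsv"),
                drug_sims = character(0), disease_sims = character(0))
  write_interactions_tsv(interactions, paths$interactions)
  write_triples(make_kg(spec, interactions), paths$kg)
  for (side in c("drugs", "diseases")) {
    stack <- make_similarity_stack(spec, side)
    for (i in seq_along(stack)) {
      p <- file.path(out_dir, sprintf("sim_%s_%02d.tsv", side, i))
      write_similarity_tsv(stack[[i]], p)
      key <- if (side == "drugs") "drug_sims" else "disease_sims"
      paths[[key]] <- c(paths[[key]], p)
    }
  }
  invisible(paths)
}
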