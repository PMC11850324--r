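# Knowledge-graph handling and ComplEx embeddings.
#
# Triples are (head, relation, tail) identifier strings in the style of the
# public drug-repurposing knowledge graphs; the drug-disease relation is one
# named relation type among many.

#' Construct a triple store
#'
#' @param triples data.frame (or 3-column matrix) with columns head,
#'   relation, tail.  Duplicates are removed and entity/relation indices are
#'   assigned in sorted order so the store is independent of input ordering.
#' @param extra_entities entities to index even when no triple mentions
#'   them (isolated benchmark entities still need embeddings).
#' @return object of class `kgrdr_triples` with fields `triples`
#'   (data.frame head/relation/tail), `entity_index`, `relation_index`
#'   (named integer maps).
#' @export
triple_store <- function(triples, extra_entities = character(0)) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  if (ncol(triples) != 3) stop_invalid("triples must have 3 columns")
  names(triples) <- c("head", "relation", "tail")
  triples[] <- lapply(triples, as.character)
  triples <- unique(triples)
  triples <- triples[order(triples$head, triples$relation, triples$tail), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  entities <- sort(unique(c(triples$head, triples$tail, extra_entities)))
  relations <- sort(unique(triples$relation))
  structure(list(
    triples = triples,
    entity_index = stats::setNames(seq_along(entities), entities),
    relation_index = stats::setNames(seq_along(relations), relations)
  ), class = "kgrdr_triples")
}

#' @export
print.kgrdr_triples <- function(x, ...) {
  cat(sprintf("<kgrdr_triples: %d triples, %d entities, %d relations>\n",
              nrow(x$triples), length(x$entity_index),
              length(x$relation_index)))
  invisible(x)
}

#' Read knowledge-graph triples from a 3-column TSV
#'
#' @param path file path; each line `head<TAB>relation<TAB>tail`.
#' @return a [triple_store()]; duplicate lines collapse to one triple.
#' @export
read_triples <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(triple_store(data.frame(head = character(0),
                                   relation = character(0),
                                   tail = character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop_invalid("malformed triple at line %d of %s: expected 3 columns, got %d",
                 bad[1], path, length(parts[[bad[1]]]))
  }
  m <- do.call(rbind, parts)
  triple_store(data.frame(head = m[, 1], relation = m[, 2], tail = m[, 3]))
}

#' Write a triple store as 3-column TSV
#' @param store a [triple_store()].
#' @param path output path.
#' @export
write_triples <- function(store, path) {
  utils::write.table(store$triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Align the knowledge graph's drug-disease edges with a benchmark
#'
#' Removes every `dd_relation` triple not present in the benchmark
#' interaction matrix, adds a `dd_relation` triple for every known
#' interaction, and leaves all other relations untouched.  Interaction
#' entities missing from the graph are added to the entity index (count
#' logged).
#'
#' @param kg a [triple_store()].
#' @param interactions a [interaction_matrix()].
#' @param dd_relation name of the drug-disease relation type.
#' @return a new [triple_store()].
#' @export
align_benchmark <- function(kg, interactions, dd_relation = "Compound:Disease") {
  tr <- kg$triples
  is_dd <- tr$relation == dd_relation
  pos <- which(interactions$values == 1, arr.ind = TRUE)
  dd_new <- data.frame(
    head = interactions$drug_ids[pos[, 1]],
    relation = rep(dd_relation, nrow(pos)),
    tail = interactions$disease_ids[pos[, 2]],
    stringsAsFactors = FALSE
  )
  known_entities <- names(kg$entity_index)
  bench <- c(interactions$drug_ids, interactions$disease_ids)
  added <- setdiff(bench, known_entities)
  if (length(added)) {
    message(sprintf("align_benchmark: %d benchmark entit(ies) added to the graph",
                    length(added)))
  }
  triple_store(rbind(tr[!is_dd, , drop = FALSE], dd_new),
               extra_entities = bench)
}

#' Construct a ComplEx embedding table
#'
#' Complex-valued entity and relation embeddings stored as four real
#' matrices.
#'
#' @param store a [triple_store()].
#' @param k embedding dimension.
#' @param reg_lambda L2 weight-decay coefficient.
#' @param seed initialization seed (entries `N(0, 0.01)`).
#' @return object of class `kgrdr_complex` with fields `entity_real`,
#'   `entity_imag`, `relation_real`, `relation_imag`, `k`, `reg_lambda`,
#'   `entity_index`, `relation_index`.
#' @export
complex_embedding <- function(store, k, reg_lambda = 1e-7, seed = 1) {
  ne <- length(store$entity_index)
  nr <- length(store$relation_index)
  with_seed(seed, {
    mk <- function(n) matrix(stats::rnorm(n * k, sd = 0.1), n, k)
    structure(list(entity_real = mk(ne), entity_imag = mk(ne),
                   relation_real = mk(nr), relation_imag = mk(nr),
                   k = k, reg_lambda = reg_lambda,
                   entity_index = store$entity_index,
                   relation_index = store$relation_index),
              class = "kgrdr_complex")
  })
}

#' ComplEx score of one or more triples
#'
#' Trilinear real part of `<w_r, e_s, conj(e_o)>`:
#' `<Re w, Re s, Re o> + <Re w, Im s, Im o> + <Im w, Re s, Im o>
#'  - <Im w, Im s, Re o>`, each term summed over the k dimensions.
#'
#' @param idx integer matrix (or length-3 vector) with columns `s`, `r`, `o`
#'   giving entity/relation/entity indices.
#' @param emb a [complex_embedding()] table.
#' @return numeric score vector.
#' @export
score_triple <- function(idx, emb) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  s <- idx[, 1]; r <- idx[, 2]; o <- idx[, 3]
  sr <- emb$entity_real[s, , drop = FALSE]
  si <- emb$entity_imag[s, , drop = FALSE]
  or_ <- emb$entity_real[o, , drop = FALSE]
  oi <- emb$entity_imag[o, , drop = FALSE]
  rr <- emb$relation_real[r, , drop = FALSE]
  ri <- emb$relation_imag[r, , drop = FALSE]
  rowSums(rr * sr * or_ + rr * si * oi + ri * sr * oi - ri * si * or_)
}

#' Probability that a triple holds
#'
#' Logistic inverse link of the ComplEx score.
#'
#' @param score numeric score(s).
#' @return probabilities in (0, 1).
#' @export
triple_probability <- function(score) sigmoid(score)

# canonical key used both for the positive-set membership test and for the
# content-derived negative-sampling seed
triple_key <- function(s, r, o) paste(s, r, o, sep = "\r")

#' Sample corrupted (negative) triples for one positive triple
#'
#' Each draw flips a fair coin to corrupt head or tail with a uniformly
#' random entity, resampling while the corruption reproduces a known
#' positive (or the original triple).  With `typed = TRUE` corruption is
#' type-constrained: replacement entities are drawn from the entities
#' observed as heads (resp. tails) of the same relation.  The effective seed
#' combines `seed` with a hash of the triple content, so dataset ordering
#' cannot alter the samples.
#'
#' @param triple length-3 integer vector `(s, r, o)` of indices.
#' @param store a [triple_store()] supplying the positive set.
#' @param n_neg number of corruptions.
#' @param seed base seed.
#' @param typed corrupt within the relation's observed head/tail entity
#'   sets or over all entities (default).
#' @return `n_neg` x 3 integer matrix of corrupted `(s, r, o)`.
#' @export
sample_negatives <- function(triple, store, n_neg, seed = 1, typed = FALSE) {
  ne <- length(store$entity_index)
  if (ne < 2) stop_invalid("cannot corrupt triples in a 1-entity store")
  if (n_neg < 1) stop_invalid("n_neg must be >= 1")
  pos_keys <- with(store$triples, triple_key(
    store$entity_index[head], store$relation_index[relation],
    store$entity_index[tail]))
  pos_set <- new.env(hash = TRUE, parent = emptyenv())
  for (kk in pos_keys) assign(kk, TRUE, envir = pos_set)
  dom <- relation_domains(store)
  heads <- if (typed) dom$heads[[triple[2]]] else seq_len(ne)
  tails <- if (typed) dom$tails[[triple[2]]] else seq_len(ne)
  if (length(heads) < 2 && length(tails) < 2) {
    heads <- tails <- seq_len(ne)
  }
  tseed <- (seed + string_hash31(triple_key(triple[1], triple[2], triple[3]))) %%
    2147483647
  with_seed(tseed, {
    out <- matrix(rep(triple, each = n_neg), n_neg, 3)
    for (i in seq_len(n_neg)) {
      repeat {
        cand <- triple
        slot <- if (stats::runif(1) < 0.5) 1L else 3L
        pool <- if (slot == 1L) heads else tails
        cand[slot] <- pool[sample.int(length(pool), 1L)]
        key <- triple_key(cand[1], cand[2], cand[3])
        if (!identical(cand, triple) &&
            !exists(key, envir = pos_set, inherits = FALSE)) {
          out[i, ] <- cand
          break
        }
      }
    }
    out
  })
}

# observed head/tail entity pools per relation index
relation_domains <- function(store) {
  idx <- indexed_triples(store)
  nr <- length(store$relation_index)
  list(heads = lapply(seq_len(nr), function(r) sort(unique(idx[idx[, 2] == r, 1]))),
       tails = lapply(seq_len(nr), function(r) sort(unique(idx[idx[, 2] == r, 3]))))
}

# indexed triple matrix for a store
indexed_triples <- function(store) {
  cbind(s = unname(store$entity_index[store$triples$head]),
        r = unname(store$relation_index[store$triples$relation]),
        o = unname(store$entity_index[store$triples$tail]))
}

complex_l2 <- function(emb) {
  sum(emb$entity_real^2) + sum(emb$entity_imag^2) +
    sum(emb$relation_real^2) + sum(emb$relation_imag^2)
}

#' Fit ComplEx embeddings by logistic loss with negative sampling
#'
#' Minimizes `sum log(1 + exp(-Y * phi))` over positive (`Y = +1`) and
#' sampled corrupted (`Y = -1`) triples plus an L2 penalty
#' `reg_lambda * ||Theta||^2`, by mini-batch gradient descent.  Positives
#' are visited in canonical store order and negative-sampling seeds derive
#' from triple content, so results do not depend on input file ordering.
#'
#' Parameters are updated with AdaGrad (the optimizer the original ComplEx
#' training scheme uses), which keeps the stated learning rate stable where
#' plain SGD diverges.
#'
#' @param store a [triple_store()].
#' @param k embedding dimension.
#' @param lr AdaGrad learning rate.
#' @param reg_lambda L2 coefficient.
#' @param epochs maximum epochs; early stop when the relative loss change
#'   stays below `1e-5` over 10 epochs.
#' @param n_neg negatives per positive.
#' @param batch_size mini-batch size.
#' @param seed RNG seed (initialization and sampling).
#' @param typed type-constrained corruption (see [sample_negatives()]);
#'   uniform corruption by default.
#' @param reg_type `"l2"` (weight decay, the published penalty) or `"n3"`
#'   (cubed-magnitude penalty on the embeddings touched by each batch, the
#'   regularizer modern ComplEx training favours for generalization).
#' @return a [complex_embedding()] with an added `loss_trace` data.frame
#'   (`loss`, `logistic`, `l2` per epoch).
#' @export
fit_complex <- function(store, k = 16, lr = 0.1, reg_lambda = 1e-7,
                        epochs = 200, n_neg = 2, batch_size = 512, seed = 1,
                        typed = FALSE, reg_type = c("l2", "n3")) {
  reg_type <- match.arg(reg_type)
  if (nrow(store$triples) == 0) stop_invalid("cannot train on an empty store")
  if (k < 1) stop_invalid("k must be >= 1")
  emb <- complex_embedding(store, k, reg_lambda, seed)
  pos <- indexed_triples(store)
  npos <- nrow(pos)
  # pre-sample negatives once per positive (content-seeded, epoch-reseeded
  # would be costlier; resampling each epoch uses epoch-shifted seeds)
  loss_trace <- data.frame(loss = numeric(0), logistic = numeric(0),
                           l2 = numeric(0))
  ne <- length(store$entity_index)
  pos_keys <- triple_key(pos[, 1], pos[, 2], pos[, 3])

  dom <- if (typed) relation_domains(store) else NULL
  pick_pool <- function(r, slot) {
    if (!typed) return(seq_len(ne))
    pool <- if (slot == 1L) dom$heads[[r]] else dom$tails[[r]]
    if (length(pool) < 2) seq_len(ne) else pool
  }
  sample_neg_block <- function(epoch) {
    # corruption pools are all entities, or the relation's observed
    # head/tail pools when typed; one RNG stream per epoch
    with_seed((seed + epoch * 10007) %% 2147483647, {
      idx <- pos[rep(seq_len(npos), each = n_neg), , drop = FALSE]
      orig <- idx
      slot <- ifelse(stats::runif(nrow(idx)) < 0.5, 1L, 3L)
      for (r in unique(idx[, 2])) {
        for (sl in c(1L, 3L)) {
          rows <- which(idx[, 2] == r & slot == sl)
          if (!length(rows)) next
          pool <- pick_pool(r, sl)
          idx[cbind(rows, sl)] <- pool[sample.int(length(pool), length(rows),
                                                  replace = TRUE)]
        }
      }
      clash <- triple_key(idx[, 1], idx[, 2], idx[, 3]) %in% pos_keys
      for (i in which(clash)) {
        repeat {
          c2 <- orig[i, ]
          sl <- if (stats::runif(1) < 0.5) 1L else 3L
          pool <- pick_pool(c2[2], sl)
          c2[sl] <- pool[sample.int(length(pool), 1L)]
          if (!(triple_key(c2[1], c2[2], c2[3]) %in% pos_keys)) {
            idx[i, ] <- c2
            break
          }
        }
      }
      idx
    })
  }

  ada <- list(entity_real = emb$entity_real * 0,
              entity_imag = emb$entity_imag * 0,
              relation_real = emb$relation_real * 0,
              relation_imag = emb$relation_imag * 0)
  prev_losses <- rep(NA_real_, 10)
  for (epoch in seq_len(epochs)) {
    neg <- sample_neg_block(epoch)
    allt <- rbind(pos, neg)
    y <- c(rep(1, npos), rep(-1, nrow(neg)))
    nb <- ceiling(nrow(allt) / batch_size)
    epoch_logistic <- 0
    for (b in seq_len(nb)) {
      rows <- ((b - 1) * batch_size + 1):min(b * batch_size, nrow(allt))
      tb <- allt[rows, , drop = FALSE]
      yb <- y[rows]
      s <- tb[, 1]; r <- tb[, 2]; o <- tb[, 3]
      sr <- emb$entity_real[s, , drop = FALSE]
      si <- emb$entity_imag[s, , drop = FALSE]
      or_ <- emb$entity_real[o, , drop = FALSE]
      oi <- emb$entity_imag[o, , drop = FALSE]
      rr <- emb$relation_real[r, , drop = FALSE]
      ri <- emb$relation_imag[r, , drop = FALSE]
      phi <- rowSums(rr * sr * or_ + rr * si * oi + ri * sr * oi - ri * si * or_)
      if (any(!is.finite(phi))) {
        stop_invalid("fit_complex diverged (non-finite score); reduce lr=%g", lr)
      }
      epoch_logistic <- epoch_logistic + sum(log1p(exp(pmin(-yb * phi, 700))))
      g <- -yb * sigmoid(-yb * phi)          # d loss / d phi
      g_sr <- g * (rr * or_ + ri * oi)
      g_si <- g * (rr * oi - ri * or_)
      g_or <- g * (rr * sr - ri * si)
      g_oi <- g * (rr * si + ri * sr)
      g_rr <- g * (sr * or_ + si * oi)
      g_ri <- g * (sr * oi - si * or_)
      acc <- function(slot, idx, G) {
        u <- rowsum(G, group = idx)
        ui <- as.integer(rownames(u))
        M <- emb[[slot]]
        Mi <- M[ui, , drop = FALSE]
        reg_grad <- if (reg_type == "l2") 2 * reg_lambda * Mi else
          3 * reg_lambda * sign(Mi) * Mi^2
        g <- u + reg_grad
        ada[[slot]][ui, ] <<- ada[[slot]][ui, , drop = FALSE] + g^2
        M[ui, ] <- M[ui, ] - lr * g / (sqrt(ada[[slot]][ui, , drop = FALSE]) + 1e-8)
        emb[[slot]] <<- M
      }
      acc("entity_real", c(s, o), rbind(g_sr, g_or))
      acc("entity_imag", c(s, o), rbind(g_si, g_oi))
      acc("relation_real", r, g_rr)
      acc("relation_imag", r, g_ri)
    }
    l2 <- if (reg_type == "l2") reg_lambda * complex_l2(emb) else
      reg_lambda * (sum(abs(emb$entity_real)^3) + sum(abs(emb$entity_imag)^3) +
                    sum(abs(emb$relation_real)^3) + sum(abs(emb$relation_imag)^3))
    tot <- epoch_logistic + l2
    if (!is.finite(tot)) {
      stop_invalid("fit_complex diverged (loss is not finite); reduce lr=%g", lr)
    }
    loss_trace <- rbind(loss_trace,
                        data.frame(loss = tot, logistic = epoch_logistic,
                                   l2 = l2))
    prev_losses <- c(prev_losses[-1], tot)
    if (epoch > 10 && all(is.finite(prev_losses))) {
      rel <- abs(diff(prev_losses)) / pmax(abs(prev_losses[-1]), 1e-12)
      if (all(rel < 1e-5)) break
    }
  }
  emb$loss_trace <- loss_trace
  emb
}

#' Extract real-valued topological features from a ComplEx table
#'
#' One row per requested entity: concatenation of the real and imaginary
#' embedding parts, width `2k`, in the order of `entity_ids`.
#'
#' @param emb a [complex_embedding()] (typically from [fit_complex()]).
#' @param entity_ids character vector of entity identifiers.
#' @return numeric matrix `length(entity_ids)` x `2k` with rownames.
#' @export
extract_features <- function(emb, entity_ids) {
  missing <- setdiff(entity_ids, names(emb$entity_index))
  if (length(missing)) {
    stop_invalid("unknown entit(ies): %s", paste(missing, collapse = ", "))
  }
  idx <- emb$entity_index[entity_ids]
  Y <- cbind(emb$entity_real[idx, , drop = FALSE],
             emb$entity_imag[idx, , drop = FALSE])
  rownames(Y) <- entity_ids
  colnames(Y) <- c(paste0("re", seq_len(emb$k)), paste0("im", seq_len(emb$k)))
  Y
}
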