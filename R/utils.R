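#' @keywords internal
"_PACKAGE"

# ---- small numeric helpers -------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax with max subtraction
#'
#' Numerically safe row-wise softmax: each row of the result sums to one.
#'
#' @param Z numeric matrix of logits.
#' @return row-stochastic matrix of the same shape.
#' @keywords internal
row_softmax <- function(Z) {
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  Keeps every stochastic operation in the
# package deterministic and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Deterministic 31-bit string hash (djb2 variant); used to derive per-triple
# sampling seeds so that dataset ordering cannot change results.
string_hash31 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_square_symmetric <- function(M, tol = 1e-8, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop_invalid("%s must be a square matrix", what)
  }
  if (max(abs(M - t(M))) > tol) {
    stop_invalid("%s must be symmetric within %g", what, tol)
  }
  invisible(TRUE)
}

# ---- domain containers -----------------------------------------------------

#' Construct a similarity matrix object
#'
#' A `kgrdr_similarity` wraps a square symmetric matrix of pairwise
#' similarities in \[0, 1\] over a single entity set, together with the
#' entity identifiers and a label naming the originating similarity view.
#'
#' @param values square numeric matrix, entries in \[0, 1\], symmetric
#'   within `1e-8`.
#' @param ids character vector of entity identifiers (defaults to the
#'   rownames of `values`).
#' @param source_name label of the similarity view.
#' @return an object of class `kgrdr_similarity` with fields `values`,
#'   `ids`, `source_name`.
#' @export
similarity_matrix <- function(values, ids = rownames(values),
                              source_name = "similarity") {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) {
    stop_invalid("length(ids) must equal nrow(values)")
  }
  check_square_symmetric(values, what = sprintf("similarity '%s'", source_name))
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stop_invalid("similarity entries must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, source_name = source_name),
            class = "kgrdr_similarity")
}

#' @export
print.kgrdr_similarity <- function(x, ...) {
  cat(sprintf("<kgrdr_similarity '%s': %d entities>\n",
              x$source_name, length(x$ids)))
  invisible(x)
}

#' Construct a binary drug-disease interaction matrix
#'
#' @param values binary numeric matrix (drugs in rows, diseases in columns).
#' @param drug_ids,disease_ids identifier vectors; default to dimnames.
#' @return an object of class `kgrdr_interactions`.
#' @export
interaction_matrix <- function(values, drug_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(disease_ids)) disease_ids <- paste0("disease", seq_len(ncol(values)))
  drug_ids <- as.character(drug_ids)
  disease_ids <- as.character(disease_ids)
  if (length(drug_ids) != nrow(values) || length(disease_ids) != ncol(values)) {
    stop_invalid("id lengths must match interaction matrix dimensions")
  }
  if (!all(values %in% c(0, 1))) {
    stop_invalid("interaction entries must be 0 or 1")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(drug_ids, disease_ids)
  structure(list(values = values, drug_ids = drug_ids,
                 disease_ids = disease_ids),
            class = "kgrdr_interactions")
}

#' @export
print.kgrdr_interactions <- function(x, ...) {
  cat(sprintf("<kgrdr_interactions: %d drugs x %d diseases, %d known pairs>\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

# ---- plain-text readers/writers -------------------------------------------

#' Read a dense similarity matrix from TSV
#'
#' First row and first column carry entity identifiers; cells are decimals
#' in \[0, 1\].
#'
#' @param path file path.
#' @param source_name view label (defaults to the file name).
#' @return a [similarity_matrix()] object.
#' @export
read_similarity_tsv <- function(path, source_name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  similarity_matrix(as.matrix(df), ids = rownames(df),
                    source_name = source_name)
}

#' Write a similarity matrix as dense TSV
#' @param sim a [similarity_matrix()] object.
#' @param path output path.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(id = sim$ids, sim$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-disease interaction table
#'
#' Auto-detects the format by column count: two columns are treated as an
#' edge list (`drug_id<TAB>disease_id`), more as a dense 0/1 matrix with a
#' header row and an identifier column.
#'
#' @param path file path.
#' @param drug_ids,disease_ids optional full universes for the edge-list
#'   form (ids never seen in the file would otherwise be dropped).
#' @return a [interaction_matrix()] object.
#' @export
read_interactions_tsv <- function(path, drug_ids = NULL, disease_ids = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(first) == 2L) {
    el <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("drug", "disease"),
                            colClasses = "character")
    if (is.null(drug_ids)) drug_ids <- sort(unique(el$drug))
    if (is.null(disease_ids)) disease_ids <- sort(unique(el$disease))
    A <- matrix(0, length(drug_ids), length(disease_ids),
                dimnames = list(drug_ids, disease_ids))
    A[cbind(el$drug, el$disease)] <- 1
    interaction_matrix(A)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
    interaction_matrix(as.matrix(df))
  }
}

#' Write an interaction matrix as dense 0/1 TSV
#' @param interactions a [interaction_matrix()] object.
#' @param path output path.
#' @export
write_interactions_tsv <- function(interactions, path) {
  df <- data.frame(id = interactions$drug_ids, interactions$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix (entity id + numeric columns) as dense TSV
#' @param X numeric matrix with rownames.
#' @param path output path.
#' @export
write_features_tsv <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_tsv()]
#' @param path file path.
#' @return numeric matrix with entity rownames.
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
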