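# Similarity-constrained Monte-Carlo train/test splits.
#
# A split must keep every test protein below a percent-identity threshold
# (default 20%) against every train protein. Construction is greedy: proteins
# are visited in seeded random order; a protein joins the test pool while the
# pool is below its 10% target and the protein is compatible with all current
# train proteins, otherwise it joins train if compatible with all current
# test proteins, otherwise it is removed — mirroring the removal of
# irreconcilable proteins from the corpus.

#' Build one similarity-constrained train/test split
#'
#' @param proteins Character vector of unique protein sequences, or an
#'   `smi_curated` object (its unique proteins are used).
#' @param threshold_pct Maximum allowed percent identity (exclusive) between
#'   any test and any train protein. Default 20.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param test_fraction Target test share, default 0.1.
#' @param id_matrix Optional precomputed [identity_matrix()] (avoids
#'   realigning when building several splits). Must match `proteins` order.
#' @param params Alignment parameters, used when `id_matrix` is missing.
#' @param replicate_index Bookkeeping index stored in the result.
#' @return List of class `smi_split`: `train`, `test`, `removed` (character
#'   vectors of sequences), `threshold_pct`, `replicate_index`, `seed`.
#' @export
build_split <- function(proteins, threshold_pct = 20, seed = 1L,
                        test_fraction = 0.1, id_matrix = NULL,
                        params = alignment_params(), replicate_index = 1L) {
  if (inherits(proteins, "smi_curated")) proteins <- proteins$unique_proteins
  proteins <- unique(as.character(proteins))
  n <- length(proteins)
  if (n < 2) abort("build_split: need at least 2 unique proteins.")
  if (is.null(id_matrix)) id_matrix <- identity_matrix(proteins, params)
  stopifnot(nrow(id_matrix) == n, ncol(id_matrix) == n)

  n_test_target <- max(1L, round(test_fraction * n))
  order_idx <- withr::with_seed(seed, sample.int(n))

  test <- integer(0); train <- integer(0); removed <- integer(0)
  for (k in order_idx) {
    ok_vs_train <- length(train) == 0 || max(id_matrix[k, train]) < threshold_pct
    ok_vs_test <- length(test) == 0 || max(id_matrix[k, test]) < threshold_pct
    if (length(test) < n_test_target && ok_vs_train) {
      test <- c(test, k)
    } else if (ok_vs_test) {
      train <- c(train, k)
    } else {
      removed <- c(removed, k)
    }
  }
  if (length(test) == 0 || length(train) == 0) {
    abort(sprintf(
      "build_split: no feasible split at threshold %s%% (test %d, train %d).",
      threshold_pct, length(test), length(train)))
  }
  structure(list(train = proteins[sort(train)], test = proteins[sort(test)],
                 removed = proteins[sort(removed)],
                 threshold_pct = threshold_pct,
                 replicate_index = as.integer(replicate_index),
                 seed = as.integer(seed)),
            class = "smi_split")
}

#' @export
print.smi_split <- function(x, ...) {
  cat(sprintf(
    "Protein split (replicate %d, threshold %s%%): %d train / %d test / %d removed\n",
    x$replicate_index, x$threshold_pct, length(x$train), length(x$test),
    length(x$removed)))
  invisible(x)
}

#' Repeated Monte-Carlo splits
#'
#' Builds `n_replicates` independent similarity-constrained splits, each with
#' its own derived seed, for Monte-Carlo cross-validation (train and evaluate
#' once per replicate).
#'
#' @inheritParams build_split
#' @param n_replicates Number of splits (the standard protocol uses 5).
#' @return List of `smi_split` objects with replicate_index 1..n_replicates.
#' @export
monte_carlo_splits <- function(proteins, n_replicates = 5, threshold_pct = 20,
                               seed = 1L, test_fraction = 0.1,
                               id_matrix = NULL, params = alignment_params()) {
  stopifnot(n_replicates >= 1)
  if (inherits(proteins, "smi_curated")) proteins <- proteins$unique_proteins
  proteins <- unique(as.character(proteins))
  if (is.null(id_matrix)) id_matrix <- identity_matrix(proteins, params)
  purrr::map(seq_len(n_replicates), function(r) {
    build_split(proteins, threshold_pct = threshold_pct,
                seed = as.integer(seed) + r - 1L,
                test_fraction = test_fraction, id_matrix = id_matrix,
                replicate_index = r)
  })
}

#' Verify a split by exhaustive realignment
#'
#' Recomputes every test-by-train percent identity from scratch and checks
#' the constraint, independently of whatever matrix the split was built from.
#'
#' @param split An `smi_split`.
#' @param params Alignment parameters.
#' @return `TRUE` invisibly if the split is valid; otherwise an error listing
#'   the first violating pair. The maximum cross identity found is attached
#'   as attribute `"max_cross_identity"`.
#' @export
verify_split <- function(split, params = alignment_params()) {
  stopifnot(inherits(split, "smi_split"))
  worst <- -Inf
  for (te in split$test) {
    for (tr in split$train) {
      v <- as.numeric(pairwise_identity(te, tr, params))
      worst <- max(worst, v)
      if (v >= split$threshold_pct) {
        abort(sprintf(
          "Split violates constraint: identity %.2f%% >= %s%% for a test/train pair.",
          v, split$threshold_pct))
      }
    }
  }
  structure(invisible(TRUE), max_cross_identity = worst)
}

#' Write / read split manifests as JSON
#'
#' @param split An `smi_split` (or list of them for `write_splits_json`).
#' @param path File path.
#' @name split_json
#' @export
write_split_json <- function(split, path) {
  stopifnot(inherits(split, "smi_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname split_json
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("train", "test", "removed")) x[[f]] <- as.character(x[[f]] %||% character(0))
  structure(x, class = "smi_split")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
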