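# Rank-based analysis of docking-score sets: ROC/AUC by pair counting, the
# Mann-Whitney U test, the identity AUC = U / (n1 * n2), and the AUC-based
# structure-discrimination filter.
#
# Orientation: docking scores are binding free-energy estimates where more
# negative means stronger predicted binding, so by default the positive class
# is ranked by -score. Ties receive midranks (equivalently, tied pairs count
# one half).

rank_u_statistic <- function(pos, neg) {
  # U for "positive outranks negative", midrank tie handling.
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))  # midranks
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

check_scores <- function(x, arg) {
  if (length(x) == 0) abort(sprintf("%s: empty score set.", arg))
  if (!all(is.finite(x))) abort(sprintf("%s: non-finite score.", arg))
  invisible(x)
}

#' ROC curve and AUC for two score sets
#'
#' Computes the area under the empirical ROC curve by pair counting (ties
#' worth one half), which satisfies AUC = U / (n1 * n2) with the
#' Mann-Whitney U statistic, together with the ROC curve points themselves.
#'
#' @param positives,negatives Numeric score vectors (e.g. docking scores of
#'   known binders and of random compounds).
#' @param orientation `"lower_is_positive"` (default; docking scores, lower =
#'   stronger binding) or `"higher_is_positive"`.
#' @return List of class `smi_roc`: `n1`, `n2`, `U`, `auc`, `p_value`
#'   (two-sided Mann-Whitney), and `curve` (tibble fpr, tpr).
#' @export
roc_auc <- function(positives, negatives,
                    orientation = c("lower_is_positive", "higher_is_positive")) {
  orientation <- match.arg(orientation)
  check_scores(positives, "positives"); check_scores(negatives, "negatives")
  pos <- if (orientation == "lower_is_positive") -positives else positives
  neg <- if (orientation == "lower_is_positive") -negatives else negatives
  n1 <- length(pos); n2 <- length(neg)
  U <- rank_u_statistic(pos, neg)
  mw <- mann_whitney(positives, negatives, orientation = orientation)

  # empirical ROC: sweep thresholds over unique scores, descending
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  curve <- tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(n1 = n1, n2 = n2, U = U, auc = U / (n1 * n2),
                 p_value = mw$p_value, orientation = orientation,
                 curve = curve),
            class = "smi_roc")
}

#' @export
print.smi_roc <- function(x, ...) {
  cat(sprintf("ROC: n1 = %d, n2 = %d, U = %.1f, AUC = %.4f, p = %.3g\n",
              x$n1, x$n2, x$U, x$auc, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U by rank sum with midranks for ties. The p-value uses exact enumeration
#' of the tie-free U distribution when `n1 * n2 <= 400` and no ties are
#' present, and otherwise the normal approximation with tie-corrected
#' variance and continuity correction. `U_a + U_b = n1 * n2` always holds.
#'
#' @param a,b Numeric score vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param orientation As in [roc_auc()]; `"higher_is_positive"` tests the
#'   raw values. With `"lower_is_positive"`, scores are negated first so
#'   that "greater" means "a is the stronger-binding group".
#' @return List with `U`, `n1`, `n2`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         orientation = c("higher_is_positive",
                                         "lower_is_positive")) {
  alternative <- match.arg(alternative)
  orientation <- match.arg(orientation)
  check_scores(a, "a"); check_scores(b, "b")
  if (orientation == "lower_is_positive") { a <- -a; b <- -b }
  n1 <- length(a); n2 <- length(b)
  U <- rank_u_statistic(a, b)
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)

  if (length(unique(c(a, b))) == 1) {
    warn("mann_whitney: all values tied across both sets; p = 1.")
    return(list(U = U, n1 = n1, n2 = n2, p_value = 1, method = "degenerate"))
  }

  if (!has_ties && n1 * n2 <= 400) {
    p <- switch(alternative,
      two.sided = {
        lo <- stats::pwilcox(U, n1, n2)
        hi <- 1 - stats::pwilcox(U - 1, n1, n2)
        min(1, 2 * min(lo, hi))
      },
      greater = 1 - stats::pwilcox(U - 1, n1, n2),
      less = stats::pwilcox(U, n1, n2))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    z <- U - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, max(p, 1e-300))  # keep p in (0, 1] under extreme separation
    method <- "normal_approx"
  }
  list(U = U, n1 = n1, n2 = n2, p_value = p, method = method)
}

#' Filter structures by discrimination AUC
#'
#' Drops structures whose binders-versus-random AUC falls below the
#' threshold — i.e. structures for which docking fails to discriminate known
#' actives from randomly selected compounds (the conventional cutoff is
#' AUC < 0.6).
#'
#' @param comparisons Data frame with columns `structure_id` and `auc` (or a
#'   named numeric vector of AUCs).
#' @param threshold AUC threshold in (0.5, 1]; structures with
#'   `auc < threshold` are dropped.
#' @return Tibble with columns `structure_id`, `auc`, `retained`.
#' @export
discriminability_filter <- function(comparisons, threshold = 0.6) {
  if (!(threshold > 0.5 && threshold <= 1)) {
    abort("discriminability_filter: threshold must lie in (0.5, 1].")
  }
  if (!is.data.frame(comparisons)) {
    comparisons <- tibble(structure_id = names(comparisons),
                          auc = as.numeric(comparisons))
  }
  mutate(as_tibble(comparisons), retained = .data$auc >= threshold)
}

standard_contrasts <- function() {
  tibble(contrast = c("binders_vs_random", "binders_vs_generated_for_others",
                      "generated_vs_random", "generated_vs_binders"),
         group_a = c("known_binders", "known_binders", "generated_for_target",
                     "generated_for_target"),
         group_b = c("random", "generated_for_others", "random",
                     "known_binders"))
}

#' Pairwise score-set comparison report
#'
#' Runs [roc_auc()] for the four standard contrasts (known binders vs random
#' compounds; binders vs molecules generated for other targets; molecules
#' generated for this target vs random; generated vs binders) over a long
#' table of labeled docking scores; contrasts whose labels are absent are
#' skipped with a warning.
#'
#' @param scores Data frame with columns `group` and `score` (and optionally
#'   `ligand_id`).
#' @param contrasts Tibble with columns `contrast`, `group_a`, `group_b`;
#'   defaults to the four standard contrasts over labels `known_binders`,
#'   `random`, `generated_for_target`, `generated_for_others`.
#' @param orientation As in [roc_auc()].
#' @return Tibble of class `smi_group_report`: contrast, n1, n2, U, auc,
#'   p_value; the `smi_roc` objects are attached as attribute `"roc"`.
#' @export
group_report <- function(scores, contrasts = standard_contrasts(),
                         orientation = "lower_is_positive") {
  stopifnot(all(c("group", "score") %in% names(scores)))
  if (length(unique(scores$group)) < 2) {
    abort("group_report: need at least two labeled score sets.")
  }
  rocs <- list()
  rows <- purrr::pmap_dfr(contrasts, function(contrast, group_a, group_b) {
    a <- scores$score[scores$group == group_a]
    b <- scores$score[scores$group == group_b]
    if (length(a) == 0 || length(b) == 0) {
      warn(sprintf("group_report: label '%s' or '%s' absent; contrast '%s' skipped.",
                   group_a, group_b, contrast))
      return(NULL)
    }
    r <- roc_auc(a, b, orientation = orientation)
    rocs[[contrast]] <<- r
    tibble(contrast = contrast, n1 = r$n1, n2 = r$n2, U = r$U, auc = r$auc,
           p_value = r$p_value)
  })
  structure(rows, roc = rocs, class = c("smi_group_report", class(rows)))
}

#' Parse docking scores from SMINA stdout logs
#'
#' Extracts the best (mode 1) affinity from each "Affinity (kcal/mol)" result
#' table in a captured SMINA log. Ligand names are taken from lines of the
#' form `Refine ligand: <name>` or `## Name <name>` when present, else
#' numbered in order.
#'
#' @param path Path to the log file (or a character vector of lines).
#' @return Tibble with columns `ligand_id` and `score`.
#' @export
parse_smina_scores <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  header <- grep("^mode \\|", lines)
  if (length(header) == 0) abort("parse_smina_scores: no SMINA result table found.")
  names_at <- grep("^(Refine ligand:|## Name)", lines)
  ligand_for <- function(h) {
    prior <- names_at[names_at < h]
    if (length(prior) == 0) return(NA_character_)
    sub("^(Refine ligand:|## Name)\\s*", "", lines[max(prior)])
  }
  out <- purrr::map_dfr(seq_along(header), function(k) {
    h <- header[k]
    # first data row: "   1     -7.4   0.000   0.000"
    row <- lines[(h + 1):min(h + 10, length(lines))]
    row <- row[grepl("^\\s*1\\s+-?[0-9.]+", row)][1]
    if (is.na(row)) return(NULL)
    score <- as.numeric(strsplit(trimws(row), "\\s+")[[1]][2])
    id <- ligand_for(h)
    tibble(ligand_id = ifelse(is.na(id), sprintf("ligand_%d", k), id),
           score = score)
  })
  out
}

#' Read a scores TSV (ligand_id, group, score)
#'
#' @param path File path.
#' @return Tibble with `ligand_id` (character), `group` (character),
#'   `score` (numeric).
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "score") %in% names(df)))
  as_tibble(df) |>
    mutate(score = as.numeric(.data$score))
}
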