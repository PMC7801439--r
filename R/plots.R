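# ggplot2 views of the package's result objects.

#' @importFrom ggplot2 ggplot aes geom_histogram geom_line geom_abline
#'   facet_wrap labs theme_minimal autoplot geom_step
NULL

#' Plot pairwise protein similarity distributions
#'
#' Histogram of percent identities, optionally faceted by comparison group
#' (e.g. test-vs-train, within-test, within-train).
#'
#' @param identities Tibble with a column `identity_pct` and optionally
#'   `comparison` (facet).
#' @param binwidth Histogram bin width in percent.
#' @return A ggplot.
#' @export
plot_similarity_distribution <- function(identities, binwidth = 2.5) {
  p <- ggplot(identities, aes(x = .data$identity_pct)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey35") +
    labs(x = "Pairwise sequence identity (%)", y = "Protein pairs") +
    theme_minimal()
  if ("comparison" %in% names(identities)) {
    p <- p + facet_wrap(~comparison, scales = "free_y")
  }
  p
}

#' Plot the training loss curve
#'
#' @param model An `smi_model` (or its `tidy()` log).
#' @return A ggplot of loss against optimizer step.
#' @export
plot_train_log <- function(model) {
  log <- if (inherits(model, "smi_model")) model$log else model
  ggplot(log, aes(x = .data$step, y = .data$loss)) +
    geom_line(color = "grey25") +
    labs(x = "Optimizer step", y = "Label-smoothed cross entropy") +
    theme_minimal()
}

#' Histograms of molecular property distributions
#'
#' One panel per physicochemical property, optionally overlaying several
#' profiled sets.
#'
#' @param profile A [property_profile()] tibble, or a named list of them
#'   (names become the `set` legend).
#' @param bins Histogram bin count.
#' @return A ggplot.
#' @export
plot_property_profile <- function(profile, bins = 30) {
  if (!is.data.frame(profile)) {
    profile <- bind_rows(purrr::imap(profile, ~mutate(.x, set = .y)))
  }
  long <- tidyr::pivot_longer(profile,
                              cols = c("logP", "mol_weight_Da", "n_h_donors",
                                       "n_h_acceptors", "n_rotatable_bonds",
                                       "tpsa_A2", "qed", "sas"),
                              names_to = "property", values_to = "value")
  p <- ggplot(long, aes(x = .data$value))
  p <- if ("set" %in% names(long)) {
    p + geom_histogram(aes(fill = .data$set), bins = bins, alpha = 0.6,
                       position = "identity")
  } else {
    p + geom_histogram(bins = bins, fill = "grey35")
  }
  p + facet_wrap(~property, scales = "free") +
    labs(x = NULL, y = "Molecules") + theme_minimal()
}

#' Histogram of nearest-neighbor Tanimoto similarities
#'
#' @param novelty An `smi_novelty` object from [nearest_neighbor_tanimoto()].
#' @param binwidth Bin width on the \[0, 1\] similarity axis.
#' @return A ggplot.
#' @export
plot_nn_tanimoto <- function(novelty, binwidth = 0.05) {
  ggplot(novelty$nn, aes(x = .data$nn_tanimoto)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey35") +
    labs(x = "Nearest-neighbor Tanimoto similarity", y = "Molecules") +
    theme_minimal()
}

#' @rdname plot_nn_tanimoto
#' @param object,... Method arguments.
#' @export
autoplot.smi_novelty <- function(object, ...) plot_nn_tanimoto(object, ...)

#' ROC curve plot
#'
#' @param roc An `smi_roc` from [roc_auc()], or a named list of them.
#' @return A ggplot with the diagonal no-skill reference.
#' @export
plot_roc <- function(roc) {
  df <- if (inherits(roc, "smi_roc")) {
    mutate(roc$curve, curve_id = sprintf("AUC = %.3f", roc$auc))
  } else {
    bind_rows(purrr::imap(roc, function(r, nm) {
      mutate(r$curve, curve_id = sprintf("%s (AUC = %.3f)", nm, r$auc))
    }))
  }
  ggplot(df, aes(x = .data$fpr, y = .data$tpr, color = .data$curve_id)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    labs(x = "False positive rate", y = "True positive rate", color = NULL) +
    theme_minimal()
}

#' @rdname plot_roc
#' @param object,... Method arguments.
#' @export
autoplot.smi_roc <- function(object, ...) plot_roc(object)
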