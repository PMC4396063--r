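#' Harmonise a two-disease cell-line panel
#'
#' Applies the panel preparation used before signature training: split by
#' disease group, median-centre each sub-panel, scale the second group's
#' per-gene variance to the reference (first) group, and merge. The
#' reference sub-panel is returned as well, because patient cohorts are
#' later variance-matched against it.
#'
#' @param panel A collapsed [expression_panel] with exactly two disease
#'   groups.
#' @param reference_group Group used as the variance reference (default the
#'   first group encountered).
#' @return List: `panel` (merged, harmonised), `reference` (the centred
#'   reference sub-panel).
#' @export
harmonise_cell_panel <- function(panel, reference_group = panel$disease_group[1]) {
  stopifnot(inherits(panel, "expression_panel"))
  groups <- unique(panel$disease_group)
  if (length(groups) != 2) stop("expected exactly two disease groups")
  other_group <- setdiff(groups, reference_group)
  ref <- expression_panel(panel$values[, panel$disease_group == reference_group,
                                       drop = FALSE],
                          rep(reference_group, sum(panel$disease_group == reference_group)),
                          id = reference_group, collapsed = TRUE)
  oth <- expression_panel(panel$values[, panel$disease_group == other_group,
                                       drop = FALSE],
                          rep(other_group, sum(panel$disease_group == other_group)),
                          id = other_group, collapsed = TRUE)
  ref <- median_center(ref)
  oth <- scale_to_reference(median_center(oth), ref)
  list(panel = merge_panels(ref, oth, id = paste0(panel$id, "_harmonised")),
       reference = ref)
}

#' Harmonise a patient cohort to the training reference
#'
#' Median-centres the cohort panel and matches each gene's variance to the
#' reference sub-panel of the training screen.
#'
#' @param cohort_panel A collapsed [expression_panel] of patient samples.
#' @param reference The `reference` element of [harmonise_cell_panel()].
#' @return The harmonised cohort panel.
#' @export
harmonise_cohort <- function(cohort_panel, reference) {
  scale_to_reference(median_center(cohort_panel), reference)
}

#' Train classifier and predictor signatures for every drug
#'
#' For each drug: tertile labels within disease groups feed a regularised
#' logistic classifier (intermediate lines dropped), and the raw AUC0
#' values feed a regularised linear predictor with an unpenalised disease
#' indicator.
#'
#' @param panel_h Harmonised training panel ([harmonise_cell_panel()]).
#' @param auc0_table data.frame with cell_line, drug, auc0 (or true_auc0)
#'   and disease_group columns, as produced by [auc0_table()] joined to the
#'   screen design (or by [simulate_cell_panel()]).
#' @param classifier_config,predictor_config [elastic_net_config()]s.
#' @param drugs Drugs to train (default: all in the table).
#' @return List of class `regs_set`: `classifiers`, `predictors`, `labels`
#'   (per drug).
#' @export
train_regs_set <- function(panel_h, auc0_table,
                           classifier_config = elastic_net_config("binomial"),
                           predictor_config = elastic_net_config("gaussian"),
                           drugs = unique(auc0_table$drug)) {
  if (!"auc0" %in% names(auc0_table) && "true_auc0" %in% names(auc0_table))
    auc0_table$auc0 <- auc0_table$true_auc0
  out <- list(classifiers = list(), predictors = list(), labels = list())
  for (d in drugs) {
    tab <- auc0_table[auc0_table$drug == d, , drop = FALSE]
    auc0v <- stats::setNames(tab$auc0, tab$cell_line)
    lab <- categorise_tertiles(auc0v, tab$disease_group)
    out$labels[[d]] <- lab
    out$classifiers[[d]] <- train_regs(panel_h, lab, d, classifier_config)
    out$predictors[[d]] <- train_regs(panel_h, auc0v, d, predictor_config)
  }
  class(out) <- "regs_set"
  out
}

#' @export
print.regs_set <- function(x, ...) {
  for (d in names(x$classifiers)) {
    cat(sprintf("%s: classifier %d genes, predictor %d genes\n", d,
                length(x$classifiers[[d]]$coefficients),
                length(x$predictors[[d]]$coefficients)))
  }
  invisible(x)
}

#' Score a harmonised cohort with a trained signature set
#'
#' Applies every per-drug classifier and predictor and fuses them:
#' probabilities by the odds-product rule (and, for reference, the naive
#' product and the resistant-drug count), indices by the geometric mean.
#'
#' @param regs A `regs_set` from [train_regs_set()].
#' @param cohort_h Harmonised cohort panel ([harmonise_cohort()]).
#' @param disease_indicator Value of the predictors' disease indicator for
#'   this cohort (0 = reference-group-like).
#' @return List: `probabilities` (sample x drug), `indices` (sample x
#'   drug), `combined` (data.frame with sample_id, p_combined, p_product,
#'   n_resistant, index_combined).
#' @export
score_cohort <- function(regs, cohort_h, disease_indicator = 0) {
  stopifnot(inherits(regs, "regs_set"))
  drugs <- names(regs$classifiers)
  probs <- sapply(drugs, function(d) predict_probability(regs$classifiers[[d]], cohort_h))
  idx <- sapply(drugs, function(d) predict_index(regs$predictors[[d]], cohort_h,
                                                 disease_indicator))
  probs <- matrix(probs, ncol = length(drugs),
                  dimnames = list(colnames(cohort_h$values), drugs))
  idx <- matrix(idx, ncol = length(drugs),
                dimnames = list(colnames(cohort_h$values), drugs))
  list(probabilities = probs, indices = idx,
       combined = data.frame(sample_id = rownames(probs),
                             p_combined = graham_combine(probs),
                             p_product = product_combine(probs),
                             n_resistant = count_combine(probs),
                             index_combined = geometric_mean_index(idx),
                             stringsAsFactors = FALSE))
}
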