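#' Expression panel
#'
#' A genes x samples matrix of log2 intensities with per-sample disease
#' group labels and harmonisation state flags. The harmonisation pipeline
#' is collapse probe-sets -> median-centre -> variance-match -> merge, and
#' each operation checks the flags of its input.
#'
#' @param values Numeric matrix, rows = genes/probe-sets, columns = samples.
#'   Must have row and column names.
#' @param disease_group Character/factor of length `ncol(values)` (e.g.
#'   "DLBCL"/"MM", or a cohort name).
#' @param id Panel identifier used by [scale_to_reference()] bookkeeping.
#' @param collapsed Set `TRUE` when rows are already one per gene.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, disease_group, id = "panel",
                             collapsed = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || (ncol(values) > 0 && is.null(colnames(values))))
    stop("values must have row (gene) and column (sample) names")
  if (length(disease_group) != ncol(values))
    stop("disease_group must have one label per sample")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  structure(list(values = values,
                 disease_group = as.character(disease_group),
                 id = id,
                 state = list(collapsed = collapsed, centred = FALSE,
                              scaled_to = NA_character_)),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  st <- x$state
  cat(sprintf("expression_panel '%s': %d genes x %d samples [%s]\n",
              x$id, nrow(x$values), ncol(x$values),
              paste(c(if (st$collapsed) "collapsed", if (st$centred) "centred",
                      if (!is.na(st$scaled_to)) paste0("scaled to ", st$scaled_to)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Collapse probe-sets to genes by maximal variance
#'
#' Each gene interrogated by several probe-sets is represented by the
#' probe-set with the largest variance across samples within this dataset;
#' ties are broken by the lexicographically smallest probe-set id.
#' Probe-sets absent from the map are dropped (their count is messaged).
#'
#' @param panel An [expression_panel] whose rows are probe-sets.
#' @param probe_to_gene_map data.frame with columns `probe_set` and `gene`.
#' @return A collapsed `expression_panel` with one row per gene.
#' @export
collapse_probesets <- function(panel, probe_to_gene_map) {
  stopifnot(inherits(panel, "expression_panel"))
  map <- probe_to_gene_map
  if (is.null(map) || nrow(map) == 0) stop("empty probe-to-gene map")
  if (!all(c("probe_set", "gene") %in% names(map)))
    stop("map must have columns probe_set and gene")
  probes <- rownames(panel$values)
  unmapped <- setdiff(probes, map$probe_set)
  if (length(unmapped) > 0)
    message(length(unmapped), " probe-sets without gene mapping dropped")
  map <- map[map$probe_set %in% probes, , drop = FALSE]
  v <- apply(panel$values[map$probe_set, , drop = FALSE], 1, stats::var)
  # order so that within each gene the highest variance comes first,
  # ties resolved by probe-set id
  ord <- order(map$gene, -v, map$probe_set)
  map <- map[ord, , drop = FALSE]
  keep <- map$probe_set[!duplicated(map$gene)]
  genes <- map$gene[!duplicated(map$gene)]
  out <- panel$values[keep, , drop = FALSE]
  rownames(out) <- genes
  res <- expression_panel(out, panel$disease_group, id = panel$id,
                          collapsed = TRUE)
  res
}

#' Median-centre every gene
#'
#' Subtracts the per-gene median so each row has median zero.
#'
#' @param panel A collapsed [expression_panel].
#' @return The centred panel (idempotent).
#' @export
median_center <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!panel$state$collapsed)
    stop("panel must be collapsed to genes before centring")
  med <- apply(panel$values, 1, stats::median)
  panel$values <- panel$values - med
  panel$state$centred <- TRUE
  panel
}

#' Scale every gene to the variance observed in a reference panel
#'
#' Each gene row is multiplied by `sd_ref / sd_self` so its variance matches
#' the reference (unbiased sample variance). Genes absent from the reference
#' are dropped (messaged); genes with zero own variance are left as-is and
#' genes with zero reference variance are set to zero.
#'
#' @param panel,reference_panel Centred [expression_panel]s.
#' @return The scaled panel, restricted to the gene intersection, with
#'   `state$scaled_to` set to the reference id.
#' @export
scale_to_reference <- function(panel, reference_panel) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(reference_panel, "expression_panel"))
  if (!panel$state$centred || !reference_panel$state$centred)
    stop("both panels must be median-centred before variance matching")
  common <- intersect(rownames(panel$values), rownames(reference_panel$values))
  if (length(common) == 0) stop("no genes shared with the reference panel")
  dropped <- nrow(panel$values) - length(common)
  if (dropped > 0)
    message(dropped, " genes absent from the reference dropped")
  x <- panel$values[common, , drop = FALSE]
  sd_self <- apply(x, 1, stats::sd)
  sd_ref <- apply(reference_panel$values[common, , drop = FALSE], 1, stats::sd)
  fac <- ifelse(sd_self > 0, sd_ref / sd_self, 1)
  fac[sd_ref == 0] <- 0
  panel$values <- x * fac
  panel$state$scaled_to <- reference_panel$id
  panel
}

#' Merge two harmonised panels by column concatenation
#'
#' Joins two centred panels on their gene intersection. The second panel
#' must already be variance-matched to the first (see
#' [scale_to_reference()]); disease-group labels are preserved.
#'
#' @param panel_a Reference-side panel.
#' @param panel_b Panel scaled to `panel_a` (may have zero samples).
#' @param id Identifier for the merged panel.
#' @return The merged `expression_panel`.
#' @export
merge_panels <- function(panel_a, panel_b, id = paste0(panel_a$id, "+", panel_b$id)) {
  stopifnot(inherits(panel_a, "expression_panel"),
            inherits(panel_b, "expression_panel"))
  if (ncol(panel_b$values) == 0) return(panel_a)
  if (!panel_a$state$centred || !panel_b$state$centred)
    stop("panels must be centred before merging")
  if (is.na(panel_b$state$scaled_to) || panel_b$state$scaled_to != panel_a$id)
    stop("panel_b must be scaled to panel_a's variance before merging")
  common <- intersect(rownames(panel_a$values), rownames(panel_b$values))
  if (length(common) == 0) stop("no genes in common")
  if (any(colnames(panel_b$values) %in% colnames(panel_a$values)))
    stop("duplicate sample ids across panels")
  vals <- cbind(panel_a$values[common, , drop = FALSE],
                panel_b$values[common, , drop = FALSE])
  out <- expression_panel(vals,
                          c(panel_a$disease_group, panel_b$disease_group),
                          id = id, collapsed = TRUE)
  out$state$centred <- TRUE
  out
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows (first column = gene/probe-set id) and a header row
#' of sample ids.
#'
#' @param path TSV file.
#' @param disease_group Per-sample labels (recycled if length 1).
#' @param id Panel id.
#' @return An [expression_panel].
#' @export
read_expression_tsv <- function(path, disease_group = "unknown", id = "panel") {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  expression_panel(m, rep_len(disease_group, ncol(m)), id = id)
}
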