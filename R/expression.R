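#' Collapse probeset-level intensities to gene level
#'
#' Microarray platforms usually interrogate a gene with several probesets. For
#' gene-level analysis each gene is represented by its highest-intensity
#' probeset: the one with the largest mean log-intensity across all samples.
#' Ties are broken toward the lexicographically smaller probeset id so the
#' collapse is deterministic.
#'
#' @param data Tibble whose first column holds probeset ids and whose remaining
#'   columns are numeric sample intensities (log scale).
#' @param map Tibble with columns `probeset` and `gene` (many probesets to one
#'   gene). Probesets absent from the map are dropped with a message.
#' @return Tibble with one row per gene (first column `gene`), same sample
#'   columns, carrying the intensities of the winning probeset.
#' @export
collapse_probesets <- function(data, map) {
  stopifnot(is.data.frame(data), is.data.frame(map))
  if (!all(c("probeset", "gene") %in% names(map))) {
    abort("map must have columns 'probeset' and 'gene'")
  }
  if (nrow(map) == 0) abort("empty probeset-to-gene map")
  id <- .id_col(data)
  m <- .as_value_matrix(data)
  means <- rowMeans(m)
  tbl <- tibble(probeset = data[[id]], .mean = means)
  unmapped <- setdiff(tbl$probeset, map$probeset)
  if (length(unmapped)) {
    inform(paste0("dropping ", length(unmapped), " unmapped probeset(s)"))
  }
  winners <- tbl |>
    inner_join(map, by = "probeset") |>
    arrange(.data$gene, dplyr::desc(.data$.mean), .data$probeset) |>
    group_by(.data$gene) |>
    slice_head(n = 1) |>
    ungroup()
  winners <- arrange(winners, match(.data$probeset, data[[id]]))
  out <- data[match(winners$probeset, data[[id]]), , drop = FALSE]
  out[[id]] <- winners$gene
  names(out)[1] <- "gene"
  out
}

#' Signed fold change
#'
#' Ratio convention used throughout: the fold change of `x` against reference
#' `ref` is `x/ref` when that ratio is at least 1, and `-ref/x` otherwise, so a
#' halving is reported as -2 rather than 0.5. Values in the open interval
#' (-1, 1) are unrepresentable by construction.
#'
#' @param x Numerator intensities (linear scale, non-negative). Vectorised.
#' @param ref Reference intensities (linear scale, strictly positive).
#' @return Signed fold changes with `|value| >= 1`.
#' @examples
#' signed_fold_change(15, 10) # 1.5
#' signed_fold_change(10, 15) # -1.5
#' @export
signed_fold_change <- function(x, ref) {
  if (any(ref == 0)) abort("zero reference")
  if (any(ref < 0) || any(x < 0)) abort("intensities must be non-negative")
  r <- x / ref
  ifelse(r >= 1, r, -1 / r)
}

#' Fold changes against the per-gene median of reference samples
#'
#' Computes, for every gene and sample, the signed fold change of that sample's
#' intensity to the gene's median intensity across a designated set of
#' reference (baseline) samples. Intensities are assumed to arrive log2-scale
#' and are de-logged before ratios are formed, so the output is on the linear
#' scale practitioners report.
#'
#' @param data Expression tibble (first column ids, remaining columns log2
#'   intensities) unless `log2_input = FALSE`.
#' @param reference_samples Character vector of sample column names forming the
#'   baseline.
#' @param log2_input Are the intensities log2-scale? Default `TRUE`.
#' @return Tibble of signed fold changes, same shape as `data`, with the
#'   reference sample names stored in attribute `reference_samples`.
#' @export
median_reference_fold_change <- function(data, reference_samples,
                                         log2_input = TRUE) {
  stopifnot(length(reference_samples) >= 1)
  missing <- setdiff(reference_samples, .sample_cols(data))
  if (length(missing)) {
    abort(paste0("reference samples not in data: ", paste(missing, collapse = ", ")))
  }
  m <- .as_value_matrix(data)
  if (log2_input) m <- 2^m
  ref <- apply(m[, reference_samples, drop = FALSE], 1, median)
  zero <- rownames(m)[ref == 0]
  if (length(zero)) {
    abort(paste0("zero reference median for gene(s): ", paste(zero, collapse = ", ")))
  }
  fc <- matrix(signed_fold_change(as.vector(m), rep(ref, ncol(m))),
    nrow = nrow(m), dimnames = dimnames(m)
  )
  out <- .matrix_to_tbl(fc, .id_col(data))
  attr(out, "reference_samples") <- reference_samples
  out
}

#' Discretise fold changes into up/zero/down calls
#'
#' Maps signed fold changes to calls in \{-1, 0, +1\}: +1 when the fold change
#' is at least `up`, -1 when it is at most `down`, 0 otherwise. Both thresholds
#' are inclusive.
#'
#' @param fc Fold-change tibble (first column ids) or numeric vector/matrix.
#' @param up Upregulation threshold, default 1.5.
#' @param down Downregulation threshold, default -1.5.
#' @return Same shape as the input with integer calls.
#' @export
discretize_calls <- function(fc, up = 1.5, down = -1.5) {
  stopifnot(up >= 1, down <= -1)
  code <- function(v) (v >= up) - (v <= down)
  if (is.data.frame(fc)) {
    m <- .as_value_matrix(fc)
    out <- .matrix_to_tbl(code(m) * 1L, .id_col(fc))
    out[[1]] <- fc[[1]]
    return(out)
  }
  code(fc) * 1L
}

#' Drop genes with inconsistent replicate calls and collapse to conditions
#'
#' A gene is kept only if, within every condition, its discrete calls agree
#' across all technical replicates; the condition-level call is then the shared
#' value. Any disagreement in any condition drops the whole gene. This is the
#' conservative reading of replicate consistency.
#'
#' @param calls Discrete-call tibble (first column gene ids, one column per
#'   sample, values in -1/0/1).
#' @param design Tibble with columns `sample`, `group` (the condition) and
#'   optionally `replicate`.
#' @return List with `calls` (tibble gene x condition) and `dropped`
#'   (character vector of removed genes).
#' @export
filter_inconsistent_replicates <- function(calls, design) {
  .check_design(design, samples = .sample_cols(calls))
  conds <- unique(design$group)
  design <- filter(design, .data$sample %in% .sample_cols(calls))
  empty <- setdiff(conds, unique(design$group))
  if (length(empty)) {
    abort(paste0("condition with zero replicates: ", paste(empty, collapse = ", ")))
  }
  m <- .as_value_matrix(calls)
  cond_call <- matrix(0L, nrow(m), length(conds),
    dimnames = list(rownames(m), conds)
  )
  consistent <- rep(TRUE, nrow(m))
  for (cc in conds) {
    cols <- design$sample[design$group == cc]
    sub <- m[, cols, drop = FALSE]
    agree <- matrixStats_rowAllEqual(sub)
    consistent <- consistent & agree
    cond_call[, cc] <- as.integer(sub[, 1])
  }
  dropped <- rownames(m)[!consistent]
  kept <- cond_call[consistent, , drop = FALSE]
  list(
    calls = .matrix_to_tbl(kept, .id_col(calls)),
    dropped = dropped
  )
}

# all columns equal within each row (base implementation; no extra deps)
matrixStats_rowAllEqual <- function(m) {
  if (ncol(m) == 1) return(rep(TRUE, nrow(m)))
  rowSums(m == m[, 1]) == ncol(m)
}

#' Per-gene one-way ANOVA across treatment groups
#'
#' Fits a fixed-effects one-way ANOVA per gene on log-scale intensities and
#' returns the F statistic and upper-tail p-value. Degenerate rows are handled
#' explicitly: when the within-group variance is zero and group means differ,
#' the p-value is reported as the smallest representable positive double (the
#' F statistic is infinite); when all values are identical the row gets F = 0,
#' p = 1.
#'
#' @param data Expression tibble (first column gene ids).
#' @param design Design tibble with `sample` and `group` columns; every group
#'   needs at least two samples.
#' @return Tibble with columns `gene`, `F`, `p`.
#' @export
anova_de <- function(data, design) {
  .check_design(design, samples = .sample_cols(data))
  design <- filter(design, .data$sample %in% .sample_cols(data))
  grp <- factor(design$group)
  if (nlevels(grp) < 2) abort("need at least two groups")
  if (any(table(grp) < 2)) abort("every group needs at least two samples")
  m <- .as_value_matrix(data)[, design$sample, drop = FALSE]
  res <- apply(m, 1, function(v) {
    within_var <- tapply(v, grp, stats::var)
    if (all(within_var == 0)) {
      means <- tapply(v, grp, mean)
      if (max(means) - min(means) == 0) return(c(0, 1))
      return(c(Inf, .Machine$double.xmin))
    }
    fit <- oneway.test(v ~ grp, var.equal = TRUE)
    c(unname(fit$statistic), unname(fit$p.value))
  })
  n_degenerate <- sum(!is.finite(res[1, ]))
  if (n_degenerate > 0) {
    inform(paste0(n_degenerate, " gene(s) with zero within-group variance; ",
                  "p set to smallest positive double"))
  }
  tibble(gene = rownames(m), F = unname(res[1, ]), p = unname(res[2, ]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin, order-preserving wrapper
#' around [stats::p.adjust()] with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1 | is.na(p))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Flags genes passing both the fold-change and FDR thresholds (inclusive).
#'
#' @param de Tibble with columns `gene`, a signed fold-change column `fc`
#'   (or named via `fc_col`), and `q`.
#' @param fc_cut Minimum absolute signed fold change, default 1.2.
#' @param q_cut Maximum q-value, default 0.05.
#' @param fc_col Name of the fold-change column, default `"fc"`.
#' @return The input tibble with a logical `is_de` column added.
#' @export
call_de_genes <- function(de, fc_cut = 1.2, q_cut = 0.05, fc_col = "fc") {
  stopifnot(fc_cut >= 1)
  if (!all(c("gene", fc_col, "q") %in% names(de))) {
    abort(paste0("de table needs columns gene, ", fc_col, ", q"))
  }
  mutate(de, is_de = abs(.data[[fc_col]]) >= fc_cut & .data$q <= q_cut)
}

#' Build a differential-expression table for one contrast
#'
#' Convenience wrapper tying the pieces together: per-gene one-way ANOVA across
#' all groups, BH adjustment, linear-scale signed fold change of the contrast
#' group's mean against the reference group's mean, and the inclusive DE call.
#'
#' @inheritParams anova_de
#' @param contrast Group label whose mean forms the numerator.
#' @param reference Group label forming the denominator (baseline).
#' @param fc_cut,q_cut Thresholds passed to [call_de_genes()].
#' @param log2_input Are intensities log2-scale? Default `TRUE`.
#' @return Tibble with columns `gene`, `fc`, `F`, `p`, `q`, `is_de`.
#' @export
de_table <- function(data, design, contrast, reference,
                     fc_cut = 1.2, q_cut = 0.05, log2_input = TRUE) {
  .check_design(design, samples = .sample_cols(data))
  stats_tbl <- anova_de(data, design)
  m <- .as_value_matrix(data)
  if (log2_input) m <- 2^m
  num <- rowMeans(m[, design$sample[design$group == contrast], drop = FALSE])
  den <- rowMeans(m[, design$sample[design$group == reference], drop = FALSE])
  stats_tbl |>
    mutate(
      fc = signed_fold_change(num[.data$gene], den[.data$gene]),
      q = bh_fdr(.data$p)
    ) |>
    select("gene", "fc", "F", "p", "q") |>
    call_de_genes(fc_cut = fc_cut, q_cut = q_cut)
}

#' Relative expression by the comparative Ct method
#'
#' Standard qPCR quantification: `2^-((Ct_target,t - Ct_ref,t) -
#' (Ct_target,c - Ct_ref,c))`, i.e. two to the minus delta-delta-Ct.
#'
#' @param ct_target_treated,ct_ref_treated Cycle thresholds for the gene of
#'   interest and the housekeeping reference in the treated sample.
#' @param ct_target_control,ct_ref_control The same in the control sample.
#' @return Relative fold change (1 means no change).
#' @examples
#' delta_delta_ct(20, 15, 21, 15) # 2
#' @export
delta_delta_ct <- function(ct_target_treated, ct_ref_treated,
                           ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) abort("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
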