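#' Threshold a DE record table into a gene set
#'
#' Selects genes whose absolute signed fold change is at least `fc_cut`
#' (inclusive) and whose p-value is strictly below `p_cut` — the convention
#' used when matching gene lists across exposures or platforms.
#'
#' @param records Tibble with columns `gene`, `fc`, `p` (or supply the column
#'   names via `fc_col`/`p_col`).
#' @param fc_cut Fold-change cutoff (inclusive), must be `>= 1`.
#' @param p_cut P-value cutoff (strict).
#' @param fc_col,p_col Column names, defaults `"fc"` and `"p"`.
#' @return Character vector of gene ids.
#' @export
threshold_geneset <- function(records, fc_cut, p_cut,
                              fc_col = "fc", p_col = "p") {
  stopifnot(fc_cut >= 1)
  if (nrow(records) == 0) return(character(0))
  keep <- abs(records[[fc_col]]) >= fc_cut & records[[p_col]] < p_cut
  records$gene[keep]
}

#' Partition two or three gene sets into disjoint Venn regions
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble with columns `region` (membership pattern such as `"A&B"`),
#'   `n`, and `genes` (list-column). Regions are pairwise disjoint and their
#'   union is the union of the inputs.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) abort("venn_partition supports 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  sets <- map(sets, unique)
  all_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, names(sets)))
  patterns <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  # enumerate all 2^k - 1 patterns so empty regions are reported as zero
  combos <- unlist(lapply(seq_len(k), function(i) {
    utils::combn(names(sets), i, paste, collapse = "&", simplify = FALSE)
  }))
  rows <- map(combos, function(pat) {
    genes <- if (length(all_genes)) sort(all_genes[patterns == pat]) else character(0)
    tibble(region = pat, n = length(genes), genes = list(genes))
  })
  bind_rows(rows)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap of at least `k_overlap` genes between
#' two sets of sizes `n_a` and `n_b` drawn without replacement from a universe
#' of `n_universe` genes. The choice of test is an extension — the underlying
#' study asserts overlap significance without naming one — and output headers
#' label it as such.
#'
#' @param n_a,n_b Sizes of the two gene sets.
#' @param k_overlap Observed overlap.
#' @param n_universe Universe size (default 21249).
#' @return Upper-tail probability `P(X >= k_overlap)`.
#' @export
hypergeometric_overlap <- function(n_a, n_b, k_overlap, n_universe = 21249) {
  if (k_overlap > min(n_a, n_b) || n_a > n_universe || n_b > n_universe ||
      any(c(n_a, n_b, k_overlap) < 0)) {
    abort("invalid overlap bounds")
  }
  phyper(k_overlap - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}

#' Count genes with a strict dose-response relationship
#'
#' Among genes with fold changes at two doses, counts those whose high-dose
#' fold change is strictly greater than the low-dose one, and lists the
#' violators.
#'
#' @param records Tibble with columns `gene`, `fc_high`, `fc_low`.
#' @return List with `n_monotone`, `n_total`, and `violators` (gene ids with
#'   `fc_high <= fc_low`).
#' @export
dose_response_monotonicity <- function(records) {
  if (nrow(records) == 0) {
    return(list(n_monotone = 0L, n_total = 0L, violators = character(0)))
  }
  stopifnot(all(c("gene", "fc_high", "fc_low") %in% names(records)))
  mono <- records$fc_high > records$fc_low
  list(
    n_monotone = sum(mono),
    n_total = nrow(records),
    violators = records$gene[!mono]
  )
}
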