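#' Build a 2x2 contingency table for a gene set against a term
#'
#' Cross-classifies the gene universe by membership in a query gene set (e.g.
#' differentially expressed genes) and in a functional term's annotation:
#' `a` = in both, `b` = query only, `c` = term only, `d` = neither. Genes with
#' no annotation stay in the universe and populate `b`/`d`, matching the use of
#' a fixed whole-genome universe count.
#'
#' @param geneset Character vector of query gene ids; must be a subset of the
#'   universe.
#' @param term_genes Character vector of gene ids annotated to the term.
#' @param universe Either a character vector of all gene ids, or a single
#'   integer universe size (in which case subset checks on `geneset` are
#'   limited to counts).
#' @return Named integer vector `c(a, b, c, d)` summing to the universe size.
#' @export
build_contingency <- function(geneset, term_genes, universe) {
  geneset <- unique(geneset)
  term_genes <- unique(term_genes)
  if (is.character(universe)) {
    universe <- unique(universe)
    offenders <- setdiff(geneset, universe)
    if (length(offenders)) {
      abort(paste0("gene(s) absent from universe: ",
                   paste(head(offenders, 10), collapse = ", ")))
    }
    term_genes <- intersect(term_genes, universe)
    n <- length(universe)
  } else {
    n <- as.integer(universe)
    if (length(geneset) > n || length(term_genes) > n) {
      abort("gene set larger than universe")
    }
  }
  a <- length(intersect(geneset, term_genes))
  b <- length(geneset) - a
  cc <- length(term_genes) - a
  d <- n - a - b - cc
  if (d < 0) abort("universe smaller than union of gene set and term")
  c(a = a, b = b, c = cc, d = d)
}

#' Chi-square test with Yates' continuity correction on a 2x2 table
#'
#' Computes the continuity-corrected statistic
#' `N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` and its
#' upper-tail p-value on one degree of freedom. Tables with a zero marginal are
#' uninformative and are returned as chi2 = 0, p = 1 with a message.
#'
#' @param tab Named vector or list with elements `a`, `b`, `c`, `d`.
#' @return Named list with `chi2` and `p`.
#' @export
chi_square_yates <- function(tab) {
  a <- as.numeric(tab[["a"]]); b <- as.numeric(tab[["b"]])
  cc <- as.numeric(tab[["c"]]); d <- as.numeric(tab[["d"]])
  if (any(c(a, b, cc, d) < 0)) abort("negative cell count")
  n <- a + b + cc + d
  if (n <= 0) abort("empty table")
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (any(marg == 0)) {
    inform("zero marginal in contingency table; returning chi2 = 0, p = 1")
    return(list(chi2 = 0, p = 1))
  }
  num <- max(abs(a * d - b * cc) - n / 2, 0)
  chi2 <- n * num^2 / prod(marg)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Term over/under-representation for a gene set
#'
#' Scores every annotated term by the Yates-corrected chi-square of its 2x2
#' table against the universe. The significance flag uses the raw p-value
#' (`p < alpha`); a BH-adjusted column is included for reference but does not
#' drive the flag. Direction is `"enriched"` when the term is relatively more
#' frequent inside the gene set than outside, `"depleted"` otherwise.
#'
#' @param geneset Character vector of query genes.
#' @param annotation Tibble with columns `gene` and `term` (one row per
#'   annotation; genes may carry many terms). An optional `term_name` column is
#'   carried through.
#' @param universe Character vector of universe gene ids or a single count
#'   (default 21249, a whole-genome universe).
#' @param alpha Raw-p significance cutoff, default 0.05.
#' @return Tibble with one row per term: counts `a`-`d`, `chi2`, `p`, `q`,
#'   `direction`, `significant`, sorted by ascending p then term id.
#' @export
enrich_terms <- function(geneset, annotation, universe = 21249, alpha = 0.05) {
  if (!all(c("gene", "term") %in% names(annotation))) {
    abort("annotation needs columns 'gene' and 'term'")
  }
  if (nrow(annotation) == 0) abort("empty annotation")
  geneset <- unique(geneset)
  if (length(geneset) == 0) {
    return(tibble(
      term = character(), a = integer(), b = integer(), c = integer(),
      d = integer(), chi2 = numeric(), p = numeric(), q = numeric(),
      direction = character(), significant = logical()
    ))
  }
  terms <- split(annotation$gene, annotation$term)
  rows <- imap(terms, function(genes, id) {
    tab <- build_contingency(geneset, genes, universe)
    test <- chi_square_yates(tab)
    prop_in <- if (tab[["a"]] + tab[["b"]] > 0) tab[["a"]] / (tab[["a"]] + tab[["b"]]) else 0
    prop_out <- if (tab[["c"]] + tab[["d"]] > 0) tab[["c"]] / (tab[["c"]] + tab[["d"]]) else 0
    tibble(
      term = id, a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
      chi2 = test$chi2, p = test$p,
      direction = if (prop_in > prop_out) "enriched" else "depleted"
    )
  })
  out <- bind_rows(rows) |>
    mutate(q = bh_fdr(.data$p), significant = .data$p < alpha) |>
    select("term", "a", "b", "c", "d", "chi2", "p", "q", "direction", "significant") |>
    arrange(.data$p, .data$term)
  out
}
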