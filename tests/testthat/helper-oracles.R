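# Independent oracles used to verify the package's statistics, plus small
# fixture builders. Everything here is deliberately naive: direct formulas,
# enumeration, O(n^2) loops — never the code paths under test.

# step-up FDR straight from the definition: q_i = min over j with p_(j) >= p_(i)
# of m * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- vapply(seq(rank_i, m), function(j) m * p[ord[j]] / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# textbook one-way ANOVA from sums of squares
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hyper <- function(n_a, n_b, k, n_universe) {
  universe <- seq_len(n_universe)
  set_a <- seq_len(n_a)
  draws <- combn(n_universe, n_b)
  hits <- apply(draws, 2, function(d) sum(d %in% set_a))
  mean(hits >= k)
}

# Yates statistic evaluated longhand (no shared code with the package)
oracle_yates <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- abs(a * d - b * c) - n / 2
  if (num < 0) num <- 0
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# tiny intensity tibble: genes x samples from a matrix
make_expr <- function(m, id = "gene") {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id := rownames(m)), out)
}

# hand-built feature object with explicit motif presence
make_features <- function(presence) {
  structure(
    list(presence = presence, k_list = nchar(colnames(presence)[1]),
         with_revcomp = FALSE),
    class = "kmer_features"
  )
}

# hand-built panel from a state matrix (tfs x conditions)
make_panel <- function(states) {
  structure(
    list(states = states, tfs = rownames(states),
         conditions = colnames(states)),
    class = "regulator_panel"
  )
}

# a linearly separable toy: two genes carry the motif and are always up, two
# lack it and are always down
separable_toy <- function(n_conditions = 3) {
  conds <- paste0("c", seq_len(n_conditions))
  presence <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1,
                     dimnames = list(paste0("g", 1:4), "AAAAA"))
  states <- matrix(1L, 1, n_conditions, dimnames = list("tfX", conds))
  calls <- tibble::tibble(gene = paste0("g", 1:4))
  for (cc in conds) calls[[cc]] <- c(1L, 1L, -1L, -1L)
  list(
    features = make_features(presence),
    panel = make_panel(states),
    examples = regulonboost::build_examples(calls)
  )
}

# random small boosting instance for bound checks
random_instance <- function(seed, n_genes = 8, n_conditions = 4, n_motifs = 6) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  conds <- paste0("c", seq_len(n_conditions))
  motifs <- vapply(seq_len(n_motifs), function(i) {
    paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
  }, character(1))
  motifs <- make.unique(motifs)
  presence <- matrix(runif(n_genes * n_motifs) < 0.5, n_genes, n_motifs,
                     dimnames = list(genes, motifs))
  states <- matrix(sample(c(-1L, 1L), 2 * n_conditions, replace = TRUE),
                   2, n_conditions, dimnames = list(c("tfA", "tfB"), conds))
  calls <- tibble::tibble(gene = genes)
  for (cc in conds) calls[[cc]] <- sample(c(-1L, 1L), n_genes, replace = TRUE)
  list(
    features = make_features(presence),
    panel = make_panel(states),
    examples = regulonboost::build_examples(calls)
  )
}
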