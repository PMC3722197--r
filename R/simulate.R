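#' Simulate a planted regulatory network
#'
#' Generates the inputs the boosting learner consumes, with known ground
#' truth: candidate TFs with per-condition states drawn uniformly from
#' \{-1, +1\}; disjoint regulons whose members inherit their TF's state with
#' probability `1 - noise` (flipped otherwise); decoy genes with uniform
#' random calls so the learner must exploit features rather than class
#' imbalance; and i.i.d. uniform-background promoters in which each regulon
#' member carries at least one planted occurrence of its TF's motif at a
#' uniformly drawn position. Everything is a pure function of the parameters
#' and seed.
#'
#' @param n_tfs Number of planted TFs, default 5.
#' @param targets_per_tf Regulon size, default 40.
#' @param n_decoys Decoy target genes with random calls, default 50.
#' @param motif_length Planted motif length (must be a learner k-mer length),
#'   default 6.
#' @param promoter_length Promoter length in bp, default 1000.
#' @param noise Label-flip probability in `[0, 0.5)`, default 0.1.
#' @param n_conditions Number of conditions, default 20.
#' @param background Base-composition probabilities, default uniform.
#' @param seed Integer seed.
#' @return List with `promoters` (named character vector), `calls`
#'   (condition-level tibble over TFs, targets and decoys), `tfs`, and
#'   `truth` (motifs, regulons, parameters).
#' @export
generate_planted_network <- function(n_tfs = 5, targets_per_tf = 40,
                                     n_decoys = 50, motif_length = 6,
                                     promoter_length = 1000, noise = 0.1,
                                     n_conditions = 20,
                                     background = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25),
                                     seed = 1L) {
  stopifnot(noise >= 0, noise < 0.5, n_tfs >= 1, targets_per_tf >= 1)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  bases <- names(background)
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  target_ids <- sprintf("T%03d", seq_len(n_tfs * targets_per_tf))
  decoy_ids <- if (n_decoys > 0) sprintf("D%03d", seq_len(n_decoys)) else character(0)
  gene_ids <- c(tf_ids, target_ids, decoy_ids)

  # distinct motifs under reverse-complement canonicalisation
  motifs <- character(0)
  while (length(motifs) < n_tfs) {
    cand <- paste(sample(bases, motif_length, replace = TRUE), collapse = "")
    canon <- canonical_motif(cand)
    if (canon %in% canonical_motif(motifs)) {
      inform("motif collision; regenerating")
      next
    }
    motifs <- c(motifs, cand)
  }
  names(motifs) <- tf_ids

  promoters <- vapply(gene_ids, function(g) {
    paste(sample(bases, promoter_length, replace = TRUE, prob = background),
          collapse = "")
  }, character(1))

  regulons <- split(target_ids, rep(tf_ids, each = targets_per_tf))
  regulons <- regulons[tf_ids]
  for (tf in tf_ids) {
    for (g in regulons[[tf]]) {
      pos <- sample.int(promoter_length - motif_length + 1, 1)
      substr(promoters[[g]], pos, pos + motif_length - 1) <- motifs[[tf]]
    }
  }

  conds <- sprintf("cond%02d", seq_len(n_conditions))
  tf_states <- matrix(sample(c(-1L, 1L), n_tfs * n_conditions, replace = TRUE),
                      nrow = n_tfs, dimnames = list(tf_ids, conds))
  calls <- matrix(0L, length(gene_ids), n_conditions,
                  dimnames = list(gene_ids, conds))
  calls[tf_ids, ] <- tf_states
  for (tf in tf_ids) {
    members <- regulons[[tf]]
    flips <- matrix(runif(length(members) * n_conditions) < noise,
                    nrow = length(members))
    base <- matrix(tf_states[tf, ], nrow = length(members),
                   ncol = n_conditions, byrow = TRUE)
    calls[members, ] <- ifelse(flips, -base, base)
  }
  if (length(decoy_ids)) {
    calls[decoy_ids, ] <- sample(c(-1L, 1L), length(decoy_ids) * n_conditions,
                                 replace = TRUE)
  }

  list(
    promoters = promoters,
    calls = .matrix_to_tbl(calls, "gene"),
    tfs = tf_ids,
    truth = list(
      motifs = motifs, regulons = regulons, noise = noise,
      n_conditions = n_conditions, background = background,
      promoter_length = promoter_length
    )
  )
}

#' Simulate a dose-response expression experiment
#'
#' Log2 intensities are a per-gene baseline plus, for planted genes, a group
#' effect (the low-dose effect is a configurable fraction of the high-dose
#' effect, mirroring a dose-response design) plus Gaussian noise. The truth
#' table records each gene's planted signed linear fold changes.
#'
#' @param n_genes Number of genes, default 1000.
#' @param n_de Number of planted differentially expressed genes, default 100.
#' @param replicates Replicates per group, default 3.
#' @param fold_range Range of planted high-dose linear fold changes, default
#'   `c(2, 6)`.
#' @param low_fraction Low-dose effect as a fraction of the high-dose log2
#'   effect, default 0.25.
#' @param sigma Log2-scale noise standard deviation, default 0.1.
#' @param baseline_range Range of per-gene baseline log2 intensity, default
#'   `c(6, 12)`.
#' @param seed Integer seed.
#' @return List with `data` (log2 intensity tibble), `design` (sample, group,
#'   replicate), `truth` (gene, planted, fc_high, fc_low).
#' @export
generate_expression_experiment <- function(n_genes = 1000, n_de = 100,
                                           replicates = 3,
                                           fold_range = c(2, 6),
                                           low_fraction = 0.25, sigma = 0.1,
                                           baseline_range = c(6, 12),
                                           seed = 1L) {
  stopifnot(replicates >= 2, all(fold_range >= 1), n_de <= n_genes)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  genes <- sprintf("G%04d", seq_len(n_genes))
  groups <- c("control", "low_dose", "high_dose")
  design <- tibble(
    sample = paste0(rep(groups, each = replicates), "_", seq_len(replicates)),
    group = rep(groups, each = replicates),
    replicate = rep(seq_len(replicates), times = length(groups))
  )
  baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
  planted <- sort(sample.int(n_genes, n_de))
  sign_dir <- sample(c(-1, 1), n_de, replace = TRUE)
  fold <- runif(n_de, fold_range[1], fold_range[2])
  eff_high <- numeric(n_genes)
  eff_high[planted] <- sign_dir * log2(fold)
  eff_low <- eff_high * low_fraction

  effect <- matrix(0, n_genes, nrow(design))
  effect[, design$group == "low_dose"] <- eff_low
  effect[, design$group == "high_dose"] <- eff_high
  m <- baseline + effect +
    matrix(rnorm(n_genes * nrow(design), sd = sigma), n_genes)
  dimnames(m) <- list(genes, design$sample)

  to_signed <- function(log2_eff) ifelse(log2_eff >= 0, 2^log2_eff, -2^(-log2_eff))
  truth <- tibble(
    gene = genes,
    planted = seq_len(n_genes) %in% planted,
    fc_high = to_signed(eff_high),
    fc_low = to_signed(eff_low)
  )
  list(data = .matrix_to_tbl(m, "gene"), design = design, truth = truth)
}
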