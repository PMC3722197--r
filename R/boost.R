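#' Regulator panel: discrete states of candidate TFs across conditions
#'
#' Binds a candidate-regulator list to its condition-level discrete expression
#' calls, the state source for `regulator_state` features.
#'
#' @param calls Condition-level call tibble (first column gene ids, one column
#'   per condition, values in -1/0/+1).
#' @param tfs Character vector of candidate TF ids; each must be a row of
#'   `calls`.
#' @return Object of class `regulator_panel` with `states` (tf x condition
#'   integer matrix), `tfs`, `conditions`.
#' @export
regulator_panel <- function(calls, tfs) {
  m <- .as_value_matrix(calls)
  missing <- setdiff(tfs, rownames(m))
  if (length(missing)) {
    abort(paste0("TF(s) absent from call matrix: ", paste(missing, collapse = ", ")))
  }
  states <- m[tfs, , drop = FALSE]
  storage.mode(states) <- "integer"
  structure(
    list(states = states, tfs = tfs, conditions = colnames(states)),
    class = "regulator_panel"
  )
}

#' @export
print.regulator_panel <- function(x, ...) {
  cat("<regulator_panel> ", length(x$tfs), " TFs x ", length(x$conditions),
      " conditions\n", sep = "")
  invisible(x)
}

#' Build training examples from discrete expression calls
#'
#' One example per (gene, condition) pair with a nonzero call; the label is
#' the call itself and initial weights are uniform. Baseline (zero) calls are
#' excluded — the learner predicts up versus down.
#'
#' @param calls Condition-level call tibble (first column gene ids).
#' @param target_genes Optional subset of genes to train on (default: all rows
#'   of `calls`).
#' @param conditions Optional subset of condition columns (default: all).
#' @return Tibble with columns `gene`, `condition`, `label`, `weight`.
#' @export
build_examples <- function(calls, target_genes = NULL, conditions = NULL) {
  id <- .id_col(calls)
  if (!is.null(target_genes)) {
    missing <- setdiff(target_genes, calls[[id]])
    if (length(missing)) {
      abort(paste0("target gene(s) absent from calls: ",
                   paste(head(missing, 10), collapse = ", ")))
    }
    calls <- calls[calls[[id]] %in% target_genes, , drop = FALSE]
  }
  if (!is.null(conditions)) {
    calls <- calls[, c(id, conditions), drop = FALSE]
  }
  long <- tidyr::pivot_longer(calls, -dplyr::all_of(id),
    names_to = "condition", values_to = "label"
  )
  names(long)[1] <- "gene"
  long <- filter(long, .data$label != 0)
  if (nrow(long) == 0) abort("nothing to learn: no nonzero calls")
  mutate(long, label = as.integer(.data$label), weight = 1 / n())
}

#' Learner configuration
#'
#' @param k_list Motif lengths for promoter features, default `c(5, 6)`.
#' @param epsilon Smoothing added to block weights; default `NULL` means
#'   `1 / (2 * n_examples)` at training time.
#' @param subsample Per-round motif-candidate retention rate in (0, 1],
#'   default 0.5. Regulator-state features are never subsampled.
#' @param max_depth Maximum feature conjunction depth; 2 allows one motif
#'   coupled with one regulator state, 1 disables conjunctions.
#' @param with_revcomp Reverse-complement folding for motif features.
#' @return Named list of class `boost_config`.
#' @export
boost_config <- function(k_list = c(5, 6), epsilon = NULL, subsample = 0.5,
                         max_depth = 2, with_revcomp = TRUE) {
  stopifnot(subsample > 0, subsample <= 1, max_depth >= 1)
  structure(
    list(
      k_list = k_list, epsilon = epsilon, subsample = subsample,
      max_depth = max_depth, with_revcomp = with_revcomp
    ),
    class = "boost_config"
  )
}

.condition_repr <- function(kind, motif, tf, state) {
  switch(kind,
    regulator_state = sprintf("%s/%+d", tf, state),
    motif = motif,
    conjunction = sprintf("%s&%s/%+d", motif, tf, state)
  )
}

.kind_rank <- c(regulator_state = 1L, motif = 2L, conjunction = 3L)

#' Evaluate a feature predicate on (gene, condition) pairs
#'
#' A `motif` condition is true when the motif occurs in the gene's promoter
#' (condition-independent); a `regulator_state` condition is true when the
#' TF's discrete call in that condition equals the stated state; a
#' `conjunction` requires both.
#'
#' @param cond List with elements `kind` (one of `"motif"`,
#'   `"regulator_state"`, `"conjunction"`), and as applicable `motif`, `tf`,
#'   `state`.
#' @param gene,condition Vectors of gene ids and condition ids (recycled to a
#'   common length).
#' @param features `kmer_features` object.
#' @param panel `regulator_panel` object.
#' @return Logical vector.
#' @export
evaluate_condition <- function(cond, gene, condition, features, panel) {
  n <- max(length(gene), length(condition))
  gene <- rep_len(gene, n)
  condition <- rep_len(condition, n)
  motif_part <- function() {
    gi <- match(gene, rownames(features$presence))
    if (anyNA(gi)) abort("unknown gene in evaluate_condition")
    if (!cond$motif %in% colnames(features$presence)) return(rep(FALSE, n))
    unname(features$presence[gi, cond$motif])
  }
  reg_part <- function() {
    if (!cond$tf %in% panel$tfs) abort(paste0("unknown TF: ", cond$tf))
    ci <- match(condition, panel$conditions)
    if (anyNA(ci)) abort("unknown condition in evaluate_condition")
    unname(panel$states[cond$tf, ci] == cond$state)
  }
  switch(cond$kind,
    motif = motif_part(),
    regulator_state = reg_part(),
    conjunction = motif_part() & reg_part(),
    abort(paste0("unknown condition kind: ", cond$kind))
  )
}

#' Select the weak-learner condition minimising the boosting normaliser
#'
#' For every candidate condition the weighted examples are split into the
#' satisfied and unsatisfied blocks; with `W_b^+`/`W_b^-` the positive and
#' negative label weights in block `b` and smoothing `eps`, the normaliser is
#' `Z = sum_b 2 * sqrt((W_b^+ + eps) * (W_b^- + eps))`. The candidate with the
#' smallest Z wins; exact ties are resolved by kind
#' (regulator_state < motif < conjunction) and then by the lexicographic order
#' of the condition's canonical string form, so selection is deterministic.
#'
#' @param candidates List of condition lists (see [evaluate_condition()]).
#' @param examples Example tibble with normalised `weight`s and `label`s.
#' @param features,panel Feature sources.
#' @param epsilon Smoothing; default `1 / (2 * nrow(examples))`.
#' @return List with `condition` and `z`.
#' @export
best_condition <- function(candidates, examples, features, panel,
                           epsilon = NULL) {
  if (length(candidates) == 0) abort("no candidate conditions")
  eps <- epsilon %||% (1 / (2 * nrow(examples)))
  w <- examples$weight
  posw <- w * (examples$label > 0)
  negw <- w * (examples$label < 0)
  stats <- map(candidates, function(cond) {
    sat <- evaluate_condition(cond, examples$gene, examples$condition,
                              features, panel)
    sp <- sum(posw[sat]); sm <- sum(negw[sat])
    up <- sum(posw) - sp; um <- sum(negw) - sm
    z <- 2 * (sqrt((sp + eps) * (sm + eps)) + sqrt((up + eps) * (um + eps)))
    tibble(
      z = z, kind = cond$kind,
      repr = .condition_repr(cond$kind, cond$motif %||% NA_character_,
                             cond$tf %||% NA_character_, cond$state %||% NA_integer_)
    )
  }) |> bind_rows()
  ord <- order(stats$z, .kind_rank[stats$kind], stats$repr)
  best <- ord[1]
  list(condition = candidates[[best]], z = stats$z[best])
}

#' Train a confidence-rated boosting model of discrete expression
#'
#' MEDUSA-style boosting: each round selects, from a seeded subsample of
#' promoter-motif features plus all regulator-state features (and conjunctions
#' of the two anchored on conditions already in the model), the predicate that
#' minimises the block normaliser Z; the two blocks receive confidence-rated
#' weights `alpha_b = 0.5 * log((W_b^+ + eps) / (W_b^- + eps))` and example
#' weights are re-normalised. The per-round Z and training error are recorded;
#' the usual boosting bound (training error bounded by the product of the Z's)
#' holds and is exercised in the test-suite.
#'
#' @param examples Example tibble from [build_examples()].
#' @param features `kmer_features` for every gene appearing in `examples`.
#' @param panel `regulator_panel` of candidate TFs.
#' @param rounds Number of boosting rounds, `>= 1`.
#' @param seed Integer seed driving motif subsampling (the only stochastic
#'   step); identical seed, config and inputs reproduce the model exactly.
#' @param config A [boost_config()].
#' @return Object of class `boost_model`: `rules` tibble (round, kind, motif,
#'   tf, state, alpha_sat, alpha_unsat, z), `trace` tibble (round, z,
#'   normalizer, train_error), plus `config`, `seed`, `n_examples`.
#' @export
boost_train <- function(examples, features, panel, rounds = 100, seed = 1L,
                        config = boost_config()) {
  if (rounds < 1) abort("rounds must be >= 1")
  gene_ids <- rownames(features$presence)
  miss <- setdiff(unique(examples$gene), gene_ids)
  if (length(miss)) {
    abort(paste0("example gene(s) without promoter features: ",
                 paste(head(miss, 10), collapse = ", ")))
  }
  missc <- setdiff(unique(examples$condition), panel$conditions)
  if (length(missc)) {
    abort(paste0("example condition(s) unknown to panel: ",
                 paste(head(missc, 10), collapse = ", ")))
  }
  if (!all(examples$label %in% c(-1L, 1L))) abort("labels must be -1 or +1")

  M <- features$presence * 1
  tM <- t(M)
  motifs <- colnames(M)
  J <- ncol(M)
  G <- nrow(M)
  conds <- panel$conditions
  C <- length(conds)
  gi <- match(examples$gene, gene_ids)
  ci <- match(examples$condition, conds)
  y <- examples$label
  nex <- nrow(examples)
  eps <- config$epsilon %||% (1 / (2 * nex))
  pos <- y > 0
  idx_pos <- cbind(gi[pos], ci[pos])
  idx_neg <- cbind(gi[!pos], ci[!pos])

  tfs <- panel$tfs
  Tn <- length(tfs)
  # condition x regulator-state indicator (columns: +1 states then -1 states)
  S <- cbind((t(panel$states) == 1) * 1, (t(panel$states) == -1) * 1)
  rs_tf <- c(tfs, tfs)
  rs_state <- c(rep(1L, Tn), rep(-1L, Tn))
  rs_repr <- sprintf("%s/%+d", rs_tf, rs_state)

  # restore caller RNG state on exit
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  w <- rep(1 / nex, nex)
  Fvec <- numeric(nex)
  rule_motif_idx <- integer(0)
  rule_rs_idx <- integer(0)
  rule_rows <- vector("list", rounds)
  trace_rows <- vector("list", rounds)
  zfun <- function(sp, sm, totp, totm) {
    2 * (sqrt((sp + eps) * (sm + eps)) +
           sqrt((totp - sp + eps) * (totm - sm + eps)))
  }

  for (t in seq_len(rounds)) {
    keep <- which(stats::runif(J) < config$subsample)
    has_rs <- Tn > 0
    if (!has_rs && length(keep) == 0) {
      inform(paste0("round ", t, ": all candidates subsampled away; skipped"))
      next
    }
    Wpc <- matrix(0, G, C)
    Wmc <- matrix(0, G, C)
    Wpc[idx_pos] <- w[pos]
    Wmc[idx_neg] <- w[!pos]
    totp <- sum(w[pos])
    totm <- sum(w[!pos])

    z_best <- Inf
    # each entry: list(kind, motif_idx, rs_idx, z)
    contenders <- list()
    consider <- function(z_vec, builder) {
      zm <- suppressWarnings(min(z_vec))
      if (!is.finite(zm)) return()
      if (zm < z_best - 1e-15) {
        z_best <<- zm
        contenders <<- builder(which(z_vec <= zm))
      } else if (zm <= z_best + 1e-15) {
        contenders <<- c(contenders, builder(which(z_vec <= zm + 1e-15)))
      }
    }

    if (has_rs) {
      cp <- colSums(Wpc)
      cm <- colSums(Wmc)
      rs_sp <- as.vector(cp %*% S)
      rs_sm <- as.vector(cm %*% S)
      z_rs <- zfun(rs_sp, rs_sm, totp, totm)
      consider(z_rs, function(ix) map(ix, function(i) {
        list(kind = "regulator_state", motif_idx = NA_integer_, rs_idx = i)
      }))
    }
    if (length(keep)) {
      gp <- rowSums(Wpc)
      gm <- rowSums(Wmc)
      mot_sp <- as.vector(tM[keep, , drop = FALSE] %*% gp)
      mot_sm <- as.vector(tM[keep, , drop = FALSE] %*% gm)
      z_mot <- zfun(mot_sp, mot_sm, totp, totm)
      consider(z_mot, function(ix) map(ix, function(i) {
        list(kind = "motif", motif_idx = keep[i], rs_idx = NA_integer_)
      }))
    }
    if (config$max_depth >= 2 && has_rs &&
        (length(rule_motif_idx) || (length(rule_rs_idx) && length(keep)))) {
      conj_rows <- sort(unique(c(
        rule_motif_idx,
        if (length(rule_rs_idx)) keep else integer(0)
      )))
      CP <- tM[conj_rows, , drop = FALSE] %*% Wpc %*% S
      CM <- tM[conj_rows, , drop = FALSE] %*% Wmc %*% S
      z_conj <- zfun(CP, CM, totp, totm)
      allowed <- outer(conj_rows %in% rule_motif_idx, rep(TRUE, 2 * Tn)) |
        outer(conj_rows %in% keep, seq_len(2 * Tn) %in% rule_rs_idx, "&")
      z_conj[!allowed] <- Inf
      consider(z_conj, function(ix) map(ix, function(i) {
        r <- ((i - 1) %% length(conj_rows)) + 1
        s <- ((i - 1) %/% length(conj_rows)) + 1
        list(kind = "conjunction", motif_idx = conj_rows[r], rs_idx = s)
      }))
    }

    # deterministic tie-break: kind rank then lexicographic representation
    if (length(contenders) > 1) {
      reprs <- map_chr(contenders, function(cd) {
        .condition_repr(cd$kind,
          if (is.na(cd$motif_idx)) NA_character_ else motifs[cd$motif_idx],
          if (is.na(cd$rs_idx)) NA_character_ else rs_tf[cd$rs_idx],
          if (is.na(cd$rs_idx)) NA_integer_ else rs_state[cd$rs_idx]
        )
      })
      ranks <- .kind_rank[map_chr(contenders, "kind")]
      chosen <- contenders[[order(ranks, reprs)[1]]]
    } else {
      chosen <- contenders[[1]]
    }

    sat <- rep(TRUE, nex)
    if (!is.na(chosen$motif_idx)) sat <- sat & (M[cbind(gi, chosen$motif_idx)] > 0)
    if (!is.na(chosen$rs_idx)) sat <- sat & (S[cbind(ci, chosen$rs_idx)] > 0)
    wsp <- sum(w[sat & pos])
    wsm <- sum(w[sat & !pos])
    wup <- totp - wsp
    wum <- totm - wsm
    a_sat <- 0.5 * log((wsp + eps) / (wsm + eps))
    a_uns <- 0.5 * log((wup + eps) / (wum + eps))
    contrib <- ifelse(sat, a_sat, a_uns)
    Fvec <- Fvec + contrib
    wnew <- w * exp(-y * contrib)
    normalizer <- sum(wnew)
    w <- wnew / normalizer
    z_sel <- zfun(wsp, wsm, totp, totm)

    rule_rows[[t]] <- tibble(
      round = t,
      kind = chosen$kind,
      motif = if (is.na(chosen$motif_idx)) NA_character_ else motifs[chosen$motif_idx],
      tf = if (is.na(chosen$rs_idx)) NA_character_ else rs_tf[chosen$rs_idx],
      state = if (is.na(chosen$rs_idx)) NA_integer_ else rs_state[chosen$rs_idx],
      alpha_sat = a_sat,
      alpha_unsat = a_uns,
      z = z_sel
    )
    trace_rows[[t]] <- tibble(
      round = t, z = z_sel, normalizer = normalizer,
      train_error = mean(y * Fvec <= 0)
    )
    if (!is.na(chosen$motif_idx)) {
      rule_motif_idx <- union(rule_motif_idx, chosen$motif_idx)
    }
    if (!is.na(chosen$rs_idx)) {
      rule_rs_idx <- union(rule_rs_idx, chosen$rs_idx)
    }
  }

  structure(
    list(
      rules = bind_rows(rule_rows),
      trace = bind_rows(trace_rows),
      config = config,
      seed = seed,
      n_examples = nex
    ),
    class = "boost_model"
  )
}

#' @export
print.boost_model <- function(x, ...) {
  cat("<boost_model> ", nrow(x$rules), " rules (seed ", x$seed, ")\n", sep = "")
  if (nrow(x$trace)) {
    cat("  final training error: ",
        signif(x$trace$train_error[nrow(x$trace)], 3), "\n", sep = "")
  }
  kinds <- table(x$rules$kind)
  cat("  rule kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Margin score of a boosting model on (gene, condition) pairs
#'
#' The margin `F` is the sum over rules of the satisfied or unsatisfied block
#' weight, depending on whether the rule's condition holds for the pair. Its
#' sign is the predicted expression direction; its magnitude is the model's
#' confidence.
#'
#' @param model A `boost_model`.
#' @param gene,condition Vectors of ids (recycled to a common length).
#' @param features,panel Feature sources (promoters may differ from training).
#' @return Numeric vector of margins.
#' @export
predict_score <- function(model, gene, condition, features, panel) {
  n <- max(length(gene), length(condition))
  gene <- rep_len(gene, n)
  condition <- rep_len(condition, n)
  gi <- match(gene, rownames(features$presence))
  if (anyNA(gi)) {
    abort(paste0("unknown gene(s): ",
                 paste(head(unique(gene[is.na(gi)]), 5), collapse = ", ")))
  }
  ci <- match(condition, panel$conditions)
  if (anyNA(ci)) abort("unknown condition(s) in predict_score")
  Fv <- numeric(n)
  rules <- model$rules
  if (is.null(rules) || nrow(rules) == 0) return(Fv)
  Mp <- features$presence
  for (r in seq_len(nrow(rules))) {
    sat <- rep(TRUE, n)
    if (!is.na(rules$motif[r])) {
      sat <- if (rules$motif[r] %in% colnames(Mp)) {
        sat & Mp[cbind(gi, match(rules$motif[r], colnames(Mp)))]
      } else {
        rep(FALSE, n)
      }
    }
    if (!is.na(rules$tf[r])) {
      if (!rules$tf[r] %in% panel$tfs) abort(paste0("unknown TF: ", rules$tf[r]))
      sat <- sat & (panel$states[rules$tf[r], ci] == rules$state[r])
    }
    Fv <- Fv + ifelse(sat, rules$alpha_sat[r], rules$alpha_unsat[r])
  }
  Fv
}
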