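#' Mean prediction score of a model over an example set
#'
#' The prediction score of a gene set is the arithmetic mean of the model
#' margin over its (gene, condition) examples — typically the pairs called
#' upregulated in the experimental condition(s) of interest.
#'
#' @param model A `boost_model`.
#' @param examples Tibble with `gene` and `condition` columns (non-empty).
#' @param features,panel Feature sources.
#' @return Mean margin (scalar).
#' @export
geneset_prediction_score <- function(model, examples, features, panel) {
  if (nrow(examples) == 0) abort("empty example set")
  mean(predict_score(model, examples$gene, examples$condition, features, panel))
}

#' Examples upregulated in designated conditions
#'
#' Convenience filter: the (gene, condition) pairs whose call is +1 within the
#' chosen experimental conditions.
#'
#' @param examples Example tibble with a `label` column.
#' @param conditions Conditions of interest; default all.
#' @return Filtered tibble.
#' @export
upregulated_examples <- function(examples, conditions = NULL) {
  out <- filter(examples, .data$label == 1)
  if (!is.null(conditions)) out <- filter(out, .data$condition %in% conditions)
  out
}

#' Remove every rule referencing a transcription factor
#'
#' Drops rules whose condition mentions the TF as a regulator state, directly
#' or inside a conjunction. Motif-only rules are untouched (motifs are learned
#' de novo and not attributed to any TF). The input model is not modified.
#'
#' @param model A `boost_model`.
#' @param tf TF id (may be absent from the model).
#' @return A new `boost_model` without the TF's rules.
#' @export
ablate_tf <- function(model, tf) {
  out <- model
  out$rules <- filter(model$rules, is.na(.data$tf) | .data$tf != !!tf)
  out
}

#' Ablation significance score of a transcription factor
#'
#' The drop in mean prediction score over an upregulated example set when all
#' rules referencing the TF are removed from the model. Large positive scores
#' mean the TF's rules push the model toward predicting upregulation for that
#' set.
#'
#' @inheritParams geneset_prediction_score
#' @param tf TF id.
#' @return Significance score (scalar; 0 when the TF is absent from the model).
#' @export
tf_significance <- function(model, tf, examples, features, panel) {
  geneset_prediction_score(model, examples, features, panel) -
    geneset_prediction_score(ablate_tf(model, tf), examples, features, panel)
}

#' Ablation significance of every panel TF
#'
#' @inheritParams tf_significance
#' @return Tibble with columns `tf`, `score`, sorted by descending score.
#' @export
score_all_tfs <- function(model, examples, features, panel) {
  base <- geneset_prediction_score(model, examples, features, panel)
  scores <- map_dbl(panel$tfs, function(tf) {
    base - geneset_prediction_score(ablate_tf(model, tf), examples, features, panel)
  })
  tibble(tf = panel$tfs, score = scores) |>
    arrange(dplyr::desc(.data$score), .data$tf)
}

#' Top-k TFs by significance score
#'
#' @param tf_scores Tibble with columns `tf`, `score`.
#' @param k Number of TFs to keep, default 20. If fewer TFs are available all
#'   are returned with a message.
#' @return Tibble of at most `k` rows, descending score, ties by TF id.
#' @export
top_k_tfs <- function(tf_scores, k = 20) {
  stopifnot(k >= 1)
  if (nrow(tf_scores) < k) {
    inform(paste0("only ", nrow(tf_scores), " TFs available for top-", k))
  }
  tf_scores |>
    arrange(dplyr::desc(.data$score), .data$tf) |>
    slice_head(n = k)
}

#' Consensus significant TFs across independently seeded runs
#'
#' A TF is consensus-significant when it appears in the per-run top-k list in
#' at least `min_runs` runs; consensus TFs are ranked by their mean
#' significance across the runs where they appear and truncated to `final_k`.
#'
#' @param run_lists List of per-run top-k tibbles (columns `tf`, `score`).
#' @param min_runs Minimum supporting runs, default 4.
#' @param final_k Maximum consensus list length, default 10.
#' @return Object of class `consensus_report` (TF part): tibble `tfs` with
#'   columns `tf`, `support`, `mean_score`, plus parameters.
#' @export
consensus_tfs <- function(run_lists, min_runs = 4, final_k = 10) {
  if (length(run_lists) < min_runs) {
    abort("need at least min_runs run lists")
  }
  pooled <- bind_rows(run_lists, .id = "run")
  tfs <- pooled |>
    group_by(.data$tf) |>
    summarise(support = n(), mean_score = mean(.data$score), .groups = "drop") |>
    filter(.data$support >= min_runs) |>
    arrange(dplyr::desc(.data$mean_score), .data$tf) |>
    slice_head(n = final_k)
  structure(
    list(
      tfs = tfs,
      n_runs = length(run_lists),
      params = list(min_runs = min_runs, final_k = final_k)
    ),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> ", nrow(x$tfs), " consensus TFs from ", x$n_runs,
      " runs (min_runs = ", x$params$min_runs, ")\n", sep = "")
  print(x$tfs, n = 10)
  invisible(x)
}

#' Per-gene ablation significance of a TF
#'
#' For each gene, the mean over that gene's examples of the drop in margin
#' after removing the TF's rules — the per-pair score used for edge calling.
#'
#' @inheritParams tf_significance
#' @param examples Example tibble; genes with no examples are omitted.
#' @return Tibble with columns `gene`, `score`.
#' @export
tf_gene_scores <- function(model, tf, examples, features, panel) {
  full <- predict_score(model, examples$gene, examples$condition, features, panel)
  reduced <- predict_score(ablate_tf(model, tf), examples$gene,
                           examples$condition, features, panel)
  tibble(gene = examples$gene, drop = full - reduced) |>
    group_by(.data$gene) |>
    summarise(score = mean(.data$drop), .groups = "drop")
}

#' Per-gene ablation significance for every panel TF
#'
#' @inheritParams tf_gene_scores
#' @return Tibble with columns `tf`, `gene`, `score`.
#' @export
score_all_tf_gene_pairs <- function(model, examples, features, panel) {
  bind_rows(lapply(panel$tfs, function(tf) {
    mutate(tf_gene_scores(model, tf, examples, features, panel), tf = tf)
  })) |>
    select("tf", "gene", "score")
}

#' Consensus TF-gene edges across runs
#'
#' Keeps (TF, gene) pairs whose per-run significance score reaches `threshold`
#' (inclusive) in at least `min_runs` runs.
#'
#' @param per_run_pair_scores List of per-run tibbles with columns `tf`,
#'   `gene`, `score`.
#' @param threshold Score threshold, default 1 (inclusive).
#' @param min_runs Minimum supporting runs, default 4.
#' @return Tibble with columns `tf`, `gene`, `support`, `mean_score`.
#' @export
consensus_edges <- function(per_run_pair_scores, threshold = 1, min_runs = 4) {
  if (length(per_run_pair_scores) < min_runs) {
    abort("need at least min_runs runs")
  }
  bind_rows(per_run_pair_scores, .id = "run") |>
    filter(.data$score >= threshold) |>
    group_by(.data$tf, .data$gene) |>
    summarise(support = n(), mean_score = mean(.data$score), .groups = "drop") |>
    filter(.data$support >= min_runs) |>
    arrange(.data$tf, .data$gene)
}

#' Export a TF-gene network as SIF plus a node-attribute table
#'
#' Writes the standard SIF interaction format (`tf<TAB>regulates<TAB>gene`)
#' and a node table with role (a node acting as both TF and target is labelled
#' `tf`), expression direction, and degree. [read_sif()] round-trips the edge
#' set.
#'
#' @param edges Tibble with columns `tf`, `gene` (non-empty).
#' @param direction Optional named vector or tibble (`node`, `direction`)
#'   giving per-node expression direction (`"up"`, `"down"`); nodes without an
#'   entry get `"none"`.
#' @param sif_path,attr_path Output file paths.
#' @return Invisibly, the node-attribute tibble.
#' @export
export_network <- function(edges, sif_path, attr_path, direction = NULL) {
  if (nrow(edges) == 0) abort("no edges to export")
  sif <- sprintf("%s\tregulates\t%s", edges$tf, edges$gene)
  writeLines(sif, sif_path)
  nodes <- tibble(node = c(edges$tf, edges$gene),
                  role = rep(c("tf", "target"), each = nrow(edges)))
  degree <- count(nodes, .data$node, name = "degree")
  roles <- nodes |>
    group_by(.data$node) |>
    summarise(role = if (any(.data$role == "tf")) "tf" else "target",
              .groups = "drop")
  dir_tbl <- if (is.null(direction)) {
    tibble(node = character(), direction = character())
  } else if (is.data.frame(direction)) {
    as_tibble(direction)
  } else {
    tibble(node = names(direction), direction = unname(direction))
  }
  attr_tbl <- roles |>
    left_join(degree, by = "node") |>
    left_join(dir_tbl, by = "node") |>
    mutate(direction = dplyr::coalesce(.data$direction, "none")) |>
    select("node", "role", "direction", "degree") |>
    arrange(.data$node)
  readr::write_tsv(attr_tbl, attr_path)
  invisible(attr_tbl)
}

#' Read a SIF interaction file back into an edge tibble
#'
#' @param path SIF file written by [export_network()].
#' @return Tibble with columns `tf`, `gene`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) abort(paste0("malformed SIF line ", bad[1]))
  tibble(
    tf = map_chr(parts, 1),
    gene = map_chr(parts, 3)
  )
}
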