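#' Pipeline configuration
#'
#' Collects every numeric threshold the pipeline uses, with the defaults used
#' throughout the package: DE calling at 1.2-fold and q <= 0.05;
#' discretisation at +/-1.5-fold; cross-dataset overlap at 1.5-fold and
#' p < 1e-4; a five-run training protocol with top-20 per-run TFs, consensus
#' support of at least 4 runs, edge threshold 1 and a final consensus list of
#' at most 10; and a whole-genome universe of 21,249 genes.
#'
#' @param fc_de,q_de DE thresholds (inclusive).
#' @param fc_discrete Discretisation threshold (+/-, inclusive).
#' @param overlap_fc,overlap_p Cross-dataset thresholding (fc inclusive, p
#'   strict).
#' @param k_list,rounds,epsilon,subsample,max_depth Learner settings (see
#'   [boost_config()]).
#' @param runs,k_top,min_runs,edge_threshold,final_k Consensus protocol.
#' @param universe_size Gene universe for enrichment/overlap.
#' @param seed Base seed; run `r` of the protocol uses `seed + r - 1`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_de = 1.2, q_de = 0.05, fc_discrete = 1.5,
                            overlap_fc = 1.5, overlap_p = 1e-4,
                            k_list = c(5, 6), rounds = 100, epsilon = NULL,
                            subsample = 0.5, max_depth = 2,
                            runs = 5, k_top = 20, min_runs = 4,
                            edge_threshold = 1, final_k = 10,
                            universe_size = 21249, seed = 1L) {
  stopifnot(fc_de >= 1, q_de > 0, q_de <= 1, fc_discrete >= 1,
            overlap_fc >= 1, overlap_p > 0, rounds >= 1, runs >= 1,
            k_top >= 1, final_k >= 1, universe_size >= 1)
  if (min_runs > runs) abort("min_runs cannot exceed runs")
  structure(
    list(
      fc_de = fc_de, q_de = q_de, fc_discrete = fc_discrete,
      overlap_fc = overlap_fc, overlap_p = overlap_p,
      k_list = k_list, rounds = rounds, epsilon = epsilon,
      subsample = subsample, max_depth = max_depth,
      runs = runs, k_top = k_top, min_runs = min_runs,
      edge_threshold = edge_threshold, final_k = final_k,
      universe_size = universe_size, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path Optional file path.
#' @return JSON string or (invisibly) the path; `config_from_json` returns the
#'   restored `pipeline_config`.
#' @export
config_to_json <- function(config, path = NULL) {
  json <- jsonlite::toJSON(config[!map_lgl(config, is.null)],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Run the analysis pipeline end to end
#'
#' Executes the stage order: discretise (fold changes against the reference
#' group's median, replicate-consistency filter), differential expression,
#' optional enrichment and overlap, multi-seed boosting, TF ablation scoring,
#' consensus, edge calling and network export. Every artefact is written under
#' `out_dir` together with a config snapshot, and outputs are deterministic
#' functions of (inputs, config): re-running with the same seed reproduces
#' them byte for byte.
#'
#' @param inputs Named list. Either `expression` + `design` (triggering the
#'   discretise and DE stages; `reference_group`/`experimental_group` name the
#'   baseline and contrast groups, defaults `"control"`/`"high_dose"`) or a
#'   pre-discretised condition-level `calls` tibble. For training stages:
#'   `promoters` (named character vector) and `tfs` (character vector).
#'   Optional: `annotation` (gene/term tibble) for enrichment, `gene_sets`
#'   (named list) for overlap.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run; default all stages whose
#'   inputs are present. Known stages: `"discretize"`, `"de"`, `"enrich"`,
#'   `"overlap"`, `"train"`, `"consensus"`, `"network"`.
#' @return Invisibly, a list with the main in-memory results (`calls`,
#'   `de`, `enrichment`, `overlap`, `runs`, `consensus`, `edges`) and
#'   `paths` of written artefacts.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir,
                         stages = NULL) {
  all_stages <- c("discretize", "de", "enrich", "overlap", "train",
                  "consensus", "network")
  if (is.null(stages)) {
    stages <- character(0)
    if (!is.null(inputs$expression)) stages <- c("discretize", "de")
    if (!is.null(inputs$calls)) stages <- c(stages, character(0))
    if (!is.null(inputs$annotation)) stages <- c(stages, "enrich")
    if (!is.null(inputs$gene_sets)) stages <- c(stages, "overlap")
    if (!is.null(inputs$promoters) && !is.null(inputs$tfs)) {
      stages <- c(stages, "train", "consensus", "network")
    }
  }
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))

  # fail before any work if a requested stage lacks its inputs
  need <- function(stage, ok, what) {
    if (stage %in% stages && !ok) {
      abort(paste0("stage '", stage, "' requested but missing input: ", what))
    }
  }
  have_expr <- !is.null(inputs$expression) && !is.null(inputs$design)
  have_calls <- !is.null(inputs$calls) || "discretize" %in% stages
  need("discretize", have_expr, "expression + design")
  need("de", have_expr, "expression + design")
  need("enrich", !is.null(inputs$annotation) && (have_expr || !is.null(inputs$geneset)),
       "annotation (and a DE gene set)")
  need("overlap", !is.null(inputs$gene_sets), "gene_sets")
  need("train", (!is.null(inputs$promoters)) && (!is.null(inputs$tfs)) && have_calls,
       "promoters + tfs + calls (or expression to discretise)")
  need("consensus", "train" %in% stages, "train stage")
  need("network", "consensus" %in% stages, "consensus stage")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(out_dir, "config.json"))
  config_to_json(config, paths$config)
  res <- list()

  reference_group <- inputs$reference_group %||% "control"
  experimental_group <- inputs$experimental_group %||% "high_dose"

  calls <- inputs$calls
  if ("discretize" %in% stages) {
    design <- inputs$design
    ref_samples <- design$sample[design$group == reference_group]
    fc <- median_reference_fold_change(inputs$expression, ref_samples)
    sample_calls <- discretize_calls(fc, up = config$fc_discrete,
                                     down = -config$fc_discrete)
    filt <- filter_inconsistent_replicates(sample_calls, design)
    calls <- filt$calls
    inform(paste0("discretize: ", nrow(calls), " consistent genes, ",
                  length(filt$dropped), " dropped"))
    paths$calls <- file.path(out_dir, "calls.tsv")
    write_expression_tsv(calls, paths$calls)
    writeLines(filt$dropped, file.path(out_dir, "dropped_genes.txt"))
  }
  res$calls <- calls

  if ("de" %in% stages) {
    res$de <- de_table(inputs$expression, inputs$design,
                       contrast = experimental_group,
                       reference = reference_group,
                       fc_cut = config$fc_de, q_cut = config$q_de)
    inform(paste0("de: ", sum(res$de$is_de), " genes called"))
    paths$de <- file.path(out_dir, "de_table.tsv")
    readr::write_tsv(res$de, paths$de)
  }

  if ("enrich" %in% stages) {
    geneset <- inputs$geneset %||% res$de$gene[res$de$is_de]
    res$enrichment <- enrich_terms(geneset, inputs$annotation,
                                   universe = config$universe_size)
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(res$enrichment, paths$enrichment)
  }

  if ("overlap" %in% stages) {
    sets <- inputs$gene_sets
    res$overlap <- venn_partition(sets)
    venn_out <- res$overlap |>
      mutate(genes = map_chr(.data$genes, paste, collapse = ",")) |>
      select("region", "n", "genes")
    paths$overlap <- file.path(out_dir, "venn.tsv")
    readr::write_tsv(venn_out, paths$overlap)
    if (length(sets) == 2) {
      k <- length(intersect(sets[[1]], sets[[2]]))
      res$overlap_p <- hypergeometric_overlap(
        length(unique(sets[[1]])), length(unique(sets[[2]])), k,
        config$universe_size
      )
    }
  }

  if ("train" %in% stages) {
    features <- extract_kmer_features(inputs$promoters, k_list = config$k_list)
    panel <- regulator_panel(calls, inputs$tfs)
    target_genes <- setdiff(calls[[1]], inputs$tfs)
    examples <- build_examples(calls, target_genes = target_genes)
    up <- upregulated_examples(examples, inputs$experimental_conditions)
    bcfg <- boost_config(k_list = config$k_list, epsilon = config$epsilon,
                         subsample = config$subsample,
                         max_depth = config$max_depth)
    res$runs <- map(seq_len(config$runs), function(r) {
      run_seed <- config$seed + r - 1L
      model <- boost_train(examples, features, panel,
                           rounds = config$rounds, seed = run_seed,
                           config = bcfg)
      list(
        run = r, seed = run_seed, model = model,
        tf_scores = score_all_tfs(model, up, features, panel),
        pair_scores = score_all_tf_gene_pairs(model, up, features, panel)
      )
    })
    paths$runs <- map_chr(res$runs, function(rr) {
      p <- file.path(out_dir, sprintf("run%02d.json", rr$run))
      payload <- list(run = rr$run, seed = rr$seed,
                      tf_scores = rr$tf_scores, pair_scores = rr$pair_scores)
      writeLines(jsonlite::toJSON(payload, dataframe = "columns",
                                  auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), p)
      model_to_json(rr$model, file.path(out_dir, sprintf("model%02d.json", rr$run)))
      p
    })
  }

  if ("consensus" %in% stages) {
    top_lists <- map(res$runs, function(rr) top_k_tfs(rr$tf_scores, k = config$k_top))
    res$consensus <- consensus_tfs(top_lists, min_runs = config$min_runs,
                                   final_k = config$final_k)
    res$edges <- consensus_edges(map(res$runs, "pair_scores"),
                                 threshold = config$edge_threshold,
                                 min_runs = config$min_runs)
    inform(paste0("consensus: ", nrow(res$consensus$tfs), " TFs, ",
                  nrow(res$edges), " edges"))
    paths$consensus <- file.path(out_dir, "consensus.json")
    writeLines(jsonlite::toJSON(
      list(tfs = res$consensus$tfs, edges = res$edges,
           params = res$consensus$params, n_runs = res$consensus$n_runs),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE
    ), paths$consensus)
    readr::write_tsv(res$consensus$tfs, file.path(out_dir, "consensus_tfs.tsv"))
    readr::write_tsv(res$edges, file.path(out_dir, "consensus_edges.tsv"))
  }

  if ("network" %in% stages && nrow(res$edges) > 0) {
    m <- .as_value_matrix(calls)
    dir_call <- sign(rowSums(m))
    direction <- tibble(
      node = rownames(m),
      direction = dplyr::case_when(dir_call > 0 ~ "up",
                                   dir_call < 0 ~ "down",
                                   TRUE ~ "none")
    )
    paths$sif <- file.path(out_dir, "network.sif")
    paths$node_attrs <- file.path(out_dir, "node_attributes.tsv")
    export_network(res$edges, paths$sif, paths$node_attrs,
                   direction = direction)
  }

  res$paths <- paths
  invisible(res)
}
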