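#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols rename distinct n
#'   slice_head across pull count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap keep
#' @importFrom stats median oneway.test p.adjust pchisq phyper rnorm runif
#'   setNames
#' @importFrom utils head modifyList
#' @importFrom methods is
NULL

# first column of an expression tibble is the id column; the rest are samples
.id_col <- function(data) names(data)[1]

.sample_cols <- function(data) setdiff(names(data), .id_col(data))

.as_value_matrix <- function(data) {
  m <- as.matrix(data[, .sample_cols(data), drop = FALSE])
  rownames(m) <- data[[.id_col(data)]]
  storage.mode(m) <- "double"
  m
}

.matrix_to_tbl <- function(m, id_name = "gene") {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_name := rownames(m)), out)
}

.check_design <- function(design, samples = NULL) {
  stopifnot(is.data.frame(design))
  need <- c("sample", "group")
  if (!all(need %in% names(design))) {
    abort("design must have columns 'sample' and 'group' (optionally 'replicate')")
  }
  if (anyDuplicated(design$sample)) abort("duplicate sample ids in design")
  if (!is.null(samples)) {
    missing <- setdiff(samples, design$sample)
    if (length(missing)) {
      abort(paste0("samples missing from design: ", paste(missing, collapse = ", ")))
    }
  }
  invisible(design)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289) %% 2147483647)
}
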