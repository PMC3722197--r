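#' Read a tab-separated expression matrix
#'
#' First column holds row ids, the header row holds sample ids; cells are
#' numeric. Lines starting with `#` are ignored. Ragged rows, duplicate ids
#' and non-numeric cells raise errors naming the offending line.
#'
#' @param path File path.
#' @return Tibble (first column ids, numeric sample columns).
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) abort("empty data section")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (length(header) < 2) abort("header must name at least one sample")
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample id: ",
                 samples[duplicated(samples)][1]))
  }
  body <- parts[-1]
  bad <- which(lengths(body) != length(header))
  if (length(bad)) {
    abort(paste0("ragged row at line ", line_no[-1][bad[1]]))
  }
  ids <- map_chr(body, 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate row id: ", ids[duplicated(ids)][1]))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(map(body, function(p) p[-1]))),
           nrow = length(body), byrow = TRUE,
           dimnames = list(ids, samples))
  )
  if (anyNA(vals)) {
    bad_row <- which(rowSums(is.na(vals)) > 0)[1]
    abort(paste0("non-numeric cell at line ", line_no[-1][bad_row]))
  }
  out <- .matrix_to_tbl(vals, header[1])
  out
}

#' Write an expression tibble as TSV
#'
#' @param data Expression tibble.
#' @param path Output path.
#' @export
write_expression_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read a sample design sidecar table
#'
#' Three tab-separated columns: sample, group, replicate.
#'
#' @param path File path.
#' @return Tibble with columns `sample`, `group`, `replicate`.
#' @export
read_design_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       comment = "#")
  if (!all(c("sample", "group", "replicate") %in% names(d))) {
    abort("design file needs columns sample, group, replicate")
  }
  .check_design(d)
  d
}

#' Read promoter sequences from FASTA
#'
#' Record ids are the header text up to the first whitespace; sequences are
#' upper-cased and must use only A/C/G/T/N. Duplicate ids, empty sequences and
#' other letters raise errors naming the record.
#'
#' @param path FASTA file path.
#' @return Named character vector of promoter sequences.
#' @export
read_fasta_promoters <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate promoter id: ", ids[duplicated(ids)][1]))
  }
  if (any(Biostrings::width(seqs) == 0)) {
    abort(paste0("empty sequence for record: ",
                 ids[Biostrings::width(seqs) == 0][1]))
  }
  chars <- toupper(as.character(seqs))
  ok <- !grepl("[^ACGTN]", chars)
  if (!all(ok)) {
    abort(paste0("illegal character in record: ", ids[!ok][1]))
  }
  setNames(chars, ids)
}

#' Write promoters as FASTA
#'
#' @param promoters Named character vector.
#' @param path Output path.
#' @export
write_fasta_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path
  )
  invisible(path)
}

#' Read a one-id-per-line gene list
#'
#' @param path File path; `#` comment lines and blanks are skipped.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path TSV with columns `gene` and `term` (header required).
#' @return Tibble.
#' @export
read_annotation_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       comment = "#")
  if (!all(c("gene", "term") %in% names(d))) {
    abort("annotation file needs columns gene, term")
  }
  d
}

#' Serialise a boosting model to JSON
#'
#' @param model A `boost_model`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(
    rules = model$rules,
    trace = model$trace,
    config = model$config[!map_lgl(model$config, is.null)],
    seed = model$seed,
    n_examples = model$n_examples
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Restore a boosting model from JSON
#'
#' @param path File written by [model_to_json()] (or a JSON string).
#' @return A `boost_model`.
#' @export
model_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  cfg <- do.call(boost_config, payload$config[names(payload$config) %in%
                                                names(formals(boost_config))])
  structure(
    list(
      rules = as_tibble(payload$rules),
      trace = as_tibble(payload$trace),
      config = cfg,
      seed = payload$seed,
      n_examples = payload$n_examples
    ),
    class = "boost_model"
  )
}
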