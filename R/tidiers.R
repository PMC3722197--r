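#' @importFrom generics tidy glance
NULL

#' Tidy a boosting model into its rule table
#'
#' @param x A `boost_model`.
#' @param ... Unused.
#' @return Tibble with one row per rule: `round`, `kind`, `motif`, `tf`,
#'   `state`, `alpha_sat`, `alpha_unsat`, `z`.
#' @method tidy boost_model
#' @export
tidy.boost_model <- function(x, ...) {
  as_tibble(x$rules)
}

#' One-row summary of a boosting model
#'
#' @param x A `boost_model`.
#' @param ... Unused.
#' @return Tibble with `rounds`, `n_examples`, `train_error` (final),
#'   `z_product` (the multiplicative bound on training error), `n_motif`,
#'   `n_regulator`, `n_conjunction` rule counts, `seed`.
#' @method glance boost_model
#' @export
glance.boost_model <- function(x, ...) {
  kinds <- table(factor(x$rules$kind,
                        levels = c("motif", "regulator_state", "conjunction")))
  tibble(
    rounds = nrow(x$rules),
    n_examples = x$n_examples,
    train_error = if (nrow(x$trace)) x$trace$train_error[nrow(x$trace)] else NA_real_,
    z_product = prod(x$trace$z),
    n_motif = unname(kinds[["motif"]]),
    n_regulator = unname(kinds[["regulator_state"]]),
    n_conjunction = unname(kinds[["conjunction"]]),
    seed = x$seed
  )
}

#' Tidy a consensus report into its TF table
#'
#' @param x A `consensus_report`.
#' @param ... Unused.
#' @return Tibble with `tf`, `support`, `mean_score`.
#' @method tidy consensus_report
#' @export
tidy.consensus_report <- function(x, ...) {
  x$tfs
}

#' One-row summary of a consensus report
#'
#' @param x A `consensus_report`.
#' @param ... Unused.
#' @return Tibble with `n_consensus`, `n_runs`, `min_runs`, `final_k`.
#' @method glance consensus_report
#' @export
glance.consensus_report <- function(x, ...) {
  tibble(
    n_consensus = nrow(x$tfs),
    n_runs = x$n_runs,
    min_runs = x$params$min_runs,
    final_k = x$params$final_k
  )
}

#' @export
generics::tidy

#' @export
generics::glance
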