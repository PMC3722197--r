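#' Extract k-mer presence features from promoter sequences
#'
#' Scans each promoter for every k-mer of the requested lengths and records
#' binary presence. With `with_revcomp = TRUE` a k-mer and its reverse
#' complement are folded into one canonical motif (the lexicographically
#' smaller of the pair), so a motif is present if either strand carries it.
#' Windows containing `N` never match. Only motifs occurring in at least one
#' promoter are kept.
#'
#' @param promoters Named character vector (or `Biostrings::DNAStringSet`) of
#'   uppercase promoter sequences over A/C/G/T/N.
#' @param k_list Integer vector of k-mer lengths, each `>= 3`; default
#'   `c(5, 6)`.
#' @param with_revcomp Fold reverse complements? Default `TRUE`.
#' @return Object of class `kmer_features`: a list with `presence` (logical
#'   gene x motif matrix), `k_list`, `with_revcomp`.
#' @export
extract_kmer_features <- function(promoters, k_list = c(5, 6),
                                  with_revcomp = TRUE) {
  if (any(k_list < 3)) abort("all k-mer lengths must be >= 3")
  seqs <- if (methods::is(promoters, "DNAStringSet")) {
    promoters
  } else {
    Biostrings::DNAStringSet(toupper(unlist(promoters)))
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("promoters must carry unique names")
  }
  lens <- Biostrings::width(seqs)
  if (any(lens == 0)) abort("empty promoter sequence")
  blocks <- map(k_list, function(k) {
    if (all(lens < k)) abort(paste0("k = ", k, " exceeds every promoter length"))
    counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
    pres <- counts > 0
    if (with_revcomp) {
      kmers <- colnames(pres)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
      canon <- pmin(kmers, rc)
      pres <- t(rowsum(t(pres * 1L), group = canon)) > 0
    }
    pres
  })
  presence <- do.call(cbind, blocks)
  rownames(presence) <- names(seqs)
  presence <- presence[, colSums(presence) > 0, drop = FALSE]
  presence <- presence[, order(colnames(presence)), drop = FALSE]
  structure(
    list(presence = presence, k_list = k_list, with_revcomp = with_revcomp),
    class = "kmer_features"
  )
}

#' @export
print.kmer_features <- function(x, ...) {
  cat("<kmer_features> ", nrow(x$presence), " promoters x ",
      ncol(x$presence), " motifs (k in {", paste(x$k_list, collapse = ", "),
      "}, revcomp ", if (x$with_revcomp) "on" else "off", ")\n", sep = "")
  invisible(x)
}

#' Canonical form of a motif under reverse complementation
#'
#' @param motif Character vector of DNA k-mers.
#' @return The lexicographically smaller of each k-mer and its reverse
#'   complement.
#' @export
canonical_motif <- function(motif) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(motif)))
  pmin(motif, rc)
}
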