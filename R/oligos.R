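#' Load the packaged lambda oligonucleotide catalog
#'
#' Returns the synthetic spike-in and control oligo sequences shipped with the
#' package: a six-member single-stranded ladder (`lambda_30` ... `lambda_200`)
#' used to measure length-dependent extraction recovery, plus the
#' `Lambda_dsDNA_Control` and `Lambda_ssDNA_Control` sequences used as
#' digestion controls. Sequences are stored verbatim as published, including
#' degenerate `N` positions.
#'
#' Note the published strings do not all measure exactly their nominal sizes:
#' the ladder records measure 30/51/75/100/150/198 nt (each within 2 nt of
#' the name), the dsDNA control 459 nt (nominal 460), and the ssDNA control
#' 349 nt (nominally reported as both 350 and 356 nt). The catalog keeps the
#' printed strings rather than editing them; `ladder_sizes()` reports the
#' nominal sizes used to label recovery results.
#'
#' @return An object of class `oligo_catalog`: a named character vector of
#'   sequences over `{A,C,G,T,N}`.
#' @examples
#' cat <- load_oligos()
#' nchar(cat[["lambda_30"]])  # 30
#' @export
load_oligos <- function() {
  fa <- system.file("extdata", "lambda_oligos.fasta", package = "uscfseq",
                    mustWork = TRUE)
  dss <- Biostrings::readDNAStringSet(fa)
  out <- stats::setNames(as.character(dss), names(dss))
  structure(out, class = "oligo_catalog")
}

#' @rdname load_oligos
#' @param catalog an `oligo_catalog`.
#' @return `ladder_sizes()`: named integer vector mapping ladder record names
#'   to their nominal sizes (30, 50, 75, 100, 150, 200).
#' @export
ladder_sizes <- function(catalog = load_oligos()) {
  nm <- grep("^lambda_[0-9]+$", names(catalog), value = TRUE)
  sz <- as.integer(sub("^lambda_", "", nm))
  stats::setNames(sz[order(sz)], nm[order(sz)])
}

#' @export
print.oligo_catalog <- function(x, ...) {
  cat("Lambda oligo catalog:", length(x), "records\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %4d nt\n", nm, nchar(x[[nm]])))
  invisible(x)
}
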