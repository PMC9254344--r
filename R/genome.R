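#' Define a synthetic genome model
#'
#' A genome model is an ordered set of contigs with declared lengths, exactly
#' one of which is flagged as the mitochondrial contig. The default build has
#' two autosome-like contigs of 10 Mb each plus a 16,569 bp mitochondrial
#' contig, so the mitochondrial base-pair fraction is
#' 16,569 / 20,016,569 ~= 8.28e-4 (< 0.1%), matching the minor mitochondrial
#' contribution expected of plasma cfDNA.
#'
#' @param contigs named integer vector of contig lengths (bp), in order.
#' @param mito_name name of the mitochondrial contig; must be present in
#'   `contigs`.
#' @return An object of class `genome_model`: a list with `contigs`
#'   (data.frame `name`, `length`) and `mito_name`.
#' @examples
#' gm <- genome_model()
#' mito_fraction(gm)
#' @export
genome_model <- function(contigs = c(chrA = 10000000L, chrB = 10000000L,
                                     chrM = 16569L),
                         mito_name = "chrM") {
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig name: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]),
               collapse = ", "))
  lens <- as.numeric(contigs)
  if (any(!is.finite(lens)) || any(lens < 1))
    stop("contig lengths must be >= 1")
  if (!mito_name %in% names(contigs))
    stop("mito_name '", mito_name, "' is not a declared contig")
  structure(
    list(contigs = data.frame(name = names(contigs), length = lens,
                              stringsAsFactors = FALSE),
         mito_name = mito_name),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic genome model:", nrow(x$contigs), "contigs,",
      format(sum(x$contigs$length), big.mark = ","), "bp total\n")
  for (i in seq_len(nrow(x$contigs)))
    cat(sprintf("  %-8s %12s bp%s\n", x$contigs$name[i],
                format(x$contigs$length[i], big.mark = ","),
                if (x$contigs$name[i] == x$mito_name) "  [mitochondrial]" else ""))
  invisible(x)
}

#' @rdname genome_model
#' @param genome a `genome_model`.
#' @export
mito_fraction <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  len <- genome$contigs$length
  len[genome$contigs$name == genome$mito_name] / sum(len)
}

contig_length <- function(genome, contig) {
  i <- match(contig, genome$contigs$name)
  if (anyNA(i)) stop("unknown contig: ",
                     paste(unique(contig[is.na(i)]), collapse = ", "))
  genome$contigs$length[i]
}

#' Build a synthetic genome and write its FASTA
#'
#' Generates uniform-random nucleotide sequence for each declared contig and
#' writes it to `fasta`. The same seed always yields byte-identical output.
#'
#' @param genome a `genome_model` (see [genome_model()]).
#' @param fasta output FASTA path, or `NULL` to skip sequence generation and
#'   only validate/return the model (coordinates do not require sequence).
#' @param seed integer seed controlling sequence content.
#' @return The `genome_model`, invisibly if `fasta` was written.
#' @export
build_genome <- function(genome = genome_model(), fasta = NULL, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(fasta)) return(genome)
  set.seed(seed)
  seqs <- lapply(genome$contigs$length, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- genome$contigs$name
  Biostrings::writeXStringSet(dss, fasta)
  invisible(genome)
}

#' Read a genome model back from a FASTA file
#'
#' @param fasta FASTA path.
#' @param mito_name mitochondrial contig name (must be present).
#' @return A `genome_model` with contig lengths taken from the sequences.
#' @export
read_genome_fasta <- function(fasta, mito_name = "chrM") {
  dss <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(dss))
  genome_model(stats::setNames(Biostrings::width(dss), nm),
               mito_name = mito_name)
}
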