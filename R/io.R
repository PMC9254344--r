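#' Write / read a fragment table TSV
#'
#' The documented columns are contig, start, end, strand, state, nicks,
#' duplex_length, umi, population, treatment_history (plus library_size when
#' present). Files round-trip exactly.
#'
#' @param fragments a [fragment_set()].
#' @param path file path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_set"))
  df <- as.data.frame(fragments)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @param genome optional [genome_model()] for coordinate validation.
#' @export
read_fragments_tsv <- function(path, genome = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE,
                          na.strings = "NA")
  for (col in c("nicks", "treatment_history", "umi"))
    if (col %in% names(df)) {
      df[[col]] <- as.character(df[[col]])
      df[[col]][is.na(df[[col]])] <- ""
    }
  fragment_set(df, genome)
}

#' Write a fragment set as BED6+
#'
#' BED columns: contig, start, end, name (`population:state`), score
#' (length), strand; native 0-based half-open coordinates.
#'
#' @param fragments a [fragment_set()].
#' @param path file path.
#' @export
write_fragments_bed <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_set"))
  df <- data.frame(fragments$contig, fragments$start, fragments$end,
                   paste0(fragments$population, ":", fragments$state),
                   fragment_lengths(fragments), fragments$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A serializable description of a full replay: seed plus the parameters of
#' each stage. Round-trips exactly through YAML.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param n_total,frac_uscf,nick_fraction main population parameters
#'   (forwarded to [population_config()]).
#' @param n_genes annotation density.
#' @param extraction extraction method name or `NULL` to skip.
#' @param spikein_copies ladder spike-in copies per size (0 to skip).
#' @param treatments list of lists with `enzyme` and optional `efficiency`,
#'   `s1_trim_total` entries, applied in order.
#' @param library `NULL`, or a list with `kit` and optional
#'   `heat_denaturation` passed to [library_prep()].
#' @param genome_contigs named lengths for [genome_model()].
#' @param mito_name mitochondrial contig name.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_total = 50000L,
                       frac_uscf = 0.5,
                       nick_fraction = 0.25,
                       n_genes = 400L,
                       extraction = NULL,
                       spikein_copies = 0L,
                       treatments = list(),
                       library = NULL,
                       genome_contigs = c(chrA = 10000000, chrB = 10000000,
                                          chrM = 16569),
                       mito_name = "chrM") {
  structure(list(seed = as.integer(seed), n_total = as.integer(n_total),
                 frac_uscf = as.numeric(frac_uscf),
                 nick_fraction = as.numeric(nick_fraction),
                 n_genes = as.integer(n_genes),
                 extraction = extraction,
                 spikein_copies = as.integer(spikein_copies),
                 treatments = treatments, library = library,
                 genome_contigs = as.list(genome_contigs),
                 mito_name = mito_name),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- do.call(run_config, x[setdiff(names(x),
                                       c("treatments", "library",
                                         "extraction", "genome_contigs"))])
  cfg$treatments <- if (is.null(x$treatments)) list() else x$treatments
  cfg$library <- x$library
  cfg$extraction <- x$extraction
  if (!is.null(x$genome_contigs)) cfg$genome_contigs <- x$genome_contigs
  cfg
}
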