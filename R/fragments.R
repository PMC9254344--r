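#' Fragment tables
#'
#' The universal currency between the simulator, the treatment operators and
#' the analysis statistics is a fragment table: one row per simulated cfDNA
#' molecule with columns
#' \describe{
#'   \item{contig}{contig name (genome contig or `lambda_spike`)}
#'   \item{start,end}{0-based half-open genomic interval; `end - start` is the
#'     molecule length as observed after single-stranded denaturation (bp for
#'     a duplex, nt for a single strand)}
#'   \item{strand}{`+` or `-`}
#'   \item{state}{`ss`, `ds_intact`, or `ds_nicked`}
#'   \item{nicks}{comma-separated within-fragment nick offsets, strictly
#'     inside `(0, length)`; empty unless `state == "ds_nicked"`}
#'   \item{duplex_length}{for `ds_nicked`, the full duplex length of which the
#'     observed interval is the post-denaturation piece; `NA` otherwise}
#'   \item{umi}{8-mer unique molecular identifier}
#'   \item{population}{generative label `uscf`, `mncf`, or `spikein`}
#'   \item{treatment_history}{comma-separated record of operators applied}
#' }
#'
#' @param df data.frame with the columns above.
#' @param genome optional [genome_model()]; when given, coordinates are
#'   checked against contig lengths (the spike-in contig is exempt).
#' @return `df` validated, with class `fragment_set` prepended.
#' @export
fragment_set <- function(df, genome = NULL) {
  req <- c("contig", "start", "end", "strand", "state", "nicks",
           "duplex_length", "umi", "population", "treatment_history")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("schema error: fragment table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$end - df$start < 1))
      stop("fragment intervals must satisfy start >= 0 and length >= 1")
    if (!all(df$state %in% c("ss", "ds_intact", "ds_nicked")))
      stop("unknown strandedness state")
    if (!all(df$population %in% c("uscf", "mncf", "spikein")))
      stop("unknown population label")
    nicked <- df$state == "ds_nicked"
    if (any(nicked & df$nicks == ""))
      stop("ds_nicked fragments must carry nick offsets")
    if (!is.null(genome)) {
      gi <- df$contig %in% genome$contigs$name
      if (any(gi) && any(df$end[gi] > contig_length(genome, df$contig[gi])))
        stop("fragment end beyond contig length")
    }
  }
  if (!inherits(df, "fragment_set")) class(df) <- c("fragment_set", class(df))
  df
}

empty_fragment_set <- function() {
  fragment_set(data.frame(
    contig = character(), start = numeric(), end = numeric(),
    strand = character(), state = character(), nicks = character(),
    duplex_length = numeric(), umi = character(), population = character(),
    treatment_history = character(), stringsAsFactors = FALSE))
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("Fragment set:", nrow(x), "molecules\n")
  if (nrow(x)) {
    cat("  populations:",
        paste(sprintf("%s=%d", names(table(x$population)),
                      as.integer(table(x$population))), collapse = " "), "\n")
    cat("  states:     ",
        paste(sprintf("%s=%d", names(table(x$state)),
                      as.integer(table(x$state))), collapse = " "), "\n")
    cat("  length range:", min(fragment_lengths(x)), "-",
        max(fragment_lengths(x)), "\n")
  }
  invisible(x)
}

#' @rdname fragment_set
#' @param fragments a `fragment_set`.
#' @return `fragment_lengths()`: integer vector `end - start`.
#' @export
fragment_lengths <- function(fragments) {
  as.integer(fragments$end - fragments$start)
}

#' @rdname fragment_set
#' @return `fragment_midpoints()`: 0-based midpoint `floor((start + end)/2)`.
#' @export
fragment_midpoints <- function(fragments) {
  floor((fragments$start + fragments$end) / 2)
}

# append a tag to the treatment_history column
note_treatment <- function(fragments, tag) {
  h <- fragments$treatment_history
  fragments$treatment_history <- ifelse(h == "", tag, paste(h, tag, sep = ","))
  fragments
}

random_umis <- function(n, width = 8L) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
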