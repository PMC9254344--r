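#' Synthesize an electropherogram trace from a library
#'
#' Emulates a capillary-electrophoresis readout: each library molecule
#' contributes a Gaussian kernel centered at its `library_size`, discretized
#' on a 1 bp axis (default 35-1000 bp). The integrated intensity is
#' proportional to the number of molecules.
#'
#' @param library a [prepare_library()] output (must carry `library_size`).
#' @param kernel_sd Gaussian kernel standard deviation in bp (default 5,
#'   matching typical band widths).
#' @param axis integer bp axis.
#' @return list of class `trace` with `sizes` and `intensity`.
#' @export
synthesize_trace <- function(library, kernel_sd = 5, axis = 35:1000) {
  if (!nrow(library)) stop("empty library: no trace")
  if (is.null(library$library_size))
    stop("schema error: fragment table is missing column(s): library_size")
  stopifnot(kernel_sd > 0, all(diff(axis) > 0))
  tab <- table(library$library_size)
  sizes <- as.numeric(names(tab))
  counts <- as.numeric(tab)
  intensity <- as.numeric(
    outer(axis, sizes, function(a, s) stats::dnorm(a, s, kernel_sd)) %*%
      counts)
  structure(list(sizes = as.integer(axis), intensity = intensity),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat("Electropherogram trace:", length(x$sizes), "points, axis",
      min(x$sizes), "-", max(x$sizes), "bp; peak at",
      x$sizes[which.max(x$intensity)], "bp\n")
  invisible(x)
}

#' Quantify the ultrashort share of an electropherogram
#'
#' Computes `area(A) / (area(A) + area(B))` by trapezoidal integration on
#' the 1 bp axis, where region A is the ultrashort library band (default
#' inclusive 180-250 bp) and region B the mononucleosomal band (default
#' inclusive 251-350 bp; set `region_b = c(250, 350)` for the alternative
#' published variant).
#'
#' @param trace a `trace`.
#' @param region_a,region_b inclusive integer bp bounds.
#' @return the ultrashort fraction in `[0, 1]`.
#' @export
quantify_trace <- function(trace, region_a = c(180, 250),
                           region_b = c(251, 350)) {
  stopifnot(inherits(trace, "trace"))
  rng <- range(trace$sizes)
  if (region_a[1] < rng[1] || region_b[2] > rng[2])
    stop("quantification regions outside trace axis")
  area <- function(r) {
    i <- which(trace$sizes >= r[1] & trace$sizes <= r[2])
    y <- trace$intensity[i]
    sum((y[-1] + y[-length(y)]) / 2)
  }
  a <- area(region_a); b <- area(region_b)
  if (a + b == 0) stop("no intensity in the quantification regions")
  a / (a + b)
}

#' Convert a library size to an insert size
#'
#' `insert = library_size - adapter_total`; library sizes at or below the
#' adapter total are in the adapter-dimer regime and are an error.
#'
#' @param library_size observed library molecule size in bp.
#' @param adapter_total total adapter bp (default 150).
#' @return insert size in bp.
#' @examples
#' library_to_insert(200)  # 50
#' @export
library_to_insert <- function(library_size, adapter_total = 150) {
  if (any(library_size <= adapter_total))
    stop("library_size <= adapter_total: adapter-dimer regime")
  library_size - adapter_total
}

#' Write / read a trace as 2-column TSV
#'
#' @param trace a `trace`.
#' @param path file path.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(data.frame(size = trace$sizes,
                                intensity = trace$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (any(df$intensity < 0)) stop("trace intensities must be non-negative")
  if (any(diff(df$size) <= 0)) stop("trace axis must be strictly increasing")
  structure(list(sizes = as.integer(df$size),
                 intensity = as.numeric(df$intensity)), class = "trace")
}
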