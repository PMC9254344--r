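#' Configure the simulated cfDNA population
#'
#' Parameterizes the bimodal fragmentome mixture: an ultrashort
#' single-stranded (uscf) population with modal length 50 nt on support
#' 25-100 nt, and a mononucleosomal double-stranded (mncf) population with
#' modal length 160 bp on support 101-250 bp. A fraction `nick_fraction` of
#' mncf molecules is generated as nicked duplexes (`ds_nicked`) whose
#' observed, post-denaturation lengths fall on a 10 bp ladder
#' (150/140/130/120/110 bp with mild geometric decay and +-1 bp jitter),
#' producing the 10 bp periodicity on the left shoulder of the 160 bp peak;
#' their full duplex length is drawn from the intact law truncated above the
#' ladder piece.
#'
#' Both length laws are discretized two-sided exponential (Laplace-type)
#' peaks: a smooth wide bell has a nearly flat discrete top, which would not
#' pin the sample mode to a single length at realistic depths, whereas the
#' exponential peak concentrates enough mass at the modal length that the
#' sample mode is stable. The uscf law is asymmetric (heavier right tail), so
#' mass rises gently toward 100 nt.
#'
#' Element-placement enrichment is expressed as per-class multipliers of the
#' genomic baseline, optionally modulated for the uscf population by
#' piecewise-linear multiplier curves over fragment length (knots at
#' 25/45/55/100 nt): the promoter multiplier peaks at 45-55 nt and the
#' intergenic multiplier rises toward 100 nt. With all multipliers equal to 1
#' placement is uniform over the genome.
#'
#' @param n_total number of fragments to simulate.
#' @param frac_uscf mixture fraction of the uscf population (the in-plasma
#'   abundance ratio of the two populations is not established, so this
#'   stays configurable).
#' @param uscf_mode,uscf_range,uscf_scale_left,uscf_scale_right uscf length
#'   law: mode, inclusive support, and left/right exponential scales (nt).
#' @param mncf_mode,mncf_range,mncf_scale intact mncf length law (bp).
#' @param nick_fraction fraction of mncf molecules generated as `ds_nicked`.
#' @param ladder,ladder_decay ladder lengths for nicked molecules and the
#'   geometric decay of their weights along `ladder`.
#' @param ladder_jitter probabilities of -1/0/+1 bp jitter on ladder lengths.
#' @param element_weights list with `uscf` and `mncf` named multiplier
#'   vectors over classes promoter/TTS/exon/intron/intergenic.
#' @param size_conditioned named list (per class) of two-column matrices
#'   `cbind(length, multiplier)` interpolated piecewise-linearly; applied to
#'   the uscf population only. `NULL` entries mean a flat multiplier of 1.
#' @param mito_weight relative per-bp sampling weight of the mitochondrial
#'   contig (1 = proportional to length).
#' @param umi_width UMI length in nt (default 8; 4^8 tag space, exact-match
#'   deduplication semantics).
#' @return list of class `population_config`.
#' @export
population_config <- function(n_total = 50000L,
                              frac_uscf = 0.5,
                              uscf_mode = 50L,
                              uscf_range = c(25L, 100L),
                              uscf_scale_left = 6,
                              uscf_scale_right = 13,
                              mncf_mode = 160L,
                              mncf_range = c(101L, 250L),
                              mncf_scale = 6,
                              nick_fraction = 0.25,
                              ladder = c(150L, 140L, 130L, 120L, 110L),
                              ladder_decay = 0.85,
                              ladder_jitter = c(0.25, 0.5, 0.25),
                              element_weights = list(
                                uscf = c(promoter = 2.0, TTS = 1.0,
                                         exon = 1.4, intron = 1.3,
                                         intergenic = 0.75),
                                mncf = c(promoter = 0.6, TTS = 0.9,
                                         exon = 0.7, intron = 0.8,
                                         intergenic = 1.25)),
                              size_conditioned = list(
                                promoter = cbind(c(25, 45, 55, 100),
                                                 c(0.7, 1.8, 1.8, 0.5)),
                                intergenic = cbind(c(25, 45, 55, 100),
                                                   c(1.0, 0.85, 0.85, 1.7))),
                              mito_weight = 1,
                              umi_width = 8L) {
  stopifnot(n_total >= 0, frac_uscf >= 0, frac_uscf <= 1,
            nick_fraction >= 0, nick_fraction <= 1,
            uscf_range[1] <= uscf_mode, uscf_mode <= uscf_range[2],
            mncf_range[1] <= mncf_mode, mncf_mode <= mncf_range[2],
            uscf_scale_left > 0, uscf_scale_right > 0, mncf_scale > 0,
            ladder_decay > 0, mito_weight > 0,
            all(unlist(element_weights) > 0),
            abs(sum(ladder_jitter) - 1) < 1e-9)
  structure(as.list(environment()), class = "population_config")
}

# discretized asymmetric Laplace pmf on an inclusive integer support
.laplace_pmf <- function(support, mode, scale_left, scale_right = scale_left) {
  x <- seq(support[1], support[2])
  w <- ifelse(x <= mode, exp(-(mode - x) / scale_left),
              exp(-(x - mode) / scale_right))
  stats::setNames(w / sum(w), x)
}

#' Length probability mass functions of the configured populations
#'
#' @param config a [population_config()].
#' @return named numeric vector: probability per integer length.
#' @export
uscf_length_pmf <- function(config = population_config()) {
  .laplace_pmf(config$uscf_range, config$uscf_mode,
               config$uscf_scale_left, config$uscf_scale_right)
}

#' @rdname uscf_length_pmf
#' @export
mncf_length_pmf <- function(config = population_config()) {
  .laplace_pmf(config$mncf_range, config$mncf_mode, config$mncf_scale)
}

ladder_pmf <- function(config) {
  w <- config$ladder_decay ^ (seq_along(config$ladder) - 1)
  stats::setNames(w / sum(w), config$ladder)
}

# piecewise-linear size-conditioned multiplier for one class, evaluated at
# integer lengths; identity curve when the class has no entry
size_multiplier <- function(config, class, lengths) {
  kn <- config$size_conditioned[[class]]
  if (is.null(kn)) return(rep(1, length(lengths)))
  stats::approx(kn[, 1], kn[, 2], xout = lengths, rule = 2)$y
}
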