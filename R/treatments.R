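#' Specify an in-silico nuclease treatment
#'
#' The enzymes and their susceptibility rules:
#' \describe{
#'   \item{dsDNase}{double-strand-specific: removes `ds_intact` and
#'     `ds_nicked` molecules with probability `efficiency`.}
#'   \item{S1, P1, ExoI}{single-strand-specific: remove `ss` molecules with
#'     probability `efficiency`. S1 additionally (i) converts acted-on nicked
#'     duplexes into double-strand breaks at their nick offsets, the pieces
#'     re-entering the set as intact duplexes, and (ii) trims the jagged ends
#'     of every surviving duplex by a total of about `s1_trim_total` bp,
#'     split binomially between the two ends. The trim reproduces the
#'     observed 10 bp downshift of the mononucleosomal mode (160 to 150 bp)
#'     and, by destroying the nicked subpopulation, flattens the 10 bp
#'     ladder.}
#'   \item{DNaseI}{strand-agnostic: removes any molecule with probability
#'     `efficiency`.}
#'   \item{nick_repair}{converts `ds_nicked` to `ds_intact` with probability
#'     `efficiency`; the repaired molecule is restored to its full duplex
#'     length (the ladder piece was its post-denaturation appearance) and its
#'     nicks are cleared, so downstream histograms lose the ladder modes.}
#'   \item{RNase}{identity: every simulated molecule is DNA.}
#' }
#'
#' @param enzyme one of `dsDNase`, `S1`, `P1`, `ExoI`, `DNaseI`,
#'   `nick_repair`, `RNase`.
#' @param efficiency probability in `[0, 1]` that a susceptible molecule is
#'   acted on; nucleases default to 0.95.
#' @param s1_trim_total mean total jagged-end trim in bp (S1 only). The draw
#'   is concentrated: `s1_trim_total + {-1, 0, +1}` with probabilities
#'   0.1/0.8/0.1.
#' @return list of class `treatment_spec`.
#' @export
treatment_spec <- function(enzyme = c("dsDNase", "S1", "P1", "ExoI",
                                      "DNaseI", "nick_repair", "RNase"),
                           efficiency = 0.95, s1_trim_total = 10) {
  enzyme <- tryCatch(match.arg(enzyme),
                     error = function(e) stop("configuration error: unknown ",
                                              "enzyme '", enzyme[1], "'"))
  stopifnot(efficiency >= 0, efficiency <= 1, s1_trim_total >= 0)
  structure(list(enzyme = enzyme, efficiency = efficiency,
                 s1_trim_total = s1_trim_total), class = "treatment_spec")
}

#' Digest a fragment set with a strand-specific nuclease
#'
#' @param fragments a [fragment_set()].
#' @param spec a [treatment_spec()].
#' @param seed integer seed.
#' @param genome optional [genome_model()] used to keep repaired duplexes
#'   inside their contig.
#' @return The treated [fragment_set()]. No treatment increases molecule
#'   length; only S1 cleavage of nicked molecules increases molecule count,
#'   and total bp never increases.
#' @examples
#' # dsDNase at efficiency 1 leaves only single strands
#' @export
digest <- function(fragments, spec, seed = 1L, genome = NULL) {
  stopifnot(inherits(fragments, "fragment_set"),
            inherits(spec, "treatment_spec"))
  set.seed(seed)
  n <- nrow(fragments)
  tag <- paste0("digest:", spec$enzyme)
  if (n == 0) return(fragments)
  acted <- stats::runif(n) < spec$efficiency
  ss <- fragments$state == "ss"
  ds <- !ss

  out <- switch(spec$enzyme,
    RNase = fragments,
    DNaseI = fragments[!acted, , drop = FALSE],
    dsDNase = fragments[!(acted & ds), , drop = FALSE],
    P1 = fragments[!(acted & ss), , drop = FALSE],
    ExoI = fragments[!(acted & ss), , drop = FALSE],
    nick_repair = {
      fr <- fragments
      fix <- which(acted & fr$state == "ds_nicked")
      if (length(fix)) {
        d <- fr$duplex_length[fix]
        fr$end[fix] <- fr$start[fix] + d
        if (!is.null(genome)) {
          clen <- contig_length(genome, fr$contig[fix])
          over <- fr$end[fix] > clen
          fr$start[fix][over] <- clen[over] - d[over]
          fr$end[fix][over] <- clen[over]
        }
        fr$state[fix] <- "ds_intact"
        fr$nicks[fix] <- ""
        fr$duplex_length[fix] <- NA_real_
      }
      fr
    },
    S1 = {
      keep <- fragments[!(acted & ss), , drop = FALSE]
      keep_acted <- acted[!(acted & ss)]
      # cleave acted-on nicked duplexes at their nick offsets
      cut <- keep$state == "ds_nicked" & keep_acted
      pieces <- NULL
      if (any(cut)) {
        cd <- keep[cut, , drop = FALSE]
        off <- as.integer(cd$nicks)  # one residual nick per molecule
        left <- cd; left$end <- left$start + off
        right <- cd; right$start <- right$start + off
        pieces <- rbind(left, right)
        pieces$state <- "ds_intact"
        pieces$nicks <- ""
        pieces$duplex_length <- NA_real_
        keep <- keep[!cut, , drop = FALSE]
      }
      keep <- rbind(keep, pieces)
      # jagged-end trim of every surviving duplex
      dsk <- which(keep$state != "ss")
      if (length(dsk)) {
        total <- spec$s1_trim_total +
          sample(c(-1L, 0L, 1L), length(dsk), replace = TRUE,
                 prob = c(0.1, 0.8, 0.1))
        total <- pmax(0L, total)
        at_start <- stats::rbinom(length(dsk), total, 0.5)
        keep$start[dsk] <- keep$start[dsk] + at_start
        keep$end[dsk] <- keep$end[dsk] - (total - at_start)
      }
      keep <- keep[keep$end - keep$start >= 1, , drop = FALSE]
      keep
    })
  rownames(out) <- NULL
  fragment_set(note_treatment(out, tag))
}

#' Specify a library preparation
#'
#' @param kit `"ss"` (single-stranded chemistry) or `"ds"` (double-stranded
#'   chemistry, which only ligates duplex substrates).
#' @param heat_denaturation whether the ss protocol's initial heat
#'   denaturation step is performed.
#' @param adapter_total_bp total adapter bp added to each molecule
#'   (default 150): library size = insert + `adapter_total_bp`.
#' @param ds_without_heat_efficiency small probability that a duplex enters an
#'   ss library when heat denaturation is skipped.
#' @param include_nicked_in_ds whether the ds kit also ligates nicked
#'   duplexes (at their full duplex length); nicked duplexes are physically
#'   ligatable, so this defaults to `TRUE` but is configurable.
#' @return list of class `library_prep`.
#' @export
library_prep <- function(kit = c("ss", "ds"), heat_denaturation = TRUE,
                         adapter_total_bp = 150,
                         ds_without_heat_efficiency = 0.05,
                         include_nicked_in_ds = TRUE) {
  kit <- match.arg(kit)
  stopifnot(adapter_total_bp >= 0, ds_without_heat_efficiency >= 0,
            ds_without_heat_efficiency <= 1)
  structure(list(kit = kit, heat_denaturation = heat_denaturation,
                 adapter_total_bp = adapter_total_bp,
                 ds_without_heat_efficiency = ds_without_heat_efficiency,
                 include_nicked_in_ds = include_nicked_in_ds),
            class = "library_prep")
}

#' Convert a fragment set into a sequencing library
#'
#' Admission rules: the ds kit accepts intact duplexes (and, by default,
#' nicked duplexes at their full duplex length) and no single strands; the ss
#' kit with heat denaturation accepts single strands, denatured intact
#' duplexes (counted once per original molecule, a deliberate simplification
#' of strand stoichiometry) and nicked duplexes as their denatured ladder
#' pieces; the ss kit without heat accepts single strands, and duplexes only
#' with a small leak probability. Every accepted molecule receives
#' `library_size = insert + adapter_total_bp`.
#'
#' @param fragments a [fragment_set()].
#' @param prep a [library_prep()].
#' @param seed integer seed (used for the no-heat duplex leak).
#' @return A [fragment_set()] with a `library_size` column.
#' @export
prepare_library <- function(fragments, prep = library_prep(), seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"),
            inherits(prep, "library_prep"))
  set.seed(seed)
  ss <- fragments$state == "ss"
  insert <- as.numeric(fragment_lengths(fragments))
  if (prep$kit == "ds") {
    ok <- fragments$state == "ds_intact"
    if (prep$include_nicked_in_ds) {
      nick <- fragments$state == "ds_nicked"
      insert[nick] <- fragments$duplex_length[nick]
      ok <- ok | nick
    }
  } else if (prep$heat_denaturation) {
    ok <- rep(TRUE, nrow(fragments))  # ss, denatured intact, ladder pieces
  } else {
    leak <- stats::runif(nrow(fragments)) < prep$ds_without_heat_efficiency
    ok <- ss | (!ss & leak)
  }
  out <- fragments[ok, , drop = FALSE]
  out$library_size <- insert[ok] + prep$adapter_total_bp
  rownames(out) <- NULL
  tag <- paste0("library:", prep$kit,
                if (prep$kit == "ss" && !prep$heat_denaturation) "-noheat"
                else "")
  fragment_set(note_treatment(out, tag))
}
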