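#' Simulate a synthetic cfDNA fragmentome
#'
#' Draws `config$n_total` fragments. Per fragment: the population is chosen
#' by the mixture fraction; a length is drawn from that population's law (a
#' nicked mncf molecule instead draws its post-denaturation 10 bp ladder
#' length, with its full duplex length stored alongside); a functional class
#' is chosen with probability proportional to genomic baseline x per-class
#' enrichment multiplier (x the length-conditioned multiplier for uscf); a
#' genomic position is drawn uniformly within that class and the fragment is
#' placed so its midpoint lies on it; strand and UMI are uniform. Identical
#' seeds give identical fragment sets.
#'
#' @param genome a [genome_model()].
#' @param annotation an [annotate_elements()] result covering `genome`.
#' @param config a [population_config()].
#' @param seed integer seed.
#' @param max_retries bounded number of placement redraws for fragments that
#'   do not fit their contig.
#' @return A [fragment_set()].
#' @examples
#' gm <- genome_model(c(chrA = 200000L, chrM = 16569L))
#' ann <- annotate_elements(gm, n_genes = 5, seed = 1)
#' fr <- simulate_population(gm, ann, population_config(n_total = 1000), seed = 1)
#' table(fr$population)
#' @export
simulate_population <- function(genome, annotation,
                                config = population_config(),
                                seed = 1L, max_retries = 50L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(annotation, "element_annotation"),
            inherits(config, "population_config"))
  set.seed(seed)
  n <- config$n_total
  if (n == 0) return(empty_fragment_set())

  pop <- ifelse(stats::runif(n) < config$frac_uscf, "uscf", "mncf")
  is_us <- pop == "uscf"
  n_us <- sum(is_us); n_mn <- n - n_us

  len <- integer(n)
  state <- character(n)
  duplex <- rep(NA_real_, n)
  nicks <- rep("", n)

  # uscf: single-stranded by construction
  if (n_us) {
    pmf <- uscf_length_pmf(config)
    len[is_us] <- sample(as.integer(names(pmf)), n_us, replace = TRUE,
                         prob = pmf)
    state[is_us] <- "ss"
  }

  # mncf: intact duplexes, or nicked duplexes observed at a ladder length
  if (n_mn) {
    mi <- which(!is_us)
    nicked <- stats::runif(n_mn) < config$nick_fraction
    state[mi] <- ifelse(nicked, "ds_nicked", "ds_intact")
    pmf <- mncf_length_pmf(config)
    supp <- as.integer(names(pmf))
    if (any(!nicked))
      len[mi[!nicked]] <- sample(supp, sum(!nicked), replace = TRUE,
                                 prob = pmf)
    if (any(nicked)) {
      lw <- ladder_pmf(config)
      base <- sample(as.integer(names(lw)), sum(nicked), replace = TRUE,
                     prob = lw)
      jit <- sample(c(-1L, 0L, 1L), sum(nicked), replace = TRUE,
                    prob = config$ladder_jitter)
      piece <- base + jit
      len[mi[nicked]] <- piece
      # full duplex length: intact law truncated strictly above the piece
      d <- numeric(sum(nicked))
      for (p in unique(piece)) {
        sel <- piece == p
        ok <- supp > p
        d[sel] <- sample(supp[ok], sum(sel), replace = TRUE,
                         prob = pmf[ok])
      }
      duplex[mi[nicked]] <- d
      # one residual nick strictly inside the observed piece
      off <- pmin(piece - 1L,
                  pmax(1L, floor(piece * stats::runif(sum(nicked),
                                                      0.25, 0.75))))
      nicks[mi[nicked]] <- as.character(off)
    }
  }

  # class choice: baseline x enrichment (x size curve for uscf), per fragment
  classes <- names(annotation$baseline)
  pw <- matrix(rep(annotation$baseline, each = n), nrow = n,
               dimnames = list(NULL, classes))
  for (cl in classes) {
    w <- ifelse(is_us, config$element_weights$uscf[[cl]],
                config$element_weights$mncf[[cl]])
    pw[, cl] <- pw[, cl] * w
    if (any(is_us))
      pw[is_us, cl] <- pw[is_us, cl] * size_multiplier(config, cl,
                                                       len[is_us])
  }
  pw <- pw / rowSums(pw)
  u <- stats::runif(n)
  cum <- t(apply(pw, 1, cumsum))
  cls_idx <- rowSums(u > cum) + 1L
  cls <- classes[cls_idx]

  # midpoint placement within the chosen class; bounded resampling at edges
  contig <- character(n)
  start <- numeric(n)
  for (cl in unique(cls)) {
    sel <- which(cls == cl)
    ln <- len[sel]
    sp <- .sample_positions_weighted(annotation, cl, length(sel),
                                     config$mito_weight, genome$mito_name)
    st <- sp$pos - floor(ln / 2)
    en <- st + ln
    clen <- contig_length(genome, sp$contig)
    bad <- which(st < 0 | en > clen)
    tries <- 0
    while (length(bad) && tries < max_retries) {
      rp <- .sample_positions_weighted(annotation, cl, length(bad),
                                       config$mito_weight, genome$mito_name)
      sp$contig[bad] <- rp$contig
      sp$pos[bad] <- rp$pos
      st[bad] <- rp$pos - floor(ln[bad] / 2)
      en[bad] <- st[bad] + ln[bad]
      clen <- contig_length(genome, sp$contig)
      bad <- which(st < 0 | en > clen)
      tries <- tries + 1
    }
    if (length(bad))
      stop("could not place ", length(bad), " fragment(s) of class '", cl,
           "' within ", max_retries, " retries")
    contig[sel] <- sp$contig
    start[sel] <- st
  }

  df <- data.frame(
    contig = contig, start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    state = state, nicks = nicks, duplex_length = duplex,
    umi = random_umis(n, config$umi_width), population = pop,
    treatment_history = "", stringsAsFactors = FALSE)
  fragment_set(df, genome)
}

# position sampling within a class with an optional mitochondrial reweight
.sample_positions_weighted <- function(annotation, class, n, mito_weight,
                                       mito_name) {
  p <- annotation$partition
  p <- p[p$class == class, , drop = FALSE]
  if (nrow(p) == 0)
    stop("configuration error: class '", class,
         "' has no bp in this genome")
  w <- (p$end - p$start) * ifelse(p$contig == mito_name, mito_weight, 1)
  i <- sample.int(nrow(p), n, replace = TRUE, prob = w)
  width <- p$end[i] - p$start[i]
  list(contig = p$contig[i], pos = p$start[i] + floor(stats::runif(n) * width))
}

#' Append spike-in ladder fragments
#'
#' Adds `copies_per_size` single-stranded molecules per ladder oligo on a
#' dedicated `lambda_spike` contig. Input fragments are untouched; spike-in
#' lengths are the actual catalog string lengths.
#'
#' @param fragments a [fragment_set()].
#' @param catalog an [load_oligos()] catalog.
#' @param copies_per_size copies per ladder oligo.
#' @param seed seed for UMI assignment.
#' @return A [fragment_set()] with spike-ins appended.
#' @export
add_spikeins <- function(fragments, catalog = load_oligos(),
                         copies_per_size = 100L, seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"), copies_per_size >= 0)
  if (copies_per_size == 0) return(fragments)
  set.seed(seed)
  nm <- names(ladder_sizes(catalog))
  lens <- nchar(catalog[nm])
  k <- length(nm) * copies_per_size
  df <- data.frame(
    contig = "lambda_spike", start = 0,
    end = rep(as.numeric(lens), each = copies_per_size),
    strand = "+", state = "ss", nicks = "", duplex_length = NA_real_,
    umi = random_umis(k), population = "spikein", treatment_history = "",
    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(fragments), df)
  fragment_set(out)
}

#' Length-dependent extraction retention models
#'
#' Retention is a logistic curve of molecule length,
#' `floor + (ceiling - floor) / (1 + exp(-(L - midpoint)/slope))`, monotone
#' non-decreasing in length. The three presets emulate the qualitative
#' ranking observed with spike-in ladders: the standard silica-column
#' protocol (`QiaC`) loses most sub-100 nt material, the small-RNA variant
#' (`QiaM`) and the magnetic-bead protocol (`SPRI`) retain it far better,
#' with SPRI strongest at 30-50 nt.
#'
#' @param method `"QiaC"`, `"QiaM"` or `"SPRI"`; or `"custom"` with explicit
#'   parameters.
#' @param floor,ceiling,midpoint,slope logistic parameters (probabilities,
#'   bp, bp).
#' @return list of class `extraction_model` with a `retention(length)`
#'   function.
#' @examples
#' m <- extraction_model("SPRI")
#' m$retention(c(30, 50, 160))
#' @export
extraction_model <- function(method = c("QiaC", "QiaM", "SPRI", "custom"),
                             floor = NULL, ceiling = NULL, midpoint = NULL,
                             slope = NULL) {
  method <- match.arg(method)
  preset <- switch(method,
    QiaC = list(floor = 0.02, ceiling = 0.90, midpoint = 130, slope = 20),
    QiaM = list(floor = 0.25, ceiling = 0.90, midpoint = 70, slope = 15),
    SPRI = list(floor = 0.45, ceiling = 0.90, midpoint = 60, slope = 15),
    custom = list(floor = floor, ceiling = ceiling, midpoint = midpoint,
                  slope = slope))
  if (!is.null(floor)) preset$floor <- floor
  if (!is.null(ceiling)) preset$ceiling <- ceiling
  if (!is.null(midpoint)) preset$midpoint <- midpoint
  if (!is.null(slope)) preset$slope <- slope
  stopifnot(preset$floor >= 0, preset$ceiling <= 1,
            preset$floor <= preset$ceiling, preset$slope > 0)
  ret <- local({
    p <- preset
    function(length) {
      p$floor + (p$ceiling - p$floor) /
        (1 + exp(-(length - p$midpoint) / p$slope))
    }
  })
  structure(c(list(method = method, retention = ret), preset),
            class = "extraction_model")
}

#' Apply length-dependent extraction loss
#'
#' Each fragment independently survives with probability
#' `model$retention(length)`.
#'
#' @param fragments a [fragment_set()].
#' @param model an [extraction_model()].
#' @param seed integer seed.
#' @return The surviving [fragment_set()].
#' @export
apply_extraction <- function(fragments, model, seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"),
            inherits(model, "extraction_model"))
  set.seed(seed)
  p <- model$retention(fragment_lengths(fragments))
  if (any(p < 0 | p > 1)) stop("retention probabilities must be in [0, 1]")
  keep <- stats::runif(nrow(fragments)) < p
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  note_treatment(out, paste0("extract:", model$method))
}

#' Spike-in recovery per ladder size
#'
#' Compares spike-in counts before and after an extraction (or any loss
#' process) and reports the recovered fraction per observed spike-in length.
#' Sizes absent from the input are reported as `NA` (undefined), not zero.
#'
#' @param pre,post [fragment_set()]s carrying `population == "spikein"` rows.
#' @return named numeric vector: recovered fraction per spike-in length.
#' @export
spikein_recovery <- function(pre, post) {
  a <- pre[pre$population == "spikein", , drop = FALSE]
  b <- post[post$population == "spikein", , drop = FALSE]
  la <- fragment_lengths(a); lb <- fragment_lengths(b)
  if (length(setdiff(lb, la)))
    stop("consistency error: post set contains spike-in sizes absent from ",
         "the pre set: ", paste(setdiff(lb, la), collapse = ", "))
  sizes <- sort(unique(la))
  n_pre <- as.numeric(table(factor(la, levels = sizes)))
  n_post <- as.numeric(table(factor(lb, levels = sizes)))
  frac <- ifelse(n_pre > 0, n_post / n_pre, NA_real_)
  stats::setNames(frac, sizes)
}
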