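#' Annotate a synthetic genome with functional elements
#'
#' Places non-overlapping gene models on the non-mitochondrial contigs and
#' resolves the genome into a single-class-per-bp functional map with the
#' precedence promoter > TTS > exon > intron > intergenic, the convention used
#' by peak-annotation tools. The promoter is `[TSS - promoter_window[1],
#' TSS + promoter_window[2])` on the gene strand; the transcription
#' termination site (TTS) window mirrors it at the other end of the gene.
#' Intergenic is the complement of all gene-derived classes and is never
#' represented by explicit gene intervals.
#'
#' All coordinates are 0-based half-open internally; BED files are written in
#' the same convention (native BED).
#'
#' @param genome a [genome_model()]. The mitochondrial contig never carries
#'   gene models.
#' @param n_genes number of genes to place. The default density leaves the
#'   genome intergenic-dominated (>= 60% of bp).
#' @param promoter_window integer pair `(upstream, downstream)` of the TSS in
#'   bp; default `c(1000, 100)`.
#' @param tts_window integer pair `(upstream, downstream)` of the TES in bp;
#'   default `c(100, 1000)`, symmetric with the promoter choice.
#' @param exon_count_range,exon_length_range,intron_length_range integer
#'   ranges sampled uniformly per gene to build exon/intron geometry.
#' @param max_attempts bounded number of placement attempts per gene before a
#'   placement error is raised.
#' @param seed integer seed for gene placement.
#' @return An object of class `element_annotation`: list with `genes`
#'   (data.frame), `exons` (raw exon intervals per gene, before precedence
#'   resolution), `intervals` (resolved non-intergenic class intervals,
#'   0-based half-open), `partition` (full single-class partition of the
#'   genome including intergenic, used for lookup and sampling), `baseline`
#'   (named fraction of genome bp per class, exact counting), `precedence`,
#'   and the `genome`.
#' @examples
#' gm <- genome_model(c(chrA = 100000L, chrM = 16569L))
#' ann <- annotate_elements(gm, n_genes = 3, seed = 1)
#' ann$baseline
#' @export
annotate_elements <- function(genome,
                              n_genes = 400L,
                              promoter_window = c(1000L, 100L),
                              tts_window = c(100L, 1000L),
                              exon_count_range = c(3L, 8L),
                              exon_length_range = c(150L, 400L),
                              intron_length_range = c(500L, 3000L),
                              max_attempts = 200L,
                              seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  stopifnot(length(promoter_window) == 2, all(promoter_window >= 0),
            length(tts_window) == 2, all(tts_window >= 0), n_genes >= 0)
  set.seed(seed)

  auto <- genome$contigs[genome$contigs$name != genome$mito_name, ,
                         drop = FALSE]
  if (n_genes > 0 && nrow(auto) == 0)
    stop("no non-mitochondrial contig available for gene placement")
  flank <- max(promoter_window[1], tts_window[2])
  # occupied intervals are stored expanded by flank + 100 bp so that the
  # flank windows of neighbouring genes can never touch
  margin <- flank + 100L

  occupied <- stats::setNames(vector("list", nrow(auto)), auto$name)
  genes <- vector("list", n_genes)
  exon_iv <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    n_ex <- sample(seq(exon_count_range[1], exon_count_range[2]), 1)
    ex_len <- sample(seq(exon_length_range[1], exon_length_range[2]), n_ex,
                     replace = TRUE)
    in_len <- if (n_ex > 1)
      sample(seq(intron_length_range[1], intron_length_range[2]), n_ex - 1,
             replace = TRUE) else integer(0)
    body <- sum(ex_len) + sum(in_len)

    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      ci <- sample.int(nrow(auto), 1, prob = auto$length)
      cname <- auto$name[ci]
      lo <- flank
      hi <- auto$length[ci] - body - flank
      if (hi <= lo) next
      start <- lo + floor(stats::runif(1) * (hi - lo))
      end <- start + body
      occ <- occupied[[cname]]
      clash <- FALSE
      if (length(occ))
        clash <- any(start - margin < occ[, 2] & end + margin > occ[, 1])
      if (clash) next
      occupied[[cname]] <- rbind(occ, c(start - margin, end + margin))
      strand <- sample(c("+", "-"), 1)
      genes[[g]] <- data.frame(name = sprintf("gene%04d", g), contig = cname,
                               start = start, end = end, strand = strand,
                               stringsAsFactors = FALSE)
      ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
      exon_iv[[g]] <- data.frame(contig = cname, start = ex_start,
                                 end = ex_start + ex_len,
                                 stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("placement error: could not place gene ", g, " within ",
           max_attempts, " attempts; lower n_genes or enlarge the genome")
  }
  genes <- if (n_genes > 0) do.call(rbind, genes) else
    data.frame(name = character(), contig = character(), start = numeric(),
               end = numeric(), strand = character())
  exons <- if (n_genes > 0) do.call(rbind, exon_iv) else
    data.frame(contig = character(), start = numeric(), end = numeric())

  # class windows (0-based half-open), clipped to contigs during resolution
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)   # TSS as a bp coordinate
  tes <- ifelse(plus, genes$end, genes$start)
  prom <- data.frame(
    contig = genes$contig,
    start = ifelse(plus, tss - promoter_window[1], tss - promoter_window[2]),
    end   = ifelse(plus, tss + promoter_window[2], tss + promoter_window[1]))
  tts <- data.frame(
    contig = genes$contig,
    start = ifelse(plus, tes - tts_window[1], tes - tts_window[2]),
    end   = ifelse(plus, tes + tts_window[2], tes + tts_window[1]))
  body <- data.frame(contig = genes$contig, start = genes$start,
                     end = genes$end)

  class_iv <- list(promoter = prom, TTS = tts, exon = exons, intron = body)
  precedence <- c("promoter", "TTS", "exon", "intron", "intergenic")
  res <- .resolve_precedence(class_iv, genome,
                             precedence[precedence != "intergenic"])

  ann <- structure(
    list(genes = genes, exons = exons, intervals = res$intervals,
         partition = res$partition, baseline = res$baseline,
         precedence = precedence, genome = genome,
         params = list(promoter_window = promoter_window,
                       tts_window = tts_window)),
    class = "element_annotation")
  ann
}

# Resolve possibly-overlapping class windows into a one-class-per-bp map.
# class_iv: named list of data.frames (contig, start, end), 0-based half-open;
# 'intron' intervals are whole gene bodies and lose bp to exon by precedence.
.resolve_precedence <- function(class_iv, genome, precedence) {
  sl <- stats::setNames(genome$contigs$length, genome$contigs$name)
  to_gr <- function(df) {
    if (nrow(df) == 0)
      return(GenomicRanges::GRanges(seqlengths = sl))
    s <- pmax(df$start, 0)
    e <- pmin(df$end, sl[df$contig])
    keep <- e > s
    GenomicRanges::GRanges(df$contig[keep],
                           IRanges::IRanges(s[keep] + 1, e[keep]),
                           seqlengths = sl)
  }
  assigned <- GenomicRanges::GRanges(seqlengths = sl)
  pieces <- list()
  for (cls in precedence) {
    gr <- GenomicRanges::reduce(to_gr(class_iv[[cls]]))
    gr <- GenomicRanges::setdiff(gr, assigned)
    pieces[[cls]] <- gr
    assigned <- GenomicRanges::reduce(c(assigned, gr))
  }
  whole <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1, sl),
                                  seqlengths = sl)
  pieces$intergenic <- GenomicRanges::setdiff(whole, assigned)

  df <- do.call(rbind, lapply(names(pieces), function(cls) {
    gr <- pieces[[cls]]
    if (length(gr) == 0)
      return(NULL)
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr), class = cls,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(match(df$contig, names(sl)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  bp <- tapply(df$end - df$start, factor(df$class, levels = c(precedence,
                                                              "intergenic")),
               sum, default = 0)
  baseline <- as.numeric(bp) / sum(sl)
  names(baseline) <- names(bp)
  list(intervals = df[df$class != "intergenic", , drop = FALSE],
       partition = df, baseline = baseline)
}

#' @export
print.element_annotation <- function(x, ...) {
  cat("Functional-element annotation:", nrow(x$genes), "genes on",
      length(unique(x$partition$contig)), "contigs\n")
  cat("Genomic baseline (fraction of bp):\n")
  print(round(x$baseline, 4))
  invisible(x)
}

#' Look up the functional class of genomic positions
#'
#' Returns the class of the single bp at each position under the resolved
#' precedence map.
#'
#' @param annotation an `element_annotation`.
#' @param contig,pos parallel vectors of contig names and 0-based positions.
#' @return character vector of classes.
#' @export
classify_positions <- function(annotation, contig, pos) {
  stopifnot(inherits(annotation, "element_annotation"))
  if (length(contig) == 1 && length(pos) > 1)
    contig <- rep(contig, length(pos))
  stopifnot(length(contig) == length(pos))
  lens <- contig_length(annotation$genome, contig)  # validates contigs
  if (any(pos < 0 | pos >= lens))
    stop("position outside genome")
  out <- character(length(pos))
  part <- annotation$partition
  for (cn in unique(contig)) {
    sel <- contig == cn
    p <- part[part$contig == cn, , drop = FALSE]
    idx <- findInterval(pos[sel], p$start)
    out[sel] <- p$class[idx]
  }
  out
}

# Sample 0-based bp positions uniformly within a class (interval weighted by
# width); used by the simulator to target fragment midpoints.
sample_class_positions <- function(annotation, class, n) {
  p <- annotation$partition
  p <- p[p$class == class, , drop = FALSE]
  if (nrow(p) == 0)
    stop("configuration error: class '", class,
         "' has no bp in this genome")
  w <- p$end - p$start
  i <- sample.int(nrow(p), n, replace = TRUE, prob = w)
  pos <- p$start[i] + floor(stats::runif(n) * w[i])
  list(contig = p$contig[i], pos = pos)
}

#' Write / read element annotation as BED6
#'
#' The resolved non-intergenic class intervals are written as BED6 with the
#' name field carrying the class (intergenic is the complement and is
#' reconstructed on read). The genomic baseline can be written as a TSV of
#' `class`, `bp`, `fraction`.
#'
#' @param annotation an `element_annotation`.
#' @param bed,tsv file paths.
#' @param genome a `genome_model` used to recompute the partition and
#'   baseline when reading.
#' @return `read_annotation_bed` returns an `element_annotation` (without
#'   gene models, which are a generative detail not stored in BED).
#' @export
write_annotation_bed <- function(annotation, bed) {
  iv <- annotation$intervals
  sl <- stats::setNames(annotation$genome$contigs$length,
                        annotation$genome$contigs$name)
  gr <- GenomicRanges::GRanges(iv$contig,
                               IRanges::IRanges(iv$start + 1, iv$end),
                               seqlengths = sl)
  S4Vectors::mcols(gr)$name <- iv$class
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, bed, format = "BED")
  invisible(bed)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(bed, genome) {
  gr <- rtracklayer::import(bed, format = "BED")
  iv <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   class = S4Vectors::mcols(gr)$name,
                   stringsAsFactors = FALSE)
  class_iv <- split(iv[c("contig", "start", "end")], iv$class)
  precedence <- c("promoter", "TTS", "exon", "intron", "intergenic")
  present <- precedence[precedence %in% names(class_iv)]
  res <- .resolve_precedence(class_iv, genome, present)
  # keep the canonical class order even for classes absent from the BED
  base <- stats::setNames(numeric(length(precedence)), precedence)
  base[names(res$baseline)] <- res$baseline
  structure(
    list(genes = NULL, intervals = res$intervals, partition = res$partition,
         baseline = base, precedence = precedence, genome = genome,
         params = list()),
    class = "element_annotation")
}

#' @rdname write_annotation_bed
#' @export
write_baseline_tsv <- function(annotation, tsv) {
  total <- sum(annotation$genome$contigs$length)
  df <- data.frame(class = names(annotation$baseline),
                   bp = round(annotation$baseline * total),
                   fraction = annotation$baseline)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv)
}

#' @rdname write_annotation_bed
#' @export
read_baseline_tsv <- function(tsv) {
  df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$fraction, df$class)
}
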