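# Shared fixtures, built in code. Heavy objects (default genome annotation,
# default simulations) are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_genome <- function(len = 200000L) {
  genome_model(c(chrA = len, chrM = 16569L))
}

toy_annotation <- function(len = 200000L, n_genes = 3L, seed = 11L) {
  annotate_elements(toy_genome(len), n_genes = n_genes, seed = seed)
}

default_genome <- function() cached("gm", genome_model())

default_annotation <- function() {
  cached("ann", annotate_elements(default_genome(), seed = 1L))
}

default_simulation <- function() {
  cached("sim", simulate_population(default_genome(), default_annotation(),
                                    population_config(), seed = 42L))
}

uniform_config <- function(n_total = 50000L, ...) {
  flat <- c(promoter = 1, TTS = 1, exon = 1, intron = 1, intergenic = 1)
  population_config(n_total = n_total,
                    element_weights = list(uscf = flat, mncf = flat),
                    size_conditioned = list(), ...)
}

# a minimal hand-built fragment set: all fields valid, one row per length
make_fragments <- function(lengths, contig = "chrA", state = "ss",
                           population = "uscf", start = 1000,
                           umi = NULL, strand = "+") {
  n <- length(lengths)
  if (is.null(umi))
    umi <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
      character(1))
  fragment_set(data.frame(
    contig = rep_len(contig, n), start = rep_len(start, n),
    end = rep_len(start, n) + lengths, strand = rep_len(strand, n),
    state = rep_len(state, n), nicks = rep_len("", n),
    duplex_length = rep_len(NA_real_, n), umi = umi,
    population = rep_len(population, n),
    treatment_history = rep_len("", n), stringsAsFactors = FALSE))
}

# Independent per-bp oracle: classify every bp of a contig by membership in
# the raw gene-derived windows, applying precedence directly on bp masks
# (a different mechanism from the package's interval setdiff resolution).
brute_force_classes <- function(ann, contig) {
  len <- ann$genome$contigs$length[ann$genome$contigs$name == contig]
  mask <- function(df) {
    v <- logical(len)
    df <- df[df$contig == contig, , drop = FALSE]
    for (i in seq_len(nrow(df))) {
      s <- max(0, df$start[i]); e <- min(len, df$end[i])
      if (e > s) v[(s + 1):e] <- TRUE
    }
    v
  }
  g <- ann$genes
  plus <- g$strand == "+"
  tss <- ifelse(plus, g$start, g$end)
  tes <- ifelse(plus, g$end, g$start)
  pw <- ann$params$promoter_window
  tw <- ann$params$tts_window
  prom <- data.frame(contig = g$contig,
                     start = ifelse(plus, tss - pw[1], tss - pw[2]),
                     end = ifelse(plus, tss + pw[2], tss + pw[1]))
  tts <- data.frame(contig = g$contig,
                    start = ifelse(plus, tes - tw[1], tes - tw[2]),
                    end = ifelse(plus, tes + tw[2], tes + tw[1]))
  body <- data.frame(contig = g$contig, start = g$start, end = g$end)
  m_prom <- mask(prom); m_tts <- mask(tts)
  m_exon <- mask(ann$exons); m_body <- mask(body)
  out <- rep("intergenic", len)
  out[m_body] <- "intron"
  out[m_exon] <- "exon"
  out[m_tts] <- "TTS"
  out[m_prom] <- "promoter"
  out
}
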