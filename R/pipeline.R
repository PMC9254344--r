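#' Pipeline stage runners
#'
#' One function per replay stage, mirroring the experimental matrix: fixture
#' generation, simulation (with optional spike-ins and extraction),
#' treatment (digestions and/or library preparation), analysis, and trace
#' quantification. Each stage reads its inputs from and writes its outputs
#' to `out_dir`, together with a JSON manifest recording inputs, seed,
#' package version and output checksums, so a replay with identical
#' config and seed produces identical files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the files written.
#' @name pipeline
NULL

.manifest <- function(out_dir, stage, config, files) {
  man <- list(stage = stage,
              package = "uscfseq",
              version = as.character(utils::packageVersion("uscfseq")),
              seed = config$seed,
              config = unclass(config),
              outputs = as.list(tools::md5sum(unlist(files))))
  jsonlite::write_json(man, file.path(out_dir,
                                      paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.cfg_genome <- function(config) {
  genome_model(stats::setNames(as.numeric(unlist(config$genome_contigs)),
                               names(config$genome_contigs)),
               mito_name = config$mito_name)
}

#' @rdname pipeline
#' @export
run_make_fixtures <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- .cfg_genome(config)
  build_genome(gm, fasta = file.path(out_dir, "genome.fasta"),
               seed = config$seed)
  ann <- annotate_elements(gm, n_genes = config$n_genes,
                           seed = config$seed + 1L)
  write_annotation_bed(ann, file.path(out_dir, "annotation.bed"))
  write_baseline_tsv(ann, file.path(out_dir, "baseline.tsv"))
  file.copy(system.file("extdata", "lambda_oligos.fasta",
                        package = "uscfseq"),
            file.path(out_dir, "oligos.fasta"), overwrite = TRUE)
  files <- file.path(out_dir, c("genome.fasta", "annotation.bed",
                                "baseline.tsv", "oligos.fasta"))
  .manifest(out_dir, "make_fixtures", config, files)
  invisible(files)
}

#' @rdname pipeline
#' @export
run_simulate <- function(config, out_dir) {
  gm <- .cfg_genome(config)
  ann <- read_annotation_bed(file.path(out_dir, "annotation.bed"), gm)
  pc <- population_config(n_total = config$n_total,
                          frac_uscf = config$frac_uscf,
                          nick_fraction = config$nick_fraction)
  fr <- simulate_population(gm, ann, pc, seed = config$seed + 2L)
  if (config$spikein_copies > 0)
    fr <- add_spikeins(fr, load_oligos(), config$spikein_copies,
                       seed = config$seed + 3L)
  if (!is.null(config$extraction)) {
    pre <- fr
    fr <- apply_extraction(fr, extraction_model(config$extraction),
                           seed = config$seed + 4L)
    if (config$spikein_copies > 0) {
      rec <- spikein_recovery(pre, fr)
      utils::write.table(data.frame(size = as.integer(names(rec)),
                                    recovered_fraction = rec),
                         file.path(out_dir, "spikein_recovery.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_fragments_tsv(fr, file.path(out_dir, "fragments.tsv"))
  .manifest(out_dir, "simulate", config,
            file.path(out_dir, "fragments.tsv"))
  invisible(file.path(out_dir, "fragments.tsv"))
}

#' @rdname pipeline
#' @export
run_treat <- function(config, out_dir) {
  gm <- .cfg_genome(config)
  fr <- read_fragments_tsv(file.path(out_dir, "fragments.tsv"))
  s <- config$seed + 10L
  for (tr in config$treatments) {
    spec <- treatment_spec(enzyme = tr$enzyme,
                           efficiency = tr$efficiency %||% 0.95,
                           s1_trim_total = tr$s1_trim_total %||% 10)
    fr <- digest(fr, spec, seed = s, genome = gm)
    s <- s + 1L
  }
  if (!is.null(config$library)) {
    prep <- library_prep(kit = config$library$kit,
                         heat_denaturation =
                           config$library$heat_denaturation %||% TRUE)
    fr <- prepare_library(fr, prep, seed = s)
    if (nrow(fr)) {
      tr <- synthesize_trace(fr)
      write_trace_tsv(tr, file.path(out_dir, "trace.tsv"))
    }
  }
  write_fragments_tsv(fr, file.path(out_dir, "treated.tsv"))
  .manifest(out_dir, "treat", config, file.path(out_dir, "treated.tsv"))
  invisible(file.path(out_dir, "treated.tsv"))
}

#' @rdname pipeline
#' @param fragments_file which fragment table to analyse (defaults to
#'   `treated.tsv` when present, else `fragments.tsv`).
#' @export
run_analyze <- function(config, out_dir, fragments_file = NULL) {
  gm <- .cfg_genome(config)
  ann <- read_annotation_bed(file.path(out_dir, "annotation.bed"), gm)
  if (is.null(fragments_file)) {
    fragments_file <- file.path(out_dir, "treated.tsv")
    if (!file.exists(fragments_file))
      fragments_file <- file.path(out_dir, "fragments.tsv")
  }
  fr <- read_fragments_tsv(fragments_file)
  fr <- fr[fr$contig != "lambda_spike", , drop = FALSE]
  if (!nrow(fr)) stop("no fragments to analyze")
  fr <- deduplicate(fr)
  parts <- size_filter_classify(fr)

  hist_us <- length_histogram(parts$uscf)
  hist_mn <- length_histogram(parts$mncf)
  utils::write.table(rbind(cbind(class = "uscf", hist_us),
                           cbind(class = "mncf", hist_mn)),
                     file.path(out_dir, "length_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cd <- chrom_distribution(fr, gm)
  utils::write.table(cd, file.path(out_dir, "chrom_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_input = nrow(fr),
    n_uscf = nrow(parts$uscf), n_mncf = nrow(parts$mncf),
    n_excluded = nrow(parts$excluded),
    modal_uscf = if (nrow(parts$uscf)) modal_length(hist_us) else NA,
    modal_mncf = if (nrow(parts$mncf)) modal_length(hist_mn) else NA,
    chrM_fraction = cd$fraction[cd$contig == gm$mito_name])

  if (nrow(parts$mncf)) {
    per <- periodicity(hist_mn)
    summary$dominant_period <- per$period
    summary$periodicity_contrast <- per$contrast
  }

  if (nrow(parts$uscf) && nrow(parts$mncf)) {
    cov <- list(uscf = bin_coverage(parts$uscf, gm),
                mncf = bin_coverage(parts$mncf, gm))
    pm <- tryCatch(pearson_matrix(cov), error = function(e) NULL)
    if (!is.null(pm))
      utils::write.table(pm, file.path(out_dir, "pearson_matrix.tsv"),
                         sep = "\t", quote = FALSE)
  }

  for (nm in c("uscf", "mncf")) {
    if (!nrow(parts[[nm]])) next
    prof <- element_profile(annotate_fragments(parts[[nm]], ann),
                            ann$baseline)
    utils::write.table(prof,
                       file.path(out_dir,
                                 paste0("element_profile_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(parts$uscf)) {
    sbp <- size_binned_profile(parts$uscf, ann)
    utils::write.table(sbp, file.path(out_dir, "size_binned_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  trace_file <- file.path(out_dir, "trace.tsv")
  if (file.exists(trace_file))
    summary$pct_uscfDNA <- 100 * quantify_trace(read_trace_tsv(trace_file))

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .manifest(out_dir, "analyze", config,
            file.path(out_dir, "summary.json"))
  invisible(file.path(out_dir, "summary.json"))
}

#' @rdname pipeline
#' @param trace_path path to a 2-column trace TSV.
#' @export
run_quantify_trace <- function(trace_path, out_dir = dirname(trace_path)) {
  tr <- read_trace_tsv(trace_path)
  res <- list(pct_uscfDNA = 100 * quantify_trace(tr))
  jsonlite::write_json(res, file.path(out_dir, "trace_quantification.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
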