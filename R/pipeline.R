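#' Default pipeline configuration
#'
#' The full default configuration for \code{\link{runPipeline}}, one section
#' per stage. Values supplied by the user (or a YAML file) override these
#' defaults section-wise.
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    pipeline = "simulate",
    seed = 1L,
    output_dir = "tilac_out",
    simulate = list(
      n_transcripts = 50L, reads_per_transcript = 500,
      read_count_mode = "fixed", ratio_mode = "constant", ratio = 1,
      ratios = c(0.01, 0.1, 0.5, 1, 1.5, 2, 10, 100),
      regulation_mode = "down", theta_noise_sd = 0.5,
      read_length = 200L, p_U = 0.25, p_G = 0.25,
      rate_tc_labelled = 0.05, rate_tc_background = 0.001,
      rate_ga_labelled = 0.02, rate_ga_background = 0.004,
      emit_sam = FALSE,
      samples = list(
        list(sample_id = "fwd1", combination = "forward", replicate = 1L),
        list(sample_id = "rev1", combination = "reverse", replicate = 1L),
        list(sample_id = "unl1", combination = "unlabelled", replicate = 1L))),
    tally = list(
      samples = list(), fasta = NULL, annotation = NULL, vcf = NULL,
      mapq_min = 2L, base_qual_min = 20L, stranded = "no"),
    filter = list(min_reads = 200L, min_samples = 2L),
    fit = list(chains = 4L, warmup = 1000L, iter = 1000L),
    test = list(mu_cutoff = 0.5, alpha = 0.05))
}

.merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param file YAML path; sections missing from the file take their
#'   defaults from \code{\link{defaultConfig}}.
#' @return merged configuration list.
#' @export
readConfig <- function(file) {
  .merge_config(defaultConfig(), yaml::read_yaml(file))
}

.design_from_config <- function(samples) {
  tilacDesign(vapply(samples, `[[`, "", "sample_id"),
              vapply(samples, `[[`, "", "combination"),
              vapply(samples, function(s)
                as.integer(s$replicate %||% 1L), 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(log_file, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stage = stage), list(...))
  message(sprintf("[tilac] %s: %s", stage,
                  paste(names(entry[-(1:2)]), unlist(entry[-(1:2)]),
                        sep = "=", collapse = " ")))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = log_file, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes either \code{tally -> aggregate -> filter -> fit -> test} (on
#' aligned reads) or \code{simulate -> filter -> fit -> test} (on synthetic
#' data), writing every stage's output, a JSON-lines log with record counts
#' in and out of each stage, and a run manifest (configuration, seed, file
#' checksums, timestamps) into the output directory.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}) or
#'   path to a YAML file.
#' @param output_dir overrides the configured output directory.
#' @param seed overrides the configured seed.
#' @return invisibly, a list with the fitted model, test results, truth
#'   table (simulation mode) and the manifest path.
#' @export
runPipeline <- function(config = defaultConfig(), output_dir = NULL,
                        seed = NULL) {
  if (is.character(config)) config <- readConfig(config)
  config <- .merge_config(defaultConfig(), config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log_file <- out("pipeline.log.jsonl")
  if (file.exists(log_file)) unlink(log_file)
  t0 <- Sys.time()
  truth <- NULL

  if (config$pipeline == "simulate") {
    sc <- config$simulate
    design <- .design_from_config(sc$samples)
    ratios <- switch(sc$ratio_mode,
      constant = rep(sc$ratio, sc$n_transcripts),
      grid = rep_len(rep(sc$ratios,
                         each = ceiling(sc$n_transcripts / length(sc$ratios))),
                     sc$n_transcripts),
      template = {
        tpl <- syntheticTemplate(sc$template_file %||% NULL)
        i <- seq_len(min(sc$n_transcripts, nrow(tpl)))
        2^applyRegulationMode(tpl$log2_ratio[i], sc$regulation_mode)
      },
      stop("unknown ratio_mode: ", sc$ratio_mode))
    sim <- simulateReads(
      ratios, design, reads_per_transcript = sc$reads_per_transcript,
      read_count_mode = sc$read_count_mode, read_length = sc$read_length,
      p_U = sc$p_U, p_G = sc$p_G,
      rate_tc_labelled = sc$rate_tc_labelled,
      rate_tc_background = sc$rate_tc_background,
      rate_ga_labelled = sc$rate_ga_labelled,
      rate_ga_background = sc$rate_ga_background,
      theta_noise_sd = sc$theta_noise_sd, seed = config$seed)
    truth <- sim$truth
    write.table(truth, out("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts <- sim$counts
    writeCountTable(counts, out("counts.tsv"), out("samples.tsv"))
    if (isTRUE(sc$emit_sam))
      emitSyntheticSam(sim$tallies, out("reads.sam"), out("reference.fa"),
                       out("annotation.gtf"))
    .log_stage(log_file, "simulate", transcripts = length(ratios),
               reads = nrow(sim$tallies))
  } else if (config$pipeline == "tally") {
    tc <- config$tally
    if (!length(tc$samples)) stop("stage tally: no samples configured")
    design <- .design_from_config(tc$samples)
    tallies <- do.call(rbind, lapply(tc$samples, function(s)
      tallyReads(s$sam, tc$fasta, tc$annotation, s$sample_id,
                 vcf_file = tc$vcf, mapq_min = tc$mapq_min,
                 base_qual_min = tc$base_qual_min,
                 stranded = tc$stranded)))
    writeTallyFile(tallies, out("tallies.tsv"))
    counts <- aggregateReads(tallies, design)
    writeCountTable(counts, out("counts.tsv"), out("samples.tsv"))
    .log_stage(log_file, "tally", reads = nrow(tallies),
               groups = nrow(countTable(counts)))
  } else stop("unknown pipeline mode: ", config$pipeline)

  n_before <- length(unique(countTable(counts)$gene_id))
  counts <- filterLowCoverage(counts, config$filter$min_reads,
                              config$filter$min_samples)
  n_after <- length(unique(countTable(counts)$gene_id))
  .log_stage(log_file, "filter", genes_in = n_before, genes_out = n_after,
             removed = n_before - n_after,
             min_reads = config$filter$min_reads)
  if (!n_after) stop("stage filter: no genes pass the coverage filter")

  fit <- fitTilac(counts, chains = config$fit$chains,
                  warmup = config$fit$warmup, iter = config$fit$iter,
                  seed = config$seed)
  writePosterior(fit, out("posterior.tsv"), out("fit_metadata.json"))
  .log_stage(log_file, "fit", genes = nrow(posteriorSummary(fit)),
             converged = sum(posteriorSummary(fit)$converged))

  tests <- callSignificance(fit, config$test$mu_cutoff, config$test$alpha)
  writeTestResults(tests, out("results.tsv"))
  .log_stage(log_file, "test", tested = nrow(testResults(tests)),
             significant = sum(testResults(tests)$significant))

  if (nrow(testResults(tests)))
    tilacReport(tests, fit, counts, config$output_dir)
  else .log_stage(log_file, "report", skipped = "no tested genes")
  manifest <- .write_manifest(config, config$output_dir, t0)
  invisible(list(fit = fit, tests = tests, truth = truth,
                 counts = counts, manifest = manifest))
}

.write_manifest <- function(config, dir, t0) {
  files <- setdiff(list.files(dir), "manifest.json")
  paths <- file.path(dir, files)
  manifest <- list(
    tool = "tilac", version = as.character(packageVersion("tilac")),
    subcommand = config$pipeline, seed = config$seed, config = config,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(seq_along(files), function(i)
      list(file = files[i], md5 = unname(tools::md5sum(paths[i])))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Summary report of a fitted analysis
#'
#' Writes a ranked gene table (ordered by posterior mean log2 ratio), a
#' significance count table by direction, and an MA-style scatter of log2
#' ratio against per-gene read count (PDF).
#'
#' @param tests a \code{\linkS4class{TilacTests}} object.
#' @param fit the \code{\linkS4class{TilacFit}} behind it.
#' @param counts optional \code{\linkS4class{TilacCounts}} supplying read
#'   depths for the scatter.
#' @param output_dir directory for the report files.
#' @return invisibly, the significance count table.
#' @export
tilacReport <- function(tests, fit, counts = NULL, output_dir = ".") {
  stopifnot(is(tests, "TilacTests"))
  res <- testResults(tests)
  if (!nrow(res)) stop("empty results: nothing to report")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ranked <- res[order(-res$log2_ratio_mean), ]
  write.table(ranked, file.path(output_dir, "ranked_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  counts_tab <- as.data.frame(table(direction = factor(
    res$direction, levels = c("up", "down", "none"))))
  names(counts_tab)[2] <- "n_genes"
  write.table(counts_tab, file.path(output_dir, "significance_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(counts)) {
    tot <- rowSums(geneReadTotals(counts))
    depth <- tot[res$gene_id]
    grDevices::pdf(file.path(output_dir, "ma_plot.pdf"), width = 6,
                   height = 5)
    plot(log10(depth), res$log2_ratio_mean,
         col = ifelse(res$significant, "firebrick", "grey40"),
         pch = 16, cex = 0.6, xlab = "log10 total reads",
         ylab = "log2 TILAC ratio",
         main = "Internally normalized abundance ratios")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
  invisible(counts_tab)
}
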