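#' Draw labelled fractions for a target TILAC ratio
#'
#' Generates a (\eqn{\theta_{exp}}, \eqn{\theta_{cntl}}) pair whose ratio is
#' the requested abundance ratio: \eqn{\mathrm{logit}(\theta_{cntl})} is
#' drawn Normal around \eqn{\mathrm{logit}(1/(1 + \mathrm{ratio}))} with sd
#' \code{noise_sd}, and \eqn{\theta_{exp} = \mathrm{ratio} \cdot
#' \theta_{cntl}}. When the pair sums above 1 it is rescaled to sum to
#' \eqn{1 - 10^{-6}}, which preserves the ratio. With zero noise and ratio 1
#' both fractions are exactly 0.5.
#'
#' @param ratio positive true abundance ratio(s).
#' @param noise_sd sd of the logit-scale perturbation (default 0.5).
#' @return data.frame with columns \code{theta_exp}, \code{theta_cntl}.
#' @export
drawThetas <- function(ratio, noise_sd = 0.5) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  tc <- plogis(rnorm(length(ratio), qlogis(1 / (1 + ratio)), noise_sd))
  te <- ratio * tc
  tot <- te + tc
  over <- tot > 1 - 1e-6
  sc <- ifelse(over, (1 - 1e-6) / tot, 1)
  data.frame(theta_exp = te * sc, theta_cntl = tc * sc)
}

#' Simulate a dual-label experiment with known truth
#'
#' The generative model: per transcript, true labelled fractions are drawn
#' by \code{\link{drawThetas}} from the requested ratio; per sample, the
#' read count is either fixed or Poisson around a per-transcript mean; each
#' read is assigned by a Multinomial draw to the experimental-labelled,
#' control-labelled or unlabelled pool with probabilities
#' (\eqn{\theta_{exp}}, \eqn{\theta_{cntl}},
#' \eqn{1 - \theta_{exp} - \theta_{cntl}}); the read's U and G content is
#' Multinomial(read_length; p_U, p_G); mutation counts are Binomial in the
#' covered sites at the labelled or background per-base rate, with the
#' sample's labelling combination deciding which pool carries which label.
#' Unlabelled control samples use background rates throughout. Defaults are
#' the generative settings used throughout the package's calibration
#' studies: 200-base reads with quarter-U/quarter-G composition, s4U
#' (T-to-C) rates 0.05 labelled / 0.001 background, s6G (G-to-A) rates
#' 0.02 labelled / 0.004 background.
#'
#' @param ratios vector of true abundance ratios, one per transcript.
#' @param design labelling design from \code{\link{tilacDesign}}.
#' @param reads_per_transcript fixed read count, or per-transcript Poisson
#'   means when \code{read_count_mode = "poisson"}; recycled across
#'   transcripts.
#' @param read_count_mode \code{"fixed"} (default) or \code{"poisson"}.
#' @param read_length read length in bases (default 200).
#' @param p_U,p_G per-base probabilities of a U (reference T) and G site
#'   (defaults 0.25 each).
#' @param rate_tc_labelled,rate_tc_background per-U T-to-C mutation
#'   probabilities (defaults 0.05, 0.001).
#' @param rate_ga_labelled,rate_ga_background per-G G-to-A mutation
#'   probabilities (defaults 0.02, 0.004).
#' @param theta_noise_sd logit-scale noise on the control fraction
#'   (default 0.5).
#' @param gene_ids optional transcript identifiers.
#' @param seed optional integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return list with \code{tallies} (per-read data.frame), \code{counts}
#'   (a \code{\linkS4class{TilacCounts}}) and \code{truth} (per-transcript
#'   data.frame of true ratios, realized fractions and per-sample read
#'   counts).
#' @export
simulateReads <- function(ratios, design,
                          reads_per_transcript = 500,
                          read_count_mode = c("fixed", "poisson"),
                          read_length = 200L, p_U = 0.25, p_G = 0.25,
                          rate_tc_labelled = 0.05, rate_tc_background = 0.001,
                          rate_ga_labelled = 0.02, rate_ga_background = 0.004,
                          theta_noise_sd = 0.5, gene_ids = NULL,
                          seed = NULL) {
  read_count_mode <- match.arg(read_count_mode)
  stopifnot(p_U >= 0, p_G >= 0, p_U + p_G <= 1,
            rate_tc_labelled >= rate_tc_background,
            rate_ga_labelled >= rate_ga_background)
  msg <- .validate_design(design)
  if (!is.null(msg)) stop(msg)
  if (!any(design$combination == "forward") ||
      !any(design$combination == "reverse"))
    warning("design lacks a forward or a reverse sample; the model is ",
            "fittable but unbalanced")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  nT <- length(ratios)
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%0*d", nchar(nT), seq_len(nT))
  mu_reads <- rep_len(reads_per_transcript, nT)

  th <- drawThetas(ratios, theta_noise_sd)
  nS <- nrow(design)
  counts_mat <- matrix(0L, nT, nS,
                       dimnames = list(gene_ids, design$sample_id))

  pieces <- vector("list", nT * nS)
  pc <- 0L
  for (s in seq_len(nS)) {
    comb <- design$combination[s]
    n_reads <- if (read_count_mode == "fixed") as.integer(mu_reads)
               else rpois(nT, mu_reads)
    counts_mat[, s] <- n_reads
    for (g in seq_len(nT)) {
      n <- n_reads[g]
      if (n == 0L) next
      if (comb == "unlabelled") {
        pool <- rep(3L, n)  # no label in this sample
      } else {
        pool <- sample.int(3L, n, replace = TRUE,
                           prob = c(th$theta_exp[g], th$theta_cntl[g],
                                    1 - th$theta_exp[g] - th$theta_cntl[g]))
      }
      ## which pools carry which label in this sample
      s4u <- switch(comb, forward = pool == 1L, reverse = pool == 2L,
                    unlabelled = rep(FALSE, n))
      s6g <- switch(comb, forward = pool == 2L, reverse = pool == 1L,
                    unlabelled = rep(FALSE, n))
      base <- rmultinom(n, read_length, c(p_U, p_G, 1 - p_U - p_G))
      n_U <- base[1L, ]; n_G <- base[2L, ]
      y_TC <- rbinom(n, n_U,
                     ifelse(s4u, rate_tc_labelled, rate_tc_background))
      y_GA <- rbinom(n, n_G,
                     ifelse(s6g, rate_ga_labelled, rate_ga_background))
      pc <- pc + 1L
      pieces[[pc]] <- data.frame(
        read_id = paste0(design$sample_id[s], ":", gene_ids[g], ":",
                         seq_len(n)),
        sample_id = design$sample_id[s], gene_id = gene_ids[g],
        feature_class = "exonic", n_U = n_U, n_G = n_G,
        y_TC = y_TC, y_GA = y_GA, stringsAsFactors = FALSE)
    }
  }
  tallies <- if (pc) do.call(rbind, pieces[seq_len(pc)]) else .empty_tally()
  rownames(tallies) <- NULL
  truth <- data.frame(gene_id = gene_ids, true_ratio = ratios,
                      log2_true_ratio = log2(ratios),
                      theta_exp = th$theta_exp, theta_cntl = th$theta_cntl,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, setNames(as.data.frame(counts_mat),
                                 paste0("reads_", design$sample_id)))
  rownames(truth) <- NULL
  list(tallies = tallies,
       counts = aggregateReads(tallies, design),
       truth = truth)
}

#' Transform template log2 ratios into a regulation regime
#'
#' Emulates three regimes from one template of (mostly negative, i.e.
#' repressed) log2 ratios: \code{"down"} leaves the template unchanged,
#' \code{"up"} negates each log2 ratio (an involution), and
#' \code{"symmetric"} centres the template so the mean log2 ratio is
#' exactly zero.
#'
#' @param log2_ratios template log2 ratios (non-empty).
#' @param mode \code{"down"}, \code{"up"} or \code{"symmetric"}.
#' @return transformed log2 ratios.
#' @export
applyRegulationMode <- function(log2_ratios, mode = c("down", "up", "symmetric")) {
  if (!length(log2_ratios)) stop("template list is empty")
  mode <- match.arg(mode)
  switch(mode,
         down = log2_ratios,
         up = -log2_ratios,
         symmetric = log2_ratios - mean(log2_ratios))
}

#' Packaged synthetic simulation template
#'
#' A synthetic template of per-transcript read counts and log2 ratios whose
#' shape (long-tailed counts, predominantly repressed ratios) mimics a
#' transcription-inhibition experiment. It is generated data, not a real
#' dataset; real templates with the same two columns are accepted anywhere
#' this one is.
#'
#' @param file optional path to a template TSV with columns
#'   \code{read_count} and \code{log2_ratio}; defaults to the packaged
#'   synthetic template.
#' @return data.frame with columns \code{read_count}, \code{log2_ratio}.
#' @export
syntheticTemplate <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "synthetic_template.tsv",
                        package = "tilac", mustWork = TRUE)
  tpl <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("read_count", "log2_ratio") %in% names(tpl)))
  tpl
}

#' Accuracy sweep over read depths and mutation rates
#'
#' Simulates, fits and scores cells of a (read count x labelled mutation
#' rate) grid, each cell spanning a grid of true ratios. Reported per cell:
#' bias and RMSE of the posterior mean log2 ratio against truth and the
#' empirical coverage of central 95\% posterior intervals.
#'
#' @param read_counts vector of reads per transcript per sample.
#' @param tc_rates,ga_rates labelled per-base mutation rates to cross
#'   (defaults 0.05 and 0.02; vary one, fix the other).
#' @param ratios true-ratio grid simulated in every cell (default the
#'   standard grid 0.01 to 100).
#' @param n_per_ratio transcripts per ratio per cell (default 10; cells are
#'   deliberately desk-scale).
#' @param design labelling design; default one forward, one reverse, one
#'   unlabelled sample.
#' @param chains,warmup,iter sampler settings per cell (reduced defaults for
#'   sweep throughput).
#' @param seed integer seed.
#' @param out_file optional TSV path for the report.
#' @return data.frame, one row per (read_count, tc_rate, ga_rate) cell.
#' @export
accuracySweep <- function(read_counts = c(50, 200, 500),
                          tc_rates = 0.05, ga_rates = 0.02,
                          ratios = c(0.01, 0.1, 0.5, 1, 1.5, 2, 10, 100),
                          n_per_ratio = 10, design = NULL,
                          chains = 2L, warmup = 400L, iter = 400L,
                          seed = 1L, out_file = NULL) {
  if (is.null(design))
    design <- tilacDesign(c("fwd1", "rev1", "unl1"),
                          c("forward", "reverse", "unlabelled"))
  grid <- expand.grid(read_count = read_counts, tc_rate = tc_rates,
                      ga_rate = ga_rates)
  truth_ratios <- rep(ratios, each = n_per_ratio)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- simulateReads(
      truth_ratios, design, reads_per_transcript = grid$read_count[i],
      rate_tc_labelled = grid$tc_rate[i], rate_ga_labelled = grid$ga_rate[i],
      seed = seed + i)
    fit <- fitTilac(sim$counts, chains = chains, warmup = warmup,
                    iter = iter, seed = seed + i)
    s <- posteriorSummary(fit)
    s <- s[match(sim$truth$gene_id, s$gene_id), ]
    err <- s$log2_ratio_mean - sim$truth$log2_true_ratio
    lo <- s$log2_ratio_mean - 1.96 * s$log2_ratio_sd
    hi <- s$log2_ratio_mean + 1.96 * s$log2_ratio_sd
    data.frame(grid[i, , drop = FALSE],
               n_transcripts = length(truth_ratios),
               bias = mean(err), rmse = sqrt(mean(err^2)),
               coverage95 = mean(sim$truth$log2_true_ratio >= lo &
                                 sim$truth$log2_true_ratio <= hi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_file))
    write.table(out, out_file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Write simulated tallies as a synthetic SAM/FASTA/GTF fixture
#'
#' Materializes simulator output as an alignment fixture: one synthetic
#' contig per gene, each read given its own segment of the contig whose
#' base composition matches the read's tallied U/G content, with the
#' tallied number of T-to-C and G-to-A mismatches injected into the read
#' sequence. Running \code{\link{tallyReads}} on the emitted files
#' reproduces the input tallies exactly. Reads are emitted with FLAG 99
#' (in the accepted filter set) and MAPQ 60.
#'
#' @param tallies per-read tally data.frame (single sample).
#' @param sam_file,fasta_file,gtf_file output paths (GTF optional but
#'   needed for a round trip through \code{\link{tallyReads}}).
#' @return invisibly, a list with the written paths.
#' @export
emitSyntheticSam <- function(tallies, sam_file, fasta_file, gtf_file = NULL) {
  .validate_tallies(tallies)
  tallies <- tallies[!is.na(tallies$gene_id), , drop = FALSE]
  genes <- unique(tallies$gene_id)
  contigs <- setNames(character(length(genes)), genes)
  sam_lines <- character(nrow(tallies))
  offs <- setNames(integer(length(genes)), genes)
  for (i in seq_len(nrow(tallies))) {
    g <- tallies$gene_id[i]
    nU <- tallies$n_U[i]; nG <- tallies$n_G[i]
    fill <- 10L
    ref_seg <- c(rep("T", nU), rep("G", nG), rep("A", fill))
    read_seg <- ref_seg
    if (tallies$y_TC[i] > 0)
      read_seg[seq_len(tallies$y_TC[i])] <- "C"
    if (tallies$y_GA[i] > 0)
      read_seg[nU + seq_len(tallies$y_GA[i])] <- "A"
    pos <- offs[[g]] + 1L
    offs[[g]] <- offs[[g]] + length(ref_seg)
    contigs[[g]] <- paste0(contigs[[g]], paste(ref_seg, collapse = ""))
    sam_lines[i] <- paste(
      tallies$read_id[i], 99L, g, pos, 60L,
      paste0(length(read_seg), "M"), "=", pos, 0L,
      paste(read_seg, collapse = ""),
      paste(rep("I", length(read_seg)), collapse = ""), sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", genes, "\tLN:", nchar(contigs[genes])))
  writeLines(c(header, sam_lines), sam_file)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(contigs), fasta_file)
  if (!is.null(gtf_file)) {
    gtf <- c(
      paste(genes, "synthetic", "gene", 1L, nchar(contigs[genes]), ".",
            "+", ".", sprintf('gene_id "%s";', genes), sep = "\t"),
      paste(genes, "synthetic", "exon", 1L, nchar(contigs[genes]), ".",
            "+", ".", sprintf('gene_id "%s";', genes), sep = "\t"))
    writeLines(gtf, gtf_file)
  }
  invisible(list(sam = sam_file, fasta = fasta_file, gtf = gtf_file))
}
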