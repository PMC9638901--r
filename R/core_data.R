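#' Construct a labelling design
#'
#' Describes which reciprocal labelling scheme each sequencing sample used.
#' In the \emph{forward} combination the experimental condition carries s4U
#' (read out through T-to-C mismatches) and the control carries s6G (G-to-A);
#' the \emph{reverse} combination swaps the two. \emph{Unlabelled} samples
#' carry neither analogue and anchor the background mutation rate. The
#' labelled indicator is 0 exactly for unlabelled samples.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param combination one of \code{"forward"}, \code{"reverse"},
#'   \code{"unlabelled"} per sample.
#' @param replicate positive integer replicate index per sample (default 1).
#' @return data.frame with columns \code{sample_id}, \code{combination},
#'   \code{replicate}, \code{labelled}.
#' @examples
#' tilacDesign(c("f1", "r1", "u1"), c("forward", "reverse", "unlabelled"))
#' @export
tilacDesign <- function(sample_id, combination, replicate = 1L) {
  combination <- match.arg(combination, COMBINATIONS, several.ok = TRUE)
  des <- data.frame(
    sample_id = as.character(sample_id),
    combination = combination,
    replicate = as.integer(replicate),
    labelled = as.integer(combination != "unlabelled"),
    stringsAsFactors = FALSE)
  msg <- .validate_design(des)
  if (!is.null(msg)) stop(msg)
  des
}

## channel -> condition routing for labelled samples
.channel_condition <- function(combination, mut_type) {
  ifelse(combination == "forward",
         ifelse(mut_type == "TC", "experimental", "control"),
         ifelse(combination == "reverse",
                ifelse(mut_type == "TC", "control", "experimental"),
                NA_character_))
}

.validate_tallies <- function(tallies) {
  need <- c("read_id", "sample_id", "gene_id", "feature_class",
            "n_U", "n_G", "y_TC", "y_GA")
  miss <- setdiff(need, names(tallies))
  if (length(miss))
    stop("tallies missing columns: ", paste(miss, collapse = ", "))
  if (any(tallies$y_TC > tallies$n_U) || any(tallies$y_GA > tallies$n_G) ||
      any(tallies$y_TC < 0) || any(tallies$y_GA < 0))
    stop("malformed tallies: mutation counts must satisfy 0 <= y <= covered bases")
  invisible(tallies)
}

#' Aggregate per-read tallies into grouped counts
#'
#' Collapses per-read mutation tallies into groups sharing
#' (gene, sample, mutation channel, mutations per read). Every read
#' contributes one increment per channel: once for its T-to-C count against
#' the reference-T positions it covers, once for its G-to-A count against
#' reference-G positions. The grouped counts are the model's input.
#'
#' @param tallies data.frame of per-read tallies as produced by
#'   \code{\link{tallyReads}} or \code{\link{simulateReads}}: columns
#'   \code{read_id}, \code{sample_id}, \code{gene_id}, \code{feature_class},
#'   \code{n_U}, \code{n_G}, \code{y_TC}, \code{y_GA}.
#' @param design labelling design from \code{\link{tilacDesign}}; defaults to
#'   a single-sample design inferred from the tallies (all samples must then
#'   be supplied explicitly for model fitting).
#' @param drop_ambiguous drop reads whose \code{feature_class} is
#'   \code{"ambiguous"} (default TRUE); reads assigned to no gene
#'   (\code{gene_id} NA) are always dropped.
#' @return a \code{\linkS4class{TilacCounts}} object.
#' @examples
#' tl <- data.frame(read_id = c("r1", "r2", "r3"), sample_id = "s1",
#'   gene_id = "g1", feature_class = "exonic",
#'   n_U = 50, n_G = 50, y_TC = c(0, 0, 2), y_GA = 0)
#' aggregateReads(tl, tilacDesign("s1", "forward"))
#' @export
aggregateReads <- function(tallies, design = NULL, drop_ambiguous = TRUE) {
  .validate_tallies(tallies)
  keep <- !is.na(tallies$gene_id)
  if (drop_ambiguous) keep <- keep & tallies$feature_class != "ambiguous"
  tallies <- tallies[keep, , drop = FALSE]
  if (is.null(design))
    design <- tilacDesign(unique(tallies$sample_id), "forward")
  if (!nrow(tallies))
    return(new("TilacCounts", counts = .empty_counts(), design = design))
  long <- rbind(
    data.frame(gene_id = tallies$gene_id, sample_id = tallies$sample_id,
               mut_type = "TC", n_mut = tallies$y_TC, bases = tallies$n_U),
    data.frame(gene_id = tallies$gene_id, sample_id = tallies$sample_id,
               mut_type = "GA", n_mut = tallies$y_GA, bases = tallies$n_G))
  if (nrow(long)) {
    grp <- paste(long$gene_id, long$sample_id, long$mut_type, long$n_mut,
                 sep = "\r")
    n_reads <- as.vector(table(grp)[unique(grp)])
    mean_bases <- tapply(long$bases, grp, mean)[unique(grp)]
    key <- do.call(rbind, strsplit(unique(grp), "\r", fixed = TRUE))
    cnt <- data.frame(
      gene_id = key[, 1], sample_id = key[, 2], mut_type = key[, 3],
      n_mut = as.integer(key[, 4]), n_reads = as.integer(n_reads),
      mean_bases = as.numeric(mean_bases), stringsAsFactors = FALSE)
  } else {
    cnt <- .empty_counts()
  }
  cnt <- .sort_counts(cnt)
  new("TilacCounts", counts = cnt, design = design)
}

.empty_counts <- function() {
  data.frame(gene_id = character(), sample_id = character(),
             mut_type = character(), n_mut = integer(), n_reads = integer(),
             mean_bases = numeric(), stringsAsFactors = FALSE)
}

## deterministic row order so written tables are diffable
.sort_counts <- function(cnt) {
  o <- order(cnt$gene_id, cnt$sample_id, cnt$mut_type, cnt$n_mut)
  cnt <- cnt[o, , drop = FALSE]
  rownames(cnt) <- NULL
  cnt
}

#' Per-gene, per-sample total read counts
#'
#' Sums group counts over one mutation channel (both channels tally every
#' read, so either gives the total).
#'
#' @param x a \code{\linkS4class{TilacCounts}} object.
#' @return matrix of read counts, genes x samples.
#' @export
geneReadTotals <- function(x) {
  stopifnot(is(x, "TilacCounts"))
  cnt <- countTable(x)
  cnt <- cnt[cnt$mut_type == "TC", , drop = FALSE]
  genes <- sort(unique(cnt$gene_id))
  samples <- sampleDesign(x)$sample_id
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(cnt)) {
    agg <- aggregate(n_reads ~ gene_id + sample_id, cnt, sum)
    m[cbind(agg$gene_id, agg$sample_id)] <- agg$n_reads
  }
  m
}

#' Remove genes with insufficient read coverage
#'
#' Keeps genes with at least \code{min_reads} reads in at least
#' \code{min_samples} samples. Posterior ratio estimates for genes below this
#' coverage are dominated by the prior and unstable, so they are removed
#' before model fitting. The default threshold of 200 reads in two samples
#' reflects the depth at which simulation shows abundance ratios between 0.1
#' and 100 are recovered with high confidence.
#'
#' @param x a \code{\linkS4class{TilacCounts}} object.
#' @param min_reads minimum total reads per sample (default 200); the
#'   boundary is inclusive (a gene with exactly \code{min_reads} is kept).
#' @param min_samples minimum number of samples reaching \code{min_reads}
#'   (default 2).
#' @param verbose log the number of genes removed (default FALSE).
#' @return a filtered \code{\linkS4class{TilacCounts}} object.
#' @export
filterLowCoverage <- function(x, min_reads = 200L, min_samples = 2L,
                              verbose = FALSE) {
  stopifnot(is(x, "TilacCounts"))
  if (min_reads < 1) stop("min_reads must be >= 1")
  if (nrow(sampleDesign(x)) < 1) stop("design lists no samples")
  tot <- geneReadTotals(x)
  keep <- rownames(tot)[rowSums(tot >= min_reads) >= min_samples]
  cnt <- countTable(x)
  dropped <- length(unique(cnt$gene_id)) - length(keep)
  if (verbose)
    message(sprintf("filterLowCoverage: removed %d genes (< %d reads in >= %d samples); %d retained",
                    dropped, min_reads, min_samples, length(keep)))
  cnt <- cnt[cnt$gene_id %in% keep, , drop = FALSE]
  rownames(cnt) <- NULL
  new("TilacCounts", counts = cnt, design = sampleDesign(x))
}

#' Raw per-gene mutation rates
#'
#' Model-free mutation rates per gene, sample and feature class: total
#' mismatches divided by total observations of the reference base (T-to-C
#' mutations over covered T positions; G-to-A over covered G positions).
#' Exonic and intronic reads are summarized separately. Genes whose read
#' count in a (sample, feature class) stratum falls below \code{min_reads}
#' are omitted, as are strata with no observed reference bases (the rate is
#' undefined there, not zero).
#'
#' @param tallies per-read tally data.frame (see \code{\link{aggregateReads}}).
#' @param min_reads minimum reads per (gene, sample, feature class) stratum
#'   (default 200, inclusive).
#' @return data.frame with columns \code{gene_id}, \code{sample_id},
#'   \code{feature_class}, \code{rate_TC}, \code{rate_GA}, \code{n_reads}.
#' @export
rawMutationRates <- function(tallies, min_reads = 200L) {
  .validate_tallies(tallies)
  tallies <- tallies[!is.na(tallies$gene_id) &
                     tallies$feature_class != "ambiguous", , drop = FALSE]
  if (!nrow(tallies))
    return(data.frame(gene_id = character(), sample_id = character(),
                      feature_class = character(), rate_TC = numeric(),
                      rate_GA = numeric(), n_reads = integer()))
  agg <- aggregate(cbind(n_U, n_G, y_TC, y_GA, n_reads = 1) ~
                     gene_id + sample_id + feature_class, tallies, sum)
  agg <- agg[agg$n_reads >= min_reads & agg$n_U > 0 & agg$n_G > 0, ,
             drop = FALSE]
  out <- data.frame(
    gene_id = agg$gene_id, sample_id = agg$sample_id,
    feature_class = agg$feature_class,
    rate_TC = agg$y_TC / agg$n_U, rate_GA = agg$y_GA / agg$n_G,
    n_reads = as.integer(agg$n_reads), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$sample_id, out$feature_class), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- TSV readers/writers ----------------------------------------------

#' Read and write grouped count tables and sample sheets
#'
#' Tab-separated interchange formats. The count table has one row per
#' (gene, sample, channel, mutations-per-read) group with columns
#' \code{gene_id}, \code{sample_id}, \code{mut_type}, \code{n_mut},
#' \code{n_reads}, \code{mean_bases}; rows are sorted deterministically so
#' written outputs are diffable. The sample sheet has columns
#' \code{sample_id}, \code{combination}, \code{replicate}.
#'
#' @param counts_file,sheet_file paths to TSV files.
#' @param x a \code{\linkS4class{TilacCounts}} object (for writers, which
#'   emit both files).
#' @return \code{readCountTable}: a \code{TilacCounts};
#'   \code{readSampleSheet}: a design data.frame; writers return their input
#'   invisibly.
#' @name count-io
NULL

#' @rdname count-io
#' @export
readSampleSheet <- function(sheet_file) {
  sh <- read.delim(sheet_file, stringsAsFactors = FALSE)
  need <- c("sample_id", "combination", "replicate")
  if (!all(need %in% names(sh)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  tilacDesign(sh$sample_id, sh$combination, sh$replicate)
}

#' @rdname count-io
#' @export
readCountTable <- function(counts_file, sheet_file = NULL) {
  cnt <- read.delim(counts_file, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character",
                                   sample_id = "character"))
  design <- if (is.null(sheet_file))
    tilacDesign(unique(cnt$sample_id), "forward")
  else readSampleSheet(sheet_file)
  new("TilacCounts", counts = .sort_counts(cnt), design = design)
}

#' @rdname count-io
#' @export
writeCountTable <- function(x, counts_file, sheet_file = NULL) {
  stopifnot(is(x, "TilacCounts"))
  write.table(.sort_counts(countTable(x)), counts_file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_file)) {
    sh <- sampleDesign(x)[, c("sample_id", "combination", "replicate")]
    write.table(sh, sheet_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Read or write per-read tallies as TSV
#'
#' @param tallies per-read tally data.frame.
#' @param file path to a TSV file.
#' @return \code{readTallyFile}: the tally data.frame; the writer returns its
#'   input invisibly.
#' @export
writeTallyFile <- function(tallies, file) {
  .validate_tallies(tallies)
  write.table(tallies, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tallies)
}

#' @rdname writeTallyFile
#' @export
readTallyFile <- function(file) {
  .validate_tallies(read.delim(file, stringsAsFactors = FALSE,
                               colClasses = c(read_id = "character",
                                              sample_id = "character",
                                              gene_id = "character")))
}
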