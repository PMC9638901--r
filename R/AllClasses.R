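#' @import methods
#' @importFrom stats dpois dnorm rnorm runif rbinom rpois rmultinom plogis
#'   qlogis pnorm p.adjust sd var setNames aggregate lm coef quantile rexp
#'   acf median
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom graphics plot abline
#' @importFrom grDevices pdf dev.off
NULL

MUTATION_TYPES <- c("TC", "GA")
COMBINATIONS <- c("forward", "reverse", "unlabelled")

#' TilacCounts: grouped per-read mutation counts for a dual-label experiment
#'
#' Reads are aggregated into groups sharing (gene, sample, mutation channel,
#' mutations per read); the group sizes are the sufficient statistics of the
#' Poisson-mixture model. Each read contributes one group increment per
#' mutation channel (T-to-C and G-to-A), so summing group counts over either
#' channel recovers the gene's total read count in that sample.
#'
#' @slot counts data.frame with columns \code{gene_id}, \code{sample_id},
#'   \code{mut_type} (\code{"TC"} or \code{"GA"}), \code{n_mut}
#'   (mutations per read defining the group), \code{n_reads} (group size) and
#'   \code{mean_bases} (mean number of reference T or G positions covered by
#'   the group's reads).
#' @slot design data.frame describing the labelling scheme; see
#'   \code{\link{tilacDesign}}.
#'
#' @seealso \code{\link{aggregateReads}}, \code{\link{readCountTable}},
#'   \code{\link{fitTilac}}
#' @export
setClass("TilacCounts", slots = c(counts = "data.frame", design = "data.frame"))

setValidity("TilacCounts", function(object) {
  cnt <- object@counts
  des <- object@design
  need <- c("gene_id", "sample_id", "mut_type", "n_mut", "n_reads", "mean_bases")
  if (!all(need %in% names(cnt)))
    return(paste("counts must have columns:", paste(need, collapse = ", ")))
  if (nrow(cnt)) {
    if (!all(cnt$mut_type %in% MUTATION_TYPES))
      return("mut_type must be 'TC' or 'GA'")
    if (any(cnt$n_mut < 0)) return("n_mut must be non-negative")
    if (any(cnt$n_reads < 1)) return("n_reads must be positive")
  }
  msg <- .validate_design(des)
  if (!is.null(msg)) return(msg)
  if (nrow(cnt) && !all(cnt$sample_id %in% des$sample_id))
    return("counts contain sample ids absent from the design")
  TRUE
})

.validate_design <- function(des) {
  need <- c("sample_id", "combination", "replicate", "labelled")
  if (!all(need %in% names(des)))
    return(paste("design must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(des$sample_id)) return("duplicate sample ids in design")
  if (!all(des$combination %in% COMBINATIONS))
    return("combination must be forward, reverse or unlabelled")
  if (any(des$replicate < 1)) return("replicate must be a positive integer")
  bad <- xor(des$combination == "unlabelled", des$labelled == 0L)
  if (any(bad)) return("labelled indicator must be 0 exactly for unlabelled samples")
  NULL
}

#' TilacFit: posterior of the dual-label Poisson mixture model
#'
#' Holds posterior draws and summaries for the per-gene labelled fractions
#' (\eqn{\theta_{exp}}, \eqn{\theta_{cntl}}), the derived log2 TILAC ratio
#' \eqn{\log_2(\theta_{exp}/\theta_{cntl})}, and the global per-channel
#' mutation rates, together with sampler diagnostics.
#'
#' @slot summary per-gene posterior summary data.frame.
#' @slot rates per-channel global-rate posterior summary data.frame.
#' @slot draws list of draw matrices (rows = kept draws across chains):
#'   \code{log2_ratio}, \code{theta_exp}, \code{theta_cntl} (columns = genes),
#'   \code{lambda_u}, \code{lambda_l}, \code{TL} (columns = channels).
#' @slot settings list recording priors, sampler configuration and seed.
#' @export
setClass("TilacFit", slots = c(
  summary = "data.frame", rates = "data.frame",
  draws = "list", settings = "list"))

#' TilacTests: composite-null test results on log2 TILAC ratios
#'
#' @slot results per-gene data.frame with the TREAT-style composite-null
#'   p-value, its Benjamini-Hochberg adjustment, the significance call and
#'   direction.
#' @slot config list with \code{mu_cutoff} and \code{alpha}.
#' @slot excluded character vector of gene ids excluded from testing
#'   (failed convergence gates).
#' @export
setClass("TilacTests", slots = c(
  results = "data.frame", config = "list", excluded = "character"))

setMethod("show", "TilacCounts", function(object) {
  cnt <- object@counts
  cat("TilacCounts:", length(unique(cnt$gene_id)), "genes,",
      nrow(object@design), "samples,", nrow(cnt), "count groups\n")
  tab <- table(factor(object@design$combination, levels = COMBINATIONS))
  cat("  design:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "TilacFit", function(object) {
  s <- object@summary
  cat("TilacFit:", nrow(s), "genes;",
      object@settings$chains, "chains x", object@settings$iter, "kept draws\n")
  if (nrow(s)) {
    cat(sprintf("  log2 TILAC ratio: median %.3f [%.3f, %.3f]\n",
        stats::median(s$log2_ratio_mean), min(s$log2_ratio_mean),
        max(s$log2_ratio_mean)))
    cat(sprintf("  convergence: %d/%d genes pass (Rhat <= %.2f, ESS >= %d)\n",
        sum(s$converged), nrow(s), object@settings$rhat_max,
        object@settings$ess_min))
  }
  invisible(object)
})

setMethod("show", "TilacTests", function(object) {
  r <- object@results
  cat("TilacTests:", nrow(r), "genes tested;",
      sum(r$significant), "significant at FDR", object@config$alpha,
      "(|log2 ratio| cutoff", object@config$mu_cutoff, ")\n")
  if (length(object@excluded))
    cat("  excluded (non-converged):", length(object@excluded), "genes\n")
  invisible(object)
})
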