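#' Composite-null p-value for a fold-change threshold
#'
#' Tests the composite null that the true log2 abundance ratio lies inside
#' \eqn{[-c, c]} (rather than the point null of exactly zero), using the
#' normal approximation to the posterior of the log2 ratio. The p-value is
#' the two-boundary tail sum
#' \deqn{p = S\left(\frac{|m| - c}{s}\right) + S\left(\frac{|m| + c}{s}\right)}
#' where \eqn{m} and \eqn{s} are the posterior mean and sd, \eqn{c} the
#' magnitude cutoff and \eqn{S} the standard-normal upper-tail function.
#' Evaluated at the boundary of the null set, this is conservative; at
#' \eqn{m = 0} the two tails are complementary and \eqn{p = 1} exactly.
#'
#' @param mean posterior mean(s) of the log2 ratio.
#' @param sd posterior standard deviation(s), strictly positive.
#' @param mu_cutoff magnitude threshold \eqn{c \ge 0} on the log2 scale
#'   (default 0.5).
#' @return p-value(s) in (0, 1].
#' @examples
#' treatPvalue(1.5, 0.25)           # strong effect
#' treatPvalue(0, 0.25)             # exactly 1
#' @export
treatPvalue <- function(mean, sd, mu_cutoff = 0.5) {
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("sd must be positive")
  if (mu_cutoff < 0) stop("mu_cutoff must be >= 0")
  p <- pnorm((abs(mean) - mu_cutoff) / sd, lower.tail = FALSE) +
       pnorm((abs(mean) + mu_cutoff) / sd, lower.tail = FALSE)
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' preserving input order. Thin wrapper over \code{stats::p.adjust} with
#' input validation matching the testing layer's contract.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bhAdjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Call significant changes in the TILAC ratio
#'
#' Applies the composite-null test to every converged gene in a model fit,
#' adjusts across the tested family with Benjamini-Hochberg, and calls a
#' gene significant when its adjusted p-value falls below \code{alpha}.
#' Genes failing the sampler's convergence gates are excluded from the
#' tested family (not assigned p = 1) and reported in the result object.
#'
#' @param fit a \code{\linkS4class{TilacFit}} object.
#' @param mu_cutoff magnitude threshold on the log2 ratio (default 0.5).
#' @param alpha FDR level (default 0.05).
#' @return a \code{\linkS4class{TilacTests}} object; per-gene columns are
#'   \code{gene_id}, \code{log2_ratio_mean}, \code{log2_ratio_sd},
#'   \code{p_value}, \code{p_adjusted}, \code{significant} and
#'   \code{direction} (\code{"up"}, \code{"down"} or \code{"none"}).
#' @export
callSignificance <- function(fit, mu_cutoff = 0.5, alpha = 0.05) {
  stopifnot(is(fit, "TilacFit"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- posteriorSummary(fit)
  if (!nrow(s)) {
    warning("empty posterior summary; no genes to test")
    return(new("TilacTests", results = .empty_results(),
               config = list(mu_cutoff = mu_cutoff, alpha = alpha),
               excluded = character()))
  }
  excluded <- s$gene_id[!s$converged]
  if (length(excluded))
    message(sprintf("callSignificance: excluding %d non-converged genes from the BH family",
                    length(excluded)))
  s <- s[s$converged, , drop = FALSE]
  p <- treatPvalue(s$log2_ratio_mean, s$log2_ratio_sd, mu_cutoff)
  padj <- bhAdjust(p)
  sig <- padj < alpha
  res <- data.frame(
    gene_id = s$gene_id,
    log2_ratio_mean = s$log2_ratio_mean,
    log2_ratio_sd = s$log2_ratio_sd,
    p_value = p, p_adjusted = padj, significant = sig,
    direction = ifelse(!sig, "none",
                       ifelse(s$log2_ratio_mean > 0, "up", "down")),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  new("TilacTests", results = res,
      config = list(mu_cutoff = mu_cutoff, alpha = alpha),
      excluded = as.character(excluded))
}

.empty_results <- function() {
  data.frame(gene_id = character(), log2_ratio_mean = numeric(),
             log2_ratio_sd = numeric(), p_value = numeric(),
             p_adjusted = numeric(), significant = logical(),
             direction = character(), stringsAsFactors = FALSE)
}

#' Write test results to TSV
#'
#' @param tests a \code{\linkS4class{TilacTests}} object.
#' @param file output path.
#' @return the input, invisibly.
#' @export
writeTestResults <- function(tests, file) {
  stopifnot(is(tests, "TilacTests"))
  write.table(testResults(tests), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tests)
}
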