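#' Prior configuration for the dual-label mixture model
#'
#' Weakly informative priors. The background per-read Poisson rate
#' \eqn{\lambda_u} gets a Normal prior on the log scale centred at -2
#' (about 0.14 mutations per read, generous for sequencing error); the
#' labelling increment \eqn{TL} gets an exponential prior with rate 0.5
#' (mean 2, the scale of per-read mutation counts in well-labelled reads);
#' the labelled rate is the sum \eqn{\lambda_l = \lambda_u + TL}, which
#' enforces \eqn{\lambda_l \ge \lambda_u}. Per-gene labelled fractions are
#' given Normal(0, 1.5) priors on the logit scale, close to uniform on (0,1)
#' with light shrinkage away from the boundaries.
#'
#' @param mu_log_lambda_u,sd_log_lambda_u Normal prior on
#'   \eqn{\log \lambda_u} (defaults -2 and 2).
#' @param tl_rate rate of the exponential prior on \eqn{TL} (default 0.5).
#' @param theta_logit_sd sd of the Normal prior on logit labelled fractions
#'   (default 1.5).
#' @return list of prior parameters.
#' @export
tilacPriors <- function(mu_log_lambda_u = -2, sd_log_lambda_u = 2,
                        tl_rate = 0.5, theta_logit_sd = 1.5) {
  stopifnot(sd_log_lambda_u > 0, tl_rate > 0, theta_logit_sd > 0)
  list(mu_log_lambda_u = mu_log_lambda_u, sd_log_lambda_u = sd_log_lambda_u,
       tl_rate = tl_rate, theta_logit_sd = theta_logit_sd)
}

#' Per-read mixture log-likelihood
#'
#' Log-probability of observing \code{y} mutations in one read under the
#' two-component Poisson mixture: with probability \eqn{I\theta} the read
#' carries the metabolic label and mutates at the labelled rate
#' \eqn{\lambda_l}; otherwise at the background rate \eqn{\lambda_u}.
#' \deqn{\log[\, I\theta\,\mathrm{Pois}(y;\lambda_l) +
#'   (1 - I\theta)\,\mathrm{Pois}(y;\lambda_u)\,]}
#' For an unlabelled control (\code{labelled = 0}) this reduces to the pure
#' background Poisson log-pmf. Computed by log-space summation.
#'
#' @param y non-negative mutation count(s) per read.
#' @param theta mixing fraction in [0, 1] (fraction of reads labelled).
#' @param lambda_l,lambda_u labelled and background Poisson rates
#'   (mutations per read), positive.
#' @param labelled indicator: 1 for labelled samples, 0 for unlabelled
#'   controls.
#' @return log-likelihood, vectorized over \code{y}.
#' @export
readLogLikelihood <- function(y, theta, lambda_l, lambda_u, labelled = 1) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  if (any(lambda_l <= 0) || any(lambda_u <= 0)) stop("rates must be positive")
  th <- labelled * theta
  a <- ifelse(th > 0, log(th) + dpois(y, lambda_l, log = TRUE), -Inf)
  b <- ifelse(th < 1, log1p(-th) + dpois(y, lambda_u, log = TRUE), -Inf)
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

## rates as a validated (lambda_u, lambda_l) pair per channel, ordered TC, GA
.check_rates <- function(rates) {
  need <- c("mut_type", "lambda_u", "lambda_l")
  if (!all(need %in% names(rates)))
    stop("rates must have columns: ", paste(need, collapse = ", "))
  if (!setequal(rates$mut_type, MUTATION_TYPES))
    stop("rates must cover both mutation types TC and GA")
  rates <- rates[match(MUTATION_TYPES, rates$mut_type), , drop = FALSE]
  if (any(rates$lambda_u <= 0) || any(rates$lambda_l < rates$lambda_u))
    stop("need lambda_l >= lambda_u > 0")
  rates
}

## internal model frame: rows of the likelihood, split into mixture rows
## (labelled samples, routed to a gene x condition theta) and pure-background
## rows (unlabelled controls)
.model_frame <- function(x) {
  cnt <- countTable(x)
  des <- sampleDesign(x)
  genes <- sort(unique(cnt$gene_id))
  comb <- setNames(des$combination, des$sample_id)[cnt$sample_id]
  if (anyNA(comb)) stop("counts contain sample ids absent from the design")
  chan <- match(cnt$mut_type, MUTATION_TYPES)
  gi <- match(cnt$gene_id, genes)
  cond <- match(.channel_condition(comb, cnt$mut_type),
                c("experimental", "control"))
  is_mix <- comb != "unlabelled"
  mk <- function(idx) list(
    g = gi[idx], cond = cond[idx], chan = chan[idx],
    y = cnt$n_mut[idx], w = cnt$n_reads[idx],
    lgy = lgamma(cnt$n_mut[idx] + 1))
  list(genes = genes, mix = mk(which(is_mix)), bg = mk(which(!is_mix)))
}

## vectorized mixture log-lik over model-frame rows at clamped theta
.mix_ll <- function(fr, theta_row, log_ll, log_lu, lam_l, lam_u) {
  a <- log(theta_row) + fr$y * log_ll[fr$chan] - lam_l[fr$chan] - fr$lgy
  b <- log1p(-theta_row) + fr$y * log_lu[fr$chan] - lam_u[fr$chan] - fr$lgy
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

.bg_ll <- function(fr, log_lu, lam_u) {
  sum(fr$w * (fr$y * log_lu[fr$chan] - lam_u[fr$chan] - fr$lgy))
}

.clamp_theta <- function(theta, floor = 1e-6) pmin(pmax(theta, floor), 1 - floor)

#' Joint log-likelihood of a grouped count table
#'
#' Sums the per-read mixture log-likelihood over both mutation channels of
#' every count group (weighted by group size), routing the labelled fraction
#' by each sample's labelling combination: in a forward sample the T-to-C
#' channel reads off the experimental condition's fraction and G-to-A the
#' control's; a reverse sample swaps them; unlabelled controls contribute
#' pure background terms.
#'
#' @param x a \code{\linkS4class{TilacCounts}} object.
#' @param thetas data.frame with columns \code{gene_id}, \code{theta_exp},
#'   \code{theta_cntl}, one row per gene in \code{x}.
#' @param rates data.frame with columns \code{mut_type}, \code{lambda_u},
#'   \code{lambda_l} covering both channels.
#' @return scalar log-likelihood.
#' @export
datasetLogLikelihood <- function(x, thetas, rates) {
  stopifnot(is(x, "TilacCounts"))
  rates <- .check_rates(rates)
  fr <- .model_frame(x)
  if (!length(fr$mix$y) && !length(fr$bg$y)) return(0)
  i <- match(fr$genes, thetas$gene_id)
  if (anyNA(i) && length(fr$mix$y))
    stop("thetas missing genes: ",
         paste(head(fr$genes[is.na(i)]), collapse = ", "))
  th <- cbind(thetas$theta_exp[i], thetas$theta_cntl[i])
  if (any(th < 0 | th > 1, na.rm = TRUE)) stop("theta must lie in [0, 1]")
  lam_u <- rates$lambda_u; lam_l <- rates$lambda_l
  ll <- .bg_ll(fr$bg, log(lam_u), lam_u)
  if (length(fr$mix$y)) {
    theta_row <- .clamp_theta(th[cbind(fr$mix$g, fr$mix$cond)])
    ll <- ll + sum(fr$mix$w *
      .mix_ll(fr$mix, theta_row, log(lam_l), log(lam_u), lam_l, lam_u))
  }
  ll
}

#' TILAC ratio from labelled fractions
#'
#' The internally normalized abundance ratio between the experimental and
#' control conditions: \eqn{\theta_{exp}/\theta_{cntl}}, reported alongside
#' its log2, the scale used for testing and reporting.
#'
#' @param theta_exp,theta_cntl labelled fractions in (0, 1);
#'   \code{theta_cntl} must be strictly positive.
#' @return data.frame with columns \code{ratio} and \code{log2_ratio}.
#' @examples
#' tilacRatio(0.6, 0.3)   # ratio 2, log2 ratio 1
#' @export
tilacRatio <- function(theta_exp, theta_cntl) {
  if (any(theta_cntl <= 0)) stop("theta_cntl must be > 0: ratio undefined")
  if (any(theta_exp < 0)) stop("theta_exp must be >= 0")
  r <- theta_exp / theta_cntl
  data.frame(ratio = r, log2_ratio = log2(r))
}
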