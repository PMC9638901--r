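#' Deterministic quadrature posterior for a single gene
#'
#' Computes the exact posterior of one gene's labelled fractions by 2-D
#' numerical integration over (logit \eqn{\theta_{exp}},
#' logit \eqn{\theta_{cntl}}), with the global mutation rates held fixed.
#' With fixed rates the likelihood factorizes over the two conditions, so
#' the 2-D quadrature is evaluated as the product of two 1-D grids; the
#' grid is refined (doubled) until the posterior mean of the log2 ratio is
#' stable. This serves as an independent check of the MCMC sampler: it
#' shares no code path with it beyond the count-table container.
#'
#' @param x a \code{\linkS4class{TilacCounts}} object containing exactly one
#'   gene (unlabelled samples, if present, are inert here since the rates
#'   are fixed).
#' @param rates fixed global rates: data.frame (\code{mut_type},
#'   \code{lambda_u}, \code{lambda_l}).
#' @param theta_logit_sd sd of the Normal(0, sd) prior on the logit
#'   fractions (default 1.5, matching \code{\link{tilacPriors}}).
#' @param tol convergence tolerance on the posterior mean of the log2 ratio
#'   between successive grid refinements (default 1e-4).
#' @param max_n maximum number of grid nodes per dimension (default 16385);
#'   failure to converge by then is an error.
#' @return list with \code{log2_ratio_mean}, \code{log2_ratio_sd},
#'   \code{theta_exp_mean}, \code{theta_cntl_mean} and the final grid size
#'   \code{n_grid}.
#' @export
gridPosterior <- function(x, rates, theta_logit_sd = 1.5, tol = 1e-4,
                          max_n = 16385L) {
  stopifnot(is(x, "TilacCounts"))
  rates <- .check_rates(rates)
  fr <- .model_frame(x)
  if (length(fr$genes) > 1)
    stop("gridPosterior handles a single gene; got ", length(fr$genes))
  lam_u <- rates$lambda_u; lam_l <- rates$lambda_l
  mix <- fr$mix

  ## 1-D log-likelihood over a logit grid for one condition's rows
  cond_ll <- function(grid, cond) {
    i <- mix$cond == cond
    if (!any(i)) return(numeric(length(grid)))
    y <- mix$y[i]; w <- mix$w[i]; ch <- mix$chan[i]; lgy <- mix$lgy[i]
    dl <- y * log(lam_l[ch]) - lam_l[ch] - lgy
    du <- y * log(lam_u[ch]) - lam_u[ch] - lgy
    vapply(grid, function(a) {
      th <- .clamp_theta(plogis(a))
      aa <- log(th) + dl; bb <- log1p(-th) + du
      m <- pmax(aa, bb)
      sum(w * (m + log(exp(aa - m) + exp(bb - m))))
    }, numeric(1))
  }

  marg <- function(n) {
    grid <- seq(-13, 13, length.out = n)
    lapply(1:2, function(cond) {
      lp <- dnorm(grid, 0, theta_logit_sd, log = TRUE) + cond_ll(grid, cond)
      wgt <- exp(lp - max(lp)); wgt <- wgt / sum(wgt)
      l2 <- log2(.clamp_theta(plogis(grid)))
      list(mean_l2 = sum(wgt * l2),
           m2_l2 = sum(wgt * l2^2),
           mean_theta = sum(wgt * plogis(grid)))
    })
  }

  n <- 513L
  prev <- marg(n)
  repeat {
    n <- 2L * (n - 1L) + 1L
    if (n > max_n) stop("quadrature did not converge at max grid resolution")
    cur <- marg(n)
    d <- abs((cur[[1]]$mean_l2 - cur[[2]]$mean_l2) -
             (prev[[1]]$mean_l2 - prev[[2]]$mean_l2))
    if (d < tol) break
    prev <- cur
  }
  v <- (cur[[1]]$m2_l2 - cur[[1]]$mean_l2^2) +
       (cur[[2]]$m2_l2 - cur[[2]]$mean_l2^2)
  list(log2_ratio_mean = cur[[1]]$mean_l2 - cur[[2]]$mean_l2,
       log2_ratio_sd = sqrt(max(v, 0)),
       theta_exp_mean = cur[[1]]$mean_theta,
       theta_cntl_mean = cur[[2]]$mean_theta,
       n_grid = n)
}
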