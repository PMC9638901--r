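#' Fit the dual-label Bayesian Poisson mixture model
#'
#' Estimates the joint posterior over the global per-channel mutation rates
#' (background \eqn{\lambda_u} and labelled \eqn{\lambda_l = \lambda_u + TL},
#' shared across genes) and every gene's pair of labelled fractions
#' (\eqn{\theta_{exp}}, \eqn{\theta_{cntl}}), under the priors of
#' \code{\link{tilacPriors}}. The per-gene log2 TILAC ratio
#' \eqn{\log_2(\theta_{exp}/\theta_{cntl})} is derived from the draws.
#'
#' Sampling uses adaptive Metropolis-within-Gibbs: a joint random-walk
#' update of the four global rate parameters (on the log scale) alternating
#' with per-gene random-walk updates of the logit labelled fractions, which
#' are conditionally independent across genes given the global rates and are
#' therefore proposed and accepted for all genes simultaneously in
#' vectorized form. Proposal scales adapt during warm-up only. Labelled
#' fractions are kept inside \eqn{(10^{-6}, 1 - 10^{-6})} via the logit
#' parameterization; all mixture terms are evaluated by log-space summation.
#'
#' The background rate is anchored by unlabelled control samples; fitting
#' refuses to run without at least one unlabelled sample unless the
#' background (or the full rate set) is fixed explicitly. Convergence is
#' assessed per reported quantity with split-\eqn{\hat{R}} and effective
#' sample size; failing genes are flagged (\code{converged = FALSE}), never
#' silently accepted.
#'
#' @param x a \code{\linkS4class{TilacCounts}} object, normally after
#'   \code{\link{filterLowCoverage}}.
#' @param priors prior configuration from \code{\link{tilacPriors}}.
#' @param chains,warmup,iter number of chains (default 4), warm-up sweeps
#'   and kept sweeps per chain (default 1000 each).
#' @param seed integer seed; chains are run sequentially from one stream so
#'   the fit is fully reproducible.
#' @param fixed_background optional named vector \code{c(TC = , GA = )}
#'   fixing \eqn{\lambda_u} (mutations per read) instead of estimating it
#'   from unlabelled controls.
#' @param fixed_rates optional data.frame (\code{mut_type},
#'   \code{lambda_u}, \code{lambda_l}) fixing all global rates; only the
#'   gene fractions are then sampled.
#' @param rhat_max,ess_min convergence gates: split-\eqn{\hat{R}} at most
#'   \code{rhat_max} (default 1.01) and at least \code{ess_min} effective
#'   draws (default 100) for the reported log2 ratio.
#' @param verbose log progress.
#' @return a \code{\linkS4class{TilacFit}} object.
#' @export
fitTilac <- function(x, priors = tilacPriors(), chains = 4L, warmup = 1000L,
                     iter = 1000L, seed = 1L, fixed_background = NULL,
                     fixed_rates = NULL, rhat_max = 1.01, ess_min = 100,
                     verbose = FALSE) {
  stopifnot(is(x, "TilacCounts"), chains >= 1, warmup >= 0, iter >= 1)
  des <- sampleDesign(x)
  if (!is.null(fixed_rates)) fixed_rates <- .check_rates(fixed_rates)
  if (is.null(fixed_rates) && is.null(fixed_background) &&
      !any(des$combination == "unlabelled"))
    stop("no unlabelled control sample in the design: the background ",
         "mutation rate is not identifiable. Add an unlabelled sample or ",
         "fix the background with 'fixed_background'/'fixed_rates'.")
  if (!is.null(fixed_background)) {
    if (!all(MUTATION_TYPES %in% names(fixed_background)) ||
        any(fixed_background <= 0))
      stop("fixed_background must be a positive named vector c(TC=, GA=)")
    fixed_background <- fixed_background[MUTATION_TYPES]
  }
  fr <- .model_frame(x)
  G <- length(fr$genes)
  if (!G) stop("count table is empty")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  init <- .sampler_init(fr, priors, fixed_background, fixed_rates)
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (verbose) message("fitTilac: chain ", ch, "/", chains)
    runs[[ch]] <- .run_chain(fr, priors, init, warmup, iter)
  }
  .assemble_fit(fr, runs, priors, chains, warmup, iter, seed,
                rhat_max, ess_min, fixed_rates, verbose)
}

## data-informed starting point (each chain jitters around it)
.sampler_init <- function(fr, priors, fixed_background, fixed_rates) {
  emp_rate <- function(rows, k) {
    i <- rows$chan == k
    if (any(i)) max(sum(rows$w[i] * rows$y[i]) / sum(rows$w[i]), 1e-4)
    else exp(priors$mu_log_lambda_u)
  }
  if (!is.null(fixed_rates)) {
    list(u0 = log(fixed_rates$lambda_u),
         t0 = log(pmax(fixed_rates$lambda_l - fixed_rates$lambda_u, 1e-8)),
         free_u = FALSE, free_t = FALSE)
  } else {
    u0 <- if (!is.null(fixed_background)) log(fixed_background)
          else log(c(emp_rate(fr$bg, 1), emp_rate(fr$bg, 2)))
    lab <- c(emp_rate(fr$mix, 1), emp_rate(fr$mix, 2))
    t0 <- log(pmax(2 * lab - exp(u0), 0.2))
    list(u0 = u0, t0 = t0, free_u = is.null(fixed_background), free_t = TRUE)
  }
}

.run_chain <- function(fr, priors, init, warmup, iter) {
  G <- length(fr$genes)
  mix <- fr$mix
  ie <- which(mix$cond == 1L); ic <- which(mix$cond == 2L)
  sub <- function(idx) list(g = mix$g[idx], chan = mix$chan[idx],
                            y = mix$y[idx], w = mix$w[idx], lgy = mix$lgy[idx])
  re <- sub(ie); rc <- sub(ic)

  jit <- function(x, s) x + rnorm(length(x), 0, s)
  u <- if (init$free_u) jit(init$u0, 0.3) else init$u0
  t <- if (init$free_t) jit(init$t0, 0.3) else init$t0
  A <- rnorm(G, 0, 1); B <- rnorm(G, 0, 1)

  lam <- function(u, t) {
    lu <- exp(u); ll <- lu + exp(t)
    list(lu = lu, ll = ll, log_lu = log(lu), log_ll = log(ll))
  }
  L <- lam(u, t)
  te <- .clamp_theta(plogis(A)); tc <- .clamp_theta(plogis(B))
  ll_e <- .mix_ll(re, te[re$g], L$log_ll, L$log_lu, L$ll, L$lu)
  ll_c <- .mix_ll(rc, tc[rc$g], L$log_ll, L$log_lu, L$ll, L$lu)

  ## coordinate-wise global updates; each coordinate touches one channel,
  ## so only that channel's likelihood rows are recomputed
  coords <- rbind(
    if (init$free_u) data.frame(par = "u", k = 1:2),
    if (init$free_t) data.frame(par = "t", k = 1:2))
  sample_global <- !is.null(coords) && nrow(coords) > 0
  ie_ch <- lapply(1:2, function(k) which(re$chan == k))
  ic_ch <- lapply(1:2, function(k) which(rc$chan == k))
  ibg_ch <- lapply(1:2, function(k) which(fr$bg$chan == k))
  sub_rows <- function(rows, idx) list(g = rows$g[idx], chan = rows$chan[idx],
    y = rows$y[idx], w = rows$w[idx], lgy = rows$lgy[idx])
  lp_coord <- function(par, val) {
    if (par == "u") dnorm(val, priors$mu_log_lambda_u,
                          priors$sd_log_lambda_u, log = TRUE)
    else log(priors$tl_rate) - priors$tl_rate * exp(val) + val
  }

  s_glob <- rep(0.1, if (sample_global) nrow(coords) else 0)
  sA <- rep(0.8, G); sB <- rep(0.8, G)
  tsd <- priors$theta_logit_sd

  keep_te <- matrix(NA_real_, iter, G)
  keep_tc <- matrix(NA_real_, iter, G)
  keep_u <- matrix(NA_real_, iter, 2)
  keep_tl <- matrix(NA_real_, iter, 2)

  total <- warmup + iter
  for (sweep in seq_len(total)) {
    adapting <- sweep <= warmup
    gam <- if (adapting) min(0.25, 2 / sweep^0.6) else 0

    if (sample_global) {
      for (ci in seq_len(nrow(coords))) {
        par <- coords$par[ci]; k <- coords$k[ci]
        up <- u; tp <- t
        if (par == "u") up[k] <- u[k] + rnorm(1, 0, s_glob[ci])
        else tp[k] <- t[k] + rnorm(1, 0, s_glob[ci])
        Lp <- lam(up, tp)
        se <- ie_ch[[k]]; sc <- ic_ch[[k]]; sb <- ibg_ch[[k]]
        rek <- sub_rows(re, se); rck <- sub_rows(rc, sc)
        ll_ep <- .mix_ll(rek, te[rek$g], Lp$log_ll, Lp$log_lu, Lp$ll, Lp$lu)
        ll_cp <- .mix_ll(rck, tc[rck$g], Lp$log_ll, Lp$log_lu, Lp$ll, Lp$lu)
        bgk <- sub_rows(fr$bg, sb)
        newv <- if (par == "u") up[k] else tp[k]
        oldv <- if (par == "u") u[k] else t[k]
        lar <- sum(re$w[se] * (ll_ep - ll_e[se])) +
               sum(rc$w[sc] * (ll_cp - ll_c[sc])) +
               .bg_ll(bgk, Lp$log_lu, Lp$lu) - .bg_ll(bgk, L$log_lu, L$lu) +
               lp_coord(par, newv) - lp_coord(par, oldv)
        acc <- is.finite(lar) && log(runif(1)) < lar
        if (acc) {
          u <- up; t <- tp; L <- Lp
          ll_e[se] <- ll_ep; ll_c[sc] <- ll_cp
        }
        if (adapting)
          s_glob[ci] <- min(max(s_glob[ci] * exp(gam * (acc - 0.35)), 1e-4), 5)
      }
    }

    ## vectorized per-gene updates: genes are conditionally independent
    upd <- function(rows, par, th, ll_rows, sc) {
      parp <- par + rnorm(G, 0, sc)
      thp <- .clamp_theta(plogis(parp))
      llp <- .mix_ll(rows, thp[rows$g], L$log_ll, L$log_lu, L$ll, L$lu)
      delta <- numeric(G)
      if (length(rows$g)) {
        rs <- rowsum(rows$w * (llp - ll_rows), rows$g)
        delta[as.integer(rownames(rs))] <- rs[, 1]
      }
      lar <- delta + dnorm(parp, 0, tsd, log = TRUE) -
                     dnorm(par, 0, tsd, log = TRUE)
      acc <- log(runif(G)) < lar
      ri <- acc[rows$g]
      ll_rows[ri] <- llp[ri]
      list(par = ifelse(acc, parp, par), th = ifelse(acc, thp, th),
           ll = ll_rows, acc = acc)
    }
    r1 <- upd(re, A, te, ll_e, sA)
    A <- r1$par; te <- r1$th; ll_e <- r1$ll
    r2 <- upd(rc, B, tc, ll_c, sB)
    B <- r2$par; tc <- r2$th; ll_c <- r2$ll
    if (adapting) {
      sA <- pmin(pmax(sA * exp(gam * (r1$acc - 0.44)), 0.02), 20)
      sB <- pmin(pmax(sB * exp(gam * (r2$acc - 0.44)), 0.02), 20)
    }

    if (sweep > warmup) {
      k <- sweep - warmup
      keep_te[k, ] <- te; keep_tc[k, ] <- tc
      keep_u[k, ] <- exp(u); keep_tl[k, ] <- exp(t)
    }
  }
  list(theta_exp = keep_te, theta_cntl = keep_tc,
       lambda_u = keep_u, TL = keep_tl)
}

.assemble_fit <- function(fr, runs, priors, chains, warmup, iter, seed,
                          rhat_max, ess_min, fixed_rates, verbose) {
  G <- length(fr$genes)
  bind <- function(name) do.call(rbind, lapply(runs, `[[`, name))
  te <- bind("theta_exp"); tc <- bind("theta_cntl")
  lu <- bind("lambda_u"); tl <- bind("TL")
  lr <- log2(te) - log2(tc)
  colnames(te) <- colnames(tc) <- colnames(lr) <- fr$genes
  colnames(lu) <- colnames(tl) <- MUTATION_TYPES
  ll <- lu + tl

  per_chain <- function(mat) lapply(seq_along(runs), function(ch)
    mat[seq_len(iter) + (ch - 1L) * iter, , drop = FALSE])
  rhat_lr <- .split_rhat(per_chain(lr))
  rhat_te <- .split_rhat(per_chain(te))
  rhat_tc <- .split_rhat(per_chain(tc))
  ess_lr <- .ess_chains(per_chain(lr))
  rhat_all <- pmax(rhat_lr, rhat_te, rhat_tc)
  converged <- is.finite(rhat_all) & rhat_all <= rhat_max & ess_lr >= ess_min

  summ <- data.frame(
    gene_id = fr$genes,
    theta_exp_mean = colMeans(te), theta_exp_sd = apply(te, 2, sd),
    theta_cntl_mean = colMeans(tc), theta_cntl_sd = apply(tc, 2, sd),
    log2_ratio_mean = colMeans(lr), log2_ratio_sd = apply(lr, 2, sd),
    rhat_max = rhat_all, n_eff_min = ess_lr, converged = converged,
    stringsAsFactors = FALSE, row.names = NULL)

  rates_fixed <- !is.null(fixed_rates)
  rates <- data.frame(
    mut_type = MUTATION_TYPES,
    lambda_u_mean = colMeans(lu), lambda_u_sd = apply(lu, 2, sd),
    lambda_l_mean = colMeans(ll), lambda_l_sd = apply(ll, 2, sd),
    TL_mean = colMeans(tl),
    rhat = if (rates_fixed) rep(1, 2) else .split_rhat(per_chain(lu)),
    n_eff = if (rates_fixed) rep(Inf, 2) else .ess_chains(per_chain(lu)),
    stringsAsFactors = FALSE, row.names = NULL)

  n_bad <- sum(!converged)
  if (n_bad && verbose)
    warning(sprintf("fitTilac: %d/%d genes failed convergence gates", n_bad, G))
  new("TilacFit", summary = summ, rates = rates,
      draws = list(log2_ratio = lr, theta_exp = te, theta_cntl = tc,
                   lambda_u = lu, lambda_l = ll, TL = tl),
      settings = list(priors = priors, chains = chains, warmup = warmup,
                      iter = iter, seed = seed, rhat_max = rhat_max,
                      ess_min = ess_min, fixed_rates = fixed_rates))
}

#' Write posterior summaries to TSV, with run metadata
#'
#' @param fit a \code{\linkS4class{TilacFit}} object.
#' @param file output TSV of per-gene posterior summaries.
#' @param metadata_file optional JSON path recording priors, seed and
#'   sampler settings.
#' @return the fit, invisibly.
#' @export
writePosterior <- function(fit, file, metadata_file = NULL) {
  stopifnot(is(fit, "TilacFit"))
  write.table(posteriorSummary(fit), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(metadata_file)) {
    s <- fit@settings
    s$fixed_rates <- if (is.null(s$fixed_rates)) NULL else as.list(s$fixed_rates)
    jsonlite::write_json(s, metadata_file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(fit)
}

#' Read a posterior summary TSV back as a minimal fit object
#'
#' Reconstructs a \code{\linkS4class{TilacFit}} carrying summaries only
#' (no draws), sufficient for \code{\link{callSignificance}}.
#'
#' @param file TSV written by \code{\link{writePosterior}}.
#' @return a \code{\linkS4class{TilacFit}} object without draws.
#' @export
readPosterior <- function(file) {
  s <- read.delim(file, stringsAsFactors = FALSE,
                  colClasses = c(gene_id = "character"))
  new("TilacFit", summary = s, rates = data.frame(),
      draws = list(), settings = list(chains = NA, iter = NA,
                                      rhat_max = NA, ess_min = NA))
}
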