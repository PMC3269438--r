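## EM estimation of K-component Gaussian mixtures (K <= 3) whose last
## component is optionally right-censored at the saturation threshold S, and
## information-criterion selection of K with a relative-difference rule.
##
## Internals operate on plain numeric vectors for speed (the simulation
## harness runs thousands of fits); the exported S4 surface wraps them.

.startWeightsDefault <- function(K) {
  switch(K, `1` = 1, `2` = c(0.8, 0.2), `3` = c(0.7, 0.1, 0.2))
}

## deterministic initialization from contiguous blocks of ordered pixel
## values, block sizes proportional to the starting weights
.blockInit <- function(y, K, start_weights, S) {
  n <- length(y)
  if (n < 3L * K)
    stop("too few pixels (", n, ") to initialize a ", K,
         "-component mixture")
  if (is.null(start_weights))
    start_weights <- .startWeightsDefault(K)
  if (length(start_weights) != K)
    stop("start weights must have length K")
  if (abs(sum(start_weights) - 1) > 1e-8)
    stop("start weights must sum to 1")
  ys <- sort(y)
  bnd <- round(cumsum(start_weights) * n)
  bnd[K] <- n
  # guarantee non-empty blocks
  for (k in seq_len(K - 1))
    bnd[k] <- max(bnd[k], k)
  for (k in rev(seq_len(K - 1)))
    bnd[k] <- min(bnd[k], bnd[k + 1] - 1L)
  lo <- c(0L, bnd[-K])
  mu <- sd_ <- numeric(K)
  for (k in seq_len(K)) {
    blk <- ys[(lo[k] + 1L):bnd[k]]
    mu[k] <- mean(blk)
    sd_[k] <- sqrt(mean((blk - mu[k])^2))
  }
  floor_ <- .sigmaFloor(S, y)
  sd_ <- pmax(sd_, floor_)
  eps <- max(floor_, 1e-8)
  if (K > 1)
    for (k in 2:K)
      if (mu[k] <= mu[k - 1]) mu[k] <- mu[k - 1] + eps
  list(weights = start_weights, means = mu, sds = sd_)
}

## n x K matrix of per-component log densities; the last column uses the
## censored-normal mass at saturated pixels when censored = TRUE
.logCompDens <- function(y, means, sds, S, censored) {
  K <- length(means)
  L <- matrix(0, length(y), K)
  for (k in seq_len(K))
    L[, k] <- stats::dnorm(y, means[k], sds[k], log = TRUE)
  if (censored && is.finite(S)) {
    cens <- y >= S
    if (any(cens))
      L[cens, K] <- stats::pnorm((S - means[K]) / sds[K],
                                 lower.tail = FALSE, log.p = TRUE)
  }
  L
}

.rowLogSumExp <- function(L) {
  m <- L[, 1]
  K <- ncol(L)
  if (K > 1) for (k in 2:K) m <- pmax(m, L[, k])
  bad <- !is.finite(m)
  if (any(bad))
    stop("numerical underflow: zero mixture density for some pixels")
  m + log(rowSums(exp(L - m)))
}

## E-step on raw numerics: returns resp and the observed-data loglik
.eStepCore <- function(y, weights, means, sds, S, censored) {
  L <- .logCompDens(y, means, sds, S, censored)
  L <- sweep(L, 2, log(weights), "+")
  ls <- .rowLogSumExp(L)
  list(resp = exp(L - ls), loglik = sum(ls))
}

## M-step on raw numerics; prev_* seed the censored Newton solve
.mStepCore <- function(y, resp, S, censored, prev_means = NULL,
                       prev_sds = NULL) {
  n <- length(y)
  K <- ncol(resp)
  cs <- colSums(resp)
  if (any(cs < 1e-8 * n))
    stop("component ", which.min(cs), " collapsed (responsibility mass ",
         format(min(cs)), ")")
  flags <- character(0)
  w <- cs / n
  mu <- sd_ <- numeric(K)
  floor_ <- .sigmaFloor(S, y)
  for (k in seq_len(K)) {
    mu[k] <- sum(resp[, k] * y) / cs[k]
    sd_[k] <- sqrt(sum(resp[, k] * (y - mu[k])^2) / cs[k])
  }
  if (censored && is.finite(S) && any(y >= S)) {
    zK <- resp[, K]
    wu <- sum(zK[y < S])
    if (wu < 1e-8 * cs[K]) {
      # all foreground mass saturated: location not identifiable
      mu[K] <- S
      sd_[K] <- floor_
      flags <- c(flags, "degenerate_fg")
    } else {
      init <- if (!is.null(prev_means))
        list(mu = prev_means[K], sigma = prev_sds[K]) else NULL
      cf <- .fitCensnormCore(y, zK, S, init_mu = init$mu,
                             init_sigma = init$sigma)
      mu[K] <- cf$mu
      sd_[K] <- cf$sigma
    }
  }
  sd_ <- pmax(sd_, floor_)
  if (any(sd_ <= floor_)) flags <- c(flags, "sigma_floored")
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = sd_[ord], flags = flags)
}

## full EM fit on raw numerics
.emFit <- function(y, S, K, censored, tol = 1e-6, max_iter = 500L,
                   start_weights = NULL) {
  n <- length(y)
  floor_ <- .sigmaFloor(S, y)
  flags <- character(0)
  if (K == 1L) {
    if (censored && is.finite(S) && any(y >= S)) {
      if (all(y >= S)) stop("all pixels saturated: K = 1 censored fit is ",
                            "non-identifiable")
      cf <- .fitCensnormCore(y, rep(1, n), S)
      mu <- cf$mu; sd_ <- max(cf$sigma, floor_)
      ll <- cf$loglik
    } else {
      mu <- mean(y)
      sd_ <- max(sqrt(mean((y - mu)^2)), floor_)
      ll <- sum(stats::dnorm(y, mu, sd_, log = TRUE))
    }
    p <- 2L
    return(list(weights = 1, means = mu, sds = sd_,
                resp = matrix(1, n, 1), loglik = ll, trace = ll,
                n_iter = 1L, converged = TRUE, n_params = p,
                aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(n),
                flags = flags))
  }
  init <- .blockInit(y, K, start_weights, S)
  w <- init$weights; mu <- init$means; sd_ <- init$sds
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  prev <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    e <- .eStepCore(y, w, mu, sd_, S, censored)
    if (!is.null(prev) && e$loglik < prev$ll - 1e-8 * abs(prev$ll)) {
      # a censored fit can lose likelihood when the component ordering (and
      # with it the censored label) flips near S; keep the best iterate
      w <- prev$w; mu <- prev$mu; sd_ <- prev$sd; resp <- prev$resp
      flags <- union(flags, "em_stalled")
      converged <- TRUE
      break
    }
    resp <- e$resp
    trace <- c(trace, e$loglik)
    if (!is.null(prev) &&
        abs(e$loglik - prev$ll) / (abs(prev$ll) +
                                   .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
    prev <- list(w = w, mu = mu, sd = sd_, resp = resp, ll = e$loglik)
    m <- .mStepCore(y, resp, S, censored, prev_means = mu, prev_sds = sd_)
    flags <- union(flags, m$flags)
    if ("degenerate_fg" %in% m$flags) {
      # all censored-component mass saturated: the foreground location is
      # no longer identifiable; stop at the last proper iterate and flag
      converged <- TRUE
      break
    }
    w <- m$weights; mu <- m$means; sd_ <- m$sds
  }
  if (!converged) {
    # responsibilities/loglik must match the returned parameters
    e <- .eStepCore(y, w, mu, sd_, S, censored)
    resp <- e$resp
    trace <- c(trace, e$loglik)
    flags <- union(flags, "not_converged")
  }
  ll <- trace[length(trace)]
  p <- 3L * K - 1L
  list(weights = w, means = mu, sds = sd_, resp = resp, loglik = ll,
       trace = trace, n_iter = it, converged = converged, n_params = p,
       aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(n), flags = flags)
}

## the relative-difference selection rule: smallest K whose criterion lies
## within rel_threshold of the best; crit may contain NA for failed fits
.pickK <- function(crit, rel_threshold = 0.001) {
  stopifnot(any(is.finite(crit)))
  best <- min(crit, na.rm = TRUE)
  excess <- (crit - best) / max(abs(best), .Machine$double.eps)
  which(!is.na(excess) & excess < rel_threshold)[1]
}

.fitToS4 <- function(fit, K, censored, S, spotId, selection = list()) {
  new("MixtureFit",
      params = MixtureParams(fit$weights, fit$means, fit$sds,
                             censoredLast = censored, satThreshold = S),
      resp = fit$resp, logLik = fit$loglik, logLikTrace = fit$trace,
      nIter = fit$n_iter, converged = fit$converged,
      nParams = as.integer(fit$n_params), aic = fit$aic, bic = fit$bic,
      flags = fit$flags, spotId = spotId, selection = selection)
}

#' Mixture density with an optionally censored last component
#'
#' Evaluates \eqn{\sum_{k<K} \pi_k \phi(y; \mu_k, \sigma_k) + \pi_K
#' f_K(y)}, where \eqn{f_K} is either a normal density or, when
#' \code{isCensored(params)}, the censored-normal mixed density of
#' \code{\link{dCensNorm}} (a point mass at the saturation threshold).
#'
#' @param y intensity value(s); must not exceed the saturation threshold
#'   when the last component is censored.
#' @param params a \code{\linkS4class{MixtureParams}}.
#' @param log return the log density?
#' @return numeric vector of (log) densities.
#' @export
mixtureDensity <- function(y, params, log = FALSE) {
  stopifnot(is(params, "MixtureParams"))
  validObject(params)
  S <- params@satThreshold
  if (params@censoredLast && any(y > S))
    stop("values above the saturation threshold cannot occur under the ",
         "censored model")
  L <- .logCompDens(y, params@means, params@sds, S, params@censoredLast)
  L <- sweep(L, 2, log(params@weights), "+")
  ls <- .rowLogSumExp(L)
  if (log) ls else exp(ls)
}

#' Deterministic mixture initialization from ordered pixel values
#'
#' Sorts the mask's pixel values and partitions them into \code{K}
#' contiguous blocks with sizes proportional to the starting weights
#' (defaults 0.8/0.2 for two components and 0.7/0.1/0.2 for three,
#' reflecting typical background/intermediate/spot area fractions in a
#' target mask).  Block means and ML standard deviations seed the component
#' parameters and the starting weights seed the mixing weights.  Zero-
#' variance blocks are floored in scale and tied means are separated by a
#' small epsilon so the ordering constraint holds strictly.
#'
#' @param mask a \code{\linkS4class{PixelMask}} with at least \code{3K}
#'   pixels.
#' @param K number of components (1, 2 or 3).
#' @param startWeights optional starting weights, length \code{K}, summing
#'   to 1.
#' @return a \code{\linkS4class{MixtureParams}} (regular components; the
#'   censored flag is applied by the fitting functions).
#' @examples
#' m <- PixelMask(1:10, satThreshold = 100)
#' mixMeans(initializeMixture(m, 2))   # 4.5, 9.5
#' @export
initializeMixture <- function(mask, K, startWeights = NULL) {
  stopifnot(is(mask, "PixelMask"), K %in% 1:3)
  init <- .blockInit(mask@values, as.integer(K), startWeights,
                     mask@satThreshold)
  MixtureParams(init$weights, init$means, init$sds, censoredLast = FALSE,
                satThreshold = mask@satThreshold)
}

#' E-step: posterior component responsibilities
#'
#' \eqn{z_{ik} = \pi_k f_k(y_i) / f(y_i)}, computed in log space; the last
#' component uses the censored-normal density when
#' \code{isCensored(params)}.  Rows sum to one.
#'
#' @param mask a \code{\linkS4class{PixelMask}}.
#' @param params a \code{\linkS4class{MixtureParams}}.
#' @return n x K responsibility matrix.
#' @export
eStep <- function(mask, params) {
  stopifnot(is(mask, "PixelMask"), is(params, "MixtureParams"))
  .eStepCore(mask@values, params@weights, params@means, params@sds,
             params@satThreshold, params@censoredLast)$resp
}

#' M-step: weighted parameter updates
#'
#' Closed-form weighted updates \eqn{\pi_k = \sum_i z_{ik}/n}, \eqn{\mu_k =
#' \sum_i z_{ik} y_i / \sum_i z_{ik}}, \eqn{\sigma_k^2 = \sum_i z_{ik}(y_i -
#' \mu_k)^2 / \sum_i z_{ik}} for the regular components; the censored last
#' component is refit by \code{\link{fitCensoredNormal}} with the
#' responsibilities as weights (seeded from \code{params}).  Components are
#' re-sorted by mean afterwards so the identification ordering holds.
#'
#' @param mask a \code{\linkS4class{PixelMask}}.
#' @param resp n x K responsibility matrix with positive column sums.
#' @param censoredLast is the last component censored at the mask's
#'   saturation threshold?
#' @param params optional previous \code{\linkS4class{MixtureParams}} used
#'   to seed the censored-normal solve.
#' @return updated \code{\linkS4class{MixtureParams}}.
#' @export
mStep <- function(mask, resp, censoredLast = FALSE, params = NULL) {
  stopifnot(is(mask, "PixelMask"), is.matrix(resp),
            nrow(resp) == length(mask@values))
  m <- .mStepCore(mask@values, resp, mask@satThreshold, censoredLast,
                  prev_means = if (is.null(params)) NULL else params@means,
                  prev_sds = if (is.null(params)) NULL else params@sds)
  if ("degenerate_fg" %in% m$flags)
    warning("censored component carries all its mass on saturated pixels")
  MixtureParams(m$weights, m$means, m$sds, censoredLast = censoredLast,
                satThreshold = mask@satThreshold)
}

#' Fit a K-component (censored) Gaussian mixture by EM
#'
#' Alternates \code{\link{eStep}} and \code{\link{mStep}} from the
#' deterministic block initialization until the relative increase of the
#' observed-data log-likelihood falls below \code{tol} or \code{maxIter}
#' iterations are reached.  \code{K = 1} is fitted in closed form (via the
#' censored-normal MLE when \code{censored} and saturated pixels are
#' present).  AIC and BIC use \code{3K - 1} free parameters.
#'
#' @param mask a \code{\linkS4class{PixelMask}}.
#' @param K number of components (1, 2 or 3).
#' @param censored treat pixels at the saturation threshold as
#'   right-censored (the censored mixture) rather than as exact values (the
#'   regular mixture)?
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param startWeights optional initialization weights.
#' @return a \code{\linkS4class{MixtureFit}}.
#' @examples
#' set.seed(7)
#' y <- pmin(c(rnorm(400, 8000, 2000), rnorm(100, 64000, 6000)), 65535)
#' fit <- fitMixture(PixelMask(y), K = 2, censored = TRUE)
#' mixMeans(fit)
#' @export
fitMixture <- function(mask, K, censored = FALSE, tol = 1e-6,
                       maxIter = 500L, startWeights = NULL) {
  stopifnot(is(mask, "PixelMask"))
  if (!K %in% 1:3) stop("K must be 1, 2 or 3")
  fit <- .emFit(mask@values, mask@satThreshold, as.integer(K), censored,
                tol = tol, max_iter = as.integer(maxIter),
                start_weights = startWeights)
  if (!fit$converged)
    warning("EM did not converge in ", maxIter, " iterations for spot ",
            mask@spotId)
  .fitToS4(fit, K, censored, mask@satThreshold, mask@spotId)
}

## selection core shared by selectK and the simulation harness
.selectCore <- function(y, S, censored, criterion = "BIC",
                        rel_threshold = 0.001, Kmax = 3L, tol = 1e-6,
                        max_iter = 500L, warn = TRUE) {
  fits <- vector("list", Kmax)
  crit <- rep(NA_real_, Kmax)
  for (k in seq_len(Kmax)) {
    f <- tryCatch(.emFit(y, S, k, censored, tol = tol,
                         max_iter = max_iter),
                  error = function(e) e)
    if (inherits(f, "error")) {
      if (warn) warning("K = ", k, " fit failed: ", conditionMessage(f))
      next
    }
    fits[[k]] <- f
    crit[k] <- if (criterion == "BIC") f$bic else f$aic
  }
  if (!any(is.finite(crit))) stop("all mixture fits failed")
  chosen <- .pickK(crit, rel_threshold)
  list(K = chosen, fit = fits[[chosen]], criterion = criterion,
       values = crit)
}

#' Select the number of mixture components
#'
#' Fits mixtures with \code{K = 1, ..., Kmax} components and selects
#' \code{K} by an information criterion with a relative-difference rule: the
#' returned fit is the one with the smallest \code{K} whose criterion
#' exceeds the minimum by less than \code{relThreshold} in relative terms,
#' so a simpler model within 0.1\% (by default) of the best is preferred
#' over a more complex one.  A selected \code{K = 1} marks a blank or weak
#' spot.
#'
#' @inheritParams fitMixture
#' @param criterion \code{"BIC"} (default) or \code{"AIC"}.
#' @param relThreshold relative-difference threshold (default 0.001).
#' @param Kmax largest number of components considered (at most 3).
#' @return the selected \code{\linkS4class{MixtureFit}}; its
#'   \code{selection} slot records the criterion values for every \code{K}.
#' @export
selectK <- function(mask, censored = FALSE, criterion = c("BIC", "AIC"),
                    relThreshold = 0.001, Kmax = 3L, tol = 1e-6,
                    maxIter = 500L) {
  stopifnot(is(mask, "PixelMask"))
  criterion <- match.arg(criterion)
  if (!Kmax %in% 1:3) stop("Kmax must be 1, 2 or 3")
  sel <- .selectCore(mask@values, mask@satThreshold, censored, criterion,
                     relThreshold, as.integer(Kmax), tol,
                     as.integer(maxIter))
  .fitToS4(sel$fit, sel$K, censored, mask@satThreshold, mask@spotId,
           selection = list(criterion = criterion, values = sel$values,
                            K = sel$K, relThreshold = relThreshold))
}

#' @describeIn fitMixture log-likelihood of a fitted mixture.
#' @param object a \code{MixtureFit}.
#' @param ... unused.
#' @export
setMethod("logLik", "MixtureFit", function(object, ...) {
  structure(object@logLik, df = object@nParams, class = "logLik")
})

#' @describeIn fitMixture Akaike information criterion, \code{-2l + 2(3K-1)}.
#' @param k unused (signature compatibility).
#' @export
setMethod("AIC", "MixtureFit", function(object, ..., k = 2) object@aic)

#' @describeIn fitMixture Bayesian information criterion,
#'   \code{-2l + (3K-1) log n}.
#' @export
setMethod("BIC", "MixtureFit", function(object, ...) object@bic)
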