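## Weighted ML estimation for a univariate normal right-censored at a known
## threshold S. This is the numerical kernel behind the censored last mixture
## component: observations recorded exactly at S contribute the survival mass
## 1 - Phi((S - mu)/sigma) instead of a density ordinate, and the weighted
## log-likelihood is maximized by Newton-Raphson in (mu, log sigma).

.sigmaFloor <- function(S, y = NULL) {
  if (is.finite(S)) 1e-6 * S else 1e-6 * max(abs(y), 1)
}

## inverse Mills ratio phi(z) / (1 - Phi(z)), computed in log space
.mills <- function(z) {
  exp(stats::dnorm(z, log = TRUE) -
        stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

## sufficient statistics: censoring is exact equality y == S (>= defensively)
.censnormStats <- function(y, w, S) {
  cens <- y >= S
  wu <- w[!cens]
  yu <- y[!cens]
  list(Wu = sum(wu), A = sum(wu * yu), B = sum(wu * yu^2),
       Wc = sum(w[cens]))
}

.censnormLoglik <- function(mu, tau, st, S) {
  sigma <- exp(tau)
  Q <- st$B - 2 * mu * st$A + mu^2 * st$Wu
  ll <- -0.5 * st$Wu * log(2 * pi) - st$Wu * tau - Q / (2 * sigma^2)
  if (st$Wc > 0)
    ll <- ll + st$Wc * stats::pnorm((S - mu) / sigma, lower.tail = FALSE,
                                    log.p = TRUE)
  ll
}

.censnormGradHess <- function(mu, tau, st, S) {
  sigma <- exp(tau)
  Wu <- st$Wu; A <- st$A; Wc <- st$Wc
  Q <- st$B - 2 * mu * A + mu^2 * Wu
  R <- A - Wu * mu
  g_mu <- R / sigma^2
  g_tau <- -Wu + Q / sigma^2
  h_mm <- -Wu / sigma^2
  h_mt <- -2 * R / sigma^2
  h_tt <- -2 * Q / sigma^2
  if (Wc > 0) {
    z <- (S - mu) / sigma
    m <- .mills(z)
    mp <- m * (m - z)              # d mills / dz
    g_mu <- g_mu + Wc * m / sigma
    g_tau <- g_tau + Wc * m * z
    h_mm <- h_mm - Wc * mp / sigma^2
    cross <- -Wc * (mp * z + m) / sigma
    h_mt <- h_mt + cross
    h_tt <- h_tt - Wc * z * (mp * z + m)
  }
  list(g = c(g_mu, g_tau),
       H = matrix(c(h_mm, h_mt, h_mt, h_tt), 2L, 2L))
}

## core fitter on precomputable statistics; returns mu, sigma, loglik
.fitCensnormCore <- function(y, w, S, init_mu = NULL, init_sigma = NULL,
                             tol = 1e-8, max_iter = 100L) {
  st <- .censnormStats(y, w, S)
  floor_ <- .sigmaFloor(S, y)
  if (st$Wu <= 1e-12 * (st$Wu + st$Wc) || st$Wu <= 0)
    stop("censored normal fit is non-identifiable: all weighted mass lies ",
         "on censored observations")
  if (st$Wc == 0) {
    mu <- st$A / st$Wu
    sigma <- sqrt(max(st$B / st$Wu - mu^2, 0))
    sigma <- max(sigma, floor_)
    return(list(mu = mu, sigma = sigma,
                loglik = .censnormLoglik(mu, log(sigma), st, S),
                n_iter = 0L, converged = TRUE))
  }
  if (is.null(init_mu) || is.null(init_sigma)) {
    W <- st$Wu + st$Wc
    init_mu <- (st$A + st$Wc * S) / W
    init_sigma <- sqrt(max((st$B + st$Wc * S^2) / W - init_mu^2, 0))
  }
  mu <- init_mu
  tau <- log(max(init_sigma, floor_))
  ll <- .censnormLoglik(mu, tau, st, S)
  converged <- FALSE
  it <- 0L
  fallback <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    gh <- .censnormGradHess(mu, tau, st, S)
    step <- tryCatch(solve(gh$H, -gh$g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      fallback <- TRUE
      break
    }
    # backtracking line search: Newton direction, halved until ascent
    t_ <- 1
    improved <- FALSE
    for (bt in 1:40) {
      mu_n <- mu + t_ * step[1]
      tau_n <- max(tau + t_ * step[2], log(floor_))
      ll_n <- .censnormLoglik(mu_n, tau_n, st, S)
      if (is.finite(ll_n) && ll_n >= ll) {
        improved <- TRUE
        break
      }
      t_ <- t_ / 2
    }
    if (!improved) {
      fallback <- TRUE
      break
    }
    done <- abs(ll_n - ll) < tol
    mu <- mu_n; tau <- tau_n; ll <- ll_n
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (fallback) {
    # derivative-free safeguard when the Newton step is unusable
    opt <- stats::optim(c(mu, tau),
                        function(p) -.censnormLoglik(p[1], max(p[2],
                                                               log(floor_)),
                                                     st, S),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    mu <- opt$par[1]
    tau <- max(opt$par[2], log(floor_))
    ll <- .censnormLoglik(mu, tau, st, S)
    converged <- opt$convergence == 0
  }
  list(mu = mu, sigma = exp(tau), loglik = ll, n_iter = it,
       converged = converged)
}

#' Density of a normal right-censored at a saturation threshold
#'
#' Mixed density of a normal distribution observed only up to \code{S}: the
#' ordinary normal pdf for \code{y < S} and the point-mass probability
#' \code{1 - pnorm((S - mu)/sigma)} for \code{y = S}.  Values above \code{S}
#' cannot be observed and raise an error.
#'
#' @param y intensity value(s), all \code{<= S}.
#' @param mu,sigma location and scale (\code{sigma > 0}).
#' @param S censoring (saturation) threshold, finite.
#' @param log return log density?
#' @return numeric vector of (log) densities/masses.
#' @examples
#' dCensNorm(65535, mu = 65535, sigma = 100, S = 65535)  # 0.5
#' @export
dCensNorm <- function(y, mu, sigma, S, log = FALSE) {
  if (!is.finite(S)) stop("S must be finite")
  if (sigma <= 0) stop("sigma must be positive")
  if (any(y > S)) stop("values above the censoring threshold S cannot occur")
  out <- stats::dnorm(y, mu, sigma, log = TRUE)
  cens <- y >= S
  if (any(cens))
    out[cens] <- stats::pnorm((S - mu) / sigma, lower.tail = FALSE,
                              log.p = TRUE)
  if (log) out else exp(out)
}

#' Weighted log-likelihood of a right-censored normal
#'
#' \eqn{\sum_i w_i \log f(y_i)} where \eqn{f} is the mixed censored-normal
#' density of \code{\link{dCensNorm}}.  Terms with zero weight are dropped
#' (so they contribute 0 even when their density vanishes); \code{-Inf} is a
#' legitimate return value when a positively weighted term has zero density.
#'
#' @param y intensities, all \code{<= S}.
#' @param w non-negative weights, same length as \code{y}.
#' @inheritParams dCensNorm
#' @return scalar weighted log-likelihood.
#' @export
censNormLogLik <- function(y, w, mu, sigma, S) {
  if (length(w) != length(y)) stop("y and w must have the same length")
  if (any(w < 0)) stop("weights must be non-negative")
  pos <- w > 0
  if (!any(pos)) return(0)
  sum(w[pos] * dCensNorm(y[pos], mu, sigma, S, log = TRUE))
}

#' Weighted maximum likelihood for a right-censored normal
#'
#' Maximizes \code{\link{censNormLogLik}} by Newton-Raphson in
#' \code{(mu, log sigma)} with analytic gradient and Hessian, backtracking
#' line search, and a derivative-free Nelder-Mead safeguard if a Newton step
#' is unusable.  With no censored observation the closed-form normal MLE
#' (mean and ML standard deviation, divisor n) is returned directly.  The
#' fitted \code{mu} may exceed \code{S} -- that is the point of the model:
#' when most of the weighted mass is saturated, the maximum-likelihood
#' location lies beyond the scanner ceiling.
#'
#' @param y intensities, all \code{<= S}; values equal to \code{S} are
#'   treated as right-censored.
#' @param w non-negative weights (default all 1).  Effective weight on at
#'   least one uncensored observation is required, otherwise the likelihood
#'   increases without bound in \code{mu} and an error is raised.
#' @param S censoring threshold, finite.
#' @param init optional list with elements \code{mu}, \code{sigma} giving
#'   starting values (e.g. the previous EM iterate).
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param maxIter maximum Newton iterations.
#' @return list with \code{mu}, \code{sigma}, \code{S}, \code{logLik},
#'   \code{nIter} and \code{converged}.
#' @examples
#' set.seed(1)
#' y <- pmin(rnorm(200, 60000, 5000), 65535)
#' fitCensoredNormal(y, S = 65535)$mu   # close to 60000
#' @export
fitCensoredNormal <- function(y, w = rep(1, length(y)), S, init = NULL,
                              tol = 1e-8, maxIter = 100L) {
  if (length(w) != length(y)) stop("y and w must have the same length")
  if (any(w < 0)) stop("weights must be non-negative")
  if (!is.finite(S)) stop("S must be finite")
  if (any(y > S)) stop("values above the censoring threshold S cannot occur")
  fit <- .fitCensnormCore(y, w, S,
                          init_mu = init$mu, init_sigma = init$sigma,
                          tol = tol, max_iter = as.integer(maxIter))
  if (!fit$converged)
    warning("censored normal fit did not converge in ", maxIter,
            " iterations")
  list(mu = fit$mu, sigma = fit$sigma, S = S, logLik = fit$loglik,
       nIter = fit$n_iter, converged = fit$converged)
}
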