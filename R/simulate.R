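## Simulation harness for the selection-rate and relative-bias study.
## Generating mixtures mimic immunosignaturing target masks: a dominant
## low-intensity background, optionally an intermediate component, and a
## bright foreground placed so that a target fraction of its draws is
## saturated.  Three analysis arms are compared: GMM0 (regular mixture on
## the uncensored data), CGMM (censored mixture on the censored data) and
## GMM1 (regular mixture on the censored data).

.scenarioDefaults <- list(
  `2` = list(weights = c(0.8, 0.2), means = c(8000, NA),
             sds = c(2000, 6000)),
  `3` = list(weights = c(0.7, 0.1, 0.2), means = c(2000, 15000, NA),
             sds = c(1000, 6000, 6000))
)

#' Construct a simulation scenario
#'
#' Builds the generating censored mixture for a design point of the
#' simulation study.  Fixed parameters: for \code{kTrue = 2},
#' \eqn{\pi = (0.8, 0.2)} with background \eqn{N(8000, 2000^2)}; for
#' \code{kTrue = 3}, \eqn{\pi = (0.7, 0.1, 0.2)} with background
#' \eqn{N(2000, 1000^2)} and intermediate \eqn{N(15000, 6000^2)}.  The
#' foreground scale is fixed at \eqn{\sigma_K = 6000} and its location is
#' solved from the target saturation fraction,
#' \eqn{\mu_K = S - \sigma_K \Phi^{-1}(1 - p_{sat})}, so that exactly a
#' fraction \code{pSat} of foreground draws exceeds the threshold in
#' expectation.
#'
#' @param kTrue true number of components, 2 or 3.
#' @param pSat target foreground saturation fraction in (0, 1); the study
#'   design uses 0.10, 0.40 and 0.70.
#' @param overrides named list overriding \code{weights}, \code{means},
#'   \code{sds} (full vectors; an \code{NA} foreground mean is re-solved
#'   from \code{pSat}), \code{sigmaFG}, \code{nPixels}, \code{nTrials} or
#'   \code{S}.
#' @param S saturation threshold (default 65535).
#' @param nPixels pixels per simulated mask (default 500).
#' @param nTrials default trial count for \code{\link{runExperiment}}
#'   (default 1000).
#' @return a \code{\linkS4class{SimScenario}}.
#' @examples
#' makeScenario(2, 0.5)   # foreground mean lands exactly at S
#' @export
makeScenario <- function(kTrue, pSat, overrides = list(), S = 65535,
                         nPixels = 500L, nTrials = 1000L) {
  kTrue <- as.integer(kTrue)
  if (!kTrue %in% c(2L, 3L)) stop("kTrue must be 2 or 3")
  if (pSat <= 0 || pSat >= 1) stop("pSat must lie in (0, 1)")
  def <- .scenarioDefaults[[as.character(kTrue)]]
  weights <- overrides$weights %||% def$weights
  sds <- overrides$sds %||% def$sds
  if (!is.null(overrides$sigmaFG)) sds[kTrue] <- overrides$sigmaFG
  means <- overrides$means %||% def$means
  S <- overrides$S %||% S
  if (is.na(means[kTrue]))
    means[kTrue] <- S - sds[kTrue] * stats::qnorm(1 - pSat)
  nPixels <- as.integer(overrides$nPixels %||% nPixels)
  nTrials <- as.integer(overrides$nTrials %||% nTrials)
  if (any(diff(means) <= 0))
    stop("scenario means must be strictly increasing")
  new("SimScenario", kTrue = kTrue, satThreshold = as.numeric(S),
      weights = as.numeric(weights), means = as.numeric(means),
      sds = as.numeric(sds),
      pSat = stats::pnorm((S - means[kTrue]) / sds[kTrue],
                          lower.tail = FALSE),
      nPixels = nPixels, nTrials = nTrials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## raw draws from the generating mixture, continuous scale, uncensored
.simValues <- function(scenario) {
  lab <- sample.int(scenario@kTrue, scenario@nPixels, replace = TRUE,
                    prob = scenario@weights)
  stats::rnorm(scenario@nPixels, scenario@means[lab], scenario@sds[lab])
}

#' Simulate one target mask under a scenario
#'
#' Draws component labels from \code{Multinomial(weights)} and values from
#' the component normals (continuous scale), then censors at the saturation
#' threshold.  Uses the current RNG state, so wrap with \code{set.seed} for
#' reproducible masks.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @return list with elements \code{uncensored} (a
#'   \code{\linkS4class{PixelMask}} with \code{satThreshold = Inf}) and
#'   \code{censored} (the same values censored at the scenario threshold).
#' @export
simulateMask <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  v <- .simValues(scenario)
  list(uncensored = PixelMask(v, satThreshold = Inf, spotId = "sim"),
       censored = PixelMask(pmin(v, scenario@satThreshold),
                            satThreshold = scenario@satThreshold,
                            spotId = "sim"))
}

#' Relative bias of a set of estimates
#'
#' \code{(mean(estimates) - truth) / truth}: the simulation study's bias
#' measure, computed over the trials in which the number of components was
#' correctly selected.
#'
#' @param estimates numeric vector of per-trial estimates (at least one).
#' @param truth true parameter value, non-zero.
#' @return scalar relative bias.
#' @export
relativeBias <- function(estimates, truth) {
  if (length(estimates) < 1) stop("need at least one estimate")
  if (truth == 0) stop("relative bias is undefined for a zero truth")
  (mean(estimates) - truth) / truth
}

.paramNames <- function(K) {
  c(paste0("pi", seq_len(K - 1)), paste0("mu", seq_len(K)),
    paste0("sigma", seq_len(K)))
}

.paramTruth <- function(scenario) {
  K <- scenario@kTrue
  stats::setNames(c(scenario@weights[seq_len(K - 1)], scenario@means,
                    scenario@sds), .paramNames(K))
}

.paramEstimates <- function(fit, K) {
  c(fit$weights[seq_len(K - 1)], fit$means, fit$sds)
}

#' Run the selection/bias simulation experiment
#'
#' For each trial a mask is simulated once and analyzed by every requested
#' method on identical data (paired design): \code{GMM0} fits regular
#' mixtures to the uncensored values, \code{CGMM} fits censored mixtures to
#' the censored values, and \code{GMM1} fits regular mixtures to the
#' censored values.  Each method selects \code{K} over 1..3 by the
#' information criterion with the relative-difference rule; the summary
#' records the percent of trials selecting the true \code{K} and, over the
#' correctly-selected trials only, the relative bias of every parameter.
#' Per-trial RNG seeds are derived from \code{seed}, so summaries are
#' exactly reproducible.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @param methods subset of \code{c("GMM0", "CGMM", "GMM1")}.
#' @param nTrials number of trials (default: the scenario's).
#' @param seed master RNG seed.
#' @param criterion \code{"BIC"} (default) or \code{"AIC"}.
#' @param relThreshold relative-difference selection threshold.
#' @return a \code{\linkS4class{SimSummary}}.
#' @examples
#' sc <- makeScenario(2, 0.4, overrides = list(nPixels = 200L))
#' runExperiment(sc, methods = "CGMM", nTrials = 5, seed = 1)
#' @export
runExperiment <- function(scenario, methods = c("GMM0", "CGMM", "GMM1"),
                          nTrials = NULL, seed = 1L,
                          criterion = c("BIC", "AIC"),
                          relThreshold = 0.001) {
  stopifnot(is(scenario, "SimScenario"))
  criterion <- match.arg(criterion)
  methods <- match.arg(methods, c("GMM0", "CGMM", "GMM1"),
                       several.ok = TRUE)
  nTrials <- as.integer(nTrials %||% scenario@nTrials)
  K_true <- scenario@kTrue
  S <- scenario@satThreshold
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(.Machine$integer.max, nTrials)
  correct <- matrix(FALSE, nTrials, length(methods),
                    dimnames = list(NULL, methods))
  failed <- matrix(FALSE, nTrials, length(methods),
                   dimnames = list(NULL, methods))
  est <- array(NA_real_, c(nTrials, 3L * K_true - 1L, length(methods)),
               dimnames = list(NULL, .paramNames(K_true), methods))
  for (t in seq_len(nTrials)) {
    set.seed(trial_seeds[t])
    v <- .simValues(scenario)
    vc <- pmin(v, S)
    for (m in methods) {
      y <- if (m == "GMM0") v else vc
      yS <- if (m == "GMM0") Inf else S
      cens <- m == "CGMM"
      sel <- tryCatch(
        .selectCore(y, yS, cens, criterion, relThreshold, warn = FALSE),
        error = function(e) NULL)
      if (is.null(sel)) {
        failed[t, m] <- TRUE
        next
      }
      if (sel$K == K_true) {
        correct[t, m] <- TRUE
        est[t, , m] <- .paramEstimates(sel$fit, K_true)
      }
    }
  }
  truth <- .paramTruth(scenario)
  relBias <- relBiasSE <- matrix(NA_real_, length(truth), length(methods),
                                 dimnames = list(names(truth), methods))
  for (m in methods) {
    if (!any(correct[, m])) next
    for (p in names(truth)) {
      e <- est[correct[, m], p, m]
      relBias[p, m] <- relativeBias(e, truth[p])
      relBiasSE[p, m] <- stats::sd(e) / sqrt(length(e)) / abs(truth[p])
    }
  }
  new("SimSummary", scenario = scenario, methods = methods,
      nTrials = nTrials,
      selectionRate = 100 * colMeans(correct),
      relBias = relBias,
      relBiasSE = relBiasSE,
      nTrialsUsed = stats::setNames(as.integer(colSums(correct)), methods),
      nFailed = stats::setNames(as.integer(colSums(failed)), methods))
}

#' Export a simulation summary as JSON
#'
#' @param summary a \code{\linkS4class{SimSummary}}.
#' @param path output JSON path.
#' @return invisibly, the list that was serialized.
#' @export
writeSimSummary <- function(summary, path) {
  stopifnot(is(summary, "SimSummary"))
  sc <- summary@scenario
  out <- list(
    scenario = list(k_true = sc@kTrue, p_sat = sc@pSat,
                    s = sc@satThreshold, n_pixels = sc@nPixels,
                    weights = sc@weights, means = sc@means, sds = sc@sds),
    n_trials = summary@nTrials,
    selection_rate = as.list(summary@selectionRate),
    relative_bias = lapply(seq_along(summary@methods), function(j)
      as.list(stats::setNames(summary@relBias[, j],
                              rownames(summary@relBias)))),
    relative_bias_se = lapply(seq_along(summary@methods), function(j)
      as.list(stats::setNames(summary@relBiasSE[, j],
                              rownames(summary@relBiasSE)))),
    n_trials_used = as.list(summary@nTrialsUsed),
    n_failed = as.list(summary@nFailed))
  names(out$relative_bias) <- summary@methods
  names(out$relative_bias_se) <- summary@methods
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
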