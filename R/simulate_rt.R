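#' Ex-Gaussian distribution
#'
#' Convolution of a normal(mu, sigma) and an exponential(mean tau)
#' distribution, the standard descriptive model for reaction times.
#' `sigma = 0` and/or `tau = 0` degenerate gracefully (shifted exponential,
#' plain normal, or a point mass).
#'
#' @param q,p,n Quantiles, probabilities, number of draws.
#' @param mu,sigma,tau Parameters in ms; `sigma, tau >= 0`.
#' @return `pexgauss` the CDF, `qexgauss` the quantile function (by
#'   numerical inversion), `rexgauss` random draws.
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  if (sigma < 0 || tau < 0) stop("sigma and tau must be >= 0")
  if (tau == 0) return(if (sigma == 0) as.numeric(q >= mu) else stats::pnorm(q, mu, sigma))
  if (sigma == 0) return(stats::pexp(pmax(q - mu, 0), rate = 1 / tau))
  z <- (q - mu) / sigma
  k <- sigma / tau
  # P(X <= q) = Phi(z) - exp(k^2/2 - z*k) * Phi(z - k), computed in logs
  lg <- (k^2) / 2 - z * k + stats::pnorm(z - k, log.p = TRUE)
  stats::pnorm(z) - exp(lg)
}

#' @rdname pexgauss
#' @export
qexgauss <- function(p, mu, sigma, tau) {
  vapply(p, function(pp) {
    if (pp <= 0) return(-Inf)
    if (pp >= 1) return(Inf)
    lo <- mu - 10 * max(sigma, 1e-9)
    hi <- mu + 10 * max(sigma, 1e-9) + 20 * max(tau, 1e-9)
    stats::uniroot(function(x) pexgauss(x, mu, sigma, tau) - pp,
                   c(lo, hi), extendInt = "upX", tol = 1e-8)$root
  }, numeric(1))
}

#' @rdname pexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  g <- if (sigma == 0) rep(mu, n) else stats::rnorm(n, mu, sigma)
  e <- if (tau == 0) 0 else stats::rexp(n, rate = 1 / tau)
  g + e
}

#' Configuration of the synthetic reaction-time generator
#'
#' Reaction times for the redundant-target paradigm are generated from a
#' two-channel race: each trial has latent auditory and visual finishing
#' times with ex-Gaussian channel distributions.  Under
#' `race_independent` the channels are independent and the audiovisual
#' double-target RT is their minimum, which satisfies the race model
#' inequality in expectation; `race_correlated` correlates the Gaussian
#' components with coefficient `rho`; `coactivation` subtracts
#' `coactivation_shift` ms from the minimum (floored at `min_rt`),
#' producing genuine violations.
#'
#' @param model One of `"race_independent"`, `"race_correlated"`,
#'   `"coactivation"`.
#' @param channel_params Named list with elements `A` and `V`, each a named
#'   numeric vector `c(mu=, sigma=, tau=)` in ms.
#' @param rho Correlation of channel finishing times (Gaussian components),
#'   used only by `race_correlated`.
#' @param coactivation_shift Speedup in ms beyond the race bound; must be
#'   nonnegative.
#' @param min_rt Floor (ms) applied after the coactivation shift.
#' @param target_prob Probability that a stimulus is a target; determines
#'   how many standard (non-target) trials accompany the targets.
#' @param miss_rate Probability that a target response is missing (the
#'   response is deleted, the reaction time is not censored).
#' @param false_alarm_rate Probability of a response to a standard.
#' @param n_trials Targets per class and congruence level per participant.
#' @param n_participants Number of participants.
#' @param group Group label.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return An object of class `rt_sim_config`.
#' @export
rt_sim_config <- function(model = c("race_independent", "race_correlated",
                                    "coactivation"),
                          channel_params = list(
                            A = c(mu = 350, sigma = 40, tau = 90),
                            V = c(mu = 380, sigma = 40, tau = 90)),
                          rho = 0,
                          coactivation_shift = 0,
                          min_rt = 100,
                          target_prob = 0.2,
                          miss_rate = 0.02,
                          false_alarm_rate = 0.01,
                          n_trials = 100,
                          n_participants = 12,
                          group = "CTRL",
                          seed = 1) {
  model <- match.arg(model)
  if (coactivation_shift < 0) stop("coactivation_shift must be >= 0")
  if (target_prob <= 0 || target_prob >= 1) stop("target_prob must be in (0,1)")
  for (m in c("A", "V")) {
    cp <- channel_params[[m]]
    if (is.null(cp) || any(!c("mu", "sigma", "tau") %in% names(cp))) {
      stop("channel_params$", m, " must provide mu, sigma, tau")
    }
    if (cp[["sigma"]] < 0 || cp[["tau"]] < 0) stop("sigma and tau must be >= 0")
  }
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  structure(list(model = model, channel_params = channel_params, rho = rho,
                 coactivation_shift = coactivation_shift, min_rt = min_rt,
                 target_prob = target_prob, miss_rate = miss_rate,
                 false_alarm_rate = false_alarm_rate,
                 n_trials = as.integer(n_trials),
                 n_participants = as.integer(n_participants),
                 group = group, seed = as.integer(seed)),
            class = "rt_sim_config")
}

# Latent channel finishing times for n trials.
.rt_channels <- function(n, cfg) {
  a <- cfg$channel_params$A; v <- cfg$channel_params$V
  if (cfg$model == "race_correlated" && cfg$rho != 0) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    za <- z1
    zv <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * z2
    ta <- a[["mu"]] + a[["sigma"]] * za +
      (if (a[["tau"]] > 0) stats::rexp(n, 1 / a[["tau"]]) else 0)
    tv <- v[["mu"]] + v[["sigma"]] * zv +
      (if (v[["tau"]] > 0) stats::rexp(n, 1 / v[["tau"]]) else 0)
  } else {
    ta <- rexgauss(n, a[["mu"]], a[["sigma"]], a[["tau"]])
    tv <- rexgauss(n, v[["mu"]], v[["sigma"]], v[["tau"]])
  }
  list(A = ta, V = tv)
}

#' Simulate a redundant-target reaction-time dataset
#'
#' Produces a per-trial table with the five target classes of the paradigm
#' (unimodal auditory `A^T`, unimodal visual `V^T`, bimodal with only an
#' auditory target `A^T V^0`, bimodal with only a visual target `A^0 V^T`,
#' and bimodal double targets `A^T V^T`), spatial congruence labels for
#' bimodal stimuli, accompanying standard trials, and misses flagged by a
#' deleted response.
#'
#' @param config An [rt_sim_config()].
#' @return Data frame of class `rt_dataset` with columns `participant`,
#'   `group`, `stim_type` (`A`, `V`, `AV`), `target_class` (`A_only`,
#'   `V_only`, `AV_double`, `standard`), `congruence` (`congruent`,
#'   `incongruent`, `none`), `is_target`, `responded`, `rt` (ms, NA when no
#'   response) and `correct`.
#' @export
simulate_rt_dataset <- function(config) {
  stopifnot(inherits(config, "rt_sim_config"))
  set.seed(config$seed)
  cls <- data.frame(
    stim_type   = c("A", "V", "AV", "AV", "AV", "AV", "AV", "AV"),
    target_class = c("A_only", "V_only", "A_only", "A_only",
                     "V_only", "V_only", "AV_double", "AV_double"),
    congruence  = c("none", "none", "congruent", "incongruent",
                    "congruent", "incongruent", "congruent", "incongruent"),
    stringsAsFactors = FALSE)
  out <- vector("list", config$n_participants)
  ids <- sprintf("%s%02d", config$group, seq_len(config$n_participants))
  for (p in seq_len(config$n_participants)) {
    tt <- cls[rep(seq_len(nrow(cls)), each = config$n_trials), , drop = FALSE]
    n <- nrow(tt)
    lat <- .rt_channels(n, config)
    rt <- ifelse(tt$target_class == "A_only", lat$A,
          ifelse(tt$target_class == "V_only", lat$V,
                 pmin(lat$A, lat$V)))
    if (config$model == "coactivation") {
      dbl <- tt$target_class == "AV_double"
      rt[dbl] <- pmax(rt[dbl] - config$coactivation_shift, config$min_rt)
    }
    tt$is_target <- TRUE
    tt$rt <- rt
    miss <- stats::runif(n) < config$miss_rate
    tt$rt[miss] <- NA_real_
    tt$responded <- !miss
    tt$correct <- !miss
    n_std <- round(n * (1 - config$target_prob) / config$target_prob)
    if (n_std > 0) {
      fa <- stats::runif(n_std) < config$false_alarm_rate
      std <- data.frame(
        stim_type = sample(c("A", "V", "AV"), n_std, replace = TRUE),
        target_class = "standard", congruence = "none",
        is_target = FALSE, rt = NA_real_, responded = fa, correct = !fa,
        stringsAsFactors = FALSE)
      std$rt[fa] <- rexgauss(sum(fa), 500, 80, 100)
      tt <- rbind(tt, std)
    }
    tt$participant <- ids[p]
    tt$group <- config$group
    rownames(tt) <- NULL
    out[[p]] <- tt
  }
  res <- do.call(rbind, out)
  res <- res[, c("participant", "group", "stim_type", "target_class",
                 "congruence", "is_target", "responded", "rt", "correct")]
  class(res) <- c("rt_dataset", "data.frame")
  res
}
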