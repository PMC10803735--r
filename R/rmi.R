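#' Hit and false-positive rates
#'
#' Hit rate = responded targets / targets, per participant and target
#' class; false-positive rate = responded standards / standards, per
#' participant.  Responses outside `response_window` do not count.
#'
#' @param rts An `rt_dataset` (see [simulate_rt_dataset()]) or data frame
#'   with the same columns.
#' @param response_window ms pair; responses with `rt` inside it count.
#' @return List with data frames `hits` (participant, target_class,
#'   n_targets, hit_rate) and `false_positives` (participant, n_standards,
#'   fp_rate).
#' @export
performance_rates <- function(rts, response_window = c(0, Inf)) {
  stopifnot(is.data.frame(rts))
  tgt <- rts[rts$is_target, , drop = FALSE]
  std <- rts[!rts$is_target, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("no target trials")
  in_win <- function(df) {
    df$responded &
      (is.na(df$rt) | (df$rt >= response_window[1L] & df$rt <= response_window[2L]))
  }
  tgt$ok <- in_win(tgt)
  hits <- stats::aggregate(ok ~ participant + target_class, tgt,
                           function(x) mean(x))
  names(hits)[names(hits) == "ok"] <- "hit_rate"
  cnt <- stats::aggregate(ok ~ participant + target_class, tgt, length)
  hits$n_targets <- cnt$ok
  fps <- if (nrow(std) > 0L) {
    std$fa <- in_win(std)
    f <- stats::aggregate(fa ~ participant, std, mean)
    names(f)[names(f) == "fa"] <- "fp_rate"
    f$n_standards <- stats::aggregate(fa ~ participant, std, length)$fa
    f
  } else {
    data.frame(participant = character(0), fp_rate = numeric(0),
               n_standards = integer(0))
  }
  list(hits = hits[, c("participant", "target_class", "n_targets", "hit_rate")],
       false_positives = fps)
}

# Mean correct RT per class cell; classes are the five of the paradigm.
.class_means <- function(df) {
  cells <- list(
    AT   = df$stim_type == "A" & df$target_class == "A_only",
    ATV0 = df$stim_type == "AV" & df$target_class == "A_only",
    VT   = df$stim_type == "V" & df$target_class == "V_only",
    A0VT = df$stim_type == "AV" & df$target_class == "V_only",
    ATVT = df$target_class == "AV_double")
  vapply(cells, function(s) {
    x <- df$rt[s & df$correct & !is.na(df$rt)]
    if (length(x) == 0L) NA_real_ else mean(x)
  }, numeric(1))
}

#' Audiovisual redundancy gain
#'
#' gain_AV = min(mean RT of the four single-target classes: unimodal
#' auditory `A^T`, bimodal auditory-only target `A^T V^0`, unimodal visual
#' `V^T`, bimodal visual-only target `A^0 V^T`) minus the mean RT to double
#' bimodal targets `A^T V^T`.  May be negative.  Only correct responses
#' with a recorded RT enter the means.
#'
#' @param rts An `rt_dataset` or compatible data frame.
#' @param scope `"participant"` (one gain per participant) or `"group"`
#'   (pooled over each group).
#' @return Data frame with the class means (ms) and `gain_av` (ms).
#' @export
redundancy_gain <- function(rts, scope = c("participant", "group")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(rts))
  key <- if (scope == "participant") rts$participant else rts$group
  out <- lapply(split(rts, key), function(df) {
    m <- .class_means(df)
    if (anyNA(m)) stop("empty target class for ", df$participant[1L])
    data.frame(unit = if (scope == "participant") df$participant[1L] else df$group[1L],
               group = df$group[1L],
               mean_at = m[["AT"]], mean_atv0 = m[["ATV0"]],
               mean_vt = m[["VT"]], mean_a0vt = m[["A0VT"]],
               mean_atvt = m[["ATVT"]],
               gain_av = min(m[c("AT", "ATV0", "VT", "A0VT")]) - m[["ATVT"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[1L] <- scope
  rownames(out) <- NULL
  out
}

# Linear-interpolation empirical quantile (type 7) and its inverse.
.equantile <- function(x, p) as.numeric(stats::quantile(x, p, type = 7, names = FALSE))

.ecdf_interp <- function(x, t) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(as.numeric(t >= x))
  p <- (seq_len(n) - 1) / (n - 1)
  if (anyDuplicated(x)) {            # ties: average the order-statistic ranks
    agg <- tapply(p, x, mean)
    xs <- as.numeric(names(agg)); ps <- as.numeric(agg)
    if (length(xs) == 1L) return(as.numeric(t >= xs))
    stats::approx(xs, ps, xout = t, rule = 2)$y
  } else {
    stats::approx(x, p, xout = t, rule = 2)$y
  }
}

# RTs of the three racing classes for one congruence level.  Unimodal
# targets carry no congruence label and enter both levels.
.race_classes <- function(df, congruence) {
  ok <- df$correct & !is.na(df$rt)
  list(
    A = df$rt[ok & df$target_class == "A_only" &
                df$congruence %in% c(congruence, "none")],
    V = df$rt[ok & df$target_class == "V_only" &
                df$congruence %in% c(congruence, "none")],
    AV = df$rt[ok & df$target_class == "AV_double" &
                 df$congruence == congruence])
}

#' Estimate the three reaction-time CDFs on the percentile grid
#'
#' For each participant and congruence level, evaluates the empirical
#' quantile functions of the auditory, visual and audiovisual target RTs by
#' linear interpolation between order statistics (type-7 convention) at the
#' percentile grid (default 5th-30th in steps of 5), pools the three
#' quantiles per grid point into a common time point (their mean), and
#' evaluates all three empirical CDFs at these pooled time points, so
#' `F_A`, `F_V` and `F_AV` are comparable at every grid point.
#'
#' Participants with fewer than `min_trials` correct target RTs in any
#' class are excluded; exclusions are recorded (with the reason) in the
#' `"excluded"` attribute.
#'
#' @param rts An `rt_dataset` or compatible data frame.
#' @param grid Percentile grid as probabilities (default `seq(.05,.30,.05)`).
#' @param congruence Congruence levels to analyze.
#' @param min_trials Minimum correct target RTs per class.
#' @return Data frame with one row per participant x congruence x grid
#'   point: `participant`, `group`, `congruence`, `percentile`, `t` (ms),
#'   `f_a`, `f_v`, `f_av`, and the class counts.
#' @export
estimate_cdfs <- function(rts, grid = seq(0.05, 0.30, by = 0.05),
                          congruence = c("congruent", "incongruent"),
                          min_trials = 10) {
  stopifnot(is.data.frame(rts), all(grid > 0 & grid < 1))
  out <- list(); excl <- list()
  for (pid in unique(rts$participant)) {
    df <- rts[rts$participant == pid, , drop = FALSE]
    for (cg in congruence) {
      cl <- .race_classes(df, cg)
      ns <- vapply(cl, length, 0L)
      if (any(ns < min_trials)) {
        excl[[length(excl) + 1L]] <- data.frame(
          participant = pid, congruence = cg,
          reason = paste0("insufficient trials (",
                          paste(names(ns), ns, sep = "=", collapse = ", "),
                          ", need >= ", min_trials, ")"),
          stringsAsFactors = FALSE)
        next
      }
      tpool <- (vapply(grid, function(p) .equantile(cl$A, p), 0) +
                vapply(grid, function(p) .equantile(cl$V, p), 0) +
                vapply(grid, function(p) .equantile(cl$AV, p), 0)) / 3
      out[[length(out) + 1L]] <- data.frame(
        participant = pid, group = df$group[1L], congruence = cg,
        percentile = grid, t = tpool,
        f_a = .ecdf_interp(cl$A, tpool),
        f_v = .ecdf_interp(cl$V, tpool),
        f_av = .ecdf_interp(cl$AV, tpool),
        n_a = ns[["A"]], n_v = ns[["V"]], n_av = ns[["AV"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    stop("no participant had enough trials for CDF estimation")
  attr(res, "excluded") <- if (length(excl) > 0L) do.call(rbind, excl) else NULL
  rownames(res) <- NULL
  res
}

#' Violation profiles for the permutation test
#'
#' Per participant and congruence level, the race-model excess
#' `F_AV(t) - F_A(t) - F_V(t)` at each percentile grid point (positive
#' values indicate a violation of the race bound).
#'
#' @inheritParams estimate_cdfs
#' @return List of matrices (one per congruence level), participants x
#'   grid points, with participant row names; the `"excluded"` attribute
#'   of [estimate_cdfs()] is forwarded.
#' @export
rmi_profiles <- function(rts, grid = seq(0.05, 0.30, by = 0.05),
                         congruence = c("congruent", "incongruent"),
                         min_trials = 10) {
  cdfs <- estimate_cdfs(rts, grid, congruence, min_trials)
  out <- lapply(congruence, function(cg) {
    d <- cdfs[cdfs$congruence == cg, , drop = FALSE]
    ex <- d$f_av - d$f_a - d$f_v
    m <- matrix(ex, ncol = length(grid), byrow = TRUE)
    rownames(m) <- unique(d$participant)
    colnames(m) <- paste0("p", grid * 100)
    m
  })
  names(out) <- congruence
  attr(out, "excluded") <- attr(cdfs, "excluded")
  out
}

#' Race-model-inequality violation area
#'
#' The nonnegative area between `F_AV` and `F_A + F_V`, i.e. the integral
#' of `max(F_AV(t) - F_A(t) - F_V(t), 0)` over time, in ms; a geometric
#' measure of integration beyond statistical facilitation.  Zero when the
#' race bound holds everywhere.
#'
#' Inputs are either three CDF functions with an explicit `range`, or
#' three numeric RT samples, whose empirical CDFs (linear interpolation
#' between order statistics) are integrated over the pooled RT range.  The
#' integral is a composite trapezoid on a dense grid (default step 0.25 ms,
#' fine enough that the discretization error is far below 1e-3 ms for
#' smooth CDFs).
#'
#' @param f_a,f_v,f_av CDF functions of t (ms), or numeric RT samples.
#' @param range ms pair over which to integrate (required for functions;
#'   defaults to the pooled sample range for samples).
#' @param dt Grid step in ms.
#' @return Violation area in ms (nonnegative scalar).
#' @export
rmi_violation_area <- function(f_a, f_v, f_av, range = NULL, dt = 0.25) {
  if (is.function(f_a)) {
    stopifnot(is.function(f_v), is.function(f_av))
    if (is.null(range)) stop("`range` is required for CDF functions")
    FA <- f_a; FV <- f_v; FAV <- f_av
  } else {
    stopifnot(is.numeric(f_a), is.numeric(f_v), is.numeric(f_av))
    if (is.null(range)) range <- base::range(c(f_a, f_v, f_av))
    a <- f_a; v <- f_v; av <- f_av
    FA <- function(t) .ecdf_interp(a, t)
    FV <- function(t) .ecdf_interp(v, t)
    FAV <- function(t) .ecdf_interp(av, t)
  }
  tg <- seq(range[1L], range[2L], by = dt)
  if (tg[length(tg)] < range[2L]) tg <- c(tg, range[2L])
  ya <- FA(tg); yv <- FV(tg); yav <- FAV(tg)
  for (y in list(ya, yv, yav)) {
    if (any(diff(y) < -1e-8)) stop("non-monotone CDF input")
  }
  g <- pmax(yav - ya - yv, 0)
  sum((g[-1L] + g[-length(g)]) / 2 * diff(tg))
}

#' Per-participant violation areas
#'
#' Computes the race-model violation area for every participant and
#' congruence level of an RT dataset, applying the same trial-count
#' exclusion rule as [estimate_cdfs()].
#'
#' @inheritParams estimate_cdfs
#' @param dt Integration step in ms.
#' @return Data frame `participant`, `group`, `congruence`, `area` (ms)
#'   with the `"excluded"` attribute as in [estimate_cdfs()].
#' @export
violation_areas <- function(rts, congruence = c("congruent", "incongruent"),
                            min_trials = 10, dt = 0.25) {
  out <- list(); excl <- list()
  for (pid in unique(rts$participant)) {
    df <- rts[rts$participant == pid, , drop = FALSE]
    for (cg in congruence) {
      cl <- .race_classes(df, cg)
      ns <- vapply(cl, length, 0L)
      if (any(ns < min_trials)) {
        excl[[length(excl) + 1L]] <- data.frame(
          participant = pid, congruence = cg,
          reason = paste0("insufficient trials (",
                          paste(names(ns), ns, sep = "=", collapse = ", "), ")"),
          stringsAsFactors = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        participant = pid, group = df$group[1L], congruence = cg,
        area = rmi_violation_area(cl$A, cl$V, cl$AV, dt = dt),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no participant had enough trials")
  res <- do.call(rbind, out)
  attr(res, "excluded") <- if (length(excl) > 0L) do.call(rbind, excl) else NULL
  rownames(res) <- NULL
  res
}

#' Cluster-based sign-flip permutation test of race-bound violations
#'
#' One-sided group-level test of `E[d(t)] > 0` over the percentile grid.
#' At each grid point a one-sample t statistic across participants is
#' computed; clusters are maximal runs of adjacent grid points whose t
#' exceeds the cluster-forming threshold (default: the one-sided critical
#' value at `alpha_cluster` with n-1 df); the cluster mass is the sum of t
#' within a cluster.  The null distribution is the maximal cluster mass
#' over `n_perm` random sign flips of whole participant profiles (first
#' permutation fixed to the identity), and the cluster p-value is
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)`, so the smallest attainable
#' p is `2 / (n_perm + 1)`.
#'
#' @param d Numeric matrix, participants x grid points (violation
#'   profiles, see [rmi_profiles()]); needs >= 2 rows.
#' @param n_perm Number of permutations (default 10001).
#' @param alpha_cluster Cluster-forming alpha (default 0.05).
#' @param threshold Optional explicit cluster-forming t threshold.
#' @param seed Optional seed for the sign flips.
#' @return List with `clusters` (data frame: start, end, mass, p,
#'   significant at `alpha_cluster`), `t_observed`, `threshold`,
#'   `n_perm`.  No rows in `clusters` means no violation anywhere reached
#'   the threshold.
#' @export
cluster_permutation_test <- function(d, n_perm = 10001, alpha_cluster = 0.05,
                                     threshold = NULL, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d); G <- ncol(d)
  if (n < 2L) stop("need at least 2 participants")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(threshold)) threshold <- stats::qt(1 - alpha_cluster, df = n - 1L)
  tstat <- function(m, v) {
    t <- m / sqrt(v / n)
    t[v == 0] <- ifelse(m[v == 0] > 0, Inf, 0)
    t
  }
  cl_masses <- function(t) {
    above <- t > threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(keep, function(k)
                 sum(t[starts[k]:ends[k]]), 0))
  }
  m_obs <- colMeans(d)
  v_obs <- apply(d, 2L, stats::var)
  t_obs <- tstat(m_obs, v_obs)
  obs <- cl_masses(t_obs)
  if (is.null(obs)) {
    return(list(clusters = data.frame(start = integer(0), end = integer(0),
                                      mass = numeric(0), p = numeric(0),
                                      significant = logical(0)),
                t_observed = t_obs, threshold = threshold, n_perm = n_perm))
  }
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  S[1L, ] <- 1                       # identity permutation always included
  ss <- colSums(d^2)
  M <- (S %*% d) / n
  V <- sweep(-n * M^2, 2L, ss, "+") / (n - 1L)
  V[V < 0] <- 0
  maxmass <- vapply(seq_len(n_perm), function(i) {
    cl <- cl_masses(tstat(M[i, ], V[i, ]))
    if (is.null(cl)) 0 else max(cl$mass)
  }, 0)
  obs$p <- vapply(obs$mass, function(ms)
    (1 + sum(maxmass >= ms)) / (n_perm + 1), 0)
  obs$significant <- obs$p <= alpha_cluster
  list(clusters = obs, t_observed = t_obs, threshold = threshold,
       n_perm = n_perm)
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return Data frame `p`, `p_adjusted` (monotone BH-adjusted p-values),
#'   `reject`.
#' @export
bh_correct <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, reject = adj <= q)
}

#' Exponential-null Bayesian test of the violation areas
#'
#' Violation areas are nonnegative by construction, so testing them against
#' zero is ill-posed.  Instead the intercept of a hierarchical model of the
#' areas (participant random intercept) carries an exponential prior whose
#' rate is set so the prior variance `1/lambda^2` equals the sample
#' variance of the areas; evidence that the areas are distributed away from
#' zero beyond that benchmark is the Savage-Dickey density ratio at
#' intercept = 0 (the exponential prior density at 0 is `lambda`).  The
#' ROPE decision for the intercept is reported alongside.  When group
#' and/or congruence vary, a second, factorial model (sum-coded
#' Group x Congruence with the normal prior rule) reports per-factor Bayes
#' factors.
#'
#' @param areas Data frame with columns `participant`, `area`, and
#'   optionally `group`, `congruence` (see [violation_areas()]).
#' @param spec A [model_spec()].
#' @param min_prior_sd Floor (ms) for the prior scale, making the
#'   degenerate all-zero case well-defined (it then yields `BF_10 << 1`).
#' @return List with `intercept` (data frame: estimate, HDI, `bf_10`,
#'   ROPE decision, decision), `factorial` (data frame or NULL),
#'   `prior_rate`, `fit`.
#' @export
exponential_null_test <- function(areas, spec = model_spec(),
                                  min_prior_sd = 1) {
  stopifnot(is.data.frame(areas), all(c("participant", "area") %in% names(areas)))
  if (any(areas$area < 0)) stop("violation areas must be nonnegative")
  if (length(unique(areas$participant)) < 2L) stop("need >= 2 participants")
  y <- areas$area
  sd_y <- stats::sd(y)
  prior_scale <- max(sd_y, min_prior_sd, na.rm = TRUE)
  lambda <- 1 / prior_scale
  X <- matrix(1, length(y), 1L, dimnames = list(NULL, "intercept"))
  fit <- .gibbs_lmm(y, X, areas$participant, prior_sd = prior_scale,
                    draws = spec$draws, warmup = spec$warmup,
                    exp_prior_rate = lambda, seed = spec$seed)
  rope_h <- spec$rope_scale * prior_scale
  dr <- fit$beta[, 1L]
  bf10 <- lambda / fit$dens0[1L]
  rt <- rope_test(dr, rope_h, spec$hdi_prob)
  intercept <- data.frame(
    estimate = mean(dr), hdi_lower = rt$hdi[1L], hdi_upper = rt$hdi[2L],
    bf_10 = bf10, rope_decision = rt$decision,
    decision = .decide(bf10, rt$decision, spec$bf_threshold),
    stringsAsFactors = FALSE)

  factorial <- NULL
  fac <- c("group", "congruence")[vapply(c("group", "congruence"), function(f)
    f %in% names(areas) && length(unique(areas[[f]])) > 1L, TRUE)]
  if (length(fac) > 0L) {
    Xf <- matrix(1, length(y), 1L, dimnames = list(NULL, "intercept"))
    for (f in fac) {
      v <- factor(areas[[f]])
      cc <- stats::model.matrix(~v, contrasts.arg = list(v = "contr.sum"))[, -1L, drop = FALSE]
      colnames(cc) <- paste0(f, seq_len(ncol(cc)))
      Xf <- cbind(Xf, cc)
    }
    if (length(fac) == 2L) {
      inter <- Xf[, "group1"] * Xf[, "congruence1"]
      Xf <- cbind(Xf, `group:congruence` = inter)
    }
    sdn <- max(sd_y, min_prior_sd, na.rm = TRUE)
    prior_sd <- rep(spec$prior_scale_coef * sdn, ncol(Xf))
    prior_sd[1L] <- spec$prior_scale_intercept * sdn
    ff <- .gibbs_lmm(y, Xf, areas$participant, prior_sd,
                     draws = spec$draws, warmup = spec$warmup, seed = spec$seed)
    factorial <- do.call(rbind, lapply(seq_len(ncol(Xf)), function(j) {
      drj <- ff$beta[, j]
      bf <- bayes_factor_directional(drj, prior_sd[j],
                                     posterior_density0 = ff$dens0[j],
                                     prob_positive = ff$pgt0[j])
      rtj <- rope_test(drj, rope_h, spec$hdi_prob)
      data.frame(term = colnames(Xf)[j], estimate = mean(drj),
                 hdi_lower = rtj$hdi[1L], hdi_upper = rtj$hdi[2L],
                 bf_10 = bf$bf_10, rope_decision = rtj$decision,
                 stringsAsFactors = FALSE)
    }))
  }
  list(intercept = intercept, factorial = factorial,
       prior_rate = lambda, fit = fit)
}
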