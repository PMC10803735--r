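#' Specification of the Bayesian hierarchical models
#'
#' Bundles the sampling budget, the seed and the prior rule used by all
#' model-fitting functions.  Priors are weakly informative normals whose
#' standard deviations scale with the data: `prior_scale_coef` times the SD
#' of the response for non-intercept coefficients (default 2.5) and
#' `prior_scale_intercept` times the SD for the global intercept
#' (default 10).  The default budget is 40,000 draws; tests run at reduced
#' budgets with widened tolerances.
#'
#' @param draws Number of retained posterior draws.
#' @param warmup Warmup iterations (default `draws / 5`, at least 200).
#' @param seed Integer seed for the sampler.
#' @param prior_scale_coef,prior_scale_intercept Prior-SD multipliers.
#' @param rope_scale ROPE half-width as a fraction of the response SD
#'   (default 0.1).
#' @param hdi_prob Credible-interval mass (default 0.95).
#' @param bf_threshold Evidence threshold (default 3).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(draws = 40000, warmup = NULL, seed = 1,
                       prior_scale_coef = 2.5, prior_scale_intercept = 10,
                       rope_scale = 0.1, hdi_prob = 0.95, bf_threshold = 3) {
  stopifnot(draws >= 100, prior_scale_coef > 0, prior_scale_intercept > 0)
  structure(list(draws = as.integer(draws), warmup = warmup,
                 seed = as.integer(seed),
                 prior_scale_coef = prior_scale_coef,
                 prior_scale_intercept = prior_scale_intercept,
                 rope_scale = rope_scale, hdi_prob = hdi_prob,
                 bf_threshold = bf_threshold),
            class = "model_spec")
}

#' Highest-density interval from posterior draws
#'
#' Shortest interval containing `prob` of the draws (not equal-tailed).
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Interval mass.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 20L) stop("too few draws for a stable HDI (need >= 20)")
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(draws[1L], draws[n]))
  starts <- seq_len(n - k)
  widths <- draws[starts + k] - draws[starts]
  i <- which.min(widths)
  c(draws[i], draws[i + k])
}

#' ROPE decision for a posterior
#'
#' Compares the highest-density interval of the draws with a region of
#' practical equivalence `[-h, +h]`.  The effect passes the ROPE test
#' ("outside") only when the whole interval falls outside the region.
#'
#' @param draws Posterior draws.
#' @param rope_halfwidth Half-width `h` of the ROPE, on the response scale
#'   (the conventional choice is 0.1 times the SD of the data).
#' @param hdi_prob Credible mass of the interval.
#' @return List with `decision` (`"outside"`, `"inside"` or `"overlap"`),
#'   `hdi`, `rope` and `hdi_fraction_in_rope` (share of within-HDI draws
#'   that fall inside the ROPE).
#' @export
rope_test <- function(draws, rope_halfwidth, hdi_prob = 0.95) {
  stopifnot(rope_halfwidth >= 0, all(is.finite(draws)))
  h <- hdi(draws, hdi_prob)
  inside_hdi <- draws >= h[1L] & draws <= h[2L]
  frac <- mean(abs(draws[inside_hdi]) <= rope_halfwidth)
  decision <- if (h[1L] > rope_halfwidth || h[2L] < -rope_halfwidth) {
    "outside"
  } else if (h[1L] >= -rope_halfwidth && h[2L] <= rope_halfwidth) {
    "inside"
  } else "overlap"
  list(decision = decision, hdi = h, rope = c(-rope_halfwidth, rope_halfwidth),
       hdi_fraction_in_rope = frac)
}

#' Savage-Dickey Bayes factors
#'
#' Computes the two-sided Bayes factor `BF_10` for a parameter with a
#' zero-mean normal prior as the ratio of prior to posterior density at
#' zero (Savage-Dickey density ratio), and the one-sided `BF_+0` for the
#' directional hypothesis `theta > 0` by reweighting with the posterior
#' mass above zero (the prior being symmetric, its mass above zero is 1/2).
#'
#' The posterior density at zero defaults to a moment-matched normal
#' approximation of the draws, which is exact for the conjugate Gaussian
#' models used in this package; `density_method = "kernel"` uses a kernel
#' estimate instead and falls back to the normal approximation (with a
#' warning) when too few draws lie near zero for a stable estimate.
#' Model-fitting functions pass their Rao-Blackwellized conditional density
#' via `posterior_density0`, which overrides both.
#'
#' @param draws Posterior draws of the parameter.
#' @param prior_sd SD of the zero-mean normal prior.
#' @param posterior_density0 Optional externally computed posterior density
#'   at zero.
#' @param density_method `"normal"` (default) or `"kernel"`.
#' @param prob_positive Optional externally computed posterior
#'   `P(theta > 0)`; defaults to the fraction of positive draws.
#' @return List with `bf_10`, `bf_plus0`, `posterior_density0`,
#'   `prior_density0`.
#' @export
bayes_factor_directional <- function(draws, prior_sd,
                                     posterior_density0 = NULL,
                                     density_method = c("normal", "kernel"),
                                     prob_positive = NULL) {
  density_method <- match.arg(density_method)
  stopifnot(prior_sd > 0)
  if (is.null(posterior_density0)) {
    m <- mean(draws); s <- stats::sd(draws)
    if (!is.finite(s) || s == 0) {
      posterior_density0 <- if (m == 0) Inf else 0
    } else if (density_method == "normal") {
      posterior_density0 <- stats::dnorm(0, m, s)
    } else {
      d <- stats::density(draws, bw = "SJ")
      near <- mean(abs(draws) < 3 * d$bw)
      if (near < 0.01) {
        warning("too few draws near 0 for a stable kernel density; ",
                "falling back to the normal approximation")
        posterior_density0 <- stats::dnorm(0, m, s)
      } else {
        posterior_density0 <- stats::approx(d$x, d$y, xout = 0, rule = 2)$y
      }
    }
  }
  if (is.null(prob_positive)) prob_positive <- mean(draws > 0)
  prior_density0 <- stats::dnorm(0, 0, prior_sd)
  bf10 <- prior_density0 / posterior_density0
  list(bf_10 = bf10, bf_plus0 = bf10 * prob_positive / 0.5,
       posterior_density0 = posterior_density0,
       prior_density0 = prior_density0)
}

# Decision rule shared by all inference summaries.
.decide <- function(bf, rope_decision, threshold = 3) {
  if (is.na(bf)) return("inconclusive")
  if (bf > threshold && rope_decision == "outside") return("present")
  if (bf < 1 / threshold || rope_decision == "inside") return("absent-evidence")
  "inconclusive"
}

# Validate a difference-wave table.
.check_c1_table <- function(table) {
  req <- c("participant", "condition", "electrode", "delta_c1")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0L) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(table$delta_c1))) stop("delta_c1 must be finite")
  if (!"group" %in% names(table)) table$group <- "all"
  table
}

#' Fit the hierarchical cell-means model to a difference-wave table
#'
#' Estimates the mean difference-wave amplitude of every
#' group x condition x electrode cell simultaneously in one Gaussian
#' hierarchical model with a participant-level random intercept shared
#' across electrodes.  Every cell mean carries a normal prior with SD
#' `prior_scale_coef * SD(response)` (the cell-means parameterization has
#' no global intercept).  The presence of a positive amplitude in each cell
#' is assessed with the one-sided Savage-Dickey Bayes factor `BF_+0`
#' combined with the ROPE test; the shipped decision rule is
#' "present" when `BF_+0 > 3` and the 95% HDI falls outside the ROPE.
#'
#' @param table Difference-wave table (see [delta_c1_table()]); needs at
#'   least 2 participants.
#' @param spec A [model_spec()].
#' @return Object of class `c1_fit`: list with `summary` (one row per
#'   cell), `draws` (posterior draws per cell), `fit` (sampler output incl.
#'   effective sample sizes and split-Rhat), `data_sd`, `rope_halfwidth`,
#'   `sigma_mean` and `spec`.
#' @export
fit_cell_means <- function(table, spec = model_spec()) {
  table <- .check_c1_table(table)
  if (length(unique(table$participant)) < 2L) stop("need >= 2 participants")
  y <- table$delta_c1
  multi_group <- length(unique(table$group)) > 1L
  cell <- if (multi_group) {
    interaction(table$group, table$condition, table$electrode, sep = ".", drop = TRUE)
  } else {
    interaction(table$condition, table$electrode, sep = ".", drop = TRUE)
  }
  X <- matrix(0, length(y), nlevels(cell),
              dimnames = list(NULL, levels(cell)))
  X[cbind(seq_along(y), as.integer(cell))] <- 1
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1e-3
  prior_sd <- rep(spec$prior_scale_coef * sd_y, ncol(X))
  fit <- .gibbs_lmm(y, X, table$participant, prior_sd,
                    draws = spec$draws, warmup = spec$warmup, seed = spec$seed)
  rope_h <- spec$rope_scale * sd_y
  sig <- mean(fit$sigma)
  summ <- lapply(seq_len(ncol(X)), function(j) {
    dr <- fit$beta[, j]
    bf <- bayes_factor_directional(dr, prior_sd[j],
                                   posterior_density0 = fit$dens0[j],
                                   prob_positive = fit$pgt0[j])
    rt <- rope_test(dr, rope_h, spec$hdi_prob)
    data.frame(parameter = colnames(X)[j], mean = mean(dr),
               hdi_lower = rt$hdi[1L], hdi_upper = rt$hdi[2L],
               bf_plus0 = bf$bf_plus0, bf_10 = bf$bf_10,
               rope_halfwidth = rope_h,
               hdi_fraction_in_rope = rt$hdi_fraction_in_rope,
               rope_decision = rt$decision,
               decision = .decide(bf$bf_plus0, rt$decision, spec$bf_threshold),
               d = mean(dr) / sig,
               ess = fit$ess[j], rhat = fit$rhat[j],
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  parts <- strsplit(summ$parameter, ".", fixed = TRUE)
  if (multi_group) {
    summ$group <- vapply(parts, `[`, "", 1L)
    summ$condition <- vapply(parts, `[`, "", 2L)
    summ$electrode <- vapply(parts, `[`, "", 3L)
  } else {
    summ$condition <- vapply(parts, `[`, "", 1L)
    summ$electrode <- vapply(parts, `[`, "", 2L)
  }
  structure(list(summary = summ, draws = fit$beta, fit = fit,
                 data_sd = sd_y, rope_halfwidth = rope_h,
                 sigma_mean = sig, spec = spec),
            class = "c1_fit")
}

#' @export
print.c1_fit <- function(x, ...) {
  cat("<c1_fit> hierarchical cell-means model,", nrow(x$summary),
      "cells,", x$fit$draws, "draws\n")
  print(x$summary[, c("parameter", "mean", "hdi_lower", "hdi_upper",
                      "bf_plus0", "rope_decision", "decision")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' The shipped set of a-priori contrasts
#'
#' Builds the five planned contrasts comparing a sight-recovery group with
#' its matched control group: the two within-deprived-group comparisons of
#' the unimodal visual condition against each audiovisual condition, and
#' the three between-group comparisons per condition.
#'
#' @param deprived,control Group labels (e.g. `"CC"` and `"MCC"`, or
#'   `"DC"` and `"MDC"`).
#' @return Named list of numeric contrast vectors over the six
#'   `group.condition` cells (attribute `"cells"` gives the cell order).
#' @export
delta_c1_contrast_matrix <- function(deprived = "CC", control = "MCC") {
  conds <- c("V", "AV_i", "AV_c")
  cells <- c(outer(c(deprived, control), conds, paste, sep = "."))
  cv <- function(plus, minus) {
    v <- stats::setNames(numeric(length(cells)), cells)
    v[plus] <- 1; v[minus] <- -1
    v
  }
  ctr <- list(
    cv(paste(deprived, "V", sep = "."), paste(deprived, "AV_i", sep = ".")),
    cv(paste(deprived, "V", sep = "."), paste(deprived, "AV_c", sep = ".")),
    cv(paste(control, "V", sep = "."), paste(deprived, "V", sep = ".")),
    cv(paste(control, "AV_i", sep = "."), paste(deprived, "AV_i", sep = ".")),
    cv(paste(control, "AV_c", sep = "."), paste(deprived, "AV_c", sep = ".")))
  names(ctr) <- c(
    paste0(deprived, ":V-AV_i"), paste0(deprived, ":V-AV_c"),
    paste0("V:", control, "-", deprived),
    paste0("AV_i:", control, "-", deprived),
    paste0("AV_c:", control, "-", deprived))
  attr(ctr, "cells") <- cells
  ctr
}

#' Complete a contrast set to a full-rank square matrix
#'
#' Prepends the unit-weight intercept row (the grand cell mean) and appends
#' orthogonal completion rows spanning the remainder of the cell space, so
#' the contrast parameterization is a bijection of the cell means.
#'
#' @param contrasts Named list of contrast vectors over cells (all the same
#'   length, with cell names).
#' @param cells Cell names (defaults to the names of the first contrast).
#' @return Square numeric matrix, rows named `intercept`, the contrast
#'   names, and `aux1`, `aux2`, ... for completion rows.
#' @export
complete_contrasts <- function(contrasts, cells = NULL) {
  if (is.null(cells)) cells <- names(contrasts[[1L]])
  k <- length(cells)
  C <- do.call(rbind, lapply(contrasts, function(v) {
    if (length(v) != k) stop("contrast length mismatch")
    if (!is.null(names(v))) v <- v[cells]
    as.numeric(v)
  }))
  rownames(C) <- names(contrasts)
  C <- rbind(intercept = rep(1 / k, k), C)
  if (qr(C)$rank < nrow(C)) stop("contrast set (with intercept) is rank-deficient")
  if (nrow(C) < k) {
    ns <- MASS::Null(t(C))           # orthonormal completion of the row space
    ns <- t(ns)
    rownames(ns) <- paste0("aux", seq_len(nrow(ns)))
    C <- rbind(C, ns)
  }
  colnames(C) <- cells
  C
}

#' Test planned contrasts on the difference-wave table
#'
#' Reparameterizes the hierarchical cell-means model with the planned
#' contrasts so each contrast is a model coefficient with its own normal
#' prior (SD `2.5 * SD(response)`; the intercept row gets `10 * SD`), fits
#' the same contrast set simultaneously at every electrode, and reports the
#' two-sided Savage-Dickey Bayes factor, HDI, ROPE decision and effect size
#' per contrast and electrode.  A contrast is flagged `substantial` when
#' `BF_10 > 3` and the HDI falls outside the ROPE.  Zero contrasts (a cell
#' against itself) are degenerate: the difference is identically 0, which
#' is reported with `BF_10 = 0`.
#'
#' No correction across contrasts is applied: the hierarchical model with
#' proper, non-flat priors shrinks estimates toward zero, which is the
#' rationale for reporting uncorrected Bayes factors.
#'
#' @param table Difference-wave table with exactly the groups/conditions
#'   the contrasts mention.
#' @param contrasts Named list of contrast vectors over `group.condition`
#'   cells, e.g. [delta_c1_contrast_matrix()]; defaults to the shipped set
#'   for the two groups present (alphabetical: control is the
#'   lexicographically later label unless exactly one of CC/DC is present).
#' @param spec A [model_spec()].
#' @return Object of class `c1_contrasts`: list with `summary` (one row
#'   per contrast x electrode), `draws`, `fit`, `data_sd`,
#'   `rope_halfwidth`, `spec`.
#' @export
test_contrasts <- function(table, contrasts = NULL, spec = model_spec()) {
  table <- .check_c1_table(table)
  if (is.null(contrasts)) {
    grps <- sort(unique(table$group))
    if (length(grps) != 2L) stop("default contrasts need exactly two groups")
    dep <- grps[grps %in% c("CC", "DC")]
    if (length(dep) != 1L) dep <- grps[1L]
    contrasts <- delta_c1_contrast_matrix(dep, setdiff(grps, dep))
  }
  zero <- vapply(contrasts, function(v) all(v == 0), TRUE)
  Cfull <- complete_contrasts(contrasts[!zero])
  cells <- colnames(Cfull)
  Minv <- solve(Cfull)
  cell_lab <- paste(table$group, table$condition, sep = ".")
  if (!all(cell_lab %in% cells)) {
    stop("table contains cells not covered by the contrasts: ",
         paste(setdiff(unique(cell_lab), cells), collapse = ", "))
  }
  electrodes <- sort(unique(table$electrode))
  y <- table$delta_c1
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1e-3
  blocks <- lapply(electrodes, function(e) {
    rows <- table$electrode == e
    M <- matrix(0, sum(rows), length(cells),
                dimnames = list(NULL, cells))
    M[cbind(seq_len(sum(rows)), match(cell_lab[rows], cells))] <- 1
    M %*% Minv
  })
  p_blk <- nrow(Cfull)
  X <- matrix(0, nrow(table), p_blk * length(electrodes))
  cn <- character(0)
  for (i in seq_along(electrodes)) {
    rows <- table$electrode == electrodes[i]
    X[rows, (i - 1L) * p_blk + seq_len(p_blk)] <- blocks[[i]]
    cn <- c(cn, paste0(rownames(Cfull), "@", electrodes[i]))
  }
  colnames(X) <- cn
  prior_sd <- rep(spec$prior_scale_coef * sd_y, ncol(X))
  prior_sd[grepl("^intercept@", cn)] <- spec$prior_scale_intercept * sd_y
  fit <- .gibbs_lmm(y, X, table$participant, prior_sd,
                    draws = spec$draws, warmup = spec$warmup, seed = spec$seed)
  rope_h <- spec$rope_scale * sd_y
  sig <- mean(fit$sigma)
  grid <- expand.grid(contrast = names(contrasts), electrode = electrodes,
                      stringsAsFactors = FALSE)
  summ <- lapply(seq_len(nrow(grid)), function(i) {
    nm <- grid$contrast[i]; e <- grid$electrode[i]
    if (zero[[nm]]) {
      return(data.frame(contrast = nm, electrode = e, estimate = 0,
                        hdi_lower = 0, hdi_upper = 0, bf_10 = 0,
                        rope_decision = "inside", substantial = FALSE,
                        d = 0, ess = NA_real_, rhat = NA_real_,
                        stringsAsFactors = FALSE))
    }
    j <- match(paste0(nm, "@", e), cn)
    dr <- fit$beta[, j]
    bf <- bayes_factor_directional(dr, prior_sd[j],
                                   posterior_density0 = fit$dens0[j],
                                   prob_positive = fit$pgt0[j])
    rt <- rope_test(dr, rope_h, spec$hdi_prob)
    data.frame(contrast = nm, electrode = e, estimate = mean(dr),
               hdi_lower = rt$hdi[1L], hdi_upper = rt$hdi[2L],
               bf_10 = bf$bf_10, rope_decision = rt$decision,
               substantial = bf$bf_10 > spec$bf_threshold &&
                 rt$decision == "outside",
               d = mean(dr) / sig, ess = fit$ess[j], rhat = fit$rhat[j],
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  structure(list(summary = summ, draws = fit$beta, fit = fit,
                 data_sd = sd_y, rope_halfwidth = rope_h, spec = spec),
            class = "c1_contrasts")
}

#' @export
print.c1_contrasts <- function(x, ...) {
  cat("<c1_contrasts>", nrow(x$summary), "contrast x electrode tests\n")
  print(x$summary[, c("contrast", "electrode", "estimate", "hdi_lower",
                      "hdi_upper", "bf_10", "substantial")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Ordered-factor linear-trend test
#'
#' Models the difference-wave amplitude of a single group as a function of
#' the ordered condition factor (V, AV_i, AV_c), i.e. increasing spatial
#' specificity of the concurrent sound, using orthogonal-polynomial coding
#' shared across the five electrodes, electrode offsets (sum-coded), a
#' global intercept and a participant random intercept.  The linear
#' component is reported as a *decline* coefficient (positive when the
#' amplitude decreases along V > AV_i > AV_c) with its two-sided Bayes
#' factor and ROPE decision; the quadratic component is reported alongside.
#'
#' @param table Difference-wave table restricted to one group, containing
#'   all three conditions.
#' @param spec A [model_spec()].
#' @return Object of class `c1_trend`: list with `summary` (rows
#'   `linear_decline` and `quadratic`), `draws`, `fit`, `data_sd`,
#'   `rope_halfwidth`, `spec`.
#' @export
linear_trend_test <- function(table, spec = model_spec()) {
  table <- .check_c1_table(table)
  if (length(unique(table$group)) > 1L) {
    stop("restrict the table to a single group before testing the trend")
  }
  conds <- c("V", "AV_i", "AV_c")
  if (!all(conds %in% table$condition)) {
    stop("all three conditions (V, AV_i, AV_c) must be present")
  }
  y <- table$delta_c1
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1e-3
  pol <- stats::contr.poly(3)           # rows ordered V, AV_i, AV_c
  ci <- match(table$condition, conds)
  decline <- -pol[ci, 1L]               # positive = decreasing amplitude
  quad <- pol[ci, 2L]
  elec <- factor(table$electrode)
  Xe <- if (nlevels(elec) > 1L) {
    stats::model.matrix(~ elec, contrasts.arg = list(elec = "contr.sum"))[, -1L, drop = FALSE]
  } else NULL
  X <- cbind(intercept = 1,
             if (!is.null(Xe)) Xe,
             linear_decline = decline, quadratic = quad)
  prior_sd <- rep(spec$prior_scale_coef * sd_y, ncol(X))
  prior_sd[1L] <- spec$prior_scale_intercept * sd_y
  fit <- .gibbs_lmm(y, X, table$participant, prior_sd,
                    draws = spec$draws, warmup = spec$warmup, seed = spec$seed)
  rope_h <- spec$rope_scale * sd_y
  summ <- lapply(c("linear_decline", "quadratic"), function(nm) {
    j <- match(nm, colnames(X))
    dr <- fit$beta[, j]
    bf <- bayes_factor_directional(dr, prior_sd[j],
                                   posterior_density0 = fit$dens0[j],
                                   prob_positive = fit$pgt0[j])
    rt <- rope_test(dr, rope_h, spec$hdi_prob)
    data.frame(component = nm, estimate = mean(dr),
               hdi_lower = rt$hdi[1L], hdi_upper = rt$hdi[2L],
               bf_10 = bf$bf_10, bf_plus0 = bf$bf_plus0,
               rope_decision = rt$decision,
               substantial = bf$bf_10 > spec$bf_threshold &&
                 rt$decision == "outside",
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, summ), draws = fit$beta, fit = fit,
                 data_sd = sd_y, rope_halfwidth = rope_h, spec = spec),
            class = "c1_trend")
}

#' @export
print.c1_trend <- function(x, ...) {
  cat("<c1_trend> ordered-factor trend test\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
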