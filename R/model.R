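#' Parameters of the task-accuracy model
#'
#' Bundles the parameter vector of the psychometric task-accuracy model:
#' sensitivities to absolute gaze-target displacement (`beta_d`, 1/deg) and
#' absolute slippage (`beta_s`, s/deg), the lapse probability `lambda`, and
#' the chance level `gamma`. The chance level is fixed by the task design
#' (0.25 for a four-alternative forced choice) and is never estimated.
#'
#' @param beta_d Sensitivity to displacement, per degree; must be >= 0.
#' @param beta_s Sensitivity to slippage, per (deg/s); must be >= 0.
#' @param lapse Lapse probability in `[0, 1]`: the rate of errors unrelated
#'   to stimulus visibility (attention lapses, response slips).
#' @param chance Guessing success probability; 0.25 for the 4AFC probe.
#' @return An object of class `occlu_params` (a named list).
#' @examples
#' p <- model_params(beta_d = 0.18, beta_s = 0.01, lapse = 0.03)
#' predict_accuracy(0, 0, p) # 1 - lambda + lambda * gamma = 0.9775
#' @export
model_params <- function(beta_d = 0.18, beta_s = 0.01, lapse = 0.03,
                         chance = 0.25) {
  if (beta_d < 0 || beta_s < 0)
    stop_input("beta_d and beta_s must be non-negative (got %g, %g)",
               beta_d, beta_s)
  if (lapse < 0 || lapse > 1)
    stop_input("lapse must be a probability in [0, 1] (got %g)", lapse)
  if (chance < 0 || chance > 1)
    stop_input("chance must be a probability in [0, 1] (got %g)", chance)
  structure(list(beta_d = beta_d, beta_s = beta_s, lapse = lapse,
                 chance = chance),
            class = "occlu_params")
}

#' @export
print.occlu_params <- function(x, ...) {
  cat(sprintf(
    "Task-accuracy model parameters: beta_d = %.4g  beta_s = %.4g  lapse = %.4g  chance = %.4g\n",
    x$beta_d, x$beta_s, x$lapse, x$chance))
  invisible(x)
}

#' Tracking-quality function F(d, s)
#'
#' The separable product of two Gaussian-decay kernels,
#' `F(d, s) = exp(-(beta_d * d)^2) * exp(-(beta_s * s)^2)`,
#' evaluated on absolute displacement `d` (deg) and absolute slippage `s`
#' (deg/s). `F` equals 1 at the origin (perfect position and velocity match)
#' and decreases towards 0 as either error grows. It is the stimulus-driven
#' part of the accuracy model and, on its own, the tracking-quality metric
#' used to score gaze continuously during occlusion (chance level and lapse
#' rate are omitted by construction, so `F` does not depend on them).
#'
#' @param d Absolute displacement in degrees (negative inputs are
#'   absolute-valued).
#' @param s Absolute slippage in deg/s (negative inputs are absolute-valued).
#' @param params An [model_params()] object.
#' @return Numeric vector of quality values in `[0, 1]`.
#' @examples
#' tracking_quality(0, 0, model_params())            # 1
#' tracking_quality(2.5, 0, model_params(0.18, 0.01)) # exp(-0.2025)
#' @export
tracking_quality <- function(d, s, params) {
  stopifnot(inherits(params, "occlu_params"))
  d <- abs(d)
  s <- abs(s)
  exp(-(params$beta_d * d)^2 - (params$beta_s * s)^2)
}

#' Predicted discrimination accuracy A(d, s)
#'
#' The full psychometric model
#' `A = gamma + (1 - gamma) * (1 - lambda) * F(d, s)`:
#' probability of a correct 4AFC response given absolute displacement and
#' slippage at the moment the probe appears. At the origin it equals
#' `1 - lambda + lambda * gamma`; as `d` or `s` grow it plateaus at the
#' chance level `gamma`.
#'
#' @inheritParams tracking_quality
#' @return Numeric vector of probabilities in `[gamma, 1 - lambda*(1-gamma)]`.
#' @export
predict_accuracy <- function(d, s, params) {
  g <- params$chance
  g + (1 - g) * (1 - params$lapse) * tracking_quality(d, s, params)
}

# Probability clamp applied before taking logs in the likelihood.
# Needed e.g. when lapse = 0 makes p = 1 on a failure trial.
.p_eps <- 1e-12

#' Negative Bernoulli log-likelihood of trial features under the model
#'
#' @param features A data frame with one row per trial and columns `d`
#'   (absolute displacement, deg), `s` (absolute slippage, deg/s) and
#'   `outcome` (1 = correct, 0 = incorrect).
#' @param params An [model_params()] object.
#' @return Scalar negative log-likelihood (>= 0).
#' @export
negative_log_likelihood <- function(features, params) {
  if (nrow(features) == 0)
    stop_input("empty feature table: likelihood undefined")
  if (any(!is.finite(features$d)) || any(!is.finite(features$s)))
    stop_input("non-finite d or s in feature table")
  y <- as.numeric(features$outcome)
  p <- predict_accuracy(features$d, features$s, params)
  p <- pmin(pmax(p, .p_eps), 1 - .p_eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' The reduced-model ladder
#'
#' Returns the seven model variants compared in the analysis: the full model
#' (free `beta_d`, `beta_s`, `lambda`) and every reduction obtained by
#' pinning some of those parameters at zero. A parameter pinned at zero
#' removes the corresponding effect (a zero sensitivity ignores that error
#' dimension; zero lapse removes the accuracy ceiling below 1).
#'
#' @return A named list; each element has `name` and `free` (character
#'   vector naming the free parameters).
#' @export
model_variants <- function() {
  v <- list(
    full                 = c("beta_d", "beta_s", "lapse"),
    remove_lambda        = c("beta_d", "beta_s"),
    remove_beta_s        = c("beta_d", "lapse"),
    remove_beta_s_lambda = c("beta_d"),
    remove_beta_d        = c("beta_s", "lapse"),
    remove_beta_d_lambda = c("beta_s"),
    remove_beta_d_beta_s = c("lapse")
  )
  lapply(setNames(names(v), names(v)),
         function(nm) list(name = nm, free = v[[nm]]))
}

#' Default box bounds for the maximum-likelihood search
#'
#' @return Named list of `c(lower, upper)` per parameter.
#' @export
default_bounds <- function() {
  list(beta_d = c(0, 2), beta_s = c(0, 1), lapse = c(0, 0.5))
}

# Vectorised NLL over a parameter grid: rows = grid points.
# Grid columns beta_d, beta_s, lapse; returns NLL per grid point.
.nll_grid <- function(d, s, y, grid, chance) {
  # n_trials x n_grid matrix of F values
  logF <- -outer(d^2, grid[, "beta_d"]^2) - outer(s^2, grid[, "beta_s"]^2)
  p <- chance + (1 - chance) *
    sweep(exp(logF), 2, 1 - grid[, "lapse"], `*`)
  p <- pmin(pmax(p, .p_eps), 1 - .p_eps)
  -as.vector(crossprod(log(p), y) + crossprod(log1p(-p), 1 - y))
}

#' Fit the accuracy model to one participant by maximum likelihood
#'
#' Deterministic box-constrained global search (a dense grid of at least
#' 5000 objective evaluations over the free-parameter box) followed by
#' `L-BFGS-B` local refinement started from the best grid incumbents.
#' Non-free parameters of the requested variant are pinned at zero. The
#' refinement can only improve the objective, and identical input always
#' yields identical output.
#'
#' @param features Trial feature table (columns `d`, `s`, `outcome`); at
#'   least 20 trials with non-missing features are required.
#' @param variant A variant name from [model_variants()] (default `"full"`)
#'   or one of the list elements it returns.
#' @param bounds Named list of box bounds, as [default_bounds()].
#' @param chance Fixed chance level (0.25 for the 4AFC task).
#' @param participant_id Optional identifier carried into the result.
#' @return An `occlu_fit` list: `participant_id`, `variant`, `params`
#'   ([model_params()] with pinned zeros filled in), `log_likelihood`,
#'   `n_trials`, `k_free`, `converged`, `at_boundary` and an optimizer
#'   trace summary (`n_eval_grid`, `n_refine`).
#' @export
fit_participant <- function(features, variant = "full",
                            bounds = default_bounds(), chance = 0.25,
                            participant_id = NA) {
  if (is.character(variant)) {
    variants <- model_variants()
    if (!variant %in% names(variants))
      stop_input("unknown model variant '%s'", variant)
    variant <- variants[[variant]]
  }
  keep <- is.finite(features$d) & is.finite(features$s) &
    !is.na(features$outcome)
  features <- features[keep, , drop = FALSE]
  if (nrow(features) < 20)
    stop_input("need >= 20 trials with non-missing features (got %d)",
               nrow(features))
  d <- abs(features$d); s <- abs(features$s)
  y <- as.numeric(features$outcome)

  free <- variant$free
  k <- length(free)
  all_names <- c("beta_d", "beta_s", "lapse")
  fixed <- setdiff(all_names, free)

  # Grid resolution per number of free parameters, keeping the total number
  # of global evaluations at or above 5000.
  n_per_dim <- switch(as.character(k), "0" = 1L, "1" = 5001L, "2" = 75L,
                      "3" = 18L)
  axes <- lapply(all_names, function(nm) {
    if (nm %in% free) seq(bounds[[nm]][1], bounds[[nm]][2],
                          length.out = n_per_dim)
    else 0
  })
  names(axes) <- all_names
  grid <- as.matrix(expand.grid(beta_d = axes$beta_d, beta_s = axes$beta_s,
                                lapse = axes$lapse))
  nll_g <- .nll_grid(d, s, y, grid, chance)
  if (any(!is.finite(nll_g)))
    stop_input("non-finite objective on the global grid")
  ord <- order(nll_g)

  obj <- function(theta) {
    par <- list(beta_d = 0, beta_s = 0, lapse = 0)
    par[free] <- as.list(theta)
    f <- exp(-(par$beta_d * d)^2 - (par$beta_s * s)^2)
    p <- chance + (1 - chance) * (1 - par$lapse) * f
    p <- pmin(pmax(p, .p_eps), 1 - .p_eps)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }

  best_par <- grid[ord[1], free]
  best_val <- nll_g[ord[1]]
  n_refine <- 0L
  converged <- TRUE
  if (k > 0) {
    lower <- vapply(bounds[free], `[`, numeric(1), 1)
    upper <- vapply(bounds[free], `[`, numeric(1), 2)
    starts <- ord[seq_len(min(3, length(ord)))]
    for (i in starts) {
      fit <- tryCatch(
        optim(grid[i, free], obj, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(factr = 1e4)),
        error = function(e) NULL)
      if (is.null(fit)) next
      n_refine <- n_refine + 1L
      if (fit$value < best_val) {
        best_val <- fit$value
        best_par <- fit$par
        converged <- fit$convergence == 0
      }
    }
    if (n_refine == 0L) converged <- FALSE
  }

  if (k > 0) {
    lower <- vapply(bounds[free], `[`, numeric(1), 1)
    upper <- vapply(bounds[free], `[`, numeric(1), 2)
    best_par <- pmin(pmax(unlist(best_par), lower), upper)
  }
  full_par <- list(beta_d = 0, beta_s = 0, lapse = 0)
  full_par[free] <- as.list(unname(best_par))
  at_boundary <- if (k > 0) {
    lower <- vapply(bounds[free], `[`, numeric(1), 1)
    upper <- vapply(bounds[free], `[`, numeric(1), 2)
    any(abs(unlist(best_par) - lower) < 1e-10 |
          abs(unlist(best_par) - upper) < 1e-10)
  } else FALSE

  structure(list(
    participant_id = participant_id,
    variant = variant$name,
    params = model_params(full_par$beta_d, full_par$beta_s, full_par$lapse,
                          chance),
    log_likelihood = -best_val,
    n_trials = nrow(features),
    k_free = k,
    converged = converged,
    at_boundary = at_boundary,
    n_eval_grid = nrow(grid),
    n_refine = n_refine
  ), class = "occlu_fit")
}

#' @export
print.occlu_fit <- function(x, ...) {
  cat(sprintf(
    "ML fit [%s] participant %s: LL = %.3f on %d trials (k = %d)%s\n",
    x$variant, as.character(x$participant_id), x$log_likelihood,
    x$n_trials, x$k_free,
    if (x$at_boundary) " [boundary]" else ""))
  print(x$params)
  invisible(x)
}

#' Fit every model variant for every participant of a cohort
#'
#' @param trials Feature table with columns `participant_id`, `d`, `s`,
#'   `outcome`.
#' @param variants Character vector of variant names, or `"all"`.
#' @inheritParams fit_participant
#' @return A tibble with one row per participant x variant: estimates,
#'   log-likelihood, `k_free`, convergence flags.
#' @export
fit_cohort <- function(trials, variants = "all", bounds = default_bounds(),
                       chance = 0.25) {
  if (identical(variants, "all")) variants <- names(model_variants())
  pids <- unique(trials$participant_id)
  rows <- list()
  for (pid in pids) {
    sub <- trials[trials$participant_id == pid, , drop = FALSE]
    for (v in variants) {
      f <- fit_participant(sub, v, bounds, chance, participant_id = pid)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, variant = v,
        beta_d = f$params$beta_d, beta_s = f$params$beta_s,
        lapse = f$params$lapse,
        log_likelihood = f$log_likelihood, n_trials = f$n_trials,
        k_free = f$k_free, converged = f$converged,
        at_boundary = f$at_boundary)
    }
  }
  dplyr::bind_rows(rows)
}

#' Akaike information criterion from a log-likelihood
#'
#' @param log_likelihood Summed log-likelihood.
#' @param k Total number of free parameters.
#' @return `2 * k - 2 * log_likelihood`.
#' @export
aic <- function(log_likelihood, k) 2 * k - 2 * log_likelihood

#' Model-comparison ladder across participants
#'
#' Sums per-participant log-likelihoods for each variant and computes the
#' summed AIC with `K = k_free * n_participants` free parameters (each
#' participant has their own parameter set). The table is sorted by AIC,
#' lowest (best) first.
#'
#' @param fits Tibble as returned by [fit_cohort()] (needs
#'   `participant_id`, `variant`, `log_likelihood`, `k_free`).
#' @return Tibble with columns `variant`, `log_likelihood`, `k_total`,
#'   `aic`, `rank`.
#' @export
compare_models <- function(fits) {
  pids <- unique(fits$participant_id)
  vars <- unique(fits$variant)
  have <- table(fits$participant_id, fits$variant)
  if (any(have != 1)) {
    gaps <- which(have != 1, arr.ind = TRUE)
    stop_input("missing or duplicated fits for %d participant/variant pairs (first: %s / %s)",
               nrow(gaps), rownames(have)[gaps[1, 1]],
               colnames(have)[gaps[1, 2]])
  }
  out <- dplyr::summarise(
    dplyr::group_by(fits, .data$variant),
    log_likelihood = sum(.data$log_likelihood),
    k_total = .data$k_free[1] * length(pids),
    .groups = "drop")
  out$aic <- aic(out$log_likelihood, out$k_total)
  out <- out[order(out$aic), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Percentile bootstrap confidence interval for a cross-participant mean
#'
#' Resamples participant-level statistics with replacement (via the `boot`
#' package) and returns the mean with a percentile interval.
#'
#' @param values Numeric vector of per-participant statistics (length >= 2).
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `mean`, `lower`, `upper`, `n`, `n_resamples`.
#' @export
bootstrap_ci <- function(values, n_resamples = 5000, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop_input("bootstrap_ci needs at least 2 non-missing values")
  b <- boot::boot(values, function(x, i) mean(x[i]), R = n_resamples)
  alpha <- (1 - level) / 2
  qs <- quantile(b$t[, 1], c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(mean = mean(values), lower = qs[1], upper = qs[2],
                 n = length(values), n_resamples = n_resamples)
}

#' Binned observed accuracy with model predictions at bin centres
#'
#' Cross-tabulates trials into half-open displacement x slippage bins and
#' reports the observed success proportion per bin, flagging bins with
#' fewer than `min_count` trials. If cohort-mean parameters are supplied,
#' the model prediction at each bin centre is attached.
#'
#' @param features Feature table (`d`, `s`, `outcome`).
#' @param d_edges Strictly increasing displacement bin edges (deg);
#'   default 0 to 15 deg in 2.5-deg steps.
#' @param s_edges Strictly increasing slippage bin edges (deg/s); default
#'   slippage quartiles of the data.
#' @param params_mean Optional [model_params()] with cohort-mean values.
#' @param min_count Minimum trials for a bin not to be flagged `low_n`.
#' @return Tibble with bin indices, centres, counts, observed rate,
#'   `low_n`, and (optionally) `predicted`.
#' @export
binned_accuracy <- function(features, d_edges = seq(0, 15, by = 2.5),
                            s_edges = NULL, params_mean = NULL,
                            min_count = 5) {
  if (is.unsorted(d_edges, strictly = TRUE))
    stop_input("d_edges must be strictly increasing")
  if (is.null(s_edges)) {
    s_edges <- unique(quantile(features$s, c(0, 0.25, 0.5, 0.75, 1),
                               names = FALSE))
    s_edges[length(s_edges)] <- s_edges[length(s_edges)] + 1e-9
  }
  if (is.unsorted(s_edges, strictly = TRUE))
    stop_input("s_edges must be strictly increasing")
  di <- findInterval(features$d, d_edges, rightmost.closed = FALSE)
  si <- findInterval(features$s, s_edges, rightmost.closed = FALSE)
  inb <- di >= 1 & di < length(d_edges) & si >= 1 & si < length(s_edges)
  sub <- features[inb, , drop = FALSE]
  di <- di[inb]; si <- si[inb]
  key <- interaction(di, si, drop = TRUE)
  agg <- tapply(as.numeric(sub$outcome), key, function(v) c(length(v), mean(v)))
  idx <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  out <- tibble::tibble(
    d_bin = as.integer(idx[, 1]),
    s_bin = as.integer(idx[, 2]),
    d_center = (d_edges[as.integer(idx[, 1])] +
                  d_edges[as.integer(idx[, 1]) + 1]) / 2,
    s_center = (s_edges[as.integer(idx[, 2])] +
                  s_edges[as.integer(idx[, 2]) + 1]) / 2,
    n = vapply(agg, `[`, numeric(1), 1),
    rate = vapply(agg, `[`, numeric(1), 2))
  out$low_n <- out$n < min_count
  if (!is.null(params_mean))
    out$predicted <- predict_accuracy(out$d_center, out$s_center, params_mean)
  out[order(out$d_bin, out$s_bin), ]
}
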