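# The task-accuracy model: F, A, likelihood, fitting, AIC ladder,
# bootstrap, binned accuracy.

test_that("tracking quality is 1 at the origin and follows closed forms", {
  p <- model_params(beta_d = 0.18, beta_s = 0.01)
  expect_equal(tracking_quality(0, 0, p), 1)
  expect_equal(tracking_quality(2.5, 0, p), exp(-(0.18 * 2.5)^2))
  expect_equal(tracking_quality(2.5, 10, p),
               exp(-0.2025) * exp(-0.01), tolerance = 1e-12)
  # negative inputs are absolute-valued
  expect_equal(tracking_quality(-2.5, -10, p),
               tracking_quality(2.5, 10, p))
})

test_that("quality is separable, bounded, and monotone", {
  p <- model_params(beta_d = 0.3, beta_s = 0.02)
  set.seed(1)
  d <- runif(200, 0, 20); s <- runif(200, 0, 100)
  q <- tracking_quality(d, s, p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(abs(q - tracking_quality(d, 0, p) *
                        tracking_quality(0, s, p)) <= 1e-12))
  dd <- sort(d)
  expect_true(all(diff(tracking_quality(dd, 5, p)) <= 0))
})

test_that("accuracy prediction has the stated ceiling, floor and limits", {
  p <- model_params(beta_d = 0.18, beta_s = 0.01, lapse = 0.03,
                    chance = 0.25)
  expect_equal(predict_accuracy(0, 0, model_params(lapse = 0)), 1)
  expect_equal(predict_accuracy(0, 0, p), 0.9775)   # 1 - lambda + lambda*gamma
  expect_equal(predict_accuracy(1e6, 0, p), 0.25, tolerance = 1e-12)
  set.seed(2)
  a <- predict_accuracy(runif(500, 0, 50), runif(500, 0, 300), p)
  expect_true(all(a >= 0.25 - 1e-12))
  expect_true(all(a <= 1 - p$lapse * (1 - p$chance) + 1e-12))
})

test_that("the likelihood matches a per-trial loop oracle", {
  # single constructed trial with p = 0.5
  p_half <- model_params(beta_d = sqrt(log(2)), beta_s = 0, lapse = 0,
                         chance = 0)
  one <- tibble::tibble(d = 1, s = 0, outcome = 1)
  expect_equal(negative_log_likelihood(one, p_half), log(2))
  one$outcome <- 0
  expect_equal(negative_log_likelihood(one, p_half), log(2))
  # additivity over identical trials
  many <- one[rep(1, 17), ]
  expect_equal(negative_log_likelihood(many, p_half), 17 * log(2))

  # independently coded loop oracle on random instances
  loop_nll <- function(f, pars) {
    tot <- 0
    for (i in seq_len(nrow(f))) {
      pa <- pars$chance + (1 - pars$chance) * (1 - pars$lapse) *
        exp(-(pars$beta_d * abs(f$d[i]))^2) *
        exp(-(pars$beta_s * abs(f$s[i]))^2)
      pa <- min(max(pa, 1e-12), 1 - 1e-12)
      tot <- tot - (f$outcome[i] * log(pa) +
                      (1 - f$outcome[i]) * log(1 - pa))
    }
    tot
  }
  for (seed in 1:100) {
    f <- random_features(50, seed)
    set.seed(seed + 1e4)
    pars <- model_params(runif(1, 0, 1), runif(1, 0, 0.1),
                         runif(1, 0, 0.4))
    expect_lt(abs(negative_log_likelihood(f, pars) - loop_nll(f, pars)),
              1e-9)
  }
  expect_error(negative_log_likelihood(random_features(0, 1),
                                       model_params()), "empty")
})

test_that("the seven-variant ladder is constructible", {
  v <- model_variants()
  expect_length(v, 7)
  frees <- lapply(v, `[[`, "free")
  expect_equal(max(lengths(frees)), 3L)
  expect_setequal(frees$remove_lambda, c("beta_d", "beta_s"))
  expect_setequal(frees$remove_beta_s_lambda, "beta_d")
  expect_setequal(frees$remove_beta_d_beta_s, "lapse")
})

test_that("the lapse-only fit matches a 1-D grid oracle", {
  f <- random_features(120, 3)
  set.seed(33)
  f$outcome <- rbinom(nrow(f), 1, 0.85)   # keeps the optimum interior
  fit <- fit_participant(f, "remove_beta_d_beta_s")
  # oracle: dense 1-D grid over lapse; p = gamma + (1-gamma)(1-lambda)
  lam <- seq(0, 0.5, length.out = 200001)
  p <- 0.25 + 0.75 * (1 - lam)
  nll <- -(sum(f$outcome) * log(p) + sum(1 - f$outcome) * log(1 - p))
  expect_lt(abs(fit$params$lapse - lam[which.min(nll)]), 1e-4)
  expect_lte(-fit$log_likelihood, min(nll) + 1e-8)
  # closed-form optimality condition: fitted mean p equals success rate
  expect_lt(abs((0.25 + 0.75 * (1 - fit$params$lapse)) - mean(f$outcome)),
            1e-5)
})

test_that("all-success data at the origin pins the lapse at zero", {
  f <- tibble::tibble(d = rep(0, 25), s = 0, outcome = 1)
  fit <- fit_participant(f, "remove_beta_d_beta_s")
  expect_equal(fit$params$lapse, 0)
  expect_true(fit$at_boundary)
})

test_that("fitting is deterministic", {
  f <- random_features(80, 11)
  a <- fit_participant(f, "full")
  b <- fit_participant(f, "full")
  expect_identical(a$params, b$params)
  expect_identical(a$log_likelihood, b$log_likelihood)
})

test_that("model comparison reproduces the AIC arithmetic exactly", {
  # nine participants; per-variant LLs chosen to sum to published-scale
  # totals; the identity AIC = 2K - 2LL must hold exactly
  mk_fits <- function(ll_sum, variant, k_free) tibble::tibble(
    participant_id = 1:9, variant = variant,
    log_likelihood = ll_sum / 9, k_free = k_free)
  fits <- dplyr::bind_rows(
    mk_fits(-369.88, "full", 3),
    mk_fits(-377.24, "remove_lambda", 2),
    mk_fits(-417.80, "remove_beta_s_lambda", 1))
  tab <- compare_models(fits)
  expect_equal(tab$aic[tab$variant == "full"], 793.76, tolerance = 1e-8)
  expect_equal(tab$aic[tab$variant == "remove_lambda"], 790.48,
               tolerance = 1e-8)
  expect_equal(tab$aic[tab$variant == "remove_beta_s_lambda"], 853.60,
               tolerance = 1e-8)
  # sorted ascending, best first
  expect_equal(tab$variant[1], "remove_lambda")
  expect_equal(tab$rank, 1:3)
  expect_equal(aic(0, 0), 0)
  # missing fits are an error, not a silent drop
  expect_error(compare_models(fits[-1, ]), "missing")
})

test_that("percentile bootstrap matches exhaustive enumeration", {
  b <- bootstrap_ci(rep(4.2, 5), n_resamples = 500)
  expect_equal(unlist(b[, c("mean", "lower", "upper")]),
               c(mean = 4.2, lower = 4.2, upper = 4.2))
  # two participants {0, 1}: resample means are {0, 1/2, 1} with
  # probabilities {1/4, 1/2, 1/4}; the 95% percentile interval is [0, 1]
  set.seed(8)
  b2 <- bootstrap_ci(c(0, 1), n_resamples = 5000)
  expect_equal(b2$lower, 0)
  expect_equal(b2$upper, 1)
  # endpoints always within the data range
  for (seed in 1:10) {
    set.seed(seed)
    v <- rnorm(7)
    bb <- bootstrap_ci(v, n_resamples = 300)
    expect_gte(bb$lower, min(v))
    expect_lte(bb$upper, max(v))
  }
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("binned accuracy partitions trials and matches predictions", {
  f <- random_features(400, 21)
  f$outcome <- 1
  tab <- binned_accuracy(f, d_edges = seq(0, 10, 2.5),
                         s_edges = c(0, 10, 20, 50))
  expect_true(all(tab$rate == 1))
  in_range <- f$d >= 0 & f$d < 10 & f$s >= 0 & f$s < 50
  expect_equal(sum(tab$n), sum(in_range))
  expect_true(all(tab$low_n == (tab$n < 5)))

  # generative self-consistency on a larger simulated table
  set.seed(22)
  p_true <- model_params(0.18, 0.01, 0.03)
  d <- abs(rnorm(5000, 2, 2)); s <- abs(rnorm(5000, 10, 10))
  out <- simulate_outcome(d, s, p_true, seed = 23)
  f2 <- tibble::tibble(d = d, s = s, outcome = out$outcome)
  tab2 <- binned_accuracy(f2, d_edges = seq(0, 10, 2.5),
                          s_edges = c(0, 10, 20, 40),
                          params_mean = p_true)
  big <- tab2[tab2$n >= 50, ]
  se <- sqrt(big$predicted * (1 - big$predicted) / big$n)
  expect_true(all(abs(big$rate - big$predicted) < 3 * se + 0.02))
})
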