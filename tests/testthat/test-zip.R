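test_that("with one file and no zero inflation the fit reduces to a Poisson GLM", {
  set.seed(10)
  d <- tibble::tibble(file_id = "f1", bin = rep(bin_levels(), each = 30),
                      bin_width = rep(bin_widths(), each = 30))
  d$count <- rpois(nrow(d), exp(sim_beta()[d$bin] + log(d$bin_width)))
  expect_warning(
    fit <- fit_zip_mixed(d, zero_inflation = FALSE),
    "fewer than 2 files"
  )
  ref <- glm(count ~ 0 + factor(bin, levels = bin_levels()) + offset(log(bin_width)),
             family = poisson(), data = d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("marginal likelihood equals brute-force numerical integration", {
  d <- simulate_zip_counts(sim_beta(), pi = 0.2, sigma_u = 0.5,
                           n_files = 4, seed = 3)
  fit <- fit_zip_mixed(d, nodes = 15, hessian = FALSE)
  oracle <- zip_marginal_ll_trapezoid(coef(fit), fit$pi, fit$sigma_u, d)
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)
})

test_that("quadrature and Laplace agree closely and match glmmTMB", {
  skip_if_not_installed("glmmTMB")
  d <- simulate_zip_counts(sim_beta(), pi = 0.2, sigma_u = 0.5,
                           n_files = 40, seed = 7)
  ours <- fit_zip_mixed(d, method = "laplace")
  agq <- fit_zip_mixed(d, method = "agq", hessian = FALSE)
  expect_equal(ours$loglik, agq$loglik, tolerance = 0.01)

  d$binf <- factor(d$bin, levels = bin_levels())
  g <- glmmTMB::glmmTMB(count ~ 0 + binf + (1 | file_id),
                        offset = log(d$bin_width), ziformula = ~1,
                        family = poisson(), data = d)
  expect_equal(ours$loglik, as.numeric(logLik(g)), tolerance = 1e-5)
  expect_equal(unname(coef(ours)), unname(glmmTMB::fixef(g)$cond),
               tolerance = 1e-4)
  expect_equal(ours$sigma_u,
               sqrt(glmmTMB::VarCorr(g)$cond$file_id[1]), tolerance = 1e-3)
  expect_equal(unname(ours$se), unname(sqrt(diag(stats::vcov(g)$cond))),
               tolerance = 1e-4)
})

test_that("with no observed zeros the ZIP fit collapses to the Poisson fit", {
  d <- simulate_zip_counts(setNames(rep(log(150), 6), bin_levels()),
                           pi = 0, sigma_u = 0.4, n_files = 10, seed = 4)
  expect_equal(sum(d$count == 0), 0)
  zip <- fit_zip_mixed(d, hessian = FALSE)
  pois <- fit_zip_mixed(d, zero_inflation = FALSE, hessian = FALSE)
  expect_lt(zip$pi, 1e-3)
  expect_equal(zip$loglik, pois$loglik, tolerance = 1e-2)
  expect_equal(coef(zip), coef(pois), tolerance = 1e-4)
})

test_that("rescaling all bin widths shifts only the intercept level", {
  d <- simulate_zip_counts(sim_beta(), pi = 0.15, sigma_u = 0.4,
                           n_files = 12, seed = 5)
  f1 <- fit_zip_mixed(d)
  d2 <- d
  d2$bin_width <- d2$bin_width * 7
  f2 <- fit_zip_mixed(d2)
  expect_equal(coef(f2) + log(7), coef(f1), tolerance = 1e-5)
  c1 <- posthoc_contrasts(f1)
  c2 <- posthoc_contrasts(f2)
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-5)
  expect_equal(c1$se, c2$se, tolerance = 1e-4)
})

test_that("fitted likelihood is at least the likelihood at the truth", {
  beta <- sim_beta()
  d <- simulate_zip_counts(beta, pi = 0.2, sigma_u = 0.5, n_files = 5, seed = 6)
  fit <- fit_zip_mixed(d, hessian = FALSE)
  ll_true <- zip_marginal_ll_trapezoid(beta, 0.2, 0.5, d)
  expect_gte(fit$loglik, ll_true)
})

test_that("contrast SEs match a finite-difference Hessian of the brute-force likelihood", {
  d <- simulate_zip_counts(sim_beta(), pi = 0.2, sigma_u = 0.5,
                           n_files = 4, seed = 3)
  fit <- fit_zip_mixed(d)
  theta <- c(coef(fit), zeta = fit$zeta, log_sigma = log(fit$sigma_u))
  nll_oracle <- function(th) {
    -zip_marginal_ll_trapezoid(setNames(th[1:6], bin_levels()),
                               plogis(th[7]), exp(th[8]), d,
                               half_width = 12, n_grid = 4001)
  }
  V <- solve(fd_hessian_oracle(nll_oracle, unname(theta)))
  cvec <- c(1, -1, rep(0, 6))  # off1:1 - on1:1 in bin_levels() order
  se_oracle <- sqrt(drop(t(cvec) %*% V %*% cvec))
  ct <- posthoc_contrasts(fit, pairs = list(c("off1:1", "on1:1")))
  expect_equal(ct$se, se_oracle, tolerance = 1e-4)
  expect_equal(ct$statistic, ct$estimate / ct$se)
})

test_that("a contrast of a level with itself is null", {
  d <- simulate_zip_counts(sim_beta(), pi = 0.15, sigma_u = 0.4,
                           n_files = 8, seed = 9)
  fit <- fit_zip_mixed(d)
  ct <- posthoc_contrasts(fit, pairs = list(c("on1:1", "on1:1")))
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p_value, 1)
  expect_error(posthoc_contrasts(fit, pairs = list(c("on1:1", "nope"))),
               class = "contrast_error")
})

test_that("a two-level balanced design recovers the log rate ratio", {
  set.seed(12)
  lam <- c("on1:1" = 40, "off1:1" = 15)
  d <- tibble::tibble(file_id = "f1",
                      bin = rep(names(lam), each = 150), bin_width = 1)
  d$count <- rpois(nrow(d), lam[d$bin])
  fit <- suppressWarnings(fit_zip_mixed(d, zero_inflation = FALSE))
  ct <- posthoc_contrasts(fit, pairs = list(c("off1:1", "on1:1")))
  expect_equal(ct$estimate, log(mean(d$count[d$bin == "off1:1"]) /
                                  mean(d$count[d$bin == "on1:1"])),
               tolerance = 1e-6)
  expect_lt(abs(ct$estimate - log(lam["off1:1"] / lam["on1:1"])), 3 * ct$se)
})

test_that("identical models give a null LRT and misordered fits error", {
  d <- simulate_zip_counts(sim_beta(), pi = 0.15, sigma_u = 0.4,
                           n_files = 6, seed = 13)
  fit <- fit_zip_mixed(d, hessian = FALSE)
  out <- lrt_full_vs_null(fit, fit)
  expect_equal(out$chi2, 0)
  expect_equal(out$df, 0)
  expect_equal(out$p_value, 1)
  worse <- fit
  worse$loglik <- fit$loglik + 1
  expect_error(lrt_full_vs_null(fit, worse), class = "convergence_error")
})

test_that("the LRT detects a strong on/off rhythm signal", {
  rejections <- vapply(1:20, function(s) {
    d <- simulate_zip_counts(sim_beta(), pi = 0.2, sigma_u = 0.5,
                             n_files = 40, seed = 100 + s)
    full <- fit_zip_mixed(d, method = "laplace", hessian = FALSE)
    null <- fit_zip_mixed(d, include_fixed = FALSE, method = "laplace",
                          hessian = FALSE)
    lrt_full_vs_null(full, null)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})
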