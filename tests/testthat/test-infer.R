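test_that("SFS log-likelihood is a well-behaved multinomial", {
  m <- demographic_model("Div", theta = 1e-3, T = 5)
  counts <- c(kA = 10, kB = 12, kAB = 0, kAABB = 50, invariant = 10000)
  ll <- sfs_loglik(m, counts)
  expect_true(is.finite(ll) && ll < 0)

  # named input in any order gives the same answer
  expect_equal(sfs_loglik(m, counts[c(5, 3, 1, 2, 4)]), ll)

  # nearly all invariant sites with tiny theta: per-site lnL approaches 0
  small <- demographic_model("Div", theta = 1.1e-5, T = 0.01)
  inv_only <- c(kA = 0, kB = 0, kAB = 0, kAABB = 0, invariant = 1000)
  expect_gt(sfs_loglik(small, inv_only) / 1000, -1e-4)
  expect_lt(sfs_loglik(small, inv_only), 0)
})

test_that("bSFS log-likelihood multiplies block probabilities and filters", {
  m <- demographic_model("Div", theta = 0.001, T = 0)
  one <- data.frame(orthogroup = "b1", n_sites = 150, kA = 0, kB = 0,
                    kAB = 0, kAABB = 0, four_gamete_pass = TRUE)
  expect_equal(bsfs_loglik(m, one), log(panmictic_invariant_prob(0.075)),
               tolerance = 1e-10)

  two <- rbind(one, one)
  expect_equal(bsfs_loglik(m, two), 2 * bsfs_loglik(m, one), tolerance = 1e-12)

  # four-gamete violators are excluded, and block order is irrelevant
  tab <- toy_blocks()
  m2 <- bombina_bsfs_model()
  expect_message(ll <- bsfs_loglik(m2, tab), "excluded")
  shuffled <- tab[c(4, 2, 6, 1, 3, 5), ]
  expect_equal(bsfs_loglik(m2, shuffled, quiet = TRUE), ll)
  clean <- tab[tab$four_gamete_pass, ]
  expect_equal(bsfs_loglik(m2, clean, quiet = TRUE), ll)
})

test_that("likelihoods at the truth dominate perturbed parameters", {
  set.seed(99)
  truth <- demographic_model("IM2", theta = 0.0013, T = 12, M = 0.03,
                             direction = "B->A", size_factor = 2,
                             factor_target = "B")
  wins <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    tab <- data.frame(simulate_blocks(truth, 600), n_sites = 150)
    tab$four_gamete_pass <- !(tab$kAB > 0 & tab$kAABB > 0)
    ll_true <- bsfs_loglik(truth, tab, quiet = TRUE)
    pert <- demographic_model("IM2", theta = 0.0013 * 1.5, T = 12 * 0.5,
                              M = 0.03, direction = "B->A",
                              size_factor = 2, factor_target = "B")
    if (ll_true >= bsfs_loglik(pert, tab, quiet = TRUE)) wins <- wins + 1L
  }
  expect_gte(wins, n_rep - 1L)
})

test_that("fitting respects model nesting and flags collapses", {
  set.seed(17)
  truth <- demographic_model("Div", theta = 0.002, T = 8)
  tab <- data.frame(simulate_blocks(truth, 800), n_sites = 150)
  tab$four_gamete_pass <- !(tab$kAB > 0 & tab$kAABB > 0)

  fit <- fit_divergence(tab, mode = "bSFS", models = c("Div", "IM"),
                        n_starts = 3, seed = 4, maxit = 120)
  cmp <- fit$comparison
  lnl_div <- cmp$lnL[cmp$variant == "Div"]
  for (v in c("IM[A->B]", "IM[B->A]"))
    expect_gte(cmp$lnL[cmp$variant == v], lnl_div - 1e-6)
  # data without gene flow: migration estimates collapse towards zero
  expect_lt(min(cmp$M[cmp$model_class == "IM"]), 0.01)
  expect_identical(sum(cmp$dlnL == 0), 1L)

  # parameter recovery in the simple model
  est <- coef(fit)
  expect_lt(abs(est[["theta"]] - 0.002) / 0.002, 0.25)
  expect_lt(abs(est[["T"]] - 8) / 8, 0.25)

  # methods on the fit object
  expect_s3_class(fit, "divmig_fit")
  expect_identical(attr(logLik(fit), "df"),
                   length(divmig:::.variant_parnames(
                     fit$fits[[fit$best]]$model_class)))
  pr <- predict(fit)
  expect_equal(sum(pr), 1)
  sim <- simulate(fit, seed = 1, n_blocks = 50)
  expect_identical(nrow(sim), 50L)
  expect_output(print(fit), "Model support")
})

test_that("SFS mode refuses IM2 and fits three-parameter variants", {
  tab <- toy_blocks()
  expect_error(fit_divergence(tab, mode = "SFS", models = c("Div", "IM2")),
               "IM2")
  set.seed(2)
  truth <- demographic_model("Div2", theta = 0.003, T = 4, size_factor = 0.3,
                             factor_target = "A")
  tab <- data.frame(simulate_blocks(truth, 1000), n_sites = 150)
  fit <- fit_divergence(tab, mode = "SFS", models = c("Div", "Div2"),
                        n_starts = 3, seed = 5)
  cmp <- fit$comparison
  expect_gte(cmp$lnL[cmp$variant == "Div2[NA]"], cmp$lnL[cmp$variant == "Div"] - 1e-6)
  expect_identical(sum(cmp$dlnL == 0), 1L)
})

test_that("model comparison tabulates dlnL and rejects mixed modes", {
  fake <- function(label, lnL, class = "Div") {
    list(label = label, model_class = class, direction = "B->A",
         target = "A", par = c(theta = 1e-3, T = 1, M = 0, factor = 1),
         lnL = lnL, convergence = 0L, n_starts = 1L, collapsed = FALSE)
  }
  x <- structure(list(mode = "bSFS", fits = list(a = fake("a", -100),
                                                 b = fake("b", -103))),
                 class = "divmig_fit")
  cmp <- compare_models(x)
  expect_equal(sort(cmp$dlnL), c(-3, 0))
  # permuting fit order leaves the result invariant
  y <- x
  y$fits <- rev(y$fits)
  expect_equal(compare_models(y)[order(compare_models(y)$variant), "dlnL"],
               cmp[order(cmp$variant), "dlnL"])
  x2 <- x
  x2$mode <- "SFS"
  expect_error(compare_models(list(x, x2)), "modes")
})

test_that("bootstrap reproduces its draws and degenerates to SD zero", {
  # every block identical with exactly one variable site: no resampling
  # variance at all
  tab <- data.frame(orthogroup = sprintf("b%d", 1:40), n_sites = 150,
                    kA = 0, kB = 0, kAB = 0, kAABB = 1,
                    four_gamete_pass = TRUE)
  fit <- fit_divergence(tab, mode = "SFS", models = "Div", n_starts = 2,
                        seed = 1)
  bs <- bootstrap_sfs(tab, fit, B = 5, seed = 3, n_starts = 0)
  expect_identical(nrow(bs$estimates), 5L)
  expect_true(all(bs$sd[c("theta", "T")] == 0))
  expect_true(all(bs$ci["lower", ] <= bs$point & bs$point <= bs$ci["upper", ]))

  set.seed(31)
  truth <- demographic_model("Div", theta = 0.002, T = 6)
  tab2 <- data.frame(simulate_blocks(truth, 300), n_sites = 150)
  fit2 <- fit_divergence(tab2, mode = "SFS", models = "Div", n_starts = 2,
                         seed = 1)
  b1 <- bootstrap_sfs(tab2, fit2, B = 8, seed = 11, n_starts = 0)
  b2 <- bootstrap_sfs(tab2, fit2, B = 8, seed = 11, n_starts = 0)
  expect_equal(b1$estimates, b2$estimates)
  expect_error(bootstrap_sfs(tab2, fit2, B = 1), "at least 2")
})

test_that("absolute conversions reproduce the published arithmetic", {
  # scabra pair, bSFS estimates: theta 0.00129, T 12 -> ~2.5 My
  a <- to_absolute(c(theta = 0.00129, T = 12.0, M = 0.032))
  expect_equal(a$t_years / 1e6, 2.5, tolerance = 0.03)
  # introgressed fraction 1 - exp(-MT) = 0.257 at M 0.015, T 19.8
  b <- to_absolute(c(theta = 0.00154, T = 19.8, M = 0.015))
  expect_equal(b$introgressed_fraction, 0.257, tolerance = 0.01)
  expect_equal(b$immigrant_waiting_years, 200)
  # no migration
  z <- to_absolute(c(theta = 0.001, T = 5))
  expect_identical(z$introgressed_fraction, 0)
  expect_identical(z$immigrant_waiting_years, Inf)
  # homogeneity: jointly rescaling theta and mu leaves N_anc and t fixed,
  # since both depend on them only through theta / mu
  h1 <- to_absolute(c(theta = 0.001, T = 5), mu = 1e-8)
  h2 <- to_absolute(c(theta = 0.01, T = 5), mu = 1e-7)
  expect_equal(h1$N_anc, h2$N_anc)
  expect_equal(h1$t_years, h2$t_years)
})

test_that("excess-block tests match exact binomial tails", {
  m <- bombina_bsfs_model()
  tab <- toy_blocks()
  res <- excess_block_test(tab, m, pinned = "kAABB")
  # oracle: count blocks by hand among four-gamete passes and use the
  # exact binomial survival function
  clean <- tab[tab$four_gamete_pass, ]
  obs <- sum(clean$kAABB == 0)
  expect_identical(res$observed, obs)
  expect_identical(res$n, nrow(clean))
  expect_equal(res$P, pbinom(obs - 1, nrow(clean), res$p_model,
                             lower.tail = FALSE))

  # observed zero: upper tail is 1 by construction
  none <- tab
  none$kAABB <- 5
  none$kAB <- 0
  expect_equal(excess_block_test(none, m, "kAABB")$P, 1)

  # large-sample sanity: observed close to expectation gives mid-range P
  p_model <- pattern_probability_marginal(m, "kAABB")
  n <- 1479
  obs_central <- round(n * p_model)
  P <- pbinom(obs_central - 1, n, p_model, lower.tail = FALSE)
  big <- data.frame(orthogroup = as.character(1:n), n_sites = 150,
                    kA = 0, kB = 0, kAB = 0,
                    kAABB = c(rep(0, obs_central), rep(3, n - obs_central)),
                    four_gamete_pass = TRUE)
  expect_equal(excess_block_test(big, m, "kAABB")$P, P)
  expect_gt(P, 0.2)
  expect_lt(P, 0.8)
})
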