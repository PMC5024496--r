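std_sim <- function(seed, n_geno = 200, trials = 5) {
  map <- make_map(seq(0, 90, 10))
  g <- simulate_dh_genotypes(map, n_geno, seed = 1)
  des <- trial_design(data.frame(trial = paste0("T", seq_len(trials)),
                                 design = "split_plot", n_replicates = 2))
  tr <- sim_truth(mu = 10, sigma2_G = 4, sigma2_GxN = 1, sigma2_GxT = 2,
                  sigma2_GxNxT = 0.5, sigma2_e = 3,
                  trial_means = stats::setNames(seq_len(trials) - 3,
                                                paste0("T", seq_len(trials))),
                  n_level_shift = 0.5, seed = seed)
  list(g = g, des = des,
       rec = simulate_trial_phenotypes(g, des, tr, "SY"))
}

test_that("noise-free single-environment decomposition is exact", {
  rec <- data.frame(genotype = rep(c("A", "B", "C"), each = 2), trial = "T1",
                    n_level = "N1", replicate = rep(1:2, 3), block = NA,
                    trait = "SY", value = rep(c(8, 10, 12), each = 2))
  class(rec) <- c("phenotype_records", "data.frame")
  vc <- fit_variance_components(rec, model_spec("single_env_6", "SY"), "mom")
  expect_equal(vc$components[["sigma2_e"]], 0, tolerance = 1e-12)
  expect_equal(vc$components[["sigma2_G"]], stats::var(c(8, 10, 12)),
               tolerance = 1e-10)
})

test_that("method of moments equals the hand-built EMS oracle and recovers truth", {
  sim <- std_sim(31)
  vc <- fit_variance_components(sim$rec, model_spec("multi_env_1", "SY"), "mom")
  oracle <- ems_oracle_multi(sim$rec)
  for (nm in names(oracle)) {
    expect_equal(vc$pre_clamp[[nm]], oracle[[nm]], tolerance = 1e-8)
  }
  truth <- c(sigma2_G = 4, sigma2_GxN = 1, sigma2_GxT = 2, sigma2_GxNxT = 0.5,
             sigma2_e = 3)
  # single seed: estimates in the sampling neighbourhood of the truth (the
  # 10-seed mean test below pins the recovery tolerance)
  for (nm in names(truth)) {
    expect_lt(abs(vc$components[[nm]] - truth[[nm]]),
              pmax(0.3 * truth[[nm]], 0.2))
  }
})

test_that("mean variance-component estimates over 10 seeds recover truth", {
  truth <- c(sigma2_G = 4, sigma2_GxN = 1, sigma2_GxT = 2, sigma2_GxNxT = 0.5,
             sigma2_e = 3)
  est <- sapply(1:10, function(s) {
    sim <- std_sim(500 + s)
    fit_variance_components(sim$rec, model_spec("multi_env_1", "SY"),
                            "mom")$components[names(truth)]
  })
  m <- rowMeans(est)
  for (nm in names(truth)) {
    expect_lt(abs(m[[nm]] - truth[[nm]]) / truth[[nm]], 0.10)
  }
})

test_that("negative moment estimates are clamped with pre-clamp retained", {
  set.seed(5)
  # sigma2_GxN = 0: the moment estimate fluctuates around zero
  got_negative <- FALSE
  for (s in 1:5) {
    map <- make_map(c(0, 10))
    g <- simulate_dh_genotypes(map, 30, seed = s)
    des <- trial_design(data.frame(trial = c("T1", "T2"), design = "split_plot",
                                   n_replicates = 2))
    tr <- sim_truth(mu = 10, sigma2_G = 1, sigma2_e = 3, seed = 100 + s)
    rec <- simulate_trial_phenotypes(g, des, tr, "SY")
    vc <- fit_variance_components(rec, model_spec("multi_env_1", "SY"), "mom")
    expect_true(all(vc$components >= 0))
    if (vc$pre_clamp[["sigma2_GxN"]] < 0) {
      got_negative <- TRUE
      expect_equal(vc$components[["sigma2_GxN"]], 0)
    }
  }
  expect_true(got_negative)
})

test_that("EM-REML agrees with MoM on balanced data and with lme4", {
  map <- make_map(seq(0, 50, 10))
  g <- simulate_dh_genotypes(map, 40, seed = 2)
  des <- trial_design(data.frame(trial = paste0("T", 1:3),
                                 design = "split_plot", n_replicates = 2))
  tr <- sim_truth(mu = 10, sigma2_G = 4, sigma2_GxN = 2, sigma2_GxT = 3,
                  sigma2_GxNxT = 1, sigma2_e = 2, sigma2_rep = 0.5,
                  trial_means = c(T1 = -3, T2 = 0, T3 = 3), seed = 5)
  rec <- simulate_trial_phenotypes(g, des, tr, "SY")
  spec <- model_spec("multi_env_1", "SY")
  vm <- fit_variance_components(rec, spec, "mom")
  vr <- fit_variance_components(rec, spec, "reml")
  expect_equal(vr$components, vm$components, tolerance = 1e-3)

  skip_if_not_installed("lme4")
  fit <- lme4::lmer(
    value ~ n_level + (1 | genotype) + (1 | trial) + (1 | trial:replicate) +
      (1 | genotype:n_level) + (1 | genotype:trial) +
      (1 | genotype:n_level:trial),
    data = rec, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc_l <- as.data.frame(lme4::VarCorr(fit))
  ref <- stats::setNames(vc_l$vcov, vc_l$grp)
  expect_equal(vr$components[["sigma2_G"]], ref[["genotype"]], tolerance = 1e-2)
  expect_equal(vr$components[["sigma2_GxT"]], ref[["genotype:trial"]],
               tolerance = 1e-2)
  expect_equal(vr$components[["sigma2_e"]], ref[["Residual"]], tolerance = 1e-2)
})

test_that("unbalanced data requires REML; unidentifiable terms are dropped", {
  sim <- std_sim(7, n_geno = 20, trials = 2)
  rec <- sim$rec[-1, ]  # break balance
  expect_error(fit_variance_components(rec, model_spec("multi_env_1", "SY"),
                                       "mom"), "reml")
  one_trial <- sim$rec[sim$rec$trial == "T1", ]
  expect_warning(fit_variance_components(one_trial,
                                         model_spec("multi_env_1", "SY"), "mom"),
                 "unidentifiable")
})

test_that("heritability formulas reproduce hand-computed values", {
  vc <- structure(list(components = c(sigma2_G = 4, sigma2_GxN = 2,
                                      sigma2_GxT = 3, sigma2_e = 6),
                       n_levels = c(n = 2, t = 3, r = 2)),
                  class = "variance_components")
  expect_equal(heritability(vc, "multi_2")$h2, 4 / 6.5, tolerance = 1e-12)
  expect_equal(heritability(vc, "per_trial_5")$h2, 4 / (4 + 1 + 6 / 4),
               tolerance = 1e-12)
  expect_equal(heritability(vc, "single_7")$h2, 4 / 7, tolerance = 1e-12)

  vc$components <- c(sigma2_G = 1, sigma2_GxN = 0, sigma2_GxT = 0, sigma2_e = 0)
  expect_equal(heritability(vc, "multi_2")$h2, 1)
  vc$components <- c(sigma2_G = 0, sigma2_e = 5)
  vc$n_levels <- c(n = 1, t = 1, r = 3)
  expect_equal(heritability(vc, "single_7")$h2, 0)
  vc$components <- c(sigma2_G = 0, sigma2_e = 0)
  expect_true(is.na(heritability(vc, "single_7")$h2))
  # monotone in genetic variance
  h <- sapply(c(1, 2, 4, 8), function(sg) {
    v <- structure(list(components = c(sigma2_G = sg, sigma2_GxN = 1,
                                       sigma2_GxT = 1, sigma2_e = 2),
                        n_levels = c(n = 2, t = 3, r = 2)),
                   class = "variance_components")
    heritability(v, "multi_2")$h2
  })
  expect_true(all(diff(h) > 0))
})

test_that("adjusted means equal raw means on balanced data; BLUPs shrink", {
  sim <- std_sim(13, n_geno = 60, trials = 3)
  spec <- model_spec("multi_env_1", "SY")
  adj <- genotype_estimates(sim$rec, spec, "adjusted_mean")
  raw <- tapply(sim$rec$value, sim$rec$genotype, mean)
  expect_equal(adj$value, as.numeric(raw[adj$genotype]), tolerance = 1e-8)

  blup <- genotype_estimates(sim$rec, spec, "blup")
  expect_lte(stats::var(blup$value), stats::var(adj$value))
  expect_equal(order(blup$value), order(adj$value))
})

test_that("BLUPs track the simulated genotype effects", {
  map <- make_map(seq(0, 30, 10))
  g <- simulate_dh_genotypes(map, 200, seed = 3)
  des <- trial_design(data.frame(trial = c("T1", "T2"), design = "split_plot",
                                 n_replicates = 2))
  tr <- sim_truth(mu = 0, sigma2_G = 4, sigma2_e = 1, seed = 17)
  rec <- simulate_trial_phenotypes(g, des, tr, "SY")
  # recompute the truth genotype effects the generator drew
  set.seed(17)
  poly <- rnorm(200, 0, 2)
  blup <- suppressWarnings(
    genotype_estimates(rec, model_spec("multi_env_1", "SY"), "blup"))
  expect_gte(stats::cor(blup$value, poly), 0.9)
})

test_that("trait correlations: identity, recovery and null behaviour", {
  map <- make_map(seq(0, 30, 10))
  g <- simulate_dh_genotypes(map, 300, seed = 4)
  des <- trial_design(data.frame(trial = c("T1", "T2"), design = "split_plot",
                                 n_replicates = 2))
  tx <- sim_truth(mu = 5, sigma2_G = 2, sigma2_e = 2, seed = 11)
  ty <- sim_truth(mu = 8, sigma2_G = 3, sigma2_e = 3, seed = 12)

  rec <- simulate_trial_phenotypes(g, des, tx, "O")
  self <- rec; self$trait <- "Pr"
  both <- rbind(rec, self)
  class(both) <- c("phenotype_records", "data.frame")
  tc <- trait_correlations(both, c("O", "Pr"))
  expect_equal(tc$r_p, 1)
  expect_equal(tc$r_g, 1, tolerance = 1e-10)

  rc <- simulate_correlated_traits(g, des, tx, ty, r_g = 0.8)
  expect_lt(abs(trait_correlations(rc, c("O", "Pr"))$r_g - 0.8), 0.1)

  # null: three-trial design so genotype values are estimated precisely and
  # the spread of r_g reflects finite-sample correlation alone
  des3 <- trial_design(data.frame(trial = paste0("T", 1:3),
                                  design = "split_plot", n_replicates = 2))
  tx0 <- sim_truth(mu = 5, sigma2_G = 2, sigma2_e = 1, seed = 0)
  ty0 <- sim_truth(mu = 8, sigma2_G = 3, sigma2_e = 1, seed = 0)
  null_ok <- 0
  for (s in 1:10) {
    tx0$seed <- 300 + s
    rc0 <- simulate_correlated_traits(g, des3, tx0, ty0, r_g = 0)
    rg <- trait_correlations(rc0, c("O", "Pr"))$r_g
    if (is.na(rg) || abs(rg) < 0.15) null_ok <- null_ok + 1
  }
  expect_gte(null_ok, 9)
})
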