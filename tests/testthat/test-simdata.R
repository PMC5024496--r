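test_that("genetic map spacing, cardinality and determinism", {
  map <- simulate_genetic_map(1, 100, 11, seed = 1)
  expect_equal(map$position_cM, seq(0, 100, by = 10))

  big <- simulate_genetic_map(19, 50, 50, seed = 2)
  expect_equal(nrow(big), 19 * 50)
  expect_false(anyDuplicated(big$marker) > 0)
  expect_setequal(unique(big$linkage_group),
                  c(paste0("A", 1:10), paste0("C", 1:9)))
  for (lg in unique(big$linkage_group)) {
    expect_false(is.unsorted(big$position_bp[big$linkage_group == lg],
                             strictly = TRUE))
  }

  expect_identical(simulate_genetic_map(3, 80, 20, spacing = "random", seed = 7),
                   simulate_genetic_map(3, 80, 20, spacing = "random", seed = 7))
  expect_error(simulate_genetic_map(1, -5, 10), "positive")
  expect_error(simulate_genetic_map(1, 50, 1), ">= 2")
})

test_that("DH recombination follows the Haldane map function", {
  # zero distance: identical columns
  map0 <- make_map(c(10, 10))
  g0 <- simulate_dh_genotypes(map0, 300, seed = 3)
  expect_equal(g0$calls[, 1], g0$calls[, 2])
  expect_true(all(g0$calls %in% c(0, 2)))

  # observed recombinant fractions within 3 binomial SE of 0.5(1 - e^(-2d/100))
  n <- 2000
  for (d in c(1, 10, 50)) {
    g <- simulate_dh_genotypes(make_map(c(0, d)), n, seed = d + 11)
    r_obs <- mean(g$calls[, 1] != g$calls[, 2])
    r_exp <- 0.5 * (1 - exp(-2 * d / 100))
    se <- sqrt(r_exp * (1 - r_exp) / n)
    expect_lt(abs(r_obs - r_exp), 3 * se)
  }

  # Mendelian allele frequency 0.5 in DH
  g <- simulate_dh_genotypes(make_map(seq(0, 90, by = 10)), 2000, seed = 5)
  af <- colMeans(g$calls) / 2
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.25 / 2000)))

  expect_identical(simulate_dh_genotypes(map0, 50, seed = 9),
                   simulate_dh_genotypes(map0, 50, seed = 9))
})

test_that("panel mosaic produces distance-decaying LD and founder structure", {
  map <- make_map(c(seq(0, 1, 0.1), seq(50, 51, 0.1)))
  g <- simulate_panel_genotypes(map, 300, n_founders = 6, admixture_alpha = 2,
                                seed = 4)
  expect_true(all(g$calls %in% 0:2))
  pr <- pairwise_r2(filter_markers(g), max_dist_cM = Inf)
  near <- mean(pr$r2[pr$dist_cM < 2])
  far <- mean(pr$r2[pr$dist_cM > 40])
  expect_gt(near, far)

  # degenerate mosaic: two founders, no switching, inbred => two clone blocks
  g2 <- simulate_panel_genotypes(make_map(seq(0, 90, 10)), 30, n_founders = 2,
                                 admixture_alpha = 0, inbred = TRUE, seed = 6)
  K <- ibs_kinship(g2)
  expect_true(all(K %in% c(K[1, 1], min(K))))  # only within/between values
  expect_identical(
    simulate_panel_genotypes(map, 40, seed = 8)$calls,
    simulate_panel_genotypes(map, 40, seed = 8)$calls)
})

test_that("phenotype generator honours its degenerate contracts", {
  map <- make_map(c(0, 10))
  g <- simulate_dh_genotypes(map, 20, seed = 1)
  des <- trial_design(data.frame(trial = c("T1", "T2"), design = "split_plot",
                                 n_replicates = 2))
  # all variances and effects zero: constant field
  rec <- simulate_trial_phenotypes(g, des, sim_truth(mu = 10, seed = 1), "SY")
  expect_true(all(rec$value == 10))
  expect_equal(nrow(rec), 20 * 2 * 2 * 2)

  # no G x N and no residual: ecovalence over N exactly zero
  tr <- sim_truth(mu = 5, sigma2_G = 2, sigma2_GxT = 1, seed = 2,
                  trial_means = c(T1 = -1, T2 = 1), n_level_shift = 0.4)
  rec2 <- simulate_trial_phenotypes(g, des, tr, "SY")
  W <- ecovalence(two_way_means(rec2, "SY", "n_level"))$W
  expect_equal(W, rep(0, 20), tolerance = 1e-12)

  # unknown QTL marker is named in the error
  bad <- sim_truth(mu = 1, qtl_effects = data.frame(marker = "nope", add = 1),
                   seed = 3)
  expect_error(simulate_trial_phenotypes(g, des, bad, "SY"), "nope")
})

test_that("realized variance components match targets on the standard design", {
  map <- make_map(seq(0, 90, 10))
  g <- simulate_dh_genotypes(map, 200, seed = 11)
  des <- trial_design(data.frame(trial = paste0("T", 1:5),
                                 design = "split_plot", n_replicates = 2))
  truth <- c(sigma2_G = 4, sigma2_GxT = 2, sigma2_e = 3)
  tr <- sim_truth(mu = 10, sigma2_G = 4, sigma2_GxT = 2, sigma2_e = 3,
                  trial_means = stats::setNames(1:5, paste0("T", 1:5)),
                  seed = 21)
  rec <- simulate_trial_phenotypes(g, des, tr, "SY")
  est <- ems_oracle_multi(rec)
  for (nm in names(truth)) {
    expect_lt(abs(est[[nm]] - truth[[nm]]) / truth[[nm]], 0.15)
  }
})

test_that("derived-trait identities hold exactly on simulated components", {
  map <- make_map(c(0, 10))
  g <- simulate_dh_genotypes(map, 10, seed = 2)
  des <- trial_design(data.frame(trial = "T1", design = "split_plot",
                                 n_replicates = 2))
  mk <- function(code, mu, seed) {
    simulate_trial_phenotypes(g, des, sim_truth(mu = mu, sigma2_G = 0.2,
                                                sigma2_e = 0.1, seed = seed),
                              code)
  }
  rec <- rbind(mk("SY", 3, 1), mk("TSW", 4.5, 2), mk("O", 45, 3), mk("Pr", 22, 4))
  out <- derive_component_traits(rec)
  key <- c("genotype", "trial", "n_level", "replicate")
  wide <- stats::reshape(out[c(key, "trait", "value")], idvar = key,
                         timevar = "trait", direction = "wide")
  expect_equal(wide$value.SN, wide$value.SY * 1e5 / wide$value.TSW)
  expect_equal(wide$value.OPr, wide$value.O / wide$value.Pr)
})
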