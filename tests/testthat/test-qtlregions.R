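sig_panel <- function(seed, n = 250, causal = "LG1_M0023") {
  map <- simulate_genetic_map(2, 100, 45, seed = seed)
  g <- simulate_panel_genotypes(map, n, n_founders = 8, admixture_alpha = 2,
                                seed = seed + 50)
  K <- ibs_kinship(g)
  set.seed(seed + 99)
  x <- g$calls[, causal] - 1
  y <- stats::setNames(0.8 * x + rnorm(n), rownames(g$calls))
  list(g = g, res = mlm_scan(g, y, K))
}

test_that("interval builder: singleton, split and merged clusters", {
  # one causal locus with LD proxies: a single interval whose peak is the
  # smallest q among the cluster members, CI covering the cluster
  sp <- sig_panel(1)
  qi <- suppressWarnings(build_gwas_qtl_intervals(sp$res, sp$g, trait = "SY"))
  on_lg1 <- qi[qi$linkage_group == "LG1", ]
  sig <- sp$res[sp$res$fdr_q < 0.15 & sp$res$linkage_group == "LG1", ]
  expect_gte(nrow(on_lg1), 1)
  main <- on_lg1[which.min(on_lg1$peak_stat), ]
  expect_equal(main$peak_marker,
               sig$marker[order(sig$fdr_q, -abs(sig$beta), sig$position_cM)][1])
  expect_true(main$ci_lo_cM <= main$peak_cM && main$peak_cM <= main$ci_hi_cM)

  # two unlinked causal loci on different groups give separate intervals
  map <- simulate_genetic_map(2, 100, 45, seed = 7)
  g <- simulate_panel_genotypes(map, 250, n_founders = 8, admixture_alpha = 2,
                                seed = 57)
  K <- ibs_kinship(g)
  set.seed(11)
  x1 <- g$calls[, "LG1_M0010"] - 1
  x2 <- g$calls[, "LG2_M0035"] - 1
  y <- stats::setNames(0.8 * x1 + 0.8 * x2 + rnorm(250), rownames(g$calls))
  qi2 <- suppressWarnings(
    build_gwas_qtl_intervals(mlm_scan(g, y, K), g, trait = "SY"))
  expect_setequal(unique(qi2$linkage_group), c("LG1", "LG2"))
})

test_that("interval clustering matches a transitive-closure oracle", {
  for (s in 1:20) {
    sp <- sig_panel(100 + s)
    res <- sp$res
    g <- sp$g
    qi <- suppressWarnings(build_gwas_qtl_intervals(res, g, trait = "SY"))
    sig <- res[res$fdr_q < 0.15, , drop = FALSE]
    if (nrow(sig) == 0) {
      expect_equal(nrow(qi), 0)
      next
    }
    # oracle: single linkage on (r2 >= 0.2 | gap <= LG extent), per LG
    total <- 0
    for (lg in unique(sig$linkage_group)) {
      ss <- sig[sig$linkage_group == lg, ]
      ss <- ss[order(ss$position_cM), ]
      lg_pairs <- pairwise_r2(g, max_dist_cM = Inf)
      lg_pairs <- lg_pairs[lg_pairs$linkage_group == lg, ]
      ext <- tryCatch(fit_ld_decay(lg_pairs)$extent_cM_at_r2[["0.2"]],
                      error = function(e) 1)
      k <- nrow(ss)
      comp <- seq_len(k)
      if (k > 1) {
        r2m <- suppressWarnings(
          stats::cor(g$calls[, ss$marker, drop = FALSE],
                     use = "pairwise.complete.obs")^2)
        changed <- TRUE
        while (changed) {
          changed <- FALSE
          for (i in seq_len(k - 1)) for (j in (i + 1):k) {
            linked <- (is.finite(r2m[i, j]) && r2m[i, j] >= 0.2) ||
              abs(ss$position_cM[j] - ss$position_cM[i]) <= ext
            if (linked && comp[i] != comp[j]) {
              comp[comp == comp[j]] <- comp[i]
              changed <- TRUE
            }
          }
        }
      }
      total <- total + length(unique(comp))
    }
    expect_equal(nrow(qi), total)
  }
})

test_that("mutually linked significant SNPs collapse to one interval", {
  sp <- sig_panel(31)
  res <- sp$res
  sig <- res[res$fdr_q < 0.15, ]
  r2m <- suppressWarnings(
    stats::cor(sp$g$calls[, sig$marker, drop = FALSE])^2)
  if (nrow(sig) >= 2 && all(r2m >= 0.2)) {
    qi <- suppressWarnings(build_gwas_qtl_intervals(res, sp$g, trait = "SY"))
    expect_equal(nrow(qi), 1)
  } else succeed("panel did not produce a fully linked significant set")
})

test_that("noise-free trait maps exactly onto its marker", {
  map <- make_map(seq(0, 60, 5))
  g <- simulate_dh_genotypes(map, 120, seed = 2)
  x <- g$calls[, "LG1_m07"] - 1  # marker at 30 cM
  y <- stats::setNames(5 + 0.7 * x, rownames(g$calls))
  q <- dh_interval_mapping(g, y, n_permutations = 100, seed = 1)
  expect_equal(q$peak_cM[1], 30)
  expect_equal(q$effect[1], 0.7, tolerance = 1e-8)
  cls <- tapply(y, g$calls[, "LG1_m07"], mean)
  expect_equal(q$effect[1], unname(diff(cls)) / 2, tolerance = 1e-8)
  expect_equal(q$favorable[1], "P2")
})

test_that("linkage scan finds a 30 %-variance QTL and respects the null", {
  found <- 0
  for (s in 1:10) {
    map <- simulate_genetic_map(3, 100, 21, seed = 3)
    g <- simulate_dh_genotypes(map, 150, seed = s + 10)
    set.seed(s + 400)
    x <- g$calls[, "LG2_M0011"] - 1  # 50 cM
    b <- sqrt(0.3 / 0.7 / stats::var(x))
    y <- stats::setNames(b * x + rnorm(150), rownames(g$calls))
    q <- dh_interval_mapping(g, y, n_permutations = 200, seed = s)
    hit <- any(q$linkage_group == "LG2" & q$ci_lo_cM <= 50 & q$ci_hi_cM >= 50)
    found <- found + hit
  }
  expect_gte(found, 9)

  null_hits <- 0
  for (s in 1:10) {
    map <- simulate_genetic_map(3, 100, 21, seed = 3)
    g <- simulate_dh_genotypes(map, 150, seed = s + 30)
    set.seed(s + 600)
    y <- stats::setNames(rnorm(150), rownames(g$calls))
    q <- dh_interval_mapping(g, y, n_permutations = 200, seed = s)
    null_hits <- null_hits + (nrow(q) > 0)
  }
  expect_lte(null_hits / 10, 0.05 + 0.15)  # genome-wide level plus slack
})

test_that("DH mapping refuses heterozygous populations", {
  map <- make_map(c(0, 10))
  calls <- matrix(c(0, 1, 2, 0), 2)
  g <- make_gm(calls, map, "dh")
  y <- stats::setNames(c(1, 2), rownames(calls))
  expect_error(dh_interval_mapping(g, y), "homozygous")
})

test_that("QTL projection interpolates between shared anchors", {
  src <- make_map(c(0, 10, 20, 40), "LG1")
  tgt <- make_map(c(5, 30, 50, 90), "LG1")
  tgt$marker <- src$marker  # same markers, different positions
  qtls <- random_intervals(1, "LG1", "multi_env", seed = 1)
  qtls$peak_cM <- 15; qtls$ci_lo_cM <- 10; qtls$ci_hi_cM <- 20
  pr <- project_qtl(stabQTL:::new_qtl_intervals(qtls), src, tgt)
  expect_true(pr$projected)
  expect_equal(pr$ci_lo_cM, 30)   # anchor identity
  expect_equal(pr$peak_cM, 40)    # midway 10-20 -> midway 30-50
  expect_equal(pr$ci_hi_cM, 50)
  expect_true(pr$ci_lo_cM <= pr$peak_cM && pr$peak_cM <= pr$ci_hi_cM)

  # positions outside the shared anchor span are flagged
  out <- qtls
  out$peak_cM <- 2; out$ci_lo_cM <- 1; out$ci_hi_cM <- 3
  src2 <- make_map(c(10, 20, 40), "LG1")
  tgt2 <- make_map(c(30, 50, 90), "LG1")
  tgt2$marker <- src2$marker
  pr2 <- project_qtl(stabQTL:::new_qtl_intervals(out), src2, tgt2)
  expect_false(pr2$projected)
  expect_true(is.na(pr2$peak_cM))
})

test_that("locus stability classes follow the overlap rules", {
  add <- random_intervals(1, "LG1", "multi_env", seed = 1)
  add$ci_lo_cM <- 10; add$ci_hi_cM <- 20; add$peak_cM <- 15
  gxn <- random_intervals(1, "LG1", "ecov_GxN", seed = 2)
  gxn$ci_lo_cM <- 15; gxn$ci_hi_cM <- 25; gxn$peak_cM <- 18
  gxt <- random_intervals(1, "LG1", "ecov_GxT", seed = 3)
  cl <- classify_locus_stability(add, gxn, gxt[0, ])
  expect_equal(cl$class, "additive_N_modulated")

  cl2 <- classify_locus_stability(add, gxn[0, ], gxt[0, ])
  expect_equal(cl2$class, "stable_additive")
})

test_that("classification matches the all-pairs oracle on random sets", {
  for (s in 1:20) {
    add <- random_intervals(4, c("LG1", "LG2"), "multi_env", seed = s)
    gxn <- random_intervals(4, c("LG1", "LG2"), "ecov_GxN", seed = s + 70)
    gxt <- random_intervals(4, c("LG1", "LG2"), "ecov_GxT", seed = s + 140)
    cl <- classify_locus_stability(add, gxn, gxt)
    add_rows <- cl[seq_len(nrow(add)), ]
    expect_equal(add_rows$class, classify_oracle(add, gxn, gxt))
    # partition: every interaction QTL in exactly one locus
    members <- unlist(strsplit(cl$member_ids, ","))
    expect_setequal(members, c(add$qtl_id, gxn$qtl_id, gxt$qtl_id))
    expect_equal(anyDuplicated(members), 0)
    expect_equal(sum(cl$class %in% c("stable_additive", "additive_N_modulated",
                                     "additive_T_modulated",
                                     "additive_N_and_T_modulated")),
                 nrow(add))
  }
})

test_that("homoeologous gene pairs are counted inside physical intervals", {
  qtls <- rbind(random_intervals(1, "A1", "multi_env", seed = 1),
                random_intervals(1, "C1", "multi_env", seed = 2),
                random_intervals(1, "A2", "multi_env", seed = 3))
  qtls$ci_lo_bp <- c(100, 1000, 5000)
  qtls$ci_hi_bp <- c(500, 2000, 6000)
  qtls$linkage_group <- c("A1", "C1", "A2")
  genes <- data.frame(
    gene_id = c("a1", "a2", "a3", "c1", "c2", "c3", "zz"),
    chromosome = c("A1", "A1", "A1", "C1", "C1", "C1", "Ann"),
    start_bp = c(110, 200, 300, 1100, 1200, 1500, 1),
    end_bp = c(150, 240, 350, 1150, 1290, 1600, 10))
  pairs <- data.frame(gene_A = c("a1", "a2", "a3", "a1", "a2", "a3"),
                      gene_C = c("c1", "c2", "c9", "c9", "c8", "c7"))
  rep_ <- homoeologous_region_pairs(stabQTL:::new_qtl_intervals(qtls),
                                    genes, pairs)
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$n_homoeologous_gene_pairs, 2)  # (a1,c1), (a2,c2)

  empty <- homoeologous_region_pairs(stabQTL:::new_qtl_intervals(qtls), genes,
                                     pairs[0, ])
  expect_equal(nrow(empty), 0)
})
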