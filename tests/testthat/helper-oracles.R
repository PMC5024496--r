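# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (explicit loops and closed forms only).

make_map <- function(pos, lg = "LG1", bp_per_cM = 1e5) {
  map <- data.frame(marker = sprintf("%s_m%02d", lg, seq_along(pos)),
                    linkage_group = lg, position_cM = pos, chromosome = lg,
                    position_bp = as.integer(round(pos * bp_per_cM)) +
                      seq_along(pos),
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

make_gm <- function(calls, map, kind = "panel") {
  rownames(calls) <- sprintf("G%03d", seq_len(nrow(calls)))
  stabQTL:::new_genotype_matrix(calls, map, kind)
}

# Wricke ecovalence straight from its definition, cell by cell
ecovalence_oracle <- function(Y) {
  gm <- mean(Y)
  W <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      W[i] <- W[i] + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + gm)^2
    }
  }
  W
}

# Pairwise IBS sharing by explicit enumeration
ibs_oracle <- function(calls) {
  n <- nrow(calls)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sc <- c()
      for (m in seq_len(ncol(calls))) {
        a <- calls[i, m]; b <- calls[j, m]
        if (is.na(a) || is.na(b)) next
        sc <- c(sc, if (a == b) 1 else if (abs(a - b) == 1) 0.5 else 0)
      }
      K[i, j] <- if (length(sc)) mean(sc) else NA
    }
  }
  diag(K) <- 1
  K
}

# Benjamini-Hochberg step-up computed by its textbook definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive grid search for the Sved curve (step 1 on Ne)
sved_grid_oracle <- function(dist_cM, r2, grid = 10:5000) {
  c_m <- dist_cM / 100
  sse <- vapply(grid, function(ne) sum((r2 - 1 / (1 + 4 * ne * c_m))^2), 0)
  grid[which.min(sse)]
}

# Balanced-design variance components for the multi-environment model from
# explicit group means (expected mean squares solved by hand)
ems_oracle_multi <- function(rec) {
  rec <- rec[!is.na(rec$value), ]
  g <- length(unique(rec$genotype)); n <- length(unique(rec$n_level))
  t <- length(unique(rec$trial)); r <- length(unique(rec$replicate))
  y <- rec$value
  gmean <- mean(y)
  m_i <- tapply(y, rec$genotype, mean)
  m_j <- tapply(y, rec$n_level, mean)
  m_l <- tapply(y, rec$trial, mean)
  m_ij <- tapply(y, list(rec$genotype, rec$n_level), mean)
  m_il <- tapply(y, list(rec$genotype, rec$trial), mean)
  m_jl <- tapply(y, list(rec$n_level, rec$trial), mean)
  m_ijl <- tapply(y, list(rec$genotype, rec$n_level, rec$trial), mean)
  m_lk <- tapply(y, list(rec$trial, rec$replicate), mean)
  ss_g <- n * t * r * sum((m_i - gmean)^2)
  ss_n <- g * t * r * sum((m_j - gmean)^2)
  ss_t <- g * n * r * sum((m_l - gmean)^2)
  ss_tr <- g * n * sum(sweep(m_lk, 1, m_l)^2)
  ss_gn <- t * r * sum((sweep(sweep(m_ij, 1, m_i), 2, m_j) + gmean)^2)
  ss_gt <- n * r * sum((sweep(sweep(m_il, 1, m_i), 2, m_l) + gmean)^2)
  # the model carries no N x T term, so everything left among cell means
  # beyond the fitted margins belongs to the three-way stratum
  ss_cells <- r * sum((m_ijl - gmean)^2)
  ss_gnt <- ss_cells - ss_g - ss_n - ss_t - ss_gn - ss_gt
  df_gnt <- (g * n * t - 1) - (g - 1) - (n - 1) - (t - 1) -
    (g - 1) * (n - 1) - (g - 1) * (t - 1)
  ss_tot <- sum((y - gmean)^2)
  ss_e <- ss_tot - ss_cells - ss_tr
  df_e <- g * n * t * (r - 1) - t * (r - 1)
  ms <- c(G = ss_g / (g - 1), GN = ss_gn / ((g - 1) * (n - 1)),
          GT = ss_gt / ((g - 1) * (t - 1)), GNT = ss_gnt / df_gnt,
          E = ss_e / df_e)
  s_e <- ms[["E"]]
  s_gnt <- (ms[["GNT"]] - s_e) / r
  s_gt <- (ms[["GT"]] - ms[["GNT"]]) / (r * n)
  s_gn <- (ms[["GN"]] - ms[["GNT"]]) / (r * t)
  s_g <- (ms[["G"]] - ms[["GT"]] - ms[["GN"]] + ms[["GNT"]]) / (r * n * t)
  c(sigma2_G = s_g, sigma2_GxN = s_gn, sigma2_GxT = s_gt,
    sigma2_GxNxT = s_gnt, sigma2_e = s_e)
}

# Adjusted Rand index from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# All-pairs interval-overlap oracle for locus classification
classify_oracle <- function(add, gxn, gxt) {
  ov <- function(a, b) a$linkage_group == b$linkage_group &&
    a$ci_lo_cM <= b$ci_hi_cM && b$ci_lo_cM <= a$ci_hi_cM
  cls <- character(nrow(add))
  for (i in seq_len(nrow(add))) {
    hn <- any(vapply(seq_len(nrow(gxn)),
                     function(j) ov(add[i, ], gxn[j, ]), TRUE))
    ht <- any(vapply(seq_len(nrow(gxt)),
                     function(j) ov(add[i, ], gxt[j, ]), TRUE))
    cls[i] <- if (hn && ht) "additive_N_and_T_modulated"
      else if (hn) "additive_N_modulated"
      else if (ht) "additive_T_modulated"
      else "stable_additive"
  }
  cls
}

random_intervals <- function(n, lgs = c("LG1", "LG2"), tag, seed) {
  set.seed(seed)
  lo <- runif(n, 0, 80)
  data.frame(qtl_id = sprintf("%s_%02d", tag, seq_len(n)),
             trait = "SY", dataset_tag = tag,
             linkage_group = sample(lgs, n, replace = TRUE),
             peak_marker = NA, peak_cM = lo + 2, peak_bp = NA,
             ci_lo_cM = lo, ci_hi_cM = lo + runif(n, 1, 12),
             ci_lo_bp = NA, ci_hi_bp = NA, peak_stat = runif(n),
             stat_type = "fdr_q", favorable = "alt", effect = rnorm(n),
             method = "gwas", stringsAsFactors = FALSE)
}

scenario_config <- function(seed) {
  pipeline_config(traits = "SY",
                  dataset_tags = c("multi_env", "ecov_GxN", "ecov_GxT"),
                  seed = seed)
}
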