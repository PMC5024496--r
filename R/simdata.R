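#' Simulate a genetic map
#'
#' Builds a marker map on one or more linkage groups. When 19 linkage groups
#' are requested they are named after the Brassica napus A and C subgenomes
#' (A1--A10, C1--C9); otherwise LG1, LG2, ... Physical positions are derived
#' from the genetic positions at a constant rate, made strictly increasing
#' within each chromosome.
#'
#' @param n_linkage_groups Number of linkage groups (>= 1).
#' @param length_cM Length of each group in centimorgans; recycled.
#' @param markers_per_group Markers per group (>= 2); recycled.
#' @param bp_per_cM Physical distance per centimorgan (default 1e5 bp/cM,
#'   a typical plant genome-wide average).
#' @param spacing "uniform" places markers on a regular grid including both
#'   ends; "random" draws positions uniformly and sorts them (ends pinned).
#' @param seed Integer seed; identical inputs and seed give identical maps.
#' @return A `genetic_map` data frame with columns `marker`, `linkage_group`,
#'   `position_cM`, `chromosome`, `position_bp`.
#' @export
simulate_genetic_map <- function(n_linkage_groups, length_cM, markers_per_group,
                                 bp_per_cM = 1e5, spacing = c("uniform", "random"),
                                 seed = 1L) {
  spacing <- match.arg(spacing)
  if (n_linkage_groups < 1) stop("n_linkage_groups must be >= 1")
  length_cM <- rep_len(length_cM, n_linkage_groups)
  markers_per_group <- rep_len(as.integer(markers_per_group), n_linkage_groups)
  if (any(length_cM <= 0)) stop("linkage group lengths must be positive")
  if (any(markers_per_group < 2)) stop("markers_per_group must be >= 2")
  if (bp_per_cM <= 0) stop("bp_per_cM must be positive")
  set.seed(seed)

  lg_names <- if (n_linkage_groups == 19L) {
    c(paste0("A", 1:10), paste0("C", 1:9))
  } else {
    paste0("LG", seq_len(n_linkage_groups))
  }

  entries <- lapply(seq_len(n_linkage_groups), function(g) {
    m <- markers_per_group[g]
    L <- length_cM[g]
    pos <- if (spacing == "uniform") {
      seq(0, L, length.out = m)
    } else {
      c(0, sort(stats::runif(m - 2L, 0, L)), L)
    }
    bp <- round(pos * bp_per_cM)
    # enforce strictly increasing bp despite rounding collisions
    for (i in seq_along(bp)[-1]) if (bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1L
    data.frame(
      marker = sprintf("%s_M%04d", lg_names[g], seq_len(m)),
      linkage_group = lg_names[g],
      position_cM = pos,
      chromosome = lg_names[g],
      position_bp = as.integer(bp),
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, entries)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  validate_genetic_map(map)
  map
}

#' @keywords internal
validate_genetic_map <- function(map) {
  stopifnot(all(c("marker", "linkage_group", "position_cM") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in map")
  if (any(map$position_cM < 0)) stop("negative cM positions")
  for (lg in unique(map$linkage_group)) {
    p <- map$position_cM[map$linkage_group == lg]
    if (is.unsorted(p)) stop("cM positions not non-decreasing within ", lg)
  }
  invisible(map)
}

#' Haldane map function
#'
#' Recombination fraction for a genetic distance under no interference:
#' r = (1 - exp(-2 d / 100)) / 2 with d in centimorgans.
#'
#' @param d_cM Genetic distance in centimorgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Inverse Haldane map function
#' @param r Recombination fraction in [0, 0.5).
#' @return Distance in centimorgans.
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * r)

new_genotype_matrix <- function(calls, map, population_kind) {
  stopifnot(ncol(calls) == nrow(map))
  colnames(calls) <- map$marker
  obj <- list(calls = calls, map = map, population_kind = population_kind)
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d markers (%s), %d linkage group(s)\n",
    nrow(x$calls), ncol(x$calls), x$population_kind,
    length(unique(x$map$linkage_group))
  ))
  invisible(x)
}

#' Simulate doubled-haploid genotypes
#'
#' Each line is a single recombinant gamete doubled, so calls are fully
#' homozygous (0 or 2). Crossovers between adjacent markers occur with the
#' Haldane probability for their cM distance; linkage groups segregate
#' independently; the two parental alleles start at frequency 1/2.
#'
#' @param map A `genetic_map`.
#' @param n_individuals Number of DH lines (>= 1).
#' @param seed Integer seed.
#' @return A `genotype_matrix` with `population_kind = "dh"`.
#' @export
simulate_dh_genotypes <- function(map, n_individuals, seed = 1L) {
  if (nrow(map) == 0) stop("empty genetic map")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  set.seed(seed)
  calls <- matrix(NA_integer_, n_individuals, nrow(map))
  col0 <- 0L
  for (lg in unique(map$linkage_group)) {
    idx <- which(map$linkage_group == lg)
    m <- length(idx)
    r <- haldane_r(diff(map$position_cM[idx]))
    hap <- matrix(0L, n_individuals, m)
    hap[, 1] <- as.integer(stats::runif(n_individuals) < 0.5)
    if (m > 1) {
      sw <- matrix(stats::runif(n_individuals * (m - 1L)), n_individuals) <
        matrix(r, n_individuals, m - 1L, byrow = TRUE)
      # parity of crossovers determines the parental phase at each marker
      flips <- t(apply(sw, 1L, cumsum)) %% 2L
      hap[, -1] <- (hap[, 1] + flips) %% 2L
    }
    calls[, idx] <- 2L * hap
    col0 <- col0 + m
  }
  rownames(calls) <- sprintf("G%03d", seq_len(n_individuals))
  new_genotype_matrix(calls, map, "dh")
}

#' Simulate diversity-panel genotypes by a founder-mosaic model
#'
#' Founder haplotypes carry independent per-marker alleles at uniform random
#' frequencies; each individual's haplotypes are mosaics of founders with
#' block structure along the map, which induces kinship structure and LD
#' decaying with genetic distance. This is a pragmatic stand-in for the LD
#' structure of a real diversity panel, not a coalescent model.
#'
#' @param map A `genetic_map`.
#' @param n_individuals Panel size.
#' @param n_founders Number of founder haplotypes (>= 2).
#' @param admixture_alpha Expected founder switches per morgan along a
#'   haplotype (0 = intact founder haplotypes).
#' @param inbred If `TRUE` a single haplotype is doubled (calls 0/2),
#'   matching highly inbred accessions; otherwise calls are 0/1/2.
#' @param seed Integer seed.
#' @return A `genotype_matrix` with `population_kind = "panel"`.
#' @export
simulate_panel_genotypes <- function(map, n_individuals, n_founders = 8L,
                                     admixture_alpha = 2, inbred = FALSE,
                                     seed = 1L) {
  if (nrow(map) == 0) stop("empty genetic map")
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (admixture_alpha < 0) stop("admixture_alpha must be >= 0")
  set.seed(seed)
  m <- nrow(map)
  freq <- stats::runif(m, 0.1, 0.9)
  founders <- matrix(as.integer(stats::runif(n_founders * m) <
                                  rep(freq, each = n_founders)),
                     n_founders, m)
  draw_hap <- function() {
    hap <- integer(m)
    for (lg in unique(map$linkage_group)) {
      idx <- which(map$linkage_group == lg)
      p_switch <- 1 - exp(-admixture_alpha * diff(map$position_cM[idx]) / 100)
      f <- sample.int(n_founders, 1L)
      hap[idx[1]] <- founders[f, idx[1]]
      if (length(idx) > 1) {
        for (j in seq_along(p_switch)) {
          if (stats::runif(1) < p_switch[j]) f <- sample.int(n_founders, 1L)
          hap[idx[j + 1L]] <- founders[f, idx[j + 1L]]
        }
      }
    }
    hap
  }
  calls <- matrix(0L, n_individuals, m)
  for (i in seq_len(n_individuals)) {
    calls[i, ] <- if (inbred) 2L * draw_hap() else draw_hap() + draw_hap()
  }
  rownames(calls) <- sprintf("G%03d", seq_len(n_individuals))
  new_genotype_matrix(calls, map, "panel")
}

#' Describe a set of trials
#'
#' @param trials Data frame with columns `trial` (id), `design`
#'   ("split_plot" or "alpha_plan"), `n_replicates` (>= 1) and, for
#'   alpha-plan trials, `n_blocks_per_replicate`.
#' @param nni Data frame with columns `trial`, `n_level` ("N1"/"N2") and
#'   `nni` (nitrogen nutrition index at bolting, in (0, 1.6)); metadata used
#'   by the stress classifier, not by the generator.
#' @return A `trial_design` object.
#' @export
trial_design <- function(trials, nni = NULL) {
  stopifnot(all(c("trial", "design", "n_replicates") %in% names(trials)))
  if (!all(trials$design %in% c("split_plot", "alpha_plan"))) {
    stop("design must be split_plot or alpha_plan")
  }
  if (any(trials$design == "alpha_plan")) {
    if (!"n_blocks_per_replicate" %in% names(trials) ||
        any(is.na(trials$n_blocks_per_replicate[trials$design == "alpha_plan"]))) {
      stop("alpha_plan trials require n_blocks_per_replicate")
    }
  }
  if (any(trials$n_replicates < 1)) stop("n_replicates must be >= 1")
  if (!is.null(nni)) {
    stopifnot(all(c("trial", "n_level", "nni") %in% names(nni)))
    if (!all(nni$n_level %in% c("N1", "N2"))) stop("N levels must be N1 and N2")
    if (any(nni$nni <= 0 | nni$nni >= 1.6)) stop("NNI must lie in (0, 1.6)")
  }
  obj <- list(trials = trials, nni = nni, n_levels = c("N1", "N2"))
  class(obj) <- "trial_design"
  obj
}

#' Ground truth for a phenotype simulation
#'
#' Collects the generative parameters of the multi-environment model: the
#' population mean, QTL effects (additive, N-interactive, trial-interactive),
#' the variance targets of the random genotype-by-environment terms, trial
#' means and the fixed nitrogen shift.
#'
#' @param mu Population mean (trait units).
#' @param qtl_effects Data frame with columns `marker`, `add` (additive
#'   allelic effect), `gxn` (extra allelic effect expressed under N1) and
#'   optionally one column per trial id holding trial-specific allelic
#'   effects; may be `NULL` for a purely polygenic trait.
#' @param sigma2_G,sigma2_GxN,sigma2_GxT,sigma2_GxNxT,sigma2_e Non-negative
#'   variance targets of the background random terms (trait units squared).
#' @param trial_means Named numeric vector of trial main effects.
#' @param n_level_shift Fixed effect added under N2 (the optimal condition).
#' @param sigma2_rep,sigma2_block Replicate-within-trial and
#'   block-within-replicate variances (alpha-plan designs only use the
#'   latter).
#' @param genetic_cov Optional 2x2 genetic covariance matrix (dimnames =
#'   trait codes) for bivariate runs.
#' @param seed Integer seed used when phenotypes are generated.
#' @return A `sim_truth` object.
#' @export
sim_truth <- function(mu, qtl_effects = NULL, sigma2_G = 0, sigma2_GxN = 0,
                      sigma2_GxT = 0, sigma2_GxNxT = 0, sigma2_e = 0,
                      trial_means = NULL, n_level_shift = 0,
                      sigma2_rep = 0, sigma2_block = 0,
                      genetic_cov = NULL, seed = 1L) {
  v <- c(sigma2_G, sigma2_GxN, sigma2_GxT, sigma2_GxNxT, sigma2_e,
         sigma2_rep, sigma2_block)
  if (any(v < 0)) stop("variance targets must be non-negative")
  obj <- list(
    mu = mu, qtl_effects = qtl_effects,
    sigma2_G = sigma2_G, sigma2_GxN = sigma2_GxN, sigma2_GxT = sigma2_GxT,
    sigma2_GxNxT = sigma2_GxNxT, sigma2_e = sigma2_e,
    sigma2_rep = sigma2_rep, sigma2_block = sigma2_block,
    trial_means = trial_means, n_level_shift = n_level_shift,
    genetic_cov = genetic_cov, seed = as.integer(seed)
  )
  class(obj) <- "sim_truth"
  obj
}

#' Simulate plot-level phenotypes for a multi-environment trial series
#'
#' Generates one record per genotype x trial x N level x replicate following
#' the multi-environment decomposition: population mean, QTL and polygenic
#' genotype effects, fixed N shift, trial means, replicate-within-trial
#' effects, genotype-by-N, genotype-by-trial and genotype-by-N-by-trial
#' deviations, and residual noise. Background deviations are drawn i.i.d.
#' normal with the target variances; QTL-driven effects add on top of them
#' and contribute to the same components. Allele dosage is centred
#' (calls - 1) so additive effects are per-allele additivities.
#'
#' @param genotypes A `genotype_matrix`.
#' @param design A `trial_design`.
#' @param truth A `sim_truth`.
#' @param trait_code Trait code, one of DTF, SY, TSW, SN, O, Pr, OPr.
#' @param missing_fraction Fraction of records masked at random (default 0).
#' @return A `phenotype_records` data frame with columns `genotype`, `trial`,
#'   `n_level`, `replicate`, `block`, `trait`, `value`.
#' @export
simulate_trial_phenotypes <- function(genotypes, design, truth,
                                      trait_code = "SY",
                                      missing_fraction = 0) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(design, "trial_design"), inherits(truth, "sim_truth"))
  if (!is.null(truth$qtl_effects)) {
    missing_q <- setdiff(truth$qtl_effects$marker, colnames(genotypes$calls))
    if (length(missing_q)) {
      stop("QTL marker(s) absent from genotypes: ",
           paste(missing_q, collapse = ", "))
    }
  }
  set.seed(truth$seed)
  ids <- rownames(genotypes$calls)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(nrow(genotypes$calls)))
  n_g <- length(ids)
  trials <- design$trials$trial
  n_t <- length(trials)
  n_levels <- design$n_levels

  trial_means <- truth$trial_means
  if (is.null(trial_means)) trial_means <- stats::setNames(rep(0, n_t), trials)

  # genotype-level effect pieces
  poly <- stats::rnorm(n_g, 0, sqrt(truth$sigma2_G))
  gxn_dev <- matrix(stats::rnorm(n_g * 2, 0, sqrt(truth$sigma2_GxN)), n_g, 2,
                    dimnames = list(ids, n_levels))
  gxt_dev <- matrix(stats::rnorm(n_g * n_t, 0, sqrt(truth$sigma2_GxT)), n_g, n_t,
                    dimnames = list(ids, trials))
  gxnxt_dev <- array(stats::rnorm(n_g * 2 * n_t, 0, sqrt(truth$sigma2_GxNxT)),
                     c(n_g, 2, n_t), dimnames = list(ids, n_levels, trials))

  qtl_add <- rep(0, n_g)
  qtl_gxn <- rep(0, n_g)
  qtl_gxt <- matrix(0, n_g, n_t, dimnames = list(ids, trials))
  if (!is.null(truth$qtl_effects)) {
    qe <- truth$qtl_effects
    x <- genotypes$calls[, qe$marker, drop = FALSE] - 1  # centred dosage
    if ("add" %in% names(qe)) qtl_add <- drop(x %*% ifelse(is.na(qe$add), 0, qe$add))
    if ("gxn" %in% names(qe)) qtl_gxn <- drop(x %*% ifelse(is.na(qe$gxn), 0, qe$gxn))
    for (tr in intersect(trials, names(qe))) {
      qtl_gxt[, tr] <- qtl_gxt[, tr] + drop(x %*% ifelse(is.na(qe[[tr]]), 0, qe[[tr]]))
    }
  }

  rows <- vector("list", n_t)
  for (ti in seq_len(n_t)) {
    tr <- trials[ti]
    r <- design$trials$n_replicates[ti]
    alpha <- design$trials$design[ti] == "alpha_plan"
    nb <- if (alpha) design$trials$n_blocks_per_replicate[ti] else NA_integer_
    rep_eff <- stats::rnorm(r, 0, sqrt(truth$sigma2_rep))
    grid <- expand.grid(genotype = ids, n_level = n_levels,
                        replicate = seq_len(r), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    gi <- match(grid$genotype, ids)
    ni <- match(grid$n_level, n_levels)
    block <- rep(NA_integer_, nrow(grid))
    blk_eff <- 0
    if (alpha) {
      # genotypes allocated to incomplete blocks, same layout across N levels
      block <- ((gi - 1L) %% nb) + 1L
      beff <- matrix(stats::rnorm(r * nb, 0, sqrt(truth$sigma2_block)), r, nb)
      blk_eff <- beff[cbind(grid$replicate, block)]
    }
    val <- truth$mu +
      poly[gi] + qtl_add[gi] +
      ifelse(grid$n_level == "N2", truth$n_level_shift, 0) +
      trial_means[[tr]] +
      rep_eff[grid$replicate] +
      gxn_dev[cbind(gi, ni)] +
      ifelse(grid$n_level == "N1", qtl_gxn[gi], 0) +
      gxt_dev[gi, ti] + qtl_gxt[gi, ti] +
      gxnxt_dev[cbind(gi, ni, ti)] +
      blk_eff +
      stats::rnorm(nrow(grid), 0, sqrt(truth$sigma2_e))
    rows[[ti]] <- data.frame(genotype = grid$genotype, trial = tr,
                             n_level = grid$n_level, replicate = grid$replicate,
                             block = block, trait = trait_code, value = val,
                             stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  if (missing_fraction > 0) {
    mask <- stats::runif(nrow(rec)) < missing_fraction
    rec$value[mask] <- NA_real_
  }
  rownames(rec) <- NULL
  class(rec) <- c("phenotype_records", "data.frame")
  rec
}

#' Simulate two genetically correlated traits
#'
#' Draws the polygenic genotype effects of two traits from a bivariate
#' normal with the requested genetic correlation; all other components are
#' independent between traits. Used to study genetic-correlation recovery.
#'
#' @param genotypes A `genotype_matrix`.
#' @param design A `trial_design`.
#' @param truth_x,truth_y `sim_truth` objects for the two traits (their
#'   `sigma2_G` set the marginal genetic variances; `truth_x$seed` drives all
#'   randomness).
#' @param r_g Genetic correlation in [-1, 1].
#' @param trait_codes Character vector of length 2.
#' @return A `phenotype_records` data frame holding both traits.
#' @export
simulate_correlated_traits <- function(genotypes, design, truth_x, truth_y,
                                       r_g, trait_codes = c("O", "Pr")) {
  stopifnot(abs(r_g) <= 1)
  set.seed(truth_x$seed)
  n_g <- nrow(genotypes$calls)
  z <- matrix(stats::rnorm(2 * n_g), n_g, 2)
  cv <- r_g * sqrt(truth_x$sigma2_G * truth_y$sigma2_G)
  S <- matrix(c(truth_x$sigma2_G, cv, cv, truth_y$sigma2_G), 2, 2)
  L <- chol(S + diag(1e-12, 2))
  gg <- z %*% L
  seeds <- sample.int(.Machine$integer.max, 2L)
  tx <- truth_x; tx$sigma2_G <- 0; tx$seed <- seeds[1]
  ty <- truth_y; ty$sigma2_G <- 0; ty$seed <- seeds[2]
  rx <- simulate_trial_phenotypes(genotypes, design, tx, trait_codes[1])
  ry <- simulate_trial_phenotypes(genotypes, design, ty, trait_codes[2])
  ids <- unique(rx$genotype)
  rx$value <- rx$value + gg[match(rx$genotype, ids), 1]
  ry$value <- ry$value + gg[match(ry$genotype, ids), 2]
  out <- rbind(rx, ry)
  class(out) <- c("phenotype_records", "data.frame")
  out
}

#' Reference simulation: one stable and two interaction-specific QTL
#'
#' Builds the standard known-truth scenario used to exercise the pipeline
#' end to end: an inbred diversity panel on five linkage groups carrying
#' (i) a purely additive QTL, (ii) a crossover N-interactive QTL whose
#' allelic effect has opposite signs under the two N conditions (zero
#' marginal effect), and (iii) a crossover trial-interactive QTL with
#' trial-specific effects summing to zero. QTL markers are chosen at
#' intermediate but asymmetric allele frequencies (MAF 0.15--0.35 where
#' available), where the squared-deviation signature that makes ecovalence
#' mappable is strongest. Effect sizes are fixed so each QTL explains a
#' substantial share (roughly 15--40 %) of the variance of its own mapping
#' dataset against a polygenic background.
#'
#' @param seed Integer seed driving map, genotypes and phenotypes.
#' @param n_genotypes Panel size (default 200).
#' @param n_trials Number of trials (default 5; two N conditions, two
#'   replicates each).
#' @return A list: `genotypes`, `records`, `design`, `truth` (the
#'   `sim_truth` used) and `truth_loci` (marker, linkage group, cM and the
#'   expected stability class of each simulated QTL).
#' @export
simulate_stability_scenario <- function(seed = 1L, n_genotypes = 200L,
                                        n_trials = 5L) {
  map <- simulate_genetic_map(5, 90, 45, seed = seed)
  g <- simulate_panel_genotypes(map, n_genotypes, n_founders = 8,
                                admixture_alpha = 2, inbred = TRUE,
                                seed = seed + 1000L)
  pick <- function(lg) {
    mk <- g$map$marker[g$map$linkage_group == lg]
    p <- colMeans(g$calls[, mk]) / 2
    maf <- pmin(p, 1 - p)
    pos <- g$map$position_cM[match(mk, g$map$marker)]
    cand <- mk[maf >= 0.15 & maf <= 0.35]
    if (!length(cand)) cand <- mk
    cand[which.min(abs(pos[match(cand, mk)] - 45))]
  }
  qA <- pick("LG1"); qN <- pick("LG2"); qT <- pick("LG3")
  trials <- paste0("T", seq_len(n_trials))
  qe <- data.frame(marker = c(qA, qN, qT), add = c(0.6, -0.4, 0),
                   gxn = c(0, 0.8, 0), stringsAsFactors = FALSE)
  tsign <- rep_len(c(1, -1), n_trials)
  tsign <- tsign - mean(tsign)  # trial effects sum to zero
  for (i in seq_len(n_trials)) qe[[trials[i]]] <- c(0, 0, 0.5 * tsign[i])
  design <- trial_design(data.frame(trial = trials, design = "split_plot",
                                    n_replicates = 2))
  truth <- sim_truth(
    mu = 10, qtl_effects = qe, sigma2_G = 0.4, sigma2_GxN = 0.05,
    sigma2_GxT = 0.05, sigma2_GxNxT = 0.02, sigma2_e = 0.2,
    trial_means = stats::setNames(
      rep_len(c(-1, 0, 0.5, 1, -0.5), n_trials), trials),
    n_level_shift = 0.5, seed = seed + 2000L)
  records <- simulate_trial_phenotypes(g, design, truth, "SY")
  truth_loci <- data.frame(
    marker = c(qA, qN, qT), linkage_group = c("LG1", "LG2", "LG3"),
    position_cM = g$map$position_cM[match(c(qA, qN, qT), g$map$marker)],
    class = c("stable_additive", "GxN_specific", "GxT_specific"),
    stringsAsFactors = FALSE)
  list(genotypes = g, records = records, design = design, truth = truth,
       truth_loci = truth_loci)
}
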