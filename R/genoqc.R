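#' Filter markers on minor allele frequency and missingness
#'
#' Keeps markers whose MAF (computed on non-missing calls) is at least
#' `maf_min` and whose missing fraction is at most `missing_max`. The
#' defaults mirror common SNP-array practice: MAF >= 5 %, missingness
#' <= 10 %.
#'
#' @param g A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency in [0, 0.5].
#' @param missing_max Maximum missing-call fraction in [0, 1].
#' @return A filtered `genotype_matrix`; the removal report (marker, maf,
#'   missing fraction, reason) is attached as attribute `"removed"`.
#' @export
filter_markers <- function(g, maf_min = 0.05, missing_max = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1) stop("missing_max must lie in [0, 1]")
  calls <- g$calls
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  miss <- colMeans(is.na(calls))
  keep <- maf >= maf_min & miss <= missing_max
  reason <- rep(NA_character_, ncol(calls))
  reason[maf < maf_min] <- "maf"
  reason[miss > missing_max] <- "missing"
  reason[maf < maf_min & miss > missing_max] <- "maf+missing"
  removed <- data.frame(marker = colnames(calls)[!keep], maf = maf[!keep],
                        missing = miss[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep)) warning("all markers removed by QC filters")
  out <- new_genotype_matrix(calls[, keep, drop = FALSE],
                             {
                               mp <- g$map[keep, , drop = FALSE]
                               rownames(mp) <- NULL
                               class(mp) <- class(g$map)
                               mp
                             },
                             g$population_kind)
  attr(out, "removed") <- removed
  out
}

#' Identity-by-state kinship matrix
#'
#' K[i, j] is the mean allele-sharing score over markers non-missing in both
#' individuals: 1 for identical calls, 0.5 when one allele is shared (calls
#' differing by one dosage unit), 0 for opposite homozygotes.
#'
#' @param g A `genotype_matrix`.
#' @return A symmetric numeric matrix with unit diagonal, dimnames set to
#'   individual ids. Pairs with no shared non-missing marker are `NA` and
#'   listed in attribute `"unscored_pairs"`.
#' @export
ibs_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  if (ncol(calls) < 1) stop("need at least one marker")
  obs <- !is.na(calls)
  x <- calls
  x[!obs] <- 0
  # |xi - xj| summed over shared markers via dosage-class indicators
  a0 <- (x == 0) & obs; a1 <- (x == 1) & obs; a2 <- (x == 2) & obs
  A0 <- matrix(as.numeric(a0), nrow(x)); A1 <- matrix(as.numeric(a1), nrow(x))
  A2 <- matrix(as.numeric(a2), nrow(x))
  one_step <- A0 %*% t(A1) + A1 %*% t(A0) + A1 %*% t(A2) + A2 %*% t(A1)
  two_step <- A0 %*% t(A2) + A2 %*% t(A0)
  shared <- matrix(as.numeric(obs), nrow(x)) %*% t(matrix(as.numeric(obs), nrow(x)))
  K <- 1 - (0.5 * one_step + 1 * two_step) / shared
  K[shared == 0] <- NA_real_
  diag(K) <- 1
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(nrow(calls)))
  dimnames(K) <- list(ids, ids)
  bad <- which(is.na(K) & upper.tri(K), arr.ind = TRUE)
  attr(K, "unscored_pairs") <- if (nrow(bad)) {
    data.frame(id_a = ids[bad[, 1]], id_b = ids[bad[, 2]])
  } else NULL
  K
}

#' Pairwise linkage disequilibrium (r-squared) within linkage groups
#'
#' r-squared is the squared Pearson correlation of allele dosages across
#' individuals with pairwise-complete calls (composite LD, valid for both
#' homozygous and heterozygous coding). Only pairs on the same linkage group
#' and within `max_dist_cM` are returned.
#'
#' @param g A `genotype_matrix`.
#' @param map A `genetic_map` covering the markers of `g` (defaults to the
#'   map carried by `g`).
#' @param max_dist_cM Maximum pair distance in centimorgans (default `Inf`).
#' @return Data frame (marker_a, marker_b, linkage_group, dist_cM, dist_bp,
#'   r2). Pairs involving a zero-variance marker are skipped; their count is
#'   attached as attribute `"n_skipped"`.
#' @export
pairwise_r2 <- function(g, map = g$map, max_dist_cM = Inf) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- map[match(colnames(g$calls), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("markers missing from map")
  out <- list()
  n_skipped <- 0L
  for (lg in unique(map$linkage_group)) {
    idx <- which(map$linkage_group == lg)
    if (length(idx) < 2) next
    x <- g$calls[, idx, drop = FALSE]
    suppressWarnings(cc <- stats::cor(x, use = "pairwise.complete.obs"))
    pos <- map$position_cM[idx]
    bp <- if ("position_bp" %in% names(map)) map$position_bp[idx] else rep(NA, length(idx))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- abs(pos[pr[, 2]] - pos[pr[, 1]])
    okdist <- d <= max_dist_cM
    pr <- pr[okdist, , drop = FALSE]; d <- d[okdist]
    r2 <- cc[pr]^2
    skip <- is.na(r2)
    n_skipped <- n_skipped + sum(skip)
    out[[lg]] <- data.frame(
      marker_a = colnames(x)[pr[!skip, 1]], marker_b = colnames(x)[pr[!skip, 2]],
      linkage_group = rep(lg, sum(!skip)), dist_cM = d[!skip],
      dist_bp = abs(bp[pr[!skip, 2]] - bp[pr[!skip, 1]]),
      r2 = r2[!skip], stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(marker_a = character(), marker_b = character(),
               linkage_group = character(), dist_cM = numeric(),
               dist_bp = numeric(), r2 = numeric())
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Fit the Sved LD-decay curve and report LD extent
#'
#' Fits E[r2] = 1 / (1 + 4 Ne c), with c the recombination distance in
#' morgans, to observed marker-pair r2 values by least squares over Ne
#' (bounded, multi-start; ties broken towards the smallest Ne). The LD
#' extent at a threshold t solves t = 1/(1 + 4 Ne c), i.e. c = (1/t - 1) /
#' (4 Ne), reported in centimorgans.
#'
#' @param pairs Output of [pairwise_r2()] (needs `dist_cM` and `r2`).
#' @param thresholds r2 thresholds at which to report the extent
#'   (default 0.2).
#' @param ne_bounds Search bounds for Ne.
#' @return An `ld_decay_fit` list: `Ne_hat`, `extent_cM_at_r2` (named by
#'   threshold), `n_pairs_used`, `sse`.
#' @export
fit_ld_decay <- function(pairs, thresholds = 0.2, ne_bounds = c(1, 1e6)) {
  ok <- is.finite(pairs$r2) & is.finite(pairs$dist_cM) & pairs$dist_cM > 0
  d_m <- pairs$dist_cM[ok] / 100  # morgans
  r2 <- pairs$r2[ok]
  if (length(r2) < 10) stop("need at least 10 pairs with positive distance")
  sse <- function(log_ne) {
    ne <- exp(log_ne)
    sum((r2 - 1 / (1 + 4 * ne * d_m))^2)
  }
  starts <- log(c(50, 500, 5000))
  fits <- lapply(starts, function(s) {
    stats::optim(s, sse, method = "L-BFGS-B",
                 lower = log(ne_bounds[1]), upper = log(ne_bounds[2]),
                 control = list(factr = 10))
  })
  vals <- vapply(fits, function(f) f$value, 0)
  best <- vals <= min(vals) + 1e-12
  ne_hat <- min(vapply(fits[best], function(f) exp(f$par), 0))
  # polish around the winner for high-precision recovery on clean data
  pol <- stats::optimize(sse, interval = log(c(ne_hat / 1.5, ne_hat * 1.5)),
                         tol = 1e-12)
  if (pol$objective <= sse(log(ne_hat))) ne_hat <- exp(pol$minimum)
  extent <- vapply(thresholds, function(th) 100 * (1 / th - 1) / (4 * ne_hat), 0)
  names(extent) <- as.character(thresholds)
  structure(list(Ne_hat = ne_hat, extent_cM_at_r2 = extent,
                 n_pairs_used = length(r2), sse = sse(log(ne_hat))),
            class = "ld_decay_fit")
}
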