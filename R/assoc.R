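#' Kinship-based single-marker mixed-model association scan
#'
#' Fits y = mu + x beta + u + e with a random polygenic effect
#' u ~ N(0, sigma2_g K) and e ~ N(0, sigma2_e I). The variance ratio is
#' estimated once on the null model by restricted maximum likelihood over
#' the spectral decomposition of K (exact one-dimensional profile
#' likelihood) and, with `p3d = TRUE` (default), reused for every marker;
#' each marker then gets a generalized-least-squares effect estimate and a
#' Wald test on the decorrelated scale. With `p3d = FALSE` the ratio is
#' re-estimated under each marker model.
#'
#' @param g A `genotype_matrix`.
#' @param y Mapping phenotype: a named numeric vector, or a data frame with
#'   a `genotype` column and a `value` (or `W`) column, e.g. the output of
#'   [genotype_estimates()] or [ecovalence()].
#' @param k Kinship matrix with individual ids as dimnames (e.g. from
#'   [ibs_kinship()]).
#' @param p3d Estimate variance components once on the null model and reuse
#'   them across markers.
#' @param min_maf Markers below this MAF are excluded from the scan.
#' @return An `association_result` data frame: marker, linkage_group,
#'   position_cM, position_bp, maf, beta (allele-dosage effect =
#'   additivity), favorable_allele ("ref"/"alt"), p_value, fdr_q, r2_marker.
#'   Skipped markers (monomorphic / below MAF) are listed in attribute
#'   `"skipped"`.
#' @export
mlm_scan <- function(g, y, k, p3d = TRUE, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  yv <- extract_phenotype_vector(y)
  ids <- intersect(rownames(g$calls), names(yv))
  ids <- intersect(ids, rownames(k))
  if (length(ids) < 20) stop("need at least 20 individuals shared by y, g and k")
  yv <- yv[ids]
  calls <- g$calls[ids, , drop = FALSE]
  K <- k[ids, ids]

  if (stats::var(yv) == 0) {
    res <- empty_assoc_result()
    attr(res, "skipped") <- data.frame(marker = colnames(calls),
                                       reason = "constant phenotype")
    return(res)
  }

  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    eg <- eigen((K + t(K)) / 2 + diag(1e-8, nrow(K)), symmetric = TRUE)
    if (min(eg$values) < -1e-8) stop("kinship matrix is not positive semi-definite")
  }
  dvals <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, yv))
  onet <- drop(crossprod(U, rep(1, length(yv))))

  # profile REML over delta = sigma2_e / sigma2_g on the rotated scale
  reml_ll <- function(log_delta, Xt) {
    delta <- exp(log_delta)
    w <- 1 / (dvals + delta)
    XtWX <- crossprod(Xt * w, Xt)
    XtWy <- crossprod(Xt * w, yt)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    np <- length(yt) - ncol(Xt)
    s2 <- sum(w * r^2) / np
    -0.5 * (np * log(s2) + sum(log(dvals + delta)) +
              determinant(XtWX, logarithm = TRUE)$modulus + np)
  }
  est_delta <- function(Xt) {
    gridv <- vapply(seq(-10, 10, by = 0.5), reml_ll, 0, Xt = Xt)
    at <- seq(-10, 10, by = 0.5)[which.max(gridv)]
    stats::optimize(reml_ll, interval = c(at - 1, at + 1), Xt = Xt,
                    maximum = TRUE, tol = 1e-8)$maximum
  }
  X0 <- matrix(onet, ncol = 1)
  log_delta0 <- est_delta(X0)

  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mono <- !is.finite(maf) | maf <= 0
  below <- !mono & maf < min_maf
  keep <- which(!mono & !below)
  skipped <- data.frame(
    marker = colnames(calls)[mono | below],
    reason = ifelse(mono[mono | below], "monomorphic", "maf_below_threshold"))

  n <- length(yt)
  df <- n - 2L
  xm <- calls[, keep, drop = FALSE]
  if (anyNA(xm)) {  # mean imputation per marker
    mus <- colMeans(xm, na.rm = TRUE)
    idxna <- which(is.na(xm), arr.ind = TRUE)
    xm[idxna] <- mus[idxna[, 2]]
  }
  XT <- crossprod(U, xm)  # rotated dosages, one column per marker
  beta_v <- p_v <- r2_v <- rep(NA_real_, length(keep))
  for (i in seq_along(keep)) {
    xt <- XT[, i]
    ld <- if (p3d) log_delta0 else est_delta(cbind(onet, xt))
    w <- 1 / (dvals + exp(ld))
    a11 <- sum(w * onet^2); a12 <- sum(w * onet * xt); a22 <- sum(w * xt^2)
    b1 <- sum(w * onet * yt); b2 <- sum(w * xt * yt)
    det <- a11 * a22 - a12^2
    if (det <= .Machine$double.eps * a11 * a22) next
    beta1 <- (a11 * b2 - a12 * b1) / det
    beta0 <- (a22 * b1 - a12 * b2) / det
    ss1 <- sum(w * (yt - beta0 * onet - beta1 * xt)^2)
    ss0 <- sum(w * (yt - (b1 / a11) * onet)^2)
    s2 <- ss1 / df
    se <- sqrt(s2 * a11 / det)
    pval <- 2 * stats::pt(-abs(beta1 / se), df)
    beta_v[i] <- beta1
    p_v[i] <- min(max(pval, .Machine$double.xmin), 1)
    r2_v[i] <- max(0, (ss0 - ss1) / ss0)  # variance explained, rotated scale
  }
  ok <- is.finite(p_v)
  if (!any(ok)) {
    res <- empty_assoc_result()
    attr(res, "skipped") <- skipped
    return(res)
  }
  res <- data.frame(marker = colnames(calls)[keep][ok], beta = beta_v[ok],
                    p_value = p_v[ok], r2_marker = r2_v[ok], maf = maf[keep][ok],
                    stringsAsFactors = FALSE)
  mp <- g$map[match(res$marker, g$map$marker), ]
  res$linkage_group <- mp$linkage_group
  res$position_cM <- mp$position_cM
  res$position_bp <- if ("position_bp" %in% names(mp)) mp$position_bp else NA
  res$favorable_allele <- ifelse(res$beta >= 0, "alt", "ref")
  res$fdr_q <- adjust_fdr(res$p_value)
  res <- res[c("marker", "linkage_group", "position_cM", "position_bp", "maf",
               "beta", "favorable_allele", "p_value", "fdr_q", "r2_marker")]
  rownames(res) <- NULL
  class(res) <- c("association_result", "data.frame")
  attr(res, "skipped") <- skipped
  attr(res, "delta_hat") <- exp(log_delta0)
  res
}

extract_phenotype_vector <- function(y) {
  if (is.numeric(y) && !is.null(names(y))) return(y)
  if (is.data.frame(y)) {
    val_col <- intersect(c("value", "W"), names(y))[1]
    if (is.na(val_col) || !"genotype" %in% names(y)) {
      stop("phenotype data frame needs 'genotype' and 'value' (or 'W') columns")
    }
    return(stats::setNames(y[[val_col]], y$genotype))
  }
  stop("y must be a named numeric vector or a genotype/value data frame")
}

empty_assoc_result <- function() {
  res <- data.frame(marker = character(), linkage_group = character(),
                    position_cM = numeric(), position_bp = numeric(),
                    maf = numeric(), beta = numeric(),
                    favorable_allele = character(), p_value = numeric(),
                    fdr_q = numeric(), r2_marker = numeric())
  class(res) <- c("association_result", "data.frame")
  res
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: q_(i) = min over j >= i of p_(j) * m / j, monotone and
#' never below the raw p-value.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the input order.
#' @export
adjust_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
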