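#' Model specifications for the trial mixed models
#'
#' Four nested model layouts are supported, all with the genotype terms
#' random and the nitrogen condition fixed:
#' \describe{
#'   \item{multi_env_1}{all trials and N conditions confounded: genotype,
#'     trial, replicate-within-trial, G x N, G x T and G x N x T random.}
#'   \item{split_plot_3}{one trial, both N conditions: genotype, replicate
#'     and G x N random.}
#'   \item{alpha_plan_4}{one alpha-plan trial: genotype, replicate,
#'     block-within-replicate and G x N random.}
#'   \item{single_env_6}{one trial x N combination: genotype and replicate
#'     random.}
#' }
#'
#' @param model_id One of "multi_env_1", "split_plot_3", "alpha_plan_4",
#'   "single_env_6".
#' @param trait_code Trait the model is fitted to.
#' @return A `model_spec` list with the fixed and random term definitions.
#' @export
model_spec <- function(model_id = c("multi_env_1", "split_plot_3",
                                    "alpha_plan_4", "single_env_6"),
                       trait_code = "SY") {
  model_id <- match.arg(model_id)
  random_terms <- switch(model_id,
    multi_env_1 = list(G = "genotype", T = "trial",
                       `T:R` = c("trial", "replicate"),
                       `G:N` = c("genotype", "n_level"),
                       `G:T` = c("genotype", "trial"),
                       `G:N:T` = c("genotype", "n_level", "trial")),
    split_plot_3 = list(G = "genotype", R = "replicate",
                        `G:N` = c("genotype", "n_level")),
    alpha_plan_4 = list(G = "genotype", R = "replicate",
                        `R:B` = c("replicate", "block"),
                        `G:N` = c("genotype", "n_level")),
    single_env_6 = list(G = "genotype", R = "replicate")
  )
  fixed <- if (model_id == "single_env_6") character() else "n_level"
  structure(list(model_id = model_id, trait_code = trait_code,
                 fixed_terms = fixed, random_terms = random_terms),
            class = "model_spec")
}

sigma_name <- function(term) {
  switch(term, G = "sigma2_G", T = "sigma2_T", `T:R` = "sigma2_RinT",
         R = "sigma2_R", `R:B` = "sigma2_BinR", `G:N` = "sigma2_GxN",
         `G:T` = "sigma2_GxT", `G:N:T` = "sigma2_GxNxT", term)
}

prepare_vc_data <- function(records, spec) {
  d <- records[records$trait == spec$trait_code & !is.na(records$value), ,
               drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait ", spec$trait_code)
  need <- unique(unlist(spec$random_terms))
  if ("block" %in% need && all(is.na(d$block))) {
    stop("alpha_plan model requires block information")
  }
  d$genotype <- factor(d$genotype)
  d$n_level <- factor(d$n_level)
  d$trial <- factor(d$trial)
  d$replicate <- factor(d$replicate)
  if ("block" %in% names(d)) d$block <- factor(d$block)
  d
}

#' Estimate variance components for a trial mixed model
#'
#' The default engine solves the Henderson-III expected-mean-squares
#' equations on the balanced analysis of variance (all random terms plus the
#' residual), which is exact for the balanced layouts the models describe.
#' EM-REML (restricted maximum likelihood by expectation-maximization on the
#' mixed-model equations) is provided for unbalanced data such as alpha-plan
#' designs; it iterates to a tolerance of 1e-8 on the components, up to 500
#' iterations. Negative moment estimates are clamped to zero with the
#' pre-clamp value retained for diagnostics. The fixed nitrogen contrast is
#' estimated by generalized least squares (equal to the N-level mean
#' difference in balanced layouts).
#'
#' @param records A `phenotype_records` data frame.
#' @param spec A `model_spec`.
#' @param method "mom" (expected mean squares; requires balance) or "reml".
#' @return A `variance_components` list: `components` (named, clamped),
#'   `pre_clamp`, `fixed_effects`, `n_levels` (n = N conditions, t = trials,
#'   r = replicates per genotype x N x trial), `method`, `model_id`.
#' @export
fit_variance_components <- function(records, spec, method = c("mom", "reml")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  d <- prepare_vc_data(records, spec)

  # drop unidentifiable terms (e.g. G:T with a single trial)
  rt <- spec$random_terms
  single <- vapply(names(rt), function(tm) {
    any(vapply(rt[[tm]], function(f) nlevels(d[[f]]) < 2L, TRUE))
  }, TRUE)
  if (any(single)) {
    warning("dropping unidentifiable term(s): ",
            paste(names(rt)[single], collapse = ", "))
    rt <- rt[!single]
  }

  n_lev <- c(n = nlevels(d$n_level), t = nlevels(d$trial),
             r = harmonic_mean_reps(d))

  if (method == "mom") {
    cell <- interaction(d[unique(unlist(rt))], drop = FALSE)
    counts <- table(lapply(unique(unlist(rt)), function(f) d[[f]]))
    if (length(unique(as.vector(counts))) != 1L) {
      stop("unbalanced data: method-of-moments requires equal cell counts; ",
           "use method = 'reml'")
    }
    est <- mom_components(d, rt)
  } else {
    est <- em_reml(d, rt, fixed = spec$fixed_terms)
  }

  comp <- pmax(est, 0)
  names(comp) <- names(est) <- vapply(names(est), identity, "")
  fixed <- c(mu = mean(d$value))
  if ("n_level" %in% spec$fixed_terms && nlevels(d$n_level) == 2) {
    mm <- tapply(d$value, d$n_level, mean)
    fixed <- c(fixed, N2_minus_N1 = unname(mm["N2"] - mm["N1"]))
  }
  structure(list(components = comp, pre_clamp = est, fixed_effects = fixed,
                 n_levels = n_lev, method = method, model_id = spec$model_id,
                 trait_code = spec$trait_code),
            class = "variance_components")
}

harmonic_mean_reps <- function(d) {
  cnt <- tapply(d$value, interaction(d$genotype, d$n_level, d$trial, drop = TRUE),
                length)
  cnt <- cnt[!is.na(cnt) & cnt > 0]
  length(cnt) / sum(1 / cnt)
}

# Henderson III on balanced data: solve the expected-mean-squares system.
# Under the unrestricted mixed-model convention the coefficient of
# sigma2_u in E[MS_v] is N / levels(u) whenever the factors of v are a
# subset of the factors of u, plus sigma2_e everywhere.
mom_components <- function(d, rt) {
  terms_str <- vapply(rt, function(f) paste(f, collapse = ":"), "")
  fixed_terms <- if ("n_level" %in% names(d) && nlevels(d$n_level) > 1)
    "n_level" else character()
  # no fixed N:T margin: the model omits that term, so its stratum belongs
  # to the three-way interaction (this is what REML estimates too)
  fml <- stats::as.formula(paste(
    "value ~", paste(c(fixed_terms, terms_str), collapse = " + ")))
  a <- stats::aov(fml, data = d)
  tab <- summary(a)[[1]]
  rn <- trimws(rownames(tab))
  ms <- tab[["Mean Sq"]]
  names(ms) <- rn
  # match aov row labels to our terms irrespective of factor order
  canon <- function(s) paste(sort(strsplit(s, ":")[[1]]), collapse = ":")
  row_of <- vapply(terms_str, function(ts) {
    hit <- which(vapply(rn, canon, "") == canon(ts))
    if (!length(hit)) NA_integer_ else hit[1]
  }, 0L)
  if (anyNA(row_of)) stop("internal: ANOVA term not found")
  n_tot <- nrow(d)
  k <- length(rt)
  A <- matrix(0, k + 1, k + 1,
              dimnames = list(c(names(rt), "e"),
                              c(vapply(names(rt), sigma_name, ""), "sigma2_e")))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (all(rt[[i]] %in% rt[[j]])) {
        nl <- prod(vapply(rt[[j]], function(f) nlevels(d[[f]]), 0L))
        A[i, j] <- n_tot / nl
      }
    }
  }
  A[, k + 1] <- 1
  A[k + 1, k + 1] <- 1
  ms_vec <- c(ms[row_of], Residuals = ms[["Residuals"]])
  est <- solve(A, ms_vec)
  stats::setNames(as.numeric(est), colnames(A))
}

# EM-REML on the mixed model equations (dense; intended for the moderate
# problem sizes of single trials and simulation studies).
em_reml <- function(d, rt, fixed = character(), tol = 1e-8, max_iter = 500L) {
  y <- d$value
  n <- length(y)
  X <- stats::model.matrix(
    if (length(fixed)) stats::as.formula(paste("~", paste(fixed, collapse = "+")))
    else ~1, data = d)
  Zs <- lapply(rt, function(f) {
    fac <- if (length(f) == 1) d[[f]] else interaction(d[f], drop = TRUE)
    stats::model.matrix(~ 0 + fac)
  })
  q <- vapply(Zs, ncol, 0L)
  Z <- do.call(cbind, Zs)
  p <- qr(X)$rank
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y); yty <- sum(y^2)
  k <- length(rt)
  s2 <- rep(stats::var(y) / (k + 1), k + 1)  # components then residual
  idx <- split(seq_len(sum(q)), rep(seq_len(k), q))
  for (it in seq_len(max_iter)) {
    lambda <- ifelse(s2[1:k] > 1e-12, s2[k + 1] / s2[1:k], 1e12)
    D <- diag(rep(lambda, q), sum(q))
    C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + D))
    rhs <- rbind(Xty, Zty)
    Cinv <- tryCatch(solve(C), error = function(e) MASS_ginv(C))
    sol <- Cinv %*% rhs
    u <- sol[-seq_len(ncol(X)), , drop = FALSE]
    s2_new <- numeric(k + 1)
    dCinv <- diag(Cinv)[-seq_len(ncol(X))]
    for (j in seq_len(k)) {
      uj <- u[idx[[j]], 1]
      s2_new[j] <- (sum(uj^2) + s2[k + 1] * sum(dCinv[idx[[j]]])) / q[j]
    }
    s2_new[k + 1] <- (yty - sum(sol * rhs)) / (n - p)
    if (max(abs(s2_new - s2) / (abs(s2) + 1e-10)) < tol) {
      s2 <- s2_new
      break
    }
    s2 <- s2_new
  }
  stats::setNames(s2, c(vapply(names(rt), sigma_name, ""), "sigma2_e"))
}

MASS_ginv <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-10
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Broad-sense heritability from variance components
#'
#' Three design-adjusted formulas on the genotype-mean basis:
#' \describe{
#'   \item{multi_2}{h2 = s2_G / (s2_G + s2_GxN/n + s2_GxT/t + s2_e/(t n r)),
#'     for the multi-environment model.}
#'   \item{per_trial_5}{h2 = s2_G / (s2_G + s2_GxN/n + s2_e/(n r)), for one
#'     trial across both N conditions.}
#'   \item{single_7}{h2 = s2_G / (s2_G + s2_e/r), for one trial x N
#'     combination.}
#' }
#' The three-way G x N x T component, when present, is reported by the
#' variance-component fit but deliberately does not enter the
#' multi-environment formula.
#'
#' @param vc A `variance_components` object.
#' @param formula_id "multi_2", "per_trial_5" or "single_7".
#' @return A `heritability_result` list with `h2` in [0, 1] (or `NA` when
#'   all components are zero) and `formula_id`.
#' @export
heritability <- function(vc, formula_id = c("multi_2", "per_trial_5", "single_7")) {
  formula_id <- match.arg(formula_id)
  cm <- vc$components
  g <- function(nm) if (nm %in% names(cm)) cm[[nm]] else 0
  n <- vc$n_levels[["n"]]; t <- vc$n_levels[["t"]]; r <- vc$n_levels[["r"]]
  den <- switch(formula_id,
    multi_2 = g("sigma2_G") + g("sigma2_GxN") / n + g("sigma2_GxT") / t +
      g("sigma2_e") / (t * n * r),
    per_trial_5 = g("sigma2_G") + g("sigma2_GxN") / n + g("sigma2_e") / (n * r),
    single_7 = g("sigma2_G") + g("sigma2_e") / r)
  h2 <- if (den <= 0) NA_real_ else g("sigma2_G") / den
  structure(list(h2 = h2, formula_id = formula_id), class = "heritability_result")
}

#' Genotype estimates for downstream mapping
#'
#' Computes per-genotype phenotype estimates to be used as mapping traits:
#' least-squares adjusted means (genotype predictions averaged over the
#' observed design cells, equal to raw genotype means in balanced layouts)
#' or BLUPs (adjusted means shrunk towards the population mean by the
#' genotype-mean reliability implied by the variance components). Shrinkage
#' is monotone, so balanced-data BLUPs preserve the ordering of raw means.
#'
#' @param records A `phenotype_records` data frame.
#' @param spec A `model_spec`.
#' @param kind "adjusted_mean" or "blup".
#' @param vc Optional precomputed `variance_components` (required only for
#'   BLUPs; fitted with defaults when absent).
#' @return Data frame (genotype, trait, kind, value). Genotypes without
#'   observations are absent.
#' @export
genotype_estimates <- function(records, spec, kind = c("adjusted_mean", "blup"),
                               vc = NULL) {
  kind <- match.arg(kind)
  d <- prepare_vc_data(records, spec)
  design_fac <- setdiff(unique(unlist(spec$random_terms)), "genotype")
  design_fac <- c(design_fac, spec$fixed_terms)
  design_fac <- intersect(unique(design_fac), names(d))
  design_fac <- design_fac[vapply(design_fac,
                                  function(f) nlevels(d[[f]]) > 1, TRUE)]
  if (length(design_fac)) {
    fml <- stats::as.formula(paste("value ~ genotype +",
                                   paste(design_fac, collapse = " + ")))
    fit <- stats::lm(fml, data = d)
    cells <- unique(d[design_fac])
    grid <- merge(data.frame(genotype = levels(d$genotype)), cells, by = NULL)
    pred <- stats::predict(fit, newdata = grid)
    adj <- tapply(pred, grid$genotype, mean)
  } else {
    adj <- tapply(d$value, d$genotype, mean)
  }
  adj <- adj[levels(d$genotype)]
  val <- as.numeric(adj)
  if (kind == "blup") {
    if (is.null(vc)) {
      vc <- tryCatch(fit_variance_components(records, spec, "mom"),
                     error = function(e) fit_variance_components(records, spec, "reml"))
    }
    cm <- vc$components
    g <- function(nm) if (nm %in% names(cm)) cm[[nm]] else 0
    n <- vc$n_levels[["n"]]; t <- vc$n_levels[["t"]]; r <- vc$n_levels[["r"]]
    vbar <- switch(vc$model_id,
      multi_env_1 = g("sigma2_GxN") / n + g("sigma2_GxT") / t +
        g("sigma2_e") / (n * t * r),
      split_plot_3 = ,
      alpha_plan_4 = g("sigma2_GxN") / n + g("sigma2_e") / (n * r),
      single_env_6 = g("sigma2_e") / r)
    w <- if (g("sigma2_G") + vbar <= 0) 0 else g("sigma2_G") / (g("sigma2_G") + vbar)
    mu <- mean(val)
    val <- mu + w * (val - mu)
  }
  data.frame(genotype = names(adj), trait = spec$trait_code, kind = kind,
             value = val, stringsAsFactors = FALSE, row.names = NULL)
}

#' Phenotypic and genetic correlation between two traits
#'
#' The phenotypic correlation is the Pearson correlation of plot values
#' matched on (genotype, trial, N level, replicate). The genetic correlation
#' is a method-of-moments estimate from the between- and within-genotype
#' mean cross-products: cov_G = (MCP_between - MCP_within) / m0, analogous
#' for the genetic variances, and r_g = cov_G / sqrt(v_G(x) v_G(y)). As a
#' moment ratio r_g is not constrained to [-1, 1] and is deliberately not
#' clamped.
#'
#' @param records A `phenotype_records` data frame holding both traits.
#' @param traits Character vector of two trait codes.
#' @return A list with `r_p` and `r_g` (`r_g` is `NA` when either genetic
#'   variance estimate is non-positive).
#' @export
trait_correlations <- function(records, traits) {
  stopifnot(length(traits) == 2)
  key <- c("genotype", "trial", "n_level", "replicate")
  x <- records[records$trait == traits[1], c(key, "value")]
  y <- records[records$trait == traits[2], c(key, "value")]
  m <- merge(x, y, by = key, suffixes = c("_x", "_y"))
  m <- m[stats::complete.cases(m[c("value_x", "value_y")]), ]
  if (nrow(m) < 3) stop("too few shared plots between traits")
  r_p <- stats::cor(m$value_x, m$value_y)
  g <- factor(m$genotype)
  N <- nrow(m); ng <- nlevels(g)
  mi <- as.numeric(table(g))
  m0 <- (N - sum(mi^2) / N) / (ng - 1)
  cross <- function(a, b) {
    abar_i <- tapply(a, g, mean); bbar_i <- tapply(b, g, mean)
    B <- sum(mi * (abar_i - mean(a)) * (bbar_i - mean(b))) / (ng - 1)
    W <- sum((a - abar_i[g]) * (b - bbar_i[g])) / (N - ng)
    (B - W) / m0
  }
  v_gx <- cross(m$value_x, m$value_x)
  v_gy <- cross(m$value_y, m$value_y)
  r_g <- if (v_gx <= 0 || v_gy <= 0) NA_real_ else
    cross(m$value_x, m$value_y) / sqrt(v_gx * v_gy)
  list(r_p = r_p, r_g = r_g)
}
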