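#' Characterize environments by PCA and hierarchical clustering
#'
#' Environments are trial x N-level combinations. Each genotype x
#' environment observation is its vector of trait means (over replicates);
#' traits are centred and scaled, a PCA is run, and Ward hierarchical
#' clustering on the first `n_pcs` component scores is cut at `k` clusters.
#' Each environment is assigned to the cluster holding the plurality of its
#' observations (ties broken by environment id order). Environments missing
#' any requested trait are excluded and reported.
#'
#' @param records A `phenotype_records` data frame.
#' @param traits Traits to use (>= `n_pcs` recommended).
#' @param k Number of clusters (default 3).
#' @param n_pcs Number of principal components retained (default 5, capped
#'   at the number of traits).
#' @return An `environment_clustering` list: `observations` (genotype,
#'   environment, cluster, PC scores), `env_to_cluster`,
#'   `env_composition` (per-cluster percentage of each environment), `k`,
#'   `excluded_environments`.
#' @export
cluster_environments <- function(records, traits, k = 3, n_pcs = 5) {
  d <- records[records$trait %in% traits & !is.na(records$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for requested traits")
  d$environment <- paste(d$trial, d$n_level, sep = "_")
  cm <- stats::aggregate(value ~ genotype + environment + trait, data = d,
                         FUN = mean)
  wide <- stats::reshape(cm, idvar = c("genotype", "environment"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  # environments lacking any trait entirely are excluded (like trials where
  # a trait was not recorded); residual missing rows are dropped
  env_all <- sort(unique(d$environment))
  has_all <- vapply(env_all, function(e) {
    sub <- wide[wide$environment == e, traits, drop = FALSE]
    all(colSums(!is.na(sub)) > 0)
  }, TRUE)
  excluded <- env_all[!has_all]
  wide <- wide[wide$environment %in% env_all[has_all], , drop = FALSE]
  wide <- wide[stats::complete.cases(wide[traits]), , drop = FALSE]
  if (nrow(wide) < k) stop("fewer complete observations than clusters")
  X <- scale(as.matrix(wide[traits]))
  X[, !is.finite(colSums(X))] <- 0  # constant traits carry no signal
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  cl <- stats::cutree(hc, k = min(k, nrow(scores)))
  obs <- data.frame(genotype = wide$genotype, environment = wide$environment,
                    cluster = cl, stringsAsFactors = FALSE)
  obs <- cbind(obs, as.data.frame(scores))
  tab <- table(obs$environment, obs$cluster)
  env_to_cluster <- apply(tab, 1, function(r) as.integer(colnames(tab)[which.max(r)]))
  comp <- lapply(colnames(tab), function(cc) {
    col <- tab[, cc]
    100 * col / sum(col)
  })
  names(comp) <- colnames(tab)
  structure(list(observations = obs, env_to_cluster = env_to_cluster,
                 env_composition = comp, k = length(unique(cl)),
                 n_pcs = n_pcs, excluded_environments = excluded),
            class = "environment_clustering")
}

#' Trait deviation profiles of environment clusters
#'
#' For every environment in each cluster and every trait, the deviation of
#' the environment mean (over genotypes) from the grand mean over all
#' observations; observation-weighted deviations sum to zero per trait.
#'
#' @param clustering An `environment_clustering`.
#' @param records A `phenotype_records` data frame.
#' @param traits Traits to profile (defaults to all in `records`).
#' @return Data frame (cluster, environment, trait, deviation).
#' @export
cluster_trait_profiles <- function(clustering, records, traits = NULL) {
  if (is.null(traits)) traits <- unique(records$trait)
  d <- records[records$trait %in% traits & !is.na(records$value), , drop = FALSE]
  d$environment <- paste(d$trial, d$n_level, sep = "_")
  d <- d[d$environment %in% names(clustering$env_to_cluster), , drop = FALSE]
  out <- list()
  for (tr in traits) {
    dt <- d[d$trait == tr, ]
    if (!nrow(dt)) next
    grand <- mean(dt$value)
    em <- tapply(dt$value, dt$environment, mean)
    out[[tr]] <- data.frame(
      cluster = clustering$env_to_cluster[names(em)],
      environment = names(em), trait = tr,
      deviation = as.numeric(em) - grand, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$environment, res$trait), ]
}

#' QTL consistency across environment clusters
#'
#' Per-environment QTL are merged into loci by transitive cM overlap on a
#' common map; each locus is tagged with the set of environment clusters in
#' which at least one member was detected, and the histogram of cluster-set
#' sizes (with percentages) is returned.
#'
#' @param per_env_qtls Named list mapping environment id to a
#'   `qtl_intervals` data frame.
#' @param clustering An `environment_clustering` whose `env_to_cluster`
#'   covers the environments.
#' @return A list: `loci` (locus_id, linkage_group, span, clusters,
#'   n_clusters, member environments), `histogram` (n_clusters, n_loci,
#'   percentage), `excluded_environments`.
#' @export
qtl_cluster_consistency <- function(per_env_qtls, clustering) {
  envs <- names(per_env_qtls)
  known <- envs %in% names(clustering$env_to_cluster)
  excluded <- envs[!known]
  qtl <- list()
  for (e in envs[known]) {
    q <- per_env_qtls[[e]]
    if (is.null(q) || nrow(q) == 0) next
    q$environment <- e
    q$cluster <- clustering$env_to_cluster[[e]]
    qtl[[e]] <- as.data.frame(q)
  }
  if (!length(qtl)) {
    return(list(loci = data.frame(), histogram = data.frame(),
                excluded_environments = excluded))
  }
  allq <- do.call(rbind, lapply(qtl, function(x)
    x[c("qtl_id", "linkage_group", "ci_lo_cM", "ci_hi_cM", "environment",
        "cluster")]))
  rownames(allq) <- NULL
  comp <- seq_len(nrow(allq))
  for (i in seq_len(max(nrow(allq) - 1L, 0L))) {
    for (j in (i + 1L):nrow(allq)) {
      if (intervals_overlap(allq[i, ], allq[j, ])) comp[comp == comp[j]] <- comp[i]
    }
  }
  loci <- do.call(rbind, lapply(unique(comp), function(cl) {
    m <- allq[comp == cl, , drop = FALSE]
    cls <- sort(unique(m$cluster))
    data.frame(linkage_group = m$linkage_group[1],
               span_lo_cM = min(m$ci_lo_cM), span_hi_cM = max(m$ci_hi_cM),
               clusters = paste(cls, collapse = ","),
               n_clusters = length(cls),
               environments = paste(sort(unique(m$environment)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  loci$locus_id <- sprintf("locus_%03d", seq_len(nrow(loci)))
  hist_tab <- table(factor(loci$n_clusters, levels = seq_len(clustering$k)))
  histogram <- data.frame(n_clusters = as.integer(names(hist_tab)),
                          n_loci = as.integer(hist_tab),
                          percentage = 100 * as.integer(hist_tab) /
                            max(sum(hist_tab), 1L))
  list(loci = loci, histogram = histogram, excluded_environments = excluded)
}
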