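new_qtl_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(qtl_id = character(), trait = character(),
                     dataset_tag = character(), linkage_group = character(),
                     peak_marker = character(), peak_cM = numeric(),
                     peak_bp = numeric(), ci_lo_cM = numeric(),
                     ci_hi_cM = numeric(), ci_lo_bp = numeric(),
                     ci_hi_bp = numeric(), peak_stat = numeric(),
                     stat_type = character(), favorable = character(),
                     effect = numeric(), method = character())
  }
  rownames(df) <- NULL
  class(df) <- c("qtl_intervals", "data.frame")
  df
}

interp_bp <- function(map, lg, cm) {
  mp <- map[map$linkage_group == lg & !is.na(map$position_bp), ]
  if (nrow(mp) < 2) return(rep(NA_real_, length(cm)))
  stats::approx(mp$position_cM, mp$position_bp, xout = cm, rule = 2,
                ties = mean)$y
}

#' Confidence intervals for GWAS-detected loci from local LD decay
#'
#' Significant SNPs (FDR q below the threshold) on a linkage group are
#' grouped by single linkage: two SNPs join when their pairwise r2 is at
#' least `r2_join` or their cM gap does not exceed the linkage-group-wide LD
#' extent at r2 = 0.2. Each cluster's span is then extended on both sides by
#' the local LD-decay extent, fitted on all markers inside a window covering
#' `window_frac` of the linkage-group length centred at the cluster
#' midpoint (falling back to the genome-wide extent when the window holds
#' fewer than 10 marker pairs). The SNP with the lowest q within a cluster
#' is the peak; ties go to the larger absolute effect, then the lowest cM.
#'
#' @param assoc An `association_result` from [mlm_scan()].
#' @param g The `genotype_matrix` used for the scan (provides the map and
#'   the calls for LD).
#' @param q_threshold FDR significance threshold (default 0.15).
#' @param r2_join r2 at which significant SNPs are clustered (default 0.2).
#' @param window_frac Fraction of the linkage-group length used for the
#'   local LD window (default 0.05).
#' @param trait,dataset_tag Labels stored on the intervals.
#' @return A `qtl_intervals` data frame.
#' @export
build_gwas_qtl_intervals <- function(assoc, g, q_threshold = 0.15,
                                     r2_join = 0.2, window_frac = 0.05,
                                     trait = "trait", dataset_tag = "multi_env") {
  sig <- assoc[assoc$fdr_q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(new_qtl_intervals(NULL))
  map <- g$map
  all_pairs <- pairwise_r2(g, map, max_dist_cM = Inf)
  genome_extent <- tryCatch(
    fit_ld_decay(all_pairs)$extent_cM_at_r2[["0.2"]],
    error = function(e) NA_real_)

  out <- list()
  for (lg in unique(sig$linkage_group)) {
    s <- sig[sig$linkage_group == lg, , drop = FALSE]
    s <- s[order(s$position_cM), , drop = FALSE]
    lg_map <- map[map$linkage_group == lg, ]
    lg_lo <- min(lg_map$position_cM); lg_hi <- max(lg_map$position_cM)
    lg_len <- lg_hi - lg_lo
    lg_pairs <- all_pairs[all_pairs$linkage_group == lg, , drop = FALSE]
    lg_extent <- tryCatch(fit_ld_decay(lg_pairs)$extent_cM_at_r2[["0.2"]],
                          error = function(e) genome_extent)
    if (!is.finite(lg_extent)) lg_extent <- 1  # last-resort 1 cM gap rule

    ns <- nrow(s)
    comp <- seq_len(ns)
    if (ns > 1) {
      x <- g$calls[, s$marker, drop = FALSE]
      suppressWarnings(r2m <- stats::cor(x, use = "pairwise.complete.obs")^2)
      for (i in seq_len(ns - 1)) {
        for (j in (i + 1):ns) {
          gap <- abs(s$position_cM[j] - s$position_cM[i])
          linked <- (is.finite(r2m[i, j]) && r2m[i, j] >= r2_join) ||
            gap <= lg_extent
          if (linked) comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    for (cl in unique(comp)) {
      cs <- s[comp == cl, , drop = FALSE]
      span <- range(cs$position_cM)
      mid <- mean(span)
      win <- window_frac * lg_len / 2
      win_markers <- lg_map$marker[lg_map$position_cM >= mid - win &
                                     lg_map$position_cM <= mid + win]
      wp <- lg_pairs[lg_pairs$marker_a %in% win_markers &
                       lg_pairs$marker_b %in% win_markers, , drop = FALSE]
      ext <- if (nrow(wp) >= 10) {
        tryCatch(fit_ld_decay(wp)$extent_cM_at_r2[["0.2"]],
                 error = function(e) NULL)
      } else NULL
      if (is.null(ext)) {
        warning("local LD window too sparse on ", lg,
                "; using genome-wide extent")
        ext <- genome_extent
      }
      if (!is.finite(ext)) ext <- lg_extent
      lo <- max(lg_lo, span[1] - ext)
      hi <- min(lg_hi, span[2] + ext)
      pk <- cs[order(cs$fdr_q, -abs(cs$beta), cs$position_cM), ][1, ]
      out[[length(out) + 1L]] <- data.frame(
        qtl_id = sprintf("%s_%s_%s_%.1f", dataset_tag, trait, lg, pk$position_cM),
        trait = trait, dataset_tag = dataset_tag, linkage_group = lg,
        peak_marker = pk$marker, peak_cM = pk$position_cM,
        peak_bp = as.numeric(pk$position_bp),
        ci_lo_cM = lo, ci_hi_cM = hi,
        ci_lo_bp = interp_bp(map, lg, lo), ci_hi_bp = interp_bp(map, lg, hi),
        peak_stat = pk$fdr_q, stat_type = "fdr_q",
        favorable = pk$favorable_allele, effect = pk$beta, method = "gwas",
        stringsAsFactors = FALSE)
    }
  }
  new_qtl_intervals(do.call(rbind, out))
}

haldane_joint_prob <- function(gl, gr, rl, rr) {
  # P(carrier allele | flanking DH genotypes), no interference
  r12 <- rl + rr - 2 * rl * rr
  p11 <- (1 - rl) * (1 - rr) / (1 - r12)
  p10 <- (1 - rl) * rr / r12
  p01 <- rl * (1 - rr) / r12
  p00 <- rl * rr / (1 - r12)
  ifelse(gl == 1 & gr == 1, p11,
         ifelse(gl == 1 & gr == 0, p10,
                ifelse(gl == 0 & gr == 1, p01, p00)))
}

# Expected carrier-allele probability at each grid position for each DH line
dh_genotype_probs <- function(g, step_cM) {
  calls <- g$calls / 2  # 0/1 carrier coding
  map <- g$map
  n <- nrow(calls)
  grids <- list(); probs <- list()
  for (lg in unique(map$linkage_group)) {
    idx <- which(map$linkage_group == lg)
    pos <- map$position_cM[idx]
    gp <- sort(unique(c(pos, seq(min(pos), max(pos), by = step_cM))))
    P <- matrix(NA_real_, n, length(gp))
    skipped <- logical(length(gp))
    for (k in seq_along(gp)) {
      p <- gp[k]
      li <- which(pos <= p); ri <- which(pos >= p)
      li <- if (length(li)) idx[max(li)] else NA
      ri <- if (length(ri)) idx[min(ri)] else NA
      gl <- if (!is.na(li)) calls[, li] else rep(NA_real_, n)
      gr <- if (!is.na(ri)) calls[, ri] else rep(NA_real_, n)
      if (mean(is.na(gl) & is.na(gr)) > 0.2) { skipped[k] <- TRUE; next }
      dl <- if (!is.na(li)) p - map$position_cM[li] else NA
      dr <- if (!is.na(ri)) map$position_cM[ri] - p else NA
      if (!is.na(li) && !is.na(ri) && li == ri) {
        pk <- gl
        pk[is.na(pk)] <- 0.5
      } else {
        rl <- haldane_r(dl); rr <- haldane_r(dr)
        pk <- rep(0.5, n)
        both <- !is.na(gl) & !is.na(gr)
        onlyl <- !is.na(gl) & is.na(gr)
        onlyr <- is.na(gl) & !is.na(gr)
        if (is.na(rl)) { onlyr <- !is.na(gr); both <- onlyl <- rep(FALSE, n) }
        if (is.na(rr)) { onlyl <- !is.na(gl); both <- onlyr <- rep(FALSE, n) }
        if (any(both)) pk[both] <- haldane_joint_prob(gl[both], gr[both], rl, rr)
        if (any(onlyl)) pk[onlyl] <- ifelse(gl[onlyl] == 1, 1 - rl, rl)
        if (any(onlyr)) pk[onlyr] <- ifelse(gr[onlyr] == 1, 1 - rr, rr)
      }
      P[, k] <- pk
    }
    keep <- !skipped
    grids[[lg]] <- data.frame(linkage_group = lg, position_cM = gp[keep],
                              nearest_marker = map$marker[idx][
                                vapply(gp[keep], function(p)
                                  which.min(abs(pos - p)), 0L)],
                              stringsAsFactors = FALSE)
    probs[[lg]] <- P[, keep, drop = FALSE]
    attr(grids[[lg]], "n_skipped") <- sum(skipped)
  }
  list(meta = do.call(rbind, grids), P = do.call(cbind, probs))
}

# Haley-Knott LOD profile; S columns are expected +/-1 codings, cof_idx are
# grid columns used as covariates (dropped within window_cM of the test
# position on its own linkage group).
hk_scan <- function(S, meta, y, cof_idx = integer(), window_cM = 10) {
  n <- length(y)
  npos <- ncol(S)
  lod <- rep(NA_real_, npos)
  beta <- rep(NA_real_, npos)
  if (!length(cof_idx)) {
    yc <- y - mean(y)
    Sc <- sweep(S, 2, colMeans(S))
    ssy <- sum(yc^2)
    ssx <- colSums(Sc^2)
    num <- drop(crossprod(Sc, yc))
    r2 <- ifelse(ssx > 1e-12, num^2 / (ssx * ssy), 0)
    r2 <- pmin(r2, 1 - 1e-12)
    return(list(lod = -(n / 2) * log10(1 - r2),
                beta = ifelse(ssx > 1e-12, num / ssx, 0)))
  }
  for (k in seq_len(npos)) {
    same_lg <- meta$linkage_group[cof_idx] == meta$linkage_group[k]
    near <- same_lg & abs(meta$position_cM[cof_idx] - meta$position_cM[k]) <= window_cM
    use <- cof_idx[!near]
    X0 <- if (length(use)) cbind(rep(1, n), S[, use, drop = FALSE])
      else matrix(1, n, 1)
    q0 <- qr(X0)
    ry <- qr.resid(q0, y)
    rx <- qr.resid(q0, S[, k])
    ssx <- sum(rx^2)
    if (ssx < 1e-12) { lod[k] <- 0; beta[k] <- 0; next }
    b <- sum(rx * ry) / ssx
    rss0 <- sum(ry^2)
    rss1 <- sum((ry - b * rx)^2)
    lod[k] <- (n / 2) * log10(rss0 / max(rss1, 1e-300))
    beta[k] <- b
  }
  list(lod = lod, beta = beta)
}

#' Composite interval mapping for doubled-haploid populations
#'
#' Haley-Knott regression on expected genotypes at a cM step grid
#' (conditional carrier probabilities from flanking markers under the
#' Haldane map function), with forward selection of marker cofactors
#' entering at the genome-wide permutation threshold (at most
#' `max_cofactors`) and a final rescan in which cofactors within
#' `window_cM` of the test position are dropped from the model. QTL are
#' contiguous scan regions exceeding the threshold; supports are 1.5-LOD
#' intervals around each peak; the effect is the additivity (half the
#' difference between the parental genotype classes), and the favorable
#' parent is the class with the higher trait value.
#'
#' @param g A `genotype_matrix` with `population_kind = "dh"`.
#' @param y Mapping phenotype (named vector or genotype/value data frame).
#' @param step_cM Scan grid step (default 1 cM).
#' @param n_permutations Genome-wide permutations for the significance
#'   threshold (default 1000).
#' @param alpha Genome-wide type-I error level (default 0.05).
#' @param max_cofactors Maximum forward-selected cofactors (default 10).
#' @param window_cM Cofactor exclusion window (default 10 cM).
#' @param trait,dataset_tag,population_id Labels stored on the intervals.
#' @param seed Seed for the permutation draw.
#' @return A `qtl_intervals` data frame; the permutation threshold is
#'   attached as attribute `"lod_threshold"`.
#' @export
dh_interval_mapping <- function(g, y, step_cM = 1, n_permutations = 1000,
                                alpha = 0.05, max_cofactors = 10,
                                window_cM = 10, trait = "trait",
                                dataset_tag = "multi_env",
                                population_id = "dh", seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$population_kind != "dh" || any(g$calls == 1, na.rm = TRUE)) {
    stop("dh_interval_mapping requires a fully homozygous DH population")
  }
  yv <- extract_phenotype_vector(y)
  ids <- intersect(rownames(g$calls), names(yv))
  yv <- yv[ids]
  gsub_ <- g; gsub_$calls <- g$calls[ids, , drop = FALSE]
  gp <- dh_genotype_probs(gsub_, step_cM)
  S <- 2 * gp$P - 1  # expected -1/+1 coding; beta = additivity
  meta <- gp$meta
  n <- length(yv)

  set.seed(seed)
  null_scan <- hk_scan(S, meta, yv)
  perm_max <- vapply(seq_len(n_permutations), function(i) {
    max(hk_scan(S, meta, sample(yv))$lod, na.rm = TRUE)
  }, 0)
  thr <- stats::quantile(perm_max, 1 - alpha, names = FALSE)

  cof <- integer()
  repeat {
    sc <- hk_scan(S, meta, yv, cof, window_cM)
    lod <- sc$lod
    if (length(cof)) {
      # do not re-select inside an existing cofactor window
      for (ci in cof) {
        msk <- meta$linkage_group == meta$linkage_group[ci] &
          abs(meta$position_cM - meta$position_cM[ci]) <= window_cM
        lod[msk] <- NA
      }
    }
    if (all(is.na(lod)) || max(lod, na.rm = TRUE) < thr ||
        length(cof) >= max_cofactors) break
    pk <- which.max(lod)
    cof <- c(cof, pk)
  }

  final <- hk_scan(S, meta, yv, cof, window_cM)
  lod <- final$lod
  out <- list()
  for (lg in unique(meta$linkage_group)) {
    li <- which(meta$linkage_group == lg)
    above <- !is.na(lod[li]) & lod[li] >= thr
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (rr in which(runs$values)) {
      seg <- li[starts[rr]:ends[rr]]
      pk <- seg[which.max(lod[seg])]
      pl <- lod[pk]
      # 1.5-LOD support within the linkage group
      lo_i <- pk
      while (lo_i > min(li) && !is.na(lod[lo_i - 1L]) && lod[lo_i - 1L] >= pl - 1.5)
        lo_i <- lo_i - 1L
      hi_i <- pk
      while (hi_i < max(li) && !is.na(lod[hi_i + 1L]) && lod[hi_i + 1L] >= pl - 1.5)
        hi_i <- hi_i + 1L
      eff <- final$beta[pk]
      out[[length(out) + 1L]] <- data.frame(
        qtl_id = sprintf("%s_%s_%s_%.1f", dataset_tag, trait, lg,
                         meta$position_cM[pk]),
        trait = trait, dataset_tag = dataset_tag, linkage_group = lg,
        peak_marker = meta$nearest_marker[pk], peak_cM = meta$position_cM[pk],
        peak_bp = interp_bp(g$map, lg, meta$position_cM[pk]),
        ci_lo_cM = meta$position_cM[lo_i], ci_hi_cM = meta$position_cM[hi_i],
        ci_lo_bp = interp_bp(g$map, lg, meta$position_cM[lo_i]),
        ci_hi_bp = interp_bp(g$map, lg, meta$position_cM[hi_i]),
        peak_stat = pl, stat_type = "LOD",
        favorable = if (eff >= 0) "P2" else "P1", effect = abs(eff),
        method = "linkage", stringsAsFactors = FALSE)
    }
  }
  res <- new_qtl_intervals(do.call(rbind, out))
  res$population_id <- if (nrow(res)) population_id else character(0)
  attr(res, "lod_threshold") <- thr
  attr(res, "null_scan") <- data.frame(meta, lod = null_scan$lod)
  res
}

#' Project QTL onto a common map
#'
#' Positions (peak and interval endpoints) are carried from the source to
#' the target map by piecewise-linear interpolation between markers shared
#' by both maps on the same linkage group. QTL whose positions fall outside
#' the shared-anchor span (or on linkage groups without shared markers) are
#' flagged unprojectable (`projected = FALSE`, positions `NA`).
#'
#' @param qtls A `qtl_intervals` data frame.
#' @param source_map,target_map `genetic_map` objects.
#' @return The intervals with positions on the target map and a `projected`
#'   logical column.
#' @export
project_qtl <- function(qtls, source_map, target_map) {
  if (nrow(qtls) == 0) {
    qtls$projected <- logical(0)
    return(qtls)
  }
  out <- qtls
  out$projected <- FALSE
  for (lg in unique(qtls$linkage_group)) {
    shared <- intersect(source_map$marker[source_map$linkage_group == lg],
                        target_map$marker[target_map$linkage_group == lg])
    rows <- which(qtls$linkage_group == lg)
    if (length(shared) < 2) next
    sp <- source_map$position_cM[match(shared, source_map$marker)]
    tp <- target_map$position_cM[match(shared, target_map$marker)]
    ord <- order(sp)
    sp <- sp[ord]; tp <- tp[ord]
    mono <- c(TRUE, diff(tp) >= 0)  # drop anchors breaking monotonicity
    sp <- sp[mono]; tp <- tp[mono]
    if (length(sp) < 2) next
    proj <- function(x) stats::approx(sp, tp, xout = x, rule = 1, ties = mean)$y
    pk <- proj(qtls$peak_cM[rows])
    lo <- proj(qtls$ci_lo_cM[rows])
    hi <- proj(qtls$ci_hi_cM[rows])
    ok <- !is.na(pk) & !is.na(lo) & !is.na(hi)
    out$peak_cM[rows] <- pk
    out$ci_lo_cM[rows] <- pmin(lo, hi)
    out$ci_hi_cM[rows] <- pmax(lo, hi)
    out$peak_cM[rows] <- pmin(pmax(pk, out$ci_lo_cM[rows]), out$ci_hi_cM[rows])
    out$projected[rows] <- ok
  }
  out$peak_cM[!out$projected] <- NA_real_
  out$ci_lo_cM[!out$projected] <- NA_real_
  out$ci_hi_cM[!out$projected] <- NA_real_
  new_qtl_intervals(out)
}

intervals_overlap <- function(a, b) {
  a$linkage_group == b$linkage_group &
    a$ci_lo_cM <= b$ci_hi_cM & b$ci_lo_cM <= a$ci_hi_cM
}

#' Classify loci by the stability of their effects
#'
#' Additive QTL (from the multi-environment genotype estimates) are checked
#' for overlap, on a common map, with QTL for the G x N and G x T
#' ecovalences: an additive QTL overlapping neither is a stable additive
#' locus; overlap with only the G x N (G x T) set marks an N-modulated
#' (trial-modulated) additive locus; overlap with both marks modulation by
#' both. Interaction QTL overlapping no additive QTL form
#' interaction-specific loci, merged by transitive overlap (a merged locus
#' with members of both interaction types is labelled by its majority type,
#' ties to G x N).
#'
#' @param additive,gxn,gxt `qtl_intervals` data frames on a common map.
#' @return A `locus_classification` data frame: locus_id, class,
#'   linkage_group, span, member_ids (comma-separated qtl ids).
#' @export
classify_locus_stability <- function(additive, gxn, gxt) {
  add <- as.data.frame(additive); gn <- as.data.frame(gxn); gt <- as.data.frame(gxt)
  # membership is exclusive: an interaction QTL overlapping several additive
  # QTL joins the one with the largest cM overlap (class uses any overlap)
  best_home <- function(q) {
    if (!nrow(add)) return(NA_integer_)
    ov <- intervals_overlap(q, add)
    if (!any(ov)) return(NA_integer_)
    len <- pmin(q$ci_hi_cM, add$ci_hi_cM) - pmax(q$ci_lo_cM, add$ci_lo_cM)
    len[!ov] <- -Inf
    which.max(len)
  }
  home_gn <- vapply(seq_len(nrow(gn)), function(j) best_home(gn[j, ]), 0L)
  home_gt <- vapply(seq_len(nrow(gt)), function(j) best_home(gt[j, ]), 0L)
  used_gn <- !is.na(home_gn); used_gt <- !is.na(home_gt)
  out <- list()
  for (i in seq_len(nrow(add))) {
    a <- add[i, ]
    ov_n <- if (nrow(gn)) which(intervals_overlap(a, gn)) else integer()
    ov_t <- if (nrow(gt)) which(intervals_overlap(a, gt)) else integer()
    cls <- if (length(ov_n) && length(ov_t)) "additive_N_and_T_modulated"
      else if (length(ov_n)) "additive_N_modulated"
      else if (length(ov_t)) "additive_T_modulated"
      else "stable_additive"
    mem_n <- which(home_gn == i); mem_t <- which(home_gt == i)
    members <- c(a$qtl_id, gn$qtl_id[mem_n], gt$qtl_id[mem_t])
    out[[length(out) + 1L]] <- data.frame(
      locus_id = sprintf("locus_%03d", length(out) + 1L), class = cls,
      linkage_group = a$linkage_group,
      span_lo_cM = min(c(a$ci_lo_cM, gn$ci_lo_cM[mem_n], gt$ci_lo_cM[mem_t])),
      span_hi_cM = max(c(a$ci_hi_cM, gn$ci_hi_cM[mem_n], gt$ci_hi_cM[mem_t])),
      member_ids = paste(members, collapse = ","),
      stringsAsFactors = FALSE)
  }
  # interaction QTL touching no additive locus: merge transitively
  rest <- rbind(
    if (any(!used_gn)) cbind(gn[!used_gn, , drop = FALSE], .type = "gxn"),
    if (any(!used_gt)) cbind(gt[!used_gt, , drop = FALSE], .type = "gxt"))
  if (!is.null(rest) && nrow(rest)) {
    comp <- seq_len(nrow(rest))
    for (i in seq_len(nrow(rest) - 1L)) {
      for (j in (i + 1L):nrow(rest)) {
        if (intervals_overlap(rest[i, ], rest[j, ])) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    for (cl in unique(comp)) {
      m <- rest[comp == cl, , drop = FALSE]
      n_gn <- sum(m$.type == "gxn"); n_gt <- sum(m$.type == "gxt")
      cls <- if (n_gn >= n_gt) "GxN_specific" else "GxT_specific"
      out[[length(out) + 1L]] <- data.frame(
        locus_id = sprintf("locus_%03d", length(out) + 1L), class = cls,
        linkage_group = m$linkage_group[1],
        span_lo_cM = min(m$ci_lo_cM), span_hi_cM = max(m$ci_hi_cM),
        member_ids = paste(m$qtl_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(), class = character(),
               linkage_group = character(), span_lo_cM = numeric(),
               span_hi_cM = numeric(), member_ids = character())
  rownames(res) <- NULL
  class(res) <- c("locus_classification", "data.frame")
  res
}

#' Count homoeologous gene pairs between A- and C-subgenome QTL
#'
#' For every pair of QTL on opposite subgenomes (chromosome labels starting
#' with A vs C), counts the homoeologous gene pairs whose A-subgenome gene
#' lies inside the A-QTL physical interval and whose C-subgenome gene lies
#' inside the C-QTL interval. Pairs with at least one such gene pair are
#' reported; favorable-allele frequencies at the two peak markers can be
#' attached from a lookup table.
#'
#' @param qtls A `qtl_intervals` data frame with physical intervals
#'   (`ci_lo_bp`, `ci_hi_bp`) and `linkage_group` labels A1--A10 / C1--C9.
#' @param gene_coords Data frame (gene_id, chromosome, start_bp, end_bp).
#' @param homoeolog_pairs Data frame (gene_A, gene_C).
#' @param allele_freqs Optional data frame (marker, favorable_freq).
#' @return A `homoeology_report` data frame (qtl_A, qtl_C,
#'   n_homoeologous_gene_pairs, optional freq columns). Genes on chromosomes
#'   absent from the QTL set are counted in attribute `"n_unplaced_genes"`.
#' @export
homoeologous_region_pairs <- function(qtls, gene_coords, homoeolog_pairs,
                                      allele_freqs = NULL) {
  sub <- substr(qtls$linkage_group, 1, 1)
  a_q <- qtls[sub == "A" & !is.na(qtls$ci_lo_bp), , drop = FALSE]
  c_q <- qtls[sub == "C" & !is.na(qtls$ci_lo_bp), , drop = FALSE]
  known_chr <- c(paste0("A", 1:10), paste0("C", 1:9))
  genes_in <- function(q) {
    gene_coords$gene_id[gene_coords$chromosome == q$linkage_group &
                          gene_coords$start_bp >= q$ci_lo_bp &
                          gene_coords$end_bp <= q$ci_hi_bp]
  }
  out <- list()
  for (i in seq_len(nrow(a_q))) {
    ga <- genes_in(a_q[i, ])
    if (!length(ga)) next
    for (j in seq_len(nrow(c_q))) {
      gc_ <- genes_in(c_q[j, ])
      if (!length(gc_)) next
      cnt <- sum(homoeolog_pairs$gene_A %in% ga & homoeolog_pairs$gene_C %in% gc_)
      if (cnt >= 1) {
        row <- data.frame(qtl_A = a_q$qtl_id[i], qtl_C = c_q$qtl_id[j],
                          n_homoeologous_gene_pairs = cnt,
                          stringsAsFactors = FALSE)
        if (!is.null(allele_freqs)) {
          row$favorable_freq_A <- allele_freqs$favorable_freq[
            match(a_q$peak_marker[i], allele_freqs$marker)]
          row$favorable_freq_C <- allele_freqs$favorable_freq[
            match(c_q$peak_marker[j], allele_freqs$marker)]
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(qtl_A = character(), qtl_C = character(),
               n_homoeologous_gene_pairs = integer())
  rownames(res) <- NULL
  class(res) <- c("homoeology_report", "data.frame")
  attr(res, "n_unplaced_genes") <-
    sum(!gene_coords$chromosome %in% known_chr)
  res
}
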