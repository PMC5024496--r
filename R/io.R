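# Text dialects: TSV for maps and QTL, CSV for matrices and phenotypes,
# UTF-8, "." decimal, "NA" missing token.

#' @rdname dataset_io
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  validate_genetic_map(map)
  map
}

#' @rdname dataset_io
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(individual = rownames(g$calls), g$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_genotypes <- function(path, map, population_kind = c("panel", "dh")) {
  population_kind <- match.arg(population_kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  storage.mode(calls) <- "integer"
  missing_m <- setdiff(colnames(calls), map$marker)
  if (length(missing_m)) {
    stop("genotype markers absent from map: ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  }
  map <- map[match(colnames(calls), map$marker), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  if (population_kind == "dh" && any(calls == 1, na.rm = TRUE)) {
    stop("heterozygous calls found in a declared DH population")
  }
  new_genotype_matrix(calls, map, population_kind)
}

#' @rdname dataset_io
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_phenotypes <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "trial", "n_level", "replicate", "trait", "value")
  if (!all(need %in% names(rec))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }
  if (!"block" %in% names(rec)) rec$block <- NA_integer_
  class(rec) <- c("phenotype_records", "data.frame")
  rec
}

#' @rdname dataset_io
#' @export
write_trial_design <- function(design, path) {
  jsonlite::write_json(list(trials = design$trials, nni = design$nni), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_trial_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_design(as.data.frame(x$trials),
               if (!is.null(x$nni) && length(x$nni)) as.data.frame(x$nni) else NULL)
}

#' Import genotypes from a VCF file
#'
#' Converts GT fields to allele dosage (0/1/2 of the ALT allele). Markers
#' must be biallelic; for a declared DH population heterozygous calls are
#' rejected. Marker ids default to the VCF ID column (CHROM_POS when
#' missing).
#'
#' @param path VCF path (uncompressed or gzipped).
#' @param map A `genetic_map` covering the VCF markers.
#' @param population_kind "panel" or "dh".
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path, map, population_kind = c("panel", "dh")) {
  population_kind <- match.arg(population_kind)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  noid <- is.na(ids) | ids == "." | ids == ""
  if (any(noid)) {
    ids[noid] <- paste(v@fix[noid, "CHROM"], v@fix[noid, "POS"], sep = "_")
  }
  dosage <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_integer_)
      sum(as.integer(al))
    }, 0L)
  }
  calls <- t(apply(gt, 1, dosage))
  dimnames(calls) <- list(ids, colnames(gt))
  calls <- t(calls)
  if (population_kind == "dh" && any(calls == 1, na.rm = TRUE)) {
    stop("heterozygous calls found in a declared DH population")
  }
  keep <- colnames(calls) %in% map$marker
  if (!all(keep)) {
    stop("VCF markers absent from map: ",
         paste(utils::head(colnames(calls)[!keep], 5), collapse = ", "))
  }
  mp <- map[match(colnames(calls), map$marker), , drop = FALSE]
  rownames(mp) <- NULL
  class(mp) <- c("genetic_map", "data.frame")
  new_genotype_matrix(calls, mp, population_kind)
}

#' Read and cross-validate a full dataset
#'
#' @name dataset_io
#' @param paths Named list/vector with entries `genotypes` (CSV or VCF),
#'   `map` (TSV), `phenotypes` (CSV) and `design` (JSON).
#' @param population_kind "panel" or "dh".
#' @param map,g,records,design,path,... See individual functions.
#' @return `load_dataset()` returns a list (genotypes, map, phenotypes,
#'   design) after checking that phenotype genotype ids occur in the
#'   genotype matrix and that trials match the design.
#' @export
load_dataset <- function(paths, population_kind = c("panel", "dh")) {
  population_kind <- match.arg(population_kind)
  map <- read_genetic_map(paths[["map"]])
  g <- if (grepl("\\.vcf(\\.gz)?$", paths[["genotypes"]])) {
    read_genotypes_vcf(paths[["genotypes"]], map, population_kind)
  } else {
    read_genotypes(paths[["genotypes"]], map, population_kind)
  }
  rec <- read_phenotypes(paths[["phenotypes"]])
  design <- read_trial_design(paths[["design"]])
  unknown <- setdiff(unique(rec$genotype), rownames(g$calls))
  if (length(unknown)) {
    stop("phenotype rows reference unknown genotype(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  unknown_t <- setdiff(unique(rec$trial), design$trials$trial)
  if (length(unknown_t)) {
    stop("phenotype rows reference unknown trial(s): ",
         paste(unknown_t, collapse = ", "))
  }
  list(genotypes = g, map = g$map, phenotypes = rec, design = design)
}

#' Pipeline configuration
#'
#' Thresholds and switches for [run_pipeline()], all defaulting to the
#' values used throughout the package: MAF 0.05, missingness 0.10, FDR
#' 0.15, LD r2 0.2, linkage alpha 0.05, 3 environment clusters on 5 PCs.
#'
#' @param traits Traits to analyse.
#' @param maf_min,missing_max Marker QC thresholds.
#' @param fdr FDR significance threshold for association scans.
#' @param ld_r2 r2 threshold for LD extent and SNP clustering.
#' @param linkage_alpha Genome-wide level for linkage scans.
#' @param k_clusters,n_pcs Environment clustering settings.
#' @param dataset_tags Which of the four mapping datasets to run.
#' @param scan_method "gwas" (mixed-model scan) or "linkage" (DH interval
#'   mapping; requires a DH population).
#' @param n_permutations Permutations for linkage thresholds.
#' @param seed Seed threaded to every stochastic stage.
#' @return A `pipeline_config` list; `as_pipeline_config()` validates and
#'   round-trips from JSON.
#' @export
pipeline_config <- function(traits = "SY", maf_min = 0.05, missing_max = 0.10,
                            fdr = 0.15, ld_r2 = 0.2, linkage_alpha = 0.05,
                            k_clusters = 3, n_pcs = 5,
                            dataset_tags = c("mean_env", "multi_env",
                                             "ecov_GxN", "ecov_GxT"),
                            scan_method = c("gwas", "linkage"),
                            n_permutations = 1000, seed = 1L) {
  scan_method <- match.arg(scan_method)
  cfg <- list(traits = traits, maf_min = maf_min, missing_max = missing_max,
              fdr = fdr, ld_r2 = ld_r2, linkage_alpha = linkage_alpha,
              k_clusters = k_clusters, n_pcs = n_pcs,
              dataset_tags = dataset_tags, scan_method = scan_method,
              n_permutations = n_permutations, seed = as.integer(seed))
  stopifnot(cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$missing_max >= 0, cfg$missing_max <= 1,
            cfg$fdr > 0, cfg$fdr <= 1, cfg$ld_r2 > 0, cfg$ld_r2 < 1,
            cfg$linkage_alpha > 0, cfg$linkage_alpha < 1,
            cfg$k_clusters >= 1, cfg$n_pcs >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param x A list (e.g. parsed from JSON) of configuration fields.
#' @export
as_pipeline_config <- function(x) {
  do.call(pipeline_config, x[intersect(names(x), names(formals(pipeline_config)))])
}

#' Run the full stability-QTL analysis
#'
#' Executes the analysis end to end on one population: marker QC, kinship
#' and LD, single-environment fits and adjusted means, the
#' multi-environment fit with heritabilities, derived component traits,
#' G x N and G x T ecovalences, association (or linkage) scans on the four
#' mapping datasets, LD-based confidence intervals, locus-stability
#' classification, environment clustering and QTL-by-cluster consistency.
#'
#' @param genotypes A `genotype_matrix`.
#' @param records A `phenotype_records` data frame.
#' @param design A `trial_design`.
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, stage outputs and a run
#'   manifest (JSON with seed, thresholds and per-stage row counts) are
#'   written there.
#' @return A result bundle (named list per stage).
#' @export
run_pipeline <- function(genotypes, records, design, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, config = unclass(config), stages = list())
  bundle <- list(config = config)
  log_stage <- function(name, nrows) {
    manifest$stages[[name]] <<- list(rows = nrows)
    message(sprintf("[stabQTL] %-22s %s", name, paste(nrows, collapse = " x ")))
  }

  g <- filter_markers(genotypes, config$maf_min, config$missing_max)
  log_stage("qc", dim(g$calls))
  K <- ibs_kinship(g)
  log_stage("kinship", dim(K))
  bundle$genotypes <- g
  bundle$kinship <- K

  records <- derive_component_traits(records)
  traits <- intersect(config$traits, unique(records$trait))
  bundle$records <- records

  bundle$per_trait <- list()
  per_env_qtls_all <- list()
  for (tr in traits) {
    res <- list()
    spec1 <- model_spec("multi_env_1", tr)
    vc1 <- fit_variance_components(records, spec1, "mom")
    res$varcomp_multi <- vc1
    res$h2_multi <- heritability(vc1, "multi_2")
    res$estimates_multi <- genotype_estimates(records, spec1, "blup", vc = vc1)

    # per trial x N adjusted means (single-environment model)
    env_means <- list()
    h2_single <- list()
    for (trl in unique(records$trial)) {
      for (nl in unique(records$n_level)) {
        sub <- records[records$trial == trl & records$n_level == nl, ]
        if (!nrow(sub[sub$trait == tr & !is.na(sub$value), ])) next
        spec6 <- model_spec("single_env_6", tr)
        est <- genotype_estimates(sub, spec6, "adjusted_mean")
        env_means[[paste(trl, nl, sep = "_")]] <- est
        h2_single[[paste(trl, nl, sep = "_")]] <-
          tryCatch(heritability(fit_variance_components(sub, spec6, "mom"),
                                "single_7")$h2,
                   error = function(e) NA_real_)
      }
    }
    res$env_means <- env_means
    res$h2_single <- unlist(h2_single)

    ec_n <- ecovalence(two_way_means(records, tr, "n_level"))
    ec_t <- ecovalence(two_way_means(records, tr, "trial"))
    res$ecovalence_GxN <- ec_n
    res$ecovalence_GxT <- ec_t

    datasets <- list(
      multi_env = res$estimates_multi,
      ecov_GxN = ec_n,
      ecov_GxT = ec_t)
    scans <- list(); intervals <- list()
    for (tag in intersect(names(datasets), config$dataset_tags)) {
      if (config$scan_method == "gwas") {
        sc <- mlm_scan(g, datasets[[tag]], K, min_maf = config$maf_min)
        scans[[tag]] <- sc
        intervals[[tag]] <- build_gwas_qtl_intervals(
          sc, g, q_threshold = config$fdr, r2_join = config$ld_r2,
          trait = tr, dataset_tag = tag)
      } else {
        qi <- dh_interval_mapping(
          g, datasets[[tag]], n_permutations = config$n_permutations,
          alpha = config$linkage_alpha, trait = tr, dataset_tag = tag,
          seed = config$seed)
        intervals[[tag]] <- qi
      }
    }
    if ("mean_env" %in% config$dataset_tags && config$scan_method == "gwas") {
      per_env <- list()
      for (e in names(env_means)) {
        sc <- mlm_scan(g, env_means[[e]], K, min_maf = config$maf_min)
        per_env[[e]] <- build_gwas_qtl_intervals(
          sc, g, q_threshold = config$fdr, r2_join = config$ld_r2,
          trait = tr, dataset_tag = "mean_env")
      }
      res$per_env_intervals <- per_env
      per_env_qtls_all[[tr]] <- per_env
    }
    res$scans <- scans
    res$intervals <- intervals
    res$classification <- classify_locus_stability(
      if (!is.null(intervals$multi_env)) intervals$multi_env else new_qtl_intervals(NULL),
      if (!is.null(intervals$ecov_GxN)) intervals$ecov_GxN else new_qtl_intervals(NULL),
      if (!is.null(intervals$ecov_GxT)) intervals$ecov_GxT else new_qtl_intervals(NULL))
    bundle$per_trait[[tr]] <- res
    log_stage(paste0("trait_", tr),
              c(sum(vapply(intervals, nrow, 0L)), nrow(res$classification)))
  }

  clust_traits <- traits
  bundle$env_clustering <- tryCatch(
    cluster_environments(records, clust_traits, k = config$k_clusters,
                         n_pcs = min(config$n_pcs, length(clust_traits))),
    error = function(e) NULL)
  if (!is.null(bundle$env_clustering)) {
    log_stage("env_clustering", bundle$env_clustering$k)
    bundle$consistency <- lapply(per_env_qtls_all, qtl_cluster_consistency,
                                 clustering = bundle$env_clustering)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(K), file.path(out_dir, "kinship.csv"))
    for (tr in names(bundle$per_trait)) {
      pt <- bundle$per_trait[[tr]]
      for (tag in names(pt$intervals)) {
        write_qtl_intervals(pt$intervals[[tag]],
                            file.path(out_dir, sprintf("qtl_%s_%s.tsv", tr, tag)))
      }
      utils::write.csv(rbind(as.data.frame(pt$ecovalence_GxN),
                             as.data.frame(pt$ecovalence_GxT)),
                       file.path(out_dir, sprintf("ecovalence_%s.csv", tr)),
                       row.names = FALSE)
      utils::write.table(pt$classification,
                         file.path(out_dir, sprintf("loci_%s.tsv", tr)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle$manifest <- manifest
  bundle
}

#' Write QTL intervals as TSV or BED
#'
#' TSV carries 1-based inclusive physical coordinates; BED is 0-based
#' half-open.
#'
#' @param qtls A `qtl_intervals` data frame.
#' @param path Output path.
#' @param format "tsv" or "bed".
#' @export
write_qtl_intervals <- function(qtls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(qtls), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ok <- !is.na(qtls$ci_lo_bp) & !is.na(qtls$ci_hi_bp)
    bed <- data.frame(chrom = qtls$linkage_group[ok],
                      start = as.integer(qtls$ci_lo_bp[ok]) - 1L,
                      end = as.integer(qtls$ci_hi_bp[ok]),
                      name = qtls$qtl_id[ok])
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
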