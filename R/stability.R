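#' Genotype-by-treatment mean matrix
#'
#' Builds the two-way table Y (genotypes x treatments) that Wricke
#' ecovalence operates on. Plot values are averaged over replicates first,
#' then over trials when the treatment axis is the N level; when the axis is
#' the trial, values are averaged over replicates and both N levels.
#'
#' @param records A `phenotype_records` data frame.
#' @param trait_code Trait to tabulate.
#' @param treatment_axis "n_level" or "trial".
#' @param missing_policy "drop_genotype" removes genotypes with empty
#'   cells (complete-case); "impute_column_mean" fills empty cells with
#'   the treatment mean.
#' @return A `two_way_means` object: matrix `Y`, `treatment_axis`, and a
#'   `dropped` attribute listing removed genotypes.
#' @export
two_way_means <- function(records, trait_code,
                          treatment_axis = c("n_level", "trial"),
                          missing_policy = c("drop_genotype",
                                             "impute_column_mean")) {
  treatment_axis <- match.arg(treatment_axis)
  missing_policy <- match.arg(missing_policy)
  d <- records[records$trait == trait_code & !is.na(records$value), ,
               drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait ", trait_code)
  # replicate means within genotype x trial x N first
  cellm <- stats::aggregate(value ~ genotype + trial + n_level, data = d, FUN = mean)
  trt <- cellm[[treatment_axis]]
  Y <- tapply(cellm$value, list(cellm$genotype, trt), mean)
  dropped <- character()
  if (anyNA(Y)) {
    if (missing_policy == "drop_genotype") {
      bad <- rowSums(is.na(Y)) > 0
      dropped <- rownames(Y)[bad]
      Y <- Y[!bad, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(Y))) {
        Y[is.na(Y[, j]), j] <- mean(Y[, j], na.rm = TRUE)
      }
    }
  }
  if (nrow(Y) == 0) stop("no genotype with complete treatment coverage")
  structure(list(Y = Y, treatment_axis = treatment_axis, trait_code = trait_code,
                 dropped = dropped),
            class = "two_way_means")
}

#' Wricke ecovalence
#'
#' For each genotype i, W_i = sum_j (Y_ij - Y_i. - Y_.j + Y_..)^2 -- the
#' genotype's contribution to the genotype-by-treatment interaction sum of
#' squares of the two-way mean table. Low W_i marks a stable genotype.
#' Computed over the two N conditions this is the G x N stability model;
#' over trials, the G x T model.
#'
#' @param means A `two_way_means` object (or a plain numeric matrix, in
#'   which case `treatment_axis` defaults to "trial").
#' @return An `ecovalence_table` data frame (genotype, W, model_tag) with
#'   the total interaction sum of squares as attribute `"interaction_ss"`.
#' @export
ecovalence <- function(means) {
  if (is.matrix(means)) {
    means <- structure(list(Y = means, treatment_axis = "trial",
                            trait_code = NA_character_),
                       class = "two_way_means")
  }
  stopifnot(inherits(means, "two_way_means"))
  Y <- means$Y
  if (ncol(Y) < 2) warning("single treatment column: all ecovalences are 0")
  centered <- sweep(sweep(Y, 1, rowMeans(Y)), 2, colMeans(Y)) + mean(Y)
  W <- rowSums(centered^2)
  tag <- if (means$treatment_axis == "n_level") "GxN" else "GxT"
  gids <- rownames(Y)
  if (is.null(gids)) gids <- sprintf("G%03d", seq_len(nrow(Y)))
  out <- data.frame(genotype = gids, W = as.numeric(W),
                    model_tag = tag, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "interaction_ss") <- sum(centered^2)
  attr(out, "trait_code") <- means$trait_code
  class(out) <- c("ecovalence_table", "data.frame")
  out
}

#' Classify nitrogen stress from the nitrogen nutrition index
#'
#' Plants are considered N-stressed below an NNI of 0.90 at bolting, and
#' intensely stressed below 0.75. Boundaries follow the strict "below"
#' rule: exactly 0.90 is no stress, exactly 0.75 is moderate.
#'
#' @param nni Numeric vector of NNI values (> 0).
#' @return Character vector in {"none", "moderate", "intense"}.
#' @export
classify_n_stress <- function(nni) {
  if (any(!is.finite(nni) | nni <= 0)) stop("NNI values must be positive")
  ifelse(nni < 0.75, "intense", ifelse(nni < 0.90, "moderate", "none"))
}

#' Derive composite traits from measured ones
#'
#' Adds seed number per square metre, SN = SY x 100000 / TSW (SY in t/ha,
#' TSW in g), and the oil-to-protein ratio, OPr = O / Pr, wherever the
#' input traits are present on matching plot keys. Missing or zero-valued
#' denominators propagate to missing outputs; the affected keys are listed
#' in the attribute `"derivation_issues"`.
#'
#' @param records A `phenotype_records` data frame.
#' @return The records with SN and/or OPr rows appended.
#' @export
derive_component_traits <- function(records) {
  key <- c("genotype", "trial", "n_level", "replicate")
  issues <- list()
  derive <- function(num_code, den_code, out_code, scale) {
    num <- records[records$trait == num_code, c(key, "block", "value")]
    den <- records[records$trait == den_code, c(key, "value")]
    if (nrow(num) == 0 || nrow(den) == 0) return(NULL)
    m <- merge(num, den, by = key, suffixes = c("_num", "_den"))
    bad_den <- !is.na(m$value_den) & m$value_den == 0
    if (any(bad_den)) {
      issues[[out_code]] <<- m[bad_den, key]
      m$value_den[bad_den] <- NA_real_
    }
    data.frame(genotype = m$genotype, trial = m$trial, n_level = m$n_level,
               replicate = m$replicate, block = m$block, trait = out_code,
               value = scale * m$value_num / m$value_den,
               stringsAsFactors = FALSE)
  }
  sn <- derive("SY", "TSW", "SN", 1e5)
  opr <- derive("O", "Pr", "OPr", 1)
  out <- rbind(records[names(records)], sn, opr)
  rownames(out) <- NULL
  class(out) <- c("phenotype_records", "data.frame")
  attr(out, "derivation_issues") <- issues
  out
}
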