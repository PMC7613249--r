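# Instrument construction: significance filtering, greedy LD clumping,
# weighted score computation and instrument-strength diagnostics.

#' Greedy LD clumping of variant associations
#'
#' Drops variants at or above `p_threshold`, then repeatedly takes the
#' smallest-p remaining variant as an index and removes every variant in LD
#' with it at `r2 >= r2_threshold`. Ties on p break lexicographically by
#' variant id, so the selection is deterministic and invariant to row order.
#'
#' @param assocs Data frame with columns `variant_id`, `p` (and typically
#'   `beta`, `se`).
#' @param ld Square symmetric r-squared matrix with unit diagonal, dimnames
#'   matching `variant_id`.
#' @param p_threshold Significance threshold (default genome-wide 5e-8).
#' @param r2_threshold LD ceiling between retained variants (default 0.01).
#' @return Character vector of selected variant ids, in selection order.
#' @export
clump_variants <- function(assocs, ld, p_threshold = 5e-8,
                           r2_threshold = 0.01) {
  ids <- assocs$variant_id
  if (is.null(rownames(ld))) dimnames(ld) <- list(ids, ids)
  if (!isSymmetric(unname(ld), tol = 1e-8)) {
    abort("`ld` must be symmetric.", class = "lvmr_data_error")
  }
  keep <- assocs$p < p_threshold
  pool <- assocs[keep, c("variant_id", "p")]
  pool <- pool[order(pool$p, pool$variant_id), ]
  selected <- character(0)
  while (nrow(pool) > 0) {
    idx <- pool$variant_id[1]
    selected <- c(selected, idx)
    r2 <- ld[idx, pool$variant_id]
    pool <- pool[r2 < r2_threshold, , drop = FALSE]
  }
  selected
}

#' Define a weighted genetic risk score
#'
#' @param variant_ids Variant identifiers (no duplicates).
#' @param weights Per-allele weights (the variant-exposure betas).
#' @param p_threshold,r2_threshold,excluded_ids Provenance of the selection.
#' @return A list of class `grs_model`.
#' @export
grs_model <- function(variant_ids, weights, p_threshold = NA_real_,
                      r2_threshold = NA_real_, excluded_ids = character(0)) {
  if (anyDuplicated(variant_ids)) {
    abort("duplicate variant ids in GRS model.", class = "lvmr_data_error")
  }
  if (length(variant_ids) != length(weights) || any(!is.finite(weights))) {
    abort("weights must be finite and match variant ids.",
          class = "lvmr_data_error")
  }
  structure(list(variant_ids = as.character(variant_ids),
                 weights = as.numeric(weights),
                 provenance = list(p_threshold = p_threshold,
                                   r2_threshold = r2_threshold,
                                   excluded_ids = excluded_ids)),
            class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("<grs_model> %d variants (%d excluded upstream)\n",
              length(x$variant_ids), length(x$provenance$excluded_ids)))
  invisible(x)
}

#' Compute weighted genetic risk scores
#'
#' `score_i = sum_j weight_j * dosage_ij` over the model's variants. Missing
#' dosages are mean-imputed per variant (with a warning) unless
#' `na_action = "complete"` which drops individuals with any missing dosage.
#'
#' @param dosages n x m numeric dosage matrix with column names matching the
#'   model's variant ids (order-free; columns are matched by name).
#' @param model A [grs_model()].
#' @param na_action `"mean_impute"` or `"complete"`.
#' @return Numeric score vector of length n (NA for dropped individuals
#'   under `"complete"`).
#' @export
compute_grs <- function(dosages, model, na_action = c("mean_impute", "complete")) {
  na_action <- match.arg(na_action)
  if (is.null(colnames(dosages))) {
    if (ncol(dosages) != length(model$variant_ids)) {
      abort("dosage columns do not match the GRS model.",
            class = "lvmr_data_error")
    }
    colnames(dosages) <- model$variant_ids
  }
  missing_cols <- setdiff(model$variant_ids, colnames(dosages))
  if (length(missing_cols) > 0) {
    abort(paste0("dosage matrix lacks model variants: ",
                 paste(utils::head(missing_cols, 5), collapse = ", ")),
          class = "lvmr_data_error")
  }
  G <- dosages[, model$variant_ids, drop = FALSE]
  if (anyNA(G)) {
    if (na_action == "mean_impute") {
      n_imp <- sum(is.na(G))
      warn(sprintf("mean-imputed %d missing dosage value(s).", n_imp))
      mu <- colMeans(G, na.rm = TRUE)
      for (j in seq_len(ncol(G))) {
        nas <- is.na(G[, j])
        if (any(nas)) G[nas, j] <- mu[j]
      }
    } else {
      bad <- rowSums(is.na(G)) > 0
      G[bad, ] <- NA_real_
    }
  }
  drop(G %*% model$weights)
}

#' Instrument strength: variance explained and F statistic
#'
#' Simple regression of the measured exposure on the score:
#' `R2` with `F = (n - 2) * R2 / (1 - R2)`; instruments with F <= 10 are
#' flagged as weak.
#'
#' @param exposure,scores Equal-length numeric vectors (n >= 3).
#' @return One-row tibble: `r2`, `f_stat`, `n`, `weak_instrument`.
#' @export
variance_explained <- function(exposure, scores) {
  ok <- stats::complete.cases(exposure, scores)
  exposure <- exposure[ok]; scores <- scores[ok]
  n <- length(exposure)
  stopifnot(n >= 3, length(scores) == n)
  if (sd(scores) == 0) {
    abort("scores have zero variance: degenerate instrument.",
          class = "lvmr_degenerate_error")
  }
  r <- cor(exposure, scores)
  r2 <- r^2
  f <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  tibble::tibble(r2 = r2, f_stat = f, n = n, weak_instrument = f <= 10)
}

#' Pairwise Pearson correlation between genetic risk scores
#'
#' @param score_sets Named list of >= 2 equal-length numeric vectors.
#' @return List with symmetric matrices `r` (unit diagonal) and `p`
#'   (two-sided, from the t transform), plus a tidy tibble `pairs`.
#' @export
grs_correlation <- function(score_sets) {
  stopifnot(length(score_sets) >= 2)
  lens <- lengths(score_sets)
  if (length(unique(lens)) != 1) {
    abort("score vectors must have equal length.", class = "lvmr_data_error")
  }
  if (any(vapply(score_sets, sd, numeric(1)) == 0)) {
    abort("constant score vector: correlation undefined.",
          class = "lvmr_degenerate_error")
  }
  m <- do.call(cbind, score_sets)
  n <- nrow(m)
  r <- cor(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- tibble::tibble(
    score_a = colnames(m)[idx[, 1]], score_b = colnames(m)[idx[, 2]],
    r = r[idx], p = p[idx]
  )
  list(r = r, p = p, pairs = pairs)
}

#' Restrict a GRS model by excluding variants
#'
#' Used for the pleiotropy-restricted sensitivity instrument: listed variants
#' are removed (order of the remainder preserved) and recorded in the model's
#' provenance.
#'
#' @param model A [grs_model()].
#' @param exclusion_ids Character vector of variant ids to drop.
#' @return A new `grs_model`.
#' @export
restrict_grs <- function(model, exclusion_ids) {
  keep <- !(model$variant_ids %in% exclusion_ids)
  if (sum(keep) < 2) {
    abort("fewer than 2 variants remain after exclusion.",
          class = "lvmr_instrument_too_small")
  }
  grs_model(model$variant_ids[keep], model$weights[keep],
            p_threshold = model$provenance$p_threshold,
            r2_threshold = model$provenance$r2_threshold,
            excluded_ids = c(model$provenance$excluded_ids,
                             intersect(exclusion_ids, model$variant_ids)))
}

#' Serialize a GRS model as a score file (TSV)
#'
#' Standard polygenic-score layout: variant_id, effect_allele, weight.
#' @param model A `grs_model`.
#' @param path Output path.
#' @param effect_alleles Optional character vector of effect alleles.
#' @export
write_grs_model <- function(model, path, effect_alleles = NULL) {
  df <- data.frame(variant_id = model$variant_ids,
                   effect_allele = effect_alleles %||%
                     rep(NA_character_, length(model$variant_ids)),
                   weight = model$weights)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
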