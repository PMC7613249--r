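# Deterministic lipid and covariate preprocessing: unit conversion, Friedewald
# LDL derivation, statin and antihypertensive adjustments, covariate transforms.

# mg/dl per mmol/l; cholesterol molar mass 386.65 g/mol, triglyceride
# (average) factor 88.57 as used throughout clinical chemistry.
CHOL_MGDL_PER_MMOL <- 38.67
TG_MGDL_PER_MMOL <- 88.57

#' Convert lipid concentrations between mmol/l and mg/dl
#'
#' Cholesterol converts at 38.67 mg/dl per mmol/l, triglycerides at 88.57.
#' The returned value is unrounded; use [round_presentation()] when a printed
#' integer increment (e.g. "per 39 mg/dl") is wanted.
#'
#' @param value Non-negative concentration (scalar or vector).
#' @param analyte `"cholesterol"` or `"triglyceride"`.
#' @param direction `"mmol_to_mgdl"` or `"mgdl_to_mmol"`.
#' @return Converted concentration, same length as `value`.
#' @examples
#' convert_units(1, "cholesterol", "mmol_to_mgdl")    # 38.67
#' round_presentation(convert_units(1.02, "triglyceride", "mmol_to_mgdl")) # 90
#' @export
convert_units <- function(value,
                          analyte = c("cholesterol", "triglyceride"),
                          direction = c("mmol_to_mgdl", "mgdl_to_mmol")) {
  analyte <- match.arg(analyte)
  direction <- match.arg(direction)
  if (any(value < 0, na.rm = TRUE)) {
    abort("`value` must be non-negative.", class = "lvmr_domain_error")
  }
  factor <- if (analyte == "cholesterol") CHOL_MGDL_PER_MMOL else TG_MGDL_PER_MMOL
  if (direction == "mmol_to_mgdl") value * factor else value / factor
}

#' Round a value half-up to the nearest integer for presentation
#'
#' Internal computation is always unrounded; this is only for printing
#' increments such as 38.67 -> 39.
#' @param x Numeric vector.
#' @export
round_presentation <- function(x) floor(x + 0.5)

#' Friedewald LDL cholesterol estimate
#'
#' LDL = total cholesterol - HDL - triglycerides / 5 (all mg/dl), valid only
#' when triglycerides do not exceed `tg_ceiling` (default 155 mg/dl). Above
#' the ceiling, or when the computed LDL is negative, `NA` is returned.
#'
#' @param total_chol,hdl,triglycerides Concentrations in mg/dl (vectors).
#' @param tg_ceiling Triglyceride validity ceiling in mg/dl, > 0.
#' @return LDL in mg/dl, `NA` where not derivable.
#' @export
friedewald_ldl <- function(total_chol, hdl, triglycerides, tg_ceiling = 155) {
  if (!is.numeric(tg_ceiling) || length(tg_ceiling) != 1 || tg_ceiling <= 0) {
    abort("`tg_ceiling` must be a single positive number.",
          class = "lvmr_config_error")
  }
  if (any(c(total_chol, hdl, triglycerides) < 0, na.rm = TRUE)) {
    abort("lipid concentrations must be non-negative.",
          class = "lvmr_domain_error")
  }
  ldl <- total_chol - hdl - triglycerides / 5
  ldl[triglycerides > tg_ceiling] <- NA_real_
  n_neg <- sum(ldl < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warn(sprintf("%d negative Friedewald LDL value(s) set to missing.", n_neg))
    ldl[!is.na(ldl) & ldl < 0] <- NA_real_
  }
  ldl
}

#' Rescale measured LDL to estimated untreated LDL for statin users
#'
#' Statin users' measured LDL is multiplied by `factor` (default 1.43) to
#' approximate the untreated concentration; non-users are unchanged.
#'
#' @param ldl LDL in mg/dl (vector, `NA` allowed).
#' @param on_statin Logical vector.
#' @param factor Multiplicative adjustment, > 0.
#' @export
adjust_ldl_for_statin <- function(ldl, on_statin, factor = 1.43) {
  if (!is.numeric(factor) || factor <= 0) {
    abort("`factor` must be positive.", class = "lvmr_config_error")
  }
  if (any(ldl < 0, na.rm = TRUE)) {
    abort("`ldl` must be non-negative.", class = "lvmr_domain_error")
  }
  ifelse(as.logical(on_statin), ldl * factor, ldl)
}

#' Adjust systolic blood pressure for antihypertensive use
#'
#' Adds `increment` (default 15 mm Hg) to treated individuals.
#' @param sbp Systolic blood pressure, mm Hg, > 0.
#' @param on_antihypertensive Logical vector.
#' @param increment mm Hg to add for treated individuals.
#' @export
adjust_sbp <- function(sbp, on_antihypertensive, increment = 15) {
  if (any(sbp <= 0, na.rm = TRUE)) {
    abort("`sbp` must be positive.", class = "lvmr_domain_error")
  }
  ifelse(as.logical(on_antihypertensive), sbp + increment, sbp)
}

#' Du Bois body surface area
#'
#' BSA = 0.007184 * height^0.725 * weight^0.425 with height in cm and weight
#' in kg.
#' @param height_cm,weight_kg Positive numerics.
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE)) {
    abort("height and weight must be positive.", class = "lvmr_domain_error")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Build the numeric covariate frame used by the regression models
#'
#' Applies natural-log transforms to BMI and HbA1c, `log(met + offset)` to
#' MET-minutes per week, encodes sex / smoking / cardiovascular disease as
#' numeric, and attaches a complete-case indicator. Column order is fixed:
#' age, sex, log_bmi, bsa, sbp_adj, log_met, smoking, log_hba1c, cvd,
#' pc1..pc5 (principal components kept only if present in `data`).
#'
#' @param data Data frame with columns `age`, `sex` (`"male"`/`"female"` or
#'   0/1), `bmi`, `bsa`, `sbp_adj`, `met_min_week`, `smoking` (`"never"`,
#'   `"former"`, `"current"` or 0/1/2), `hba1c`, `cvd_present`, and optionally
#'   `pc1`..`pc5`.
#' @param met_offset Offset added to MET minutes before the log (default 1),
#'   so zero activity maps to 0.
#' @return A tibble of numeric covariates plus a logical `complete` column.
#' @export
build_covariate_frame <- function(data, met_offset = 1) {
  if (nrow(data) == 0) abort("`data` is empty.", class = "lvmr_data_error")
  enc_sex <- function(x) {
    if (is.character(x) || is.factor(x)) as.numeric(as.character(x) == "male") else as.numeric(x)
  }
  enc_smoke <- function(x) {
    if (is.character(x) || is.factor(x)) {
      unname(c(never = 0, former = 1, current = 2)[as.character(x)])
    } else as.numeric(x)
  }
  out <- tibble::tibble(
    age = as.numeric(data$age),
    sex = enc_sex(data$sex),
    log_bmi = log(as.numeric(data$bmi)),
    bsa = as.numeric(data$bsa),
    sbp_adj = as.numeric(data$sbp_adj),
    log_met = log(as.numeric(data$met_min_week) + met_offset),
    smoking = enc_smoke(data$smoking),
    log_hba1c = log(as.numeric(data$hba1c)),
    cvd = as.numeric(data$cvd_present)
  )
  for (pc in paste0("pc", 1:5)) {
    if (pc %in% names(data)) out[[pc]] <- as.numeric(data[[pc]])
  }
  all_missing <- names(out)[vapply(out, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing) > 0) {
    abort(paste0("covariate column(s) entirely missing: ",
                 paste(all_missing, collapse = ", ")),
          class = "lvmr_data_error")
  }
  out$complete <- complete.cases(out)
  out
}

#' Preprocess a raw phenotype table into analysis-ready lipids
#'
#' Resolves one LDL value per participant with provenance (`direct`,
#' `friedewald` or `missing`), applies the statin adjustment to LDL and the
#' antihypertensive adjustment to systolic blood pressure, and returns a tidy
#' tibble ready to join with genetic scores.
#'
#' @param data Data frame with columns `total_chol`, `hdl`, `triglycerides`,
#'   optionally `ldl_direct`, `on_statin`, `sbp`, `on_antihypertensive`
#'   (all concentrations in mg/dl).
#' @param tg_ceiling Friedewald triglyceride ceiling (mg/dl).
#' @param statin_factor Multiplicative statin adjustment for LDL.
#' @param sbp_increment Additive antihypertensive adjustment (mm Hg).
#' @return The input tibble with added columns `ldl`, `ldl_source`,
#'   `ldl_statin_adjusted`, and `sbp_adj` when blood pressure is present.
#' @export
preprocess_lipids <- function(data, tg_ceiling = 155, statin_factor = 1.43,
                              sbp_increment = 15) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  ldl_direct <- if ("ldl_direct" %in% names(data)) data$ldl_direct else rep(NA_real_, n)
  fw <- friedewald_ldl(data$total_chol, data$hdl, data$triglycerides,
                       tg_ceiling = tg_ceiling)
  ldl <- ifelse(!is.na(ldl_direct), ldl_direct, fw)
  source <- dplyr::case_when(
    !is.na(ldl_direct) ~ "direct",
    !is.na(fw) ~ "friedewald",
    TRUE ~ "missing"
  )
  on_statin <- if ("on_statin" %in% names(data)) as.logical(data$on_statin) else rep(FALSE, n)
  data$ldl <- adjust_ldl_for_statin(ldl, on_statin, factor = statin_factor)
  data$ldl_source <- source
  data$ldl_statin_adjusted <- on_statin & !is.na(ldl)
  if ("sbp" %in% names(data)) {
    on_aht <- if ("on_antihypertensive" %in% names(data)) {
      as.logical(data$on_antihypertensive)
    } else rep(FALSE, n)
    data$sbp_adj <- adjust_sbp(data$sbp, on_aht, increment = sbp_increment)
  }
  data
}
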