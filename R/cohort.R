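#' Classify 12-month weight-loss success
#'
#' Categories follow the long-term weight-loss convention: unsuccessful
#' (US) below 3% of baseline weight lost, moderately successful (MS) for
#' 3-10% (both boundaries inclusive), very successful (VS) above 10%.
#' Negative values (weight gain) are US.
#'
#' @param weight_loss_pct percent of baseline weight lost at 12 months
#'   (positive = loss); vectorized.
#' @return character vector of `"US"`, `"MS"`, `"VS"` (NA stays NA).
#' @export
classify_success <- function(weight_loss_pct) {
  out <- rep(NA_character_, length(weight_loss_pct))
  ok <- !is.na(weight_loss_pct)
  out[ok & weight_loss_pct < 3] <- "US"
  out[ok & weight_loss_pct >= 3 & weight_loss_pct <= 10] <- "MS"
  out[ok & weight_loss_pct > 10] <- "VS"
  out
}

#' Dietary adherence from on-diet recalls
#'
#' Percentage of total kcal coming from non-restricted foods: 100 minus the
#' mean of the restricted component's %kcal over the available on-diet
#' recalls (3, 6 and 12 months). Missing recalls are dropped from the mean;
#' if all are missing the result is NA.
#'
#' @param recall_pct_restricted numeric vector of on-diet restricted-component
#'   %kcal values (typically length 3).
#' @return adherence in percent of kcal.
#' @export
dietary_adherence <- function(recall_pct_restricted) {
  x <- recall_pct_restricted[!is.na(recall_pct_restricted)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x < 0 | x > 100))
    stop("restricted %kcal must lie in [0, 100]", call. = FALSE)
  100 - mean(x)
}

#' Dietary change from baseline to on-diet recalls
#'
#' Decrease, in percentage points of total daily kcal, in consumption of the
#' restricted component: baseline %kcal minus the mean of the available
#' on-diet recalls. Negative when intake of the restricted component
#' increased.
#'
#' @param baseline_pct_restricted baseline restricted-component %kcal.
#' @param recall_pct_restricted on-diet recall %kcal values (3/6/12 months).
#' @return change in %kcal points, NA when the baseline or all recalls are
#'   missing.
#' @export
dietary_change <- function(baseline_pct_restricted, recall_pct_restricted) {
  if (is.na(baseline_pct_restricted)) return(NA_real_)
  x <- recall_pct_restricted[!is.na(recall_pct_restricted)]
  if (length(x) == 0L) return(NA_real_)
  baseline_pct_restricted - mean(x)
}

#' Per-subject phenotype table
#'
#' Derives, for every subject, the weight-loss success category, dietary
#' adherence and dietary change from the restricted-component recall
#' columns. The restricted component is diet-determined: carbohydrates on
#' the low-carb arm, fat on the low-fat arm.
#'
#' @param metadata a `cohort_metadata` object (see [read_metadata()]).
#' @return data frame with one row per subject: `subject_id`, `diet`,
#'   `sex`, `weight_loss_pct_12mo`, `success`, `adherence_pct`,
#'   `change_pct`, `restricted_component`.
#' @export
phenotype_table <- function(metadata) {
  su <- metadata$subjects
  recalls <- as.matrix(su[, c("restricted_pct_3m", "restricted_pct_6m",
                              "restricted_pct_12m")])
  data.frame(
    subject_id = su$subject_id,
    diet = su$diet,
    sex = su$sex,
    weight_loss_pct_12mo = su$weight_loss_pct_12mo,
    success = classify_success(su$weight_loss_pct_12mo),
    adherence_pct = apply(recalls, 1L, dietary_adherence),
    change_pct = vapply(seq_len(nrow(su)), function(i)
      dietary_change(su$restricted_pct_bl[i], recalls[i, ]), numeric(1)),
    restricted_component = ifelse(su$diet == "low-carb", "carbs", "fat"),
    stringsAsFactors = FALSE
  )
}
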