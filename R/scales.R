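## Structural model of the four equine pain scales used by the pipeline.
## Only score ranges and observation times are represented; item-level
## content belongs to the original scale publications and is accepted as
## optional user-supplied metadata.

#' Built-in equine pain scale definitions
#'
#' Returns structural definitions of the four published equine pain scales
#' used throughout the pipeline: the Horse Grimace Scale (HGS, total score
#' 0-12), the Equine Utrecht University Scale of Facial Assessment of Pain
#' (EQUUS-FAP, 0-18), the Equine Pain Scale (EPS, 0-30) and the Composite
#' Orthopedic Pain Scale (CPS, 0-39). Observation time is 2 minutes for the
#' first three scales and 5 minutes for CPS. Item-level content is not
#' reproduced; totals are the analysis unit.
#'
#' @return A list of `ep_scale` objects, one per scale, each with elements
#'   `name`, `total_min`, `total_max`, `observation_minutes` and (optionally)
#'   `items`.
#' @examples
#' names(builtin_scales())
#' builtin_scales()$CPS$total_max
#' @export
builtin_scales <- function() {
  mk <- function(name, max, minutes) {
    structure(list(name = name, total_min = 0L, total_max = max,
                   observation_minutes = minutes, items = NULL),
              class = "ep_scale")
  }
  list(
    HGS         = mk("HGS", 12L, 2L),
    `EQUUS-FAP` = mk("EQUUS-FAP", 18L, 2L),
    EPS         = mk("EPS", 30L, 2L),
    CPS         = mk("CPS", 39L, 5L)
  )
}

#' Define a pain scale
#'
#' @param name Scale name.
#' @param total_max Maximum total score (non-negative integer).
#' @param observation_minutes Observation time in minutes.
#' @param items Optional data.frame with columns `item`, `min`, `max`; item
#'   maxima must sum to `total_max`.
#' @return An `ep_scale` object.
#' @export
pain_scale <- function(name, total_max, observation_minutes = 2L, items = NULL) {
  if (!is.character(name) || length(name) != 1L)
    ep_config_error("scale name must be a single string")
  if (!is.numeric(total_max) || total_max < 1)
    ep_config_error("total_max must be a positive number")
  if (!is.null(items)) {
    if (!all(c("item", "min", "max") %in% names(items)))
      ep_config_error("items must have columns item, min, max")
    if (sum(items$max) != total_max)
      ep_config_error("item maxima sum to %s, expected total_max = %s",
                      sum(items$max), total_max)
  }
  structure(list(name = name, total_min = 0L, total_max = as.integer(total_max),
                 observation_minutes = as.integer(observation_minutes),
                 items = items),
            class = "ep_scale")
}

get_scale <- function(name, scales = builtin_scales()) {
  if (!name %in% names(scales))
    ep_config_error("unknown pain scale '%s' (known: %s)", name,
                    paste(names(scales), collapse = ", "))
  scales[[name]]
}

#' Validate a pain assessment against its scale
#'
#' Range-checks a total pain score (and optional item scores) against the
#' scale definition. When item scores are supplied the total is computed as
#' their sum; a supplied total that disagrees with the item sum is an error.
#'
#' @param assessment A list or one-row data.frame with at least `scale` and
#'   `total_score`; optionally `item_scores` (numeric vector).
#' @param scale An `ep_scale` matching `assessment$scale`.
#' @return The validated assessment (as a list) with `total_score` filled in.
#' @export
validate_and_total <- function(assessment, scale) {
  a <- as.list(assessment)
  if (!identical(as.character(a$scale), scale$name))
    ep_config_error("assessment scale '%s' does not match definition '%s'",
                    a$scale, scale$name)
  if (!is.null(a$item_scores) && length(a$item_scores)) {
    items <- a$item_scores
    if (!is.null(scale$items)) {
      bad <- which(items < scale$items$min | items > scale$items$max)
      if (length(bad))
        ep_validation_error("item '%s' score %s outside [%s, %s] on %s",
                            scale$items$item[bad[1]], items[bad[1]],
                            scale$items$min[bad[1]], scale$items$max[bad[1]],
                            scale$name)
    } else if (any(items < 0)) {
      ep_validation_error("negative item score on %s", scale$name)
    }
    total <- sum(items)
    if (!is.null(a$total_score) && !is.na(a$total_score) &&
        a$total_score != total)
      ep_validation_error("total_score %s does not equal item sum %s on %s",
                          a$total_score, total, scale$name)
    a$total_score <- total
  }
  if (is.null(a$total_score) || is.na(a$total_score))
    ep_validation_error("missing total_score on %s", scale$name)
  if (a$total_score < scale$total_min || a$total_score > scale$total_max)
    ep_validation_error("total_score %s outside [%s, %s] on %s",
                        a$total_score, scale$total_min, scale$total_max,
                        scale$name)
  if (a$total_score != round(a$total_score))
    ep_validation_error("total_score %s is not an integer on %s",
                        a$total_score, scale$name)
  a
}

#' Total pain score as a percentage of the scale maximum
#'
#' @param total_score Validated total score(s).
#' @param scale An `ep_scale` object or scale name.
#' @return Percentage(s) of the scale maximum, rounded to 1 decimal.
#' @examples
#' percent_of_max(7, "HGS")   # 58.3
#' percent_of_max(9, "CPS")   # 23.1
#' @export
percent_of_max <- function(total_score, scale) {
  if (is.character(scale)) scale <- get_scale(scale)
  round(100 * total_score / scale$total_max, 1)
}

#' Descriptive summary of total pain scores by scale and phase
#'
#' Computes, per scale and induction phase, the median, 1st and 3rd quartile
#' (linear interpolation between order statistics, R quantile type 7), minimum
#' and maximum of total pain scores, plus a Shapiro-Wilk normality flag
#' (p < 0.05 taken as non-normal; degenerate inputs such as constant scores
#' are flagged not applicable with `shapiro_p = NA`).
#'
#' @param assessments Data.frame with columns `scale`, `phase`
#'   (`pre_induction` / `post_induction`) and `total_score`.
#' @return A data.frame with one row per scale x phase:
#'   `scale, phase, n, median, q1, q3, min, max, shapiro_p, non_normal`.
#'   Cells with no data carry `NA`, never a silent zero.
#' @export
summarize_scores <- function(assessments) {
  req <- c("scale", "phase", "total_score")
  if (!all(req %in% names(assessments)))
    ep_validation_error("assessments must have columns %s",
                        paste(req, collapse = ", "))
  scales <- unique(as.character(assessments$scale))
  phases <- c("pre_induction", "post_induction")
  grid <- expand.grid(scale = scales, phase = phases,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- assessments$total_score[assessments$scale == grid$scale[i] &
                                 assessments$phase == grid$phase[i]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(scale = grid$scale[i], phase = grid$phase[i], n = 0L,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        min = NA_real_, max = NA_real_,
                        shapiro_p = NA_real_, non_normal = NA))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sw <- if (length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0) {
      tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    } else NA_real_
    data.frame(scale = grid$scale[i], phase = grid$phase[i],
               n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               min = min(x), max = max(x), shapiro_p = sw,
               non_normal = if (is.na(sw)) NA else sw < 0.05)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
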