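#' Default EQ-5D-5L decrement weight table
#'
#' Per-dimension decrement weights by rating level for the five EQ-5D
#' dimensions (mobility, self-care, usual activity, pain/discomfort,
#' anxiety/depression). Utility is 1 minus the sum of the five decrements, so
#' an all-1 ("best health") response scores exactly 1 and the all-5 response
#' scores `1 - 1.285 = -0.285` under this table's level-5 column
#' (0.274, 0.203, 0.184, 0.335, 0.289).
#'
#' Only the level-5 decrements of the value set are pinned; intermediate
#' levels interpolate linearly between 0 at level 1 and the level-5 weight,
#' which keeps decrements zero at best health and non-decreasing in level.
#' Any 5 x 5 table satisfying those two constraints may be supplied instead.
#'
#' @return 5 x 5 numeric matrix, rows = dimensions, columns = levels 1-5.
#' @export
eq5d_default_weights <- function() {
  level5 <- c(mobility = 0.274, self_care = 0.203, usual_activity = 0.184,
              pain_discomfort = 0.335, anxiety_depression = 0.289)
  w <- outer(level5, (0:4) / 4)
  dimnames(w) <- list(names(level5), paste0("level", 1:5))
  w
}

validate_eq5d_weights <- function(weights) {
  if (!is.matrix(weights) || any(dim(weights) != c(5, 5)))
    stop("weights must be a 5 x 5 matrix (dimensions x levels)")
  if (any(weights[, 1] != 0))
    stop("level-1 weights must all be 0 (best health must score 1)")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(t(apply(weights, 1, diff)) < 0))
    stop("weights must be non-decreasing in level within each dimension")
  invisible(weights)
}

#' Score the EQ-5D-5L utility index
#'
#' Converts the five dimension ratings (1 "no problems" to 5 "extreme
#' problems/unable") to a single utility by summing the decrement weights
#' associated with each rating and subtracting the sum from one.
#'
#' @param ratings integer vector of length 5, each in 1..5, ordered mobility,
#'   self-care, usual activity, pain/discomfort, anxiety/depression.
#' @param weights decrement table as from [eq5d_default_weights()].
#' @return utility value in `[1 - sum(level-5 weights), 1]` (with the default
#'   table, `[-0.285, 1]`).
#' @examples
#' score_eq5d(c(1, 1, 1, 1, 1))  # 1, best health
#' score_eq5d(c(5, 5, 5, 5, 5))  # -0.285, worst health
#' @export
score_eq5d <- function(ratings, weights = eq5d_default_weights()) {
  validate_eq5d_weights(weights)
  if (length(ratings) != 5) stop("exactly 5 dimension ratings required")
  dims <- rownames(weights)
  bad <- which(!(ratings %in% 1:5))
  if (length(bad))
    stop("rating out of range 1..5 for dimension(s): ",
         paste(dims[bad], collapse = ", "))
  1 - sum(weights[cbind(1:5, ratings)])
}

#' Instrument definition for summed scales
#'
#' Metadata for an instrument scored by summing item ratings: item count,
#' rating range, transform and declared score range. Transforms: `sum` (plain
#' sum), `sum_then_double` (DASS-21 short-form convention), `reverse_sum`
#' (items reverse-keyed before summing).
#'
#' The declared score range may be narrower than `item_count * rating_max`
#' (set `range_override = TRUE`); scores are then validated against the
#' declared range only.
#'
#' @param name scale identifier.
#' @param item_count number of items.
#' @param rating_min,rating_max per-item rating range (integers).
#' @param transform one of `"sum"`, `"sum_then_double"`, `"reverse_sum"`.
#' @param score_min,score_max declared score range; defaults derived from the
#'   items and transform.
#' @param range_override set when the declared range is narrower than the
#'   arithmetic range implied by the items.
#' @return object of class `scale_definition`.
#' @export
scale_definition <- function(name, item_count, rating_min, rating_max,
                             transform = c("sum", "sum_then_double", "reverse_sum"),
                             score_min = NULL, score_max = NULL,
                             range_override = FALSE) {
  transform <- match.arg(transform)
  stopifnot(item_count >= 1, rating_min < rating_max)
  mult <- if (transform == "sum_then_double") 2 else 1
  lo <- item_count * rating_min * mult
  hi <- item_count * rating_max * mult
  if (is.null(score_min)) score_min <- lo
  if (is.null(score_max)) score_max <- hi
  if (!range_override && (score_min != lo || score_max != hi))
    stop("declared score range inconsistent with items x ratings under the ",
         "transform for scale '", name, "' (set range_override to accept)")
  structure(list(name = name, item_count = as.integer(item_count),
                 rating_min = as.integer(rating_min),
                 rating_max = as.integer(rating_max), transform = transform,
                 score_min = score_min, score_max = score_max),
            class = "scale_definition")
}

#' Registry of the study instruments
#'
#' Definitions for the summed scales used in the analysis: the three DASS-21
#' subscales (7 items, 0-3, summed and doubled, range 0-42), the three MPAI-4
#' subscales (items rated 0-4; the ability subscale's 12 items span 0-48;
#' adjustment and participation carry declared ranges 0-30, narrower than
#' their arithmetic maxima, reflecting the instrument's published score
#' ranges), the three SPRS-2 domains (4 items, 0-4, range 0-16) and the
#' Service Obstacles Scale treatment subscale (4 items rated 1-7, range 4-28,
#' higher = less satisfaction with care).
#'
#' @return named list of [scale_definition()] objects.
#' @export
scale_registry <- function() {
  dass <- function(nm) scale_definition(nm, 7, 0, 3, "sum_then_double")
  sprs <- function(nm) scale_definition(nm, 4, 0, 4, "sum")
  list(
    dass_depression = dass("dass_depression"),
    dass_anxiety = dass("dass_anxiety"),
    dass_stress = dass("dass_stress"),
    mpai_ability = scale_definition("mpai_ability", 12, 0, 4, "sum"),
    mpai_adjustment = scale_definition("mpai_adjustment", 9, 0, 4, "sum",
                                       score_min = 0, score_max = 30,
                                       range_override = TRUE),
    mpai_participation = scale_definition("mpai_participation", 8, 0, 4, "sum",
                                          score_min = 0, score_max = 30,
                                          range_override = TRUE),
    sprs_occupational = sprs("sprs_occupational"),
    sprs_interpersonal = sprs("sprs_interpersonal"),
    sprs_independent = sprs("sprs_independent"),
    sos_treatment = scale_definition("sos_treatment", 4, 1, 7, "sum")
  )
}

#' Score a summed instrument
#'
#' Applies the scale's transform to a complete vector of item ratings.
#' Missing items are not prorated: scoring requires complete responses
#' (imputation, when needed, happens upstream at score level).
#'
#' @param items numeric vector of item ratings.
#' @param definition a [scale_definition()].
#' @return integer score within the declared range.
#' @examples
#' score_summed_scale(rep(3, 7), scale_registry()$dass_depression)  # 42
#' @export
score_summed_scale <- function(items, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  if (length(items) != definition$item_count)
    stop("scale '", definition$name, "' expects ", definition$item_count,
         " items, got ", length(items))
  if (anyNA(items)) stop("scale '", definition$name, "' has missing items; ",
                         "no prorating is done")
  out_of_range <- items < definition$rating_min | items > definition$rating_max
  if (any(out_of_range))
    stop("rating(s) outside ", definition$rating_min, "..",
         definition$rating_max, " for scale '", definition$name, "' at item(s) ",
         paste(which(out_of_range), collapse = ", "))
  score <- switch(definition$transform,
                  sum = sum(items),
                  sum_then_double = 2 * sum(items),
                  reverse_sum = sum(definition$rating_max +
                                      definition$rating_min - items))
  if (score < definition$score_min || score > definition$score_max)
    stop("score ", score, " outside declared range for scale '",
         definition$name, "'")
  as.integer(score)
}

#' Recode a Service Obstacles Scale rating to agree/disagree
#'
#' SOS transport and finances items are rated 1 (strongly disagree) to 7
#' (strongly agree) and re-categorized for analysis. Ratings 1-3 are always
#' "disagree" and 5-7 always "agree". The midpoint 4 differs between the two
#' printed conventions: under `"methods"` it is undefined (`NA`); under
#' `"table3"` (the default, which governs the reported percentages) it is
#' "agree".
#'
#' @param rating integer vector of ratings in 1..7.
#' @param convention `"table3"` (4 -> agree) or `"methods"` (4 -> NA).
#' @return character vector of `"disagree"` / `"agree"` (with `NA` for 4
#'   under the methods convention).
#' @export
recode_sos_binary <- function(rating, convention = c("table3", "methods")) {
  convention <- match.arg(convention)
  if (any(!(rating %in% 1:7)))
    stop("SOS ratings must be integers in 1..7")
  out <- ifelse(rating <= 3, "disagree",
                ifelse(rating >= 5, "agree",
                       if (convention == "table3") "agree" else NA_character_))
  out
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total score))` for a
#' complete participants x items rating table. Returns `NA` when the total
#' score has zero variance (alpha undefined).
#'
#' @param item_table numeric matrix or data.frame, rows = participants,
#'   columns = items; at least 2 of each, no missing entries.
#' @return alpha as a decimal, or `NA` if undefined.
#' @export
cronbach_alpha <- function(item_table) {
  m <- as.matrix(item_table)
  if (ncol(m) < 2) stop("at least 2 items required")
  if (nrow(m) < 2) stop("at least 2 participants required")
  if (anyNA(m)) stop("item table has missing entries; impute or drop first")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) return(NA_real_)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
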