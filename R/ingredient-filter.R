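#' Select potential active ingredients by ADME criteria
#'
#' Applies the admission rule for orally relevant compounds: Caco-2
#' permeability strictly greater than `caco2_min` and drug-likeness at
#' least `dl_min`.  Compounds detected in the preparation and reported in
#' the literature (`literature_flag`) are whitelisted independently of
#' their ADME values, so the retained set is the union of the two routes.
#' A record missing either ADME value fails the ADME route (but may still
#' be whitelisted).
#'
#' @param records ingredient data.frame as returned by
#'   [read_ingredients()].
#' @param caco2_min Caco-2 threshold; strict inequality (`caco2 > caco2_min`).
#' @param dl_min drug-likeness threshold; inclusive (`dl >= dl_min`).
#' @return data.frame of decisions, one row per input record in input
#'   order: `ingredient_id`, `passed_adme`, `whitelisted`, `retained`,
#'   `reason` (one of `"adme"`, `"literature"`, `"adme+literature"`,
#'   `"failed"`).
#' @export
#' @examples
#' recs <- data.frame(ingredient_id = c("A", "B"), name = c("a", "b"),
#'                    caco2 = c(0.19, 0.10), dl = c(0.25, 0.04),
#'                    literature_flag = c(FALSE, TRUE))
#' filter_ingredients(recs)
filter_ingredients <- function(records, caco2_min = -0.4, dl_min = 0.18) {
  passed_adme <- !is.na(records$caco2) & records$caco2 > caco2_min &
    !is.na(records$dl) & records$dl >= dl_min
  whitelisted <- isTRUE_vec(records$literature_flag)
  retained <- passed_adme | whitelisted
  reason <- ifelse(passed_adme & whitelisted, "adme+literature",
            ifelse(passed_adme, "adme",
            ifelse(whitelisted, "literature", "failed")))
  data.frame(
    ingredient_id = records$ingredient_id,
    passed_adme = passed_adme,
    whitelisted = whitelisted,
    retained = retained,
    reason = reason,
    stringsAsFactors = FALSE
  )
}

isTRUE_vec <- function(x) !is.na(x) & x
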