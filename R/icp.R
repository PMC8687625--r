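#' ICP selection of the critical functional ingredients group
#'
#' The ingredients-contribution-proportion (ICP) model ranks ingredients
#' by their contribution to covering the key response proteins: starting
#' from the candidates sorted by descending raw target count, it
#' iteratively picks the ingredient with the largest *marginal* gain in
#' key-protein coverage, until the cumulative coverage reaches
#' `coverage_target` or no ingredient adds a new key protein.  Ties on
#' marginal gain are broken by higher raw target count, then by
#' lexicographic ingredient id, so the selection is deterministic.  An
#' ingredient whose targets are already covered is never picked, however
#' many targets it has.
#'
#' @param it_network result of [build_it_network()] (or a bare
#'   `cfig_network` from it), or a data.frame of associations
#'   (`ingredient_id`, `target_gene`).
#' @param key_proteins character set of key response proteins; each
#'   ingredient's targets are intersected with this set before scoring.
#' @param coverage_target stop once cumulative coverage reaches this
#'   fraction of the key proteins (default 0.90).
#' @return list of class `cfig_selection`: `picks` (data.frame `rank`,
#'   `ingredient_id`, `marginal_gain`, `cumulative_covered`,
#'   `cumulative_coverage`), `coverage_target`, `achieved_coverage`,
#'   `n_key_proteins`, `covered` (the covered key proteins), and
#'   `unreachable` (TRUE when the target exceeds what all ingredients
#'   together can cover).
#' @export
#' @examples
#' assoc <- data.frame(
#'   ingredient_id = c("A", "A", "A", "B", "B", "C"),
#'   target_gene = c("G1", "G2", "G3", "G3", "G4", "G5"))
#' icp_select(assoc, key_proteins = paste0("G", 1:5), coverage_target = 0.9)
icp_select <- function(it_network, key_proteins, coverage_target = 0.90) {
  if (coverage_target <= 0 || coverage_target > 1) {
    stop_cfig("coverage_target must be in (0, 1]", class = "cfig_validation_error")
  }
  key_proteins <- unique(as.character(key_proteins))
  if (length(key_proteins) == 0) {
    stop_cfig("key protein set is empty", class = "cfig_validation_error")
  }
  assoc <- as_associations(it_network)
  targets <- split(assoc$target_gene, assoc$ingredient_id)
  raw_count <- vapply(targets, length, integer(1))
  key_targets <- lapply(targets, function(t) intersect(t, key_proteins))
  # candidate order encodes the tie-break policy: raw target count
  # descending, then id ascending
  ord <- order(-raw_count, names(targets))
  cand <- names(targets)[ord]

  covered <- character(0)
  picks <- list()
  n_key <- length(key_proteins)
  repeat {
    gains <- vapply(cand, function(i) {
      length(setdiff(key_targets[[i]], covered))
    }, integer(1))
    if (length(gains) == 0 || max(gains) == 0) break
    best <- cand[which.max(gains)]   # first index wins: tie-break via order
    gain <- max(gains)
    covered <- union(covered, key_targets[[best]])
    cand <- setdiff(cand, best)
    picks[[length(picks) + 1L]] <- data.frame(
      ingredient_id = best, marginal_gain = gain,
      cumulative_covered = length(covered),
      cumulative_coverage = length(covered) / n_key,
      stringsAsFactors = FALSE
    )
    if (length(covered) / n_key >= coverage_target) break
  }
  picks <- if (length(picks) > 0) {
    cbind(rank = seq_along(picks), do.call(rbind, picks))
  } else {
    data.frame(rank = integer(0), ingredient_id = character(0),
               marginal_gain = integer(0), cumulative_covered = integer(0),
               cumulative_coverage = numeric(0), stringsAsFactors = FALSE)
  }
  achieved <- length(covered) / n_key
  structure(list(picks = picks, coverage_target = coverage_target,
                 achieved_coverage = achieved, n_key_proteins = n_key,
                 covered = covered,
                 unreachable = achieved < coverage_target),
            class = "cfig_selection")
}

as_associations <- function(x) {
  if (is.data.frame(x)) {
    data.frame(ingredient_id = as.character(x$ingredient_id),
               target_gene = as.character(x$target_gene),
               stringsAsFactors = FALSE)
  } else if (is.list(x) && inherits(x$network, "cfig_network")) {
    net_to_assoc(x$network)
  } else if (inherits(x, "cfig_network")) {
    net_to_assoc(x)
  } else {
    stop_cfig("cannot interpret ingredient-target input",
              class = "cfig_validation_error")
  }
}

net_to_assoc <- function(net) {
  roles <- setNames(net$nodes$role, net$nodes$id)
  e <- net$edges
  ing_from <- roles[e$from] == "ingredient"
  data.frame(
    ingredient_id = ifelse(ing_from, e$from, e$to),
    target_gene = ifelse(ing_from, e$to, e$from),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cfig_selection <- function(x, ...) {
  cat(sprintf("<cfig_selection> %d pick(s), coverage %.2f%% (target %.0f%%)%s\n",
              nrow(x$picks), 100 * x$achieved_coverage,
              100 * x$coverage_target,
              if (x$unreachable) " [target unreachable]" else ""))
  invisible(x)
}

#' Cumulative coverage curve of an ICP selection
#'
#' @param selection a `cfig_selection`.
#' @return data.frame (`rank`, `cumulative_coverage`), monotone
#'   nondecreasing; the last value equals the achieved coverage.
#' @export
coverage_curve <- function(selection) {
  stopifnot(inherits(selection, "cfig_selection"))
  if (nrow(selection$picks) == 0) {
    stop_cfig("empty selection has no coverage curve",
              class = "cfig_validation_error")
  }
  selection$picks[, c("rank", "cumulative_coverage")]
}

#' Recovery of planted critical ingredients
#'
#' On synthetic studies with a known planted critical set, measures the
#' fraction of planted ingredients found among the first `|planted|`
#' picks of a selection.
#'
#' @param selection a `cfig_selection`.
#' @param planted_ids character set of planted critical ingredient ids.
#' @return real in `[0, 1]`.
#' @export
recovery_score <- function(selection, planted_ids) {
  stopifnot(inherits(selection, "cfig_selection"))
  planted_ids <- unique(as.character(planted_ids))
  if (length(planted_ids) == 0) {
    stop_cfig("planted ingredient set is empty", class = "cfig_validation_error")
  }
  first <- utils::head(selection$picks$ingredient_id, length(planted_ids))
  length(intersect(first, planted_ids)) / length(planted_ids)
}
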