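#' Build and normalize a criterion set
#'
#' Criteria carry raw weights on the 0--100 elicitation scale; the weighted-sum
#' model uses them after normalisation to proportions, \eqn{W'_x = W_x /
#' \sum W_x}, so rescaling all raw weights by a common factor changes
#' nothing downstream.
#'
#' @param criterion_ids character vector of criterion labels.
#' @param raw_weights non-negative numeric vector, at least one positive.
#' @param source provenance tag: `"managerial_panel"`, `"dematel_derived"` or
#'   `"manual"`.
#' @return A list of class `"criterion_set"` with `criterion_ids`,
#'   `raw_weights`, `normalized_weights`, `source`.
#' @export
criterion_set <- function(criterion_ids, raw_weights,
                          source = c("managerial_panel", "dematel_derived",
                                     "manual")) {
  source <- match.arg(source)
  if (length(criterion_ids) != length(raw_weights))
    stop("criterion_ids and raw_weights must have equal length")
  if (anyDuplicated(criterion_ids))
    stop("duplicate criterion ids")
  if (any(!is.finite(raw_weights)) || any(raw_weights < 0))
    stop("raw weights must be finite and non-negative")
  cs <- structure(list(criterion_ids = as.character(criterion_ids),
                       raw_weights = stats::setNames(as.numeric(raw_weights),
                                                     criterion_ids),
                       normalized_weights = NULL,
                       source = source),
                  class = "criterion_set")
  # all-zero sets stay unnormalised until a positive-weight criterion (e.g.
  # the injected risk row) joins; scoring such a set is an error downstream
  if (sum(cs$raw_weights) > 0) cs <- normalize_weights(cs)
  cs
}

#' Normalize criterion weights to proportions
#'
#' @param raw a `"criterion_set"`, or a bare non-negative numeric vector (in
#'   which case the normalised vector is returned directly).
#' @return The criterion set with `normalized_weights` filled in (summing to
#'   1), or a numeric vector when given one.
#' @export
normalize_weights <- function(raw) {
  w <- if (inherits(raw, "criterion_set")) raw$raw_weights else as.numeric(raw)
  if (any(!is.finite(w)) || any(w < 0))
    stop("raw weights must be finite and non-negative")
  s <- sum(w)
  if (s <= 0) stop("all criterion weights are zero; nothing to normalise")
  wn <- w / s
  if (inherits(raw, "criterion_set")) {
    raw$normalized_weights <- wn
    raw
  } else wn
}

#' Weighted-sum scores for a decision matrix
#'
#' Applies the weighted-sum model: each cell of the criteria-by-alternatives
#' decision matrix is multiplied by its criterion's normalised weight, and
#' each alternative's score is the column sum \eqn{WS(A_x) = \sum_y W'_y
#' V_{yx}}. In this application every criterion points the same way -- values
#' near 100 argue for eliminating the department -- so no benefit/cost
#' direction flipping is applied, and with normalised weights and values in
#' \[0, 100\] the totals stay in \[0, 100\].
#'
#' @param weights a `"criterion_set"` (normalised weights are used; built via
#'   [criterion_set()] or [normalize_weights()]).
#' @param values numeric matrix, criteria in rows, alternatives in columns,
#'   with dimnames; row labels must match the criterion set.
#' @return An object of class `"wsm"`: list with `weighted_cells` (W' * V
#'   products), `totals` (per alternative), `ranking` (alternative ids in
#'   descending score order), `weights`, `alternative_ids`.
#' @examples
#' w <- criterion_set(c("c1", "c2"), c(50, 50))
#' V <- matrix(c(20, 80, 40, 60), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("A", "B")))
#' wsm(w, V)$totals
#' @export
wsm <- function(weights, values) {
  values <- as.matrix(values)
  if (!inherits(weights, "criterion_set"))
    stop("weights must be a criterion_set")
  if (is.null(weights$normalized_weights))
    weights <- normalize_weights(weights)
  if (nrow(values) != length(weights$criterion_ids))
    stop(sprintf("decision matrix has %d criterion rows, criterion set has %d",
                 nrow(values), length(weights$criterion_ids)))
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), weights$criterion_ids))
    stop("decision-matrix row labels do not match the criterion set")
  if (any(!is.finite(values)) || any(values < 0 | values > 100))
    stop("decision-matrix values must lie in [0, 100]")
  cells <- weights$normalized_weights * values   # row-wise recycling
  totals <- colSums(cells)
  alts <- colnames(values)
  if (is.null(alts)) alts <- paste0("A", seq_len(ncol(values)))
  names(totals) <- alts
  ord <- order(-totals)   # stable: ties keep canonical column order
  structure(list(weighted_cells = cells,
                 totals = totals,
                 ranking = alts[ord],
                 weights = weights,
                 alternative_ids = alts),
            class = "wsm")
}

#' @rdname wsm
#' @export
weighted_scores <- wsm

#' Shortlist the top alternatives of a weighted-sum result
#'
#' @param res a `"wsm"` object (or any list with `totals` and `ranking`).
#' @param top_k number of alternatives to return, at most the number
#'   available.
#' @return Data frame `alternative`, `ws`, `rank` for the top `top_k`
#'   alternatives by descending weighted sum (stable ties: canonical order).
#' @export
rank_alternatives <- function(res, top_k = 4) {
  n <- length(res$ranking)
  if (top_k < 1 || top_k > n)
    stop(sprintf("top_k must be between 1 and %d", n))
  ids <- res$ranking[seq_len(top_k)]
  data.frame(alternative = ids,
             ws = unname(res$totals[ids]),
             rank = seq_len(top_k),
             stringsAsFactors = FALSE)
}

#' @export
print.wsm <- function(x, digits = 2, ...) {
  cat("Weighted-sum model:", length(x$weights$criterion_ids), "criteria x",
      length(x$alternative_ids), "alternatives\n")
  cat("top of ranking:\n")
  top <- utils::head(x$ranking, 5)
  print(round(x$totals[top], digits))
  invisible(x)
}

#' @export
summary.wsm <- function(object, ...) {
  data.frame(alternative = object$ranking,
             ws = unname(object$totals[object$ranking]),
             rank = seq_along(object$ranking),
             stringsAsFactors = FALSE)
}

#' @export
coef.wsm <- function(object, ...) object$totals

#' Bar chart of weighted sums
#'
#' @param x a `"wsm"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.wsm <- function(x, ...) {
  graphics::barplot(x$totals, las = 2, ylab = "weighted sum (WS)",
                    main = "WSM elimination pressure by department", ...)
  invisible(x)
}
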