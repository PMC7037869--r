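#' Convert DEMATEL relations into a 0-100 infection-risk criterion
#'
#' Both strong net causes (dispatchers of infection) and strong net receivers
#' are risky, so the mapping works on the magnitude of the relation |R - C|.
#' Three modes are available:
#' \describe{
#'   \item{abs_minmax}{(default) linear min-max rescaling of |R - C| onto
#'     \[0, 100\]: the department with the smallest magnitude scores 0, the
#'     largest 100. If all magnitudes are equal the spread is degenerate and
#'     every department scores 50, with a warning.}
#'   \item{rank_based}{departments are ranked by |R - C| and scores are
#'     evenly spaced on \[0, 100\] (smallest magnitude 0, largest 100).}
#'   \item{manual}{expert-curated scores are passed through verbatim; they
#'     must cover every department and lie in \[0, 100\]. This is how a
#'     panel-drawn risk row enters the pipeline.}
#' }
#'
#' @param profile a `"dematel"` fit or `"total_relation"` result.
#' @param mode one of `"abs_minmax"`, `"rank_based"`, `"manual"`.
#' @param overrides named numeric vector of manual scores (required in
#'   `"manual"` mode), names covering `profile$departments`.
#' @return Named numeric vector of risk scores in \[0, 100\], one per
#'   department, with attribute `mapping_mode`.
#' @export
dematel_to_risk_scores <- function(profile,
                                   mode = c("abs_minmax", "rank_based",
                                            "manual"),
                                   overrides = NULL) {
  mode <- match.arg(mode)
  deps <- profile$departments
  if (mode == "manual") {
    if (is.null(overrides)) stop("manual mode requires overrides")
    missing <- setdiff(deps, names(overrides))
    if (length(missing))
      stop("missing manual risk score for: ", paste(missing, collapse = ", "))
    sc <- as.numeric(overrides[deps])
    if (any(!is.finite(sc)) || any(sc < 0 | sc > 100))
      stop("manual risk scores must lie in [0, 100]")
    return(structure(stats::setNames(sc, deps), mapping_mode = "manual"))
  }
  mag <- abs(profile$relation)
  if (mode == "abs_minmax") {
    spread <- max(mag) - min(mag)
    if (spread <= 1e-12) {
      warning("degenerate spread: all |R - C| equal; every risk score set to 50")
      sc <- rep(50, length(mag))
    } else {
      sc <- 100 * (mag - min(mag)) / spread
    }
  } else {  # rank_based
    if (length(mag) == 1) {
      sc <- 50
    } else {
      sc <- 100 * (rank(mag, ties.method = "average") - 1) / (length(mag) - 1)
    }
  }
  structure(stats::setNames(as.numeric(sc), deps), mapping_mode = mode)
}

#' Merge the infection-risk criterion into a decision matrix
#'
#' Appends the risk scores as one extra criterion row to the managerial
#' decision matrix and re-normalises the joint raw weight vector, so the risk
#' criterion competes with the managerial criteria on the same 0--100 weight
#' scale (the case study gives it the maximum raw weight, 100).
#'
#' @param values numeric decision matrix, managerial criteria in rows,
#'   departments in columns.
#' @param weights a `"criterion_set"` for the managerial criteria (raw
#'   weights on the 0--100 scale).
#' @param risk named risk-score vector from [dematel_to_risk_scores()],
#'   covering every column of `values`.
#' @param risk_weight raw weight of the risk criterion, default 100.
#' @param risk_id label for the added row, default `"infection_risk"`.
#' @return List with `values` (one extra row) and `weights` (criterion set
#'   over all criteria, re-normalised jointly).
#' @export
inject_risk_criterion <- function(values, weights, risk, risk_weight = 100,
                                  risk_id = "infection_risk") {
  values <- as.matrix(values)
  alts <- colnames(values)
  if (is.null(alts)) stop("decision matrix must have department column names")
  missing <- setdiff(alts, names(risk))
  if (length(missing))
    stop("risk scores missing for: ", paste(missing, collapse = ", "))
  merged <- rbind(values, as.numeric(risk[alts]))
  rownames(merged) <- c(weights$criterion_ids, risk_id)
  cs <- criterion_set(c(weights$criterion_ids, risk_id),
                      c(unname(weights$raw_weights), risk_weight),
                      source = "dematel_derived")
  list(values = merged, weights = cs)
}

#' Run the full rearchitecting pipeline
#'
#' Drives the four-step hybrid algorithm: (1) aggregate the infection-cluster
#' panel's pairwise influence matrices into a consensus direct-relation
#' matrix, (2) run DEMATEL to obtain the total-relation matrix, R - C and the
#' cause/effect classification, (3) map R - C to a 0--100 infection-risk
#' criterion and append it to the managerial decision matrix (itself a
#' rank-weighted panel aggregate) with joint weight renormalisation, and
#' (4) score every department with the weighted-sum model and shortlist the
#' top candidates for elimination or hygiene reinforcement.
#'
#' @param config a named list (or path to a JSON/YAML file readable by
#'   [read_config()]) with components:
#' \describe{
#'   \item{panel}{`"expert_panel"` object, or path to a panel CSV.}
#'   \item{assessments}{list of influence assessments, or character vector of
#'     per-expert matrix CSV paths (file name stem = expert id).}
#'   \item{weights_tables}{named list of per-expert raw-weight vectors (or a
#'     single vector), or a path to a weights CSV.}
#'   \item{values_tables}{named list of per-expert criteria x departments
#'     matrices (or a single matrix), or paths to value CSVs.}
#'   \item{risk_mode}{`"abs_minmax"` (default), `"rank_based"` or
#'     `"manual"`.}
#'   \item{risk_overrides}{named scores for manual mode.}
#'   \item{risk_weight}{raw weight of the risk criterion, default 100.}
#'   \item{top_k}{shortlist length, default 4.}
#'   \item{output_dir}{optional directory; when set, CSV/JSON artifacts of
#'     every stage are written there.}
#'   \item{seed}{optional integer recorded in the provenance snapshot (the
#'     pipeline itself is deterministic).}
#' }
#' @return An object of class `"hybrid_ranking"`: list with `dematel`
#'   (the fit), `risk_scores`, `wsm`, `shortlist`, `config` (snapshot).
#' @examples
#' case <- generate_case(synth_config(n_departments = 6, seed = 1))
#' res <- run_pipeline(list(panel = case$panel,
#'                          assessments = case$assessments,
#'                          weights_tables = case$weights_tables,
#'                          values_tables = case$values_tables,
#'                          top_k = 2))
#' res$shortlist
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stopifnot(is.list(config))
  cfg <- config
  cfg$risk_mode <- if (is.null(cfg$risk_mode)) "abs_minmax" else cfg$risk_mode
  cfg$risk_weight <- if (is.null(cfg$risk_weight)) 100 else cfg$risk_weight
  cfg$top_k <- if (is.null(cfg$top_k)) 4 else cfg$top_k

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  panel <- stage("panel", {
    p <- cfg$panel
    if (is.character(p)) p <- read_panel_csv(p)
    if (!inherits(p, "expert_panel"))
      p <- expert_panel(p$expert_id, p$cluster, p$rank)
    p
  })

  Z <- stage("aggregation", {
    a <- cfg$assessments
    if (is.character(a)) {
      ids <- tools::file_path_sans_ext(basename(a))
      a <- Map(function(path, id)
        influence_assessment(id, read_matrix_csv(path)), a, ids)
    }
    aggregate_influence(a, panel)
  })

  fit <- stage("dematel", dematel(Z))

  risk <- stage("risk_mapping",
                dematel_to_risk_scores(fit, mode = cfg$risk_mode,
                                       overrides = cfg$risk_overrides))

  merged <- stage("wsm", {
    wt <- cfg$weights_tables
    if (is.character(wt)) wt <- lapply(wt, read_weights_csv)
    if (is.numeric(wt)) wt <- list(wt)
    vt <- cfg$values_tables
    if (is.character(vt)) vt <- lapply(vt, read_matrix_csv)
    if (is.matrix(vt) || is.data.frame(vt)) vt <- list(vt)
    man_ids <- panel$expert_id[panel$cluster == "managerial"]
    if (is.null(names(wt)) && length(wt) == length(man_ids)) names(wt) <- man_ids
    if (is.null(names(vt)) && length(vt) == length(man_ids)) names(vt) <- man_ids
    vals <- if (length(vt) == 1) as.matrix(vt[[1]])
            else aggregate_decision_values(vt, panel, expert_ids = names(vt))
    crit <- rownames(vals)
    raw_w <- if (length(wt) == 1) {
      w <- as.numeric(wt[[1]])
      if (!is.null(names(wt[[1]]))) w <- as.numeric(wt[[1]][crit])
      w
    } else {
      tabs <- lapply(wt, function(w) {
        w <- if (is.null(names(w))) stats::setNames(as.numeric(w), crit)
             else w[crit]
        matrix(as.numeric(w), ncol = 1, dimnames = list(crit, "weight"))
      })
      drop(aggregate_decision_values(tabs, panel, expert_ids = names(wt)))
    }
    cs <- criterion_set(crit, as.numeric(raw_w))
    inject_risk_criterion(vals, cs, risk, risk_weight = cfg$risk_weight)
  })

  scores <- stage("wsm", wsm(merged$weights, merged$values))
  shortlist <- stage("ranking", rank_alternatives(scores, top_k = cfg$top_k))

  out <- structure(list(dematel = fit,
                        risk_scores = risk,
                        wsm = scores,
                        shortlist = shortlist,
                        config = cfg),
                   class = "hybrid_ranking")
  if (!is.null(cfg$output_dir)) write_pipeline_artifacts(out, cfg$output_dir)
  out
}

#' @export
print.hybrid_ranking <- function(x, ...) {
  cat("Hybrid DEMATEL-WSM ranking of",
      length(x$wsm$alternative_ids), "departments\n")
  cl <- x$dematel$classification
  cat("master dispatcher:", cl$department[cl$is_master_dispatcher],
      "| master receiver:", cl$department[cl$is_master_receiver], "\n")
  cat("shortlist for elimination / hygiene reinforcement:\n")
  print(x$shortlist)
  invisible(x)
}

#' @export
summary.hybrid_ranking <- function(object, ...) {
  data.frame(department = object$wsm$alternative_ids,
             relation = unname(object$dematel$relation[object$wsm$alternative_ids]),
             risk_score = unname(object$risk_scores[object$wsm$alternative_ids]),
             ws = unname(object$wsm$totals[object$wsm$alternative_ids]),
             shortlisted = object$wsm$alternative_ids %in%
               object$shortlist$alternative,
             stringsAsFactors = FALSE)
}
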