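#' Construct an expert panel
#'
#' An expert panel records, for each expert, a cluster label (which elicitation
#' exercise they took part in) and an integer rank weight expressing relative
#' expertise. Ranks multiply each expert's judgments before averaging, so a
#' rank-3 expert counts three times as much as a rank-1 expert ("unbalanced
#' expertise" weighting of a nominal group).
#'
#' @param expert_id character vector of unique expert identifiers.
#' @param cluster character vector, one of `"infection"` or `"managerial"` per
#'   expert. Infection-cluster experts judge pairwise cross-infection
#'   influence; managerial-cluster experts weigh and score the managerial
#'   criteria.
#' @param rank positive integer vector of rank weights (the case study uses
#'   1--3, but any positive integers are accepted).
#' @return A data frame of class `"expert_panel"` with columns `expert_id`,
#'   `cluster`, `rank`.
#' @examples
#' expert_panel(c("e1", "e2"), c("infection", "infection"), c(3, 1))
#' @export
expert_panel <- function(expert_id, cluster, rank) {
  expert_id <- as.character(expert_id)
  cluster <- as.character(cluster)
  if (anyDuplicated(expert_id))
    stop("duplicate expert_id: ",
         paste(unique(expert_id[duplicated(expert_id)]), collapse = ", "))
  bad <- setdiff(unique(cluster), c("infection", "managerial"))
  if (length(bad))
    stop("unknown cluster label(s): ", paste(bad, collapse = ", "),
         " (expected 'infection' or 'managerial')")
  if (length(rank) != length(expert_id) || length(cluster) != length(expert_id))
    stop("expert_id, cluster and rank must have equal length")
  if (any(!is.finite(rank)) || any(rank < 1) || any(rank != round(rank)))
    stop("rank must be a positive integer (>= 1) for every expert")
  structure(
    data.frame(expert_id = expert_id, cluster = cluster,
               rank = as.integer(rank), stringsAsFactors = FALSE),
    class = c("expert_panel", "data.frame")
  )
}

#' Construct a single expert's pairwise influence assessment
#'
#' Entry (i, j) is the judged influence of department i on department j on the
#' 5-point scale 0 = no effect, 1 = low, 2 = moderate, 3 = high, 4 = very
#' high. The diagonal is structurally zero (a department does not infect
#' itself in this accounting).
#'
#' @param expert_id identifier of the judging expert.
#' @param matrix square numeric matrix of integers in 0--4 with zero diagonal.
#'   Dimnames, if present, are taken as department labels.
#' @param departments optional character vector of department labels; required
#'   when `matrix` has no dimnames.
#' @return A list of class `"influence_assessment"` with elements `expert_id`,
#'   `matrix` (with department dimnames), `departments`.
#' @export
influence_assessment <- function(expert_id, matrix, departments = NULL) {
  if (is.null(departments)) departments <- rownames(matrix)
  if (is.null(departments))
    stop("departments must be supplied when the matrix has no row names")
  a <- structure(
    list(expert_id = as.character(expert_id),
         matrix = `dimnames<-`(as.matrix(matrix), list(departments, departments)),
         departments = as.character(departments)),
    class = "influence_assessment"
  )
  validate_assessment(a, departments)
}

#' Validate an influence assessment against a department list
#'
#' Checks the structural invariants of a pairwise influence matrix: square,
#' dimensions matching the department list, every entry an integer in 0--4,
#' and an exactly zero diagonal.
#'
#' @param a an [influence_assessment()] (or a bare square matrix, which is
#'   wrapped on the fly with `expert_id = NA`).
#' @param departments ordered character vector of department labels the
#'   assessment must conform to.
#' @return The validated assessment, unchanged.
#' @export
validate_assessment <- function(a, departments) {
  if (is.matrix(a))
    a <- structure(list(expert_id = NA_character_, matrix = a,
                        departments = as.character(departments)),
                   class = "influence_assessment")
  m <- a$matrix
  n <- length(departments)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("influence matrix must be square")
  if (nrow(m) != n)
    stop(sprintf("matrix is %dx%d but %d departments were given",
                 nrow(m), ncol(m), n))
  if (n < 2) stop("at least 2 departments are required")
  if (!is.null(rownames(m)) && !identical(rownames(m), as.character(departments)))
    stop("matrix row labels do not match the department list")
  if (any(!is.finite(m)))
    stop("influence matrix contains missing or non-finite entries")
  off <- m[m < 0 | m > 4 | m != round(m)]
  if (length(off)) {
    idx <- which(m < 0 | m > 4 | m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("entry (%d,%d)=%g outside the 0-4 integer scale",
                 idx[1], idx[2], m[idx[1], idx[2]]))
  }
  d <- which(diag(m) != 0)
  if (length(d))
    stop(sprintf("diagonal (%d,%d) must be 0, found %g",
                 d[1], d[1], m[d[1], d[1]]))
  a
}

# Resolve rank weights for a set of assessments/tables against a panel.
rank_weights_for <- function(expert_ids, panel) {
  if (!nrow(panel)) stop("empty expert panel")
  pos <- match(expert_ids, panel$expert_id)
  if (anyNA(pos))
    stop("assessment from unknown expert: ",
         paste(expert_ids[is.na(pos)], collapse = ", "))
  panel$rank[pos]
}

#' Aggregate expert influence assessments into a consensus matrix
#'
#' Computes the initial direct-relation matrix Z as the rank-weighted
#' arithmetic mean of the experts' matrices:
#' \deqn{Z_{ij} = \sum_k r_k X^k_{ij} / \sum_k r_k,}
#' where \eqn{r_k} is expert k's rank weight. Dividing by the summed ranks
#' keeps Z on the original 0--4 scale; the downstream DEMATEL normalisation is
#' invariant to any common rescaling of Z, so only the scale of the reported
#' consensus depends on this convention.
#'
#' @param assessments list of [influence_assessment()] objects, all over the
#'   same departments. The first assessment's department order is canonical;
#'   the others must match it by label.
#' @param panel an [expert_panel()] containing every assessing expert.
#' @return A matrix of class `"consensus_matrix"` with attributes
#'   `departments` and `aggregation_note` (the divisor used).
#' @examples
#' p <- expert_panel(c("a", "b"), c("infection", "infection"), c(2, 1))
#' m1 <- influence_assessment("a", matrix(c(0, 2, 4, 0), 2, 2,
#'   dimnames = list(c("D1", "D2"), c("D1", "D2"))))
#' m2 <- influence_assessment("b", matrix(c(0, 2, 1, 0), 2, 2,
#'   dimnames = list(c("D1", "D2"), c("D1", "D2"))))
#' aggregate_influence(list(m1, m2), p)  # (2*X1 + 1*X2) / 3
#' @export
aggregate_influence <- function(assessments, panel) {
  if (!length(assessments)) stop("at least one assessment is required")
  deps <- assessments[[1]]$departments
  for (a in assessments) {
    if (!setequal(a$departments, deps))
      stop("inconsistent department sets across assessments")
    validate_assessment(a, a$departments)
  }
  r <- rank_weights_for(vapply(assessments, `[[`, "", "expert_id"), panel)
  acc <- matrix(0, length(deps), length(deps), dimnames = list(deps, deps))
  for (k in seq_along(assessments)) {
    m <- assessments[[k]]$matrix[deps, deps, drop = FALSE]  # align by label
    acc <- acc + r[k] * m
  }
  z <- acc / sum(r)
  structure(z, class = c("consensus_matrix", class(z)),
            departments = deps,
            aggregation_note = sprintf("rank-weighted mean, divisor sum(rank)=%d",
                                       sum(r)))
}

#' Aggregate per-expert decision value tables
#'
#' Cell-wise rank-weighted mean of criteria-by-alternatives tables (criterion
#' weights or department scores on the 0--100 scale), with the same divisor
#' convention as [aggregate_influence()], so aggregated values stay in
#' \[0, 100\].
#'
#' @param tables list of numeric matrices/data frames of identical shape and
#'   dimnames, values in \[0, 100\]; names of the list (or a `expert_id`
#'   attribute per table) identify the experts.
#' @param panel an [expert_panel()].
#' @param expert_ids optional character vector naming the expert behind each
#'   table; defaults to `names(tables)`.
#' @return A numeric matrix, the rank-weighted mean table.
#' @export
aggregate_decision_values <- function(tables, panel, expert_ids = names(tables)) {
  if (!length(tables)) stop("at least one table is required")
  if (is.null(expert_ids))
    stop("tables must be named by expert_id (or pass expert_ids)")
  ref <- as.matrix(tables[[1]])
  for (tb in tables) {
    tb <- as.matrix(tb)
    if (!identical(dim(tb), dim(ref)) || !identical(dimnames(tb), dimnames(ref)))
      stop("all tables must share the same shape and labels")
    if (any(!is.finite(tb)) || any(tb < 0 | tb > 100))
      stop("table values must lie in [0, 100]")
  }
  r <- rank_weights_for(expert_ids, panel)
  acc <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (k in seq_along(tables)) acc <- acc + r[k] * as.matrix(tables[[k]])
  acc / sum(r)
}

#' @export
print.consensus_matrix <- function(x, digits = 3, ...) {
  cat("Consensus direct-relation matrix (", nrow(x), " departments)\n", sep = "")
  cat(attr(x, "aggregation_note"), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}
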