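#' Configuration for the synthetic case generator
#'
#' Defaults emulate the structure of the case study the pipeline was built
#' around: 20 diagnostic/therapeutic departments, a panel of 7 infection
#' and 7 managerial experts with rank weights in \{1, 2, 3\} (the pooled
#' rank frequencies of the 14-expert panel give the default rank
#' distribution), and 12 managerial criteria scored on 0--100.
#'
#' @param n_departments number of departments (>= 2), default 20.
#' @param n_experts_infection,n_experts_managerial panel sizes per cluster,
#'   default 7 each.
#' @param rank_distribution probabilities of ranks 1, 2, 3; must sum to 1.
#'   Default `c(3, 5, 6)/14`.
#' @param n_criteria number of managerial criteria, default 12.
#' @param influence_sparsity probability that a pairwise influence rating is
#'   0, default 0.3 (many department pairs have no direct infection
#'   pathway).
#' @param seed integer RNG seed.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_departments = 20,
                         n_experts_infection = 7,
                         n_experts_managerial = 7,
                         rank_distribution = c(3, 5, 6) / 14,
                         n_criteria = 12,
                         influence_sparsity = 0.3,
                         seed = 1L) {
  if (n_departments < 2) stop("n_departments must be >= 2")
  if (n_experts_infection < 1 || n_experts_managerial < 1)
    stop("each cluster needs at least one expert")
  if (n_criteria < 1) stop("n_criteria must be >= 1")
  if (length(rank_distribution) != 3 || any(rank_distribution < 0) ||
      abs(sum(rank_distribution) - 1) > 1e-9)
    stop("rank_distribution must be 3 probabilities over ranks {1,2,3} summing to 1")
  if (influence_sparsity < 0 || influence_sparsity > 1)
    stop("influence_sparsity must lie in [0, 1]")
  structure(list(n_departments = as.integer(n_departments),
                 n_experts_infection = as.integer(n_experts_infection),
                 n_experts_managerial = as.integer(n_experts_managerial),
                 rank_distribution = rank_distribution,
                 n_criteria = as.integer(n_criteria),
                 influence_sparsity = influence_sparsity,
                 seed = as.integer(seed)),
            class = "synth_config")
}

dep_labels <- function(n) paste0("ED", seq_len(n))
crit_labels <- function(n) paste0("MR", seq_len(n))

draw_influence_matrix <- function(deps, sparsity) {
  n <- length(deps)
  m <- matrix(0L, n, n, dimnames = list(deps, deps))
  off <- which(row(m) != col(m))
  nonzero <- stats::runif(length(off)) >= sparsity
  m[off[nonzero]] <- sample(1:4, sum(nonzero), replace = TRUE)
  m
}

#' Generate a complete synthetic case
#'
#' Draws an expert panel, one pairwise influence matrix per infection-cluster
#' expert (integer ratings 0--4, zero diagonal, zeros appearing with the
#' configured sparsity), and per managerial expert a raw criterion-weight
#' vector and a criteria-by-departments value table, both uniform on
#' \[0, 100\]. Fully reproducible from the configured seed.
#'
#' @param cfg a [synth_config()].
#' @return List with `panel`, `assessments` (influence assessments, one per
#'   infection expert), `weights_tables` (named list of raw weight vectors),
#'   `values_tables` (named list of value matrices), `departments`,
#'   `criteria`.
#' @examples
#' case <- generate_case(synth_config(n_departments = 5, seed = 42))
#' names(case$assessments)
#' @export
generate_case <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  deps <- dep_labels(cfg$n_departments)
  crits <- crit_labels(cfg$n_criteria)
  n_inf <- cfg$n_experts_infection
  n_man <- cfg$n_experts_managerial
  ids <- c(paste0("inf", seq_len(n_inf)), paste0("man", seq_len(n_man)))
  panel <- expert_panel(
    ids,
    rep(c("infection", "managerial"), c(n_inf, n_man)),
    sample(1:3, n_inf + n_man, replace = TRUE, prob = cfg$rank_distribution))
  assessments <- lapply(seq_len(n_inf), function(k)
    influence_assessment(ids[k],
                         draw_influence_matrix(deps, cfg$influence_sparsity)))
  names(assessments) <- ids[seq_len(n_inf)]
  man_ids <- ids[n_inf + seq_len(n_man)]
  weights_tables <- lapply(man_ids, function(id)
    stats::setNames(stats::runif(cfg$n_criteria, 0, 100), crits))
  names(weights_tables) <- man_ids
  values_tables <- lapply(man_ids, function(id)
    matrix(stats::runif(cfg$n_criteria * cfg$n_departments, 0, 100),
           cfg$n_criteria, cfg$n_departments,
           dimnames = list(crits, deps)))
  names(values_tables) <- man_ids
  list(panel = panel, assessments = assessments,
       weights_tables = weights_tables, values_tables = values_tables,
       departments = deps, criteria = crits)
}

#' Generate influence assessments with planted cause/effect structure
#'
#' Plants known master dispatchers (systematically high outgoing ratings,
#' low incoming) and master receivers (the reverse) in otherwise low-noise
#' matrices, so classification can be tested against a known ground truth.
#' At `noise = 0` every non-planted entry is 0 and planted entries are drawn
#' from \{3, 4\}, making recovery exact.
#'
#' @param cfg a [synth_config()].
#' @param dispatcher_ids,receiver_ids disjoint sets of department labels
#'   (`"ED<i>"`).
#' @param noise probability that a background entry is a 1 (low influence)
#'   instead of 0; default 0.
#' @return Named list of influence assessments, one per infection expert.
#' @export
generate_planted_structure <- function(cfg, dispatcher_ids, receiver_ids,
                                       noise = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(intersect(dispatcher_ids, receiver_ids)))
    stop("dispatcher and receiver id sets must be disjoint")
  set.seed(cfg$seed)
  deps <- dep_labels(cfg$n_departments)
  missing <- setdiff(c(dispatcher_ids, receiver_ids), deps)
  if (length(missing))
    stop("unknown department id(s): ", paste(missing, collapse = ", "))
  n <- length(deps)
  one <- function(id) {
    m <- matrix(0L, n, n, dimnames = list(deps, deps))
    off <- which(row(m) != col(m))
    if (noise > 0) {
      hit <- stats::runif(length(off)) < noise
      m[off[hit]] <- 1L
    }
    for (d in dispatcher_ids)
      m[d, setdiff(deps, d)] <- sample(3:4, n - 1, replace = TRUE)
    for (r in receiver_ids)
      m[setdiff(deps, r), r] <- sample(3:4, n - 1, replace = TRUE)
    # planted roles are unambiguous: dispatchers receive nothing,
    # receivers dispatch nothing
    m[, dispatcher_ids] <- 0L
    m[receiver_ids, ] <- 0L
    diag(m) <- 0L
    influence_assessment(id, m)
  }
  ids <- paste0("inf", seq_len(cfg$n_experts_infection))
  out <- lapply(ids, one)
  names(out) <- ids
  out
}
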