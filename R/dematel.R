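#' Normalize a direct-relation matrix
#'
#' Divides every element of the consensus direct-relation matrix Z by the
#' scale constant S, the largest row sum of Z, giving the normalised
#' direct-relation matrix D = Z / S whose largest row sum is exactly 1. An
#' optional variant takes S as the larger of the maximum row sum and the
#' maximum column sum, a common alternative in the DEMATEL literature; the
#' row-sum rule is the default.
#'
#' @param Z square non-negative numeric matrix (a [aggregate_influence()]
#'   consensus or any direct-relation matrix); must not be all zero.
#' @param variant `"max_row"` (default) or `"max_row_col"`.
#' @return List with elements `D` (normalised matrix) and `S` (scale
#'   constant).
#' @export
normalize_direct_relation <- function(Z, variant = c("max_row", "max_row_col")) {
  variant <- match.arg(variant)
  Z <- as.matrix(Z)
  if (nrow(Z) != ncol(Z)) stop("Z must be square")
  if (any(!is.finite(Z)) || any(Z < 0)) stop("Z must be finite and non-negative")
  S <- max(rowSums(Z))
  if (variant == "max_row_col") S <- max(S, max(colSums(Z)))
  if (S == 0)
    stop("Z is all zero: normalisation constant S = 0, division undefined")
  list(D = Z / S, S = S)
}

# spectral radius via eigen on the (possibly asymmetric) matrix
spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

#' Total-relation matrix and DEMATEL marginals
#'
#' Computes the total-relation matrix \eqn{T = D (I - D)^{-1}}, the matrix of
#' direct plus all indirect influence paths (the limit of the geometric
#' series \eqn{D + D^2 + \dots}), together with its marginals: R (row sums,
#' influence dispatched), C (column sums, influence received), prominence
#' R + C and relation R - C per department. Convergence of the series
#' requires the spectral radius of D to be strictly below 1; the function
#' refuses matrices that violate it.
#'
#' The linear system is solved with a dense `solve(I - D, D)` rather than an
#' explicit inverse, for conditioning.
#'
#' @param D normalised direct-relation matrix (from
#'   [normalize_direct_relation()]), or the list that function returns.
#' @return List of class `"total_relation"`: `T`, `R`, `C`, `prominence`,
#'   `relation`, `departments`.
#' @export
total_relation <- function(D) {
  if (is.list(D) && !is.null(D$D)) D <- D$D
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  rho <- spectral_radius(D)
  if (rho >= 1 - 1e-12)
    stop(sprintf(paste0("spectral radius of D is %.6f >= 1: the indirect-",
                        "influence series does not converge"), rho))
  Tm <- t(solve(t(diag(n) - D), t(D)))  # T = D (I - D)^{-1}
  dimnames(Tm) <- dimnames(D)
  deps <- rownames(D)
  if (is.null(deps)) deps <- paste0("V", seq_len(n))
  R <- rowSums(Tm)
  C <- colSums(Tm)
  structure(list(T = Tm,
                 R = stats::setNames(R, deps),
                 C = stats::setNames(C, deps),
                 prominence = stats::setNames(R + C, deps),
                 relation = stats::setNames(R - C, deps),
                 departments = deps),
            class = "total_relation")
}

#' Per-department relation scores
#'
#' Returns the four marginal statistics of a total-relation analysis --
#' influence dispatched R, influence received C, prominence R + C and net
#' relation R - C -- as a data frame, one row per department in canonical
#' order.
#'
#' @param res a `"total_relation"` result, a `"dematel"` fit, or any list
#'   carrying `departments` and per-department `R` and `C` vectors (e.g. a
#'   loaded fixture bundle); prominence and relation are recomputed from R
#'   and C.
#' @return Data frame with columns `department`, `R`, `C`, `prominence`,
#'   `relation`.
#' @export
relation_scores <- function(res) {
  R <- res$R[res$departments]
  C <- res$C[res$departments]
  data.frame(department = res$departments,
             R = unname(R),
             C = unname(C),
             prominence = unname(R + C),
             relation = unname(R - C),
             stringsAsFactors = FALSE)
}

#' Classify departments into cause and effect groups
#'
#' Departments with strictly positive relation R - C are net causes (they
#' dispatch more influence than they receive); strictly negative, net
#' receivers ("effect" group); exactly zero (within tolerance), neutral. The
#' department with the largest relation is flagged the master dispatcher and
#' the one with the smallest, the master receiver; ties are broken in favour
#' of the first department in canonical order and reported in the
#' `tie_note` attribute.
#'
#' @param res a `"total_relation"` result, a `"dematel"` fit, or a named
#'   numeric vector of R - C values.
#' @param tol absolute tolerance for treating a relation as zero.
#' @return Data frame with columns `department`, `relation`, `group`
#'   (`"cause"`, `"effect"` or `"neutral"`), `is_master_dispatcher`,
#'   `is_master_receiver`.
#' @export
classify_cause_effect <- function(res, tol = 1e-9) {
  if (is.numeric(res)) {
    rel <- res
    deps <- names(rel)
    if (is.null(deps)) deps <- paste0("V", seq_along(rel))
  } else {
    rel <- res$relation
    deps <- res$departments
  }
  group <- ifelse(rel > tol, "cause", ifelse(rel < -tol, "effect", "neutral"))
  i_max <- which.max(rel)   # which.max/min take the first index on ties
  i_min <- which.min(rel)
  out <- data.frame(department = deps,
                    relation = unname(rel),
                    group = unname(group),
                    is_master_dispatcher = seq_along(rel) == i_max,
                    is_master_receiver = seq_along(rel) == i_min,
                    stringsAsFactors = FALSE)
  ties <- character(0)
  if (sum(abs(rel - rel[i_max]) <= tol) > 1)
    ties <- c(ties, "tie at master dispatcher, first in canonical order kept")
  if (sum(abs(rel - rel[i_min]) <= tol) > 1)
    ties <- c(ties, "tie at master receiver, first in canonical order kept")
  attr(out, "tie_note") <- ties
  out
}

#' Fit a DEMATEL model to a direct-relation matrix
#'
#' The one-call interface to the DEMATEL (Decision-Making Trial and
#' Evaluation Laboratory) analysis: normalises the direct-relation matrix Z,
#' computes the total-relation matrix \eqn{T = D (I - D)^{-1}}, its marginals
#' R, C, R + C, R - C, and the cause/effect classification.
#'
#' @param Z square non-negative direct-relation matrix, e.g. from
#'   [aggregate_influence()]. Row i / column j reads "influence of department
#'   i on department j".
#' @param variant normalisation variant, see [normalize_direct_relation()].
#' @return An object of class `"dematel"`: list with `Z`, `D`, `S`, `T`, `R`,
#'   `C`, `prominence`, `relation`, `classification`, `departments`.
#' @examples
#' Z <- matrix(c(0, 2, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' fit <- dematel(Z)
#' fit$relation
#' summary(fit)
#' @export
dematel <- function(Z, variant = c("max_row", "max_row_col")) {
  nd <- normalize_direct_relation(Z, variant = match.arg(variant))
  tr <- total_relation(nd$D)
  structure(c(list(Z = as.matrix(Z), D = nd$D, S = nd$S),
              unclass(tr),
              list(classification = classify_cause_effect(tr))),
            class = "dematel")
}

#' @export
print.dematel <- function(x, digits = 4, ...) {
  cat("DEMATEL analysis of", length(x$departments), "departments\n")
  cat("normalisation constant S =", format(x$S, digits = digits), "\n")
  cl <- x$classification
  cat("cause group:", sum(cl$group == "cause"),
      "| effect group:", sum(cl$group == "effect"),
      "| neutral:", sum(cl$group == "neutral"), "\n")
  cat("master dispatcher:", cl$department[cl$is_master_dispatcher],
      " master receiver:", cl$department[cl$is_master_receiver], "\n")
  invisible(x)
}

#' @export
summary.dematel <- function(object, ...) {
  out <- merge(relation_scores(object),
               object$classification[, c("department", "group",
                                         "is_master_dispatcher",
                                         "is_master_receiver")],
               by = "department", sort = FALSE)
  out <- out[match(object$departments, out$department), ]
  rownames(out) <- NULL
  class(out) <- c("summary.dematel", "data.frame")
  out
}

#' @export
print.summary.dematel <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y)
  invisible(x)
}

#' @export
coef.dematel <- function(object, ...) object$relation

#' Bar chart of net relations
#'
#' Plots R - C per department in canonical order: positive bars are the cause
#' group, negative bars the effect group (mirroring the grey/black bar chart
#' convention used when presenting DEMATEL results to decision makers).
#'
#' @param x a `"dematel"` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dematel <- function(x, ...) {
  cols <- ifelse(x$relation >= 0, "grey60", "black")
  graphics::barplot(x$relation, col = cols, las = 2,
                    ylab = "relation (R - C)",
                    main = "DEMATEL cause (grey) / effect (black)", ...)
  invisible(x)
}

#' @export
as.data.frame.dematel <- function(x, ...) summary(x)

#' Truncated-series evaluation of the total-relation matrix
#'
#' Evaluates \eqn{D + D^2 + \dots + D^K} by repeated multiplication. This is
#' the defining geometric series of the total-relation matrix and serves as an
#' independent numerical check on the linear-solve route of
#' [total_relation()]; it deliberately avoids `solve()`.
#'
#' @param D normalised direct-relation matrix with spectral radius < 1.
#' @param K number of terms to sum.
#' @return The truncated series, an n x n matrix.
#' @export
total_relation_series <- function(D, K = 200) {
  D <- as.matrix(D)
  acc <- D
  P <- D
  for (k in 2:K) {
    P <- P %*% D
    acc <- acc + P
  }
  acc
}
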