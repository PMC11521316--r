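#' Solve a linear program
#'
#' Thin interface over the package's dense two-phase simplex. Constraint
#' senses follow the usual textbook convention; variable bounds may be
#' infinite on either side.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or a \pkg{Matrix} sparse matrix.
#' @param sense character vector of "<=", "=", ">=" per row.
#' @param rhs numeric right-hand sides (length m).
#' @param lower,upper variable bounds; scalars are recycled. Defaults are
#'   \code{0} and \code{Inf}.
#' @param maximize maximize (default) or minimize.
#' @param feas_tol absolute feasibility tolerance used in phase 1.
#'
#' @return list with \code{status} ("optimal", "infeasible", "unbounded",
#'   "iteration-limit"), \code{objective} and primal solution \code{x}.
#' @export
solve_lp <- function(obj, A, sense, rhs, lower = 0, upper = Inf,
                     maximize = TRUE, feas_tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m)
  sns <- match(sense, c("<=", "=", ">=")) - 2L
  if (anyNA(sns)) stop("sense entries must be one of '<=', '=', '>='")
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  # geometric equilibration: scale columns and rows to unit max magnitude
  # (keeps the tableau well conditioned when capacities span decades)
  ab <- abs(A)
  cs <- apply(ab, 2, max)
  cs[cs == 0 | !is.finite(cs)] <- 1
  A1 <- sweep(A, 2, cs, "/")
  rs <- apply(abs(A1), 1, max)
  rs[rs == 0 | !is.finite(rs)] <- 1
  A1 <- sweep(A1, 1, rs, "/")
  res <- .cpp_simplex(A1, as.numeric(rhs) / rs, sns,
                      as.numeric(obj) / cs, isTRUE(maximize),
                      lower * cs, upper * cs, feas_tol = feas_tol)
  res$x <- res$x / cs
  res$status <- c("optimal", "infeasible", "unbounded",
                  "iteration-limit")[res$status + 1L]
  names(res$x) <- colnames(A)
  res
}
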