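#' Solver settings for the community growth problem
#'
#' @param mu_tolerance bisection convergence threshold on the community
#'   growth rate (h^-1).
#' @param mu_upper_seed initial upper bound for the growth-rate bisection;
#'   by default the largest standalone FBA growth rate across guilds
#'   (doubled as needed until infeasible).
#' @param flux_resolution "none" or "parsimonious" (minimize total absolute
#'   internal flux at the optimum to pick a unique flux distribution).
#' @param zero_flux_threshold magnitude below which a reported flux is set
#'   to exact zero (mmol gO2-cell^-1 h^-1).
#' @param feas_tol LP feasibility tolerance.
#' @return list of settings.
#' @export
solver_settings <- function(mu_tolerance = 1e-6, mu_upper_seed = NULL,
                            flux_resolution = c("none", "parsimonious"),
                            zero_flux_threshold = 1e-6, feas_tol = 1e-8) {
  stopifnot(mu_tolerance > 0, zero_flux_threshold >= 0)
  list(mu_tolerance = mu_tolerance, mu_upper_seed = mu_upper_seed,
       flux_resolution = match.arg(flux_resolution),
       zero_flux_threshold = zero_flux_threshold, feas_tol = feas_tol)
}

# Build the LP "max sum X_k subject to Eq.-style constraints at fixed mu".
# Variable order: V (all guilds, concatenated), X (one per guild),
# u (per pool metabolite), e (per pool metabolite).
build_community_lp <- function(model, mu) {
  gs <- model$guilds
  K <- length(gs)
  nV <- vapply(gs, function(g) nrow(g$reactions), 0L)
  offV <- c(0L, cumsum(nV))[seq_len(K)]
  names(offV) <- names(gs)
  P <- length(model$com_mets)
  n <- sum(nV) + K + 2L * P
  iX <- sum(nV) + seq_len(K)
  iU <- sum(nV) + K + seq_len(P)
  iE <- sum(nV) + K + P + seq_len(P)

  lower <- rep(-Inf, n)
  upper <- rep(Inf, n)
  lower[iX] <- 0
  lower[iU] <- 0
  lower[iE] <- 0
  ub_u <- model$uptake_bounds[model$com_mets]
  ub_e <- model$export_bounds[model$com_mets]
  free <- model$com_mets %in% model$free_mets
  upper[iU] <- ifelse(free, Inf, ub_u)
  upper[iE] <- ifelse(free, Inf, ub_e)

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  sense <- character(0); rhs <- numeric(0)
  nrow_ <- 0L
  add_row <- function(cols, vals, sn, b) {
    ti <<- c(ti, rep(nrow_ + 1L, length(cols)))
    tj <<- c(tj, cols)
    tv <<- c(tv, vals)
    sense <<- c(sense, sn)
    rhs <<- c(rhs, b)
    nrow_ <<- nrow_ + 1L
  }

  com_idx <- stats::setNames(seq_len(P), model$com_mets)
  com_cols <- vector("list", P)   # accumulate exchange columns per pool met

  for (k in seq_len(K)) {
    g <- gs[[k]]
    off <- offV[k]
    Ssum <- Matrix::summary(g$S)
    # metabolite balance rows S v = 0 (one block per guild)
    base <- nrow_
    ti <- c(ti, base + Ssum$i)
    tj <- c(tj, off + Ssum$j)
    tv <- c(tv, Ssum$x)
    nmet <- nrow(g$metabolites)
    sense <- c(sense, rep("=", nmet))
    rhs <- c(rhs, rep(0, nmet))
    nrow_ <- nrow_ + nmet
    # abundance-scaled capacity bounds LB*X <= V <= UB*X
    for (j in seq_len(nV[k])) {
      lb <- g$reactions$lb[j]; ub <- g$reactions$ub[j]
      vcol <- off + j
      if (is.finite(lb)) {
        if (lb == 0) lower[vcol] <- 0
        else add_row(c(vcol, iX[k]), c(1, -lb), ">=", 0)
      }
      if (is.finite(ub)) {
        if (ub == 0) upper[vcol] <- 0
        else add_row(c(vcol, iX[k]), c(1, -ub), "<=", 0)
      }
    }
    # biomass coupling V_biomass = mu * X
    jb <- match(g$biomass, g$reactions$id)
    add_row(c(off + jb, iX[k]), c(1, -mu), "=", 0)
    # collect exchange columns for the COM balance
    for (rx in names(g$exchange)) {
      met <- g$exchange[[rx]]
      p <- com_idx[[met]]
      com_cols[[p]] <- c(com_cols[[p]], off + match(rx, g$reactions$id))
    }
  }
  # COM balance: u_i - e_i + sum_k Vex(i)^k = 0
  for (p in seq_len(P)) {
    cols <- c(com_cols[[p]], iU[p], iE[p])
    vals <- c(rep(1, length(com_cols[[p]])), 1, -1)
    add_row(cols, vals, "=", 0)
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nrow_, n))
  list(A = A, sense = sense, rhs = rhs, lower = lower, upper = upper,
       iX = iX, iU = iU, iE = iE, offV = offV, nV = nV)
}

parse_community_solution <- function(model, x, lp, mu, status,
                                     zero_threshold = 0) {
  gs <- model$guilds
  abund <- stats::setNames(x[lp$iX], names(gs))
  fl <- do.call(rbind, lapply(seq_along(gs), function(k) {
    g <- gs[[k]]
    v <- x[lp$offV[k] + seq_len(lp$nV[k])]
    data.frame(guild = g$guild_id, reaction = g$reactions$id, flux = v,
               stringsAsFactors = FALSE)
  }))
  if (zero_threshold > 0) fl$flux[abs(fl$flux) < zero_threshold] <- 0
  ex <- do.call(rbind, lapply(gs, function(g) {
    idx <- match(names(g$exchange), g$reactions$id)
    data.frame(guild = g$guild_id, metabolite = unname(g$exchange),
               flux = fl$flux[fl$guild == g$guild_id][idx],
               stringsAsFactors = FALSE)
  }))
  rownames(ex) <- NULL
  structure(list(mu = mu, abundances = abund, fluxes = fl,
                 exchange_fluxes = ex,
                 community_uptake = stats::setNames(x[lp$iU], model$com_mets),
                 community_export = stats::setNames(x[lp$iE], model$com_mets),
                 status = status),
            class = "steadycom_solution")
}

#' @export
print.steadycom_solution <- function(x, ...) {
  cat(sprintf("<steadycom_solution> status = %s, mu = %.6g h^-1\n",
              x$status, x$mu))
  ab <- paste(sprintf("%s = %.4f", names(x$abundances), x$abundances),
              collapse = ", ")
  cat("  abundances:", ab, "\n")
  invisible(x)
}

#' Feasibility of a community growth rate
#'
#' For a fixed growth rate mu, maximizes total community abundance
#' sum_k X^k subject to per-guild mass balance, abundance-scaled capacity
#' bounds, biomass coupling and pool metabolite balance. The community can
#' sustain total abundance X0 at growth rate mu iff the optimum is >= X0.
#'
#' @param model a \code{community_model} (with condition bounds applied).
#' @param mu community growth rate (h^-1), >= 0.
#' @param feas_tol LP feasibility tolerance.
#' @param fix_total pin the total abundance to X0 instead of maximizing
#'   it (used to extract a witness when the maximum is unbounded, e.g.
#'   under freely supplied substrate).
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{max_sigma_x}, \code{feasible} (optimum >= X0), and the witness
#'   \code{solution} (a \code{steadycom_solution}) when optimal.
#' @export
solve_at_growth <- function(model, mu, feas_tol = 1e-8,
                            fix_total = FALSE) {
  stopifnot(inherits(model, "community_model"), mu >= 0)
  lp <- build_community_lp(model, mu)
  obj <- numeric(ncol(lp$A))
  obj[lp$iX] <- 1
  A <- lp$A; sense <- lp$sense; rhs <- lp$rhs
  if (fix_total) {
    A <- rbind(A, Matrix::sparseMatrix(i = rep(1L, length(lp$iX)),
                                       j = lp$iX, x = 1,
                                       dims = c(1L, ncol(A))))
    sense <- c(sense, "=")
    rhs <- c(rhs, model$x0)
  }
  res <- solve_lp(obj, A, sense, rhs, lp$lower, lp$upper,
                  maximize = TRUE, feas_tol = feas_tol)
  if (res$status != "optimal")
    return(list(status = res$status, max_sigma_x = NA_real_,
                feasible = res$status == "unbounded", solution = NULL))
  sol <- parse_community_solution(model, res$x, lp, mu, "optimal")
  list(status = "optimal", max_sigma_x = res$objective,
       feasible = res$objective >= model$x0 - 1e-9, solution = sol)
}

#' Maximize community growth (SteadyCom)
#'
#' Finds the largest growth rate mu* at which the community can sustain
#' total abundance X0, by monotone bisection on mu over the feasibility
#' problem of \code{\link{solve_at_growth}}; the witness at mu* is rescaled
#' so that sum_k X^k = X0 (the constraint set is homogeneous in (V, X) at
#' fixed mu, so downscaling preserves feasibility). Deterministic for fixed
#' settings.
#'
#' @param model a \code{community_model} with condition bounds applied.
#' @param settings a \code{\link{solver_settings}} list.
#' @return a \code{steadycom_solution}; \code{mu = 0} with status
#'   "infeasible-growth" when no mu >= mu_tolerance is feasible. When
#'   \code{flux_resolution = "parsimonious"} the fluxes are additionally
#'   passed through \code{\link{resolve_fluxes}}.
#' @export
maximize_growth <- function(model, settings = solver_settings()) {
  stopifnot(inherits(model, "community_model"))
  tol <- settings$mu_tolerance
  base <- solve_at_growth(model, tol, feas_tol = settings$feas_tol)
  if (!isTRUE(base$feasible)) {
    lp <- build_community_lp(model, 0)
    sol <- parse_community_solution(model, numeric(ncol(lp$A)), lp, 0,
                                    "infeasible-growth")
    return(sol)
  }
  hi <- settings$mu_upper_seed
  if (is.null(hi) || !is.finite(hi) || hi <= tol) {
    hi <- max(c(tol * 10, vapply(model$guilds, function(g) {
      avail <- ifelse(model$com_mets %in% model$free_mets, Inf,
                      model$uptake_bounds[model$com_mets])
      f <- fba(g, exchange_lb = stats::setNames(-avail, model$com_mets))
      if (f$status == "optimal") f$objective else 0
    }, 0)))
  }
  lo <- tol
  while (hi < 1e4) {
    r <- solve_at_growth(model, hi, feas_tol = settings$feas_tol)
    if (isTRUE(r$feasible)) { lo <- hi; hi <- hi * 2 } else break
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- solve_at_growth(model, mid, feas_tol = settings$feas_tol)
    if (isTRUE(r$feasible)) lo <- mid else hi <- mid
  }
  fin <- solve_at_growth(model, lo, feas_tol = settings$feas_tol)
  if (fin$status == "unbounded")    # e.g. free substrate: pin the scale
    fin <- solve_at_growth(model, lo, feas_tol = settings$feas_tol,
                           fix_total = TRUE)
  if (is.null(fin$solution))
    stop("solver failed at the converged growth rate: ", fin$status)
  sol <- fin$solution
  scale <- model$x0 / sum(sol$abundances)
  sol$abundances <- sol$abundances * scale
  sol$fluxes$flux <- sol$fluxes$flux * scale
  sol$exchange_fluxes$flux <- sol$exchange_fluxes$flux * scale
  sol$community_uptake <- sol$community_uptake * scale
  sol$community_export <- sol$community_export * scale
  sol$status <- "optimal"
  if (settings$flux_resolution == "parsimonious")
    sol <- resolve_fluxes(model, sol, settings)
  else
    sol$fluxes$flux[abs(sol$fluxes$flux) < settings$zero_flux_threshold] <- 0
  sol
}

#' Parsimonious flux resolution at a fixed community optimum
#'
#' SteadyCom optima are flux-degenerate: many flux distributions support
#' the same (mu, X). With mu and the abundances fixed, this re-solves for
#' the distribution minimizing total absolute flux over internal (non
#' exchange) reactions, which zeroes free cycles and makes reported fluxes
#' unique up to remaining ties. Fluxes below the zero threshold are then
#' set to exact zero.
#'
#' @param model a \code{community_model}.
#' @param solution an optimal \code{steadycom_solution}.
#' @param settings a \code{\link{solver_settings}} list.
#' @return the solution with resolved fluxes.
#' @export
resolve_fluxes <- function(model, solution, settings = solver_settings()) {
  stopifnot(inherits(solution, "steadycom_solution"))
  if (!solution$status %in% "optimal")
    stop("resolve_fluxes needs an optimal solution")
  gs <- model$guilds
  K <- length(gs)
  X <- solution$abundances
  mu <- solution$mu
  nV <- vapply(gs, function(g) nrow(g$reactions), 0L)
  offV <- c(0L, cumsum(nV))[seq_len(K)]
  P <- length(model$com_mets)

  # internal (costed) reactions: everything but exchanges
  costed <- unlist(lapply(seq_len(K), function(k) {
    g <- gs[[k]]
    offV[k] + which(!(g$reactions$id %in% names(g$exchange)))
  }))
  nv <- sum(nV)
  n <- nv + 2L * P + length(costed)      # V, u, e, t
  iU <- nv + seq_len(P)
  iE <- nv + P + seq_len(P)
  iT <- nv + 2L * P + seq_along(costed)

  lower <- rep(-Inf, n); upper <- rep(Inf, n)
  free <- model$com_mets %in% model$free_mets
  lower[c(iU, iE)] <- 0
  upper[iU] <- ifelse(free, Inf, model$uptake_bounds[model$com_mets])
  upper[iE] <- ifelse(free, Inf, model$export_bounds[model$com_mets])
  lower[iT] <- 0

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  sense <- character(0); rhs <- numeric(0); nrow_ <- 0L
  add_row <- function(cols, vals, sn, b) {
    ti <<- c(ti, rep(nrow_ + 1L, length(cols)))
    tj <<- c(tj, cols); tv <<- c(tv, vals)
    sense <<- c(sense, sn); rhs <<- c(rhs, b)
    nrow_ <<- nrow_ + 1L
  }
  com_idx <- stats::setNames(seq_len(P), model$com_mets)
  com_cols <- vector("list", P)
  for (k in seq_len(K)) {
    g <- gs[[k]]
    off <- offV[k]
    Ssum <- Matrix::summary(g$S)
    ti <- c(ti, nrow_ + Ssum$i); tj <- c(tj, off + Ssum$j); tv <- c(tv, Ssum$x)
    nmet <- nrow(g$metabolites)
    sense <- c(sense, rep("=", nmet)); rhs <- c(rhs, rep(0, nmet))
    nrow_ <- nrow_ + nmet
    # with X fixed, capacity bounds are plain variable bounds
    lbx <- ifelse(is.finite(g$reactions$lb), g$reactions$lb * X[k], -Inf)
    ubx <- ifelse(is.finite(g$reactions$ub), g$reactions$ub * X[k], Inf)
    lower[off + seq_len(nV[k])] <- lbx
    upper[off + seq_len(nV[k])] <- ubx
    jb <- off + match(g$biomass, g$reactions$id)
    lower[jb] <- upper[jb] <- mu * X[k]
    for (rx in names(g$exchange)) {
      p <- com_idx[[g$exchange[[rx]]]]
      com_cols[[p]] <- c(com_cols[[p]], off + match(rx, g$reactions$id))
    }
  }
  for (p in seq_len(P))
    add_row(c(com_cols[[p]], iU[p], iE[p]),
            c(rep(1, length(com_cols[[p]])), 1, -1), "=", 0)
  for (q in seq_along(costed)) {       # t >= |V|
    add_row(c(iT[q], costed[q]), c(1, -1), ">=", 0)
    add_row(c(iT[q], costed[q]), c(1, 1), ">=", 0)
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nrow_, n))
  obj <- numeric(n); obj[iT] <- 1
  res <- solve_lp(obj, A, sense, rhs, lower, upper, maximize = FALSE,
                  feas_tol = settings$feas_tol)
  if (res$status != "optimal")         # numerical slack: relax equalities
    res <- solve_lp(obj, A, sense, rhs, lower, upper, maximize = FALSE,
                    feas_tol = 1e-7)
  if (res$status != "optimal")
    stop("parsimonious resolution failed: ", res$status)

  x <- res$x
  zt <- settings$zero_flux_threshold
  fl <- solution$fluxes
  v <- x[seq_len(nv)]
  v[abs(v) < zt] <- 0
  fl$flux <- v
  ex <- solution$exchange_fluxes
  ex$flux <- unlist(lapply(seq_len(K), function(k) {
    g <- gs[[k]]
    v[offV[k] + match(names(g$exchange), g$reactions$id)]
  }), use.names = FALSE)
  solution$fluxes <- fl
  solution$exchange_fluxes <- ex
  solution$community_uptake <- stats::setNames(x[iU], model$com_mets)
  solution$community_export <- stats::setNames(x[iE], model$com_mets)
  solution$total_internal_flux <- res$objective
  solution
}

#' Serialize a SteadyCom solution
#'
#' @param solution a \code{steadycom_solution}.
#' @param path output file; format picked by extension (".json" or ".tsv";
#'   TSV holds the flat flux table: guild, reaction, flux).
#' @return \code{path}, invisibly.
#' @export
write_solution <- function(solution, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(mu = solution$mu,
                              status = solution$status,
                              abundances = as.list(solution$abundances),
                              community_uptake = as.list(solution$community_uptake),
                              community_export = as.list(solution$community_export),
                              fluxes = solution$fluxes,
                              exchange_fluxes = solution$exchange_fluxes),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(solution$fluxes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
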