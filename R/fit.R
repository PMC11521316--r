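#' Capacity parameter sets
#'
#' A capacity parameter set names guild exchange-capacity bounds
#' vex(i)^k: one row per (guild, pool metabolite, bound side) with the
#' bound value in mmol gO2-cell^-1 h^-1 (negative values on the lower
#' side mean maximal consumption, positive values on the upper side mean
#' maximal secretion).
#'
#' @param guild,metabolite,side,value equal-length vectors defining the
#'   entries; \code{side} is "lower" or "upper".
#' @param provenance "manual" or "fitted".
#' @return object of class \code{capacity_set}.
#' @export
capacity_set <- function(guild, metabolite, side, value,
                         provenance = "manual") {
  side <- match.arg(side, c("lower", "upper"), several.ok = TRUE)
  entries <- data.frame(guild = guild, metabolite = metabolite,
                        side = side, value = as.numeric(value),
                        stringsAsFactors = FALSE)
  key <- paste(entries$guild, entries$metabolite)
  for (k in unique(key[duplicated(key)])) {
    e <- entries[key == k, ]
    lo <- e$value[e$side == "lower"]; hi <- e$value[e$side == "upper"]
    if (length(lo) && length(hi) && max(lo) > min(hi))
      stop("lower capacity exceeds upper capacity for ", k)
  }
  structure(list(entries = entries, provenance = provenance),
            class = "capacity_set")
}

#' Apply a capacity set to a community model
#'
#' @param model a \code{community_model}.
#' @param capacities a \code{\link{capacity_set}}.
#' @return the model with the guild exchange bounds replaced.
#' @export
apply_capacities <- function(model, capacities) {
  stopifnot(inherits(model, "community_model"),
            inherits(capacities, "capacity_set"))
  for (i in seq_len(nrow(capacities$entries))) {
    e <- capacities$entries[i, ]
    if (!e$guild %in% names(model$guilds))
      stop("unknown guild in capacity set: ", e$guild)
    g <- model$guilds[[e$guild]]
    model$guilds[[e$guild]] <-
      if (e$side == "lower") set_capacity(g, e$metabolite, lower = e$value)
      else set_capacity(g, e$metabolite, upper = e$value)
  }
  model
}

#' Percent error between predicted and observed abundances
#'
#' Per guild: |predicted - observed| / observed x 100; the average is the
#' unweighted mean. Undefined when an observed abundance is zero.
#'
#' @param predicted,observed numeric abundance vectors over the same
#'   guilds in the same order (names checked when both are named).
#' @return list with \code{per_guild} (named) and \code{average}.
#' @export
percent_error <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have the same length")
  if (!is.null(names(predicted)) && !is.null(names(observed)) &&
      !identical(names(predicted), names(observed)))
    stop("guild ordering differs between predicted and observed")
  if (any(observed <= 0)) stop("percent error undefined for observed <= 0")
  per <- abs(predicted - observed) / observed * 100
  list(per_guild = per, average = mean(per))
}

#' Fit guild exchange capacities to observed abundances
#'
#' Exhaustive deterministic grid search: each grid point is a capacity
#' assignment, evaluated by solving the community growth problem and
#' scoring the simulated abundances against the observations with
#' \code{\link{percent_error}}. With more than three axes (or when
#' \code{method = "sequential"}) the axes are instead refined one at a
#' time in order, each sweep holding the other parameters at their
#' current best. Ties keep the first point in row-major scan order.
#'
#' @param model a \code{community_model} with the condition applied.
#' @param observed data.frame(guild, abundance) or named numeric vector;
#'   must cover the model's guilds and sum to X0 (1 percent slack).
#' @param search_space named list of numeric grids; names have the form
#'   "GUILD.metabolite.side", e.g. "SOB.ac.lower".
#' @param settings solver settings.
#' @param method "joint" (full grid) or "sequential" (coordinate sweeps).
#' @return object of class \code{fit_result}: \code{best} (a
#'   \code{\link{capacity_set}} with provenance "fitted"), per-guild and
#'   average percent error, and the full \code{search_trace}.
#' @export
fit_exchange_capacities <- function(model, observed, search_space,
                                    settings = solver_settings(),
                                    method = c("joint", "sequential")) {
  stopifnot(inherits(model, "community_model"), length(search_space) >= 1)
  method <- match.arg(method)
  if (is.data.frame(observed))
    observed <- stats::setNames(observed$abundance, observed$guild)
  observed <- observed[names(model$guilds)]
  if (anyNA(observed)) stop("observed abundances must cover every guild")
  if (abs(sum(observed) - model$x0) > 0.01 * model$x0)
    stop("observed abundances must sum to X0 within 1 percent")
  axes <- lapply(search_space, as.numeric)
  if (any(!vapply(axes, length, 0L))) stop("empty search axis")
  parts <- strsplit(names(axes), ".", fixed = TRUE)
  if (any(vapply(parts, length, 0L) != 3))
    stop("search_space names must be 'GUILD.metabolite.side'")

  as_capset <- function(values, provenance = "manual")
    capacity_set(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2),
                 vapply(parts, `[[`, "", 3), values, provenance)
  evaluate <- function(values) {
    m <- apply_capacities(model, as_capset(values))
    sol <- tryCatch(maximize_growth(m, settings), error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") return(NULL)
    pe <- percent_error(sol$abundances, observed)
    list(error = pe$average, per_guild = pe$per_guild)
  }

  trace <- data.frame()
  record <- function(values, ev) {
    row <- as.data.frame(as.list(stats::setNames(values, names(axes))))
    row$average_error <- if (is.null(ev)) NA_real_ else ev$error
    row$status <- if (is.null(ev)) "infeasible" else "ok"
    trace <<- rbind(trace, row)
    ev
  }

  best <- NULL
  if (method == "joint" && length(axes) <= 3) {
    grid <- rev(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
    for (i in seq_len(nrow(grid))) {
      vals <- as.numeric(grid[i, ])
      ev <- record(vals, evaluate(vals))
      if (!is.null(ev) && (is.null(best) || ev$error < best$error - 1e-12))
        best <- c(ev, list(values = vals))
    }
  } else {
    current <- vapply(axes, function(a) a[ceiling(length(a) / 2)], 0)
    for (pass in 1:2) {
      for (j in seq_along(axes)) {
        for (v in axes[[j]]) {
          vals <- current
          vals[j] <- v
          ev <- record(vals, evaluate(vals))
          if (!is.null(ev) && (is.null(best) || ev$error < best$error - 1e-12)) {
            best <- c(ev, list(values = vals))
            current <- vals
          }
        }
      }
    }
  }
  if (is.null(best))
    return(structure(list(best = NULL, per_guild_error = NULL,
                          average_error = NA_real_, search_trace = trace,
                          status = "all grid points infeasible"),
                     class = "fit_result"))
  structure(list(best = as_capset(best$values, "fitted"),
                 best_values = stats::setNames(best$values, names(axes)),
                 per_guild_error = best$per_guild,
                 average_error = best$error,
                 search_trace = trace, status = "ok"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<fit_result>", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("<fit_result> average percent error %.3f over %d evaluated point(s)\n",
              x$average_error, nrow(x$search_trace)))
  print(x$best$entries)
  invisible(x)
}

#' Write a fit result (including the search trace) as JSON
#' @param fit a \code{fit_result}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(best = fit$best$entries,
                            per_guild_error = as.list(fit$per_guild_error),
                            average_error = fit$average_error,
                            status = fit$status,
                            search_trace = fit$search_trace),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
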