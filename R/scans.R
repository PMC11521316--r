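#' Sensitivity scans over loading, capacities and acidity
#'
#' The scan engine re-solves the community growth problem over parameter
#' grids: a joint linear butyrate/acetate loading sweep, a 2-D scan of
#' the SRB sulfide-release and SOB acetate-consumption capacities, and an
#' exponential community proton-uptake sweep. Results are returned as a
#' \code{scan_result}: a tidy per-point table (growth rate, abundances,
#' dominance) plus long-format exchange-flux series with min-max
#' normalized values.
#'
#' @name scan_engine
NULL

scan_point <- function(model, settings, axis_values) {
  sol <- tryCatch(maximize_growth(model, settings), error = function(e) NULL)
  if (is.null(sol) || sol$status != "optimal") {
    row <- data.frame(mu = NA_real_, status = if (is.null(sol)) "error"
                                              else sol$status)
    ab <- stats::setNames(rep(NA_real_, length(model$guilds)),
                          names(model$guilds))
    return(list(row = cbind(as.data.frame(as.list(axis_values)), row,
                            as.data.frame(as.list(ab))),
                exchange = NULL, solution = NULL))
  }
  row <- cbind(as.data.frame(as.list(axis_values)),
               data.frame(mu = sol$mu, status = "optimal"),
               as.data.frame(as.list(sol$abundances)))
  ex <- sol$exchange_fluxes
  ex <- cbind(as.data.frame(as.list(axis_values))[rep(1, nrow(ex)), ,
                                                  drop = FALSE], ex)
  ex$specific_flux <- ex$flux / sol$abundances[ex$guild]
  list(row = row, exchange = ex, solution = sol)
}

finish_scan <- function(rows, exchanges, axes, model, track) {
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  guilds <- names(model$guilds)
  ab <- as.matrix(tab[, guilds, drop = FALSE])
  tab$dominant <- ifelse(apply(ab, 1, function(r) all(is.na(r))),
                         NA_character_,
                         guilds[apply(ab, 1, which.max)])
  ex <- do.call(rbind, Filter(Negate(is.null), exchanges))
  norm <- NULL
  if (!is.null(ex) && nrow(ex)) {
    rownames(ex) <- NULL
    if (!is.null(track)) ex <- ex[ex$metabolite %in% track, , drop = FALSE]
    parts <- split(ex, list(ex$guild, ex$metabolite), drop = TRUE)
    norm <- do.call(rbind, lapply(parts, function(p) {
      p <- p[is.finite(p$flux), , drop = FALSE]
      if (nrow(p) >= 2) {
        p$normalized_flux <- minmax_normalize(p$flux)$values
        fin <- is.finite(p$specific_flux)
        p$normalized_specific <- NA_real_
        if (sum(fin) >= 2)
          p$normalized_specific[fin] <- minmax_normalize(p$specific_flux[fin])$values
      } else {
        p$normalized_flux <- NA_real_
        p$normalized_specific <- NA_real_
      }
      p
    }))
    rownames(norm) <- NULL
  }
  structure(list(axes = axes, solutions = tab, normalized_series = norm),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d point(s) over %s\n", nrow(x$solutions),
              paste(names(x$axes), collapse = " x ")))
  dom <- table(x$solutions$dominant, useNA = "ifany")
  cat("  dominance:", paste(names(dom), dom, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Joint organic-loading sweep
#'
#' Increases the community butyrate and acetate uptake bounds linearly
#' and jointly across their ranges (a single scalar interpolates both),
#' holding every other constraint at the base condition; one solve per
#' point, with infeasible points recorded and skipped.
#'
#' @param model a \code{community_model}.
#' @param condition_base base condition (default the low-loading preset).
#' @param butyrate_range,acetate_range sweep ranges
#'   (mmol gO2-cell^-1 h^-1).
#' @param n_points grid resolution.
#' @param settings solver settings.
#' @param track pool metabolites to keep in the normalized flux series
#'   (NULL = all).
#' @return a \code{scan_result} with axes butyrate and acetate.
#' @export
olr_sweep <- function(model, condition_base = condition_preset("L-OLR"),
                      butyrate_range = c(0.48, 3.61),
                      acetate_range = c(0.77, 2.09), n_points = 25,
                      settings = solver_settings(),
                      track = c("but", "ac", "so4", "h2s", "s0", "co2",
                                "ch4", "h2", "for")) {
  stopifnot(n_points >= 2, all(butyrate_range > 0), all(acetate_range > 0))
  t <- seq(0, 1, length.out = n_points)
  but <- butyrate_range[1] + t * diff(butyrate_range)
  ac <- acetate_range[1] + t * diff(acetate_range)
  rows <- list(); exch <- list()
  for (i in seq_len(n_points)) {
    cs <- condition_base
    cs$community_rates[["but"]] <- but[i]
    cs$community_rates[["ac"]] <- ac[i]
    p <- scan_point(apply_condition(model, cs), settings,
                    c(butyrate = but[i], acetate = ac[i]))
    rows[[i]] <- p$row; exch[[i]] <- p$exchange
  }
  finish_scan(rows, exch, list(butyrate = but, acetate = ac), model, track)
}

#' Two-dimensional SRB-SOB capacity scan
#'
#' For each combination of the SRB sulfide-release capacity (upper bound
#' of vex(Sulfide)SRB) and the SOB acetate-consumption capacity (lower
#' bound of vex(Acetate)SOB), runs a loading sweep and records the
#' dominance map and the loading at which SOB dominance is lost,
#' expressed as the percent increase of butyrate and acetate over the
#' low-loading baseline.
#'
#' @param model a \code{community_model}.
#' @param condition base condition for the embedded loading sweeps.
#' @param sob_acetate_lb_range range of the (negative) SOB acetate lower
#'   bound; default -1.05 to -3.15.
#' @param srb_sulfide_ub_range range of the SRB sulfide upper bound;
#'   default 4.39 to 13.18.
#' @param n_capacity grid points per capacity axis.
#' @param loading_points points of the embedded loading sweep.
#' @param baseline named vector with the baseline butyrate/acetate rates
#'   used for the percent-increase readout.
#' @param settings solver settings.
#' @param transient_gap abundance gap below which a grid cell is labeled
#'   transient (fraction of X0).
#' @return a \code{scan_result}; \code{solutions} carries one row per
#'   (capacity, loading) point, and \code{transitions} one row per
#'   capacity pair with the dominance-loss loading and percent increases.
#' @export
capacity_scan_2d <- function(model, condition = condition_preset("L-OLR"),
                             sob_acetate_lb_range = c(-1.05, -3.15),
                             srb_sulfide_ub_range = c(4.39, 13.18),
                             n_capacity = 3, loading_points = 9,
                             baseline = c(butyrate = 1.606, acetate = 1.245),
                             settings = solver_settings(),
                             transient_gap = 0.05) {
  sob_caps <- seq(sob_acetate_lb_range[1], sob_acetate_lb_range[2],
                  length.out = n_capacity)
  srb_caps <- seq(srb_sulfide_ub_range[1], srb_sulfide_ub_range[2],
                  length.out = n_capacity)
  rows <- list(); exch <- list(); trans <- list(); k <- 0L
  for (sc in sob_caps) for (rc in srb_caps) {
    m2 <- apply_capacities(model, capacity_set(
      c("SOB", "SRB"), c("ac", "h2s"), c("lower", "upper"), c(sc, rc)))
    sw <- olr_sweep(m2, condition, n_points = loading_points,
                    settings = settings, track = character())
    sol <- sw$solutions
    sol$sob_acetate_lb <- sc
    sol$srb_sulfide_ub <- rc
    ab <- as.matrix(sol[, names(model$guilds), drop = FALSE])
    gap <- apply(ab, 1, function(r) {
      s <- sort(r, decreasing = TRUE)
      s[1] - s[2]
    })
    sol$transient <- !is.na(gap) & gap < transient_gap * model$x0
    k <- k + 1L
    rows[[k]] <- sol
    lost <- which(sol$dominant != "SOB" & sol$status == "optimal")
    tb <- if (length(lost)) sol$butyrate[min(lost)] else NA_real_
    ta <- if (length(lost)) sol$acetate[min(lost)] else NA_real_
    trans[[k]] <- data.frame(
      sob_acetate_lb = sc, srb_sulfide_ub = rc,
      transition_butyrate = tb, transition_acetate = ta,
      pct_butyrate_increase = 100 * (tb - baseline[["butyrate"]]) /
        baseline[["butyrate"]],
      pct_acetate_increase = 100 * (ta - baseline[["acetate"]]) /
        baseline[["acetate"]])
  }
  out <- structure(list(axes = list(sob_acetate_lb = sob_caps,
                                    srb_sulfide_ub = srb_caps,
                                    loading_points = loading_points),
                        solutions = do.call(rbind, rows),
                        transitions = do.call(rbind, trans)),
                   class = "scan_result")
  rownames(out$solutions) <- rownames(out$transitions) <- NULL
  out
}

#' Exponential proton-uptake sweep
#'
#' Varies the community proton influx bound over an exponential grid
#' (neutral to acidic) under a high-loading condition, with all guilds
#' allowed to take protons up to their own capacities.
#'
#' @param model a \code{community_model}.
#' @param condition_h the high-loading condition to perturb.
#' @param h_uptake_range bounds of the proton influx grid
#'   (default 4.21e-4 to 4.21 mmol gO2-cell^-1 h^-1).
#' @param n_points grid resolution (log-spaced).
#' @param settings solver settings.
#' @param track pool metabolites kept in the normalized series.
#' @return a \code{scan_result} with axis \code{h_uptake}.
#' @export
h_plus_sweep <- function(model, condition_h = condition_preset("H-OLR"),
                         h_uptake_range = c(4.21e-4, 4.21), n_points = 15,
                         settings = solver_settings(),
                         track = c("h", "ac", "h2s", "so4", "co2")) {
  stopifnot(n_points >= 2, all(h_uptake_range > 0))
  hgrid <- exp(seq(log(h_uptake_range[1]), log(h_uptake_range[2]),
                   length.out = n_points))
  rows <- list(); exch <- list()
  for (i in seq_along(hgrid)) {
    cs <- condition_h
    cs$community_rates[["h"]] <- hgrid[i]
    p <- scan_point(apply_condition(model, cs), settings,
                    c(h_uptake = hgrid[i]))
    rows[[i]] <- p$row; exch[[i]] <- p$exchange
  }
  finish_scan(rows, exch, list(h_uptake = hgrid), model, track)
}

#' Detect transitions along a one-dimensional scan
#'
#' Reports, for one guild: (a) the axis values where the community
#' dominance label changes, (b) the first point where the guild's growth
#' (mu times abundance) slope drops below a fraction of its initial
#' slope (the phase boundary of a growth plateau), and (c) the point of
#' the guild's steepest abundance drop together with whether it crosses
#' below another guild there (the two candidate readings of a "rapid
#' drop").
#'
#' @param scan a \code{scan_result} from a 1-D sweep.
#' @param guild guild id.
#' @param slope_frac slope fraction defining the growth plateau.
#' @param axis name of the axis column (default the first axis).
#' @param log_axis treat the axis as exponential (slopes per log step);
#'   appropriate for the proton sweep.
#' @return list with \code{dominance_switch} (axis values),
#'   \code{slope_break} (axis value or NA), \code{largest_drop} (axis
#'   value or NA).
#' @export
detect_transition <- function(scan, guild, slope_frac = 0.1, axis = NULL,
                              log_axis = FALSE) {
  stopifnot(inherits(scan, "scan_result"))
  sol <- scan$solutions[scan$solutions$status == "optimal", , drop = FALSE]
  if (is.null(axis)) axis <- names(scan$axes)[1]
  x <- sol[[axis]]
  if (is.null(x)) stop("axis '", axis, "' not found in scan")
  xs <- if (log_axis) log(x) else x
  if (nrow(sol) < 2)
    return(list(dominance_switch = numeric(), slope_break = NA_real_,
                largest_drop = NA_real_))
  sw <- which(sol$dominant[-1] != sol$dominant[-nrow(sol)]) + 1L
  growth <- sol$mu * sol[[guild]]
  slopes <- diff(growth) / diff(xs)
  ref <- slopes[1]
  brk <- NA_real_
  if (is.finite(ref) && ref > 0) {
    hit <- which(slopes < slope_frac * ref)
    if (length(hit)) brk <- x[min(hit) + 1L]
  }
  dab <- diff(sol[[guild]]) / diff(xs)
  drop_i <- if (any(is.finite(dab)) && min(dab, na.rm = TRUE) < 0)
    which.min(dab) + 1L else NA_integer_
  list(dominance_switch = x[sw],
       slope_break = brk,
       largest_drop = if (is.na(drop_i)) NA_real_ else x[drop_i])
}

#' Write a scan result as long-format TSV (and optionally JSON)
#'
#' @param scan a \code{scan_result}.
#' @param path output TSV path; with a ".json" extension the full result
#'   (solutions plus normalized series) is written as JSON instead.
#' @return \code{path}, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(axes = scan$axes, solutions = scan$solutions,
                              normalized_series = scan$normalized_series,
                              transitions = scan$transitions),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(scan$solutions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
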