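#' Construct a guild-level metabolic model
#'
#' A guild model holds the stoichiometry of one functional guild (e.g. SRB,
#' MET, SOB): metabolites, reactions with flux capacity bounds in
#' mmol gO2-cell^-1 h^-1, one biomass reaction whose flux is the growth
#' rate, and exchange reactions that connect the guild to the shared
#' community pool.
#'
#' Exchange reactions are boundary reactions touching exactly one guild
#' metabolite. They are normalized so that positive flux means secretion
#' into the pool and negative flux means consumption; columns written the
#' other way round are flipped (bounds swapped accordingly).
#'
#' @param guild_id short guild label, e.g. "SRB".
#' @param metabolites data.frame with columns \code{id} and optionally
#'   \code{name}, \code{compartment}, \code{formula}.
#' @param reactions data.frame with columns \code{id}, \code{lb}, \code{ub}
#'   and optionally \code{name}. Missing bounds default to ±1000.
#' @param S stoichiometric matrix (metabolites x reactions); dimnames must
#'   match the metabolite and reaction ids.
#' @param biomass id of the biomass reaction.
#' @param exchange named character vector mapping exchange reaction ids to
#'   pool metabolite ids.
#' @param genes optional character vector of gene ids.
#' @param gpr optional named character vector: reaction id -> gene
#'   association string.
#'
#' @return object of class \code{guild_model}.
#' @export
guild_model <- function(guild_id, metabolites, reactions, S, biomass,
                        exchange = character(), genes = character(),
                        gpr = character()) {
  stopifnot(is.character(guild_id), length(guild_id) == 1, nzchar(guild_id))
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$formula)) metabolites$formula <- ""
  metabolites$formula[is.na(metabolites$formula)] <- ""
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lb)) reactions$lb <- NA_real_
  if (is.null(reactions$ub)) reactions$ub <- NA_real_
  miss <- is.na(reactions$lb) | is.na(reactions$ub)
  if (any(miss)) {
    warning(sprintf("guild %s: %d reaction(s) without bounds; defaulting to [-1000, 1000]",
                    guild_id, sum(miss)))
    reactions$lb[is.na(reactions$lb)] <- -1000
    reactions$ub[is.na(reactions$ub)] <- 1000
  }
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must carry metabolite rownames and reaction colnames")
  if (!identical(sort(rownames(S)), sort(metabolites$id)))
    stop("S rownames do not match metabolite ids")
  if (!identical(sort(colnames(S)), sort(reactions$id)))
    stop("S colnames do not match reaction ids")
  S <- S[metabolites$id, reactions$id, drop = FALSE]

  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (length(biomass) != 1 || !biomass %in% reactions$id)
    stop(sprintf("guild %s: biomass reaction '%s' not found; supply its id explicitly",
                 guild_id, paste(biomass, collapse = ",")))
  if (any(reactions$lb > reactions$ub))
    stop("reaction lower bound exceeds upper bound: ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))

  exchange <- unlist(exchange)
  if (length(exchange)) {
    if (is.null(names(exchange)) || any(!nzchar(names(exchange))))
      stop("exchange must be a named vector: reaction id -> pool metabolite id")
    bad <- setdiff(names(exchange), reactions$id)
    if (length(bad)) stop("unknown exchange reactions: ", paste(bad, collapse = ", "))
    for (rx in names(exchange)) {
      col <- S[, rx]
      nz <- which(abs(col) > 0)
      if (length(nz) != 1)
        stop(sprintf("exchange reaction %s must touch exactly one metabolite", rx))
      if (col[nz] > 0) {          # written as uptake; normalize to secretion-positive
        S[nz, rx] <- -col[nz]
        i <- match(rx, reactions$id)
        b <- c(-reactions$ub[i], -reactions$lb[i])
        reactions$lb[i] <- b[1]
        reactions$ub[i] <- b[2]
      }
    }
    if (biomass %in% names(exchange)) stop("biomass reaction cannot be an exchange")
  }

  structure(list(guild_id = guild_id, metabolites = metabolites,
                 reactions = reactions, S = S, biomass = biomass,
                 exchange = exchange, genes = unique(genes), gpr = gpr),
            class = "guild_model")
}

#' @export
print.guild_model <- function(x, ...) {
  cat(sprintf("<guild_model> %s: %d reactions, %d metabolites, %d exchanges, biomass = %s\n",
              x$guild_id, nrow(x$reactions), nrow(x$metabolites),
              length(x$exchange), x$biomass))
  invisible(x)
}

#' Set exchange capacity bounds on a guild
#'
#' Sets the per-abundance exchange capacity vex(i)^k of a pool metabolite,
#' i.e. the lower and/or upper bound of the guild's exchange reaction for
#' that metabolite (negative = consumption, positive = secretion).
#'
#' @param guild a \code{guild_model}.
#' @param met pool metabolite id.
#' @param lower,upper new bounds (either may be omitted).
#' @return the modified guild model.
#' @export
set_capacity <- function(guild, met, lower = NULL, upper = NULL) {
  stopifnot(inherits(guild, "guild_model"))
  rx <- names(guild$exchange)[guild$exchange == met]
  if (length(rx) != 1)
    stop(sprintf("guild %s has no unique exchange for pool metabolite '%s'",
                 guild$guild_id, met))
  i <- match(rx, guild$reactions$id)
  if (!is.null(lower)) guild$reactions$lb[i] <- lower
  if (!is.null(upper)) guild$reactions$ub[i] <- upper
  if (guild$reactions$lb[i] > guild$reactions$ub[i])
    stop("lower capacity exceeds upper capacity for ", met)
  guild
}

#' Flux balance analysis on a single guild
#'
#' Maximizes the flux of an objective reaction (the biomass reaction by
#' default) subject to steady-state mass balance S v = 0 and the guild's
#' capacity bounds, optionally intersected with per-metabolite availability
#' at the boundary.
#'
#' @param guild a \code{guild_model}.
#' @param exchange_lb,exchange_ub optional named numeric vectors (pool
#'   metabolite id -> bound) further restricting exchange fluxes. Uptake
#'   availability is expressed as a negative lower bound.
#' @param objective reaction id to optimize (default the biomass reaction).
#' @param maximize direction.
#'
#' @return list with \code{objective}, named \code{fluxes}, \code{status}.
#' @export
fba <- function(guild, exchange_lb = NULL, exchange_ub = NULL,
                objective = guild$biomass, maximize = TRUE) {
  stopifnot(inherits(guild, "guild_model"))
  lb <- guild$reactions$lb
  ub <- guild$reactions$ub
  names(lb) <- names(ub) <- guild$reactions$id
  for (rx in names(guild$exchange)) {
    met <- guild$exchange[[rx]]
    if (!is.null(exchange_lb) && met %in% names(exchange_lb))
      lb[rx] <- max(lb[rx], exchange_lb[[met]])
    if (!is.null(exchange_ub) && met %in% names(exchange_ub))
      ub[rx] <- min(ub[rx], exchange_ub[[met]])
  }
  obj <- as.numeric(guild$reactions$id == objective)
  A <- as.matrix(guild$S)
  res <- solve_lp(obj, A, rep("=", nrow(A)), rep(0, nrow(A)),
                  lower = pmin(lb, ub), upper = ub, maximize = maximize)
  list(objective = res$objective,
       fluxes = stats::setNames(res$x, guild$reactions$id),
       status = res$status)
}
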