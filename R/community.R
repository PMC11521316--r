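#' Assemble guild models into a compartmentalized community model
#'
#' Builds the community structure used by the SteadyCom solver: each guild
#' keeps its own (block-diagonal) stoichiometry, guild exchange reactions
#' are rewired to shared pool metabolites in a common compartment (COM),
#' and every pool metabolite receives a community uptake reaction u_i
#' (influx from the environment) and a community export reaction e_i
#' (efflux to the environment), both non-negative by construction.
#'
#' Sign conventions: positive guild exchange flux = secretion into COM,
#' negative = consumption from COM; u_i adds metabolite to COM and e_i
#' removes it, so each pool metabolite balances as
#' u_i - e_i + sum_k Vex(i)^k = 0.
#'
#' Pool identity is resolved by the base metabolite id declared in each
#' guild's exchange map. When two guilds declare different non-empty
#' chemical formulas for the same pool id, assembly fails listing the
#' offenders rather than silently merging them.
#'
#' @param guilds list of \code{guild_model} objects (at least one).
#' @param x0 total community abundance (default 1).
#' @return object of class \code{community_model}.
#' @export
assemble_community <- function(guilds, x0 = 1) {
  if (!length(guilds)) stop("need at least one guild")
  if (inherits(guilds, "guild_model")) guilds <- list(guilds)
  stopifnot(all(vapply(guilds, inherits, TRUE, "guild_model")), x0 > 0)
  ids <- vapply(guilds, `[[`, "", "guild_id")
  if (anyDuplicated(ids)) stop("duplicate guild_id: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(guilds) <- ids

  com_mets <- character()
  formulas <- list()
  for (g in guilds) {
    for (rx in names(g$exchange)) {
      met <- g$exchange[[rx]]
      gmet <- g$metabolites$id[which(abs(g$S[, rx]) > 0)]
      f <- g$metabolites$formula[match(gmet, g$metabolites$id)]
      formulas[[met]] <- c(formulas[[met]], stats::setNames(f, g$guild_id))
      com_mets <- union(com_mets, met)
    }
  }
  clash <- names(Filter(function(f) length(unique(f[nzchar(f)])) > 1, formulas))
  if (length(clash))
    stop("conflicting formulas across guilds for pool metabolite(s): ",
         paste(clash, collapse = ", "))
  pool_formula <- vapply(formulas, function(f) {
    f <- f[nzchar(f)]
    if (length(f)) f[[1]] else ""
  }, "")

  zero <- stats::setNames(numeric(length(com_mets)), com_mets)
  structure(list(guilds = guilds, com_mets = com_mets,
                 pool_formula = pool_formula[com_mets],
                 uptake_bounds = zero, export_bounds = zero,
                 free_mets = character(), x0 = x0),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d guilds (%s), %d pool metabolites, X0 = %g\n",
              length(x$guilds), paste(names(x$guilds), collapse = ", "),
              length(x$com_mets), x$x0))
  invisible(x)
}

#' Qualified (namespaced) reaction ids of a community model
#'
#' @param model a \code{community_model}.
#' @return character vector \code{guild__reaction} covering every guild.
#' @export
community_reaction_ids <- function(model) {
  unlist(lapply(model$guilds, function(g)
    paste(g$guild_id, g$reactions$id, sep = "__")), use.names = FALSE)
}

parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(numeric())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  cnt <- sub("^[A-Z][a-z]?", "", parts)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  tapply(cnt, el, sum)
}

#' Structural validation report for a community model
#'
#' Deterministic, never-raising report: model size counts, shared
#' exchange-metabolite counts between guilds (pairwise and the intersection
#' of all guilds), elementally unbalanced internal reactions, pool
#' metabolites no guild exchanges, and structural loop candidates (null
#' space support sets of each guild's internal stoichiometry, i.e. cycles
#' that can carry flux with all boundaries closed).
#'
#' Balance checking uses the declared chemical formulas; metabolites with
#' an empty formula are treated as massless carriers (photons, free
#' protons under reduced bookkeeping) and contribute nothing; reactions
#' in which no participant declares a formula are listed as unchecked.
#' Biomass and exchange reactions are exempt (boundary/lumped by design).
#'
#' @param model a \code{community_model}.
#' @return object of class \code{validation_report}.
#' @export
validate_community <- function(model) {
  stopifnot(inherits(model, "community_model"))
  gs <- model$guilds
  rxn_count <- sum(vapply(gs, function(g) nrow(g$reactions), 0L))
  met_count <- sum(vapply(gs, function(g) nrow(g$metabolites), 0L)) +
    length(model$com_mets)
  gene_count <- sum(vapply(gs, function(g) length(g$genes), 0L))

  ex_sets <- lapply(gs, function(g) unique(unname(g$exchange)))
  pairs <- list()
  if (length(gs) > 1) {
    cmb <- utils::combn(names(gs), 2)
    for (i in seq_len(ncol(cmb))) {
      a <- cmb[1, i]; b <- cmb[2, i]
      pairs[[paste(a, b, sep = ":")]] <-
        length(intersect(ex_sets[[a]], ex_sets[[b]]))
    }
  }
  common_all <- Reduce(intersect, ex_sets)
  shared_any <- if (length(gs) > 1) {
    tab <- table(unlist(ex_sets))
    sum(tab >= 2)
  } else 0L

  unbalanced <- character(); unchecked <- character()
  for (g in gs) {
    elems <- lapply(g$metabolites$formula, parse_formula)
    names(elems) <- g$metabolites$id
    has_formula <- vapply(elems, length, 0L) > 0
    skip <- c(g$biomass, names(g$exchange))
    for (rx in setdiff(g$reactions$id, skip)) {
      col <- g$S[, rx]
      nz <- which(abs(col) > 0)
      if (!length(nz)) next
      mids <- g$metabolites$id[nz]
      if (!any(has_formula[mids])) {
        unchecked <- c(unchecked, paste(g$guild_id, rx, sep = "__"))
        next
      }
      tot <- numeric()
      for (k in seq_along(nz)) {
        e <- elems[[mids[k]]] * col[nz[k]]
        for (el in names(e)) tot[el] <- sum(tot[el], e[el], na.rm = TRUE)
      }
      if (any(abs(tot) > 1e-9))
        unbalanced <- c(unbalanced, paste(g$guild_id, rx, sep = "__"))
    }
  }

  exchanged <- unique(unlist(ex_sets))
  orphans <- setdiff(model$com_mets, exchanged)

  loops <- list()
  for (g in gs) {
    internal <- setdiff(g$reactions$id, names(g$exchange))
    if (length(internal) < 2) next
    Si <- as.matrix(g$S[, internal, drop = FALSE])
    ns <- tryCatch({
      sv <- svd(Si, nu = 0)
      tol <- max(dim(Si)) * max(sv$d, 0) * 1e-10
      sv$v[, sv$d < tol | seq_along(sv$d) > sum(sv$d >= tol), drop = FALSE]
    }, error = function(e) NULL)
    if (is.null(ns) || !ncol(ns)) next
    for (j in seq_len(ncol(ns))) {
      sup <- internal[abs(ns[, j]) > 1e-8]
      if (length(sup) >= 2)
        loops[[length(loops) + 1L]] <- paste(g$guild_id, sup, sep = "__")
    }
  }

  structure(list(reaction_count = rxn_count, metabolite_count = met_count,
                 gene_count = gene_count,
                 shared_exchange_counts = list(pairwise = pairs,
                                               all_guilds = length(common_all),
                                               any_two_or_more = shared_any),
                 unbalanced_reactions = unbalanced,
                 unchecked_reactions = unchecked,
                 orphan_pool_metabolites = orphans,
                 loop_candidates = loops),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d reactions, %d metabolites, %d genes\n",
              x$reaction_count, x$metabolite_count, x$gene_count))
  cat(sprintf("  shared exchange metabolites: %d in >=2 guilds, %d in all\n",
              x$shared_exchange_counts$any_two_or_more,
              x$shared_exchange_counts$all_guilds))
  cat(sprintf("  unbalanced: %d, unchecked: %d, orphan pool metabolites: %d, loop candidates: %d\n",
              length(x$unbalanced_reactions), length(x$unchecked_reactions),
              length(x$orphan_pool_metabolites), length(x$loop_candidates)))
  invisible(x)
}

#' Write a validation report as JSON
#' @param report a \code{validation_report}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-guild exchange-metabolite sets as TSV
#' @param model a \code{community_model}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_exchange_tsv <- function(model, path) {
  rows <- do.call(rbind, lapply(model$guilds, function(g)
    data.frame(guild = g$guild_id, reaction = names(g$exchange),
               pool_metabolite = unname(g$exchange))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
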