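#' SBML import and export for guild and community models
#'
#' Constraint-based models are exchanged as SBML Level 3 Version 1 with
#' the fbc (version 2) extension: flux bounds as referenced parameters,
#' the growth objective as an fbc objective, chemical formulas as
#' fbc:chemicalFormula. Level 2 files are tolerated on input (bounds
#' from kineticLaw LOWER_BOUND/UPPER_BOUND parameters, or defaulted from
#' the reversible flag with a warning). Only the constraint-modeling
#' subset of SBML is supported; kinetics, rules and events are ignored.
#'
#' @name sbml_io
NULL

sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

num_attr <- function(x) {
  x[x == "INF"] <- "Inf"
  x[x == "-INF"] <- "-Inf"
  suppressWarnings(as.numeric(x))
}

fmt_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "INF", "-INF"),
         format(x, digits = 17, scientific = TRUE, trim = TRUE))
}

# namespace-agnostic attribute lookup ("chemicalFormula" matches
# "fbc:chemicalFormula" as well)
attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

find_all <- function(x, tag)
  xml2::xml_find_all(x, sprintf(".//*[local-name()='%s']", tag))

#' Write a model as SBML
#'
#' For a guild model, one compartment per declared metabolite
#' compartment is written and exchange reactions stay single-participant
#' boundary reactions named \code{EX_<pool metabolite>}. For a community
#' model, each guild becomes a compartment, pool metabolites live in a
#' \code{COM} compartment, guild exchange reactions link the two, and
#' community uptake/export reactions are written as \code{U_<met>} /
#' \code{E_<met>} boundary reactions carrying the condition bounds.
#'
#' @param x a \code{guild_model} or \code{community_model}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(x, path) UseMethod("write_sbml")

sbml_skeleton <- function(model_id, model_name = model_id) {
  doc <- xml2::read_xml(paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">',
    '<model id="', sid(model_id), '" name="', model_name,
    '" fbc:strict="false">',
    '<listOfCompartments/><listOfSpecies/><listOfParameters/>',
    '<listOfReactions/>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives/></fbc:objective></fbc:listOfObjectives>',
    '</model></sbml>'))
  doc
}

add_species <- function(lo_species, id, name, compartment, formula) {
  sp <- xml2::xml_add_child(lo_species, "species", id = id, name = name,
                            compartment = compartment,
                            hasOnlySubstanceUnits = "false",
                            boundaryCondition = "false", constant = "false")
  if (nzchar(formula) && !is.na(formula))
    xml2::xml_set_attr(sp, "fbc:chemicalFormula", formula)
  sp
}

add_reaction <- function(lo_rxn, lo_par, id, name, stoich_ids, stoich,
                         lb, ub) {
  xml2::xml_add_child(lo_par, "parameter", id = paste0(id, "_lb"),
                      value = fmt_num(lb), constant = "true")
  xml2::xml_add_child(lo_par, "parameter", id = paste0(id, "_ub"),
                      value = fmt_num(ub), constant = "true")
  rx <- xml2::xml_add_child(lo_rxn, "reaction", id = id, name = name,
                            reversible = if (lb < 0) "true" else "false",
                            fast = "false")
  xml2::xml_set_attr(rx, "fbc:lowerFluxBound", paste0(id, "_lb"))
  xml2::xml_set_attr(rx, "fbc:upperFluxBound", paste0(id, "_ub"))
  re <- xml2::xml_add_child(rx, "listOfReactants")
  pr <- xml2::xml_add_child(rx, "listOfProducts")
  for (k in seq_along(stoich)) {
    s <- stoich[k]
    if (s == 0) next
    parent <- if (s < 0) re else pr
    xml2::xml_add_child(parent, "speciesReference", species = stoich_ids[k],
                        stoichiometry = format(abs(s), digits = 17),
                        constant = "true")
  }
  rx
}

write_guild_into <- function(doc, g, species_prefix = TRUE) {
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  lo_comp <- xml2::xml_find_first(model, ".//*[local-name()='listOfCompartments']")
  lo_sp <- xml2::xml_find_first(model, ".//*[local-name()='listOfSpecies']")
  lo_par <- xml2::xml_find_first(model, ".//*[local-name()='listOfParameters']")
  lo_rxn <- xml2::xml_find_first(model, ".//*[local-name()='listOfReactions']")
  lo_obj <- xml2::xml_find_first(model, ".//*[local-name()='listOfFluxObjectives']")

  comp <- g$guild_id
  if (!length(xml2::xml_find_all(lo_comp, sprintf(
    ".//*[local-name()='compartment'][@id='%s']", sid(comp)))))
    xml2::xml_add_child(lo_comp, "compartment", id = sid(comp),
                        constant = "true")
  spid <- stats::setNames(paste0("M_", sid(g$metabolites$id), "_", sid(comp)),
                          g$metabolites$id)
  for (i in seq_len(nrow(g$metabolites)))
    add_species(lo_sp, spid[[g$metabolites$id[i]]], g$metabolites$id[i],
                sid(comp), g$metabolites$formula[i])
  for (i in seq_len(nrow(g$reactions))) {
    rid <- g$reactions$id[i]
    xid <- paste0("R_", sid(comp), "__", sid(rid))
    col <- g$S[, rid]
    nz <- which(abs(col) > 0)
    add_reaction(lo_rxn, lo_par, xid, rid,
                 spid[g$metabolites$id[nz]], col[nz],
                 g$reactions$lb[i], g$reactions$ub[i])
  }
  bio <- paste0("R_", sid(comp), "__", sid(g$biomass))
  ob <- xml2::xml_add_child(lo_obj, "fbc:fluxObjective")
  xml2::xml_set_attr(ob, "fbc:reaction", bio)
  xml2::xml_set_attr(ob, "fbc:coefficient", "1")
  invisible(spid)
}

#' @rdname write_sbml
#' @export
write_sbml.guild_model <- function(x, path) {
  doc <- sbml_skeleton(paste0("guild_", x$guild_id), x$guild_id)
  write_guild_into(doc, x)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_sbml
#' @export
write_sbml.community_model <- function(x, path) {
  doc <- sbml_skeleton("community", sprintf("community x0=%g", x$x0))
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  lo_comp <- xml2::xml_find_first(model, ".//*[local-name()='listOfCompartments']")
  lo_sp <- xml2::xml_find_first(model, ".//*[local-name()='listOfSpecies']")
  lo_par <- xml2::xml_find_first(model, ".//*[local-name()='listOfParameters']")
  lo_rxn <- xml2::xml_find_first(model, ".//*[local-name()='listOfReactions']")
  xml2::xml_add_child(lo_comp, "compartment", id = "COM", constant = "true")
  poolid <- stats::setNames(paste0("M_", sid(x$com_mets), "_COM"),
                            x$com_mets)
  for (met in x$com_mets)
    add_species(lo_sp, poolid[[met]], met, "COM",
                x$pool_formula[[met]])
  for (g in x$guilds) {
    spid <- write_guild_into(doc, g)
    # rewire this guild's exchange reactions to produce the pool species
    for (rx in names(g$exchange)) {
      xid <- paste0("R_", sid(g$guild_id), "__", sid(rx))
      node <- xml2::xml_find_first(doc, sprintf(
        ".//*[local-name()='reaction'][@id='%s']", xid))
      pr <- xml2::xml_find_first(node, ".//*[local-name()='listOfProducts']")
      xml2::xml_add_child(pr, "speciesReference",
                          species = poolid[[g$exchange[[rx]]]],
                          stoichiometry = "1", constant = "true")
    }
  }
  free <- x$com_mets %in% x$free_mets
  for (i in seq_along(x$com_mets)) {
    met <- x$com_mets[i]
    ub_u <- if (free[i]) Inf else x$uptake_bounds[[met]]
    ub_e <- if (free[i]) Inf else x$export_bounds[[met]]
    add_reaction(lo_rxn, lo_par, paste0("R_U_", sid(met)),
                 paste0("U_", met), poolid[[met]], 1, 0, ub_u)
    add_reaction(lo_rxn, lo_par, paste0("R_E_", sid(met)),
                 paste0("E_", met), poolid[[met]], -1, 0, ub_e)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

parse_sbml_tables <- function(doc) {
  level <- num_attr(xml2::xml_attr(xml2::xml_root(doc), "level"))
  sp_nodes <- find_all(doc, "species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = vapply(sp_nodes, attr_any, "", "chemicalFormula"),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]
  species$formula[is.na(species$formula)] <- ""
  if (anyDuplicated(species$id))
    stop("malformed SBML: duplicate species id ",
         species$id[duplicated(species$id)][1])

  pars <- find_all(doc, "parameter")
  pk <- xml2::xml_attr(pars, "id")
  global <- !vapply(pars, function(p) any(xml2::xml_name(
    xml2::xml_parents(p)) == "kineticLaw"), TRUE)
  parval <- stats::setNames(num_attr(xml2::xml_attr(pars, "value")), pk)[global[seq_along(pk)]]

  rx_nodes <- find_all(doc, "reaction")
  rxns <- vector("list", length(rx_nodes))
  warned <- FALSE
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("malformed SBML: reaction without id")
    refs <- function(tag, sgn) {
      lo <- xml2::xml_find_first(node, sprintf(
        ".//*[local-name()='%s']", tag))
      if (inherits(lo, "xml_missing")) return(NULL)
      srefs <- xml2::xml_find_all(lo, ".//*[local-name()='speciesReference']")
      if (!length(srefs)) return(NULL)
      st <- num_attr(xml2::xml_attr(srefs, "stoichiometry"))
      st[is.na(st)] <- 1
      data.frame(species = xml2::xml_attr(srefs, "species"),
                 stoich = sgn * st, stringsAsFactors = FALSE)
    }
    stoich <- rbind(refs("listOfReactants", -1), refs("listOfProducts", 1))
    lb_ref <- attr_any(node, "lowerFluxBound")
    ub_ref <- attr_any(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref)) parval[[lb_ref]] else NA_real_
    ub <- if (!is.na(ub_ref)) parval[[ub_ref]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      kl <- xml2::xml_find_all(node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kv <- num_attr(xml2::xml_attr(kl, "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[kid == "LOWER_BOUND"][1]
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[kid == "UPPER_BOUND"][1]
      }
    }
    if (is.na(lb) || is.na(ub)) {
      rev <- !(xml2::xml_attr(node, "reversible") %in% "false")
      if (is.na(lb)) lb <- if (rev) -1000 else 0
      if (is.na(ub)) ub <- 1000
      if (!warned) {
        warning("reaction(s) without flux bounds; defaulting to the ",
                "+/-1000 convention (first: ", rid, ")")
        warned <- TRUE
      }
    }
    rxns[[i]] <- list(id = rid,
                      name = {
                        nm <- xml2::xml_attr(node, "name")
                        if (is.na(nm)) rid else nm
                      },
                      stoich = stoich, lb = lb, ub = ub)
  }

  fobj <- find_all(doc, "fluxObjective")
  objectives <- vapply(fobj, attr_any, "", "reaction")
  genes <- xml2::xml_attr(find_all(doc, "geneProduct"), "id")
  list(level = level, species = species, reactions = rxns,
       objectives = objectives[!is.na(objectives)],
       genes = genes[!is.na(genes)])
}

pick_biomass <- function(candidate_ids, names_by_id, objectives, biomass,
                         where) {
  if (!is.null(biomass)) {
    if (!biomass %in% candidate_ids && !biomass %in% names_by_id)
      stop("biomass reaction '", biomass, "' not found in ", where)
    return(if (biomass %in% candidate_ids) biomass
           else candidate_ids[match(biomass, names_by_id)])
  }
  ob <- intersect(objectives, candidate_ids)
  if (length(ob) == 1) return(ob)
  hits <- candidate_ids[grepl("biomass|growth", names_by_id, ignore.case = TRUE) |
                        grepl("biomass|growth", candidate_ids, ignore.case = TRUE)]
  if (length(hits) >= 1) return(hits[1])
  stop("no biomass reaction candidate found in ", where,
       "; supply its id explicitly")
}

#' Load a guild model from SBML
#'
#' Reads a single-guild SBML file (level 3 + fbc preferred, level 2
#' tolerated): exchange reactions are identified as single-metabolite
#' boundary reactions, the biomass reaction comes from the fbc objective,
#' an id/name matching biomass/growth, or the \code{biomass} argument,
#' and the pool metabolite of an exchange reaction is taken from the
#' \code{EX_<met>} naming convention (falling back to the metabolite's
#' name). Reactions without bounds default to the +/-1000 convention
#' with a warning.
#'
#' @param sbml_source path to an SBML file.
#' @param guild_id guild label for the loaded model.
#' @param biomass optional biomass reaction id or name (overrides
#'   autodetection).
#' @return a \code{guild_model}.
#' @export
load_guild_model <- function(sbml_source, guild_id, biomass = NULL) {
  doc <- tryCatch(xml2::read_xml(sbml_source),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e)))
  tb <- parse_sbml_tables(doc)
  sp <- tb$species
  met_ids <- stats::setNames(sp$name, sp$id)   # original ids live in name
  if (anyDuplicated(met_ids)) met_ids <- stats::setNames(sp$id, sp$id)

  rx_ids <- vapply(tb$reactions, `[[`, "", "id")
  rx_names <- vapply(tb$reactions, `[[`, "", "name")
  clean <- function(x) sub("^R_([^_]+__)?", "", x)
  rxid <- ifelse(!duplicated(rx_names) & !is.na(rx_names), rx_names,
                 clean(rx_ids))

  mets <- data.frame(id = unname(met_ids[sp$id]), name = sp$name,
                     compartment = sp$compartment, formula = sp$formula,
                     stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), length(tb$reactions),
              dimnames = list(mets$id, rxid))
  lb <- ub <- numeric(length(tb$reactions))
  exchange <- character()
  for (i in seq_along(tb$reactions)) {
    r <- tb$reactions[[i]]
    if (is.null(r$stoich))
      stop("malformed SBML: reaction ", r$id, " has no participants")
    rows <- met_ids[r$stoich$species]
    if (anyNA(rows)) stop("malformed SBML: unknown species in reaction ",
                          r$id)
    for (k in seq_along(rows)) S[rows[k], i] <- S[rows[k], i] + r$stoich$stoich[k]
    lb[i] <- r$lb; ub[i] <- r$ub
    bnd <- sp$boundary[match(r$stoich$species, sp$id)]
    real <- r$stoich$species[!bnd]
    if (length(real) == 1) {
      pool <- if (grepl("^(R_)?EX_", rxid[i])) sub("^(R_)?EX_", "", rxid[i])
              else unname(met_ids[real])
      exchange[rxid[i]] <- pool
    }
  }
  bio <- pick_biomass(rxid, rx_names, ifelse(is.na(match(tb$objectives, rx_ids)),
                                             tb$objectives,
                                             rxid[match(tb$objectives, rx_ids)]),
                      biomass, "SBML model")
  # a biomass/demand reaction with one participant is not an exchange
  exchange <- exchange[setdiff(names(exchange), bio)]
  guild_model(guild_id,
              metabolites = mets,
              reactions = data.frame(id = rxid, name = rx_names,
                                     lb = lb, ub = ub,
                                     stringsAsFactors = FALSE),
              S = S, biomass = bio, exchange = exchange,
              genes = tb$genes)
}

#' Load a community model from SBML
#'
#' Reads a compartmentalized multi-guild SBML file: the pool compartment
#' is picked by name (or given explicitly), every other compartment
#' becomes one guild, reactions are assigned to the guild of their
#' non-pool participants, reactions linking one guild metabolite to one
#' pool metabolite become guild exchanges, and single-participant
#' reactions on pool species become community uptake (producing) or
#' export (consuming) bounds. The compartment tag scheme of combined
#' models varies between tools, so both the pool pattern and an explicit
#' compartment-to-guild mapping can be supplied.
#'
#' @param path SBML file.
#' @param pool_compartment id of the shared pool compartment; by default
#'   the first compartment matching \code{pool_pattern}.
#' @param pool_pattern regular expression used to autodetect the pool
#'   compartment.
#' @param guild_map optional named character vector mapping compartment
#'   ids to guild labels (default: compartment ids themselves).
#' @param biomass optional named character vector guild -> biomass
#'   reaction id, overriding autodetection.
#' @return a \code{community_model} (bounds as stored in the file).
#' @export
read_community_sbml <- function(path, pool_compartment = NULL,
                                pool_pattern = "(?i)^(com|pool|medium|u)$",
                                guild_map = NULL, biomass = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e)))
  tb <- parse_sbml_tables(doc)
  sp <- tb$species
  comps <- unique(sp$compartment)
  if (is.null(pool_compartment)) {
    hit <- comps[grepl(pool_pattern, comps, perl = TRUE)]
    if (length(hit) != 1)
      stop("cannot autodetect the pool compartment among: ",
           paste(comps, collapse = ", "), "; pass pool_compartment")
    pool_compartment <- hit
  }
  gcomps <- setdiff(comps, pool_compartment)
  if (is.null(guild_map)) guild_map <- stats::setNames(gcomps, gcomps)
  sp$base <- sp$name
  met_comp <- stats::setNames(sp$compartment, sp$id)
  met_base <- stats::setNames(sp$base, sp$id)

  per_guild <- stats::setNames(vector("list", length(gcomps)), gcomps)
  for (gc in gcomps)
    per_guild[[gc]] <- list(rxns = list(), exchange = character())
  uptake <- export <- numeric()
  objectives <- tb$objectives
  rx_ids <- vapply(tb$reactions, `[[`, "", "id")

  for (r in tb$reactions) {
    if (is.null(r$stoich)) next
    rcomp <- unique(met_comp[r$stoich$species])
    guilds_touched <- setdiff(rcomp, pool_compartment)
    if (length(guilds_touched) > 1)
      stop("reaction ", r$id, " spans multiple guild compartments: ",
           paste(guilds_touched, collapse = ", "))
    if (!length(guilds_touched)) {
      if (nrow(r$stoich) != 1) next       # pool-only, not a boundary rxn
      met <- met_base[[r$stoich$species[1]]]
      if (r$stoich$stoich[1] > 0) uptake[met] <- r$ub else export[met] <- r$ub
      next
    }
    gc <- guilds_touched
    in_pool <- met_comp[r$stoich$species] == pool_compartment
    st <- r$stoich[!in_pool, , drop = FALSE]
    entry <- list(id = r$id, name = r$name, stoich = st, lb = r$lb,
                  ub = r$ub)
    if (any(in_pool)) {
      if (sum(in_pool) != 1 || nrow(st) != 1)
        stop("exchange reaction ", r$id,
             " must link exactly one guild and one pool metabolite")
      entry$pool <- met_base[[r$stoich$species[in_pool]]]
    }
    per_guild[[gc]]$rxns[[length(per_guild[[gc]]$rxns) + 1L]] <- entry
  }

  guilds <- lapply(gcomps, function(gc) {
    gl <- per_guild[[gc]]
    gsp <- sp[sp$compartment == gc, , drop = FALSE]
    rid0 <- vapply(gl$rxns, `[[`, "", "id")
    rnm <- vapply(gl$rxns, `[[`, "", "name")
    clean <- function(x) sub(paste0("^R_", sid(gc), "__"), "", x)
    rid <- ifelse(!duplicated(rnm) & !is.na(rnm) & nzchar(rnm), rnm,
                  clean(rid0))
    S <- matrix(0, nrow(gsp), length(gl$rxns),
                dimnames = list(gsp$base, rid))
    lb <- ub <- numeric(length(gl$rxns))
    exchange <- character()
    for (i in seq_along(gl$rxns)) {
      e <- gl$rxns[[i]]
      rows <- met_base[e$stoich$species]
      for (k in seq_along(rows)) S[rows[k], i] <- S[rows[k], i] + e$stoich$stoich[k]
      lb[i] <- e$lb; ub[i] <- e$ub
      if (!is.null(e$pool)) exchange[rid[i]] <- e$pool
    }
    obj_clean <- ifelse(is.na(match(objectives, rid0)), objectives,
                        rid[match(objectives, rid0)])
    bio <- pick_biomass(rid, rnm, obj_clean,
                        if (!is.null(biomass)) biomass[[guild_map[[gc]]]]
                        else NULL,
                        paste0("guild compartment ", gc))
    guild_model(guild_map[[gc]],
                metabolites = data.frame(id = gsp$base, name = gsp$base,
                                         compartment = gc,
                                         formula = gsp$formula,
                                         stringsAsFactors = FALSE),
                reactions = data.frame(id = rid, name = rnm, lb = lb,
                                       ub = ub, stringsAsFactors = FALSE),
                S = S, biomass = bio, exchange = exchange)
  })

  x0 <- 1
  mname <- xml2::xml_attr(xml2::xml_find_first(doc, ".//*[local-name()='model']"),
                          "name")
  if (!is.na(mname) && grepl("x0=", mname))
    x0 <- as.numeric(sub(".*x0=([0-9.eE+-]+).*", "\\1", mname))
  model <- assemble_community(guilds, x0 = x0)
  model$uptake_bounds[names(uptake)] <- uptake
  model$export_bounds[names(export)] <- export
  model$free_mets <- names(uptake)[is.infinite(uptake) &
                                   is.infinite(export[names(uptake)])]
  model
}
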