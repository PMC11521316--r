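#' Specification of the synthetic three-guild community
#'
#' Parameters of the generated community: per-guild exchange capacity
#' presets (per-abundance bounds, mmol gO2-cell^-1 h^-1), biomass ATP
#' costs (the main dial setting guild growth yields), the loading
#' condition applied at assembly, total abundance, and the noise model
#' for synthetic abundance observations.
#'
#' The defaults reproduce the assumed guild physiology of sulfide-rich
#' anaerobic wastewater: SRB oxidize butyrate to acetate coupled to
#' dissimilatory sulfate reduction with hydrogen/formate overflow; MET
#' run acetoclastic methanogenesis; SOB oxidize sulfide photo-dependently
#' (sulfide -> sulfur -> sulfate), assimilate acetate and fix CO2.
#' Capacity presets sit at the fitted scale of the real community:
#' sulfide secretion of SRB capped at 6.28, acetate uptake capped at
#' 11.55 for MET and 1.50 for SOB, proton exchange of SRB/MET capped at
#' 1e-5 (all mmol gO2-cell^-1 h^-1).
#'
#' @param capacities named list of per-guild named vectors of capacity
#'   magnitudes (see defaults for the recognised entries).
#' @param biomass_atp named vector: ATP cost per unit biomass per guild.
#' @param biomass_nadh_sob NADH (reducing power) cost per unit SOB
#'   biomass; ties SOB anabolism to sulfide oxidation throughput.
#' @param sr_atp ATP yield of the lumped dissimilatory sulfate reduction
#'   chain (per sulfate reduced).
#' @param acm_atp ATP yield of acetoclastic methanogenesis (per acetate).
#' @param loading a \code{\link{condition_spec}} applied at assembly.
#' @param x0 total community abundance.
#' @param seed integer seed for randomized observations.
#' @param noise_sd relative (log-normal) noise of synthetic observations.
#' @return list of class \code{toy_community_spec}.
#' @export
toy_community_spec <- function(capacities = list(
                                 SRB = c(but = 40, h2s = 6.28, h = 1e-5),
                                 MET = c(ac = 11.55, h = 1e-5),
                                 SOB = c(ac = 1.50, photon = 12, h = Inf)),
                               biomass_atp = c(SRB = 8, MET = 7, SOB = 6),
                               biomass_nadh_sob = 6, sr_atp = 1.5,
                               acm_atp = 0.75,
                               loading = condition_preset("L-OLR"),
                               x0 = 1, seed = 1L, noise_sd = 0.05) {
  stopifnot(noise_sd >= 0, x0 > 0)
  structure(list(capacities = capacities, biomass_atp = biomass_atp,
                 biomass_nadh_sob = biomass_nadh_sob, sr_atp = sr_atp,
                 acm_atp = acm_atp, loading = loading, x0 = x0,
                 seed = as.integer(seed), noise_sd = noise_sd),
            class = "toy_community_spec")
}

#' Build a guild model from a reaction list
#'
#' Convenience constructor used by the synthetic community (and handy
#' for small test models): reactions are given as a named list of
#' \code{list(stoich = named numeric, lb, ub)} entries and the
#' stoichiometric matrix is assembled from them.
#'
#' @param guild_id guild label.
#' @param rxns named list, reaction id -> list(stoich, lb, ub).
#' @param met_formula named character vector of metabolite formulas
#'   (missing metabolites get an empty formula).
#' @param biomass biomass reaction id.
#' @param exchange named character vector, reaction id -> pool
#'   metabolite id.
#' @return a \code{guild_model}.
#' @export
build_guild <- function(guild_id, rxns, met_formula, biomass, exchange) {
  mets <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, names(rxns)))
  for (id in names(rxns)) S[names(rxns[[id]]$stoich), id] <- rxns[[id]]$stoich
  reactions <- data.frame(id = names(rxns),
                          lb = vapply(rxns, `[[`, 0, "lb"),
                          ub = vapply(rxns, `[[`, 0, "ub"),
                          stringsAsFactors = FALSE)
  metabolites <- data.frame(id = mets,
                            compartment = guild_id,
                            formula = unname(met_formula[mets]),
                            stringsAsFactors = FALSE)
  guild_model(guild_id, metabolites, reactions, S, biomass,
              exchange = exchange)
}

# reduced-bookkeeping formulas: C/S/N are real atoms; G = electron pair
# (H2 equivalent, referenced to the fully oxidized state), E = adenosine
# moiety, P = phosphate, Q = NAD moiety. Photons, protons and water are
# massless carriers here.
toy_formulas <- c(but = "C4G10", ac = "C2G4", accoa = "C2G4", co2 = "C",
                  ch4 = "CG4", "for" = "CG", h2 = "G", so4 = "S",
                  s0 = "SG3", h2s = "SG4", nh4 = "N", pi = "P",
                  atp = "EP", adp = "E", nad = "Q", nadh = "QG",
                  h = "", photon = "", h2o = "")

toy_exchange_bounds <- function(spec) {
  cp <- spec$capacities
  list(
    SRB = list(but = c(-cp$SRB[["but"]], 0), ac = c(0, Inf),
               so4 = c(-Inf, 0), h2s = c(0, cp$SRB[["h2s"]]),
               co2 = c(-Inf, Inf), h2 = c(0, Inf), "for" = c(0, Inf),
               nh4 = c(-Inf, 0), h = c(-cp$SRB[["h"]], cp$SRB[["h"]]),
               pi = c(-Inf, Inf), h2o = c(-Inf, Inf)),
    MET = list(ac = c(-Inf, -cp$MET[["ac"]]), ch4 = c(0, Inf),
               co2 = c(-Inf, Inf), nh4 = c(-Inf, 0),
               h = c(-cp$MET[["h"]], cp$MET[["h"]]),
               pi = c(-Inf, Inf), h2o = c(-Inf, Inf)),
    SOB = list(h2s = c(-Inf, 0), s0 = c(0, Inf), so4 = c(0, Inf),
               ac = c(-cp$SOB[["ac"]], 0), co2 = c(-Inf, Inf),
               photon = c(-cp$SOB[["photon"]], 0),
               h = c(-cp$SOB[["h"]], 0), nh4 = c(-Inf, 0),
               pi = c(-Inf, Inf), h2o = c(-Inf, Inf)))
}

#' Generate the synthetic three-guild community model
#'
#' Builds small (11-18 reactions per guild) but fully mass- and
#' moiety-balanced guild models for SRB, MET and SOB, assembles them into
#' a community model and applies the loading condition of the spec.
#'
#' Core pathways: SRB activate and oxidize butyrate to two acetyl units
#' (2 NADH), phosphorylate acetate off acetyl-CoA, and respire NADH via
#' lumped Apr/Dsr sulfate reduction (1.5 ATP per sulfate); NADH overflow
#' can leave as H2 or formate at an ATP cost. MET split acetate into
#' methane and CO2 with chemiosmotic ATP, and assimilate acetate into
#' biomass. SOB oxidize sulfide stepwise to sulfur and sulfate (NADH via
#' photon-dependent reverse electron flow, lumped), make ATP by cyclic
#' photophosphorylation (boosted when external protons are available),
#' assimilate acetate and fix CO2 through a lumped reductive TCA route.
#'
#' @param spec a \code{\link{toy_community_spec}}.
#' @return a \code{community_model} with the loading condition applied.
#' @export
make_toy_community <- function(spec = toy_community_spec()) {
  stopifnot(inherits(spec, "toy_community_spec"))
  ba <- spec$biomass_atp
  ex <- toy_exchange_bounds(spec)
  irr <- function(stoich, ub = Inf) list(stoich = stoich, lb = 0, ub = ub)

  mk_exchanges <- function(bnds) {
    lapply(names(bnds), function(m)
      list(stoich = stats::setNames(-1, m), lb = bnds[[m]][1],
           ub = bnds[[m]][2]))
  }

  atpm <- irr(c(atp = -1, adp = 1, pi = 1))   # maintenance / futile sink

  srb_rxns <- c(list(
    BUTOX = irr(c(but = -1, atp = -1, nad = -2, accoa = 2, nadh = 2,
                  adp = 1, pi = 1)),
    ATPM = atpm,
    ACK = irr(c(accoa = -1, adp = -0.5, pi = -0.5, ac = 1, atp = 0.5)),
    SR = irr(c(so4 = -1, nadh = -4, adp = -spec$sr_atp,
               pi = -spec$sr_atp, h2s = 1, nad = 4, atp = spec$sr_atp,
               h2o = 1)),
    H2EV = irr(c(nadh = -1, atp = -0.25, h2 = 1, nad = 1, adp = 0.25,
                 pi = 0.25)),
    FDH = irr(c(co2 = -1, nadh = -1, atp = -0.25, "for" = 1, nad = 1,
                adp = 0.25, pi = 0.25)),
    BIOMASS_SRB = irr(c(accoa = -1, atp = -ba[["SRB"]], nh4 = -0.2,
                        pi = -0.05 + ba[["SRB"]], adp = ba[["SRB"]]))),
    stats::setNames(mk_exchanges(ex$SRB), paste0("EX_", names(ex$SRB))))

  met_rxns <- c(list(
    ACM = irr(c(ac = -1, adp = -spec$acm_atp, pi = -spec$acm_atp, ch4 = 1,
                co2 = 1, atp = spec$acm_atp, h2o = 1)),
    ACAS = irr(c(ac = -1, atp = -1, accoa = 1, adp = 1, pi = 1)),
    ATPM = atpm,
    BIOMASS_MET = irr(c(accoa = -1, atp = -ba[["MET"]], nh4 = -0.2,
                        pi = -0.05 + ba[["MET"]], adp = ba[["MET"]]))),
    stats::setNames(mk_exchanges(ex$MET), paste0("EX_", names(ex$MET))))

  sob_rxns <- c(list(
    SQR = irr(c(h2s = -1, nad = -1, s0 = 1, nadh = 1)),
    SOX = irr(c(s0 = -1, nad = -3, so4 = 1, nadh = 3)),
    CYC = irr(c(photon = -1, adp = -1, pi = -1, atp = 1)),
    PSH = irr(c(photon = -1, h = -1, adp = -2, pi = -2, atp = 2)),
    CFIX = irr(c(co2 = -2, nadh = -4, atp = -3, h2o = -1, accoa = 1,
                 nad = 4, adp = 3, pi = 3)),
    ACAS = irr(c(ac = -1, atp = -1, accoa = 1, adp = 1, pi = 1)),
    ATPM = atpm,
    BIOMASS_SOB = irr(c(accoa = -3, atp = -ba[["SOB"]],
                        nadh = -spec$biomass_nadh_sob,
                        nad = spec$biomass_nadh_sob, nh4 = -0.2,
                        pi = -0.05 + ba[["SOB"]], adp = ba[["SOB"]]))),
    stats::setNames(mk_exchanges(ex$SOB), paste0("EX_", names(ex$SOB))))

  mk <- function(id, rxns, bnds)
    build_guild(id, rxns, toy_formulas, paste0("BIOMASS_", id),
                stats::setNames(names(bnds), paste0("EX_", names(bnds))))
  community <- assemble_community(list(mk("SRB", srb_rxns, ex$SRB),
                                       mk("MET", met_rxns, ex$MET),
                                       mk("SOB", sob_rxns, ex$SOB)),
                                  x0 = spec$x0)
  community <- apply_condition(community, spec$loading)
  chk <- solve_at_growth(community, 1e-6)
  if (!isTRUE(chk$feasible))
    stop("toy community infeasible at its default loading (status ",
         chk$status, "); check the spec's capacities and loading")
  community
}

#' Synthetic observed abundances with known ground truth
#'
#' Solves the community at the supplied exchange capacities, perturbs the
#' abundances with multiplicative log-normal noise and renormalizes to
#' X0. The same seed always yields the same table, and noise_sd = 0
#' returns the solver abundances exactly. Used as ground truth for
#' capacity-fitting recovery experiments.
#'
#' @param model a \code{community_model} (condition applied).
#' @param capacities optional \code{\link{capacity_set}} applied before
#'   solving (the ground-truth parameter values).
#' @param noise_sd log-scale standard deviation of the noise.
#' @param seed integer seed.
#' @param settings solver settings.
#' @return data.frame with columns guild, abundance (summing to X0).
#' @export
make_synthetic_observation <- function(model, capacities = NULL,
                                       noise_sd = 0.05, seed = 1L,
                                       settings = solver_settings()) {
  stopifnot(inherits(model, "community_model"), noise_sd >= 0)
  if (!is.null(capacities)) model <- apply_capacities(model, capacities)
  sol <- maximize_growth(model, settings)
  if (sol$status != "optimal")
    stop("community infeasible at the supplied capacities")
  ab <- sol$abundances
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    ab <- ab * exp(stats::rnorm(length(ab), 0, noise_sd))
  }
  ab <- ab / sum(ab) * model$x0
  data.frame(guild = names(ab), abundance = unname(ab),
             stringsAsFactors = FALSE)
}
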