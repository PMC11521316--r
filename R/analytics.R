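#' Flux fold change between two conditions
#'
#' log2(v_h / v_l) for a reaction flux under a high- and a low-loading
#' solution. Magnitudes below the zero threshold are treated as exact
#' zero; zero or sign-discordant pairs are flagged rather than forced
#' into a number (the ratio is undefined there).
#'
#' @param v_h,v_l fluxes under the high and low condition.
#' @param zero_threshold magnitude treated as zero
#'   (default 1e-6 mmol gO2-cell^-1 h^-1).
#' @return list with \code{ffc} (NA unless flag is "ok") and \code{flag}
#'   in ok / zeroed_L / zeroed_H / both_zero / sign_discordant.
#' @export
flux_fold_change <- function(v_h, v_l, zero_threshold = 1e-6) {
  stopifnot(is.finite(v_h), is.finite(v_l), zero_threshold >= 0)
  if (abs(v_h) < zero_threshold) v_h <- 0
  if (abs(v_l) < zero_threshold) v_l <- 0
  flag <- if (v_h == 0 && v_l == 0) "both_zero"
          else if (v_l == 0) "zeroed_L"
          else if (v_h == 0) "zeroed_H"
          else if (sign(v_h) != sign(v_l)) "sign_discordant"
          else "ok"
  list(ffc = if (flag == "ok") log2(v_h / v_l) else NA_real_, flag = flag)
}

#' Fold-change intensity category
#'
#' Buckets an absolute fold change as low (< 0.64), medium (0.64 to < 2)
#' or high (>= 2); the 0.64 cut is the butyrate-uptake fold change that
#' anchors the comparison.
#'
#' @param ffc numeric fold changes (NA allowed).
#' @return character vector low/medium/high (NA preserved).
#' @export
ffc_category <- function(ffc) {
  out <- rep(NA_character_, length(ffc))
  a <- abs(ffc)
  out[!is.na(a) & a < 0.64] <- "low"
  out[!is.na(a) & a >= 0.64 & a < 2] <- "medium"
  out[!is.na(a) & a >= 2] <- "high"
  out
}

#' Compare all fluxes between a low- and a high-loading solution
#'
#' @param solution_l,solution_h \code{steadycom_solution}s over the same
#'   model (same guilds and reactions).
#' @param zero_threshold magnitude treated as zero.
#' @return data.frame of class \code{flux_comparison}: guild, reaction,
#'   v_l, v_h, ffc, flag, category.
#' @export
flux_comparison <- function(solution_l, solution_h, zero_threshold = 1e-6) {
  fl <- solution_l$fluxes
  fh <- solution_h$fluxes
  if (!identical(fl$reaction, fh$reaction) ||
      !identical(fl$guild, fh$guild))
    stop("solutions come from different models")
  rec <- mapply(function(h, l) flux_fold_change(h, l, zero_threshold),
                fh$flux, fl$flux, SIMPLIFY = FALSE)
  out <- data.frame(guild = fl$guild, reaction = fl$reaction,
                    v_l = fl$flux, v_h = fh$flux,
                    ffc = vapply(rec, `[[`, 0, "ffc"),
                    flag = vapply(rec, `[[`, "", "flag"),
                    stringsAsFactors = FALSE)
  out$category <- ffc_category(out$ffc)
  class(out) <- c("flux_comparison", "data.frame")
  out
}

#' Write a flux comparison as TSV
#' @param comparison a \code{flux_comparison}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ffc_tsv <- function(comparison, path) {
  utils::write.table(as.data.frame(comparison), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalization with sign reinstatement
#'
#' Normalizes the absolute values of a signed flux series to [0, 1]
#' ((|v| - min|v|) / (max|v| - min|v|)) and then restores the original
#' signs elementwise, mapping a series onto [-1, 1]. A constant series
#' (max = min) is defined as all zeros and flagged.
#'
#' @param series numeric vector, length >= 2.
#' @return list with \code{values} and logical \code{constant}.
#' @export
minmax_normalize <- function(series) {
  stopifnot(is.numeric(series), length(series) >= 2, all(is.finite(series)))
  a <- abs(series)
  rng <- max(a) - min(a)
  if (rng == 0)
    return(list(values = rep(0, length(series)), constant = TRUE))
  list(values = sign(series) * (a - min(a)) / rng, constant = FALSE)
}

#' Ratio of exchange-flux magnitudes between two guilds
#'
#' |Vex(i)^a| / |Vex(i)^b| for one pool metabolite, e.g. the acetate
#' consumption of MET relative to SOB.
#'
#' @param solution a \code{steadycom_solution}.
#' @param metabolite pool metabolite id.
#' @param guild_a,guild_b guild ids (numerator, denominator).
#' @param zero_threshold magnitude below which the denominator flags the
#'   ratio as infinite.
#' @return list with \code{ratio} and logical \code{infinite}.
#' @export
exchange_ratio <- function(solution, metabolite, guild_a, guild_b,
                           zero_threshold = 1e-6) {
  ex <- solution$exchange_fluxes
  pick <- function(g) {
    v <- ex$flux[ex$guild == g & ex$metabolite == metabolite]
    if (length(v) != 1)
      stop(sprintf("guild %s has no unique exchange for '%s'", g, metabolite))
    v
  }
  num <- abs(pick(guild_a))
  den <- abs(pick(guild_b))
  if (den < zero_threshold)
    return(list(ratio = Inf, infinite = TRUE))
  list(ratio = num / den, infinite = FALSE)
}

#' Partition of reducing power between reaction groups
#'
#' Percentage of flux through a numerator reaction set relative to a
#' denominator set within one guild — e.g. the share of NADH from
#' butyrate oxidation that enters the dissimilatory sulfate reduction
#' chain, (V_Apr + V_Dsr) / (V_Acoad1 + V_Hacd1).
#'
#' @param solution a \code{steadycom_solution}.
#' @param guild guild id.
#' @param numerator_rxns,denominator_rxns reaction ids within the guild.
#' @return list with \code{percent} (NA when undefined) and logical
#'   \code{undefined}.
#' @export
nadh_partition <- function(solution, guild, numerator_rxns,
                           denominator_rxns) {
  fl <- solution$fluxes[solution$fluxes$guild == guild, ]
  get <- function(ids) {
    missing <- setdiff(ids, fl$reaction)
    if (length(missing))
      stop("reaction(s) not in guild ", guild, ": ",
           paste(missing, collapse = ", "))
    sum(fl$flux[match(ids, fl$reaction)])
  }
  num <- get(numerator_rxns)
  den <- get(denominator_rxns)
  if (abs(den) < .Machine$double.eps)
    return(list(percent = NA_real_, undefined = TRUE))
  list(percent = 100 * num / den, undefined = FALSE)
}
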