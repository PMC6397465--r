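#' Define a nutrient environment
#'
#' A medium is a set of uptake allowances over exchange reactions: an
#' allowance `a` opens the exchange to uptake by setting its lower bound to
#' `-a` (exchanges are written in the secretion direction, so negative flux
#' is uptake). Exchanges not listed are closed to uptake. An optional trace
#' set marks exchanges present only in trace amounts (e.g. serum carry-over
#' of acetate, fatty acids and amino acids).
#'
#' @param name medium name.
#' @param uptake_bounds named nonnegative numeric vector,
#'   exchange reaction id -> uptake allowance (mmol/gDW/h).
#' @param trace_set character vector of exchange ids present at trace level.
#' @return a `medium_spec`.
#' @export
medium_spec <- function(name, uptake_bounds, trace_set = character()) {
  if (length(uptake_bounds) > 0) {
    stopifnot(!is.null(names(uptake_bounds)), all(uptake_bounds >= 0))
  }
  structure(list(name = name, uptake_bounds = uptake_bounds,
                 trace_set = trace_set),
            class = "medium_spec")
}

#' Apply a medium to a model
#'
#' Listed exchanges get `lower_bound = -allowance`; every unlisted exchange
#' is closed to uptake (`lower_bound = 0`); secretion (upper) bounds are
#' untouched. Trace-set exchanges receive `trace_fraction` of the reference
#' allowance.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_spec()].
#' @param trace_fraction fraction of the reference allowance granted to
#'   trace nutrients (default 0.01).
#' @param trace_reference allowance a trace nutrient would have at standard
#'   level: its own listed allowance if present, else this value
#'   (default 10).
#' @return a constrained copy of the model.
#' @export
apply_medium <- function(model, medium, trace_fraction = 0.01,
                         trace_reference = 10) {
  ids <- names(medium$uptake_bounds)
  all_ids <- unique(c(ids, medium$trace_set))
  is_ex <- model$reactions$is_exchange[match(all_ids, model$reactions$id)]
  if (any(is.na(is_ex)) || !all(is_ex)) {
    bad <- all_ids[is.na(is_ex) | !is_ex]
    stop("medium lists non-exchange or unknown reactions: ",
         paste(bad, collapse = ","))
  }
  for (i in which(model$reactions$is_exchange)) {
    rid <- model$reactions$id[i]
    allowance <- 0
    if (rid %in% ids) allowance <- medium$uptake_bounds[[rid]]
    if (rid %in% medium$trace_set) {
      std <- if (rid %in% ids) medium$uptake_bounds[[rid]] else trace_reference
      allowance <- max(allowance, trace_fraction * std)
    }
    model$reactions$lower_bound[i] <- -allowance
  }
  model
}

#' Screen nutrient removals and excesses
#'
#' For each nutrient and mode, modifies the baseline medium (removal sets
#' the allowance to 0, excess multiplies it by `excess_factor`), solves the
#' weighted bi-objective FBA, and records biomass and acetylation fluxes.
#' One shared baseline condition is solved for reference and attached as the
#' `baseline` attribute.
#'
#' @param model augmented `metabolic_model`.
#' @param medium baseline [medium_spec()].
#' @param nutrients exchange ids to perturb (default: all listed in medium).
#' @param modes subset of `c("removal", "excess")`.
#' @param excess_factor multiplier for the excess mode (default 2).
#' @param epsilon secondary-objective weight.
#' @param settings [solver_settings()].
#' @return data.frame with one row per (nutrient, mode): fluxes, status, and
#'   the supports/not-supports call of [classify_condition()] against the
#'   baseline acetylation flux.
#' @export
nutrient_screen <- function(model, medium, nutrients = names(medium$uptake_bounds),
                            modes = c("removal", "excess"), excess_factor = 2,
                            epsilon = 1e-4, settings = solver_settings()) {
  if (is.null(model$acetylation_reaction_id)) {
    stop("model has no acetylation reaction; augment first")
  }
  base <- solve_weighted_biobjective(apply_medium(model, medium),
                                     epsilon = epsilon, settings = settings)
  rows <- list()
  for (nut in nutrients) {
    for (mode in modes) {
      med2 <- medium
      cur <- if (nut %in% names(med2$uptake_bounds)) {
        med2$uptake_bounds[[nut]]
      } else 0
      med2$uptake_bounds[[nut]] <- if (mode == "removal") 0 else excess_factor * cur
      if (mode == "removal") med2$trace_set <- setdiff(med2$trace_set, nut)
      res <- solve_weighted_biobjective(apply_medium(model, med2),
                                        epsilon = epsilon, settings = settings)
      rows[[length(rows) + 1L]] <- data.frame(
        nutrient = nut, mode = mode,
        acetylation_flux = if (res$status == "optimal") res$acetylation_flux else 0,
        biomass_flux = if (res$status == "optimal") res$biomass_flux else 0,
        status = res$status, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(nutrient = character(), mode = character(),
               acetylation_flux = numeric(), biomass_flux = numeric(),
               status = character(), stringsAsFactors = FALSE)
  }
  if (nrow(out) > 0) {
    out$classification <- classify_condition(out$acetylation_flux,
                                             base$acetylation_flux)
  }
  attr(out, "baseline") <- base
  attr(out, "excess_factor") <- excess_factor
  out
}

#' Classify whether a condition supports acetylation
#'
#' A condition supports acetylation iff its flux reaches at least
#' `threshold_frac` (default 5%) of the wild-type/baseline acetylation flux;
#' the boundary is inclusive. A zero baseline is degenerate: everything is
#' called not-supporting, with a warning.
#'
#' @param acetyl_flux numeric vector of condition fluxes.
#' @param wt_flux baseline acetylation flux (scalar, >= 0).
#' @param threshold_frac support threshold as a fraction of baseline.
#' @return character vector, "supports" / "not_supports".
#' @export
classify_condition <- function(acetyl_flux, wt_flux, threshold_frac = 0.05) {
  stopifnot(length(wt_flux) == 1, wt_flux >= 0)
  if (wt_flux == 0) {
    warning("baseline acetylation flux is 0; all conditions called not_supports")
    return(rep("not_supports", length(acetyl_flux)))
  }
  ifelse(acetyl_flux >= threshold_frac * wt_flux, "supports", "not_supports")
}

#' Genome-wide single-gene deletion screen for acetylation impact
#'
#' Deletes each gene appearing in at least one GPR rule, re-solves the
#' weighted bi-objective FBA, and classifies the deletion:
#' `impacting` when acetylation drops by 1% or more relative to wild type
#' (ratio <= 0.99), `enhancing` when acetylation increases (ratio > 1 beyond
#' numeric zero), else `neutral`. Infeasible knockouts get zero fluxes.
#'
#' @param model augmented `metabolic_model`.
#' @param medium optional [medium_spec()] applied before screening.
#' @param epsilon secondary-objective weight.
#' @param impacting_ratio impacting threshold on the acetylation ratio
#'   (default 0.99, i.e. a 1% reduction).
#' @param settings [solver_settings()]; its `zero_tol` guards the class
#'   boundaries against float jitter.
#' @return data.frame with per-gene fluxes, ratios to wild type, and class.
#' @export
gene_deletion_screen <- function(model, medium = NULL, epsilon = 1e-4,
                                 impacting_ratio = 0.99,
                                 settings = solver_settings()) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  wt <- solve_weighted_biobjective(model, epsilon = epsilon,
                                   settings = settings)
  if (wt$status != "optimal") stop("wild-type FBA not optimal: ", wt$status)
  genes <- genes_in_rules(model)
  nz <- settings$zero_tol
  rows <- lapply(genes, function(g) {
    ko <- apply_knockout(model, g)
    res <- solve_weighted_biobjective(ko, epsilon = epsilon,
                                      settings = settings)
    af <- if (res$status == "optimal") res$acetylation_flux else 0
    bf <- if (res$status == "optimal") res$biomass_flux else 0
    ar <- if (wt$acetylation_flux > nz) af / wt$acetylation_flux else {
      if (af > nz) Inf else 1
    }
    br <- if (wt$biomass_flux > nz) bf / wt$biomass_flux else {
      if (bf > nz) Inf else 1
    }
    cls <- if (ar <= impacting_ratio + nz) "impacting"
           else if (ar > 1 + nz) "enhancing" else "neutral"
    data.frame(gene = g, acetylation_flux = af, biomass_flux = bf,
               acetylation_ratio = ar, biomass_ratio = br, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(gene = character(), acetylation_flux = numeric(),
               biomass_flux = numeric(), acetylation_ratio = numeric(),
               biomass_ratio = numeric(), class = character(),
               stringsAsFactors = FALSE)
  }
  attr(out, "wild_type") <- wt
  out
}

#' Rank gene deletions that preferentially hit acetylation over growth
#'
#' Filters deletions retaining at least `biomass_floor` (default 50%) of
#' wild-type biomass, then ranks by how much more the deletion reduces
#' acetylation than biomass (descending); ties go to the deletion with the
#' higher biomass ratio.
#'
#' @param records data.frame from [gene_deletion_screen()].
#' @param biomass_floor minimum biomass ratio to keep (default 0.5).
#' @param top_n how many genes to return (default 20).
#' @return ranked data.frame (top `top_n` rows) with a `preference_score`
#'   column (`biomass_ratio - acetylation_ratio`).
#' @export
rank_preferential <- function(records, biomass_floor = 0.5, top_n = 20) {
  keep <- records[records$biomass_ratio >= biomass_floor, , drop = FALSE]
  keep$preference_score <- keep$biomass_ratio - keep$acetylation_ratio
  ord <- order(-keep$preference_score, -keep$biomass_ratio, keep$gene)
  keep <- keep[ord, , drop = FALSE]
  if (nrow(keep) < top_n) {
    warning("only ", nrow(keep), " deletions pass the biomass floor (< ",
            top_n, " requested)")
    return(keep)
  }
  keep[seq_len(top_n), , drop = FALSE]
}
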