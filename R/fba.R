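#' Solver settings for flux balance computations
#'
#' @param feasibility_tol tolerance on `|S v|` accepted at the optimum.
#' @param optimality_tol tolerance used when fixing an objective at its
#'   optimum (flux variability, lexicographic stages).
#' @param zero_tol numeric zero for reporting/classification.
#' @return a `solver_settings` list.
#' @export
solver_settings <- function(feasibility_tol = 1e-9, optimality_tol = 1e-9,
                            zero_tol = 1e-6) {
  stopifnot(feasibility_tol > 0, optimality_tol > 0, zero_tol > 0)
  structure(list(feasibility_tol = feasibility_tol,
                 optimality_tol = optimality_tol,
                 zero_tol = zero_tol),
            class = "solver_settings")
}

#' Define a (possibly multi-term) linear FBA objective
#'
#' @param weights named numeric vector, reaction id -> weight; the objective
#'   is always maximized.
#' @return an `fba_objective`.
#' @export
fba_objective <- function(weights) {
  if (length(weights) == 0 || all(weights == 0)) {
    stop("objective needs at least one nonzero weight")
  }
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("objective weights must be named by reaction id")
  }
  structure(list(weights = weights, sense = "maximize"),
            class = "fba_objective")
}

model_lp_parts <- function(model) {
  S <- as.matrix(build_stoich_matrix(model))
  list(S = S,
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       rxn_ids = model$reactions$id)
}

fba_result <- function(status, fluxes, objective_value, model, settings) {
  bio <- if (status == "optimal") unname(fluxes[model$biomass_reaction_id]) else NA_real_
  ace <- if (status == "optimal" && !is.null(model$acetylation_reaction_id)) {
    unname(fluxes[model$acetylation_reaction_id])
  } else NA_real_
  structure(list(status = status, fluxes = fluxes,
                 objective_value = objective_value,
                 biomass_flux = bio, acetylation_flux = ace),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective:  ", format(x$objective_value), "\n")
    cat("  biomass:    ", format(x$biomass_flux), "\n")
    if (!is.na(x$acetylation_flux)) {
      cat("  acetylation:", format(x$acetylation_flux), "\n")
    }
  }
  invisible(x)
}

#' Flux balance analysis
#'
#' Finds a flux vector `v` maximizing the objective subject to steady state
#' (`S v = 0`, mass balance of every internal species) and the reaction
#' bounds. Fluxes are in mmol/gDW/h.
#'
#' @param model a `metabolic_model`.
#' @param objective an [fba_objective()]; default maximizes biomass.
#' @param settings [solver_settings()].
#' @return an `fba_result` with `status`, named `fluxes`, `objective_value`,
#'   `biomass_flux` and (for augmented models) `acetylation_flux`.
#' @export
solve_fba <- function(model, objective = NULL, settings = solver_settings()) {
  if (is.null(objective)) {
    objective <- fba_objective(stats::setNames(1, model$biomass_reaction_id))
  }
  parts <- model_lp_parts(model)
  missing <- setdiff(names(objective$weights), parts$rxn_ids)
  if (length(missing) > 0) {
    stop("objective names unknown reactions: ", paste(missing, collapse = ","))
  }
  obj <- numeric(length(parts$rxn_ids))
  obj[match(names(objective$weights), parts$rxn_ids)] <- objective$weights
  sol <- lp_solve(obj, Aeq = parts$S, beq = rep(0, nrow(parts$S)),
                  lb = parts$lb, ub = parts$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(fba_result(sol$status, NULL, NA_real_, model, settings))
  }
  fluxes <- stats::setNames(sol$x, parts$rxn_ids)
  resid <- max(abs(parts$S %*% sol$x))
  if (resid > max(settings$feasibility_tol, 1e-7)) {
    warning("steady-state residual ", format(resid), " above tolerance")
  }
  fba_result("optimal", fluxes, sol$objval, model, settings)
}

#' Weighted biomass + acetylation bi-objective FBA
#'
#' Solves the single weighted LP `maximize biomass + epsilon * acetylation`.
#' Acetylation is a secondary objective: with a small positive `epsilon` the
#' acetylation flux reported is the amount of excess carbon the optimal state
#' can divert to acetylation without compromising growth, and its value is
#' insensitive to `epsilon` across orders of magnitude. A lexicographic mode
#' (maximize biomass, fix it, then maximize acetylation) is available as an
#' option.
#'
#' @param model augmented `metabolic_model` (or pass explicit ids).
#' @param biomass_id,acetyl_id reaction ids; default the model's designations.
#' @param epsilon secondary-objective weight, `0 < epsilon <= 0.01`
#'   (default 1e-4).
#' @param settings [solver_settings()].
#' @param lexicographic use the two-stage formulation instead of the single
#'   weighted LP.
#' @return an `fba_result`.
#' @export
solve_weighted_biobjective <- function(model,
                                       biomass_id = model$biomass_reaction_id,
                                       acetyl_id = model$acetylation_reaction_id,
                                       epsilon = 1e-4,
                                       settings = solver_settings(),
                                       lexicographic = FALSE) {
  if (is.null(acetyl_id)) stop("model has no acetylation reaction; augment first")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (epsilon > 0.01) {
    warning("epsilon above the validated range (0, 0.01]; acetylation may ",
            "no longer act as a secondary objective")
  }
  if (!lexicographic) {
    w <- stats::setNames(c(1, epsilon), c(biomass_id, acetyl_id))
    return(solve_fba(model, fba_objective(w), settings))
  }
  stage1 <- solve_fba(model, fba_objective(stats::setNames(1, biomass_id)),
                      settings)
  if (stage1$status != "optimal") return(stage1)
  parts <- model_lp_parts(model)
  jb <- match(biomass_id, parts$rxn_ids)
  ja <- match(acetyl_id, parts$rxn_ids)
  fix <- numeric(length(parts$rxn_ids)); fix[jb] <- 1
  obj <- numeric(length(parts$rxn_ids)); obj[ja] <- 1
  tol <- settings$optimality_tol * max(1, abs(stage1$objective_value))
  sol <- lp_solve(obj, Aeq = parts$S, beq = rep(0, nrow(parts$S)),
                  Age = matrix(fix, 1), bge = stage1$objective_value - tol,
                  lb = parts$lb, ub = parts$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(fba_result(sol$status, NULL, NA_real_, model, settings))
  }
  fluxes <- stats::setNames(sol$x, parts$rxn_ids)
  fba_result("optimal", fluxes, sum(fluxes[jb]), model, settings)
}

#' Apply gene knockouts to a model
#'
#' Every reaction whose GPR rule evaluates inactive under the deletion gets
#' bounds (0, 0); reactions without rules, and all other bounds, are
#' untouched. The input model is not modified. Deleting a gene absent from
#' the model is a no-op with a warning.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to delete.
#' @return a constrained copy of the model.
#' @export
apply_knockout <- function(model, genes) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0) {
    warning("deleted genes not in model (ignored): ",
            paste(unknown, collapse = ","))
  }
  genes <- intersect(genes, model$genes)
  if (length(genes) == 0) return(model)
  for (i in seq_len(nrow(model$reactions))) {
    g <- model$reactions$gene_rule[i]
    if (is.na(g)) next
    if (!evaluate_gene_rule(parse_gene_rule(g), deleted = genes)) {
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  }
  model
}

#' Flux variability at the optimum
#'
#' Minimum and maximum flux a reaction can carry over the optimal face of the
#' objective (objective fixed at its optimum within tolerance). Used to
#' detect alternate optima that would make a reported acetylation flux
#' ambiguous.
#'
#' @param model a `metabolic_model`.
#' @param objective an [fba_objective()]; default biomass.
#' @param reaction_ids reactions to scan (default: all).
#' @param settings [solver_settings()].
#' @return data.frame with `reaction`, `min_flux`, `max_flux`.
#' @export
flux_variability_at_optimum <- function(model, objective = NULL,
                                        reaction_ids = NULL,
                                        settings = solver_settings()) {
  if (is.null(objective)) {
    objective <- fba_objective(stats::setNames(1, model$biomass_reaction_id))
  }
  base <- solve_fba(model, objective, settings)
  if (base$status != "optimal") {
    stop("objective not solvable (status ", base$status, ")")
  }
  parts <- model_lp_parts(model)
  if (is.null(reaction_ids)) reaction_ids <- parts$rxn_ids
  wvec <- numeric(length(parts$rxn_ids))
  wvec[match(names(objective$weights), parts$rxn_ids)] <- objective$weights
  tol <- settings$optimality_tol * max(1, abs(base$objective_value))
  Age <- matrix(wvec, 1)
  bge <- base$objective_value - tol
  out <- lapply(reaction_ids, function(rid) {
    j <- match(rid, parts$rxn_ids)
    if (is.na(j)) stop("no reaction '", rid, "' in model")
    obj <- numeric(length(parts$rxn_ids)); obj[j] <- 1
    lo <- lp_solve(obj, Aeq = parts$S, beq = rep(0, nrow(parts$S)),
                   Age = Age, bge = bge, lb = parts$lb, ub = parts$ub,
                   maximize = FALSE)
    hi <- lp_solve(obj, Aeq = parts$S, beq = rep(0, nrow(parts$S)),
                   Age = Age, bge = bge, lb = parts$lb, ub = parts$ub,
                   maximize = TRUE)
    data.frame(reaction = rid, min_flux = lo$objval, max_flux = hi$objval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
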