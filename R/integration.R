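#' Settings for transcriptome integration
#'
#' @param low_quantile,high_quantile per-sample expression quantiles (over
#'   genes shared with the model) below/above which a gene is called low /
#'   high; defaults bottom and top quartile.
#' @param activation_flux absolute flux level (mmol/gDW/h) at which a
#'   highly expressed reaction counts as active (default 0.001).
#' @param penalty_weight objective weight on absolute flux through
#'   low-expressed reactions.
#' @param reward_weight objective weight on the activation shortfall of
#'   high-expressed reactions.
#' @param gimme_floor biomass floor as a fraction of the optimum in the
#'   GIMME-style program (default 0.9).
#' @param gimme_threshold_quantile expression quantile defining the GIMME
#'   penalty threshold (default 0.25).
#' @return an `integration_settings` list.
#' @export
integration_settings <- function(low_quantile = 0.25, high_quantile = 0.75,
                                 activation_flux = 0.001,
                                 penalty_weight = 1, reward_weight = 1,
                                 gimme_floor = 0.9,
                                 gimme_threshold_quantile = 0.25) {
  stopifnot(low_quantile > 0, low_quantile < high_quantile, high_quantile < 1,
            activation_flux > 0, penalty_weight >= 0, reward_weight >= 0,
            gimme_floor >= 0, gimme_floor <= 1)
  structure(list(low_quantile = low_quantile, high_quantile = high_quantile,
                 activation_flux = activation_flux,
                 penalty_weight = penalty_weight,
                 reward_weight = reward_weight,
                 gimme_floor = gimme_floor,
                 gimme_threshold_quantile = gimme_threshold_quantile),
            class = "integration_settings")
}

profile_linear <- function(profile) {
  scale <- attr(profile, "scale")
  if (identical(scale, "log2")) profile <- 2^profile
  if (any(profile < 0, na.rm = TRUE)) {
    stop("negative expression values on the linear scale")
  }
  profile
}

#' Discretize an expression profile into reaction states
#'
#' Gene states (`low` / `moderate` / `high`) come from per-sample quantile
#' thresholds over the genes shared with the model; reaction states are
#' propagated through GPR rules with `AND = min`, `OR = max` under the
#' ordering low < moderate < high. Only reactions with gene rules get
#' non-moderate states. Profiles declared `log2` (via `attr(x, "scale")`)
#' are exponentiated first.
#'
#' When a profile is one sample of a cohort, pass the pooled cohort values
#' as `reference`: thresholds are then cohort-relative (the convention when
#' integrating a cell-line panel), so that a sample's calls reflect where
#' its genes sit in the panel-wide distribution rather than forcing a fixed
#' fraction of each sample's genes into the low/high states.
#'
#' @param profile named numeric vector, gene id -> expression.
#' @param model a `metabolic_model`.
#' @param settings [integration_settings()].
#' @param reference numeric values defining the quantile thresholds
#'   (same scale as `profile`); default: the profile's own shared-gene
#'   values.
#' @return a `discretized_states` object holding `gene_states`,
#'   `reaction_states` and the rules needed to recompute them.
#' @export
discretize <- function(profile, model, settings = integration_settings(),
                       reference = NULL) {
  scale <- attr(profile, "scale")
  profile <- profile_linear(profile)
  shared <- intersect(names(profile), model$genes)
  if (length(shared) == 0) {
    stop("no genes shared between profile (e.g. '",
         paste(utils::head(names(profile), 3), collapse = "','"),
         "') and model (e.g. '",
         paste(utils::head(model$genes, 3), collapse = "','"),
         "'); check the gene id namespace")
  }
  vals <- profile[shared]
  if (is.null(reference)) {
    reference <- vals
  } else {
    attr(reference, "scale") <- scale
    reference <- profile_linear(reference)
  }
  thr <- stats::quantile(reference,
                         c(settings$low_quantile, settings$high_quantile),
                         names = FALSE, type = 7)
  gene_states <- ifelse(vals >= thr[2] & vals > thr[1], "high",
                 ifelse(vals <= thr[1] & vals < thr[2], "low", "moderate"))
  names(gene_states) <- shared
  st <- structure(list(gene_states = gene_states,
                       rules = stats::setNames(model$reactions$gene_rule,
                                               model$reactions$id),
                       settings = settings),
                  class = "discretized_states")
  st$reaction_states <- recompute_reaction_states(st)
  st
}

recompute_reaction_states <- function(states) {
  lev <- c(low = 1, moderate = 2, high = 3)
  gv <- as.list(lev[states$gene_states])
  names(gv) <- names(states$gene_states)
  out <- vapply(seq_along(states$rules), function(i) {
    g <- states$rules[[i]]
    if (is.na(g)) return("moderate")
    val <- rule_fold(parse_gene_rule(g), gv, and_fn = min, or_fn = max,
                     missing_value = 2)
    names(lev)[val]
  }, character(1))
  stats::setNames(out, names(states$rules))
}

#' Overlay a drug's differential-expression signature on reaction states
#'
#' Genes in the signature's down set are forced `low`, up-set genes forced
#' `high`; all other gene states are unchanged. Reaction states are then
#' recomputed through the GPR rules.
#'
#' @param states a `discretized_states` from [discretize()].
#' @param signature a [drug_signature()].
#' @return updated `discretized_states`.
#' @export
apply_drug_signature <- function(states, signature) {
  both <- intersect(signature$up_genes, signature$down_genes)
  if (length(both) > 0) {
    stop("signature lists genes as both up and down: ",
         paste(both, collapse = ","))
  }
  for (g in signature$down_genes) states$gene_states[[g]] <- "low"
  for (g in signature$up_genes) states$gene_states[[g]] <- "high"
  states$reaction_states <- recompute_reaction_states(states)
  states
}

#' Define a drug's up/down gene signature
#'
#' @param drug drug name.
#' @param up_genes,down_genes disjoint character vectors of gene ids.
#' @return a `drug_signature`.
#' @export
drug_signature <- function(drug, up_genes = character(),
                           down_genes = character()) {
  if (length(intersect(up_genes, down_genes)) > 0) {
    stop("up_genes and down_genes must be disjoint")
  }
  structure(list(drug = drug, up_genes = up_genes, down_genes = down_genes),
            class = "drug_signature")
}

split_var_bounds <- function(lb, ub) {
  list(p_lb = pmax(lb, 0), p_ub = pmax(ub, 0),
       q_lb = pmax(-ub, 0), q_ub = pmax(-lb, 0))
}

#' Transcriptome-constrained FBA, linear iMAT style
#'
#' Solves one LP over split fluxes (`v = p - q`, `p, q >= 0`, so `p + q`
#' linearizes `|v|`): the weighted biomass + epsilon x acetylation objective
#' is retained; each low-state reaction pays `penalty_weight` per unit of
#' absolute flux; each high-state reaction carries a soft activation reward
#' implemented as a penalized shortfall slack `s` with
#' `|v| + s >= activation_flux`, `0 <= s <= activation_flux`. Steady state
#' and bounds are hard; the expression constraints are soft, so individual
#' ones can be violated when the data conflict with mass balance.
#'
#' With all states moderate the program reduces exactly to the weighted
#' bi-objective FBA.
#'
#' @param model augmented `metabolic_model` (medium already applied).
#' @param states [discretize()] output (possibly signature-overlaid).
#' @param settings [integration_settings()].
#' @param epsilon secondary-objective weight.
#' @return an `fba_result`; the penalty-adjusted LP optimum is attached as
#'   attribute `imat_objective`.
#' @export
integrate_imat_linear <- function(model, states,
                                  settings = integration_settings(),
                                  epsilon = 1e-4) {
  if (is.null(model$acetylation_reaction_id)) {
    stop("model has no acetylation reaction; augment first")
  }
  parts <- model_lp_parts(model)
  n <- length(parts$rxn_ids)
  rs <- states$reaction_states[parts$rxn_ids]
  rs[is.na(rs)] <- "moderate"
  high <- which(rs == "high")
  low <- which(rs == "low")
  nh <- length(high)
  sb <- split_var_bounds(parts$lb, parts$ub)

  nv <- 2L * n + nh
  obj <- numeric(nv)
  jb <- match(model$biomass_reaction_id, parts$rxn_ids)
  ja <- match(model$acetylation_reaction_id, parts$rxn_ids)
  obj[jb] <- obj[jb] + 1; obj[n + jb] <- obj[n + jb] - 1
  obj[ja] <- obj[ja] + epsilon; obj[n + ja] <- obj[n + ja] - epsilon
  obj[low] <- obj[low] - settings$penalty_weight
  obj[n + low] <- obj[n + low] - settings$penalty_weight
  if (nh > 0) obj[2L * n + seq_len(nh)] <- -settings$reward_weight

  Aeq <- cbind(parts$S, -parts$S, matrix(0, nrow(parts$S), nh))
  beq <- rep(0, nrow(parts$S))
  Age <- NULL; bge <- NULL
  if (nh > 0) {
    Age <- matrix(0, nh, nv)
    for (k in seq_len(nh)) {
      Age[k, high[k]] <- 1
      Age[k, n + high[k]] <- 1
      Age[k, 2L * n + k] <- 1
    }
    bge <- rep(settings$activation_flux, nh)
  }
  lb <- c(sb$p_lb, sb$q_lb, rep(0, nh))
  ub <- c(sb$p_ub, sb$q_ub, rep(settings$activation_flux, nh))
  sol <- lp_solve(obj, Aeq = Aeq, beq = beq, Age = Age, bge = bge,
                  lb = lb, ub = ub, maximize = TRUE)
  if (sol$status != "optimal") {
    stop("iMAT program not optimal (status ", sol$status,
         "); n high=", nh, ", n low=", length(low))
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  res <- fba_result("optimal", stats::setNames(v, parts$rxn_ids),
                    sum(v[jb]), model, solver_settings())
  attr(res, "imat_objective") <- sol$objval
  res
}

#' Transcriptome-constrained FBA, GIMME style
#'
#' Three LP stages: (1) maximize biomass; (2) minimize
#' `sum_r max(0, threshold - expression_r) * |v_r|` subject to biomass at
#' least `gimme_floor` of its optimum, where reaction-level expression comes
#' from GPR rules (AND = min, OR = max) and the threshold is a per-sample
#' expression quantile; (3) within that penalty optimum (and the biomass
#' floor), re-maximize the weighted biomass + epsilon x acetylation
#' objective and report its flux state. Stage 3 uses the weighted objective
#' rather than acetylation alone so that a penalty-free profile reduces
#' exactly to the plain weighted bi-objective FBA.
#'
#' @param model augmented `metabolic_model` (medium already applied).
#' @param profile named numeric expression vector (see [discretize()] for
#'   the scale convention).
#' @param settings [integration_settings()].
#' @param epsilon secondary-objective weight.
#' @return an `fba_result`; attributes `gimme_penalty` (stage-2 optimum) and
#'   `gimme_threshold`.
#' @export
integrate_gimme <- function(model, profile,
                            settings = integration_settings(),
                            epsilon = 1e-4) {
  if (is.null(model$acetylation_reaction_id)) {
    stop("model has no acetylation reaction; augment first")
  }
  profile <- profile_linear(profile)
  shared <- intersect(names(profile), model$genes)
  if (length(shared) == 0) stop("no genes shared between profile and model")
  thr <- stats::quantile(profile[shared], settings$gimme_threshold_quantile,
                         names = FALSE, type = 7)
  gv <- as.list(profile[shared])
  w <- vapply(model$reactions$gene_rule, function(g) {
    if (is.na(g)) return(0)
    e <- rule_fold(parse_gene_rule(g), gv, and_fn = min, or_fn = max,
                   missing_value = NA)
    if (is.na(e)) 0 else max(0, thr - e)
  }, numeric(1))

  parts <- model_lp_parts(model)
  n <- length(parts$rxn_ids)
  jb <- match(model$biomass_reaction_id, parts$rxn_ids)
  ja <- match(model$acetylation_reaction_id, parts$rxn_ids)

  stage1 <- solve_fba(model)
  if (stage1$status != "optimal") {
    stop("biomass FBA not optimal: ", stage1$status)
  }
  floor_val <- settings$gimme_floor * stage1$objective_value

  sb <- split_var_bounds(parts$lb, parts$ub)
  nv <- 2L * n
  Aeq <- cbind(parts$S, -parts$S)
  beq <- rep(0, nrow(parts$S))
  lb <- c(sb$p_lb, sb$q_lb)
  ub <- c(sb$p_ub, sb$q_ub)
  floor_row <- numeric(nv); floor_row[jb] <- 1; floor_row[n + jb] <- -1

  pen_obj <- c(w, w)
  s2 <- lp_solve(pen_obj, Aeq = Aeq, beq = beq,
                 Age = matrix(floor_row, 1), bge = floor_val,
                 lb = lb, ub = ub, maximize = FALSE)
  if (s2$status != "optimal") {
    stop("GIMME penalty stage ", s2$status, " at biomass floor ",
         format(floor_val), "; try a lower gimme_floor")
  }
  budget <- s2$objval + 1e-6 * max(1, abs(s2$objval))

  obj3 <- numeric(nv)
  obj3[jb] <- 1; obj3[n + jb] <- -1
  obj3[ja] <- epsilon; obj3[n + ja] <- -epsilon
  s3 <- lp_solve(obj3, Aeq = Aeq, beq = beq,
                 Age = rbind(floor_row, -pen_obj),
                 bge = c(floor_val, -budget),
                 lb = lb, ub = ub, maximize = TRUE)
  if (s3$status != "optimal") {
    stop("GIMME flux stage not optimal: ", s3$status)
  }
  v <- s3$x[seq_len(n)] - s3$x[n + seq_len(n)]
  res <- fba_result("optimal", stats::setNames(v, parts$rxn_ids),
                    sum(v[jb]), model, solver_settings())
  attr(res, "gimme_penalty") <- s2$objval
  attr(res, "gimme_threshold") <- thr
  res
}

#' Acetylation flux change caused by a drug
#'
#' @param basal,treated optimal `fba_result`s for the basal and
#'   signature-overlaid states.
#' @return `basal$acetylation_flux - treated$acetylation_flux` (positive =
#'   the drug reduces acetylation flux).
#' @export
acetylation_delta <- function(basal, treated) {
  if (!identical(basal$status, "optimal") || !identical(treated$status, "optimal")) {
    stop("both results must be optimal")
  }
  basal$acetylation_flux - treated$acetylation_flux
}

#' Predict acetylation flux for every sample of an expression cohort
#'
#' Runs [discretize()] + [integrate_imat_linear()] (or [integrate_gimme()])
#' per sample. Samples whose discretized reaction states (or GIMME penalty
#' weights) coincide share one LP solve.
#'
#' @param model augmented `metabolic_model` with medium applied.
#' @param expr genes x samples expression matrix.
#' @param settings [integration_settings()].
#' @param method "imat" or "gimme".
#' @param epsilon secondary-objective weight.
#' @param signature optional [drug_signature()] overlaid on every sample
#'   (iMAT method only).
#' @return data.frame with `sample`, `acetylation_flux`, `biomass_flux`.
#' @export
integrate_cohort <- function(model, expr, settings = integration_settings(),
                             method = c("imat", "gimme"), epsilon = 1e-4,
                             signature = NULL) {
  method <- match.arg(method)
  if (method == "gimme" && !is.null(signature)) {
    stop("signature overlay is defined on discretized states (iMAT method)")
  }
  cache <- new.env(parent = emptyenv())
  shared <- intersect(rownames(expr), model$genes)
  reference <- as.numeric(expr[shared, , drop = FALSE])
  rows <- lapply(colnames(expr), function(sm) {
    profile <- expr[, sm]
    attr(profile, "scale") <- attr(expr, "scale")
    if (method == "imat") {
      states <- discretize(profile, model, settings, reference = reference)
      if (!is.null(signature)) states <- apply_drug_signature(states, signature)
      key <- paste(states$reaction_states, collapse = "|")
      if (is.null(cache[[key]])) {
        cache[[key]] <- integrate_imat_linear(model, states, settings, epsilon)
      }
    } else {
      key <- paste(signif(unname(profile), 10), collapse = "|")
      if (is.null(cache[[key]])) {
        cache[[key]] <- integrate_gimme(model, profile, settings, epsilon)
      }
    }
    res <- cache[[key]]
    data.frame(sample = sm, acetylation_flux = res$acetylation_flux,
               biomass_flux = res$biomass_flux, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
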