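# Small fixture networks built in code, plus independent oracles used to
# cross-check the LP machinery.

simple_met <- function(id, compartment = "c") {
  data.frame(id = id, name = id, compartment = compartment,
             formula = NA_character_, stringsAsFactors = FALSE)
}

simple_rxn <- function(id, stoich, lb = 0, ub = 1000, gene = NA_character_) {
  df <- data.frame(id = id, lower_bound = lb, upper_bound = ub,
                   gene_rule = gene, subsystem = NA_character_,
                   stringsAsFactors = FALSE)
  df$stoichiometry <- list(stoich)
  df
}

make_net <- function(mets, rxns, biomass = "BIO", acetyl = NULL) {
  metabolic_model(
    metabolites = do.call(rbind, lapply(mets, simple_met)),
    reactions = do.call(rbind, rxns),
    compartments = "c",
    biomass_reaction_id = biomass,
    acetylation_reaction_id = acetyl
  )
}

# linear chain: uptake (lb -10) -> A -> biomass
chain_net <- function() {
  make_net(list("A"), list(
    simple_rxn("EX_A", c(A = -1), lb = -10),
    simple_rxn("BIO", c(A = -1))
  ))
}

# branched: A feeds B (biomass) and C (secretion); B path capped
branch_net <- function() {
  make_net(list("A", "B", "C"), list(
    simple_rxn("EX_A", c(A = -1), lb = -10),
    simple_rxn("R_AB", c(A = -1, B = 1), ub = 6, gene = "g_ab"),
    simple_rxn("R_AC", c(A = -1, C = 1), gene = "g_ac"),
    simple_rxn("BIO", c(B = -1)),
    simple_rxn("EX_C", c(C = -1))
  ))
}

# 10 carbon units in; biomass consumes at most 7; the rest can acetylate
overflow_net <- function() {
  make_net(list("C"), list(
    simple_rxn("EX_C", c(C = -1), lb = -10),
    simple_rxn("BIO", c(C = -1), ub = 7),
    simple_rxn("ACET", c(C = -1))
  ), acetyl = "ACET")
}

# two equivalent parallel routes A -> B; optimum is degenerate across them
parallel_net <- function() {
  make_net(list("A", "B"), list(
    simple_rxn("EX_A", c(A = -1), lb = -10),
    simple_rxn("P1", c(A = -1, B = 1), gene = "g1"),
    simple_rxn("P2", c(A = -1, B = 1), gene = "g2"),
    simple_rxn("BIO", c(B = -1))
  ))
}

# seeded random bounded networks (<= 8 reactions) for oracle sweeps
random_net <- function(seed) {
  set.seed(seed)
  n_met <- sample(2:3, 1)
  n_rxn <- sample(4:8, 1)
  repeat {
    S <- matrix(sample(c(-1, 0, 1, 2), n_met * n_rxn, replace = TRUE,
                       prob = c(0.35, 0.3, 0.3, 0.05)), n_met, n_rxn)
    if (all(colSums(S != 0) > 0)) break
  }
  lb <- ifelse(stats::runif(n_rxn) < 0.4, -5, 0)
  ub <- rep(5, n_rxn)
  list(S = S, lb = lb, ub = ub)
}

# --- vertex-enumeration oracle -------------------------------------------
# Vertices of {v : S v = 0, lb <= v <= ub}: fix (n - rank(S)) coordinates at
# a bound, solve the equality system for the rest, keep feasible points.
enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  r <- qr(S)$rank
  d <- n - r
  if (d == 0) {
    v <- rep(0, n)
    return(if (all(v >= lb - tol & v <= ub + tol)) list(v) else list())
  }
  verts <- list()
  for (J in utils::combn(n, d, simplify = FALSE)) {
    free <- setdiff(seq_len(n), J)
    A <- S[, free, drop = FALSE]
    if (qr(A)$rank < length(free)) next
    for (pat in seq_len(2^d) - 1) {
      vJ <- ifelse(bitwAnd(pat, 2^(seq_len(d) - 1)) > 0, ub[J], lb[J])
      if (any(!is.finite(vJ))) next
      b <- -S[, J, drop = FALSE] %*% vJ
      vf <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(vf)) next
      v <- numeric(n); v[J] <- vJ; v[free] <- vf
      if (max(abs(S %*% v)) < tol && all(v >= lb - tol) && all(v <= ub + tol)) {
        verts[[length(verts) + 1]] <- v
      }
    }
  }
  verts
}

oracle_lp_max <- function(obj, S, lb, ub) {
  verts <- enumerate_vertices(S, lb, ub)
  if (length(verts) == 0) return(NULL)
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  list(objval = max(vals), vertex = verts[[which.max(vals)]])
}

oracle_fba <- function(model, weights) {
  S <- as.matrix(build_stoich_matrix(model))
  obj <- numeric(ncol(S))
  obj[match(names(weights), colnames(S))] <- weights
  oracle_lp_max(obj, S, model$reactions$lower_bound,
                model$reactions$upper_bound)
}

# --- truth-table GPR oracle ----------------------------------------------
# Independent evaluator: translate the rule string to an R logical
# expression and eval() it against gene presence.
oracle_rule_eval <- function(rule_string, deleted, genes) {
  expr_str <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule_string,
                                          ignore.case = TRUE),
                   ignore.case = TRUE)
  env <- as.list(stats::setNames(!(genes %in% deleted), genes))
  eval(parse(text = expr_str), envir = env)
}

random_rule <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  paste0("(", random_rule(genes, depth - 1), " ", op, " ",
         random_rule(genes, depth - 1), ")")
}

# --- piecewise-branch oracle for the linear iMAT program ------------------
# The penalty-adjusted objective is concave piecewise-linear in |v|; for
# each high reaction the activation reward has two linear branches
# (reached / shortfall). Enumerating all branch patterns and solving each
# restricted LP with boot::simplex bounds the exact optimum.
oracle_imat_objective <- function(model, states, settings, epsilon) {
  S <- as.matrix(build_stoich_matrix(model))
  n <- ncol(S)
  rxn_ids <- colnames(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  p_ub <- pmax(ub, 0); q_ub <- pmax(-lb, 0)
  p_lb <- pmax(lb, 0); q_lb <- pmax(-ub, 0)
  rs <- states$reaction_states[rxn_ids]
  rs[is.na(rs)] <- "moderate"
  high <- which(rs == "high"); low <- which(rs == "low")
  act <- settings$activation_flux
  jb <- match(model$biomass_reaction_id, rxn_ids)
  ja <- match(model$acetylation_reaction_id, rxn_ids)

  base_obj <- numeric(2 * n)
  base_obj[jb] <- 1; base_obj[n + jb] <- -1
  base_obj[ja] <- base_obj[ja] + epsilon; base_obj[n + ja] <- base_obj[n + ja] - epsilon
  base_obj[low] <- base_obj[low] - settings$penalty_weight
  base_obj[n + low] <- base_obj[n + low] - settings$penalty_weight

  Aeq3 <- cbind(S, -S)
  ub_rows <- diag(2 * n)
  best <- -Inf
  nh <- length(high)
  for (pat in seq_len(max(1, 2^nh)) - 1) {
    reached <- if (nh > 0) bitwAnd(pat, 2^(seq_len(nh) - 1)) > 0 else logical(0)
    obj <- base_obj
    A1 <- ub_rows; b1 <- c(p_ub, q_ub)
    A2 <- NULL; b2 <- NULL
    const <- 0
    for (k in seq_len(nh)) {
      row <- numeric(2 * n)
      row[high[k]] <- 1; row[n + high[k]] <- 1
      if (reached[k]) {
        A2 <- rbind(A2, row); b2 <- c(b2, act)
      } else {
        A1 <- rbind(A1, row); b1 <- c(b1, act)
        obj[high[k]] <- obj[high[k]] + settings$reward_weight
        obj[n + high[k]] <- obj[n + high[k]] + settings$reward_weight
        const <- const - settings$reward_weight * act
      }
    }
    keep_lb <- which(c(p_lb, q_lb) > 0)
    if (length(keep_lb) > 0) {
      A2 <- rbind(A2, diag(2 * n)[keep_lb, , drop = FALSE])
      b2 <- c(b2, c(p_lb, q_lb)[keep_lb])
    }
    sol <- tryCatch(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    A3 = Aeq3, b3 = rep(0, nrow(Aeq3)), maxi = TRUE,
                    n.iter = 2000),
      error = function(e) NULL)
    if (!is.null(sol) && sol$solved == 1) {
      best <- max(best, sol$value + const)
    }
  }
  best
}

toy_ready <- function() {
  apply_medium(make_toy_network(), toy_baseline_medium())
}
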