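flat_profile <- function(model, value = 5) {
  p <- stats::setNames(rep(value, length(model$genes)), model$genes)
  attr(p, "scale") <- "log2"
  p
}

test_that("flat profiles discretize to all-moderate states", {
  m <- toy_ready()
  st <- discretize(flat_profile(m), m)
  expect_true(all(st$gene_states == "moderate"))
  expect_true(all(st$reaction_states == "moderate"))
})

test_that("rule semantics: AND takes the minimum state, OR the maximum", {
  m <- branch_net()
  m$reactions$gene_rule[m$reactions$id == "R_AB"] <- "g_hi and g_lo"
  m$reactions$gene_rule[m$reactions$id == "R_AC"] <- "g_hi or g_lo"
  m$genes <- c("g_hi", "g_lo", "g_mid1", "g_mid2", "g_mid3")
  p <- c(g_hi = 100, g_lo = 1, g_mid1 = 10, g_mid2 = 10, g_mid3 = 10)
  st <- discretize(p, m)
  expect_equal(unname(st$gene_states[c("g_hi", "g_lo")]), c("high", "low"))
  expect_equal(unname(st$reaction_states[["R_AB"]]), "low")
  expect_equal(unname(st$reaction_states[["R_AC"]]), "high")
  # reactions without rules stay moderate
  expect_equal(unname(st$reaction_states[["EX_A"]]), "moderate")
})

test_that("quantile calls track the planted tail mass in a lognormal cohort", {
  m <- toy_ready()
  set.seed(21)
  p <- stats::setNames(stats::rnorm(length(m$genes), 5, 1), m$genes)
  attr(p, "scale") <- "log2"
  st <- discretize(p, m)
  n <- length(m$genes)
  expect_lt(abs(sum(st$gene_states == "high") / n - 0.25), 0.12)
  expect_lt(abs(sum(st$gene_states == "low") / n - 0.25), 0.12)
  expect_error(discretize(c(unknown_gene = 1), m), "namespace")
})

test_that("all-moderate states reduce both integrators to plain weighted FBA", {
  m <- toy_ready()
  plain <- solve_weighted_biobjective(m)
  st <- discretize(flat_profile(m), m)
  im <- integrate_imat_linear(m, st)
  expect_equal(im$acetylation_flux, plain$acetylation_flux, tolerance = 1e-6)
  expect_equal(im$biomass_flux, plain$biomass_flux, tolerance = 1e-6)
  gm <- integrate_gimme(m, flat_profile(m))
  expect_equal(gm$acetylation_flux, plain$acetylation_flux, tolerance = 1e-6)
  expect_equal(gm$biomass_flux, plain$biomass_flux, tolerance = 1e-6)
})

test_that("linear iMAT optimum matches branch-pattern enumeration", {
  skip_if_not_installed("boot")
  m <- overflow_net()
  m$reactions$gene_rule <- c(NA, "g_bio", "g_ace")
  m$genes <- c("g_bio", "g_ace")
  settings <- integration_settings(activation_flux = 0.5)
  combos <- list(c(BIO = "high", ACET = "low"),
                 c(BIO = "low", ACET = "high"),
                 c(BIO = "low", ACET = "low"),
                 c(BIO = "high", ACET = "high"))
  for (combo in combos) {
    st <- structure(list(
      gene_states = c(g_bio = unname(combo[["BIO"]]),
                      g_ace = unname(combo[["ACET"]])),
      rules = stats::setNames(m$reactions$gene_rule, m$reactions$id),
      settings = settings), class = "discretized_states")
    st$reaction_states <- acetylflux:::recompute_reaction_states(st)
    res <- integrate_imat_linear(m, st, settings)
    oracle <- oracle_imat_objective(m, st, settings, epsilon = 1e-4)
    expect_equal(attr(res, "imat_objective"), oracle, tolerance = 1e-6,
                 info = paste(combo, collapse = "/"))
  }
})

test_that("iMAT enumeration agreement holds on random small instances", {
  skip_if_not_installed("boot")
  m <- branch_net()
  m$reactions$gene_rule <- c(NA, "g_ab", "g_ac", "g_bio", "g_sec")
  m$genes <- c("g_ab", "g_ac", "g_bio", "g_sec")
  m$acetylation_reaction_id <- "EX_C"  # secretion branch as the readout
  settings <- integration_settings(activation_flux = 0.25,
                                   penalty_weight = 0.7, reward_weight = 1.3)
  set.seed(9)
  for (i in 1:8) {
    gs <- sample(c("low", "moderate", "high"), 4, replace = TRUE)
    st <- structure(list(
      gene_states = stats::setNames(gs, m$genes),
      rules = stats::setNames(m$reactions$gene_rule, m$reactions$id),
      settings = settings), class = "discretized_states")
    st$reaction_states <- acetylflux:::recompute_reaction_states(st)
    st$reaction_states[["BIO"]] <- "moderate"  # keep objective reaction free
    res <- integrate_imat_linear(m, st, settings)
    oracle <- oracle_imat_objective(m, st, settings, epsilon = 1e-4)
    expect_equal(attr(res, "imat_objective"), oracle, tolerance = 1e-6,
                 info = paste(gs, collapse = "/"))
  }
})

test_that("penalizing a reaction never increases its absolute flux", {
  m <- toy_ready()
  plain <- solve_weighted_biobjective(m)
  set.seed(13)
  with_rules <- m$reactions$id[!is.na(m$reactions$gene_rule)]
  for (rid in sample(with_rules, 6)) {
    st <- discretize(flat_profile(m), m)
    st$reaction_states[[rid]] <- "low"
    res <- integrate_imat_linear(m, st)
    expect_true(abs(res$fluxes[[rid]]) <= abs(plain$fluxes[[rid]]) + 1e-7,
                info = rid)
  }
})

test_that("GIMME routes flux around the lowly expressed of two parallel paths", {
  m <- parallel_net()
  m$genes <- c("g1", "g2", "g3", "g4", "g5")
  # the integrator requires an acetylation outlet; here it carries no flux
  rxn <- simple_rxn("ACET", c(B = -1))
  rxn$is_exchange <- TRUE
  m$reactions <- rbind(m$reactions, rxn[, names(m$reactions)])
  m$acetylation_reaction_id <- "ACET"
  p <- c(g1 = 1, g2 = 100, g3 = 10, g4 = 10, g5 = 10)
  res <- integrate_gimme(m, p)
  expect_lt(abs(res$fluxes[["P1"]]), 1e-5)                # low-expressed path
  expect_equal(res$fluxes[["P2"]], 10, tolerance = 1e-6)  # high-expressed path
})

test_that("a threshold below all expression makes GIMME penalty-free", {
  m <- toy_ready()
  p <- flat_profile(m)
  res <- integrate_gimme(m, p)
  expect_equal(attr(res, "gimme_penalty"), 0, tolerance = 1e-9)
})

test_that("drug signatures overlay, invert and recompute reaction states", {
  m <- toy_ready()
  st <- discretize(flat_profile(m), m)
  sig <- drug_signature("drugX", down_genes = c("ACLY_t", "CS_t"),
                        up_genes = "FASN_t")
  st2 <- apply_drug_signature(st, sig)
  expect_equal(unname(st2$gene_states[["ACLY_t"]]), "low")
  expect_equal(unname(st2$gene_states[["FASN_t"]]), "high")
  expect_equal(unname(st2$reaction_states[["ACLYn"]]), "low")
  expect_equal(unname(st2$reaction_states[["FASN"]]), "high")
  # empty signature changes nothing
  st3 <- apply_drug_signature(st, drug_signature("none"))
  expect_equal(st3$reaction_states, st$reaction_states)
  # inverse overlay restores the touched genes
  inv <- drug_signature("inv", up_genes = c("ACLY_t", "CS_t"))
  st4 <- apply_drug_signature(st2, inv)
  expect_equal(unname(st4$gene_states[["ACLY_t"]]), "high")
  expect_error(drug_signature("bad", up_genes = "g", down_genes = "g"),
               "disjoint")
})

test_that("downregulating ATP-citrate lyase reduces integrated acetylation", {
  m <- toy_ready()
  st <- discretize(flat_profile(m), m)
  basal <- integrate_imat_linear(m, st)
  sig <- drug_signature("kdaci_like", down_genes = c("ACLY_t", "SLC25A1_t"))
  treated <- integrate_imat_linear(m, apply_drug_signature(st, sig))
  expect_lt(treated$acetylation_flux, basal$acetylation_flux)
  d <- acetylation_delta(basal, treated)
  expect_equal(d, basal$acetylation_flux - treated$acetylation_flux)
  expect_gt(d, 0)
  expect_equal(acetylation_delta(basal, basal), 0)
  bad <- basal; bad$status <- "infeasible"
  expect_error(acetylation_delta(basal, bad), "optimal")
})

test_that("per-drug deltas match pairwise recomputation across signatures", {
  m <- toy_ready()
  st <- discretize(flat_profile(m), m)
  basal <- integrate_imat_linear(m, st)
  sigs <- list(
    drug_signature("d1", down_genes = "ACLY_t"),
    drug_signature("d2", down_genes = "MCT1_t"),
    drug_signature("d3", down_genes = c("CS_t", "SLC25A1_t")),
    drug_signature("d4", up_genes = "FASN_t")
  )
  deltas <- vapply(sigs, function(sg) {
    acetylation_delta(basal,
                      integrate_imat_linear(m, apply_drug_signature(st, sg)))
  }, numeric(1))
  for (k in seq_along(sigs)) {
    again <- acetylation_delta(
      basal, integrate_imat_linear(m, apply_drug_signature(st, sigs[[k]])))
    expect_equal(deltas[k], again, tolerance = 1e-9)
  }
  expect_gt(deltas[1], 0)
})

test_that("cohort integration separates planted groups at the flux cutoff", {
  m <- toy_ready()
  co <- make_expression_cohort(cohort_spec(n_samples = 24, seed = 101))
  fl <- integrate_cohort(m, co$expr)
  gr <- bimodal_grouping(stats::setNames(fl$acetylation_flux, fl$sample))
  expect_equal(unname(gr == "high"),
               unname(co$labels[names(gr)] == "high"))
  # bimodal: the two modes straddle the cutoff by a wide margin
  expect_gt(min(fl$acetylation_flux[co$labels[fl$sample] == "high"]), 1)
  expect_lt(max(fl$acetylation_flux[co$labels[fl$sample] == "low"]), 0.001)
})

test_that("iMAT and GIMME agree on the sign of the cohort group difference", {
  m <- toy_ready()
  agree <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    co <- make_expression_cohort(cohort_spec(n_samples = 12, seed = 300 + s))
    im <- integrate_cohort(m, co$expr, method = "imat")
    gm <- integrate_cohort(m, co$expr, method = "gimme")
    lab <- co$labels[im$sample]
    d_im <- mean(im$acetylation_flux[lab == "high"]) -
      mean(im$acetylation_flux[lab == "low"])
    d_gm <- mean(gm$acetylation_flux[lab == "high"]) -
      mean(gm$acetylation_flux[lab == "low"])
    if (sign(d_im) == sign(d_gm)) agree <- agree + 1
  }
  expect_gte(agree / n_seeds, 0.9)
})
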