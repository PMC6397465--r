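test_that("JSON dialect round-trips a model structurally", {
  m <- make_toy_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- load_model(path, quiet = TRUE)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$compartments, m$compartments)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$biomass_reaction_id, m$biomass_reaction_id)
  expect_equal(m2$acetylation_reaction_id, m$acetylation_reaction_id)
  for (i in seq_len(nrow(m$reactions))) {
    s1 <- m$reactions$stoichiometry[[i]]
    s2 <- m2$reactions$stoichiometry[[i]]
    expect_equal(s2[names(s1)], s1)
  }
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
})

test_that("a one-reaction JSON model parses with derived exchange flag", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "mini", "compartments": ["e"],
    "biomass_reaction_id": "EX_A",
    "metabolites": [{"id": "A_e", "compartment": "e"}],
    "reactions": [{"id": "EX_A", "stoichiometry": {"A_e": -1},
                   "reversible": true}]
  }', path)
  m <- load_model(path, quiet = TRUE)
  expect_equal(nrow(m$reactions), 1)
  expect_equal(nrow(m$metabolites), 1)
  expect_length(m$genes, 0)
  expect_true(m$reactions$is_exchange[1])
  # reversible default bounds
  expect_equal(m$reactions$lower_bound, -1000)
  expect_equal(m$reactions$upper_bound, 1000)
})

test_that("model validation catches structural violations", {
  m <- make_toy_network()
  bad <- m
  bad$reactions$stoichiometry[[8]] <- c(nonexistent_met = 1)
  expect_match(paste(validate_model(bad), collapse = " "), "unknown")
  bad2 <- m
  bad2$biomass_reaction_id <- "NOPE"
  expect_match(paste(validate_model(bad2), collapse = " "), "biomass")
  bad3 <- m
  bad3$reactions$lower_bound[1] <- 5
  bad3$reactions$upper_bound[1] <- -5
  expect_match(paste(validate_model(bad3), collapse = " "), "lower_bound")
})

test_that("stoichiometric matrix columns equal reaction stoichiometries", {
  m <- make_toy_network()
  S <- build_stoich_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  for (j in seq_len(ncol(S))) {
    s <- m$reactions$stoichiometry[[j]]
    col <- S[, j]
    expect_equal(unname(col[names(s)]), unname(s))
    expect_equal(sum(col != 0), length(s))
  }
  # reversing a reaction's written direction negates its column
  m2 <- m
  m2$reactions$stoichiometry[[10]] <- -m$reactions$stoichiometry[[10]]
  S2 <- build_stoich_matrix(m2)
  expect_equal(as.numeric(S2[, 10]), -as.numeric(S[, 10]))
})

test_that("steady state holds at solver output", {
  m <- toy_ready()
  S <- build_stoich_matrix(m)
  res <- solve_weighted_biobjective(m)
  expect_lt(max(abs(S %*% res$fluxes[colnames(S)])), 1e-6)
})

test_that("GPR evaluation matches a truth-table oracle on random rules", {
  genes <- c("g1", "g2", "g3", "g4")
  set.seed(7)
  for (i in 1:150) {
    rule <- random_rule(genes)
    parsed <- parse_gene_rule(rule)
    for (k in 0:15) {
      deleted <- genes[bitwAnd(k, 2^(0:3)) > 0]
      expect_equal(evaluate_gene_rule(parsed, deleted),
                   oracle_rule_eval(rule, deleted, genes),
                   info = paste(rule, "| del:", paste(deleted, collapse = ",")))
    }
  }
})

test_that("GPR basics: single gene, mixed rule, no rule", {
  expect_false(evaluate_gene_rule(parse_gene_rule("g1"), "g1"))
  expect_true(evaluate_gene_rule(parse_gene_rule("(g1 and g2) or g3"), "g1"))
  expect_false(evaluate_gene_rule(parse_gene_rule("(g1 and g2) or g3"),
                                  c("g1", "g3")))
  expect_true(evaluate_gene_rule(NULL, "g1"))
  expect_error(parse_gene_rule("g1 and (g2"), "paren")
})

test_that("GPR evaluation is monotone in the deleted set", {
  genes <- paste0("g", 1:4)
  set.seed(11)
  for (i in 1:50) {
    rule <- parse_gene_rule(random_rule(genes))
    deleted <- sample(genes, sample(0:3, 1))
    extra <- union(deleted, sample(genes, 1))
    # adding a deletion can never reactivate a rule
    expect_false(!evaluate_gene_rule(rule, deleted) &&
                   evaluate_gene_rule(rule, extra))
  }
})

test_that("SBML level 2 (notes + kinetic-law bounds) parses", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
 <model id="mini2">
  <listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>
  <listOfSpecies>
   <species id="A_e" compartment="e"/>
   <species id="A_c" compartment="c"/>
   <species id="B_b" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_A" reversible="true">
    <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: </p></body></notes>
    <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B_b" stoichiometry="1"/></listOfProducts>
    <kineticLaw><math/><listOfParameters>
      <parameter id="LOWER_BOUND" value="-10"/>
      <parameter id="UPPER_BOUND" value="999"/>
    </listOfParameters></kineticLaw>
   </reaction>
   <reaction id="T_A" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: (ga1 and ga2) or ga3</p></body></notes>
    <listOfReactants><speciesReference species="A_e"/></listOfReactants>
    <listOfProducts><speciesReference species="A_c"/></listOfProducts>
   </reaction>
   <reaction id="BIOMASS_mini" reversible="false">
    <listOfReactants><speciesReference species="A_c"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- load_model(path, quiet = TRUE)
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 2)   # boundary species dropped
  expect_equal(m$biomass_reaction_id, "BIOMASS_mini")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -10)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_A"], 999)
  expect_true(m$reactions$is_exchange[m$reactions$id == "EX_A"])
  expect_equal(m$reactions$gene_rule[m$reactions$id == "T_A"],
               "(ga1 and ga2) or ga3")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "T_A"], 0)
  expect_setequal(m$genes, c("ga1", "ga2", "ga3"))
})

test_that("SBML level 3 with fbc gene associations and bounds parses", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="mini3" fbc:strict="true">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="M_a" compartment="c" constant="false"/>
   <species id="M_b" compartment="c" constant="false"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lb_m10" value="-10" constant="true"/>
   <parameter id="ub_50" value="50" constant="true"/>
   <parameter id="zero" value="0" constant="true"/>
  </listOfParameters>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="gp1" fbc:label="GENE1"/>
   <fbc:geneProduct fbc:id="gp2" fbc:label="GENE2"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="EX_a" reversible="true" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_50" fast="false">
    <listOfReactants><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
   <reaction id="CONV" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_50" fast="false">
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:geneProductRef fbc:geneProduct="gp1"/>
      <fbc:geneProductRef fbc:geneProduct="gp2"/>
     </fbc:or>
    </fbc:geneProductAssociation>
    <listOfReactants><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="GROWTH" reversible="false" fast="false">
    <listOfReactants><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- load_model(path, quiet = TRUE)
  expect_equal(m$biomass_reaction_id, "GROWTH")  # from the fbc objective
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_a"], -10)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_a"], 50)
  expect_equal(m$reactions$gene_rule[m$reactions$id == "CONV"],
               "GENE1 or GENE2")
  # and the parsed model supports FBA
  res <- solve_fba(m)
  expect_equal(res$biomass_flux, 10, tolerance = 1e-8)
})
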