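#' Read an SBML metabolic model
#'
#' Handles the two dialects genome-scale reconstructions circulate in:
#' SBML Level 2 with COBRA conventions (flux bounds as `LOWER_BOUND` /
#' `UPPER_BOUND` kinetic-law parameters, GPR rules in a `GENE_ASSOCIATION`
#' notes line) and SBML Level 3 with the `fbc` extension (bounds as global
#' parameters referenced by `fbc:lowerFluxBound` / `fbc:upperFluxBound`,
#' rules as `fbc:geneProductAssociation` trees). Species flagged
#' `boundaryCondition="true"` are dropped from stoichiometry, which makes the
#' reactions that touched them boundary/exchange reactions.
#'
#' When a file omits bounds, defaults follow the COBRA convention:
#' (-1000, 1000) for reversible reactions, (0, 1000) otherwise.
#'
#' @param path SBML file path.
#' @param biomass_reaction_id biomass reaction id; when NULL the reader uses
#'   the fbc objective if declared, else the first reaction whose id or name
#'   contains "biomass" (case-insensitive).
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, biomass_reaction_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  sbml_attr <- function(node, ...) {
    for (a in c(...)) {
      v <- xml2::xml_attr(node, a)
      if (!is.na(v)) return(v)
    }
    NA_character_
  }

  comp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  # global parameters (L3/FBC bound values)
  par_nodes <- xml2::xml_find_all(doc,
    ".//*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  # fbc gene products: internal id -> label
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lab <- sbml_attr(n, "label", "fbc:label", "name", "id")
      lab
    }, character(1)),
    xml2::xml_attr(gp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  boundary <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = vapply(sp_nodes, function(n) {
      sbml_attr(n, "chemicalFormula", "fbc:chemicalFormula")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  boundary_ids <- mets$id[boundary]
  mets <- mets[!boundary, , drop = FALSE]

  rxn_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxn_nodes) == 0) stop("SBML file has no reactions: ", path)

  parse_side <- function(rn, which, sign) {
    refs <- xml2::xml_find_all(rn, paste0("./*[local-name()='", which,
                                   "']/*[local-name()='speciesReference']"))
    if (length(refs) == 0) return(numeric(0))
    sp <- xml2::xml_attr(refs, "species")
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    stats::setNames(sign * st, sp)
  }

  parse_fbc_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- sbml_attr(node, "geneProduct", "fbc:geneProduct")
      lab <- gp_label[[ref]]
      return(if (is.null(lab) || is.na(lab)) ref else lab)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      sub <- parse_fbc_assoc(k)
      if (grepl("\\s", sub)) paste0("(", sub, ")") else sub
    }, character(1))
    paste(parts, collapse = if (nm == "and") " and " else " or ")
  }

  rows <- lapply(rxn_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- !identical(tolower(xml2::xml_attr(rn, "reversible")), "false")
    s <- c(parse_side(rn, "listOfReactants", -1),
           parse_side(rn, "listOfProducts", +1))
    if (length(s) == 0) stop("SBML reaction '", rid, "' has no participants")
    s <- s[!(names(s) %in% boundary_ids)]
    if (length(s) == 0) {
      stop("SBML reaction '", rid, "' touches only boundary species")
    }
    # collapse duplicated species refs
    s <- tapply(unname(s), names(s), sum)
    s <- stats::setNames(as.numeric(s), names(s))

    lbd <- ubd <- NA_real_
    # L3/FBC: parameter references
    lb_ref <- sbml_attr(rn, "lowerFluxBound", "fbc:lowerFluxBound")
    ub_ref <- sbml_attr(rn, "upperFluxBound", "fbc:upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) lbd <- par_vals[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) ubd <- par_vals[[ub_ref]]
    # L2/COBRA: kineticLaw parameters
    kl <- xml2::xml_find_all(rn, "./*[local-name()='kineticLaw']//*[local-name()='parameter']")
    if (length(kl) > 0) {
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lbd) && "LOWER_BOUND" %in% kid) lbd <- kval[kid == "LOWER_BOUND"][1]
      if (is.na(ubd) && "UPPER_BOUND" %in% kid) ubd <- kval[kid == "UPPER_BOUND"][1]
    }
    if (is.na(lbd)) lbd <- if (rev) -1000 else 0
    if (is.na(ubd)) ubd <- 1000

    rule <- NA_character_
    assoc <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids) > 0) rule <- parse_fbc_assoc(kids[[1]])
    }
    if (is.na(rule)) {
      notes <- xml2::xml_find_all(rn, "./*[local-name()='notes']//*[local-name()='p']")
      txt <- xml2::xml_text(notes)
      ga <- txt[grepl("GENE.?ASSOCIATION", txt)]
      if (length(ga) > 0) {
        rule <- trimws(sub(".*GENE.?ASSOCIATION:\\s*", "", ga[1]))
        if (!nzchar(rule)) rule <- NA_character_
      }
    }

    df <- data.frame(id = rid, lower_bound = lbd, upper_bound = ubd,
                     gene_rule = rule, subsystem = NA_character_,
                     stringsAsFactors = FALSE)
    df$stoichiometry <- list(s)
    df
  })
  rxns <- do.call(rbind, rows)

  bio <- biomass_reaction_id
  if (is.null(bio)) {
    obj_ref <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(obj_ref, "xml_missing")) {
      bio <- sbml_attr(obj_ref, "reaction", "fbc:reaction")
    }
  }
  if (is.null(bio) || is.na(bio)) {
    hit <- grep("biomass", rxns$id, ignore.case = TRUE)
    if (length(hit) == 0) {
      nm <- xml2::xml_attr(rxn_nodes, "name")
      hit <- grep("biomass", nm, ignore.case = TRUE)
    }
    if (length(hit) == 0) {
      stop("no biomass reaction designated and none found by name; ",
           "pass biomass_reaction_id")
    }
    bio <- rxns$id[hit[1]]
  }

  metabolic_model(
    metabolites = mets,
    reactions = rxns[, c("id", "stoichiometry", "lower_bound", "upper_bound",
                         "gene_rule", "subsystem")],
    compartments = compartments,
    biomass_reaction_id = bio,
    id = sub("\\.(xml|sbml)$", "", basename(path), ignore.case = TRUE)
  )
}
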