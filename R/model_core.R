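#' Construct a metabolic network model
#'
#' The central container of the package: a stoichiometric reconstruction with
#' metabolites (each assigned to a compartment such as cytosol `c`,
#' mitochondrion `m`, nucleus `n`, extracellular `e`), reactions with flux
#' bounds (mmol/gDW/h) and optional GPR rules, a designated biomass reaction
#' and, after augmentation, a designated nuclear protein-acetylation reaction.
#'
#' Exchange reactions are written in the secretion direction
#' (`1 met_e ->`): positive flux exports the metabolite, uptake happens at
#' negative flux enabled by a negative lower bound.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (formula may be NA).
#' @param reactions data.frame with columns `id`, `stoichiometry` (list column
#'   of named numeric vectors, metabolite id -> signed coefficient),
#'   `lower_bound`, `upper_bound`, `gene_rule` (string or NA), `subsystem`
#'   (string or NA).
#' @param compartments character vector of declared compartment ids.
#' @param biomass_reaction_id id of the biomass reaction.
#' @param acetylation_reaction_id id of the acetylation reaction, or NULL
#'   before augmentation.
#' @param id optional model name.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, compartments,
                            biomass_reaction_id,
                            acetylation_reaction_id = NULL,
                            id = "model") {
  metabolites$formula <- if ("formula" %in% names(metabolites)) {
    as.character(metabolites$formula)
  } else NA_character_
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  for (col in c("gene_rule", "subsystem")) {
    if (!col %in% names(reactions)) reactions[[col]] <- NA_character_
  }
  reactions$is_exchange <- vapply(
    reactions$stoichiometry, function(s) length(s) == 1L, logical(1)
  )
  genes <- sort(unique(unlist(lapply(reactions$gene_rule, function(g) {
    if (is.na(g)) character() else rule_genes(g)
  }))))
  m <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    genes = genes,
    compartments = compartments,
    biomass_reaction_id = biomass_reaction_id,
    acetylation_reaction_id = acetylation_reaction_id
  ), class = "metabolic_model")
  viol <- validate_model(m)
  if (length(viol) > 0) {
    stop("invalid model: ", paste(viol, collapse = "; "))
  }
  m
}

#' Validate model invariants
#'
#' Checks id uniqueness, compartment declarations, bound ordering, that every
#' stoichiometry entry names a known metabolite, that exchange reactions touch
#' exactly one metabolite, and that the biomass reaction exists.
#'
#' @param model a `metabolic_model`.
#' @return character vector of violations (empty when valid).
#' @export
validate_model <- function(model) {
  v <- character()
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids)) v <- c(v, "duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) v <- c(v, "duplicate reaction ids")
  bad_comp <- setdiff(unique(model$metabolites$compartment), model$compartments)
  if (length(bad_comp) > 0) {
    v <- c(v, paste0("undeclared compartments: ", paste(bad_comp, collapse = ",")))
  }
  if (any(model$reactions$lower_bound > model$reactions$upper_bound)) {
    v <- c(v, "lower_bound > upper_bound for some reaction")
  }
  unknown <- setdiff(unique(unlist(lapply(model$reactions$stoichiometry, names))),
                     met_ids)
  if (length(unknown) > 0) {
    v <- c(v, paste0("stoichiometry references unknown metabolites: ",
                     paste(unknown, collapse = ",")))
  }
  if (!model$biomass_reaction_id %in% rxn_ids) {
    v <- c(v, paste0("biomass reaction '", model$biomass_reaction_id,
                     "' not in model"))
  }
  if (!is.null(model$acetylation_reaction_id) &&
      !model$acetylation_reaction_id %in% rxn_ids) {
    v <- c(v, "acetylation reaction id not in model")
  }
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (isTRUE(r$is_exchange) && length(r$stoichiometry[[1]]) != 1L) {
      v <- c(v, paste0("exchange reaction ", r$id, " touches != 1 metabolite"))
    }
    g <- r$gene_rule
    if (!is.na(g)) {
      ok <- tryCatch({ parse_gene_rule(g); TRUE },
                     error = function(e) FALSE)
      if (!ok) v <- c(v, paste0("malformed gene rule on ", r$id))
    }
  }
  v
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  reactions:   ", nrow(x$reactions), "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  genes:       ", length(x$genes),
      " (in >=1 rule: ", length(genes_in_rules(x)), ")\n",
      "  biomass:     ", x$biomass_reaction_id, "\n",
      "  acetylation: ",
      if (is.null(x$acetylation_reaction_id)) "<not augmented>"
      else x$acetylation_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Genes appearing in at least one reaction rule
#'
#' Reported separately from the full parsed gene list because reconstruction
#' distributions often register more gene ids than their rules actually use.
#'
#' @param model a `metabolic_model`.
#' @return character vector of gene ids.
#' @export
genes_in_rules <- function(model) {
  sort(unique(unlist(lapply(model$reactions$gene_rule, function(g) {
    if (is.na(g)) character() else rule_genes(g)
  }))))
}

reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("no reaction '", id, "' in model")
  i
}

#' Assemble the stoichiometric matrix S
#'
#' Rows are metabolites, columns reactions; `S v = 0` enforces steady state
#' (mass balance for every species). Returned as a sparse `dgCMatrix` with
#' dimnames giving the row/column index maps.
#'
#' @param model a `metabolic_model`.
#' @return sparse Matrix (metabolites x reactions).
#' @export
build_stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    s <- model$reactions$stoichiometry[[j]]
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Read a model from disk
#'
#' Supports the package's JSON dialect (see [write_model_json()]) and SBML
#' Level 2 (COBRA-style notes and kinetic-law bounds) or Level 3 with the
#' `fbc` extension.
#'
#' @param path file path.
#' @param format "json" or "sbml"; default guessed from the extension.
#' @param biomass_reaction_id override for the biomass reaction id when the
#'   file does not designate one.
#' @param quiet suppress the parsed-counts message.
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("guess", "json", "sbml"),
                       biomass_reaction_id = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  model <- switch(format,
    json = read_model_json(path, biomass_reaction_id = biomass_reaction_id),
    sbml = read_sbml(path, biomass_reaction_id = biomass_reaction_id)
  )
  if (!quiet) {
    message(sprintf(
      "loaded '%s': %d reactions, %d metabolites, %d genes (%d in rules)",
      basename(path), nrow(model$reactions), nrow(model$metabolites),
      length(model$genes), length(genes_in_rules(model))))
  }
  model
}

#' Read the JSON model dialect
#'
#' Minimal schema: top-level `id`, `compartments`, `biomass_reaction_id`,
#' optional `acetylation_reaction_id`, `metabolites` (array of
#' `{id, name, compartment, formula}`) and `reactions` (array of
#' `{id, stoichiometry: {met: coef}, lower_bound, upper_bound, gene_rule,
#' subsystem}`). Omitted bounds default to the COBRA convention:
#' (-1000, 1000) when `reversible` is true, (0, 1000) otherwise.
#'
#' @param path file path.
#' @param biomass_reaction_id optional override.
#' @return a `metabolic_model`.
#' @export
read_model_json <- function(path, biomass_reaction_id = NULL) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path,
                                           ": ", conditionMessage(e)))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$stoichiometry) || length(r$stoichiometry) == 0) {
      stop("reaction '", r$id, "' has no stoichiometry")
    }
    s <- unlist(r$stoichiometry)
    rev <- isTRUE(r$reversible)
    lbd <- if (!is.null(r$lower_bound)) r$lower_bound else if (rev) -1000 else 0
    ubd <- if (!is.null(r$upper_bound)) r$upper_bound else 1000
    df <- data.frame(id = r$id, lower_bound = lbd, upper_bound = ubd,
                     gene_rule = if (is.null(r$gene_rule)) NA_character_ else r$gene_rule,
                     subsystem = if (is.null(r$subsystem)) NA_character_ else r$subsystem,
                     stringsAsFactors = FALSE)
    df$stoichiometry <- list(s)
    df
  }))
  bio <- if (!is.null(biomass_reaction_id)) biomass_reaction_id else doc$biomass_reaction_id
  if (is.null(bio)) stop("model file declares no biomass_reaction_id")
  metabolic_model(
    metabolites = mets,
    reactions = rxns[, c("id", "stoichiometry", "lower_bound", "upper_bound",
                         "gene_rule", "subsystem")],
    compartments = unlist(doc$compartments),
    biomass_reaction_id = bio,
    acetylation_reaction_id = doc$acetylation_reaction_id,
    id = if (is.null(doc$id)) "model" else doc$id
  )
}

#' Write a model in the JSON dialect
#'
#' Round-trips with [read_model_json()]: `read(write(m))` is structurally
#' equal to `m`.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    compartments = model$compartments,
    biomass_reaction_id = model$biomass_reaction_id,
    acetylation_reaction_id = model$acetylation_reaction_id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      out <- list(id = r$id,
                  stoichiometry = as.list(r$stoichiometry[[1]]),
                  lower_bound = r$lower_bound,
                  upper_bound = r$upper_bound)
      if (!is.na(r$gene_rule)) out$gene_rule <- r$gene_rule
      if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
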