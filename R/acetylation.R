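#' Augment a model with nuclear protein-acetylation machinery
#'
#' Adds the reactions that make bulk protein/histone acetylation a readable
#' flux: a nuclear protein acetylation reaction
#' (`protein[n] + acetyl-CoA[n] -> acetyl-protein[n] + CoA[n]`, irreversible),
#' a nuclear ATP-citrate-lyase copy that mirrors the cytosolic ACLY
#' stoichiometry with nuclear species, reversible nucleus<->cytosol transport
#' for citrate and oxaloacetate, an unlimited source for the nuclear protein
#' substrate and a sink for acetyl-protein. The protein substrate is supplied
#' without limit so that acetylation flux is a pure readout of nuclear
#' acetyl-CoA supply.
#'
#' Augmenting an already-augmented model is an explicit error (double
#' augmentation would double-count acetylation capacity).
#'
#' @param model a `metabolic_model` without an acetylation reaction.
#' @param acly_id id of the cytosolic ATP-citrate-lyase reaction whose
#'   stoichiometry the nuclear copy mirrors.
#' @param species_map named character vector mapping cytosolic species ids to
#'   their nuclear counterparts; nuclear species are created as needed.
#'   Species of `acly_id` not in the map are kept as-is (drawn across the
#'   nuclear pore). Defaults fit the bundled toy network.
#' @param transport_species cytosolic species ids (keys of `species_map`)
#'   that get a reversible nucleus<->cytosol transport reaction; by default
#'   citrate and oxaloacetate.
#' @param nucleus id of the nuclear compartment (created if absent).
#' @return the augmented `metabolic_model` with `acetylation_reaction_id` set.
#' @export
augment_with_acetylation <- function(model,
                                     acly_id = "ACLYc",
                                     species_map = c(cit_c = "cit_n",
                                                     oaa_c = "oaa_n",
                                                     accoa_c = "accoa_n",
                                                     coa_c = "coa_n"),
                                     transport_species = c("cit_c", "oaa_c"),
                                     nucleus = "n") {
  if (!is.null(model$acetylation_reaction_id)) {
    stop("model is already augmented (acetylation reaction '",
         model$acetylation_reaction_id, "' present); refusing to augment twice")
  }
  ai <- reaction_index(model, acly_id)
  if (!nucleus %in% model$compartments) {
    model$compartments <- c(model$compartments, nucleus)
  }

  met_ids <- model$metabolites$id
  add_met <- function(id, name, formula = NA_character_) {
    if (id %in% met_ids) return(invisible())
    model$metabolites <<- rbind(
      model$metabolites,
      data.frame(id = id, name = name, compartment = nucleus,
                 formula = formula, stringsAsFactors = FALSE))
    met_ids <<- c(met_ids, id)
    invisible()
  }

  acly_stoich <- model$reactions$stoichiometry[[ai]]
  # nuclear copies of the mapped species, with formulas carried over
  for (k in seq_along(species_map)) {
    src <- names(species_map)[k]
    dst <- species_map[[k]]
    src_row <- match(src, model$metabolites$id)
    add_met(dst,
            name = if (!is.na(src_row)) {
              paste0(model$metabolites$name[src_row], " (nuclear)")
            } else dst,
            formula = if (!is.na(src_row)) model$metabolites$formula[src_row]
                      else NA_character_)
  }
  add_met("protein_n", "nuclear protein substrate", formula = "R")
  add_met("aprotein_n", "acetylated nuclear protein", formula = "RC2")
  if (!"accoa_n" %in% species_map) add_met("accoa_n", "acetyl-CoA (nuclear)", "C2")
  if (!"coa_n" %in% species_map) add_met("coa_n", "coenzyme A (nuclear)", "C0")

  nuc_stoich <- acly_stoich
  hit <- names(nuc_stoich) %in% names(species_map)
  names(nuc_stoich)[hit] <- species_map[names(nuc_stoich)[hit]]

  new_ids <- c(paste0(toupper(sub("_[a-z]+$", "", transport_species)), "tn"),
               "ACLYn", "ACETYLn", "SK_protein_n", "DM_aprotein_n")
  clash <- intersect(new_ids, model$reactions$id)
  if (length(clash) > 0) {
    stop("augmentation reaction ids already present: ",
         paste(clash, collapse = ","))
  }
  add_rxn <- function(id, stoich, lb, ub, gene_rule = NA_character_,
                      subsystem = "acetylation machinery") {
    df <- data.frame(id = id, lower_bound = lb, upper_bound = ub,
                     gene_rule = gene_rule, subsystem = subsystem,
                     is_exchange = length(stoich) == 1L,
                     stringsAsFactors = FALSE)
    df$stoichiometry <- list(stoich)
    model$reactions <<- rbind(model$reactions,
                              df[, names(model$reactions), drop = FALSE])
    invisible()
  }
  accoa_n <- if ("accoa_c" %in% names(species_map)) species_map[["accoa_c"]] else "accoa_n"
  coa_n <- if ("coa_c" %in% names(species_map)) species_map[["coa_c"]] else "coa_n"
  bad_t <- setdiff(transport_species, names(species_map))
  if (length(bad_t) > 0) {
    stop("transport_species must be keys of species_map: ",
         paste(bad_t, collapse = ","))
  }
  transport_ids <- character(0)
  for (src in transport_species) {
    tid <- paste0(toupper(sub("_[a-z]+$", "", src)), "tn")
    transport_ids <- c(transport_ids, tid)
    add_rxn(tid, stats::setNames(c(-1, 1), c(src, species_map[[src]])),
            -1000, 1000)
  }
  add_rxn("ACLYn", nuc_stoich, 0, 1000,
          gene_rule = model$reactions$gene_rule[ai])
  add_rxn("ACETYLn",
          stats::setNames(c(-1, -1, 1, 1),
                          c("protein_n", accoa_n, "aprotein_n", coa_n)),
          0, 1000)
  add_rxn("SK_protein_n", c(protein_n = 1), -1000, 1000)
  add_rxn("DM_aprotein_n", c(aprotein_n = -1), 0, 1000)

  model$acetylation_reaction_id <- "ACETYLn"
  model$genes <- sort(unique(c(model$genes, genes_in_rules(model))))
  viol <- validate_model(model)
  if (length(viol) > 0) stop("augmentation broke the model: ",
                             paste(viol, collapse = "; "))
  bal <- check_reaction_balance(model, "ACETYLn")
  if (!isTRUE(bal)) {
    warning("acetylation reaction not elementally balanced: ", bal)
  }
  model
}

#' Check elemental balance of a reaction from metabolite formulas
#'
#' Parses formula strings (e.g. `"C6H12O6"`, pseudo-elements like `"R"` for
#' a balanced protein carrier are allowed) and sums element counts weighted
#' by stoichiometry. Metabolites without a formula make the check
#' indeterminate (returns NA).
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to check.
#' @param tol imbalance tolerance.
#' @return TRUE if balanced, NA if indeterminate, else a string describing
#'   the imbalance.
#' @export
check_reaction_balance <- function(model, reaction_id, tol = 1e-9) {
  i <- reaction_index(model, reaction_id)
  s <- model$reactions$stoichiometry[[i]]
  total <- list()
  for (k in seq_along(s)) {
    mi <- match(names(s)[k], model$metabolites$id)
    f <- model$metabolites$formula[mi]
    if (is.na(f)) return(NA)
    counts <- parse_formula(f)
    for (el in names(counts)) {
      total[[el]] <- (if (is.null(total[[el]])) 0 else total[[el]]) +
        s[[k]] * counts[[el]]
    }
  }
  bad <- names(total)[vapply(total, function(x) abs(x) > tol, logical(1))]
  if (length(bad) == 0) TRUE else {
    paste(vapply(bad, function(el) paste0(el, ": ", total[[el]]), character(1)),
          collapse = ", ")
  }
}

parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(list())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  out <- list()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    ct <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(ct)) as.numeric(ct) else 1
    out[[el]] <- (if (is.null(out[[el]])) 0 else out[[el]]) + n
  }
  out
}

#' Acetyl-CoA synthesis rate per cell
#'
#' Converts a volumetric cytosolic acetyl-CoA synthesis flux (nmol per hour
#' per microliter of packed cells) into molecules per hour per cell:
#' `flux * 1e-9 * N_Avogadro / cells_per_ul`. With the measured cytosolic
#' flux of 2 nmol/h/ul and ~1e6 cells per ul (about 1 pL per cell) this is
#' ~1.2e9, i.e. 1e9 molecules/h/cell to one significant figure.
#'
#' @param flux_nmol_per_h_per_ul cytosolic acetyl-CoA synthesis flux.
#' @param cells_per_ul cell density per microliter (default 1e6).
#' @return molecules of acetyl-CoA per hour per cell.
#' @export
molecules_per_hour_per_cell <- function(flux_nmol_per_h_per_ul,
                                        cells_per_ul = 1e6) {
  if (!is.numeric(flux_nmol_per_h_per_ul) || flux_nmol_per_h_per_ul <= 0) {
    stop("flux must be > 0")
  }
  if (!is.numeric(cells_per_ul) || cells_per_ul <= 0) {
    stop("cells_per_ul must be > 0")
  }
  avogadro <- 6.02214076e23
  flux_nmol_per_h_per_ul * 1e-9 * avogadro / cells_per_ul
}

#' Fraction of acetyl-CoA flux needed to saturate acetylation sites
#'
#' Given a total number of acetylation sites per cell, the per-cell
#' acetyl-CoA synthesis rate, and a time window, returns the fraction of that
#' synthesis flux which must be diverted to acetylate every site within the
#' window: `total_sites / (rate * window)`. With 1e9 sites, a rate of 1e9
#' molecules/h/cell and a 24 h window, this is 1/24 (~4.2%), i.e. under 5% of
#' cytosolic acetyl-CoA production.
#'
#' @param total_sites acetylation sites per cell (0 allowed).
#' @param molecules_per_h_per_cell acetyl-CoA synthesis rate per cell.
#' @param window_h time window in hours (default 24).
#' @return unitless fraction.
#' @export
required_flux_fraction <- function(total_sites, molecules_per_h_per_cell,
                                   window_h = 24) {
  if (!is.numeric(total_sites) || total_sites < 0) {
    stop("total_sites must be >= 0")
  }
  if (!is.numeric(molecules_per_h_per_cell) || molecules_per_h_per_cell <= 0) {
    stop("molecules_per_h_per_cell must be > 0")
  }
  if (!is.numeric(window_h) || window_h <= 0) stop("window_h must be > 0")
  total_sites / (molecules_per_h_per_cell * window_h)
}
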