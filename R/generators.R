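#' Specify a synthetic expression cohort
#'
#' The cohort emulates a panel of cell lines with a planted dichotomy in
#' acetyl-CoA-synthesis capacity: a "high" fraction of samples has the
#' [acetyl_coa_synthesis_genes()] shifted up by half the effect size (log2
#' units) and the remaining "low" samples shifted down by the other half;
#' all other genes sit at a common baseline. Gaussian noise on the log2
#' scale makes expression lognormal on the linear scale.
#'
#' @param n_samples number of cell lines (default 60).
#' @param fraction_high fraction in the high group, in (0,1); default 0.25,
#'   making the high-capacity state the minority mode of a bimodal cohort
#'   whose planted-low expression mass just exceeds the low-quantile
#'   threshold used in discretization.
#' @param effect total log2 separation planted on acetyl-CoA-synthesis
#'   genes (default 4, i.e. 16-fold: an on/off capacity dichotomy).
#' @param sigma log2-scale noise SD (default 0.5).
#' @param baseline baseline log2 expression (default 5).
#' @param seed RNG seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 60, fraction_high = 0.25, effect = 4,
                        sigma = 0.5, baseline = 5, seed = 1) {
  stopifnot(n_samples >= 2, fraction_high > 0, fraction_high < 1, sigma > 0)
  structure(list(n_samples = n_samples, fraction_high = fraction_high,
                 effect = effect, sigma = sigma, baseline = baseline,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic expression cohort with known group labels
#'
#' Pure function of its spec: the same spec (including seed) always yields
#' the same matrix.
#'
#' @param spec a [cohort_spec()].
#' @param genes gene universe (default: the toy network's genes).
#' @param signal_genes genes carrying the planted dichotomy (default
#'   [acetyl_coa_synthesis_genes()]).
#' @return list with `expr` (genes x samples log2 matrix, `scale` attribute
#'   "log2") and `labels` (named "high"/"low" ground truth).
#' @export
make_expression_cohort <- function(spec = cohort_spec(),
                                   genes = make_toy_network()$genes,
                                   signal_genes = acetyl_coa_synthesis_genes()) {
  n_high <- round(spec$n_samples * spec$fraction_high)
  labels <- rep(c("high", "low"),
                c(n_high, spec$n_samples - n_high))
  samples <- sprintf("line%02d", seq_len(spec$n_samples))
  names(labels) <- samples
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  expr <- withr_seed({
    m <- matrix(stats::rnorm(length(genes) * spec$n_samples,
                             mean = spec$baseline, sd = spec$sigma),
                nrow = length(genes), dimnames = list(genes, samples))
    shift <- ifelse(labels == "high", spec$effect / 2, -spec$effect / 2)
    sig <- intersect(signal_genes, genes)
    m[sig, ] <- m[sig, ] + matrix(shift, length(sig), spec$n_samples,
                                  byrow = TRUE)
    m
  })
  attr(expr, "scale") <- "log2"
  list(expr = expr, labels = labels)
}

#' Specify a synthetic drug-response table
#'
#' AUC (area under the growth curve; lower = stronger growth inhibition)
#' decreases linearly with predicted acetylation flux:
#' `AUC = intercept - slope * flux - signature_strength * delta + noise`.
#' The delta term models the extra sensitivity of a cell line to the drug
#' whose transcriptomic signature reduces its acetylation flux most.
#'
#' @param drugs compound names (default the four clinically used KDAC
#'   inhibitors).
#' @param intercept AUC of a zero-flux line (default 12).
#' @param slope AUC units lost per flux unit, > 0 (default 0.26, which
#'   spaces the two flux modes of the toy cohort by about 2.6 AUC units).
#' @param sigma Gaussian AUC noise SD (default 1.5).
#' @param signature_strength AUC units lost per unit of drug-specific flux
#'   delta (default 1).
#' @param seed RNG seed.
#' @return a `response_spec`.
#' @export
response_spec <- function(drugs = c("vorinostat", "panobinostat",
                                    "belinostat", "entinostat"),
                          intercept = 12, slope = 0.26, sigma = 1.5,
                          signature_strength = 1, seed = 1) {
  stopifnot(slope > 0, sigma >= 0, length(drugs) >= 1)
  structure(list(drugs = drugs, intercept = intercept, slope = slope,
                 sigma = sigma, signature_strength = signature_strength,
                 seed = seed),
            class = "response_spec")
}

#' Generate a synthetic drug-response (AUC) table
#'
#' @param fluxes named numeric vector, cell line -> predicted acetylation
#'   flux.
#' @param spec a [response_spec()].
#' @param delta_flux optional matrix (cell lines x drugs) of drug-specific
#'   acetylation-flux reductions entering through `signature_strength`.
#' @return list with `auc` (cell lines x drugs matrix) and the ground-truth
#'   `expected` (noise-free) matrix.
#' @export
make_drug_response <- function(fluxes, spec = response_spec(),
                               delta_flux = NULL) {
  stopifnot(all(is.finite(fluxes)))
  lines <- names(fluxes)
  expected <- matrix(spec$intercept - spec$slope * fluxes,
                     nrow = length(fluxes), ncol = length(spec$drugs),
                     dimnames = list(lines, spec$drugs))
  if (!is.null(delta_flux)) {
    delta_flux <- as.matrix(delta_flux)[lines, spec$drugs, drop = FALSE]
    expected <- expected - spec$signature_strength * delta_flux
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  noise <- matrix(stats::rnorm(length(expected), sd = spec$sigma),
                  nrow = nrow(expected))
  list(auc = expected + noise, expected = expected)
}
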