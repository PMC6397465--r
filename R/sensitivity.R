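#' Split cell lines into low / high acetylation-flux groups
#'
#' The predicted acetylation flux across cell lines is bimodal; lines below
#' the cutoff (default 0.05 mmol/gDW/h) form the low group, the rest the
#' high group (a flux exactly at the cutoff is high, matching the strict
#' `flux < 0.05` definition of the low group).
#'
#' @param fluxes named numeric vector, cell line -> acetylation flux.
#' @param cutoff flux cutoff (default 0.05).
#' @return named character vector ("low"/"high") with attribute `sizes`.
#' @export
bimodal_grouping <- function(fluxes, cutoff = 0.05) {
  groups <- ifelse(fluxes < cutoff, "low", "high")
  names(groups) <- names(fluxes)
  sizes <- c(low = sum(groups == "low"), high = sum(groups == "high"))
  if (any(sizes == 0)) {
    warning("all cell lines fall in one group (", names(sizes)[sizes > 0],
            "); downstream group tests are impossible")
  }
  attr(groups, "sizes") <- sizes
  groups
}

stat_result <- function(statistic, p_value, n, direction, method) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 direction = direction, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$method, "\n",
      "  statistic: ", format(x$statistic), "\n",
      "  p value:   ", format(x$p_value), "\n",
      "  n:         ", paste(x$n, collapse = " / "), "\n",
      "  direction: ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Welch t-test between flux groups
#'
#' Compares a per-cell-line quantity (typically drug-response AUC) between
#' the high- and low-flux groups. Direction is the sign of
#' `mean(high) - mean(low)`; a negative direction on AUC means the high-flux
#' group is more sensitive (more growth inhibition).
#'
#' @param groups output of [bimodal_grouping()] (or any named
#'   "low"/"high" vector).
#' @param values named numeric vector over the same cell lines.
#' @return a `stat_result`.
#' @export
compare_groups <- function(groups, values) {
  common <- intersect(names(groups), names(values))
  common <- common[!is.na(values[common])]
  hi <- values[common[groups[common] == "high"]]
  lo <- values[common[groups[common] == "low"]]
  if (length(hi) < 2 || length(lo) < 2) {
    stop("each group needs >= 2 values (high: ", length(hi),
         ", low: ", length(lo), ")")
  }
  tt <- stats::t.test(hi, lo, var.equal = FALSE)
  stat_result(unname(tt$statistic), tt$p.value,
              c(high = length(hi), low = length(lo)),
              direction = sign(mean(hi) - mean(lo)),
              method = "Welch two-sample t-test (high vs low)")
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `stat_result` with the correlation as statistic.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result(unname(ct$estimate), ct$p.value, length(x),
              direction = sign(unname(ct$estimate)),
              method = "Pearson correlation")
}

#' Median-normalize per-cell-line drug sensitivity scores
#'
#' For each cell line, subtracts the median AUC across its drugs:
#' a score of 0 means a drug is as effective as is typical for that line,
#' negative means more sensitive than typical. Lines with fewer than two
#' drug values are excluded with a warning.
#'
#' @param auc numeric matrix, cell lines x drugs.
#' @return matrix of normalized scores (excluded lines dropped).
#' @export
median_normalize_scores <- function(auc) {
  auc <- as.matrix(auc)
  n_ok <- rowSums(!is.na(auc))
  if (any(n_ok < 2)) {
    warning(sum(n_ok < 2), " cell line(s) with < 2 drug values excluded")
    auc <- auc[n_ok >= 2, , drop = FALSE]
  }
  med <- apply(auc, 1, stats::median, na.rm = TRUE)
  sweep(auc, 1, med)
}

#' Group cell line-drug pairs by differential acetylation-flux change
#'
#' A pair (line, drug) lands in the "large-difference" class when the drug's
#' flux delta for that line deviates from the line's median delta across
#' drugs by more than `threshold`; otherwise in the "no-difference" class.
#' The two classes' median-normalized sensitivity scores are then compared
#' with a Welch t-test over all pooled pairs.
#'
#' @param deltas numeric matrix, cell lines x drugs, of acetylation-flux
#'   reductions ([acetylation_delta()] values).
#' @param scores matrix from [median_normalize_scores()] (same dimnames).
#' @param threshold absolute deviation from the per-line median delta that
#'   defines a large difference. A practical default is 10% of the cohort's
#'   median nonzero acetylation flux.
#' @return list with `classes` (character matrix), the pooled `test`
#'   (`stat_result`), and per-class score means.
#' @export
group_by_delta_difference <- function(deltas, scores, threshold) {
  deltas <- as.matrix(deltas)
  if (ncol(deltas) < 2) stop("need >= 2 drugs per line")
  stopifnot(threshold >= 0)
  med <- apply(deltas, 1, stats::median, na.rm = TRUE)
  dev <- abs(sweep(deltas, 1, med))
  classes <- ifelse(dev > threshold, "large_difference", "no_difference")
  common <- intersect(rownames(deltas), rownames(scores))
  cl <- as.vector(classes[common, , drop = FALSE])
  sc <- as.vector(as.matrix(scores)[common, colnames(deltas), drop = FALSE])
  keep <- !is.na(sc)
  cl <- cl[keep]; sc <- sc[keep]
  test <- NULL
  if (length(unique(cl)) < 2) {
    warning("all pairs fall in one class ('", unique(cl), "'); no test run")
  } else {
    grp <- stats::setNames(ifelse(cl == "large_difference", "high", "low"),
                           paste0("pair", seq_along(cl)))
    test <- compare_groups(grp, stats::setNames(sc, names(grp)))
    test$method <- "Welch t-test, large-difference vs no-difference pairs"
  }
  list(classes = classes, test = test,
       mean_scores = tapply(sc, cl, mean))
}

#' Hypergeometric test for gene-list overlap
#'
#' Upper-tail probability of observing at least the realized overlap between
#' two gene lists drawn from a common universe.
#'
#' @param list_a,list_b character vectors (subsets of `universe`).
#' @param universe character vector of all candidate genes.
#' @return a `stat_result` (statistic = observed overlap).
#' @export
hypergeometric_overlap <- function(list_a, list_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (length(setdiff(list_a, universe)) > 0 ||
      length(setdiff(list_b, universe)) > 0) {
    stop("lists must be subsets of the universe")
  }
  k <- length(intersect(list_a, list_b))
  p <- stats::phyper(k - 1, length(list_a),
                     length(universe) - length(list_a),
                     length(list_b), lower.tail = FALSE)
  stat_result(k, p, c(A = length(list_a), B = length(list_b),
                      universe = length(universe)),
              direction = 1, method = "hypergeometric overlap (upper tail)")
}

#' Are KDAC inhibitors selectively sensitive to the high-flux group?
#'
#' For every compound, computes a selectivity metric: mean AUC in the
#' high-flux group minus mean AUC in the low-flux group (negative =
#' preferentially inhibits high-flux lines). Then Welch-tests whether the
#' KDAC-inhibitor compounds are more strongly selective than the rest of the
#' library.
#'
#' @param groups output of [bimodal_grouping()].
#' @param auc numeric matrix, cell lines x compounds.
#' @param kdac_set character vector of compound names that are KDAC
#'   inhibitors.
#' @return list with per-compound `selectivity`, the `test` (`stat_result`),
#'   and the number of compounds dropped for missing data.
#' @export
selectivity_screen <- function(groups, auc, kdac_set) {
  auc <- as.matrix(auc)
  common <- intersect(names(groups), rownames(auc))
  hi <- common[groups[common] == "high"]
  lo <- common[groups[common] == "low"]
  if (length(hi) == 0 || length(lo) == 0) {
    stop("need cell lines in both flux groups")
  }
  sel <- apply(auc[common, , drop = FALSE], 2, function(col) {
    h <- col[hi]; l <- col[lo]
    if (sum(!is.na(h)) < 2 || sum(!is.na(l)) < 2) return(NA_real_)
    mean(h, na.rm = TRUE) - mean(l, na.rm = TRUE)
  })
  dropped <- sum(is.na(sel))
  if (dropped > 0) {
    message(dropped, " compound(s) dropped for insufficient data")
  }
  sel <- sel[!is.na(sel)]
  in_k <- names(sel) %in% kdac_set
  if (sum(in_k) < 2 || sum(!in_k) < 2) {
    stop("need >= 2 compounds inside and outside the KDAC set")
  }
  tt <- stats::t.test(sel[in_k], sel[!in_k], var.equal = FALSE)
  test <- stat_result(unname(tt$statistic), tt$p.value,
                      c(kdac = sum(in_k), other = sum(!in_k)),
                      direction = sign(mean(sel[in_k]) - mean(sel[!in_k])),
                      method = "Welch t-test, KDAC vs other compound selectivity")
  list(selectivity = sel, test = test, dropped = dropped)
}
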