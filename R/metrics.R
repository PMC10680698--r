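# Screening evaluation: ROC curves, AUC (0-100% scale), early enrichment,
# activity cliffs, per-atom attribution consistency.

#' @keywords internal
check_two_classes <- function(labels) {
  stopifnot(is.logical(labels))
  if (anyNA(labels)) stop("labels must not contain NA")
  if (!any(labels) || all(labels))
    stop("need at least one active and one non-active")
}

#' ROC AUC of a ranked screen, on the 0-100% scale
#'
#' Area under the receiver operating characteristic curve for a set of
#' per-compound ranking scores against active/non-active labels, computed
#' as the Mann-Whitney concordance probability: the percentage of
#' (active, non-active) pairs in which the active scores strictly better,
#' with ties given half credit. 100% means every active outranks every
#' non-active; 50% means no recognition; below 50% is anti-predictive.
#'
#' @param scores numeric ranking scores.
#' @param labels logical, `TRUE` for actives.
#' @param lower_is_better score orientation (default `TRUE`, energy-like).
#' @return AUC in percent, in `[0, 100]`.
#' @examples
#' roc_auc(c(-10, -9, -1, -2), c(TRUE, TRUE, FALSE, FALSE))  # 100
#' @export
roc_auc <- function(scores, labels, lower_is_better = TRUE) {
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  x <- if (lower_is_better) -scores else scores   # higher = better
  r <- rank(x)                                    # average ranks on ties
  na <- sum(labels); nn <- sum(!labels)
  u <- sum(r[labels]) - na * (na + 1) / 2
  100 * u / (na * nn)
}

#' ROC curve of a ranked screen
#'
#' Stepwise curve over distinct score thresholds, best scores first; tied
#' scores advance jointly, producing diagonal segments. The trapezoidal
#' area under the returned points equals [roc_auc()] (to numerical
#' precision).
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1).
#' @export
roc_curve <- function(scores, labels, lower_is_better = TRUE) {
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  x <- if (lower_is_better) scores else -scores   # ascending = best first
  o <- order(x)
  x <- x[o]; lab <- labels[o]
  na <- sum(lab); nn <- sum(!lab)
  grp <- cumsum(!duplicated(x))
  tp <- cumsum(rowsum(as.numeric(lab), grp)[, 1])
  fp <- cumsum(rowsum(as.numeric(!lab), grp)[, 1])
  fpr <- c(0, unname(fp) / nn)
  tpr <- c(0, unname(tp) / na)
  # drop interior points collinear with their neighbors (pure vertical,
  # horizontal or constant-slope runs); area is unchanged
  n <- length(fpr)
  keep <- rep(TRUE, n)
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      cross <- (fpr[i] - fpr[i - 1]) * (tpr[i + 1] - tpr[i - 1]) -
               (fpr[i + 1] - fpr[i - 1]) * (tpr[i] - tpr[i - 1])
      keep[i] <- abs(cross) > 1e-12
    }
  }
  data.frame(fpr = fpr[keep], tpr = tpr[keep])
}

#' @keywords internal
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Early enrichment factor
#'
#' Ratio of the active fraction among the best `ceiling(top_fraction * N)`
#' compounds to the active fraction in the whole screen. An EF of 1 is
#' the random expectation; the maximum is `1 / active_fraction`. Ties at
#' the cutoff are resolved by the deterministic ranking order (score,
#' then compound id when `ids` are given, then input position).
#'
#' @inheritParams roc_auc
#' @param top_fraction fraction of the ranked list to inspect, in (0, 1].
#' @param ids optional compound ids used in tie-breaking.
#' @return enrichment factor (>= 0).
#' @export
enrichment_factor <- function(scores, labels, top_fraction,
                              lower_is_better = TRUE, ids = NULL) {
  check_two_classes(labels)
  stopifnot(top_fraction > 0, top_fraction <= 1,
            length(scores) == length(labels))
  x <- if (lower_is_better) scores else -scores
  o <- if (is.null(ids)) order(x, seq_along(x)) else order(x, ids)
  n <- length(x)
  n_top <- ceiling(top_fraction * n)
  hits <- sum(labels[o][seq_len(n_top)])
  (hits / n_top) / (sum(labels) / n)
}

#' Full evaluation of a ranked screen
#'
#' Bundles the ROC curve, AUC (percent) and early enrichment factors for
#' a [rank_library()] result (or raw scores) against active labels.
#'
#' @param ranking a `compound_ranking`, or a numeric score vector named by
#'   compound id.
#' @param labels named logical vector (`TRUE` = active) or a
#'   [screening_library()] with assigned roles.
#' @param top_fractions fractions for [enrichment_factor()].
#' @return object of class `screen_evaluation`: list with `roc`
#'   (data.frame of curve points), `auc` (percent), `enrichment` (named
#'   numeric), `n_actives`, `n_nonactives`.
#' @export
evaluate_screen <- function(ranking, labels, top_fractions = c(0.01, 0.05)) {
  if (inherits(ranking, "compound_ranking")) {
    scores <- stats::setNames(ranking$score, ranking$compound_id)
  } else {
    stopifnot(is.numeric(ranking), !is.null(names(ranking)))
    scores <- ranking
  }
  labels <- as_active_labels(labels)
  lab <- labels[names(scores)]
  if (anyNA(lab))
    stop("labels missing for: ",
         paste(utils::head(names(scores)[is.na(lab)], 5), collapse = ", "))
  ef <- vapply(top_fractions, function(f) {
    enrichment_factor(scores, lab, f, ids = names(scores))
  }, numeric(1))
  structure(list(
    roc = roc_curve(scores, lab),
    auc = roc_auc(scores, lab),
    enrichment = stats::setNames(ef, paste0("EF", top_fractions)),
    n_actives = sum(lab), n_nonactives = sum(!lab)),
    class = "screen_evaluation")
}

#' @export
print.screen_evaluation <- function(x, ...) {
  cat(sprintf("screen_evaluation: AUC %.2f%% (%d actives vs %d non-actives)\n",
              x$auc, x$n_actives, x$n_nonactives))
  if (length(x$enrichment))
    cat("  enrichment:",
        paste(sprintf("%s=%.2f", names(x$enrichment), x$enrichment),
              collapse = ", "), "\n")
  invisible(x)
}

#' Find activity cliffs in a library
#'
#' An activity cliff is a pair of topologically similar compounds with a
#' large potency difference (e.g. a ~100-fold potency change at Tanimoto
#' similarity 1 between 2D-identical stereoisomers). Reports all
#' unordered compound pairs with fingerprint similarity at or above
#' `min_similarity` and an absolute pActivity difference at or above
#' `min_delta`, sorted by the difference, largest first.
#'
#' @param library a [screening_library()] with fingerprints and
#'   activities.
#' @param receptor,site which activity records to use; a compound's
#'   pActivity is its most potent matching measurement.
#' @param min_similarity Tanimoto similarity floor (default 0.85).
#' @param min_delta pActivity difference floor (default 2.0, i.e.
#'   100-fold).
#' @return data.frame with columns `compound_a`, `compound_b`,
#'   `similarity`, `delta_pactivity`.
#' @export
find_activity_cliffs <- function(library, receptor, site,
                                 min_similarity = 0.85, min_delta = 2.0) {
  stopifnot(inherits(library, "screening_library"))
  acts <- library$activities
  acts <- acts[acts$receptor == receptor & acts$site == site, , drop = FALSE]
  ids <- intersect(unique(acts$compound_id), names(library$fingerprints))
  out <- data.frame(compound_a = character(), compound_b = character(),
                    similarity = numeric(), delta_pactivity = numeric(),
                    stringsAsFactors = FALSE)
  if (length(ids) < 2L) return(out)
  pact <- vapply(ids, function(id) {
    max(acts$pactivity[acts$compound_id == id])
  }, numeric(1))
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    delta <- abs(pact[i] - pact[j])
    if (delta < min_delta) next
    sim <- tanimoto_similarity(library$fingerprints[[ids[i]]],
                               library$fingerprints[[ids[j]]])
    if (sim >= min_similarity) {
      out <- rbind(out, data.frame(
        compound_a = ids[i], compound_b = ids[j],
        similarity = sim, delta_pactivity = delta,
        stringsAsFactors = FALSE))
    }
  }
  out[order(-out$delta_pactivity), , drop = FALSE]
}

#' Check that per-atom score contributions sum to the declared total
#'
#' Per-atom score attributions (as used to map favorable interactions
#' onto predicted poses) should decompose the pose score exactly; this
#' verifies the decomposition within a tolerance.
#'
#' @param contributions numeric vector of per-atom score contributions.
#' @param total declared total score.
#' @param tolerance absolute tolerance in scorer-native units (default
#'   1e-6).
#' @return list with `pass` (logical) and `discrepancy`
#'   (|sum - total|).
#' @export
verify_atom_attribution <- function(contributions, total,
                                    tolerance = 1e-6) {
  discrepancy <- abs(sum(contributions) - total)
  list(pass = discrepancy <= tolerance, discrepancy = discrepancy)
}
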