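# Property-matched decoy selection.

#' Matching criteria for property-matched decoy selection
#'
#' Windowed matching in the DUD-E style: a candidate qualifies if it lies
#' within every property window of at least one active and is
#' topologically dissimilar (Tanimoto similarity below a cap) to all
#' actives. Defaults: +/-25 Da molecular weight, +/-1.0 logP, +/-1 HBD,
#' +/-2 HBA, +/-2 rotatable bonds, exact formal charge, similarity cap
#' 0.35, 54 decoys per active.
#'
#' @param mol_weight,logp_estimate,hbd,hba,rotatable_bonds absolute
#'   half-window widths per property.
#' @param formal_charge half-window for formal charge (0 = exact match).
#' @param max_similarity_to_actives Tanimoto similarity cap in (0, 1).
#' @param ratio decoys per active (>= 1).
#' @return object of class `match_criteria`.
#' @export
match_criteria <- function(mol_weight = 25, logp_estimate = 1.0,
                           hbd = 1, hba = 2, rotatable_bonds = 2,
                           formal_charge = 0,
                           max_similarity_to_actives = 0.35,
                           ratio = 54L) {
  stopifnot(ratio >= 1,
            max_similarity_to_actives > 0, max_similarity_to_actives < 1)
  structure(list(
    windows = c(mol_weight = mol_weight, logp_estimate = logp_estimate,
                hbd = hbd, hba = hba, rotatable_bonds = rotatable_bonds,
                formal_charge = formal_charge),
    max_similarity_to_actives = max_similarity_to_actives,
    ratio = as.integer(ratio)), class = "match_criteria")
}

#' @keywords internal
property_matrix <- function(x, ids) {
  props <- if (is.data.frame(x)) x else x$properties
  stopifnot(is.data.frame(props), "compound_id" %in% names(props))
  props <- props[match(ids, props$compound_id), , drop = FALSE]
  if (anyNA(props$compound_id))
    stop("missing property vectors for: ",
         paste(ids[is.na(match(ids, props$compound_id))], collapse = ", "))
  as.matrix(props[, c("mol_weight", "logp_estimate", "hbd", "hba",
                      "rotatable_bonds", "formal_charge")])
}

#' Select property-matched, topologically dissimilar decoys
#'
#' Selects `ratio` decoys per active (a pooled quota: the returned set has
#' exactly `ratio * n_actives` members, with no per-active allocation).
#' Every selected decoy lies within all property windows of at least one
#' active and has Tanimoto similarity below the cap to every active.
#' Ties among equally qualifying candidates are broken by seeded random
#' sampling over candidates sorted by compound id, so the selection is
#' invariant to pool order.
#'
#' @param actives,pool [screening_library()] objects (or lists with
#'   `compounds`, `properties`, `fingerprints`); pool ids must be disjoint
#'   from active ids.
#' @param criteria a [match_criteria()].
#' @param seed integer seed for the tie-breaking draw.
#' @return character vector of selected decoy compound ids, with attribute
#'   `"audit"`: a data.frame of per-candidate qualification diagnostics.
#' @export
select_decoys <- function(actives, pool, criteria = match_criteria(),
                          seed = 1L) {
  a_ids <- actives$compounds$compound_id
  p_ids <- pool$compounds$compound_id
  overlap <- intersect(a_ids, p_ids)
  if (length(overlap))
    stop("pool overlaps actives: ", paste(overlap, collapse = ", "))
  if (!length(a_ids)) stop("no actives supplied")
  A <- property_matrix(actives, a_ids)
  P <- property_matrix(pool, p_ids)
  w <- criteria$windows[colnames(A)]
  # property qualification: within every window of >= 1 active
  in_window <- matrix(FALSE, length(p_ids), length(a_ids))
  for (j in seq_along(a_ids)) {
    diffs <- abs(sweep(P, 2, A[j, ], "-"))
    in_window[, j] <- apply(sweep(diffs, 2, w, "<="), 1, all)
  }
  prop_ok <- rowSums(in_window) > 0
  # topological dissimilarity to ALL actives; running max over actives
  # with a bit-membership vector per active keeps this linear in the pool
  pool_fps <- pool$fingerprints[p_ids]
  if (any(vapply(pool_fps, is.null, logical(1))))
    stop("missing fingerprint for pool compound ",
         p_ids[which(vapply(pool_fps, is.null, logical(1)))[1]])
  pool_sizes <- lengths(pool_fps)
  n_bits <- max(unlist(pool_fps), unlist(actives$fingerprints[a_ids]), 1L)
  max_sim <- rep(0, length(p_ids))
  for (a in a_ids) {
    afp <- actives$fingerprints[[a]]
    member <- logical(n_bits)
    member[afp] <- TRUE
    inter <- vapply(pool_fps, function(p) sum(member[p]), numeric(1))
    sim <- inter / (pool_sizes + length(afp) - inter)
    sim[!is.finite(sim)] <- 1   # two empty bit sets are identical
    max_sim <- pmax(max_sim, sim)
  }
  sim_ok <- max_sim < criteria$max_similarity_to_actives
  qualifies <- prop_ok & sim_ok
  audit <- data.frame(compound_id = p_ids, property_match = prop_ok,
                      max_similarity = max_sim, qualifies = qualifies,
                      stringsAsFactors = FALSE)
  n_needed <- criteria$ratio * length(a_ids)
  cand <- sort(p_ids[qualifies])
  if (length(cand) < n_needed) {
    per_active <- colSums(in_window[qualifies, , drop = FALSE])
    stop("insufficient qualifying decoy candidates: need ", n_needed,
         ", have ", length(cand), "; qualifying candidates per active: ",
         paste(sprintf("%s=%d", a_ids, per_active), collapse = ", "))
  }
  set.seed(seed)
  chosen <- sort(sample(cand, n_needed))
  attr(chosen, "audit") <- audit
  chosen
}
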