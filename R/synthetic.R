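# Seeded synthetic-data generator: screening libraries with clustered
# chemotype fingerprints and matchable property vectors, plus pose-score
# tables with a chemotype x conformer compatibility structure emulating
# induced fit and the contrast between a strict "physics-like" scorer and
# a tolerant "AI-like" scorer.

#' Configuration for the synthetic screening benchmark
#'
#' The score model: the native pose of an active of chemotype `k` docked
#' into conformer `j` scores, under scorer `s` with compatibility
#' sensitivity `lambda_s`,
#'
#'     -(alpha * pactivity * (1 - lambda_s * (1 - C[k, j])) + beta) + eps
#'
#' with `eps ~ N(0, noise_sd)`; all other poses (non-native poses of
#' actives, and every pose of inactives and decoys) draw from a
#' background normal truncated below at the theoretical native optimum
#' (so no background pose can beat a perfectly compatible native pose).
#' `C[k, j]` is the chemotype-conformer compatibility: a conformer
#' recognizes its cognate chemotype (C = 1) better than others, and a
#' scorer with large `lambda` (strict, physics-like) is punished by
#' incompatibility much more than a tolerant, AI-like scorer with small
#' `lambda`.
#'
#' @param n_chemotypes number of active chemotypes.
#' @param actives_per_chemotype actives per chemotype.
#' @param n_inactives number of measured-but-weak compounds (spread
#'   round-robin over the chemotypes).
#' @param decoy_pool_size number of decoys (default 20x the actives).
#' @param n_conformers number of receptor conformers; defaults to
#'   `n_chemotypes` with an identity-dominant compatibility.
#' @param compatibility `n_chemotypes x n_conformers` matrix in `[0,1]`;
#'   default 1.0 on the diagonal, 0.2 off it.
#' @param active_pactivity_range,inactive_pactivity_range uniform ranges
#'   for true pActivities.
#' @param threshold active/inactive pActivity cutoff applied to every
#'   chemotype.
#' @param poses_per_pair docked poses per (compound, conformer).
#' @param scorers named numeric vector of compatibility sensitivities
#'   `lambda` in `[0,1]`; default a strict scorer `FA = 0.9` and a
#'   tolerant scorer `RTCNN = 0.2`.
#' @param alpha,beta affinity-to-score slope and offset.
#' @param noise_sd score noise standard deviation.
#' @param background_mean,background_sd background score distribution.
#' @param fp_n_bits,fp_template_bits,fp_flip_rate fingerprint bit space,
#'   on-bits per chemotype template, and per-compound bit replacement
#'   rate.
#' @param property_violation_rate fraction of decoys deliberately pushed
#'   outside one property window (exercises the decoy selector's
#'   rejection path).
#' @param seed integer seed; every generator output is a deterministic
#'   function of the config.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chemotypes = 3L,
                             actives_per_chemotype = 30L,
                             n_inactives = 30L,
                             decoy_pool_size = NULL,
                             n_conformers = NULL,
                             compatibility = NULL,
                             active_pactivity_range = c(7.5, 10.5),
                             inactive_pactivity_range = c(5, 7),
                             threshold = 7.5,
                             poses_per_pair = 10L,
                             scorers = c(FA = 0.9, RTCNN = 0.2),
                             alpha = 2.0, beta = 5.0,
                             noise_sd = 1.0,
                             background_mean = -8, background_sd = 3,
                             fp_n_bits = 2048L, fp_template_bits = 120L,
                             fp_flip_rate = 0.15,
                             property_violation_rate = 0.2,
                             seed = 1L) {
  n_conformers <- n_conformers %||% n_chemotypes
  decoy_pool_size <- decoy_pool_size %||%
    (20L * n_chemotypes * actives_per_chemotype)
  if (is.null(compatibility)) {
    compatibility <- matrix(0.2, n_chemotypes, n_conformers)
    diag(compatibility) <- 1.0
  }
  stopifnot(n_chemotypes >= 1L, actives_per_chemotype >= 0L,
            n_inactives >= 0L, decoy_pool_size >= 0L, n_conformers >= 1L,
            nrow(compatibility) == n_chemotypes,
            ncol(compatibility) == n_conformers,
            all(compatibility >= 0 & compatibility <= 1),
            length(scorers) >= 1L, !is.null(names(scorers)),
            all(scorers >= 0 & scorers <= 1),
            poses_per_pair >= 1L, noise_sd >= 0)
  if (actives_per_chemotype > 0L && n_chemotypes < 1L)
    stop("actives requested but no chemotypes configured")
  structure(as.list(environment()), class = "synthetic_config")
}

#' @keywords internal
ragged_bits <- function(template, flip_rate, n_bits) {
  drop <- stats::runif(length(template)) < flip_rate
  kept <- template[!drop]
  n_new <- stats::rbinom(1, length(template), flip_rate)
  new <- sample(setdiff(seq_len(n_bits), kept), n_new)
  sort(unique(c(kept, new)))
}

#' Generate a synthetic screening library
#'
#' Realizes the configured chemotypes as random fingerprint bit templates
#' with per-compound bit replacement (so within-chemotype Tanimoto
#' similarity is much larger than between-chemotype similarity), draws
#' property vectors such that decoys are matchable to actives, assigns
#' true pActivities, and labels roles through [assign_roles()]. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `library` (a [screening_library()]) and `truth`
#'   (data.frame of per-compound chemotype, role and true pActivity).
#' @export
gen_library <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_chemotypes
  chemos <- sprintf("CT%02d", seq_len(K))
  templates <- lapply(seq_len(K), function(k)
    sort(sample(config$fp_n_bits, config$fp_template_bits)))
  names(templates) <- chemos

  ids <- character(); chemo <- character(); role_hint <- character()
  pact <- numeric()
  for (k in seq_len(K)) {
    n <- config$actives_per_chemotype
    if (n > 0) {
      ids <- c(ids, sprintf("%s_a%03d", chemos[k], seq_len(n)))
      chemo <- c(chemo, rep(chemos[k], n))
      role_hint <- c(role_hint, rep("active", n))
      pact <- c(pact, stats::runif(n, config$active_pactivity_range[1],
                                   config$active_pactivity_range[2]))
    }
  }
  if (config$n_inactives > 0) {
    k_cycle <- rep_len(seq_len(K), config$n_inactives)
    ids <- c(ids, sprintf("%s_i%03d", chemos[k_cycle],
                          seq_len(config$n_inactives)))
    chemo <- c(chemo, chemos[k_cycle])
    role_hint <- c(role_hint, rep("inactive", config$n_inactives))
    pact <- c(pact, stats::runif(config$n_inactives,
                                 config$inactive_pactivity_range[1],
                                 config$inactive_pactivity_range[2]))
  }
  n_meas <- length(ids)
  fps <- lapply(seq_len(n_meas), function(i)
    ragged_bits(templates[[chemo[i]]], config$fp_flip_rate, config$fp_n_bits))
  names(fps) <- ids

  # measured compounds: properties in a drug-like band
  props <- data.frame(
    compound_id = ids,
    mol_weight = stats::rnorm(n_meas, 400, 50),
    logp_estimate = stats::rnorm(n_meas, 3, 1),
    hbd = stats::rpois(n_meas, 2),
    hba = stats::rpois(n_meas, 5),
    rotatable_bonds = stats::rpois(n_meas, 6),
    formal_charge = sample(c(-1L, 0L, 1L), n_meas, replace = TRUE),
    stringsAsFactors = FALSE)

  # decoys: drawn inside the property windows of a random active, with a
  # configurable violation rate to exercise rejection paths
  nd <- config$decoy_pool_size
  d_ids <- character(); d_props <- NULL; d_fps <- list()
  if (nd > 0) {
    d_ids <- sprintf("DEC_%05d", seq_len(nd))
    act_rows <- which(role_hint == "active")
    if (!length(act_rows)) act_rows <- seq_len(max(n_meas, 1L))
    anchor <- sample(act_rows, nd, replace = TRUE)
    w <- match_criteria()$windows
    d_props <- data.frame(
      compound_id = d_ids,
      mol_weight = props$mol_weight[anchor] +
        stats::runif(nd, -w["mol_weight"], w["mol_weight"]),
      logp_estimate = props$logp_estimate[anchor] +
        stats::runif(nd, -w["logp_estimate"], w["logp_estimate"]),
      hbd = pmax(0L, props$hbd[anchor] +
        sample(-w["hbd"]:w["hbd"], nd, replace = TRUE)),
      hba = pmax(0L, props$hba[anchor] +
        sample(-w["hba"]:w["hba"], nd, replace = TRUE)),
      rotatable_bonds = pmax(0L, props$rotatable_bonds[anchor] +
        sample(-w["rotatable_bonds"]:w["rotatable_bonds"], nd, replace = TRUE)),
      formal_charge = props$formal_charge[anchor],
      stringsAsFactors = FALSE)
    violate <- stats::runif(nd) < config$property_violation_rate
    d_props$mol_weight[violate] <- d_props$mol_weight[violate] +
      sample(c(-1, 1), sum(violate), replace = TRUE) * (2 * w["mol_weight"] + 50)
    d_fps <- lapply(seq_len(nd), function(i)
      sort(sample(config$fp_n_bits, config$fp_template_bits)))
    names(d_fps) <- d_ids
  }

  compounds <- data.frame(
    compound_id = c(ids, d_ids),
    smiles = NA_character_,
    alias = NA_character_,
    chemotype = c(chemo, rep(NA_character_, nd)),
    role = c(rep("unassigned", n_meas), rep("decoy", nd)),
    stringsAsFactors = FALSE)
  activities <- data.frame(
    compound_id = ids,
    receptor = "hCCR2", site = "orthosteric", measure = "IC50",
    value_M = 10^(-pact), pactivity = pact,
    stringsAsFactors = FALSE)
  thresholds <- stats::setNames(rep(config$threshold, K), chemos)
  lib <- screening_library(
    compounds = compounds, activities = activities,
    fingerprints = c(fps, d_fps),
    properties = rbind(props, d_props),
    thresholds = thresholds,
    provenance = sprintf("synthetic (seed %d)", config$seed))
  lib <- assign_roles(lib, receptor = "hCCR2", site = "orthosteric")
  truth <- data.frame(
    compound_id = lib$compounds$compound_id,
    chemotype = lib$compounds$chemotype,
    role = lib$compounds$role,
    pactivity = c(pact, rep(NA_real_, nd)),
    stringsAsFactors = FALSE)
  list(library = lib, truth = truth)
}

#' Generate a synthetic pose-score table
#'
#' Emits `poses_per_pair` poses for every (compound, conformer) pair and
#' every configured scorer. For active compounds, one pose per conformer
#' is the native pose and scores according to the compatibility model
#' (see [synthetic_config()]); all remaining poses, and all poses of
#' inactives and decoys, draw from the truncated background
#' distribution. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param library,truth output of [gen_library()] (defaults regenerate
#'   them from `config`).
#' @return list with `table` (a [pose_score_table()]) and `native`
#'   (data.frame: compound, model, native pose id).
#' @export
gen_pose_scores <- function(config, library = NULL, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(library) || is.null(truth)) {
    g <- gen_library(config)
    library <- g$library; truth <- g$truth
  }
  if (!length(config$scorers)) stop("scorer list is empty")
  set.seed(config$seed + 1000003L)
  J <- config$n_conformers
  P <- config$poses_per_pair
  models <- sprintf("conf%d", seq_len(J))
  ids <- truth$compound_id
  n <- length(ids)
  grid <- expand.grid(pose_id = seq_len(P), model_id = models,
                      compound_id = ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("compound_id", "model_id", "pose_id")]
  m <- nrow(grid)
  optimum <- -(config$alpha * config$active_pactivity_range[2] + config$beta)

  # native pose bookkeeping: one per (active, conformer)
  act <- truth$compound_id[truth$role == "active"]
  native <- NULL
  if (length(act)) {
    native <- expand.grid(compound_id = act, model_id = models,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    native$pose_id <- sample(P, nrow(native), replace = TRUE)
  }
  is_native <- rep(FALSE, m)
  if (!is.null(native)) {
    key <- paste(grid$compound_id, grid$model_id, grid$pose_id)
    is_native[key %in% paste(native$compound_id, native$model_id,
                             native$pose_id)] <- TRUE
  }
  ct <- truth$chemotype[match(grid$compound_id, truth$compound_id)]
  k_idx <- as.integer(sub("^CT", "", ct))
  j_idx <- as.integer(sub("^conf", "", grid$model_id))
  pact <- truth$pactivity[match(grid$compound_id, truth$compound_id)]

  for (s in names(config$scorers)) {
    lambda <- config$scorers[[s]]
    # truncated background: support [optimum, Inf)
    p_lo <- stats::pnorm(optimum, config$background_mean, config$background_sd)
    bg <- stats::qnorm(stats::runif(m, p_lo, 1),
                       config$background_mean, config$background_sd)
    sc <- bg
    if (any(is_native)) {
      C_kj <- config$compatibility[cbind(k_idx[is_native], j_idx[is_native])]
      mu <- -(config$alpha * pact[is_native] *
                (1 - lambda * (1 - C_kj)) + config$beta)
      sc[is_native] <- mu + stats::rnorm(sum(is_native), 0, config$noise_sd)
    }
    grid[[s]] <- sc
  }
  list(table = pose_score_table(grid, scorers = names(config$scorers)),
       native = native)
}
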