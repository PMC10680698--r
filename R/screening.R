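# Two-stage scoring schemes: pose selection by scorer X, compound ranking
# by scorer Y ("X|Y"), over single receptor models or pooled conformer
# ensembles.

#' Construct a pose-score table
#'
#' The central exchange format of the pipeline: one row per docked pose,
#' keyed by (compound, receptor model, pose), with one column per named
#' scorer. All scores are normalized to "lower is better" at
#' construction: columns named in `higher_is_better` are negated.
#'
#' @param data data.frame with columns `compound_id`, `model_id`,
#'   `pose_id` plus one numeric column per scorer.
#' @param scorers character vector naming the scorer columns; default:
#'   every non-key column.
#' @param higher_is_better scorer columns whose native orientation is
#'   "higher is better"; they are sign-flipped.
#' @return data.frame of class `pose_score_table` with attribute
#'   `"scorers"`.
#' @export
pose_score_table <- function(data, scorers = NULL,
                             higher_is_better = character()) {
  stopifnot(is.data.frame(data))
  key <- c("compound_id", "model_id", "pose_id")
  miss <- setdiff(key, names(data))
  if (length(miss)) stop("missing key columns: ", paste(miss, collapse = ", "))
  if (is.null(scorers)) scorers <- setdiff(names(data), key)
  if (!length(scorers)) stop("no scorer columns")
  bad <- setdiff(scorers, names(data))
  if (length(bad)) stop("scorer columns absent: ", paste(bad, collapse = ", "))
  if (any(data$pose_id < 1)) stop("pose_id must be >= 1")
  k <- paste(data$compound_id, data$model_id, data$pose_id, sep = "\r")
  if (anyDuplicated(k))
    stop("duplicate (compound_id, model_id, pose_id): ",
         k[duplicated(k)][1])
  for (s in scorers) {
    if (!is.numeric(data[[s]]))
      stop("scorer column '", s, "' is not numeric")
    if (anyNA(data[[s]]))
      stop("scorer column '", s, "' has missing values; every pose must ",
           "carry a value for every declared scorer")
    if (s %in% higher_is_better) data[[s]] <- -data[[s]]
  }
  attr(data, "scorers") <- scorers
  class(data) <- c("pose_score_table", class(data))
  data
}

#' Read a pose-score table from TSV
#'
#' The header row declares the key columns and one column per scorer;
#' scorer orientation is given through `higher_is_better`.
#'
#' @param path TSV file.
#' @inheritParams pose_score_table
#' @export
read_pose_table <- function(path, scorers = NULL,
                            higher_is_better = character()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pose_score_table(df, scorers = scorers, higher_is_better = higher_is_better)
}

#' @export
print.pose_score_table <- function(x, ...) {
  cat("pose_score_table:", nrow(x), "poses,",
      length(unique(x$compound_id)), "compounds,",
      length(unique(x$model_id)), "model(s); scorers:",
      paste(attr(x, "scorers"), collapse = ", "), "\n")
  invisible(x)
}

#' A two-stage scoring scheme ("selector|ranker")
#'
#' Stage (ii) of a screen selects one pose per compound by the *selector*
#' scorer; stage (iii) ranks compounds by the *ranker* scorer evaluated at
#' the selected pose. The conventional notation is `"X|Y"`, e.g.
#' `"FA|RTCNN"`: poses chosen by FA, compounds ranked by RTCNN.
#'
#' @param selector selector scorer name, or a full `"X|Y"` string.
#' @param ranker ranker scorer name (omit when `selector` is `"X|Y"`).
#' @return object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("FA|RTCNN")
#' scoring_scheme("FA", "FA")
#' @export
scoring_scheme <- function(selector, ranker = NULL) {
  if (is.null(ranker)) {
    if (!grepl("|", selector, fixed = TRUE))
      stop("ranker missing and selector is not of the form 'X|Y'")
    parts <- strsplit(selector, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("scheme notation must be 'X|Y'")
    selector <- parts[1]; ranker <- parts[2]
  }
  structure(list(selector = selector, ranker = ranker,
                 notation = paste0(selector, "|", ranker)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme:", x$notation, "\n")
  invisible(x)
}

#' @keywords internal
check_scorer <- function(table, scorer) {
  if (!scorer %in% attr(table, "scorers"))
    stop("scorer '", scorer, "' not declared in table (has: ",
         paste(attr(table, "scorers"), collapse = ", "), ")")
}

#' Select the best pose of a compound in one receptor model
#'
#' Returns the pose minimizing the selector score; ties are broken by the
#' lowest pose id.
#'
#' @param table a [pose_score_table()].
#' @param compound_id,model_id which poses to consider.
#' @param selector selector scorer name.
#' @return list with `pose_id` and `scores` (named numeric, all scorers).
#' @export
select_pose <- function(table, compound_id, model_id, selector) {
  check_scorer(table, selector)
  sub <- table[table$compound_id == compound_id &
               table$model_id == model_id, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no poses for compound '", compound_id, "' in model '", model_id, "'")
  sub <- sub[order(sub[[selector]], sub$pose_id), , drop = FALSE]
  list(pose_id = sub$pose_id[1],
       scores = unlist(sub[1, attr(table, "scorers"), drop = TRUE]))
}

#' Score one compound under a scheme over a model set
#'
#' Poses of the compound across all models of `model_set` are pooled; the
#' single pose minimizing the selector score over the pool is chosen, and
#' that pose's ranker score is returned. With one model this reduces to
#' single-model X|Y scoring. A compound may be absent from some models of
#' an ensemble (it is scored from the rest) but must occur in at least
#' one.
#'
#' @inheritParams select_pose
#' @param scheme a [scoring_scheme()].
#' @param model_set model ids to pool (default: all models in the table).
#' @return list with `score` (ranker score), `selector_score`,
#'   `model_id`, `pose_id`.
#' @export
score_compound <- function(table, compound_id, scheme, model_set = NULL) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  check_scorer(table, scheme$selector); check_scorer(table, scheme$ranker)
  if (is.null(model_set)) model_set <- unique(table$model_id)
  sub <- table[table$compound_id == compound_id &
               table$model_id %in% model_set, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("compound '", compound_id, "' absent from all models of the set")
  sub <- sub[order(sub[[scheme$selector]], sub$model_id, sub$pose_id), ,
             drop = FALSE]
  list(score = sub[[scheme$ranker]][1],
       selector_score = sub[[scheme$selector]][1],
       model_id = sub$model_id[1], pose_id = sub$pose_id[1])
}

#' Rank a compound library under a scoring scheme
#'
#' Applies [score_compound()] to every library compound present in the
#' table (pooling over `model_set`) and orders compounds by ranking score
#' ascending (better first), ties by compound id. Compounds missing from
#' the table are collected in the `"exclusions"` attribute, not silently
#' dropped.
#'
#' @inheritParams score_compound
#' @param compounds character vector of compound ids, or a
#'   [screening_library()].
#' @return data.frame of class `compound_ranking` with columns
#'   `compound_id`, `model_id`, `pose_id`, `score`; attributes `scheme`,
#'   `model_set`, `exclusions`.
#' @export
rank_library <- function(table, compounds, scheme, model_set = NULL) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (inherits(compounds, "screening_library"))
    compounds <- compounds$compounds$compound_id
  check_scorer(table, scheme$selector); check_scorer(table, scheme$ranker)
  if (is.null(model_set)) model_set <- unique(table$model_id)
  sub <- table[table$model_id %in% model_set &
               table$compound_id %in% compounds, , drop = FALSE]
  excluded <- setdiff(compounds, sub$compound_id)
  if (length(compounds) > 0L && nrow(sub) == 0L)
    stop("no library compound has poses in the selected models")
  # pooled selector-argmin per compound, deterministic tie-break
  sub <- sub[order(sub$compound_id, sub[[scheme$selector]],
                   sub$model_id, sub$pose_id), , drop = FALSE]
  best <- sub[!duplicated(sub$compound_id), , drop = FALSE]
  out <- data.frame(compound_id = best$compound_id,
                    model_id = best$model_id,
                    pose_id = best$pose_id,
                    selector_score = best[[scheme$selector]],
                    score = best[[scheme$ranker]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  attr(out, "model_set") <- model_set
  attr(out, "exclusions") <- excluded
  class(out) <- c("compound_ranking", class(out))
  out
}

#' Evaluate every selector/ranker scheme combination
#'
#' Builds the full matrix of two-stage schemes (e.g. the nine combinations
#' of three scorers) and evaluates each ranking against active labels with
#' the metrics module.
#'
#' @inheritParams rank_library
#' @param labels named logical vector (`TRUE` = active) covering the
#'   ranked compounds, or a [screening_library()] with assigned roles
#'   (actives vs everything else).
#' @param selectors,rankers scorer names defining the matrix axes
#'   (default: all scorers in the table).
#' @param top_fractions early-enrichment fractions passed to
#'   [evaluate_screen()].
#' @return list of class `scheme_matrix`: `auc` (numeric
#'   selectors x rankers matrix, percent), `evaluations` (list of
#'   `screen_evaluation` keyed by `"X|Y"`).
#' @export
scheme_matrix <- function(table, compounds, labels,
                          selectors = NULL, rankers = NULL,
                          model_set = NULL, top_fractions = c(0.01, 0.05)) {
  all_scorers <- attr(table, "scorers")
  selectors <- selectors %||% all_scorers
  rankers <- rankers %||% all_scorers
  for (s in unique(c(selectors, rankers))) check_scorer(table, s)
  labels <- as_active_labels(labels)
  auc <- matrix(NA_real_, length(selectors), length(rankers),
                dimnames = list(selectors, rankers))
  evals <- list()
  for (s in selectors) for (r in rankers) {
    sch <- scoring_scheme(s, r)
    rk <- rank_library(table, compounds, sch, model_set)
    ev <- evaluate_screen(rk, labels, top_fractions = top_fractions)
    auc[s, r] <- ev$auc
    evals[[sch$notation]] <- ev
  }
  structure(list(auc = auc, evaluations = evals), class = "scheme_matrix")
}

#' @export
print.scheme_matrix <- function(x, ...) {
  cat("scheme_matrix (AUC %, selector rows | ranker columns):\n")
  print(round(x$auc, 2))
  invisible(x)
}

#' @keywords internal
as_active_labels <- function(labels) {
  if (inherits(labels, "screening_library")) {
    stats::setNames(labels$compounds$role == "active",
                    labels$compounds$compound_id)
  } else {
    stopifnot(is.logical(labels), !is.null(names(labels)))
    labels
  }
}
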