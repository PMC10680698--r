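# Screening-library container and curation operations.

.ROLES <- c("active", "inactive", "decoy", "unassigned")
.RECEPTORS <- c("hCCR2", "hCCR5", "mCCR2", "hCCR1", "other")
.SITES <- c("orthosteric", "allosteric")

#' Construct a screening library
#'
#' A screening library bundles compound records (identity, structure,
#' chemotype, screening role), their measured activities on the pActivity
#' scale, fingerprints, physicochemical property vectors, and the
#' per-chemotype activity thresholds used for role assignment.
#'
#' @param compounds data.frame with columns `compound_id`, `smiles`,
#'   `alias`, `chemotype`, `role` (missing optional columns are filled
#'   with `NA`/`"unassigned"`).
#' @param activities data.frame with columns `compound_id`, `receptor`,
#'   `site`, `measure`, `value_M`, `pactivity`; may be `NULL`.
#' @param fingerprints named list of fingerprint bit sets keyed by
#'   compound id.
#' @param properties data.frame of property vectors with a `compound_id`
#'   column.
#' @param thresholds named numeric vector mapping chemotype to its active
#'   pActivity cutoff; the name `".default"` supplies a fallback cutoff.
#' @param provenance free-text provenance note.
#' @return object of class `screening_library`.
#' @export
screening_library <- function(compounds,
                              activities = NULL,
                              fingerprints = NULL,
                              properties = NULL,
                              thresholds = NULL,
                              provenance = "") {
  stopifnot(is.data.frame(compounds))
  if (!"compound_id" %in% names(compounds))
    stop("compounds must have a compound_id column")
  for (col in c("smiles", "alias", "chemotype"))
    if (!col %in% names(compounds)) compounds[[col]] <- NA_character_
  if (!"role" %in% names(compounds)) compounds$role <- "unassigned"
  dup <- duplicated(compounds$compound_id)
  if (any(dup)) {
    first <- match(compounds$compound_id[dup][1], compounds$compound_id)
    stop("duplicate compound_id '", compounds$compound_id[dup][1],
         "' (rows ", first, " and ", which(dup)[1], ")")
  }
  if (!all(compounds$role %in% .ROLES))
    stop("role must be one of: ", paste(.ROLES, collapse = ", "))
  if (!is.null(activities) && nrow(activities) > 0) {
    bad <- setdiff(activities$compound_id, compounds$compound_id)
    if (length(bad))
      stop("activities reference unknown compounds: ",
           paste(bad, collapse = ", "))
    decoy_ids <- compounds$compound_id[compounds$role == "decoy"]
    if (any(activities$compound_id %in% decoy_ids))
      stop("decoy compounds must not carry activities")
  }
  structure(
    list(compounds = compounds,
         activities = activities %||% empty_activities(),
         fingerprints = fingerprints %||% list(),
         properties = properties,
         thresholds = thresholds,
         provenance = provenance),
    class = "screening_library"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
empty_activities <- function() {
  data.frame(compound_id = character(), receptor = character(),
             site = character(), measure = character(),
             value_M = numeric(), pactivity = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.screening_library <- function(x, ...) {
  tab <- table(factor(x$compounds$role, levels = .ROLES))
  cat("screening_library:", nrow(x$compounds), "compounds (",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")\n")
  cat("  activities:", nrow(x$activities),
      " fingerprints:", length(x$fingerprints), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Convert a measured potency to the pActivity scale
#'
#' pActivity (pIC50, pKi, ...) is the negative decadic logarithm of a
#' potency concentration expressed in molar units; a 100-fold potency loss
#' corresponds to a pActivity drop of 2.
#'
#' @param value positive concentration values.
#' @param unit unit of `value`: one of `"M"`, `"mM"`, `"uM"`, `"nM"`,
#'   `"pM"` (recycled).
#' @return numeric vector of pActivity values.
#' @examples
#' compute_pactivity(1, "nM")   # 9
#' compute_pactivity(10, "nM")  # 8
#' @export
compute_pactivity <- function(value, unit = "M") {
  factors <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  if (!all(unit %in% names(factors)))
    stop("unknown unit(s): ",
         paste(setdiff(unit, names(factors)), collapse = ", "))
  if (any(!is.finite(value) | value <= 0))
    stop("activity values must be positive and finite")
  -log10(value * unname(factors[unit]))
}

#' Parse a compound/activity table into a screening library
#'
#' Reads a tab-separated table (columns: `compound_id`, `smiles`, optional
#' `alias`, `chemotype`, `receptor`, `site`, `measure`, `value`, `unit`)
#' or an SDF file (data fields with the same names), computes fingerprints
#' and property vectors, and converts activities to pActivity. Malformed
#' rows (unparsable structure, bad activity value) are collected into a
#' rejection report attached as attribute `"rejections"` and reported with
#' a warning -- they are never silently dropped.
#'
#' @param path input file.
#' @param format `"smiles_tsv"` or `"sdf"`.
#' @param thresholds optional named numeric chemotype cutoffs stored in
#'   the library.
#' @param fingerprint compute fingerprints and property vectors (default
#'   `TRUE`; set `FALSE` for structure-free tables).
#' @return a [screening_library()], with attribute `"rejections"`.
#' @export
parse_compound_table <- function(path, format = c("smiles_tsv", "sdf"),
                                 thresholds = NULL, fingerprint = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "smiles_tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    read_sdf_table(path)
  }
  if (nrow(df) == 0L) {
    warning("empty compound table: ", path)
    lib <- screening_library(
      data.frame(compound_id = character(), smiles = character(),
                 alias = character(), chemotype = character(),
                 role = character(), stringsAsFactors = FALSE),
      thresholds = thresholds, provenance = path)
    attr(lib, "rejections") <- data.frame(row = integer(), compound_id = character(),
                                          reason = character())
    return(lib)
  }
  need <- c("compound_id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(df$compound_id)
  if (any(dup)) {
    id <- df$compound_id[dup][1]
    stop("duplicate compound_id '", id, "' (rows ",
         paste(which(df$compound_id == id), collapse = " and "), ")")
  }
  for (col in c("alias", "chemotype", "receptor", "site", "measure",
                "value", "unit"))
    if (!col %in% names(df)) df[[col]] <- NA_character_

  rejections <- data.frame(row = integer(), compound_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  fps <- list()
  props <- list()
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (fingerprint) {
      fp <- tryCatch(compute_fingerprint(df$smiles[i]), error = identity)
      if (inherits(fp, "error")) {
        rejections <- rbind(rejections, data.frame(
          row = i, compound_id = df$compound_id[i],
          reason = conditionMessage(fp)))
        next
      }
      pv <- compute_property_vector(df$smiles[i])
      pv$compound_id <- df$compound_id[i]
      fps[[df$compound_id[i]]] <- fp
      props[[length(props) + 1L]] <- pv
    }
    keep[i] <- TRUE
  }
  df <- df[keep, , drop = FALSE]

  acts <- empty_activities()
  has_act <- !is.na(df$value) & nzchar(df$value)
  if (any(has_act)) {
    av <- suppressWarnings(as.numeric(df$value[has_act]))
    sub <- df[has_act, ]
    ok <- is.finite(av) & av > 0
    if (any(!ok)) {
      rejections <- rbind(rejections, data.frame(
        row = which(has_act)[!ok], compound_id = sub$compound_id[!ok],
        reason = "non-positive or non-numeric activity value"))
    }
    if (any(ok)) {
      acts <- data.frame(
        compound_id = sub$compound_id[ok],
        receptor = sub$receptor[ok],
        site = sub$site[ok],
        measure = sub$measure[ok],
        value_M = as.numeric(av[ok]) *
          unname(c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[sub$unit[ok]]),
        pactivity = compute_pactivity(av[ok], sub$unit[ok]),
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(rejections)) {
    warning(nrow(rejections), " row(s) rejected; see attr(x, 'rejections')")
  }
  lib <- screening_library(
    compounds = data.frame(compound_id = df$compound_id, smiles = df$smiles,
                           alias = df$alias, chemotype = df$chemotype,
                           role = "unassigned", stringsAsFactors = FALSE),
    activities = acts,
    fingerprints = fps,
    properties = if (length(props)) do.call(rbind, props) else NULL,
    thresholds = thresholds,
    provenance = path)
  attr(lib, "rejections") <- rejections
  lib
}

# Thin SDF reader: splits records on "$$$$", converts each molblock to
# SMILES via OpenBabel, and collects "> <field>" data items.
#' @keywords internal
read_sdf_table <- function(path) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(data.frame())
  starts <- c(1L, utils::head(ends, -1) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1)], starts, ends)
  rows <- lapply(recs, function(r) {
    mend <- grep("^M  END", r)[1]
    if (is.na(mend)) return(NULL)
    smi <- tryCatch({
      out <- ChemmineOB::convertFormat("SDF", "SMI",
                                       paste(c(r[1:mend], "$$$$"), collapse = "\n"))
      strsplit(trimws(out), "[ \t]")[[1]][1]
    }, error = function(e) NA_character_)
    fields <- list(smiles = smi)
    tags <- grep("^> *<", r)
    for (t in tags) {
      nm <- sub("^> *<([^>]+)>.*$", "\\1", r[t])
      fields[[nm]] <- if (t + 1 <= length(r)) trimws(r[t + 1]) else ""
    }
    if (is.null(fields$compound_id)) fields$compound_id <- trimws(r[1])
    as.data.frame(fields, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(data.frame())
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(nms, names(r))) r[[nm]] <- NA_character_
    r[nms]
  })
  do.call(rbind, rows)
}

#' Assign active/inactive screening roles under per-chemotype thresholds
#'
#' A compound with a measured activity at the requested receptor/site is
#' labelled `active` iff its best (largest) pActivity strictly exceeds its
#' chemotype's cutoff, and `inactive` otherwise. Decoys are untouched;
#' compounds without a matching measurement stay `unassigned`. When a
#' compound has several measurements for one (receptor, site) the most
#' potent one decides.
#'
#' @param library a [screening_library()] with thresholds defined.
#' @param receptor,site which activity records to use.
#' @return the library with updated roles.
#' @export
assign_roles <- function(library, receptor, site) {
  stopifnot(inherits(library, "screening_library"))
  thr <- library$thresholds
  if (is.null(thr)) stop("library has no thresholds")
  acts <- library$activities
  acts <- acts[acts$receptor == receptor & acts$site == site, , drop = FALSE]
  comp <- library$compounds
  measured <- comp$compound_id %in% acts$compound_id & comp$role != "decoy"
  if (any(measured)) {
    ct <- comp$chemotype[measured]
    key <- ifelse(is.na(ct) | !(ct %in% names(thr)), ".default", ct)
    missing_thr <- unique(ct[!(ct %in% names(thr)) &
                             !(".default" %in% names(thr))])
    if (length(missing_thr) || (any(is.na(ct)) && !(".default" %in% names(thr))))
      stop("no threshold for chemotype(s): ",
           paste(unique(c(missing_thr, if (any(is.na(ct))) "<NA>")), collapse = ", "))
    best <- vapply(comp$compound_id[measured], function(id) {
      max(acts$pactivity[acts$compound_id == id])
    }, numeric(1))
    comp$role[measured] <- ifelse(best > unname(thr[key]), "active", "inactive")
  }
  library$compounds <- comp
  library
}

#' Subset a screening library by compound id
#'
#' Keeps the named compounds together with their activities, fingerprints
#' and property vectors.
#'
#' @param library a [screening_library()].
#' @param ids compound ids to keep.
#' @return a [screening_library()].
#' @export
subset_library <- function(library, ids) {
  stopifnot(inherits(library, "screening_library"))
  miss <- setdiff(ids, library$compounds$compound_id)
  if (length(miss))
    stop("unknown compound id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  comp <- library$compounds[match(ids, library$compounds$compound_id), ,
                            drop = FALSE]
  rownames(comp) <- NULL
  acts <- library$activities
  acts <- acts[acts$compound_id %in% ids, , drop = FALSE]
  props <- library$properties
  if (!is.null(props)) {
    props <- props[props$compound_id %in% ids, , drop = FALSE]
    rownames(props) <- NULL
  }
  screening_library(
    compounds = comp, activities = acts,
    fingerprints = library$fingerprints[intersect(ids, names(library$fingerprints))],
    properties = props, thresholds = library$thresholds,
    provenance = library$provenance)
}

#' UPGMA hierarchical clustering of a distance matrix
#'
#' Unweighted pair-group average-linkage agglomeration with deterministic
#' tie-breaking: when several pairs share the minimal distance, the pair
#' whose lexicographically smallest member label is smallest (then the
#' smallest partner label) is merged first. Merge heights are
#' non-decreasing (the UPGMA ultrametric property).
#'
#' @param d symmetric distance matrix with dimnames, or a [stats::dist].
#' @return object of class `upgma_dendrogram` with hclust-compatible
#'   `merge`, `height`, `order`, `labels`; convert with `as.hclust()`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (n == 1L) {
    out <- list(merge = matrix(integer(), 0, 2), height = numeric(),
                order = 1L, labels = labels, method = "UPGMA")
    class(out) <- "upgma_dendrogram"
    return(out)
  }
  size <- rep(1, n)
  minlab <- labels                  # lexicographic rep of each cluster
  id <- -seq_len(n)                 # hclust coding
  members <- as.list(seq_len(n))
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- nrow(dm)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- dm[i, j]
      lo <- if (minlab[i] <= minlab[j]) c(minlab[i], minlab[j]) else c(minlab[j], minlab[i])
      cand <- list(d = dij, i = i, j = j, lo = lo)
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (cand$lo[1] < best$lo[1] ||
            (cand$lo[1] == best$lo[1] && cand$lo[2] < best$lo[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best$d
    # UPGMA: unweighted average over leaves
    ni <- size[i]; nj <- size[j]
    newrow <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
    size <- c(size[keep], ni + nj)
    id <- c(id[keep], step)
  }
  ord <- dendrogram_order(merge)
  out <- list(merge = merge, height = height, order = ord,
              labels = labels, method = "UPGMA")
  class(out) <- "upgma_dendrogram"
  out
}

#' @keywords internal
dendrogram_order <- function(merge) {
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  if (nrow(merge) == 0L) return(1L)
  rec(nrow(merge))
}

#' @export
as.hclust.upgma_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "tanimoto"),
            class = "hclust")
}

#' Cluster library compounds into chemotypes
#'
#' Computes pairwise Tanimoto distances between compound fingerprints,
#' builds a UPGMA dendrogram, and cuts it at `cut_height` to obtain
#' disjoint, exhaustive chemotype clusters. Cluster labels are stable
#' under permutation of the input: each cluster is named after its
#' lexicographically first compound id.
#'
#' @param library a [screening_library()] with fingerprints.
#' @param cut_height Tanimoto-distance cut (default 0.6).
#' @param relabel if `TRUE`, writes the cluster labels into
#'   `library$compounds$chemotype` of the returned library copy.
#' @return list of class `chemotype_clustering` with `dendrogram`
#'   (a `upgma_dendrogram`), `labels` (named character, compound id ->
#'   cluster label), `cut_height`, and `library` (when `relabel`).
#' @export
cluster_chemotypes <- function(library, cut_height = 0.6, relabel = FALSE) {
  stopifnot(inherits(library, "screening_library"))
  ids <- names(library$fingerprints)
  if (length(ids) < 1L) stop("library has no fingerprints to cluster")
  dmat <- fingerprint_distance_matrix(library$fingerprints)
  dend <- upgma(dmat)
  labels <- cut_chemotypes(dend, cut_height)
  out <- list(dendrogram = dend, labels = labels, cut_height = cut_height)
  if (relabel) {
    comp <- library$compounds
    m <- match(comp$compound_id, names(labels))
    comp$chemotype[!is.na(m)] <- labels[m[!is.na(m)]]
    library$compounds <- comp
    out$library <- library
  }
  class(out) <- "chemotype_clustering"
  out
}

#' @rdname cluster_chemotypes
#' @param dendrogram a `upgma_dendrogram`.
#' @export
cut_chemotypes <- function(dendrogram, cut_height) {
  hc <- stats::as.hclust(dendrogram)
  if (length(hc$height) == 0L) {
    cl <- stats::setNames(1L, hc$labels)
  } else {
    cl <- stats::cutree(hc, h = cut_height)
  }
  labs <- vapply(split(names(cl), cl), min, character(1))
  stats::setNames(unname(labs[as.character(cl)]), names(cl))
}

#' Pairwise Tanimoto distance matrix of a fingerprint set
#'
#' @param fingerprints named list of bit sets.
#' @return symmetric matrix of Tanimoto distances.
#' @export
fingerprint_distance_matrix <- function(fingerprints) {
  n <- length(fingerprints)
  dmat <- matrix(0, n, n, dimnames = list(names(fingerprints), names(fingerprints)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dij <- tanimoto_distance(fingerprints[[i]], fingerprints[[j]])
      dmat[i, j] <- dij; dmat[j, i] <- dij
    }
  }
  dmat
}
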