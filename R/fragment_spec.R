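# Declarative induced-fit refinement specifications: receptor fragments
# with mobility classes, positional tethers, hydrogen-bond distance
# restraints, and sampling directives. The refinement itself (Monte
# Carlo, minimization) is out of scope; the spec is the deliverable.

.ORTHO_TETHER_BW <- c("2.53", "2.56", "2.60", "2.63")
.ORTHO_RESTRAINT_BW <- c("1.39", "3.32", "7.36", "7.39", "7.40", "7.44")
.ALLO_RESTRAINT_BW <- c("8.49", "8.50")

#' @keywords internal
bw_helix <- function(generic_number) {
  h <- suppressWarnings(as.integer(sub("\\..*$", "", generic_number)))
  ifelse(!is.na(h) & h >= 1L & h <= 8L, h, NA_integer_)
}

#' Build an induced-fit fragment/restraint specification
#'
#' Constructs the declarative recipe for induced-fit conformational
#' optimization of a receptor-ligand complex:
#'
#' * seed residues are selected at residue granularity within
#'   `proximity_cutoff` (default 5.5 Angstrom) of the ligand;
#' * contiguous seed segments are expanded -- alternating N-/C-terminal
#'   growth starting N-terminal, with compensating extension at chain
#'   termini -- until each fragment is at least 9 residues long
#'   (orthosteric mode) or 18 (allosteric mode), then overlapping
#'   segments are merged;
#' * if a fragment contains one cysteine of an annotated disulfide, the
#'   partner cysteine's segment is added (and expanded) so the bond is
#'   never split across an included/excluded boundary;
#' * mobility is assigned per mode: orthosteric -- TM1, TM2 and TM7
#'   fragments fully flexible, all others side-chain-only; allosteric --
#'   TM6 and TM7-H8 fully flexible, TM1/TM2/TM3 side-chain-only with
#'   stationary backbones, TM4 and TM5 fragments omitted;
#' * positional tethers are placed on fragment-end backbone atoms, plus
#'   (orthosteric) the backbone carbons at BW 2.53, 2.56, 2.60, 2.63;
#' * hydrogen-bond distance restraints (1.8-2.4 Angstrom, weight 1.0)
#'   reference the side chains at BW 1.39, 3.32, 7.36, 7.39, 7.40, 7.44
#'   (orthosteric) or the backbone amides at BW 8.49 and 8.50
#'   (allosteric);
#' * sampling directives record 10,000 (orthosteric) or 100,000
#'   (allosteric) pre-minimization steps and 1e6 global Monte Carlo
#'   steps.
#'
#' @param structure an [annotated_structure()] with BW annotations.
#' @param ligand ligand group name, atom indices, or n x 3 coordinate
#'   matrix (passed to [select_proximal_atoms()]).
#' @param mode `"orthosteric"` or `"allosteric"`.
#' @param disulfides optional data.frame of disulfide bonds with columns
#'   `chain_a`, `resno_a`, `chain_b`, `resno_b`.
#' @param proximity_cutoff seed selection cutoff in Angstrom.
#' @param min_length override the per-mode minimum fragment length.
#' @return object of class `fragment_spec`.
#' @export
build_fragment_spec <- function(structure, ligand,
                                mode = c("orthosteric", "allosteric"),
                                disulfides = NULL,
                                proximity_cutoff = 5.5,
                                min_length = NULL) {
  mode <- match.arg(mode)
  if (is.null(structure$bw) || nrow(structure$bw) == 0L)
    stop("structure carries no BW annotations")
  min_length <- min_length %||% if (mode == "orthosteric") 9L else 18L

  anchors <- if (mode == "orthosteric")
    c(.ORTHO_TETHER_BW, .ORTHO_RESTRAINT_BW) else .ALLO_RESTRAINT_BW
  have <- anchors %in% structure$bw$generic_number
  if (!all(have))
    stop("required BW anchor(s) missing from annotation: ",
         paste(anchors[!have], collapse = ", "))

  at <- structure$atoms
  lig_res <- character()
  if (is.character(ligand) && length(ligand) == 1L) {
    ix <- structure$ligands[[ligand]]
    lig_res <- unique(paste(at$chain[ix], at$resno[ix]))
  } else if (!is.matrix(ligand) && !is.data.frame(ligand)) {
    ix <- as.integer(ligand)
    lig_res <- unique(paste(at$chain[ix], at$resno[ix]))
  }
  sel <- select_proximal_atoms(structure, ligand, proximity_cutoff,
                               granularity = "residue")
  seed <- attr(sel, "residues")
  seed <- seed[!(paste(seed$chain, seed$resno) %in% lig_res), , drop = FALSE]
  if (nrow(seed) == 0L)
    stop("no receptor residues within ", proximity_cutoff,
         " Angstrom of the ligand")

  # receptor residues available per chain (ligand residues excluded)
  chain_res <- lapply(split(at$resno, at$chain), function(r) sort(unique(r)))
  for (ch in names(chain_res)) {
    keep <- !(paste(ch, chain_res[[ch]]) %in% lig_res)
    chain_res[[ch]] <- chain_res[[ch]][keep]
  }

  segments <- seed_segments(seed)
  segments <- lapply(segments, expand_segment,
                     chain_res = chain_res, min_length = min_length)
  segments <- merge_segments(segments)

  # include disulfide partners, iterating to a fixed point
  if (!is.null(disulfides) && nrow(disulfides) > 0L) {
    repeat {
      added <- FALSE
      for (d in seq_len(nrow(disulfides))) {
        a_in <- covers(segments, disulfides$chain_a[d], disulfides$resno_a[d])
        b_in <- covers(segments, disulfides$chain_b[d], disulfides$resno_b[d])
        if (a_in == b_in) next
        miss <- if (a_in) list(chain = disulfides$chain_b[d],
                               resno = disulfides$resno_b[d])
                else list(chain = disulfides$chain_a[d],
                          resno = disulfides$resno_a[d])
        seg <- expand_segment(list(chain = miss$chain, start = miss$resno,
                                   end = miss$resno),
                              chain_res = chain_res, min_length = min_length)
        segments <- merge_segments(c(segments, list(seg)))
        added <- TRUE
      }
      if (!added) break
    }
  }

  frag <- do.call(rbind, lapply(segments, function(s) {
    data.frame(chain = s$chain, start = s$start, end = s$end,
               length = s$end - s$start + 1L, stringsAsFactors = FALSE)
  }))
  frag$helix <- vapply(seq_len(nrow(frag)), function(i) {
    segment_helix(structure, frag$chain[i], frag$start[i], frag$end[i])
  }, integer(1))

  if (mode == "allosteric") {
    omitted <- frag[frag$helix %in% c(4L, 5L), , drop = FALSE]
    frag <- frag[!(frag$helix %in% c(4L, 5L)), , drop = FALSE]
  } else {
    omitted <- frag[0, , drop = FALSE]
  }
  if (nrow(frag) == 0L) stop("no fragments remain after mode filtering")
  flex <- if (mode == "orthosteric") c(1L, 2L, 7L) else c(6L, 7L, 8L)
  frag$mobility <- ifelse(!is.na(frag$helix) & frag$helix %in% flex,
                          "fully_flexible", "sidechain_only")
  rownames(frag) <- NULL

  # tethers: fragment-end backbone atoms
  tethers <- do.call(rbind, lapply(seq_len(nrow(frag)), function(i) {
    ends <- unique(c(frag$start[i], frag$end[i]))
    do.call(rbind, lapply(ends, function(r) {
      sub <- at[at$chain == frag$chain[i] & at$resno == r &
                at$elety %in% c("N", "CA", "C"), , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      data.frame(chain = sub$chain, resno = sub$resno, elety = sub$elety,
                 kind = "fragment_end", stringsAsFactors = FALSE)
    }))
  }))
  if (mode == "orthosteric") {
    for (gn in .ORTHO_TETHER_BW) {
      hit <- structure$bw[structure$bw$generic_number == gn, ][1, ]
      sub <- at[at$chain == hit$chain & at$resno == hit$resno &
                at$elety %in% c("CA", "C"), , drop = FALSE]
      tethers <- rbind(tethers, data.frame(
        chain = sub$chain, resno = sub$resno, elety = sub$elety,
        kind = paste0("bw_", gn), stringsAsFactors = FALSE))
    }
  }
  tethers <- unique(tethers)
  rownames(tethers) <- NULL

  restr_bw <- if (mode == "orthosteric") .ORTHO_RESTRAINT_BW else .ALLO_RESTRAINT_BW
  restraints <- do.call(rbind, lapply(restr_bw, function(gn) {
    hit <- structure$bw[structure$bw$generic_number == gn, ][1, ]
    data.frame(generic_number = gn, chain = hit$chain, resno = hit$resno,
               atoms = if (mode == "orthosteric") "sidechain_polar"
                       else "backbone_amide",
               min = 1.8, max = 2.4, weight = 1.0,
               stringsAsFactors = FALSE)
  }))

  spec <- structure(list(
    mode = mode,
    min_length = min_length,
    fragments = frag,
    omitted = omitted,
    tethers = tethers,
    restraints = restraints,
    sampling = list(
      pre_minimization_steps = if (mode == "orthosteric") 1e4 else 1e5,
      global_steps = 1e6)),
    class = "fragment_spec")
  validate_fragment_spec(spec, disulfides = disulfides)
  spec
}

#' @keywords internal
seed_segments <- function(seed) {
  out <- list()
  for (ch in unique(seed$chain)) {
    r <- sort(unique(seed$resno[seed$chain == ch]))
    brk <- c(0L, which(diff(r) > 1L), length(r))
    for (k in seq_len(length(brk) - 1L)) {
      run <- r[(brk[k] + 1L):brk[k + 1L]]
      out[[length(out) + 1L]] <- list(chain = ch, start = min(run),
                                      end = max(run))
    }
  }
  out
}

# Alternate N-/C-terminal growth starting N-terminal; a blocked end
# (chain terminus, or numbering gap treated as a terminus) is compensated
# by extending the open end.
#' @keywords internal
expand_segment <- function(seg, chain_res, min_length) {
  avail <- chain_res[[seg$chain]]
  grow_n <- TRUE
  while (seg$end - seg$start + 1L < min_length) {
    can_n <- (seg$start - 1L) %in% avail
    can_c <- (seg$end + 1L) %in% avail
    if (!can_n && !can_c) break
    if (grow_n && can_n) {
      seg$start <- seg$start - 1L
    } else if (can_c) {
      seg$end <- seg$end + 1L
    } else {
      seg$start <- seg$start - 1L
    }
    grow_n <- !grow_n
  }
  seg
}

#' @keywords internal
merge_segments <- function(segments) {
  out <- list()
  for (ch in unique(vapply(segments, `[[`, "", "chain"))) {
    segs <- Filter(function(s) s$chain == ch, segments)
    segs <- segs[order(vapply(segs, `[[`, 0L, "start"))]
    cur <- segs[[1]]
    for (s in segs[-1]) {
      if (s$start <= cur$end + 1L) {
        cur$end <- max(cur$end, s$end)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- s
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  out
}

#' @keywords internal
covers <- function(segments, chain, resno) {
  any(vapply(segments, function(s) {
    s$chain == chain && resno >= s$start && resno <= s$end
  }, logical(1)))
}

#' @keywords internal
segment_helix <- function(structure, chain, start, end) {
  bw <- structure$bw
  h <- bw_helix(bw$generic_number[bw$chain == chain &
                                  bw$resno >= start & bw$resno <= end])
  h <- h[!is.na(h)]
  if (!length(h)) return(NA_integer_)
  tab <- sort(table(h), decreasing = TRUE)
  as.integer(names(tab)[1])
}

#' Validate a fragment specification
#'
#' Independent checker for the construction invariants: every fragment
#' meets the mode's minimum length, mobility values are legal, restraint
#' bounds are ordered, and no annotated disulfide is split across an
#' included/excluded boundary.
#'
#' @param spec a `fragment_spec`.
#' @param disulfides optional disulfide table as in
#'   [build_fragment_spec()].
#' @return `TRUE` (invisibly); errors otherwise.
#' @export
validate_fragment_spec <- function(spec, disulfides = NULL) {
  stopifnot(inherits(spec, "fragment_spec"))
  f <- spec$fragments
  if (any(f$length < spec$min_length))
    stop("fragment(s) below minimum length ", spec$min_length, ": ",
         paste(sprintf("%s:%d-%d", f$chain, f$start, f$end)[
           f$length < spec$min_length], collapse = ", "))
  if (!all(f$mobility %in% c("stationary", "sidechain_only", "fully_flexible")))
    stop("illegal mobility value")
  if (any(f$length != f$end - f$start + 1L))
    stop("inconsistent fragment length bookkeeping")
  r <- spec$restraints
  if (nrow(r) && any(r$min >= r$max))
    stop("restraint min must be below max")
  if (!is.null(disulfides) && nrow(disulfides)) {
    segs <- lapply(seq_len(nrow(f)), function(i)
      list(chain = f$chain[i], start = f$start[i], end = f$end[i]))
    for (d in seq_len(nrow(disulfides))) {
      a <- covers(segs, disulfides$chain_a[d], disulfides$resno_a[d])
      b <- covers(segs, disulfides$chain_b[d], disulfides$resno_b[d])
      if (a != b)
        stop("disulfide ", disulfides$chain_a[d], disulfides$resno_a[d],
             "-", disulfides$chain_b[d], disulfides$resno_b[d],
             " split across the fragment boundary")
    }
  }
  invisible(TRUE)
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat("fragment_spec (", x$mode, " mode, min length ", x$min_length,
      " aa):\n", sep = "")
  print(x$fragments)
  cat(nrow(x$tethers), "tether atom(s),", nrow(x$restraints),
      "distance restraint(s);",
      "pre-minimization", format(x$sampling$pre_minimization_steps,
                                 scientific = FALSE),
      "steps, global", format(x$sampling$global_steps, scientific = TRUE),
      "steps\n")
  invisible(x)
}

#' Write a fragment specification to JSON
#'
#' @param spec a `fragment_spec`.
#' @param path output file.
#' @export
write_fragment_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
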