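# Receptor structures with Ballesteros-Weinstein (BW) annotations:
# loading, superposition, distance tables, proximity selections,
# sampling boxes, mutation-edit bookkeeping.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

.AA_SIDECHAIN <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' @keywords internal
aa3 <- function(x) {
  x <- toupper(x)
  ifelse(nchar(x) == 1L, unname(.AA1TO3[x]), x)
}

#' Construct an annotated structure
#'
#' Atomic coordinates with chain/residue identity, occupancies, optional
#' Ballesteros-Weinstein generic numbers per residue, and named ligand
#' atom groups.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resid`, `elety`, `x`, `y`, `z`, `o`.
#' @param bw data.frame with columns `chain`, `resno`, `generic_number`
#'   (strings like `"2.63"`, loop notation `"45.52"`, helix-8 `"8.49"`);
#'   may be `NULL`.
#' @param ligands named list of integer atom-row indices.
#' @return object of class `annotated_structure`.
#' @export
annotated_structure <- function(atoms, bw = NULL, ligands = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!"o" %in% names(atoms)) atoms$o <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name): ",
         gsub("\r", "/", key[duplicated(key)][1]))
  if (!is.null(bw)) {
    stopifnot(all(c("chain", "resno", "generic_number") %in% names(bw)))
    if (anyDuplicated(paste(bw$chain, bw$resno)))
      stop("duplicate BW assignment to one residue")
    if (anyDuplicated(paste(bw$chain, bw$generic_number)))
      stop("BW map not injective within a chain")
  }
  structure(list(atoms = atoms, bw = bw, ligands = ligands),
            class = "annotated_structure")
}

#' @export
print.annotated_structure <- function(x, ...) {
  cat("annotated_structure:", nrow(x$atoms), "atoms,",
      nrow(unique(x$atoms[, c("chain", "resno", "insert")])), "residues,",
      if (is.null(x$bw)) 0L else nrow(x$bw), "BW annotations,",
      length(x$ligands), "ligand group(s)\n")
  invisible(x)
}

#' Load a receptor structure and attach BW annotations
#'
#' Reads a PDB or mmCIF file (via bio3d), keeps altloc A where alternate
#' locations exist, splits non-water HETATM records into named ligand
#' groups, and joins a user-supplied Ballesteros-Weinstein mapping table
#' (TSV columns: `chain`, `resnum`, `generic_number`). Mapping rows that
#' reference residues absent from the file are reported in the
#' `$unmatched` element, never silently dropped.
#'
#' @param structure_file PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param bw_file optional TSV mapping file.
#' @param format `"pdb"`, `"cif"`, or `NULL` to infer from the extension.
#' @return an [annotated_structure()] with an extra `$unmatched`
#'   data.frame.
#' @export
load_and_annotate <- function(structure_file, bw_file = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.cif$", structure_file, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(structure_file)
    else bio3d::read.pdb(structure_file),
    error = function(e) stop("malformed coordinate file '", structure_file,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  het <- at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT"))
  ligands <- list()
  if (any(het)) {
    grp <- paste(at$resid, at$chain, at$resno, sep = "_")[het]
    ligands <- lapply(split(which(het), grp), as.integer)
  }
  bw <- NULL
  unmatched <- data.frame(chain = character(), resno = integer(),
                          generic_number = character(),
                          stringsAsFactors = FALSE)
  if (!is.null(bw_file)) {
    map <- utils::read.delim(bw_file, stringsAsFactors = FALSE)
    names(map)[names(map) == "resnum"] <- "resno"
    stopifnot(all(c("chain", "resno", "generic_number") %in% names(map)))
    map$generic_number <- as.character(map$generic_number)
    present <- paste(map$chain, map$resno) %in%
      paste(atoms$chain, atoms$resno)
    unmatched <- map[!present, c("chain", "resno", "generic_number")]
    if (nrow(unmatched))
      message(nrow(unmatched), " BW mapping row(s) reference residues ",
              "absent from the structure; see $unmatched")
    bw <- map[present, c("chain", "resno", "generic_number")]
  }
  out <- annotated_structure(atoms, bw = bw, ligands = ligands)
  out$unmatched <- unmatched
  out
}

#' Write an annotated structure to PDB
#'
#' @param structure an [annotated_structure()].
#' @param path output PDB file. Atoms without coordinates (occupancy-0
#'   placeholders) are skipped.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  at <- at[!is.na(at$x), , drop = FALSE]
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain, resid = at$resid,
                   elety = at$elety, o = at$o)
  invisible(path)
}

#' @keywords internal
bw_lookup <- function(structure, generic_number, atom_name = "CA") {
  bw <- structure$bw
  if (is.null(bw)) return(NULL)
  hit <- bw[bw$generic_number == generic_number, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  at <- structure$atoms
  sel <- at$chain == hit$chain[1] & at$resno == hit$resno[1] &
    at$elety == atom_name
  if (!any(sel)) return(NULL)
  which(sel)[1]
}

#' Superpose two structures by their backbones
#'
#' Least-squares rigid-body (Kabsch) fit of the mobile structure onto the
#' reference, over backbone atoms of residues matched by BW generic
#' number (or, without annotations, by chain and residue number). The
#' reference is unchanged; the fit is applied to every mobile atom.
#'
#' @param reference,mobile [annotated_structure()] objects.
#' @param selection optional character vector of BW generic numbers to
#'   restrict the fit (e.g. a TM-domain range); default: all matched
#'   residues.
#' @param atom_names backbone atom names used in the fit (default
#'   `"CA"`).
#' @return list with `mobile` (transformed copy), `rmsd` (Angstrom, over
#'   the fitted atoms) and `n_atoms`.
#' @export
superpose_backbones <- function(reference, mobile, selection = NULL,
                                atom_names = "CA") {
  ref_key <- residue_match_keys(reference)
  mob_key <- residue_match_keys(mobile)
  common <- intersect(ref_key$key, mob_key$key)
  if (!is.null(selection)) {
    if (is.null(reference$bw) || is.null(mobile$bw))
      stop("BW selection requires annotated structures")
    common <- intersect(common, selection)
  }
  ref_xyz <- NULL; mob_idx <- integer()
  mob_at <- mobile$atoms; ref_at <- reference$atoms
  for (k in common) {
    rres <- ref_key[ref_key$key == k, ][1, ]
    mres <- mob_key[mob_key$key == k, ][1, ]
    for (an in atom_names) {
      ri <- which(ref_at$chain == rres$chain & ref_at$resno == rres$resno &
                  ref_at$elety == an & !is.na(ref_at$x))
      mi <- which(mob_at$chain == mres$chain & mob_at$resno == mres$resno &
                  mob_at$elety == an & !is.na(mob_at$x))
      if (length(ri) && length(mi)) {
        ref_xyz <- rbind(ref_xyz, as.numeric(ref_at[ri[1], c("x", "y", "z")]))
        mob_idx <- c(mob_idx, mi[1])
      }
    }
  }
  if (length(mob_idx) < 3L)
    stop("need at least 3 matched backbone atoms (have ", length(mob_idx), ")")
  mob_xyz <- as.matrix(mob_at[mob_idx, c("x", "y", "z")])
  all_xyz <- as.matrix(mob_at[, c("x", "y", "z")])
  moved <- kabsch_apply(mob_xyz, ref_xyz, all_xyz)
  fitted <- moved[mob_idx, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - ref_xyz)^2)))
  out <- mobile
  out$atoms$x <- moved[, 1]; out$atoms$y <- moved[, 2]; out$atoms$z <- moved[, 3]
  list(mobile = out, rmsd = rmsd, n_atoms = length(mob_idx))
}

#' @keywords internal
residue_match_keys <- function(structure) {
  if (!is.null(structure$bw) && nrow(structure$bw) > 0L) {
    data.frame(key = structure$bw$generic_number,
               chain = structure$bw$chain, resno = structure$bw$resno,
               stringsAsFactors = FALSE)
  } else {
    res <- unique(structure$atoms[, c("chain", "resno")])
    data.frame(key = paste(res$chain, res$resno, sep = ":"),
               chain = res$chain, resno = res$resno,
               stringsAsFactors = FALSE)
  }
}

# Kabsch fit of `from` onto `onto`; the resulting rigid transform is
# applied to `apply_to` (NA rows pass through).
#' @keywords internal
kabsch_apply <- function(from, onto, apply_to) {
  cf <- colMeans(from); co <- colMeans(onto)
  A <- sweep(from, 2, cf); B <- sweep(onto, 2, co)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(apply_to, 2, cf)
  moved <- t(R %*% t(moved))
  sweep(moved, 2, co, "+")
}

#' Table of Calpha-Calpha distances at BW positions across structures
#'
#' For each structure (row) and each BW residue pair (column), the
#' Euclidean Calpha-Calpha distance in Angstrom. Distances are
#' intra-structure, hence invariant to superposition. Pairs unresolvable
#' in a given structure yield `NA` cells, flagged in the `"missing"`
#' attribute; a pair unresolvable in every structure is an error.
#'
#' @param structures named list of [annotated_structure()] objects.
#' @param pairs data.frame with columns `bw_i`, `bw_j`, or a character
#'   vector of `"i-j"` strings (e.g. `"3.29-7.43"`).
#' @return numeric matrix, one row per structure, one column per pair
#'   (named `"i-j"`).
#' @export
bw_distance_table <- function(structures, pairs) {
  if (is.character(pairs)) {
    sp <- strsplit(pairs, "-", fixed = TRUE)
    pairs <- data.frame(bw_i = vapply(sp, `[`, "", 1),
                        bw_j = vapply(sp, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("bw_i", "bw_j") %in% names(pairs)))
  if (is.null(names(structures)))
    names(structures) <- paste0("structure", seq_along(structures))
  cn <- paste(pairs$bw_i, pairs$bw_j, sep = "-")
  out <- matrix(NA_real_, length(structures), nrow(pairs),
                dimnames = list(names(structures), cn))
  missing <- data.frame(structure = character(), pair = character(),
                        stringsAsFactors = FALSE)
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    for (p in seq_len(nrow(pairs))) {
      i <- bw_lookup(st, pairs$bw_i[p], "CA")
      j <- bw_lookup(st, pairs$bw_j[p], "CA")
      if (is.null(i) || is.null(j)) {
        missing <- rbind(missing, data.frame(
          structure = names(structures)[s], pair = cn[p]))
        next
      }
      a <- as.numeric(st$atoms[i, c("x", "y", "z")])
      b <- as.numeric(st$atoms[j, c("x", "y", "z")])
      out[s, p] <- sqrt(sum((a - b)^2))
    }
  }
  dead <- colSums(!is.na(out)) == 0L
  if (any(dead))
    stop("pair(s) unresolvable in every structure: ",
         paste(cn[dead], collapse = ", "))
  attr(out, "missing") <- missing
  out
}

#' Reconstructed default BW residue pairs for pocket-geometry comparison
#'
#' A default set of transmembrane residue pairs probing the orthosteric
#' pocket "floor" (position 3.29 against the TM6/TM7 wall) and the
#' TM1-TM7 fenestration. This list is reconstructed from the pairs
#' discussed in the accompanying analysis narrative, not a published
#' table; adjust freely.
#'
#' @return data.frame with columns `bw_i`, `bw_j`.
#' @export
default_bw_pairs <- function() {
  data.frame(
    bw_i = c("3.29", "3.29", "3.29", "1.39", "1.39"),
    bw_j = c("6.48", "7.40", "7.43", "7.40", "7.43"),
    stringsAsFactors = FALSE)
}

#' Select atoms near a reference group
#'
#' Distance-based neighborhood selection: at `granularity = "atom"`,
#' atoms whose distance to any reference atom is at most `cutoff`; at
#' `"residue"`, all atoms of any residue with at least one such atom.
#' Reference atoms themselves are excluded from the result.
#'
#' @param structure an [annotated_structure()].
#' @param reference a ligand group name, integer atom indices, or an
#'   n x 3 coordinate matrix.
#' @param cutoff distance cutoff in Angstrom.
#' @param granularity `"atom"` or `"residue"`.
#' @return sorted integer atom indices, with attribute `"residues"`
#'   (data.frame `chain`, `resno`).
#' @export
select_proximal_atoms <- function(structure, reference, cutoff,
                                  granularity = c("atom", "residue")) {
  granularity <- match.arg(granularity)
  at <- structure$atoms
  ref_idx <- integer()
  if (is.character(reference) && length(reference) == 1L) {
    if (!reference %in% names(structure$ligands))
      stop("unknown ligand group '", reference, "'")
    ref_idx <- structure$ligands[[reference]]
    ref <- as.matrix(at[ref_idx, c("x", "y", "z")])
  } else if (is.matrix(reference) || is.data.frame(reference)) {
    ref <- as.matrix(reference)
    stopifnot(ncol(ref) == 3L)
  } else {
    ref_idx <- as.integer(reference)
    ref <- as.matrix(at[ref_idx, c("x", "y", "z")])
  }
  if (nrow(ref) == 0L) stop("empty reference group")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2min <- rep(Inf, nrow(xyz))
  ok <- !is.na(xyz[, 1])
  for (r in seq_len(nrow(ref))) {
    d2 <- rowSums(sweep(xyz, 2, ref[r, ])^2)
    d2min <- pmin(d2min, d2, na.rm = FALSE)
  }
  hit <- ok & d2min <= cutoff^2
  hit[ref_idx] <- FALSE
  if (granularity == "residue") {
    reskey <- paste(at$chain, at$resno, at$insert, sep = "\r")
    hit_res <- unique(reskey[hit])
    hit <- reskey %in% hit_res
    hit[ref_idx] <- FALSE
  }
  idx <- which(hit)
  res <- unique(at[idx, c("chain", "resno")])
  rownames(res) <- NULL
  attr(idx, "residues") <- res
  idx
}

#' Axis-aligned sampling box around a ligand envelope
#'
#' The compound-sampling space of a docking run: the bounding box of the
#' supplied points expanded by a margin in each direction (default 4
#' Angstrom per axis).
#'
#' @param points n x 3 coordinate matrix (or data.frame with `x`, `y`,
#'   `z`).
#' @param margin margin in Angstrom added on every side.
#' @return object of class `envelope_box`: list with `min`, `max`
#'   (length-3 corners), `margin`, `n_points`.
#' @export
build_envelope_box <- function(points, margin = 4) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  stopifnot(is.matrix(points), ncol(points) == 3L)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) == 0L) stop("empty point set")
  structure(list(min = apply(points, 2, min) - margin,
                 max = apply(points, 2, max) + margin,
                 margin = margin, n_points = nrow(points)),
            class = "envelope_box")
}

#' @export
print.envelope_box <- function(x, ...) {
  cat(sprintf("envelope_box: [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] (margin %g A, %d points)\n",
              x$min[1], x$max[1], x$min[2], x$max[2], x$min[3], x$max[3],
              x$margin, x$n_points))
  invisible(x)
}

#' Apply mutation-reversion edits to a structure
#'
#' Bookkeeping for reverting engineered (e.g. thermostabilizing)
#' mutations: each edit renames a residue, removes side-chain atoms that
#' the target residue does not have (shrinking edits, e.g. to Ala,
#' truncate to Cbeta), and adds placeholder records for target atoms not
#' present, flagged with occupancy 0 and no invented coordinates. No
#' side-chain rebuilding is performed.
#'
#' @param structure an [annotated_structure()].
#' @param edits data.frame with columns `chain`, `resno`, `from`, `to`
#'   (1- or 3-letter residue codes).
#' @return the edited structure.
#' @export
apply_mutation_edits <- function(structure, edits) {
  stopifnot(is.data.frame(edits),
            all(c("chain", "resno", "from", "to") %in% names(edits)))
  at <- structure$atoms
  # ligand groups are row indices; remember them by atom identity so they
  # survive row insertion/removal
  lig_keys <- lapply(structure$ligands, function(ix)
    paste(at$chain[ix], at$resno[ix], at$insert[ix], at$elety[ix], sep = "\r"))
  for (e in seq_len(nrow(edits))) {
    from <- aa3(edits$from[e]); to <- aa3(edits$to[e])
    if (!to %in% names(.AA_SIDECHAIN))
      stop("unknown target residue type '", to, "'")
    sel <- at$chain == edits$chain[e] & at$resno == edits$resno[e]
    if (!any(sel))
      stop("residue ", edits$chain[e], "/", edits$resno[e], " not found")
    cur <- unique(at$resid[sel])
    if (!identical(cur, from))
      stop("residue ", edits$chain[e], "/", edits$resno[e], " is ", cur,
           ", not ", from, " as claimed by the edit")
    keep_names <- c(.BACKBONE, .AA_SIDECHAIN[[to]])
    drop <- sel & !(at$elety %in% keep_names) &
      !grepl("^H", at$elety)   # hydrogens, if present, pass through
    new_names <- setdiff(.AA_SIDECHAIN[[to]], at$elety[sel])
    at$resid[sel] <- to
    at <- at[!drop, , drop = FALSE]
    if (length(new_names)) {
      tmpl <- at[which(at$chain == edits$chain[e] &
                       at$resno == edits$resno[e])[1], , drop = FALSE]
      add <- tmpl[rep(1, length(new_names)), , drop = FALSE]
      add$elety <- new_names
      add$x <- NA_real_; add$y <- NA_real_; add$z <- NA_real_
      add$o <- 0
      add$resid <- to
      at <- rbind(at, add)
    }
  }
  rownames(at) <- NULL
  structure$atoms <- at
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  structure$ligands <- lapply(lig_keys, function(k) match(k, key))
  structure
}
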