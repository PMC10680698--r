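# SMILES handling and 2D circular fingerprints.
#
# All SMILES interpretation (valence model, aromaticity, canonicalization)
# is delegated to OpenBabel through ChemmineOB; this file only extracts the
# heavy-atom graph from OpenBabel's V2000 output and hashes atom
# environments into a fixed-width bit set.

# Atomic numbers for elements OpenBabel may emit in small-molecule work.
.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Zn = 30, Se = 34, Br = 35, I = 53
)

#' @keywords internal
ob_canonical_smiles <- function(smiles, strip_stereo = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(trimws(smiles)))
    stop("empty SMILES string")
  props <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, " m\n"),
                           function(m) ChemmineOB::prop_OB(m)),
    error = function(e) stop("unparsable SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(props) != 1L)
    stop("unparsable SMILES '", smiles, "'", call. = FALSE)
  can <- if (strip_stereo) props[[1]]$cansmiNS else props[[1]]$cansmi
  if (is.null(can) || !nzchar(can))
    stop("unparsable SMILES '", smiles, "'", call. = FALSE)
  can
}

# Parse one V2000 molblock (as produced by OpenBabel) into atom and bond
# tables. Handles bond-less (single heavy atom) molecules, which the
# SDFset container cannot.
#' @keywords internal
parse_molblock <- function(lines) {
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L)
    stop("malformed molblock: bad counts line")
  atom_lines <- lines[4 + seq_len(natoms)]
  atoms <- data.frame(
    elem   = trimws(substr(atom_lines, 32, 34)),
    charge = 0L,
    stringsAsFactors = FALSE
  )
  bonds <- if (nbonds > 0L) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    data.frame(
      a1    = as.integer(substr(bl, 1, 3)),
      a2    = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) {
      atoms$charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# SMILES -> heavy-atom graph via OpenBabel canonical SMILES and SDF.
#' @keywords internal
smiles_to_graph <- function(smiles, strip_stereo = TRUE) {
  can <- ob_canonical_smiles(smiles, strip_stereo = strip_stereo)
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(can, " m\n"))
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  parse_molblock(lines)
}

# Order-independent integer hashing in exact double arithmetic
# (all intermediates < 2^53).
.HASH_MOD <- 2147483629
#' @keywords internal
hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 131 + (v %% .HASH_MOD)) %% .HASH_MOD
  h
}

#' Hashed circular 2D fingerprint of a molecule
#'
#' Computes a stereochemistry-insensitive, connectivity-based circular
#' substructure fingerprint (ECFP-like): each heavy atom's environment out
#' to `radius` bonds is hashed into a fixed-width bit set. The input SMILES
#' is first round-tripped through OpenBabel's stereo-free canonical SMILES,
#' so any two SMILES of the same 2D molecule -- including stereoisomer
#' pairs -- yield identical fingerprints.
#'
#' @param structure a single SMILES string.
#' @param radius circular environment radius in bonds (default 2).
#' @param n_bits width of the hashed bit space (default 2048).
#' @return sorted integer vector of on-bit indices in `1:n_bits`, with
#'   attribute `n_bits`.
#' @examples
#' fp1 <- compute_fingerprint("CCO")
#' fp2 <- compute_fingerprint("OCC")
#' identical(fp1, fp2)
#' @export
compute_fingerprint <- function(structure, radius = 2L, n_bits = 2048L) {
  g <- smiles_to_graph(structure, strip_stereo = TRUE)
  n <- nrow(g$atoms)
  znum <- .ELEMENTS[g$atoms$elem]
  znum[is.na(znum)] <- 0
  deg <- integer(n)
  bsum <- integer(n)
  nbrs <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[b]; a2 <- g$bonds$a2[b]; o <- g$bonds$order[b]
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
      bsum[a1] <- bsum[a1] + o; bsum[a2] <- bsum[a2] + o
      nbrs[[a1]] <- rbind(nbrs[[a1]], c(o, a2))
      nbrs[[a2]] <- rbind(nbrs[[a2]], c(o, a1))
    }
  }
  codes <- vapply(seq_len(n), function(i) {
    hash_ints(c(znum[i], deg[i], bsum[i], g$atoms$charge[i] + 8L))
  }, numeric(1))
  all_codes <- codes
  for (r in seq_len(radius)) {
    new_codes <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (is.null(nb)) return(hash_ints(c(r, codes[i])))
      pairs <- cbind(nb[, 1], codes[nb[, 2]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_ints(c(r, codes[i], as.vector(t(pairs))))
    }, numeric(1))
    codes <- new_codes
    all_codes <- c(all_codes, codes)
  }
  bits <- sort(unique(as.integer(all_codes %% n_bits) + 1L))
  structure(bits, n_bits = as.integer(n_bits))
}

#' Tanimoto distance and similarity between fingerprint bit sets
#'
#' `tanimoto_similarity` is |intersection| / |union| of the on-bit sets;
#' `tanimoto_distance` is its complement. Two empty bit sets are defined as
#' identical (distance 0) with a warning.
#'
#' @param a,b integer vectors of on-bit indices (as returned by
#'   [compute_fingerprint()]).
#' @return a number in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  1 - tanimoto_similarity(a, b)
}

#' @rdname tanimoto_distance
#' @export
tanimoto_similarity <- function(a, b) {
  if (is.null(a) || is.null(b))
    stop("fingerprints must be non-null")
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) == 0L && length(b) == 0L) {
    warning("both fingerprints empty; similarity defined as 1")
    return(1)
  }
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Physicochemical property vector of a molecule
#'
#' Computes the six-descriptor property set used for property-matched decoy
#' selection (the DUD-E convention): molecular weight, an additive
#' atomic-contribution logP estimate, hydrogen-bond donor and acceptor
#' counts, rotatable-bond count, and net formal charge. Descriptors come
#' from OpenBabel; rotatable bonds are counted with the standard
#' non-ring-single-bond SMARTS pattern.
#'
#' @param structure a SMILES string (vectorized).
#' @return data.frame with one row per input and columns `mol_weight`,
#'   `logp_estimate`, `hbd`, `hba`, `rotatable_bonds`, `formal_charge`.
#' @examples
#' compute_property_vector("CCO")
#' @export
compute_property_vector <- function(structure) {
  res <- lapply(structure, function(smi) {
    g <- smiles_to_graph(smi, strip_stereo = TRUE)
    out <- ChemmineOB::forEachMol("SMILES", paste0(smi, " m\n"), function(m) {
      p <- ChemmineOB::prop_OB(m)
      rb <- ChemmineOB::smartsSearch_OB(
        list(m), "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
      data.frame(
        mol_weight      = p$MW,
        logp_estimate   = p$logP,
        hbd             = as.integer(p$HBD),
        hba             = as.integer(p$HBA1),
        rotatable_bonds = as.integer(rb[[1]]),
        formal_charge   = sum(g$atoms$charge)
      )
    })
    out[[1]]
  })
  do.call(rbind, res)
}
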