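# Idealized helix-bundle fixture generator: Calpha traces of vertical
# alpha-helices with BW-style generic numbering, optionally in a second
# conformational state produced by per-helix rigid shifts.

#' Default helix layout for a 7TM + helix-8 bundle
#'
#' Seven transmembrane helices on a ring (default radius 11 Angstrom)
#' plus a short helix 8 placed outside the ring near the intracellular
#' end. BW positions are centered on x.50 at mid-helix.
#'
#' @param n_helices number of ring helices (default 7).
#' @param ring_radius ring radius in Angstrom.
#' @param residues_per_helix residues per ring helix; the default spans
#'   BW positions 32-67, covering the usual pocket anchor positions.
#' @param helix8 include a short helix 8 (default `TRUE`).
#' @return data.frame with columns `helix`, `x`, `y`, `z0`, `n_res`,
#'   `bw_start` usable as the `helices` argument of
#'   [gen_helix_bundle()].
#' @export
default_helix_layout <- function(n_helices = 7L, ring_radius = 11,
                                 residues_per_helix = 36L,
                                 helix8 = TRUE) {
  ang <- 2 * pi * (seq_len(n_helices) - 1L) / n_helices
  out <- data.frame(
    helix = seq_len(n_helices),
    x = ring_radius * cos(ang),
    y = ring_radius * sin(ang),
    z0 = 0,
    n_res = residues_per_helix,
    bw_start = 50L - residues_per_helix %/% 2L)
  if (helix8) {
    out <- rbind(out, data.frame(
      helix = 8L, x = 1.6 * ring_radius, y = 0, z0 = 0,
      n_res = 20L, bw_start = 40L))
  }
  out
}

#' Generate an idealized helix-bundle structure
#'
#' Builds ideal alpha-helical Calpha traces (rise 1.5 Angstrom/residue,
#' twist 100 degrees/residue, backbone radius 2.3 Angstrom -- giving the
#' canonical ~3.8 Angstrom consecutive Calpha spacing) on vertical axes
#' at the given positions, annotates each residue with a BW-style
#' generic number `"helix.position"`, and optionally applies per-helix
#' rigid shift vectors to emulate a second ("active-like")
#' conformational state.
#'
#' @param helices data.frame as from [default_helix_layout()].
#' @param rise helical rise per residue, Angstrom.
#' @param twist helical twist per residue, degrees.
#' @param radius Calpha radius from the helix axis, Angstrom.
#' @param state_shifts optional named list mapping helix number to a
#'   length-3 shift vector.
#' @param chain chain identifier.
#' @return an [annotated_structure()] of Calpha atoms.
#' @export
gen_helix_bundle <- function(helices = default_helix_layout(),
                             rise = 1.5, twist = 100, radius = 2.3,
                             state_shifts = NULL, chain = "A") {
  stopifnot(is.data.frame(helices), nrow(helices) >= 1L)
  pos_key <- paste(round(helices$x, 6), round(helices$y, 6))
  if (anyDuplicated(pos_key))
    warning("overlapping helix axes")
  atoms <- NULL
  bw <- NULL
  for (h in seq_len(nrow(helices))) {
    hh <- helices[h, ]
    i <- seq_len(hh$n_res)
    theta <- (i - 1L) * twist * pi / 180
    xyz <- cbind(hh$x + radius * cos(theta),
                 hh$y + radius * sin(theta),
                 hh$z0 + (i - 1L) * rise)
    if (!is.null(state_shifts)) {
      sh <- state_shifts[[as.character(hh$helix)]]
      if (!is.null(sh)) xyz <- sweep(xyz, 2, sh, "+")
    }
    resno <- hh$helix * 100L + i
    atoms <- rbind(atoms, data.frame(
      chain = chain, resno = resno, insert = "", resid = "ALA",
      elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
      stringsAsFactors = FALSE))
    bw <- rbind(bw, data.frame(
      chain = chain, resno = resno,
      generic_number = sprintf("%d.%d", hh$helix, hh$bw_start + i - 1L),
      stringsAsFactors = FALSE))
  }
  annotated_structure(atoms, bw = bw)
}
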