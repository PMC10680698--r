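# In-code fixtures shared across test files.

# A small library with synthetic fingerprints/properties assigned
# directly (no SMILES needed).
make_tiny_library <- function() {
  comp <- data.frame(
    compound_id = c("act1", "act2", "weak1", "dec1"),
    smiles = NA_character_,
    alias = NA_character_,
    chemotype = c("BMS", "BMS", "BMS", NA),
    role = c("unassigned", "unassigned", "unassigned", "decoy"),
    stringsAsFactors = FALSE)
  acts <- data.frame(
    compound_id = c("act1", "act2", "weak1"),
    receptor = "hCCR2", site = "orthosteric", measure = "IC50",
    value_M = 10^-c(9.1, 8.2, 5.5), pactivity = c(9.1, 8.2, 5.5),
    stringsAsFactors = FALSE)
  fps <- list(act1 = c(1L, 2L, 3L, 4L), act2 = c(1L, 2L, 3L, 5L),
              weak1 = c(1L, 2L, 6L, 7L), dec1 = c(100L, 101L))
  props <- data.frame(
    compound_id = comp$compound_id,
    mol_weight = c(400, 410, 395, 405),
    logp_estimate = c(3.0, 3.2, 2.9, 3.1),
    hbd = c(2L, 2L, 1L, 2L), hba = c(5L, 5L, 4L, 5L),
    rotatable_bonds = c(6L, 6L, 5L, 6L), formal_charge = c(0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  screening_library(comp, acts, fps, props,
                    thresholds = c(BMS = 7.5, ".default" = 7.5))
}

# Pose table with a known two-stage structure: FA picks pose 1 of model A
# (-30), whose RTCNN value (-5) differs from the RTCNN-best pose.
make_scheme_table <- function() {
  pose_score_table(data.frame(
    compound_id = rep("c1", 4),
    model_id = rep(c("mA", "mB"), each = 2),
    pose_id = c(1L, 2L, 1L, 2L),
    FA = c(-30, -25, -20, -28),
    RTCNN = c(-5, -9, -1, -2)))
}

# Random pose table over n compounds, m models, p poses, two scorers.
random_pose_table <- function(n = 12, m = 3, p = 4, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(pose_id = seq_len(p),
                      model_id = sprintf("m%d", seq_len(m)),
                      compound_id = sprintf("c%02d", seq_len(n)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("compound_id", "model_id", "pose_id")]
  grid$FA <- rnorm(nrow(grid), -10, 4)
  grid$RTCNN <- rnorm(nrow(grid), -10, 4)
  pose_score_table(grid)
}

# Toy receptor-ligand complex: idealized 7TM+H8 bundle with a one-atom
# ligand placed radially outward from a single mid-helix Calpha, so the
# 5.5-Angstrom residue-level seed is deliberately short (1-5 residues).
make_toy_complex <- function(helix = 1L, offset = 4.5) {
  st <- gen_helix_bundle()
  at <- st$atoms
  mid <- at[at$resno == helix * 100L + 18L, ]
  # point away from the bundle center so no other helix enters the cutoff
  dir <- c(mid$x, mid$y, 0)
  dir <- dir / sqrt(sum(dir^2))
  lig <- matrix(c(mid$x, mid$y, mid$z) + offset * dir, 1, 3)
  list(structure = st, ligand = lig)
}

# Degenerate single-file chain: Calpha atoms on a straight line 3.8 A
# apart, BW-numbered as seven consecutive 36-residue helices. A ligand
# 5.4 A from one Calpha seeds exactly one residue (neighbors sit at
# sqrt(5.4^2 + 3.8^2) > 5.5), so fragment expansion must reach exactly
# the per-mode minimum.
make_line_complex <- function(seed_residue = 30L) {
  n <- 7L * 36L
  resno <- seq_len(n)
  helix <- (resno - 1L) %/% 36L + 1L
  pos <- (resno - 1L) %% 36L + 32L
  at <- data.frame(chain = "A", resno = resno, insert = "", resid = "ALA",
                   elety = "CA", x = 3.8 * (resno - 1L), y = 0, z = 0, o = 1,
                   stringsAsFactors = FALSE)
  bw <- data.frame(chain = "A", resno = resno,
                   generic_number = sprintf("%d.%d", helix, pos),
                   stringsAsFactors = FALSE)
  # helix-8 anchors for allosteric mode, far down the line
  extra <- data.frame(chain = "A", resno = n + 1:20,
                      insert = "", resid = "ALA", elety = "CA",
                      x = 3.8 * (n + 1:20 - 1L), y = 0, z = 0, o = 1,
                      stringsAsFactors = FALSE)
  bw8 <- data.frame(chain = "A", resno = n + 1:20,
                    generic_number = sprintf("8.%d", 40:59),
                    stringsAsFactors = FALSE)
  st <- annotated_structure(rbind(at, extra), rbind(bw, bw8))
  lig <- matrix(c(3.8 * (seed_residue - 1L), 5.4, 0), 1, 3)
  list(structure = st, ligand = lig)
}
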