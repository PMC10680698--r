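# Writes a minimal PDB (via bio3d) for I/O tests; all other fixtures are
# generated helix bundles.

write_test_pdb <- function(path) {
  # two residues (GLY backbone) + one HETATM ligand atom
  xyz <- c(0, 0, 0,   1.5, 0, 0,   2.0, 1.2, 0,   # res 101 N, CA, C
           3.5, 1.5, 0,  4.8, 2.2, 0,  5.5, 3.6, 0,  # res 102 N, CA, C
           8, 8, 8)                                   # ligand
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = c(101, 101, 101, 102, 102, 102, 401),
                   chain = rep("A", 7),
                   resid = c(rep("GLY", 6), "LIG"),
                   elety = c("N", "CA", "C", "N", "CA", "C", "C1"),
                   type = c(rep("ATOM", 6), "HETATM"))
  path
}

test_that("structures load with BW annotations and unmatched-row reporting", {
  pdb <- write_test_pdb(tempfile(fileext = ".pdb"))
  bwf <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum\tgeneric_number",
               "A\t101\t2.63", "A\t999\t45.52"), bwf)
  suppressMessages(st <- load_and_annotate(pdb, bwf))
  expect_s3_class(st, "annotated_structure")
  expect_equal(st$bw$generic_number[st$bw$resno == 101], "2.63")
  expect_equal(st$unmatched$resno, 999)
  expect_equal(st$unmatched$generic_number, "45.52")
  expect_length(st$ligands, 1L)
  # loop-style generic numbers are accepted as labels
  bwf2 <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum\tgeneric_number", "A\t102\t45.52"), bwf2)
  st2 <- load_and_annotate(pdb, bwf2)
  expect_equal(st2$bw$generic_number, "45.52")
  expect_error(load_and_annotate(tempfile(fileext = ".pdb")), "malformed|exist")
})

test_that("duplicate BW assignments are rejected", {
  at <- data.frame(chain = "A", resno = 1:2, resid = "ALA",
                   elety = "CA", x = c(0, 3), y = 0, z = 0)
  expect_error(annotated_structure(at, bw = data.frame(
    chain = "A", resno = c(1, 1), generic_number = c("1.50", "1.51"))),
    "duplicate BW")
  expect_error(annotated_structure(at, bw = data.frame(
    chain = "A", resno = c(1, 2), generic_number = c("1.50", "1.50"))),
    "injective")
})

test_that("superposition is exact for rigid transforms of a bundle", {
  st <- gen_helix_bundle()
  self <- superpose_backbones(st, st)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% R
  mob$atoms$x <- xyz[, 1] + 12; mob$atoms$y <- xyz[, 2] - 7
  mob$atoms$z <- xyz[, 3] + 3
  fit <- superpose_backbones(st, mob)
  expect_lt(fit$rmsd, 1e-6)
  # reference untouched
  expect_identical(st$atoms$x[1], gen_helix_bundle()$atoms$x[1])
})

test_that("superposition RMSD matches a numerical-optimization oracle", {
  st <- gen_helix_bundle(default_helix_layout(n_helices = 2, helix8 = FALSE))
  mob <- st
  mob$atoms$x[5] <- mob$atoms$x[5] + 2.0   # displace one atom
  mob$atoms$y[9] <- mob$atoms$y[9] - 1.0
  fit <- superpose_backbones(st, mob)
  ref_xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  mob_xyz <- as.matrix(mob$atoms[, c("x", "y", "z")])
  expect_equal(fit$rmsd, rmsd_fit_oracle(mob_xyz, ref_xyz), tolerance = 1e-6)
  # rigid-transform invariance of the RMSD itself
  th <- 0.4
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  mob2 <- mob
  xyz2 <- mob_xyz %*% R
  mob2$atoms$x <- xyz2[, 1] + 4; mob2$atoms$y <- xyz2[, 2]
  mob2$atoms$z <- xyz2[, 3] - 9
  fit2 <- superpose_backbones(st, mob2)
  expect_equal(fit$rmsd, fit2$rmsd, tolerance = 1e-6)
  expect_error(superpose_backbones(st, mob, selection = "1.32"),
               "at least 3")
})

test_that("BW distance tables compute Euclidean Calpha distances", {
  at <- data.frame(chain = "A", resno = 1:2, resid = "ALA", elety = "CA",
                   x = c(0, 3), y = c(0, 4), z = c(0, 0))
  bw <- data.frame(chain = "A", resno = 1:2,
                   generic_number = c("1.50", "2.50"))
  st <- annotated_structure(at, bw)
  d <- bw_distance_table(list(s = st), data.frame(bw_i = "1.50", bw_j = "2.50"))
  expect_equal(unname(d[1, 1]), 5)  # 3-4-5 triangle
  dself <- bw_distance_table(list(s = st),
                             data.frame(bw_i = "1.50", bw_j = "1.50"))
  expect_equal(unname(dself[1, 1]), 0)
  expect_error(bw_distance_table(list(s = st),
                                 data.frame(bw_i = "9.99", bw_j = "1.50")),
               "unresolvable")
  # distances are intra-structure: invariant to superposition
  st2 <- st; st2$atoms$x <- st2$atoms$x + 100
  d2 <- bw_distance_table(list(s = st2), data.frame(bw_i = "1.50",
                                                    bw_j = "2.50"))
  expect_equal(unname(d2[1, 1]), 5)
})

test_that("a two-helix bundle reports the designed axis separation", {
  lay <- data.frame(helix = 1:2, x = c(0, 10), y = 0, z0 = 0,
                    n_res = 30L, bw_start = 36L)
  st <- gen_helix_bundle(lay)
  d <- bw_distance_table(list(b = st),
                         data.frame(bw_i = "1.50", bw_j = "2.50"))
  expect_lt(abs(unname(d[1, 1]) - 10), 1.5)
  # consecutive Calpha spacing is the canonical ~3.8 A
  a <- as.numeric(st$atoms[1, c("x", "y", "z")])
  b <- as.numeric(st$atoms[2, c("x", "y", "z")])
  expect_lt(abs(sqrt(sum((a - b)^2)) - 3.8), 0.1)
  # rigid shift of one helix moves axis-parallel pairs by the projection
  sh <- c(3, 0, 0)
  st_shift <- gen_helix_bundle(lay, state_shifts = list(`2` = sh))
  d1 <- bw_distance_table(list(a = st, b = st_shift),
                          data.frame(bw_i = "1.50", bw_j = "2.50"))
  expect_equal(unname(d1["b", 1]) - unname(d1["a", 1]), 3, tolerance = 0.5)
})

test_that("proximity selection respects cutoffs and granularity", {
  at <- data.frame(chain = "A",
                   resno = c(1, 1, 2, 3),
                   resid = "ALA",
                   elety = c("CA", "CB", "CA", "CA"),
                   x = c(5.4, 9.0, 5.6, 20), y = 0, z = 0)
  st <- annotated_structure(at)
  ref <- matrix(c(0, 0, 0), 1, 3)
  hit_atom <- select_proximal_atoms(st, ref, 5.5, "atom")
  # atom at 5.4 included, 5.6 and farther excluded
  expect_equal(hit_atom, 1L, ignore_attr = TRUE)
  # residue granularity pulls in all atoms of residue 1
  hit_res <- select_proximal_atoms(st, ref, 5.5, "residue")
  expect_equal(sort(hit_res), c(1L, 2L), ignore_attr = TRUE)
  # a residue with one atom at 9 A enters at cutoff 10 with all its atoms
  hit10 <- select_proximal_atoms(st, ref, 10, "residue")
  expect_equal(sort(hit10), c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_error(select_proximal_atoms(st, matrix(numeric(), 0, 3), 5), "empty")
})

test_that("envelope boxes add the margin on every side and nest", {
  pts <- cbind(c(0, 10), c(0, 2), c(0, 3))
  box <- build_envelope_box(pts, margin = 4)
  expect_equal(unname(box$min), c(-4, -4, -4))
  expect_equal(unname(box$max), c(14, 6, 7))
  # single point: cube of edge 2*margin
  single <- build_envelope_box(matrix(c(1, 2, 3), 1, 3), margin = 4)
  expect_equal(unname(single$max - single$min), rep(8, 3))
  expect_equal(unname((single$max + single$min) / 2), c(1, 2, 3))
  # margin 0: tight bounding box
  tight <- build_envelope_box(pts, margin = 0)
  expect_equal(unname(tight$min), c(0, 0, 0))
  expect_equal(unname(tight$max), c(10, 2, 3))
  # strict nesting for larger margins
  expect_true(all(box$min < tight$min) && all(box$max > tight$max))
  expect_error(build_envelope_box(matrix(numeric(), 0, 3)), "empty")
})

test_that("mutation edits rename, truncate and placeholder correctly", {
  at <- data.frame(chain = "A",
                   resno = c(70, 70, 70, 70, 70, 70,
                             38, 38, 38, 38, 38, 38, 38, 38, 38),
                   resid = c(rep("CYS", 6), rep("LYS", 9)),
                   elety = c("N", "CA", "C", "O", "CB", "SG",
                             "N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
                   x = as.numeric(1:15), y = 0, z = 0)
  st <- annotated_structure(at)
  # growing edit C70Y: renamed, ring atoms appear with occupancy 0 and no
  # invented coordinates
  st2 <- apply_mutation_edits(st, data.frame(chain = "A", resno = 70,
                                             from = "CYS", to = "TYR"))
  res70 <- st2$atoms[st2$atoms$resno == 70, ]
  expect_true(all(res70$resid == "TYR"))
  ring <- res70[res70$elety %in% c("CG", "CD1", "CZ", "OH"), ]
  expect_true(all(ring$o == 0))
  expect_true(all(is.na(ring$x)))
  expect_false("SG" %in% res70$elety)  # not a tyrosine atom
  # shrinking edit K38A truncates to Cbeta
  st3 <- apply_mutation_edits(st, data.frame(chain = "A", resno = 38,
                                             from = "LYS", to = "ALA"))
  res38 <- st3$atoms[st3$atoms$resno == 38, ]
  expect_setequal(res38$elety, c("N", "CA", "C", "O", "CB"))
  expect_true(all(res38$resid == "ALA"))
  # mismatching from-residue errors with the residue name
  expect_error(apply_mutation_edits(st, data.frame(chain = "A", resno = 38,
                                                   from = "GLY", to = "ALA")),
               "38")
})
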