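test_that("pActivity conversion handles units and round-trips", {
  expect_equal(compute_pactivity(1, "nM"), 9)
  expect_equal(compute_pactivity(10, "nM"), 8)
  expect_equal(compute_pactivity(1, "uM"), 6)
  expect_equal(compute_pactivity(1e-9, "M"), 9)
  # a 100-fold potency loss is a pActivity drop of 2
  expect_equal(compute_pactivity(1, "nM") - compute_pactivity(100, "nM"), 2)
  for (p in seq(3, 12, by = 0.5)) {
    expect_equal(compute_pactivity(10^(-p), "M"), p, tolerance = 1e-9)
  }
  expect_error(compute_pactivity(0, "nM"), "positive")
  expect_error(compute_pactivity(-1, "M"), "positive")
  expect_error(compute_pactivity(1, "furlongs"), "unknown unit")
})

test_that("compound tables parse with aliases, rejections and duplicate detection", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "compound_id\tsmiles\talias\tchemotype\treceptor\tsite\tmeasure\tvalue\tunit",
    "cherney08a_22\tCCN(CC)CCO\tBMS CCR2 22\tBMS\thCCR2\torthosteric\tIC50\t3.2\tnM",
    "mk_1\tc1ccncc1CCN\tMK cmpd 1\tMK\thCCR2\torthosteric\tIC50\t12\tnM",
    "broken_1\tnot_a_smiles(((\t\tBMS\t\t\t\t\t"
  ), tsv)
  expect_warning(lib <- parse_compound_table(tsv, "smiles_tsv"), "rejected")
  expect_s3_class(lib, "screening_library")
  expect_equal(nrow(lib$compounds), 2L)
  # both identifiers retained
  rec <- lib$compounds[lib$compounds$compound_id == "cherney08a_22", ]
  expect_equal(rec$alias, "BMS CCR2 22")
  rej <- attr(lib, "rejections")
  expect_equal(rej$compound_id, "broken_1")
  # activities converted to pActivity
  expect_equal(lib$activities$pactivity[lib$activities$compound_id == "mk_1"],
               -log10(12e-9))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tsmiles", "a\tCCO", "a\tCCN"), dup)
  expect_error(parse_compound_table(dup, "smiles_tsv"), "duplicate compound_id")

  empty <- tempfile(fileext = ".tsv")
  writeLines("compound_id\tsmiles", empty)
  expect_warning(lib0 <- parse_compound_table(empty, "smiles_tsv"), "empty")
  expect_equal(nrow(lib0$compounds), 0L)
})

test_that("SDF input parses structures and data fields", {
  sdf <- tempfile(fileext = ".sdf")
  block <- ChemmineOB::convertFormat("SMI", "SDF", "CCO eth\nCCN amine\n")
  lines <- strsplit(block, "\n")[[1]]
  # interleave data fields before each terminator
  out <- character(); i <- 1
  ids <- c("cpd_eth", "cpd_amine")
  for (ln in lines) {
    if (grepl("^\\$\\$\\$\\$", ln)) {
      out <- c(out, "> <compound_id>", ids[i], "", ln)
      i <- i + 1
    } else out <- c(out, ln)
  }
  writeLines(out, sdf)
  lib <- parse_compound_table(sdf, "sdf")
  expect_setequal(lib$compounds$compound_id, ids)
  expect_equal(length(lib$fingerprints), 2L)
})

test_that("fingerprints are canonical, stereo-insensitive and 2D", {
  expect_identical(compute_fingerprint("CCO"), compute_fingerprint("OCC"))
  expect_identical(compute_fingerprint("c1ccccc1O"),
                   compute_fingerprint("Oc1ccccc1"))
  # stereoisomer pair differing at one center: identical 2D fingerprints,
  # so stereo activity cliffs register similarity 1
  s1 <- compute_fingerprint("C[C@H](N)C(=O)O")
  s2 <- compute_fingerprint("C[C@@H](N)C(=O)O")
  expect_identical(s1, s2)
  # methane: single heavy-atom environment, non-empty
  fm <- compute_fingerprint("C")
  expect_gt(length(fm), 0L)
  # different molecules get different bit sets
  expect_false(identical(compute_fingerprint("CCO"),
                         compute_fingerprint("CCN")))
  expect_error(compute_fingerprint("xx((("), "unparsable")
})

test_that("Tanimoto distance satisfies identity, symmetry and the set formula", {
  expect_equal(tanimoto_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(tanimoto_distance(c(1, 2), c(3, 4)), 1)
  expect_equal(tanimoto_distance(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_warning(d0 <- tanimoto_distance(integer(), integer()), "empty")
  expect_equal(d0, 0)
  set.seed(42)
  for (i in 1:200) {
    a <- sample(64, sample(1:20, 1))
    b <- sample(64, sample(1:20, 1))
    dab <- tanimoto_distance(a, b)
    expect_identical(dab, tanimoto_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(tanimoto_distance(a, a), 0)
  }
})

test_that("role assignment uses strict per-chemotype cutoffs and is idempotent", {
  lib <- make_tiny_library()
  lib <- assign_roles(lib, "hCCR2", "orthosteric")
  roles <- setNames(lib$compounds$role, lib$compounds$compound_id)
  expect_equal(unname(roles[c("act1", "act2", "weak1", "dec1")]),
               c("active", "active", "inactive", "decoy"))
  # boundary: pactivity 7.6 vs cutoff 7.5 -> active; exactly 7.5 -> inactive
  comp <- data.frame(compound_id = c("x", "y", "ucb"),
                     chemotype = c("BI", "BI", "UCB"))
  acts <- data.frame(compound_id = c("x", "y", "ucb"),
                     receptor = "hCCR2", site = "orthosteric",
                     measure = "IC50", value_M = 10^-c(7.6, 7.5, 6.6),
                     pactivity = c(7.6, 7.5, 6.6))
  lib2 <- screening_library(comp, acts,
                            thresholds = c(BI = 7.5, UCB = 6.5))
  lib2 <- assign_roles(lib2, "hCCR2", "orthosteric")
  expect_equal(lib2$compounds$role, c("active", "inactive", "active"))
  # idempotent
  expect_identical(assign_roles(lib2, "hCCR2", "orthosteric"), lib2)
  # chemotype without threshold errors
  lib3 <- screening_library(
    data.frame(compound_id = "z", chemotype = "GSK"),
    data.frame(compound_id = "z", receptor = "hCCR2", site = "orthosteric",
               measure = "IC50", value_M = 1e-8, pactivity = 8),
    thresholds = c(BI = 7.5))
  expect_error(assign_roles(lib3, "hCCR2", "orthosteric"), "GSK")
})

test_that("multiple measurements keep the most potent value", {
  comp <- data.frame(compound_id = "m", chemotype = "BMS")
  acts <- data.frame(compound_id = "m", receptor = "hCCR2",
                     site = "orthosteric", measure = "IC50",
                     value_M = c(1e-6, 1e-9), pactivity = c(6, 9))
  lib <- screening_library(comp, acts, thresholds = c(BMS = 7.5))
  lib <- assign_roles(lib, "hCCR2", "orthosteric")
  expect_equal(lib$compounds$role, "active")
})

test_that("UPGMA reproduces the hand-worked three-leaf dendrogram", {
  d <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.8, 0.6, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(d)
  expect_equal(u$height, c(0.2, 0.7))
  sets <- dendrogram_merge_sets(u)
  expect_equal(sets$merges[[1]], c("A", "B"))
  expect_equal(sets$merges[[2]], c("A", "B", "C"))
  # cutting at 0.5 separates {A,B} from {C}, labels are lexicographic reps
  cl <- cut_chemotypes(u, 0.5)
  expect_equal(unname(cl[c("A", "B", "C")]), c("A", "A", "C"))
  # all-zero distances collapse into one cluster at height 0
  dz <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  uz <- upgma(dz)
  expect_equal(uz$height, c(0, 0))
  expect_equal(unname(cut_chemotypes(uz, 0.5)), rep("A", 3))
})

test_that("UPGMA agrees with a brute-force averaging oracle and hclust", {
  set.seed(7)
  for (trial in 1:60) {
    n <- 6
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    u <- upgma(d)
    got <- dendrogram_merge_sets(u)
    want <- upgma_oracle(d)
    expect_equal(got$heights, want$heights, tolerance = 1e-12)
    expect_identical(got$merges, want$merges)
    expect_true(all(diff(u$height) >= -1e-12))
    # independent library cross-check (random matrices are tie-free)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(u$height), sort(hc$height), tolerance = 1e-12)
  }
})

test_that("chemotype labels are stable under input permutation", {
  fps <- list(a1 = c(1L, 2L, 3L), a2 = c(1L, 2L, 4L),
              b1 = c(50L, 51L, 52L), b2 = c(50L, 51L, 53L))
  comp <- data.frame(compound_id = names(fps))
  lib <- screening_library(comp, fingerprints = fps)
  cl1 <- cluster_chemotypes(lib, cut_height = 0.6)
  perm <- c("b2", "a1", "b1", "a2")
  lib2 <- screening_library(data.frame(compound_id = perm),
                            fingerprints = fps[perm])
  cl2 <- cluster_chemotypes(lib2, cut_height = 0.6)
  expect_equal(cl1$labels[sort(names(cl1$labels))],
               cl2$labels[sort(names(cl2$labels))])
  expect_setequal(unique(cl1$labels), c("a1", "b1"))
})
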