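test_that("atom classification partitions elements by polarity and backbone", {
  expect_equal(classify_atom("CA", "C", "PHE"),
               list(is_backbone = TRUE, polarity = "nonpolar"))
  expect_equal(classify_atom("OG", "O", "SER"),
               list(is_backbone = FALSE, polarity = "polar"))
  expect_equal(classify_atom("HB2", "H", "ALA"),
               list(is_backbone = FALSE, polarity = "excluded"))
  expect_equal(classify_atom("SD", "S", "MET")$polarity, "nonpolar")
  expect_warning(cl <- classify_atom("FE", "FE", "HEM"), "nonpolar")
  expect_equal(cl$polarity, "nonpolar")
  # every parsed atom lands in exactly one polarity class
  for (el in c("C", "N", "O", "S", "H")) {
    expect_true(classify_atom("X", el)$polarity %in%
                  c("polar", "nonpolar", "excluded"))
  }
})

test_that("read_pdb parses records, drops hydrogens' polarity and waters", {
  gly <- c(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       9.580   6.365  -3.900  1.00  0.00           O",
    "ATOM      5  HA  GLY A   1      12.621   6.519  -5.100  1.00  0.00           H",
    "HETATM    6  O   HOH A  99       1.000   2.000   3.000  1.00  0.00           O")
  s <- read_pdb(paste(gly, collapse = "\n"))
  expect_length(residue_keys(s), 1)
  expect_equal(sum(s$atoms$polarity != "excluded"), 4)
  expect_false("A:99" %in% residue_keys(s))
})

test_that("altloc resolves to highest occupancy with first-wins ties", {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BGLY A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   GLY A   1       2.400   0.000   0.000  1.00  0.00           C",
    "ATOM      5  O   GLY A   1       3.000   1.200   0.000  1.00  0.00           O")
  s <- read_pdb(paste(lines, collapse = "\n"))
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.000)
})

test_that("read_pdb errors name the offending line and reject empty models", {
  bad <- "ATOM      1  N   GLY A   1      xx.xxx   6.134  -6.504  1.00  0.00           N"
  expect_error(read_pdb(bad), "line 1")
  hoh <- "HETATM    1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O"
  expect_error(read_pdb(hoh), "empty model")
  expect_error(read_pdb("REMARK nothing here"), "empty model")
})

test_that("sphere membership follows closed 8 A CA-CA boundary", {
  mk_ca_chain <- function(xs) {
    toy_structure(data.frame(
      atom_name = "CA", resname = "ALA", chain = "A",
      resno = seq_along(xs), x = xs, y = 0, z = 0, element = "C",
      stringsAsFactors = FALSE))
  }
  s <- mk_ca_chain(c(0, 5))
  expect_equal(sphere_residues(s, "A:1", 8), "A:2")
  s9 <- mk_ca_chain(c(0, 9))
  expect_length(sphere_residues(s9, "A:1", 8), 0)
  # linear chain at 3.8 A spacing: 2 neighbours per side fall within 8 A
  chain <- mk_ca_chain(3.8 * (0:8))
  expect_setequal(sphere_residues(chain, "A:5", 8),
                  c("A:3", "A:4", "A:6", "A:7"))
  # boundary is closed: exactly radius counts as inside
  s8 <- mk_ca_chain(c(0, 8))
  expect_equal(sphere_residues(s8, "A:1", 8), "A:2")
})

test_that("sphere membership is order-invariant and monotone in radius", {
  set.seed(42)
  df <- data.frame(atom_name = "CA", resname = "ALA", chain = "A",
                   resno = 1:20, x = rnorm(20, 0, 6), y = rnorm(20, 0, 6),
                   z = rnorm(20, 0, 6), element = "C",
                   stringsAsFactors = FALSE)
  s <- toy_structure(df)
  perm <- toy_structure(df[sample(20), ])
  expect_setequal(sphere_residues(s, "A:7", 8), sphere_residues(perm, "A:7", 8))
  for (r in c(4, 6, 8, 10)) {
    expect_true(all(sphere_residues(s, "A:7", r) %in%
                      sphere_residues(s, "A:7", r + 2)))
  }
})

test_that("ca_rmsd is symmetric, superposition-invariant and matches hand values", {
  cfg <- synth_config(seed = 1, n_residues = 10)
  a <- make_helix_structure(cfg)
  expect_equal(ca_rmsd(a, a), 0)
  # rigid translation vanishes under superposition
  b <- a
  b$atoms$x <- b$atoms$x + 5; b$atoms$y <- b$atoms$y - 2
  expect_lt(ca_rmsd(a, b, superpose = TRUE), 1e-8)
  expect_gt(ca_rmsd(a, b, superpose = FALSE), 1)
  # hand-computed 3-point deviation without superposition:
  # per-point offsets (1,0,0),(0,2,0),(0,0,2) -> rmsd = sqrt((1+4+4)/3)
  mk <- function(m) toy_structure(data.frame(
    atom_name = "CA", resname = "GLY", chain = "A", resno = 1:3,
    x = m[, 1], y = m[, 2], z = m[, 3], element = "C",
    stringsAsFactors = FALSE))
  p <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0), 3, byrow = TRUE)
  q <- p + matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 2), 3, byrow = TRUE)
  expect_equal(ca_rmsd(mk(p), mk(q), superpose = FALSE), sqrt(3))
  # symmetry and ordering between modes
  set.seed(3)
  r <- p + matrix(rnorm(9, 0, 0.5), 3)
  expect_equal(ca_rmsd(mk(p), mk(r), superpose = FALSE),
               ca_rmsd(mk(r), mk(p), superpose = FALSE))
  expect_lte(ca_rmsd(mk(p), mk(r), superpose = TRUE),
             ca_rmsd(mk(p), mk(r), superpose = FALSE) + 1e-12)
})

test_that("ca_rmsd rejects mismatched residue sets, naming the difference", {
  cfg <- synth_config(seed = 1, n_residues = 6)
  a <- make_helix_structure(cfg)
  b <- a
  b$atoms <- b$atoms[b$atoms$resno != 6, ]
  expect_error(ca_rmsd(a, b), "A:6")
})

test_that("superposed ca_rmsd agrees with the bio3d reference", {
  skip_if_not_installed("bio3d")
  cfg <- synth_config(seed = 9, n_residues = 12)
  a <- make_helix_structure(cfg)
  b <- a
  set.seed(11)
  b$atoms$x <- b$atoms$x + rnorm(nrow(b$atoms), 0, 0.3)
  b$atoms$y <- b$atoms$y + rnorm(nrow(b$atoms), 0, 0.3)
  xa <- as.vector(t(acdtol:::ca_coords(a)))
  xb <- as.vector(t(acdtol:::ca_coords(b)))
  ref <- bio3d::rmsd(xa, xb, fit = TRUE)
  expect_equal(ca_rmsd(a, b, superpose = TRUE), ref, tolerance = 1e-3)
})
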