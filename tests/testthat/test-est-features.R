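test_that("contact counting matches hand-built toys", {
  # no two atoms within 4 A -> all zero
  far <- toy_structure(data.frame(
    atom_name = c("D1", "D1"), resname = "UNK", chain = "A", resno = 1:2,
    x = c(0, 10), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  cc <- enumerate_contacts(far, "A:1")
  expect_true(all(unclass(cc) == 0))

  # one nonpolar sidechain-sidechain inter contact at 3.5 A
  two <- toy_structure(data.frame(
    atom_name = c("D1", "D2"), resname = "UNK", chain = "A", resno = 1:2,
    x = c(0, 3.5), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  cc <- enumerate_contacts(two, "A:1")
  expect_equal(unname(unclass(cc)["np_sc_sc_inter"]), 1L)
  expect_equal(unname(unclass(cc)["total_np_contacts"]), 1L)
  expect_equal(unname(unclass(cc)["total_contacts"]), 1L)
  expect_equal(sum(unclass(cc)), 3L)  # only the one contact plus its totals

  # strict inequality: exactly 4.0 A is not a contact
  at4 <- toy_structure(data.frame(
    atom_name = c("D1", "D2"), resname = "UNK", chain = "A", resno = 1:2,
    x = c(0, 4.0), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  expect_true(all(unclass(enumerate_contacts(at4, "A:1")) == 0))

  # mixed polar/nonpolar pair counts as polar by default
  mixed <- toy_structure(data.frame(
    atom_name = c("D1", "D2"), resname = "UNK", chain = "A", resno = 1:2,
    x = c(0, 3.0), y = 0, z = 0, element = c("C", "O"),
    stringsAsFactors = FALSE))
  expect_equal(unname(unclass(enumerate_contacts(mixed, "A:1"))["p_sc_sc_inter"]), 1L)
  expect_equal(unname(unclass(enumerate_contacts(
    mixed, "A:1", mixed_polarity = "drop"))["total_contacts"]), 0L)
})

test_that("covalently bonded and 1-3 intra pairs are not contacts", {
  # three collinear atoms 1.5 A apart: 1-2, 2-3 bonded, 1-3 two-step;
  # none count despite all pairwise distances < 4
  s <- toy_structure(data.frame(
    atom_name = c("D1", "D2", "D3"), resname = "UNK", chain = "A", resno = 1,
    x = c(0, 1.5, 3.0), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE))
  expect_true(all(unclass(enumerate_contacts(s, "A:1")) == 0))
  # a fourth atom 1-4 away does count
  s4 <- toy_structure(data.frame(
    atom_name = c("D1", "D2", "D3", "D4"), resname = "UNK", chain = "A",
    resno = 1, x = c(0, 1.5, 3.0, 3.9), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE))
  cc <- enumerate_contacts(s4, "A:1")
  expect_equal(unname(unclass(cc)["np_sc_sc_intra"]), 1L)
})

test_that("peptide-junction pairs are excluded from inter contacts", {
  # site residue 1 C at origin, residue 2 N 1.33 A away: excluded
  s <- toy_structure(data.frame(
    atom_name = c("C", "N"), resname = "ALA", chain = "A", resno = 1:2,
    x = c(0, 1.33), y = 0, z = 0, element = c("C", "N"),
    stringsAsFactors = FALSE))
  expect_true(all(unclass(enumerate_contacts(s, "A:1")) == 0))
  # non-adjacent residues with the same atoms do count
  s2 <- toy_structure(data.frame(
    atom_name = c("C", "N"), resname = "ALA", chain = "A", resno = c(1, 3),
    x = c(0, 1.33), y = 0, z = 0, element = c("C", "N"),
    stringsAsFactors = FALSE))
  expect_equal(unname(unclass(enumerate_contacts(s2, "A:1"))["p_bb_bb_inter"]), 1L)
})

test_that("contact counts equal the brute-force all-pairs oracle on random toys", {
  for (seed in 1:100) {
    s <- random_toy(seed)
    got <- unclass(enumerate_contacts(s, "A:2"))
    want <- oracle_contacts(s, "A:2")
    expect_equal(got[names(want)], want, info = paste("seed", seed))
  }
})

test_that("contact counts are invariant to atom order and rigid motion", {
  s <- random_toy(7, n_res = 3)
  base <- unclass(enumerate_contacts(s, "A:2"))
  perm <- s
  set.seed(1)
  perm$atoms <- perm$atoms[sample(nrow(perm$atoms)), ]
  expect_equal(unclass(enumerate_contacts(perm, "A:2"))[names(base)], base)
  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  rot$atoms$x <- xyz[, 1] + 3; rot$atoms$y <- xyz[, 2] - 1
  rot$atoms$z <- xyz[, 3] + 2
  expect_equal(unclass(enumerate_contacts(rot, "A:2"))[names(base)], base)
})

test_that("SASA matches analytic single-sphere and additive two-sphere values", {
  lone <- toy_structure(data.frame(
    atom_name = "D1", resname = "UNK", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  got <- sum(shrake_rupley_sasa(lone))
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # two atoms 100 A apart: exact additivity of isolated spheres
  pair <- toy_structure(data.frame(
    atom_name = c("D1", "D1"), resname = "UNK", chain = "A", resno = 1:2,
    x = c(0, 100), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  expect_equal(sum(shrake_rupley_sasa(pair)), 2 * 4 * pi * 3.1^2,
               tolerance = 0.02)
})

test_that("SASA of overlapping spheres matches a Monte-Carlo oracle within 3%", {
  for (d in c(2.0, 4.0)) {
    pair <- toy_structure(data.frame(
      atom_name = c("D1", "D1"), resname = "UNK", chain = "A", resno = 1:2,
      x = c(0, d), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
    got <- sum(shrake_rupley_sasa(pair))
    want <- oracle_mc_area(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE),
                           c(3.1, 3.1), n_samples = 1e5, seed = 5)
    expect_equal(got, want, tolerance = 0.03)
  }
})

test_that("relative SASA normalises by the bundled residue maxima", {
  tab <- acdtol:::load_table("max_asa_tien2013.tsv")
  gly_max <- tab$max_asa[tab$aa == "GLY"]
  expect_equal(relative_sasa(gly_max, "GLY"), 1.0)
  expect_equal(relative_sasa(0, "TRP"), 0.0)
  expect_equal(relative_sasa(gly_max / 2, "GLY"), 0.5)
  expect_error(relative_sasa(50, "XYZ"), "max-ASA")
})

test_that("EST delta vectors are antisymmetric and internally consistent", {
  cfg <- synth_config(seed = 21, n_residues = 16)
  wt <- make_helix_structure(cfg)
  mut <- make_bulky_mutant(wt, "A:8", 8)
  ev <- est_delta_vector(wt, mut, "A:8")
  # identical structures give all-zero contact deltas
  ev0 <- est_delta_vector(wt, wt, "A:8")
  expect_true(all(ev0[acdtol:::CONTACT_CATEGORIES] == 0))
  # totals equal the sum of their category deltas
  np_cats <- grep("^np_", acdtol:::CONTACT_CATEGORIES, value = TRUE)
  p_cats <- grep("^p_", acdtol:::CONTACT_CATEGORIES, value = TRUE)
  expect_equal(ev[["total_np_contacts"]], sum(ev[np_cats]))
  expect_equal(ev[["total_p_contacts"]], sum(ev[p_cats]))
  expect_equal(ev[["total_contacts"]],
               ev[["total_np_contacts"]] + ev[["total_p_contacts"]])
  # swapping wt/mut negates every contact delta (ASA/RSA are wt properties)
  ev_swap <- suppressWarnings(est_delta_vector(mut, wt, "A:8"))
  cats <- c(acdtol:::CONTACT_CATEGORIES, "total_contacts",
            "total_np_contacts", "total_p_contacts")
  expect_equal(unname(ev_swap[cats]), unname(-ev[cats]))
  # ASA/RSA come from the wild type at the site
  asa <- shrake_rupley_sasa(wt)[["A:8"]]
  expect_equal(ev[["ASA"]], asa)
  expect_equal(ev[["RSA"]], relative_sasa(asa, "ALA"))
})

test_that("EST deltas reject pairs differing away from the site", {
  cfg <- synth_config(seed = 22, n_residues = 12)
  wt <- make_helix_structure(cfg)
  bad <- make_bulky_mutant(wt, "A:3", 6)
  expect_error(est_delta_vector(wt, bad, "A:6"), "A:3")
})
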