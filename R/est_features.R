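# Empirical Score Terms: heavy-atom contact counts around the mutation site,
# their mutant-minus-WT deltas, and accessibility (ASA/RSA) of the site
# residue in the wild-type structure.

# --- residue bond templates -------------------------------------------------
# Heavy-atom bond lists for the standard amino acids (backbone bonds
# N-CA, CA-C, C-O[, C-OXT][, CA-CB] added for all). Used to exclude
# covalently bonded (1-2) and angle (1-3) pairs from intra-residue contacts.
SIDECHAIN_BONDS <- list(
  ALA = NULL,
  ARG = list(c("CB","CG"), c("CG","CD"), c("CD","NE"), c("NE","CZ"),
             c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CB","SG")),
  GLN = list(c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","NE2")),
  GLU = list(c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","OE2")),
  GLY = NULL,
  HIS = list(c("CB","CG"), c("CG","ND1"), c("CG","CD2"), c("ND1","CE1"),
             c("CD2","NE2"), c("CE1","NE2")),
  ILE = list(c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CB","CG"), c("CG","CD"), c("CD","CE"), c("CE","NZ")),
  MET = list(c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"),
             c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CB","CG"), c("CG","CD"), c("CD","N")),
  SER = list(c("CB","OG")),
  THR = list(c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","NE1"),
             c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"), c("CE2","CZ2"),
             c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"),
             c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"), c("CZ","OH")),
  VAL = list(c("CB","CG1"), c("CB","CG2"))
)

# Bond list for one residue: template for standard residues, distance-based
# inference (pairs closer than `bond_cutoff`) for unknown residue types.
residue_bonds <- function(res_atoms, bond_cutoff = 1.8) {
  rn <- res_atoms$resname[1]
  nm <- res_atoms$atom_name
  if (rn %in% names(SIDECHAIN_BONDS)) {
    bonds <- list(c("N","CA"), c("CA","C"), c("C","O"), c("C","OXT"))
    if ("CB" %in% nm) bonds <- c(bonds, list(c("CA","CB")))
    bonds <- c(bonds, SIDECHAIN_BONDS[[rn]])
    bonds <- Filter(function(b) all(b %in% nm), bonds)
  } else {
    xyz <- as.matrix(res_atoms[, c("x","y","z")])
    d <- as.matrix(dist(xyz))
    idx <- which(d > 0 & d <= bond_cutoff & upper.tri(d), arr.ind = TRUE)
    bonds <- lapply(seq_len(nrow(idx)), function(i) nm[idx[i, ]])
  }
  bonds
}

# Set of atom-name pairs within one residue separated by <= 2 covalent bonds
# (1-2 and 1-3 partners), as "A|B" keys with A < B lexicographically.
bonded_pairs_13 <- function(res_atoms) {
  bonds <- residue_bonds(res_atoms)
  if (length(bonds) == 0) return(character(0))
  nm <- unique(res_atoms$atom_name)
  adj <- setNames(vector("list", length(nm)), nm)
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  out <- character(0)
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (a in nm) {
    nb1 <- adj[[a]] %||% character(0)
    for (b in nb1) out <- c(out, pair_key(a, b))
    for (b in nb1) {
      nb2 <- setdiff(adj[[b]] %||% character(0), a)
      for (cc in nb2) out <- c(out, pair_key(a, cc))
    }
  }
  unique(out)
}

# Inter-residue exclusions across a peptide junction between the site residue
# and a sequence-adjacent neighbour: the peptide bond itself (1-2) and its
# 1-3 partners. Returns "siteAtom|neighbourAtom" keys.
junction_exclusions <- function(site_is_nterm_side) {
  if (site_is_nterm_side) {
    # site precedes neighbour: site C - nbr N bond
    c("C|N", "CA|N", "O|N", "C|CA")
  } else {
    # neighbour precedes site: nbr C - site N bond
    c("N|C", "N|CA", "N|O", "CA|C")
  }
}

CONTACT_CATEGORIES <- as.vector(outer(
  c("p", "np"),
  as.vector(outer(c("bb_bb", "bb_sc", "sc_sc"), c("intra", "inter"),
                  function(a, b) paste(a, b, sep = "_"))),
  function(a, b) paste(a, b, sep = "_")
))

#' Count categorized heavy-atom contacts around a mutation site
#'
#' Counts unordered heavy-atom pairs closer than `cutoff` (strict inequality)
#' involving the site residue. Pairs with both atoms in the site residue are
#' intra-residue contacts; pairs with exactly one atom in the site are
#' inter-residue. Covalently bonded and angle (1-2/1-3) pairs are excluded,
#' both within the residue (bond graph from standard residue templates;
#' distance-inferred for unknown residue types) and across the two peptide
#' junctions. Each contact is categorized by polarity (np if both atoms
#' nonpolar, else p) and pairing (bb_bb, bb_sc, sc_sc).
#'
#' @param s a `structure3d`.
#' @param site residue key `"chain:resno"`.
#' @param cutoff contact distance cutoff in Angstrom (default 4.0, strict `<`).
#' @param mixed_polarity how to count mixed polar/nonpolar pairs: `"polar"`
#'   (default), `"nonpolar"` or `"drop"`.
#' @return a `contact_counts` object: named integer vector with the 12
#'   category counts plus `total_contacts`, `total_np_contacts`,
#'   `total_p_contacts`.
#' @export
enumerate_contacts <- function(s, site, cutoff = 4.0,
                               mixed_polarity = c("polar", "nonpolar", "drop")) {
  mixed_polarity <- match.arg(mixed_polarity)
  keys <- residue_keys(s)
  if (!site %in% keys) stop("site residue '", site, "' not in structure")

  atoms <- s$atoms[s$atoms$polarity != "excluded", , drop = FALSE]
  site_atoms <- atoms[atoms$residue_key == site, , drop = FALSE]
  other_atoms <- atoms[atoms$residue_key != site, , drop = FALSE]
  counts <- setNames(integer(length(CONTACT_CATEGORIES)), CONTACT_CATEGORIES)

  cat_of <- function(p1, p2, bb1, bb2, locality) {
    pol <- if (p1 == "nonpolar" && p2 == "nonpolar") "np"
           else if (p1 == "polar" && p2 == "polar") "p"
           else switch(mixed_polarity, polar = "p", nonpolar = "np", drop = NA)
    if (is.na(pol)) return(NA_character_)
    pair <- if (bb1 && bb2) "bb_bb" else if (!bb1 && !bb2) "sc_sc" else "bb_sc"
    paste(pol, pair, locality, sep = "_")
  }

  # intra-residue pairs
  n_site <- nrow(site_atoms)
  if (n_site >= 2) {
    excl <- bonded_pairs_13(site_atoms)
    xyz <- as.matrix(site_atoms[, c("x","y","z")])
    d <- as.matrix(dist(xyz))
    for (i in seq_len(n_site - 1)) for (j in (i + 1):n_site) {
      if (d[i, j] >= cutoff) next
      key <- paste(sort(c(site_atoms$atom_name[i], site_atoms$atom_name[j])),
                   collapse = "|")
      if (key %in% excl) next
      cc <- cat_of(site_atoms$polarity[i], site_atoms$polarity[j],
                   site_atoms$is_backbone[i], site_atoms$is_backbone[j], "intra")
      if (!is.na(cc)) counts[cc] <- counts[cc] + 1L
    }
  }

  # inter-residue pairs (site atom vs any other residue's atom)
  if (nrow(other_atoms) > 0 && n_site > 0) {
    # sequence-adjacent residues in the same chain get junction exclusions
    site_chain <- sub(":.*", "", site)
    site_resno <- as.integer(sub(".*:", "", site))
    prev_key <- paste0(site_chain, ":", site_resno - 1L)
    next_key <- paste0(site_chain, ":", site_resno + 1L)
    excl_next <- junction_exclusions(TRUE)
    excl_prev <- junction_exclusions(FALSE)

    sx <- as.matrix(site_atoms[, c("x","y","z")])
    ox <- as.matrix(other_atoms[, c("x","y","z")])
    for (i in seq_len(n_site)) {
      d <- sqrt(colSums((t(ox) - sx[i, ])^2))
      hits <- which(d < cutoff)
      for (j in hits) {
        ok <- other_atoms$residue_key[j]
        pk <- paste(site_atoms$atom_name[i], other_atoms$atom_name[j], sep = "|")
        if (ok == next_key && pk %in% excl_next) next
        if (ok == prev_key && pk %in% excl_prev) next
        cc <- cat_of(site_atoms$polarity[i], other_atoms$polarity[j],
                     site_atoms$is_backbone[i], other_atoms$is_backbone[j],
                     "inter")
        if (!is.na(cc)) counts[cc] <- counts[cc] + 1L
      }
    }
  }

  np <- sum(counts[startsWith(names(counts), "np_")])
  p <- sum(counts[startsWith(names(counts), "p_")])
  out <- c(counts,
           total_contacts = np + p,
           total_np_contacts = np,
           total_p_contacts = p)
  class(out) <- "contact_counts"
  out
}

#' @export
print.contact_counts <- function(x, ...) {
  cat("<contact_counts>\n")
  print(unclass(x))
  invisible(x)
}

# --- SASA -------------------------------------------------------------------

.acdtol_tables <- new.env(parent = emptyenv())

load_table <- function(fname) {
  if (is.null(.acdtol_tables[[fname]])) {
    path <- system.file("extdata", fname, package = "acdtol")
    if (path == "") path <- file.path("inst", "extdata", fname)
    .acdtol_tables[[fname]] <- utils::read.delim(path, comment.char = "#",
                                                 stringsAsFactors = FALSE)
  }
  .acdtol_tables[[fname]]
}

vdw_radius <- function(element, default = 1.7) {
  tab <- load_table("vdw_radii.tsv")
  r <- tab$radius[match(toupper(element), tab$element)]
  if (anyNA(r)) {
    warning("unknown element radius for: ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default ", default, " Angstrom")
    r[is.na(r)] <- default
  }
  r
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Rolling-probe approximation of solvent accessible surface area: each heavy
#' atom's solvent-expanded sphere (vdW radius + probe) is sampled with a
#' deterministic quasi-uniform point set; points not buried inside any
#' neighbouring atom's expanded sphere count as accessible. Per-atom areas
#' are summed per residue. Hydrogens are excluded.
#'
#' @param s a `structure3d`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points points per atom (default 960).
#' @return named numeric vector: accessible surface area (Angstrom^2) per
#'   residue key.
#' @export
shrake_rupley_sasa <- function(s, probe = 1.4, n_sphere_points = 960) {
  atoms <- s$atoms[s$atoms$polarity != "excluded", , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0) stop("no heavy atoms")
  xyz <- as.matrix(atoms[, c("x","y","z")])
  rad <- vdw_radius(atoms$element) + probe
  pts <- fibonacci_sphere(n_sphere_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can bury points of atom i
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- colSums((t(p[acc, , drop = FALSE]) - xyz[j, ])^2)
        acc[acc] <- dj2 >= rad[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * rad[i]^2 * frac
  }
  tapply(area, factor(atoms$residue_key, levels = residue_keys(s)), sum,
         default = 0)[residue_keys(s)]
}

#' Relative accessible surface area
#'
#' RSA = ASA / maxASA(residue type), with theoretical per-residue maxima from
#' the bundled normalisation table (see `inst/extdata/max_asa_tien2013.tsv`).
#' Values can exceed 1 for extended conformations.
#'
#' @param asa accessible surface area in Angstrom^2.
#' @param aa_code three-letter residue code.
#' @return unitless RSA.
#' @export
relative_sasa <- function(asa, aa_code) {
  tab <- load_table("max_asa_tien2013.tsv")
  mx <- tab$max_asa[match(toupper(aa_code), tab$aa)]
  if (anyNA(mx)) stop("no max-ASA entry for residue code '", aa_code, "'")
  asa / mx
}

#' Empirical score term delta vector for a WT/mutant structure pair
#'
#' Contact-count deltas (mutant minus wild type) for all 12 contact
#' categories and the three totals, plus ASA and RSA of the site residue
#' computed on the wild-type structure (accessibility is a property of the
#' residue about to be mutated, not a delta).
#'
#' @param wt,mut `structure3d` objects sharing residue keys and differing
#'   only at the site residue.
#' @param site residue key of the mutation site.
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @param ... passed to [enumerate_contacts()].
#' @return named numeric vector: 15 contact deltas, `ASA`, `RSA`.
#' @export
est_delta_vector <- function(wt, mut, site, cutoff = 4.0, ...) {
  kw <- residue_keys(wt); km <- residue_keys(mut)
  if (!setequal(kw, km)) {
    stop("wt and mut residue sets differ: ",
         paste(c(setdiff(kw, km), setdiff(km, kw)), collapse = ", "))
  }
  differing <- Filter(function(k) {
    aw <- residue_atoms(wt, k); am <- residue_atoms(mut, k)
    !(nrow(aw) == nrow(am) &&
        all(aw$atom_name == am$atom_name) &&
        isTRUE(all.equal(as.matrix(aw[, c("x","y","z")]),
                         as.matrix(am[, c("x","y","z")]),
                         tolerance = 1e-6, check.attributes = FALSE)))
  }, setdiff(kw, site))
  if (length(differing) > 0) {
    stop("structures differ at residues other than the site: ",
         paste(differing, collapse = ", "))
  }
  cw <- enumerate_contacts(wt, site, cutoff = cutoff, ...)
  cm <- enumerate_contacts(mut, site, cutoff = cutoff, ...)
  delta <- as.numeric(unclass(cm)) - as.numeric(unclass(cw))
  names(delta) <- names(unclass(cw))
  asa_map <- shrake_rupley_sasa(wt)
  asa <- unname(asa_map[site])
  aa <- residue_atoms(wt, site)$resname[1]
  rsa <- if (toupper(aa) %in% STANDARD_AA3) {
    unname(relative_sasa(asa, aa))
  } else {
    warning("no max-ASA entry for nonstandard residue '", aa,
            "'; RSA set to NA")
    NA_real_
  }
  c(delta, ASA = asa, RSA = rsa)
}
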