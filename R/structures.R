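# Residues treated as amino acids by default (see aa_tables.R). Nonstandard
# residues (e.g. an Acd stand-in named ACD) are also kept when they carry an
# N/CA/C backbone.

#' Classify a PDB atom by backbone membership and polarity
#'
#' Backbone atoms are exactly N, CA, C, O and OXT. Polarity follows the
#' hydrophobicity-oriented contact convention: nitrogen and oxygen are polar,
#' carbon and sulfur nonpolar, hydrogen excluded from all contact and surface
#' computation. Other elements are treated as nonpolar with a warning.
#'
#' @param atom_name PDB atom name (e.g. `"CA"`, `"OG"`).
#' @param element element symbol (e.g. `"C"`, `"O"`, `"H"`).
#' @param aa_code three-letter residue code (unused by the rule, kept for
#'   interface completeness).
#' @return list with `is_backbone` (logical) and `polarity`
#'   (`"polar"`, `"nonpolar"` or `"excluded"`).
#' @export
#' @examples
#' classify_atom("CA", "C", "PHE")   # backbone, nonpolar
#' classify_atom("OG", "O", "SER")   # sidechain, polar
classify_atom <- function(atom_name, element, aa_code = NA_character_) {
  element <- toupper(trimws(element))
  polarity <- if (element %in% c("N", "O")) {
    "polar"
  } else if (element %in% c("C", "S")) {
    "nonpolar"
  } else if (element == "H") {
    "excluded"
  } else {
    warning("element '", element, "' not in polarity table; treated as nonpolar")
    "nonpolar"
  }
  list(
    is_backbone = trimws(atom_name) %in% BACKBONE_NAMES,
    polarity = polarity
  )
}

# Infer an element symbol from a PDB atom name when columns 77-78 are blank.
infer_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  if (nchar(nm) == 0) return("C")
  substr(nm, 1, 1)
}

#' Read a protein structure from PDB-format text
#'
#' Parses ATOM/HETATM records from fixed-column PDB text. Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken by file
#' order); waters and non-amino-acid heteroatoms are dropped unless
#' `keep_het = TRUE`. Every atom is classified with [classify_atom()].
#'
#' @param x path to a PDB file, or a character vector of PDB lines.
#' @param keep_het keep heteroatom residues that are not recognisable amino
#'   acids (default `FALSE`).
#' @return a `structure3d` object: list with `id` and `atoms`
#'   (data frame with chain, resno, resname, atom_name, element, x, y, z,
#'   occupancy, is_backbone, polarity, residue_key).
#' @export
read_pdb <- function(x, keep_het = FALSE) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    id <- tools::file_path_sans_ext(basename(x))
    lines <- readLines(x, warn = FALSE)
  } else {
    id <- "structure"
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  keep <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(keep) == 0) stop("empty model: no ATOM/HETATM records")

  fx <- function(l, a, b) substr(l, a, b)
  ln <- lines[keep]
  num <- function(s, field, lineno) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    bad <- which(is.na(v) & trimws(s) != "")
    bad2 <- which(trimws(s) == "")
    bad <- sort(c(bad, bad2))
    if (length(bad) > 0) {
      stop("malformed ", field, " field at line ", lineno[bad[1]])
    }
    v
  }
  lineno <- keep
  atoms <- data.frame(
    record = trimws(fx(ln, 1, 6)),
    atom_name = trimws(fx(ln, 13, 16)),
    altloc = fx(ln, 17, 17),
    resname = trimws(fx(ln, 18, 20)),
    chain = fx(ln, 22, 22),
    resno = as.integer(num(fx(ln, 23, 26), "residue number", lineno)),
    x = num(fx(ln, 31, 38), "x coordinate", lineno),
    y = num(fx(ln, 39, 46), "y coordinate", lineno),
    z = num(fx(ln, 47, 54), "z coordinate", lineno),
    occupancy = suppressWarnings(as.numeric(trimws(fx(ln, 55, 60)))),
    element = trimws(fx(ln, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  blank_el <- atoms$element == ""
  if (any(blank_el)) {
    atoms$element[blank_el] <- vapply(atoms$atom_name[blank_el], infer_element, "")
  }
  atoms$chain[atoms$chain == " "] <- "A"
  atoms$residue_key <- paste0(atoms$chain, ":", atoms$resno)

  # drop waters; drop non-amino-acid HETATM residues unless kept
  atoms <- atoms[!(atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
  if (!keep_het) {
    is_aa_res <- vapply(split(seq_len(nrow(atoms)), atoms$residue_key), function(i) {
      rn <- atoms$resname[i[1]]
      rn %in% STANDARD_AA3 || all(c("N", "CA", "C") %in% atoms$atom_name[i])
    }, logical(1))
    ok_keys <- names(is_aa_res)[is_aa_res]
    atoms <- atoms[atoms$residue_key %in% ok_keys, , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("empty model: no amino-acid residues after filtering")

  # altloc resolution: highest occupancy, first occurrence wins ties
  grp <- paste(atoms$residue_key, atoms$atom_name, sep = "|")
  ord <- order(match(grp, unique(grp)), -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$residue_key, atoms$atom_name, sep = "|")), , drop = FALSE]
  # restore file order of residues, atom order within residue
  atoms <- atoms[order(match(atoms$residue_key, unique(atoms$residue_key))), , drop = FALSE]
  rownames(atoms) <- NULL

  cls <- Map(function(n, e) suppressWarnings(classify_atom(n, e)),
             atoms$atom_name, atoms$element)
  atoms$is_backbone <- vapply(cls, `[[`, logical(1), "is_backbone")
  atoms$polarity <- vapply(cls, `[[`, character(1), "polarity")
  atoms$record <- NULL
  atoms$altloc <- NULL

  structure(list(id = id, atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", x$id, ": ", length(unique(x$atoms$residue_key)),
      " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Residue keys of a structure, in input order
#' @param s a `structure3d`.
#' @return character vector `"chain:resno"`.
#' @export
residue_keys <- function(s) unique(s$atoms$residue_key)

# CA coordinate matrix (rows named by residue key); NA rows dropped.
ca_coords <- function(s) {
  ca <- s$atoms[s$atoms$atom_name == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$residue_key
  m
}

residue_atoms <- function(s, key) {
  s$atoms[s$atoms$residue_key == key, , drop = FALSE]
}

#' Residues whose C-alpha lies within a sphere around the mutation site
#'
#' Implements the local-relax neighbourhood definition: residues with a
#' CA-CA distance to the site CA of at most `radius` (closed boundary),
#' excluding the site itself. Residues without a CA are skipped with a
#' warning.
#'
#' @param s a `structure3d`.
#' @param site residue key of the mutation site (`"chain:resno"`).
#' @param radius sphere radius in Angstrom (default 8.0).
#' @return character vector of residue keys, in structure order.
#' @export
sphere_residues <- function(s, site, radius = 8.0) {
  keys <- residue_keys(s)
  if (!site %in% keys) stop("site residue '", site, "' not in structure")
  ca <- ca_coords(s)
  if (!site %in% rownames(ca)) stop("site residue '", site, "' has no CA atom")
  missing_ca <- setdiff(keys, rownames(ca))
  if (length(missing_ca) > 0) {
    warning("residues without CA skipped: ", paste(missing_ca, collapse = ", "))
  }
  d <- sqrt(colSums((t(ca) - ca[site, ])^2))
  hits <- rownames(ca)[d <= radius & rownames(ca) != site]
  keys[keys %in% hits]
}

#' C-alpha root-mean-square deviation between two structures
#'
#' Both structures must share the same residue keys, each with a CA atom.
#' With `superpose = TRUE` an optimal least-squares rigid-body superposition
#' (Kabsch) is applied before computing the RMSD.
#'
#' @param a,b `structure3d` objects with identical residue keys.
#' @param superpose apply optimal superposition first (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b, superpose = TRUE) {
  ma <- ca_coords(a)
  mb <- ca_coords(b)
  if (!setequal(rownames(ma), rownames(mb))) {
    only_a <- setdiff(rownames(ma), rownames(mb))
    only_b <- setdiff(rownames(mb), rownames(ma))
    stop("residue sets differ; only in first: [",
         paste(only_a, collapse = ", "), "]; only in second: [",
         paste(only_b, collapse = ", "), "]")
  }
  mb <- mb[rownames(ma), , drop = FALSE]
  if (superpose) {
    ca_ <- colMeans(ma); cb_ <- colMeans(mb)
    xa <- sweep(ma, 2, ca_); xb <- sweep(mb, 2, cb_)
    h <- t(xb) %*% xa
    sv <- svd(h)
    d <- sign(det(sv$u %*% t(sv$v)))
    r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    xb <- xb %*% r
    ma <- xa; mb <- xb
  }
  sqrt(mean(rowSums((ma - mb)^2)))
}
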