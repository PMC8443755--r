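# Structure-independent bioinformatics features of the empirical feature
# matrix: the BLOSUM62 row of the wild-type residue, three transfer
# free-energy hydrophobicity scales, and a melting-temperature-change
# measure vs glycine. All are pure lookups in bundled tables (see
# inst/extdata for provenance).

check_aa1 <- function(wt_aa) {
  wt_aa <- toupper(wt_aa)
  if (length(wt_aa) != 1 || !wt_aa %in% AA1) {
    stop("'", wt_aa, "' is not a standard one-letter amino acid code")
  }
  wt_aa
}

#' BLOSUM62 substitution scores for a wild-type residue
#'
#' Returns the full BLOSUM62 row of the wild-type residue: the substitution
#' score of replacing it with each of the 20 standard amino acids, keyed
#' `blosum62_<aa>` with lowercase three-letter codes (e.g. `blosum62_his`,
#' the score for mutating the site residue to histidine).
#'
#' @param wt_aa one-letter wild-type residue code.
#' @return named integer vector of length 20.
#' @export
blosum_features <- function(wt_aa) {
  wt_aa <- check_aa1(wt_aa)
  tab <- load_table("blosum62.tsv")
  row <- tab[tab$aa == wt_aa, AA1, drop = TRUE]
  out <- as.integer(row)
  names(out) <- paste0("blosum62_", tolower(AA1_TO_3[AA1]))
  out
}

#' Transfer free-energy hydrophobicity features
#'
#' Three sidechain transfer free-energy scale values for the wild-type
#' residue: cyclohexane to water, vapor to water, and octanol to water
#' (kcal/mol). Sources documented in the bundled table header.
#'
#' @param wt_aa one-letter wild-type residue code.
#' @return named numeric vector: `kD_cyclohexane_water`, `kD_vapor_to_water`,
#'   `kD_octanol_to_water`.
#' @export
hydrophobicity_features <- function(wt_aa) {
  wt_aa <- check_aa1(wt_aa)
  tab <- load_table("hydrophobicity_scales.tsv")
  row <- tab[tab$aa == wt_aa, c("kD_cyclohexane_water", "kD_vapor_to_water",
                                "kD_octanol_to_water")]
  unlist(row)
}

#' Melting-temperature change vs glycine
#'
#' Lookup of the change in model-peptide melting temperature when the
#' wild-type residue replaces glycine (degrees C; glycine itself is 0). The
#' bundled table is a constructed synthetic stand-in (see its header) and can
#' be swapped for an exact source table.
#'
#' @param wt_aa one-letter wild-type residue code.
#' @return named numeric scalar `delta_t_d_m`.
#' @export
delta_tm_feature <- function(wt_aa) {
  wt_aa <- check_aa1(wt_aa)
  tab <- load_table("delta_tm_vs_gly_synthetic.tsv")
  c(delta_t_d_m = tab$delta_tm[tab$aa == wt_aa])
}

#' All structure-independent bioinformatics features for a residue
#'
#' @param wt_aa one-letter wild-type residue code.
#' @return named numeric vector: 20 BLOSUM62 scores, 3 hydrophobicity scale
#'   values, `delta_t_d_m` (24 entries).
#' @export
bioinfo_vector <- function(wt_aa) {
  c(blosum_features(wt_aa), hydrophobicity_features(wt_aa),
    delta_tm_feature(wt_aa))
}
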