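# Rosetta-style per-residue energy features: ingest per-residue per-term
# weighted score tables (REU, 5 replicates per variant), average replicates,
# and reduce WT/mutant pairs to `<term>_Site` and `<term>_8A` delta features.
#
# Score-table dialect:
#   #meta protein=<id> variant=<label> replicate=<int>
#   residue <term1> <term2> ...
#   <residue_key> <value> <value> ...
# Whitespace-delimited; one row per residue; scores are pre-weighted REU.

#' Parse a per-residue score table
#'
#' @param x path to a score-table file, or a character vector of lines.
#' @return a `score_table` object: list with `protein`, `variant`,
#'   `replicate`, `terms` (ordered character vector) and `scores` (numeric
#'   matrix, rows named by residue key, columns by term).
#' @export
parse_score_table <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) stop("score table too short: need meta, header and rows")
  meta <- lines[1]
  if (!startsWith(meta, "#meta")) stop("line 1: missing '#meta' line")
  get_meta <- function(key) {
    m <- regmatches(meta, regexec(paste0(key, "=(\\S+)"), meta))[[1]]
    if (length(m) < 2) stop("line 1: missing '", key, "=' in meta line")
    m[2]
  }
  protein <- get_meta("protein")
  variant <- get_meta("variant")
  replicate <- as.integer(get_meta("replicate"))
  if (is.na(replicate)) stop("line 1: replicate is not an integer")

  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (hdr[1] != "residue") stop("line 2: header must start with 'residue'")
  terms <- hdr[-1]
  if (length(terms) == 0) stop("line 2: no term names in header")

  body <- lines[-(1:2)]
  rows <- strsplit(trimws(body), "\\s+")
  n_col <- length(terms) + 1
  bad <- which(lengths(rows) != n_col)
  if (length(bad) > 0) {
    stop("line ", bad[1] + 2, ": expected ", n_col, " fields, got ",
         lengths(rows)[bad[1]])
  }
  keys <- vapply(rows, `[[`, "", 1)
  dup <- which(duplicated(keys))
  if (length(dup) > 0) {
    stop("line ", dup[1] + 2, ": duplicate residue '", keys[dup[1]], "'")
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(rows, `[`, -1))), ncol = length(terms),
           byrow = TRUE, dimnames = list(keys, terms)))
  if (anyNA(vals)) {
    bad_row <- which(apply(is.na(vals), 1, any))[1]
    stop("line ", bad_row + 2, ": malformed numeric score field")
  }
  structure(list(protein = protein, variant = variant, replicate = replicate,
                 terms = terms, scores = vals),
            class = "score_table")
}

#' Write a score table in the package dialect
#'
#' @param tab a `score_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  lines <- c(
    sprintf("#meta protein=%s variant=%s replicate=%d",
            tab$protein, tab$variant, tab$replicate),
    paste(c("residue", tab$terms), collapse = " "),
    vapply(rownames(tab$scores), function(k) {
      paste(c(k, format(tab$scores[k, ], digits = 17, trim = TRUE,
                        scientific = FALSE)), collapse = " ")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table> ", x$protein, "/", x$variant, " replicate ", x$replicate,
      ": ", nrow(x$scores), " residues x ", length(x$terms), " terms\n",
      sep = "")
  invisible(x)
}

#' Average replicate score tables per residue and term
#'
#' Arithmetic mean across replicates (typically the five independent local
#' relax runs) of every residue-by-term cell. All tables must agree on
#' protein, variant, residues and terms.
#'
#' @param tables list of `score_table` objects.
#' @return a `score_table` with the cell means (`replicate = NA`).
#' @export
average_replicates <- function(tables) {
  if (length(tables) == 0) stop("no tables to average")
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (t$protein != ref$protein || t$variant != ref$variant)
      stop("tables mix proteins/variants: ", t$protein, "/", t$variant,
           " vs ", ref$protein, "/", ref$variant)
    if (!identical(t$terms, ref$terms))
      stop("tables have inconsistent term sets")
    if (!identical(rownames(t$scores), rownames(ref$scores)))
      stop("tables have inconsistent residue sets")
  }
  reps <- vapply(tables, function(t) as.numeric(t$replicate), numeric(1))
  if (anyDuplicated(reps)) stop("duplicate replicate ids: ",
                                paste(reps[duplicated(reps)], collapse = ", "))
  mean_scores <- Reduce(`+`, lapply(tables, `[[`, "scores")) / length(tables)
  structure(list(protein = ref$protein, variant = ref$variant,
                 replicate = NA_integer_, terms = ref$terms,
                 scores = mean_scores),
            class = "score_table")
}

#' Site and contact-sphere energy-delta feature vector
#'
#' For every score term t, computes `t_Site` = mutant minus wild-type
#' averaged score at the mutation site, and `t_8A` = the mean of the
#' per-residue deltas over the contact-sphere residues (CA within 8 Angstrom
#' of the site). An empty sphere yields `t_8A = 0` with a warning.
#'
#' @param wt,mut replicate-averaged `score_table`s sharing residues and terms.
#' @param site residue key of the mutation site.
#' @param sphere character vector of sphere residue keys (excluding the site).
#' @return named numeric vector of length `2 * n_terms`
#'   (`<term>_Site`, `<term>_8A`), in REU.
#' @export
energy_delta_vector <- function(wt, mut, site, sphere) {
  if (!identical(wt$terms, mut$terms)) stop("wt and mut term sets differ")
  if (!identical(rownames(wt$scores), rownames(mut$scores)))
    stop("wt and mut residue sets differ")
  if (!site %in% rownames(wt$scores))
    stop("site residue '", site, "' missing from score tables")
  if (site %in% sphere) stop("sphere must not contain the site residue")
  missing_sphere <- setdiff(sphere, rownames(wt$scores))
  if (length(missing_sphere) > 0)
    stop("sphere residues missing from score tables: ",
         paste(missing_sphere, collapse = ", "))
  delta <- mut$scores - wt$scores
  site_d <- delta[site, ]
  if (length(sphere) == 0) {
    warning("empty contact sphere; all _8A entries set to 0")
    sph_d <- setNames(numeric(length(wt$terms)), wt$terms)
  } else {
    sph_d <- colMeans(delta[sphere, , drop = FALSE])
  }
  out <- c(site_d, sph_d)
  names(out) <- c(paste0(wt$terms, "_Site"), paste0(wt$terms, "_8A"))
  out
}
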