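# Synthetic inputs for every pipeline stage: ideal-helix structures with a
# bulky planar mutant sidechain standing in for the tricyclic acridone of
# Acd, replicate score tables with planted site/sphere energy shifts, and
# labelled feature matrices with a known sparse linear signal mirroring the
# 51-sample two-protein dataset shape.

#' Synthetic-data configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 5 replicate score tables per variant, planted site/sphere energy shifts
#' of 2.0 / 0.5 REU with 0.3 REU Gaussian noise, and labelled datasets of
#' 51 samples (32:19 across two pseudo-proteins) with 3 informative features
#' (coefficients 3, 2, 1) among 30; `noise_sd = 0.593` places the Bayes
#' accuracy of the induced labels at 0.95.
#'
#' @param seed integer seed.
#' @param n_residues residues in the helix (default 24).
#' @param site mutation-site residue number (default middle of the helix).
#' @param sidechain_size atom count of the bulky mutant sidechain (default 8).
#' @param terms score-term names for synthetic score tables.
#' @param replicates replicate tables per variant (default 5).
#' @param site_shift planted site delta, REU (default 2.0).
#' @param sphere_shift planted sphere delta, REU (default 0.5).
#' @param score_noise_sd per-cell Gaussian noise sd, REU (default 0.3).
#' @param n_samples labelled-dataset size (default 51).
#' @param n_features feature count (default 30).
#' @param informative indices of informative features (default 1:3).
#' @param coefficients their latent-model coefficients (default 3, 2, 1).
#' @param noise_sd latent-response noise sd (default 0.593).
#' @param protein_ratio two pseudo-protein sample counts (default c(32, 19)).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_residues = 24, site = NULL,
                         sidechain_size = 8,
                         terms = c("fa_atr", "fa_rep", "fa_sol",
                                   "rama_prepro", "residue_total_score"),
                         replicates = 5, site_shift = 2.0, sphere_shift = 0.5,
                         score_noise_sd = 0.3, n_samples = 51,
                         n_features = 30, informative = 1:3,
                         coefficients = c(3, 2, 1), noise_sd = 0.593,
                         protein_ratio = c(32, 19)) {
  site <- site %||% ceiling(n_residues / 2)
  stopifnot(n_residues >= 5, replicates >= 1, score_noise_sd >= 0,
            n_samples >= 20, all(informative <= n_features),
            length(informative) == length(coefficients))
  structure(list(seed = as.integer(seed), n_residues = n_residues,
                 site = site, sidechain_size = sidechain_size, terms = terms,
                 replicates = replicates, site_shift = site_shift,
                 sphere_shift = sphere_shift, score_noise_sd = score_noise_sd,
                 n_samples = n_samples, n_features = n_features,
                 informative = informative, coefficients = coefficients,
                 noise_sd = noise_sd, protein_ratio = protein_ratio),
            class = "synth_config")
}

# Cylindrical helix placement: radius r, phase offset dphi (deg), rise dz
# relative to the CA helix angle of residue i.
helix_point <- function(i, r, dphi, dz) {
  th <- (i * 100 + dphi) * pi / 180
  c(r * cos(th), r * sin(th), i * 1.5 + dz)
}

#' Generate an ideal alpha-helix structure
#'
#' Backbone N/CA/C/O plus a single CB template sidechain atom per residue,
#' on an ideal alpha-helical cylinder (1.5 Angstrom rise and 100 degrees
#' twist per residue, consecutive CA-CA ~ 3.8 Angstrom). Residues are
#' alanine, chain A, numbered from 1.
#'
#' @param cfg a `synth_config` (only `n_residues` is used).
#' @return a `structure3d`.
#' @export
make_helix_structure <- function(cfg) {
  n <- cfg$n_residues
  rows <- list()
  for (i in seq_len(n)) {
    at <- rbind(
      N  = helix_point(i, 1.6, -28.9, -0.9),
      CA = helix_point(i, 2.3, 0, 0),
      C  = helix_point(i, 2.0, 31, 0.95),
      O  = helix_point(i, 3.2, 31, 1.15),
      CB = helix_point(i, 3.8, 0, 0)
    )
    rows[[i]] <- data.frame(
      atom_name = rownames(at), resname = "ALA", chain = "A", resno = i,
      x = at[, 1], y = at[, 2], z = at[, 3],
      element = substr(rownames(at), 1, 1), occupancy = 1.0,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  atoms$residue_key <- paste0(atoms$chain, ":", atoms$resno)
  cls <- Map(classify_atom, atoms$atom_name, atoms$element)
  atoms$is_backbone <- vapply(cls, `[[`, logical(1), "is_backbone")
  atoms$polarity <- vapply(cls, `[[`, character(1), "polarity")
  structure(list(id = "synthetic_helix", atoms = atoms), class = "structure3d")
}

#' Write a structure as PDB-format text
#'
#' Fixed-column ATOM records, occupancy 1.00, B-factor 0.00, coordinates to
#' 3 decimals (PDB precision).
#'
#' @param s a `structure3d`.
#' @param path output path; omit to return the lines invisibly only.
#' @return character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, ifelse(nchar(a$atom_name[i]) < 4,
                      paste0(" ", a$atom_name[i]), a$atom_name[i]),
            a$resname[i], a$chain[i], a$resno[i],
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0.0, a$element[i])
  }, "")
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Replace a site sidechain with a bulky planar dummy
#'
#' Strips the site residue's sidechain and grafts a planar fused-ring dummy
#' of `sidechain_size` nonpolar carbon pseudo-atoms extending outward along
#' the CA-CB direction (two staggered rows at aromatic ~1.4 Angstrom
#' spacing), mimicking a tricyclic acridone-like sidechain. All other
#' residues are untouched. Atoms are placed even if they clash with the
#' residue's own backbone (a warning is emitted): perturbed contacts are the
#' point.
#'
#' @param s a `structure3d`.
#' @param site residue key of the mutation site.
#' @param sidechain_size number of dummy sidechain atoms.
#' @return a `structure3d` with resname `ACD` at the site.
#' @export
make_bulky_mutant <- function(s, site, sidechain_size = 8) {
  atoms <- s$atoms
  if (!site %in% atoms$residue_key) stop("site residue '", site, "' not found")
  at_site <- atoms$residue_key == site
  res <- atoms[at_site, , drop = FALSE]
  ca <- as.numeric(res[res$atom_name == "CA", c("x","y","z")])
  cb <- res[res$atom_name == "CB", c("x","y","z")]
  u <- if (nrow(cb) == 1) as.numeric(cb) - ca else {
    v <- ca; v[3] <- 0; v / sqrt(sum(v^2)) # radial fallback
  }
  u <- u / sqrt(sum(u^2))
  # in-plane orthogonal: helix axis (z) component removed, then cross product
  w <- c(-u[2], u[1], 0)
  if (sqrt(sum(w^2)) < 1e-8) w <- c(1, 0, 0)
  w <- w / sqrt(sum(w^2))
  # two staggered rows of ring atoms marching outward from CB position
  pos <- t(vapply(seq_len(sidechain_size), function(j) {
    row <- (j - 1) %% 2
    col <- (j - 1) %/% 2
    ca + u * (1.5 + 1.4 * (col + 1)) + w * (row * 1.4 - 0.7)
  }, numeric(3)))
  keep <- res[res$is_backbone, , drop = FALSE]
  dummy <- data.frame(
    atom_name = sprintf("D%02d", seq_len(sidechain_size)),
    resname = "ACD", chain = keep$chain[1], resno = keep$resno[1],
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    element = "C", occupancy = 1.0,
    residue_key = site, is_backbone = FALSE, polarity = "nonpolar",
    stringsAsFactors = FALSE)
  keep$resname <- "ACD"
  bb <- as.matrix(keep[, c("x","y","z")])
  mind <- min(apply(pos, 1, function(p) min(sqrt(rowSums((bb - rep(p, each = nrow(bb)))^2)))))
  if (mind < 1.0) warning("dummy sidechain clashes with its own backbone (min ",
                          round(mind, 2), " Angstrom); atoms placed anyway")
  new_site <- rbind(keep[, names(dummy)], dummy)
  out <- atoms[!at_site, , drop = FALSE]
  # reinsert at the site's original position to keep residue order stable
  before <- which(atoms$residue_key == site)[1] - 1
  pre_keys <- unique(atoms$residue_key[seq_len(before)])
  out <- rbind(out[out$residue_key %in% pre_keys, , drop = FALSE],
               new_site,
               out[!out$residue_key %in% pre_keys, , drop = FALSE])
  rownames(out) <- NULL
  structure(list(id = paste0(s$id, "_mut"), atoms = out), class = "structure3d")
}

#' Generate WT and mutant replicate score tables with planted shifts
#'
#' Wild-type cells are i.i.d. Gaussian noise around zero; mutant cells
#' scatter with fresh noise around the empirical WT replicate mean plus the
#' planted `site_shift` at the site residue and `sphere_shift` at the
#' contact-sphere residues (CA within 8 Angstrom on the generated helix).
#' With zero noise the energy-delta vector recovers the planted shifts
#' exactly; with noise the recovery error has standard deviation
#' `score_noise_sd / sqrt(replicates)` at the site.
#'
#' @param cfg a `synth_config`.
#' @return list with `wt` and `mut` (lists of `score_table` replicates),
#'   `site` (residue key) and `sphere` (residue keys).
#' @export
make_score_tables <- function(cfg) {
  helix <- make_helix_structure(cfg)
  keys <- residue_keys(helix)
  site <- paste0("A:", cfg$site)
  sphere <- sphere_residues(helix, site, radius = 8.0)
  nt <- length(cfg$terms)
  nr <- length(keys)
  shift <- matrix(0, nr, nt, dimnames = list(keys, cfg$terms))
  shift[site, ] <- cfg$site_shift
  shift[sphere, ] <- cfg$sphere_shift
  mk <- function(variant, rep_id, base) {
    noise <- matrix(stats::rnorm(nr * nt, 0, cfg$score_noise_sd), nr, nt)
    structure(list(protein = "SYNTH", variant = variant,
                   replicate = rep_id, terms = cfg$terms,
                   scores = base + noise),
              class = "score_table")
  }
  with_seed(cfg$seed, {
    zero <- matrix(0, nr, nt, dimnames = list(keys, cfg$terms))
    wt <- lapply(seq_len(cfg$replicates), function(r) mk("WT", r, zero))
    # mutant replicates scatter around the empirical WT replicate mean plus
    # the planted shifts, so the WT noise cancels from the deltas and the
    # recovery error is governed by the fresh noise alone (sd sigma/sqrt(m))
    wt_mean <- Reduce(`+`, lapply(wt, `[[`, "scores")) / cfg$replicates
    mut <- lapply(seq_len(cfg$replicates), function(r)
      mk(paste0("site", cfg$site), r, wt_mean + shift))
    list(wt = wt, mut = mut, site = site, sphere = sphere)
  })
}

# deterministic proportional interleave of two protein tags
interleave_proteins <- function(n, ratio) {
  n1 <- round(n * ratio[1] / sum(ratio))
  tags <- character(n)
  c1 <- 0
  for (i in seq_len(n)) {
    # assign protein 1 whenever it is behind its quota
    if (c1 < i * n1 / n) { tags[i] <- "ProtA"; c1 <- c1 + 1 }
    else tags[i] <- "ProtB"
  }
  tags
}

#' Generate a labelled feature dataset with known sparse signal
#'
#' Features are i.i.d. standard normal; a latent response is a sparse linear
#' combination (`coefficients` at `informative` indices) plus Gaussian
#' noise; labels are `active` strictly above the latent median (balanced
#' within one sample). Samples are tagged to two pseudo-proteins at the
#' configured ratio, and phenotype-style records (soluble/total yield,
#' soluble fraction) are derived from the latent response so holdout
#' construction can be exercised on the dataset shape of the study.
#'
#' @param cfg a `synth_config`.
#' @return list with `X` (matrix), `labels` (factor), `latent` (numeric),
#'   `records` (phenotype data frame), `cutoff` (label cutoff on the latent
#'   scale).
#' @export
make_labeled_dataset <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_samples; p <- cfg$n_features
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("feat_%02d", seq_len(p))))
    beta <- numeric(p)
    beta[cfg$informative] <- cfg$coefficients
    latent <- as.numeric(X %*% beta) + stats::rnorm(n, 0, cfg$noise_sd)
    cutoff <- stats::median(latent)
    labels <- binarize_response(latent, cutoff)
    protein <- interleave_proteins(n, cfg$protein_ratio)
    soluble_fraction <- 100 * stats::plogis(latent - cutoff)
    total <- round(1600 * exp(stats::rnorm(n, 0, 0.5)), 1)
    soluble <- round(total * soluble_fraction / 100, 1)
    records <- data.frame(
      protein = protein,
      site = seq_len(n),
      wt_aa = sample(AA1, n, replace = TRUE),
      soluble_yield_nM = soluble,
      total_yield_nM = total,
      soluble_fraction_pct = round(soluble_fraction, 2),
      stringsAsFactors = FALSE)
    list(X = X, labels = labels, latent = latent, records = records,
         cutoff = cutoff)
  })
}
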