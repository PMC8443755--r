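# Independent oracles and fixture builders used across the suite.

# Build a structure3d directly from atom rows (bypasses read_pdb).
toy_structure <- function(df, id = "toy") {
  df$chain <- df$chain %||% "A"
  df$occupancy <- df$occupancy %||% 1.0
  df$residue_key <- paste0(df$chain, ":", df$resno)
  cls <- Map(function(n, e) suppressWarnings(classify_atom(n, e)),
             df$atom_name, df$element)
  df$is_backbone <- vapply(cls, `[[`, logical(1), "is_backbone")
  df$polarity <- vapply(cls, `[[`, character(1), "polarity")
  structure(list(id = id, atoms = df), class = "structure3d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force contact oracle: naive double loop over every atom pair,
# reclassifying categories and exclusions from scratch. Bonds are inferred
# from distance (<= 1.8 A) within residues; 1-2/1-3 exclusion by two-step
# graph expansion; peptide-junction exclusion by the same distance rule
# applied across sequence-adjacent residues' N/C/CA/O atoms.
oracle_contacts <- function(s, site, cutoff = 4.0) {
  a <- s$atoms[s$atoms$polarity != "excluded", , drop = FALSE]
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cats <- c(outer(c("p", "np"),
                  c(outer(c("bb_bb", "bb_sc", "sc_sc"), c("intra", "inter"),
                          paste, sep = "_")),
                  paste, sep = "_"))
  counts <- setNames(rep(0L, length(cats)), cats)

  # intra-residue 1-2/1-3 exclusion sets per residue (distance-inferred,
  # matching the production rule for unknown residue types; toys used with
  # this oracle must use non-template residue names)
  excl <- list()
  for (k in unique(a$residue_key)) {
    i <- which(a$residue_key == k)
    if (length(i) < 2) next
    d <- as.matrix(dist(xyz[i, , drop = FALSE]))
    bonded <- d > 0 & d <= 1.8
    two_step <- (bonded %*% bonded) > 0
    near <- bonded | two_step
    pairs <- which(near & upper.tri(near), arr.ind = TRUE)
    excl[[k]] <- paste(pmin(i[pairs[, 1]], i[pairs[, 2]]),
                       pmax(i[pairs[, 1]], i[pairs[, 2]]), sep = "_")
  }
  junction_excl <- function(ai, aj) {
    # sequence-adjacent residues: exclude peptide-bond 1-2/1-3 name pairs
    ri <- a$resno[ai]; rj <- a$resno[aj]
    ni <- a$atom_name[ai]; nj <- a$atom_name[aj]
    if (ri + 1L == rj) {
      paste(ni, nj) %in% c("C N", "CA N", "O N", "C CA")
    } else if (rj + 1L == ri) {
      paste(nj, ni) %in% c("C N", "CA N", "O N", "C CA")
    } else FALSE
  }

  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    in_i <- a$residue_key[i] == site
    in_j <- a$residue_key[j] == site
    if (!in_i && !in_j) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d >= cutoff) next
    if (in_i && in_j) {
      key <- paste(min(i, j), max(i, j), sep = "_")
      if (key %in% excl[[site]]) next
      loc <- "intra"
    } else {
      if (a$chain[i] == a$chain[j] && junction_excl(i, j)) next
      loc <- "inter"
    }
    pol <- if (a$polarity[i] == "nonpolar" && a$polarity[j] == "nonpolar")
      "np" else "p"
    pair <- if (a$is_backbone[i] && a$is_backbone[j]) "bb_bb"
    else if (!a$is_backbone[i] && !a$is_backbone[j]) "sc_sc"
    else "bb_sc"
    cc <- paste(pol, pair, loc, sep = "_")
    counts[cc] <- counts[cc] + 1L
  }
  np <- sum(counts[startsWith(names(counts), "np_")])
  p <- sum(counts[startsWith(names(counts), "p_")])
  c(counts, total_contacts = np + p, total_np_contacts = np,
    total_p_contacts = p)
}

# Monte-Carlo surface-area oracle for a set of spheres: sample points
# uniformly on each sphere, count the fraction not buried in any other.
oracle_mc_area <- function(centers, radii, n_samples = 1e5, seed = 1) {
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(centers))) {
    u <- matrix(rnorm(n_samples * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * radii[i], 2, centers[i, ], `+`)
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(nrow(centers))) {
      if (j == i) next
      dj <- sqrt(colSums((t(pts) - centers[j, ])^2))
      acc <- acc & dj >= radii[j]
    }
    total <- total + 4 * pi * radii[i]^2 * mean(acc)
  }
  total
}

# random toy structure for the contact oracle: a few residues of random
# atoms with a mix of backbone-like and dummy names, non-template resnames
random_toy <- function(seed, n_res = 4, atoms_per_res = 12) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_res)) {
    k <- sample(3:atoms_per_res, 1)
    nm <- c("N", "CA", "C", "O", sprintf("D%d", seq_len(max(0, k - 4))))[1:k]
    rows[[r]] <- data.frame(
      atom_name = nm,
      resname = "UNK", chain = "A", resno = r,
      x = rnorm(k, r * 4, 2), y = rnorm(k, 0, 2), z = rnorm(k, 0, 2),
      element = sample(c("C", "N", "O", "S"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  toy_structure(do.call(rbind, rows), id = paste0("rand", seed))
}
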