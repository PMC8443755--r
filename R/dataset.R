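# Mutant phenotype handling: the experimental readouts per Acd mutant
# (soluble yield nM, total yield nM, soluble fraction %), their binarization
# at the balance cutoffs, and the protein-balanced 20% holdout split.

#' Default response-class balance cutoffs
#'
#' Cutoffs that balance the active/inactive classes of the mutant dataset:
#' soluble yield 520 nM, total yield 1600 nM, soluble fraction 39%.
#' @return named numeric vector.
#' @export
default_cutoffs <- function() {
  c(soluble_yield_nM = 520, total_yield_nM = 1600, soluble_fraction_pct = 39)
}

#' Read a mutant phenotype table
#'
#' CSV with columns protein, site, wt_aa, soluble_yield_nM, total_yield_nM,
#' soluble_fraction_pct. Validates non-negative yields, soluble fraction in
#' \[0, 100\], and (when both yields are present) consistency of the fraction
#' with 100 * soluble / total within rounding.
#'
#' @param path CSV file path.
#' @param tol absolute tolerance (percentage points) for the fraction
#'   consistency check (default 1).
#' @return data frame of mutant records.
#' @export
read_phenotypes <- function(path, tol = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "site", "wt_aa", "soluble_yield_nM", "total_yield_nM",
            "soluble_fraction_pct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("phenotype table missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(df$soluble_yield_nM < 0, na.rm = TRUE) ||
      any(df$total_yield_nM < 0, na.rm = TRUE)) stop("negative yields")
  if (any(df$soluble_fraction_pct < 0 | df$soluble_fraction_pct > 100,
          na.rm = TRUE)) stop("soluble_fraction_pct outside [0, 100]")
  both <- !is.na(df$soluble_yield_nM) & !is.na(df$total_yield_nM) &
    df$total_yield_nM > 0 & !is.na(df$soluble_fraction_pct)
  implied <- 100 * df$soluble_yield_nM[both] / df$total_yield_nM[both]
  bad <- which(abs(implied - df$soluble_fraction_pct[both]) > tol)
  if (length(bad) > 0) {
    stop("soluble_fraction_pct inconsistent with yields at rows: ",
         paste(which(both)[bad], collapse = ", "))
  }
  df
}

#' Binarize a response at a balance cutoff
#'
#' A sample is `active` if its value is strictly above the cutoff and
#' `inactive` at or below it (values equal to the cutoff are inactive).
#'
#' @param values numeric response values.
#' @param cutoff finite numeric cutoff.
#' @return factor with levels `c("inactive", "active")`.
#' @export
binarize_response <- function(values, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (anyNA(values)) {
    stop("missing response value at records: ",
         paste(which(is.na(values)), collapse = ", "))
  }
  factor(ifelse(values > cutoff, "active", "inactive"),
         levels = c("inactive", "active"))
}

#' Construct a protein-balanced, response-representative holdout split
#'
#' The holdout comprises `round(frac * n)` samples (round half away from
#' zero), allocated as equally as possible across proteins, and drawn within
#' each protein proportionally from response quartiles so the held-out
#' response distribution is representative. Seed-deterministic. An explicit
#' holdout membership can be supplied instead via `holdout_idx` (to mirror a
#' published holdout list).
#'
#' @param protein character vector of protein ids, one per sample.
#' @param response numeric response values used for representative
#'   stratification.
#' @param frac holdout fraction in (0, 0.5] (default 0.2).
#' @param seed integer seed.
#' @param holdout_idx optional explicit holdout indices (overrides sampling).
#' @return a `split_spec`: list with `train`, `holdout` (integer indices),
#'   `seed` and `per_protein` holdout counts.
#' @export
make_holdout <- function(protein, response, frac = 0.2, seed = 1,
                         holdout_idx = NULL) {
  n <- length(protein)
  if (length(response) != n) stop("protein and response lengths differ")
  if (!is.null(holdout_idx)) {
    holdout_idx <- sort(unique(as.integer(holdout_idx)))
    if (any(holdout_idx < 1 | holdout_idx > n)) stop("holdout_idx out of range")
    spec <- list(train = setdiff(seq_len(n), holdout_idx),
                 holdout = holdout_idx, seed = NA_integer_,
                 per_protein = table(protein[holdout_idx]))
    class(spec) <- "split_spec"
    return(spec)
  }
  if (frac <= 0 || frac > 0.5) stop("holdout fraction must be in (0, 0.5]")
  prots <- unique(protein)
  if (length(prots) < 2) stop("need at least 2 proteins")
  tab <- table(factor(protein, levels = prots))
  if (any(tab < 5)) stop("need at least 5 records per protein")

  h_total <- as.integer(round_half_away(frac * n))
  # equal per-protein allocation; remainder goes to the larger proteins first
  p <- length(prots)
  base <- h_total %/% p
  extra <- h_total %% p
  alloc <- setNames(rep(base, p), prots)
  if (extra > 0) {
    order_by_size <- names(sort(tab, decreasing = TRUE))
    alloc[order_by_size[seq_len(extra)]] <- base + 1L
  }
  alloc <- pmin(alloc, as.integer(tab))

  holdout <- integer(0)
  # quartile bins of the full response distribution, so the held-out
  # response distribution tracks the dataset's (and any cutoff-defined
  # class balance) rather than each protein's internal quantiles
  qs <- stats::quantile(response, probs = c(0.25, 0.5, 0.75), type = 7)
  with_seed(seed, {
    for (pr in prots) {
      idx <- which(protein == pr)
      k <- alloc[[pr]]
      if (k == 0) next
      bin <- findInterval(response[idx], qs, left.open = TRUE) + 1L
      bins <- split(idx, bin)
      # proportional allocation with largest remainders
      quota <- k * lengths(bins) / length(idx)
      take <- floor(quota)
      rem <- k - sum(take)
      if (rem > 0) {
        # largest remainders first; exact ties broken at random (seeded) so
        # no response quartile is systematically favoured
        o <- order(-(quota - take), stats::runif(length(take)))
        take[o[seq_len(rem)]] <- take[o[seq_len(rem)]] + 1
      }
      take <- pmin(take, lengths(bins))
      short <- k - sum(take)
      if (short > 0) { # spill into bins with spare capacity
        spare <- lengths(bins) - take
        o <- order(spare, decreasing = TRUE)
        for (i in o) {
          add <- min(short, spare[i]); take[i] <- take[i] + add
          short <- short - add
          if (short == 0) break
        }
      }
      for (b in seq_along(bins)) {
        if (take[b] > 0) {
          pick <- sample.int(length(bins[[b]]), take[b])
          holdout <- c(holdout, bins[[b]][pick])
        }
      }
    }
  })
  holdout <- sort(holdout)
  spec <- list(train = setdiff(seq_len(n), holdout), holdout = holdout,
               seed = as.integer(seed),
               per_protein = table(factor(protein[holdout], levels = prots)))
  class(spec) <- "split_spec"
  spec
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec> train ", length(x$train), " / holdout ", length(x$holdout),
      " (seed ", x$seed, ")\n", sep = "")
  print(x$per_protein)
  invisible(x)
}

#' Serialize a split to JSON
#' @param spec a `split_spec`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(spec, path) {
  jsonlite::write_json(
    list(train = spec$train, holdout = spec$holdout, seed = spec$seed,
         per_protein = as.list(spec$per_protein)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
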