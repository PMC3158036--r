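# Empirical genotype-fitness tables of the A. niger type: reading/writing,
# subgraph ensembles, lethality-parameter estimation, the subgraph summary
# table and the fitness-resampling analysis.

#' Construct an empirical genotype-fitness dataset
#'
#' Holds the mean fitness of every one of the `2^L0` genotypes of an
#' L0-locus cross. Genotypes absent from the measured table are flagged
#' `missing` and carry fitness 0 (the analyses treat them as non-viable,
#' which is justified when the Poisson missing-genotype statistics of
#' [missed_genotype_stats()] rule out loss by chance). Optional replicate
#' fitness columns allow the measurement noise scale to be estimated.
#'
#' @param locus_names character vector of L0 locus labels, in bit order.
#' @param fitness numeric vector of length `2^L0` of mean fitness values
#'   (0 for non-viable/missing genotypes), genotype-index order.
#' @param missing logical vector of length `2^L0`; missing genotypes must
#'   have fitness 0.
#' @param rep1,rep2 optional replicate fitness vectors (NA where missing).
#' @return An object of class `"empirical_dataset"`.
#' @export
empirical_dataset <- function(locus_names, fitness, missing = fitness == 0,
                              rep1 = NULL, rep2 = NULL) {
  L0 <- length(locus_names)
  stopifnot(L0 >= 1, length(fitness) == 2^L0, length(missing) == 2^L0)
  if (any(fitness < 0)) stop("negative fitness", call. = FALSE)
  if (any(missing & fitness != 0))
    stop("missing genotypes must carry fitness 0", call. = FALSE)
  structure(list(L0 = L0, locus_names = as.character(locus_names),
                 fitness = as.numeric(fitness),
                 missing = as.logical(missing),
                 rep1 = rep1, rep2 = rep2),
            class = "empirical_dataset")
}

#' @export
print.empirical_dataset <- function(x, ...) {
  cat(sprintf("Empirical %d-locus fitness dataset: %d measured, %d missing\n",
              x$L0, sum(!x$missing), sum(x$missing)))
  cat("  loci:", paste(x$locus_names, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a dataset to a fitness landscape
#'
#' @param ds an [empirical_dataset()].
#' @return A [landscape()] with missing genotypes at fitness 0.
#' @export
as_landscape <- function(ds) {
  stopifnot(inherits(ds, "empirical_dataset"))
  landscape(ds$fitness, locus_names = ds$locus_names)
}

#' Read a genotype-fitness table
#'
#' Expects a tab-separated file with a header of L0 locus names followed by
#' `fitness` (and optionally `fitness_rep1`, `fitness_rep2`), one row per
#' measured genotype with 0/1 mutation-presence entries. Genotypes absent
#' from the file are the missing set and are assigned fitness 0; a row may
#' alternatively mark a missing genotype explicitly with the sentinel `x`
#' in its fitness column(s).
#'
#' @param path path to the TSV file.
#' @return An [empirical_dataset()].
#' @export
read_fitness_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  fit_cols <- intersect(c("fitness", "fitness_rep1", "fitness_rep2"),
                        names(tab))
  if (!"fitness" %in% fit_cols)
    stop("table must contain a 'fitness' column", call. = FALSE)
  locus_names <- setdiff(names(tab), fit_cols)
  L0 <- length(locus_names)
  if (L0 < 1) stop("no locus columns found", call. = FALSE)

  geno <- as.matrix(tab[, locus_names, drop = FALSE])
  if (!all(geno %in% c("0", "1")))
    stop("non-binary genotype field", call. = FALSE)
  geno <- matrix(as.integer(geno), nrow = nrow(tab))
  idx <- as.integer(geno %*% 2^(0:(L0 - 1L))) + 1L
  if (anyDuplicated(idx))
    stop("duplicate genotype rows", call. = FALSE)

  parse_fit <- function(col) {
    v <- rep(NA_real_, 2^L0)
    sentinel <- tab[[col]] %in% c("x", "X")
    num <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(num) & !sentinel))
      stop("unparseable fitness value in column ", col, call. = FALSE)
    if (any(num < 0, na.rm = TRUE))
      stop("negative fitness", call. = FALSE)
    v[idx[!sentinel]] <- num[!sentinel]
    v
  }
  fit <- parse_fit("fitness")
  missing <- is.na(fit)
  fit[missing] <- 0
  # replicate values share the zero-fitness assignment of missing genotypes
  parse_rep <- function(col) {
    v <- parse_fit(col)
    v[missing] <- 0
    v
  }
  rep1 <- if ("fitness_rep1" %in% fit_cols) parse_rep("fitness_rep1")
  rep2 <- if ("fitness_rep2" %in% fit_cols) parse_rep("fitness_rep2")
  empirical_dataset(locus_names, fit, missing, rep1 = rep1, rep2 = rep2)
}

#' Write a genotype-fitness table
#'
#' Emits the TSV dialect read by [read_fitness_table()]; the round trip is
#' exact. Missing genotypes are either omitted from the rows
#' (`style = "omit"`) or written with the sentinel `x` in the fitness
#' column(s) (`style = "sentinel"`).
#'
#' @param ds an [empirical_dataset()].
#' @param path output path.
#' @param style `"omit"` or `"sentinel"` handling of missing genotypes.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, style = c("omit", "sentinel")) {
  stopifnot(inherits(ds, "empirical_dataset"))
  style <- match.arg(style)
  L0 <- ds$L0
  geno <- bit_matrix(L0)
  colnames(geno) <- ds$locus_names
  fmt <- function(v) ifelse(is.na(v) | ds$missing, "x",
                            sprintf("%.17g", v))
  out <- data.frame(geno, check.names = FALSE)
  out$fitness <- fmt(ds$fitness)
  if (!is.null(ds$rep1)) out$fitness_rep1 <- fmt(ds$rep1)
  if (!is.null(ds$rep2)) out$fitness_rep2 <- fmt(ds$rep2)
  if (style == "omit") out <- out[!ds$missing, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate locus subsets of a given size
#'
#' All `C(L0, L)` size-L subsets of the L0 loci, in deterministic
#' lexicographic order; each subset spans one subgraph of the full
#' landscape (see [subgraph()]).
#'
#' @param L0 total number of loci.
#' @param L subset size, `1 <= L <= L0`.
#' @return List of integer vectors of locus indices.
#' @export
enumerate_subgraphs <- function(L0, L) {
  stopifnot(L >= 1, L <= L0)
  combn(L0, L, simplify = FALSE)
}

#' Is a subgraph fully viable?
#'
#' A viable subgraph (VSG) contains no non-viable genotype, i.e. every
#' fitness value in it is positive.
#'
#' @param sub a [landscape()] (typically from [subgraph()]).
#' @return Logical.
#' @export
is_viable_subgraph <- function(sub) {
  stopifnot(inherits(sub, "landscape"))
  all(sub$fitness > 0)
}

#' Estimate the two-parameter lethality model from a dataset
#'
#' Method-of-moments fit of the multiplicative lethality model: under the
#' model the expected number of viable genotypes among those not carrying
#' the focal mutation is `(2 - p_common)^(L0-1)`, and the expected total is
#' `(2 - p_focal) (2 - p_common)^(L0-1)`. Equating both to the observed
#' counts gives
#' `p_common = 2 - N_nofocal^(1/(L0-1))` and
#' `p_focal = 2 - N_total / N_nofocal`.
#'
#' @param ds an [empirical_dataset()].
#' @param focal focal locus, as a name in `locus_names` or a 1-based index.
#' @return A [lethality_model()]; estimates outside `[0, 1]` are an error.
#' @export
estimate_lethality <- function(ds, focal) {
  stopifnot(inherits(ds, "empirical_dataset"))
  focal <- match_locus(ds, focal)
  viable <- ds$fitness > 0
  has_focal <- bit_matrix(ds$L0)[, focal] == 1L
  n_nofocal <- sum(viable & !has_focal)
  n_total <- sum(viable)
  if (n_nofocal < 1)
    stop("no viable focal-free genotypes; cannot estimate", call. = FALSE)
  p_common <- 2 - n_nofocal^(1 / (ds$L0 - 1))
  p_focal <- 2 - n_total / n_nofocal
  if (p_common < 0 || p_common > 1 || p_focal < 0 || p_focal > 1)
    stop("no lethality-model solution in [0, 1] (p_common = ",
         signif(p_common, 3), ", p_focal = ", signif(p_focal, 3), ")",
         call. = FALSE)
  lethality_model(p_common, p_focal, ds$L0)
}

match_locus <- function(ds, focal) {
  if (is.character(focal)) {
    i <- match(focal, ds$locus_names)
    if (is.na(i)) stop("unknown locus: ", focal, call. = FALSE)
    i
  } else {
    i <- as.integer(focal)
    stopifnot(i >= 1, i <= ds$L0)
    i
  }
}

#' Replicate measurement noise scale
#'
#' Estimates the common per-measurement standard deviation from the mean
#' squared difference between the two replicate fitness values across all
#' measured genotypes: `sigma = sqrt(mean((rep1 - rep2)^2) / 2)`.
#'
#' @param ds an [empirical_dataset()] with replicate columns.
#' @return Estimated standard deviation of a single fitness measurement.
#' @export
replicate_sigma <- function(ds) {
  stopifnot(inherits(ds, "empirical_dataset"))
  if (is.null(ds$rep1) || is.null(ds$rep2))
    stop("dataset carries no replicate measurements", call. = FALSE)
  d <- (ds$rep1 - ds$rep2)[!ds$missing]
  sqrt(mean(d^2, na.rm = TRUE) / 2)
}

#' Resample a dataset's fitness values
#'
#' Draws one realization of the measurement-noise ensemble: every viable
#' genotype's fitness is perturbed by independent normal noise with
#' standard deviation `sigma` (default: estimated via [replicate_sigma()]),
#' while non-viable genotypes stay at exactly 0 -- the viability
#' classification is frozen at the measured one. Resampled values are not
#' truncated; in the rare event that a viable value is driven to or below
#' 0, all viable values are shifted up by a common constant, which
#' preserves the fitness ranking (and hence all accessibility statistics)
#' while keeping viable fitness positive.
#'
#' @param ds an [empirical_dataset()].
#' @param sigma noise standard deviation (`>= 0`).
#' @param seed integer seed.
#' @return An [empirical_dataset()] with perturbed fitness values.
#' @export
resample_dataset <- function(ds, sigma = NULL, seed = NULL) {
  stopifnot(inherits(ds, "empirical_dataset"))
  if (is.null(sigma)) sigma <- replicate_sigma(ds)
  stopifnot(sigma >= 0)
  f <- ds$fitness
  viable <- !ds$missing & f > 0
  f[viable] <- f[viable] + with_seed(seed, rnorm(sum(viable), 0, sigma))
  if (any(f[viable] <= 0))
    f[viable] <- f[viable] - min(f[viable]) + 1e-9
  empirical_dataset(ds$locus_names, f, missing = ds$missing,
                    rep1 = ds$rep1, rep2 = ds$rep2)
}

#' Subgraph accessibility summary table
#'
#' For each subgraph size L, enumerates all `C(L0, L)` subgraphs sharing the
#' wildtype and summarizes: the number of viable subgraphs (VSGs) with the
#' lethality-model prediction of [expected_vsg()]; the mean number of
#' lethal-free wildtype-to-L-mutant paths with the prediction of
#' [expected_lethal_free()]; the mean number of selectively accessible
#' paths; and the fraction `p_zero` of subgraphs with no accessible path.
#'
#' Accessible paths run from the subgraph's global fitness maximum to its
#' antipode within the subgraph (`axis = "global_max"`, the general
#' definition) or along the wildtype-to-full-mutant axis
#' (`axis = "wildtype"`). Lethal-free paths always use the
#' wildtype-to-full-mutant axis. A subgraph whose maximal fitness is tied
#' cannot be assigned a unique maximum: such subgraphs are recorded in the
#' `"skipped"` attribute and excluded from the accessible-path averages
#' (`n_skipped` column) rather than tie-broken silently.
#'
#' With `resample_reps > 0` the accessible-path and lethal-free columns are
#' averaged over that many measurement-noise realizations (see
#' [resample_dataset()]), and `mean_paths_sd`/`p_zero_sd` columns report
#' the spread across realizations. VSG counts are always taken from the
#' mean landscape (viability is frozen under resampling).
#'
#' @param ds an [empirical_dataset()].
#' @param sizes integer vector of subgraph sizes (default `2:6`).
#' @param focal focal locus for the lethality-model predictions (name or
#'   index); `NULL` omits the prediction columns.
#' @param axis endpoint convention for accessible-path counts.
#' @param resample_reps number of resampling realizations (0 = analyze the
#'   mean landscape only).
#' @param sigma resampling noise scale (default: [replicate_sigma()]).
#' @param seed integer seed for resampling.
#' @return A data.frame with one row per size: `L`, `n_subgraphs`, `n_vsg`,
#'   `vsg_predicted`, `lethal_free_mean`, `lethal_free_predicted`,
#'   `mean_paths`, `p_zero`, `n_skipped` (plus `mean_paths_sd`, `p_zero_sd`
#'   under resampling). Tie-skipped subgraphs are listed in
#'   `attr(, "skipped")`.
#' @export
subgraph_table <- function(ds, sizes = 2:6, focal = NULL,
                           axis = c("global_max", "wildtype"),
                           resample_reps = 0, sigma = NULL, seed = NULL) {
  stopifnot(inherits(ds, "empirical_dataset"))
  axis <- match.arg(axis)
  stopifnot(all(sizes >= 1), all(sizes <= ds$L0))
  model <- if (!is.null(focal)) estimate_lethality(ds, focal)
  lsc <- as_landscape(ds)

  landscapes <- if (resample_reps > 0) {
    if (is.null(sigma)) sigma <- replicate_sigma(ds)
    lapply(seq_len(resample_reps), function(r)
      as_landscape(resample_dataset(ds, sigma, seed = seed + r - 1L)))
  } else list(lsc)

  skipped <- list()
  rows <- lapply(sizes, function(L) {
    subsets <- enumerate_subgraphs(ds$L0, L)
    n_vsg <- 0L
    per_rep <- matrix(NA_real_, nrow = length(landscapes), ncol = 3,
                      dimnames = list(NULL, c("mean_paths", "p_zero",
                                              "lethal_free")))
    n_skip <- 0L
    for (r in seq_along(landscapes)) {
      acc <- rep(NA_real_, length(subsets))
      lf <- numeric(length(subsets))
      for (s in seq_along(subsets)) {
        sub <- subgraph(landscapes[[r]], subsets[[s]])
        if (r == 1L) n_vsg <- n_vsg + is_viable_subgraph(subgraph(lsc, subsets[[s]]))
        lf[s] <- count_lethal_free_paths(sub, rep(0L, L), rep(1L, L))
        acc[s] <- tryCatch({
          if (axis == "wildtype")
            count_accessible_paths(sub, rep(1L, L), rep(0L, L))
          else count_antipodal(sub)
        }, error = function(e) {
          skipped[[length(skipped) + 1L]] <<-
            list(L = L, loci = subsets[[s]], rep = r,
                 message = conditionMessage(e))
          NA_real_
        })
      }
      if (r == 1L) n_skip <- sum(is.na(acc))
      per_rep[r, ] <- c(mean(acc, na.rm = TRUE),
                        mean(acc == 0, na.rm = TRUE), mean(lf))
    }
    row <- data.frame(
      L = L, n_subgraphs = length(subsets), n_vsg = n_vsg,
      vsg_predicted = if (!is.null(model) && L >= 2 && L <= ds$L0 - 1)
        expected_vsg(model, L) else NA_real_,
      lethal_free_mean = mean(per_rep[, "lethal_free"]),
      lethal_free_predicted = if (!is.null(model) && L <= ds$L0 - 1)
        expected_lethal_free(model, L) else NA_real_,
      mean_paths = mean(per_rep[, "mean_paths"]),
      p_zero = mean(per_rep[, "p_zero"]),
      n_skipped = n_skip)
    if (resample_reps > 0) {
      row$mean_paths_sd <- sd(per_rep[, "mean_paths"])
      row$p_zero_sd <- sd(per_rep[, "p_zero"])
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "lethality_model") <- model
  out
}
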