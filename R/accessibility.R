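#' Count selectively accessible shortest paths
#'
#' A shortest mutational path between two genotypes at Hamming distance D
#' visits D+1 genotypes, gaining one of the D differing mutations per step;
#' it is selectively accessible if fitness *strictly* increases at every
#' step. Under strong selection and weak mutation only such paths can be
#' realized without crossing a fitness valley. Counting is exact, by an
#' iterative depth-first backtracking search over the sublattice spanned by
#' the endpoints; equal-fitness steps fail the strict comparison and block.
#'
#' @param lsc a [landscape()].
#' @param start,end genotypes (0/1 vectors) of length `lsc$L`.
#' @return The number of accessible shortest paths, between 0 and `D!`.
#' @examples
#' lsc <- landscape(c(0.10, 0.20, 0.05, 0.30))
#' count_accessible_paths(lsc, c(0, 0), c(1, 1))  # 1
#' @export
count_accessible_paths <- function(lsc, start, end) {
  ep <- check_endpoints(lsc, start, end)
  cpp_count_paths(lsc$fitness, ep[1L], ep[2L], lethal = FALSE)
}

#' Test for at least one accessible path
#'
#' Equivalent to `count_accessible_paths(...) >= 1` but short-circuits on
#' the first path found, which makes the estimation of the no-path
#' probability P0 feasible on much larger genotype spaces.
#'
#' @inheritParams count_accessible_paths
#' @return `TRUE` if at least one accessible shortest path exists.
#' @export
has_accessible_path <- function(lsc, start, end) {
  ep <- check_endpoints(lsc, start, end)
  cpp_has_path(lsc$fitness, ep[1L], ep[2L], lethal = FALSE)
}

#' Accessible paths from the antipode to the global maximum
#'
#' The canonical accessibility statistic: the number of accessible shortest
#' paths from the antipode of the (unique) global fitness maximum to the
#' maximum itself. These are the longest direct paths in the landscape and
#' hence a priori the least likely to be accessible.
#'
#' @param lsc a [landscape()].
#' @return Non-negative path count (at most `L!`).
#' @export
count_antipodal <- function(lsc) {
  top <- global_maximum(lsc)
  count_accessible_paths(lsc, antipode(top), top)
}

#' Count shortest paths free of lethal genotypes
#'
#' Number of shortest paths between the endpoints on which every genotype
#' (endpoints included) is viable (fitness > 0), ignoring the ordering of
#' the viable fitness values. On a holey landscape this is the count of
#' connecting paths; on a general landscape it isolates the contribution of
#' lethals to path blocking, and always bounds
#' [count_accessible_paths()] from above when viable fitnesses are positive.
#'
#' @inheritParams count_accessible_paths
#' @return Non-negative path count; 0 if either endpoint is lethal.
#' @export
count_lethal_free_paths <- function(lsc, start, end) {
  ep <- check_endpoints(lsc, start, end)
  cpp_count_paths(lsc$fitness, ep[1L], ep[2L], lethal = TRUE)
}

check_endpoints <- function(lsc, start, end) {
  stopifnot(inherits(lsc, "landscape"))
  start <- check_genotype(start); end <- check_genotype(end)
  if (length(start) != lsc$L || length(end) != lsc$L)
    stop("endpoint genotypes must have length L", call. = FALSE)
  c(genotype_index(start), genotype_index(end))
}

#' Ensemble statistics of accessible-path counts
#'
#' Draws `reps` independent landscape realizations and collects the
#' distribution P(n) of the number of accessible paths, its mean E(n), the
#' no-path probability P0 = P(0) and the cumulative distribution. In
#' `mode = "existence"` only path existence is recorded per realization
#' (early-exit search), which estimates P0 alone but scales to much larger
#' genotype spaces.
#'
#' Realization r uses seed `seed + r - 1`, so full-count and existence-only
#' runs with the same arguments see identical landscapes.
#'
#' @param sampler a function of a single `seed` argument returning a
#'   [landscape()], e.g. `function(s) sample_hoc(5, seed = s)`.
#' @param reps number of realizations (`>= 1`).
#' @param seed master integer seed.
#' @param mode `"full"` (count paths per realization) or `"existence"`
#'   (record only whether a path exists).
#' @param statistic function mapping a landscape to its path count; the
#'   default counts antipodal accessible paths via [count_antipodal()]. For
#'   holey landscapes use a lethal-free count between the designated
#'   endpoints.
#' @param indicator function mapping a landscape to a logical (path
#'   exists?), used in existence mode; the default tests antipodal
#'   accessibility via [has_accessible_path()].
#' @return An object of class `"path_stats"` with elements `p_n` (named
#'   probability vector over observed counts), `mean`, `se_mean`, `p0`,
#'   `se_p0`, `reps` and `mode`.
#' @examples
#' st <- ensemble_stats(function(s) sample_hoc(4, seed = s),
#'                      reps = 200, seed = 1)
#' st
#' @export
ensemble_stats <- function(sampler, reps, seed,
                           mode = c("full", "existence"),
                           statistic = count_antipodal,
                           indicator = NULL) {
  stopifnot(is.function(sampler), reps >= 1)
  mode <- match.arg(mode)
  seeds <- seed + seq_len(reps) - 1L
  if (mode == "full") {
    counts <- vapply(seeds, function(s) statistic(sampler(s)), numeric(1))
    tab <- table(counts)
    p_n <- setNames(as.numeric(tab) / reps, names(tab))
    p0 <- mean(counts == 0)
    out <- list(p_n = p_n, counts = counts,
                mean = mean(counts),
                se_mean = stats::sd(counts) / sqrt(reps),
                p0 = p0, se_p0 = sqrt(p0 * (1 - p0) / reps),
                reps = reps, mode = mode)
  } else {
    if (is.null(indicator))
      indicator <- function(lsc) {
        top <- global_maximum(lsc)
        has_accessible_path(lsc, antipode(top), top)
      }
    found <- vapply(seeds, function(s) indicator(sampler(s)), logical(1))
    p0 <- mean(!found)
    out <- list(p_n = NULL, counts = NULL, mean = NA_real_,
                se_mean = NA_real_,
                p0 = p0, se_p0 = sqrt(p0 * (1 - p0) / reps),
                reps = reps, mode = mode)
  }
  structure(out, class = "path_stats")
}

#' @export
print.path_stats <- function(x, ...) {
  cat(sprintf("Accessible-path ensemble statistics (%d realizations, %s mode)\n",
              x$reps, x$mode))
  if (x$mode == "full")
    cat(sprintf("  E[n] = %.4g (se %.2g)\n", x$mean, x$se_mean))
  cat(sprintf("  P0   = %.4g (se %.2g)\n", x$p0, x$se_p0))
  invisible(x)
}

#' Cumulative accessible-path distribution
#'
#' `cumulative(stats, n)` is the probability that a landscape drawn from the
#' ensemble has at least `n` accessible paths: `P_c(n) = sum_{m >= n} P(m)`.
#' `P_c(0) = 1` and `P_c(1) = 1 - P0`.
#'
#' @param stats a `"path_stats"` object from [ensemble_stats()] run in
#'   full-count mode.
#' @param n non-negative integer (vectorized).
#' @return Probability `P_c(n)`, non-increasing in `n`.
#' @export
cumulative <- function(stats, n) {
  stopifnot(inherits(stats, "path_stats"))
  if (stats$mode != "full")
    stop("cumulative distribution requires full-count mode", call. = FALSE)
  stopifnot(all(n >= 0))
  vapply(n, function(k) mean(stats$counts >= k), numeric(1))
}
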