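# Random-landscape ensembles. All samplers are deterministic given `seed`;
# ensemble drivers derive per-realization seeds by counter (seed + rep - 1)
# so realizations are reproducible and order-independent.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
  }
  force(expr)
}

#' Sample a House-of-Cards landscape
#'
#' Fitness values of all `2^L` genotypes are independent and identically
#' distributed (uniform on (0, 1); only fitness ranks matter for
#' accessibility, so any continuous distribution is equivalent). This is the
#' maximally rugged null model: a single mutation decorrelates fitness
#' completely.
#'
#' With `condition_antipode_min = TRUE` the realization is conditioned on the
#' antipode of the global maximum being the global *minimum*: by
#' exchangeability of the i.i.d. values this is implemented exactly by
#' relocating the smallest value to the antipode of the maximum.
#'
#' @param L number of loci.
#' @param seed integer seed; identical seeds give identical landscapes.
#' @param condition_antipode_min condition the antipodal starting genotype
#'   to be the global fitness minimum.
#' @return A [landscape()].
#' @examples
#' sample_hoc(4, seed = 1)
#' @export
sample_hoc <- function(L, seed = NULL, condition_antipode_min = FALSE) {
  stopifnot(L >= 1)
  f <- with_seed(seed, runif(2^L))
  if (condition_antipode_min) {
    i_max <- which.max(f)
    i_anti <- bitwXor(i_max - 1L, as.integer(2^L - 1L)) + 1L
    i_min <- which.min(f)
    f[c(i_anti, i_min)] <- f[c(i_min, i_anti)]
  }
  landscape(f)
}

#' Sample a Rough Mount Fuji landscape
#'
#' Fitness is an additive slope towards a designated optimum plus i.i.d.
#' noise: `F(g) = -c * d(g) + eta_g`, where `d(g)` is the Hamming distance
#' from `g` to the optimum (taken to be the all-zeros genotype) and the
#' `eta_g` are independent standard normal (default) or standard Gumbel
#' variables. `c = 0` recovers the House-of-Cards model; large `c` makes the
#' landscape additive. Values are shifted by a per-realization constant so
#' that all stored fitnesses are positive (sign-epistasis structure and path
#' accessibility are invariant under a common shift).
#'
#' @param L number of loci.
#' @param c non-negative slope constant, in units of the noise scale.
#' @param noise `"normal"` (default) or `"gumbel"`; the Gumbel choice matches
#'   the exactly solvable case of [rmf_path_prob_gumbel()].
#' @param seed integer seed.
#' @return A [landscape()].
#' @examples
#' sample_rmf(5, c = 0.5, seed = 1)
#' @export
sample_rmf <- function(L, c, noise = c("normal", "gumbel"), seed = NULL) {
  stopifnot(L >= 1, c >= 0)
  noise <- match.arg(noise)
  d <- rowSums(bit_matrix(L))  # distance to the all-zeros optimum
  eta <- with_seed(seed, switch(noise,
    normal = rnorm(2^L),
    gumbel = -log(-log(runif(2^L)))))
  f <- -c * d + eta
  landscape(f - min(f) + 1)
}

#' Sample an LK (NK) landscape
#'
#' Each of the L loci is assigned K other loci with which it interacts, and
#' contributes to total fitness an i.i.d. uniform(0, 1) amount drawn per
#' state of its interaction set (its own allele plus the K partner alleles,
#' `2^(K+1)` states per locus). Total fitness is the plain sum of the L site
#' contributions (a monotone transform of the mean, so accessibility is
#' unaffected). `K = 0` gives a purely additive landscape; `K = L - 1` is
#' equivalent to the House-of-Cards model.
#'
#' Partner sets are drawn uniformly at random per realization under
#' `scheme = "random"` (default), or taken as the K cyclically following
#' loci under `scheme = "adjacent"`; both are classical conventions.
#'
#' @param L number of loci.
#' @param K number of interaction partners per locus, `0 <= K <= L - 1`.
#' @param scheme neighborhood scheme, `"random"` or `"adjacent"`.
#' @param seed integer seed.
#' @return A [landscape()] with the partner matrix attached as attribute
#'   `"partners"` (L rows; column 1 is the locus itself).
#' @examples
#' sample_lk(5, K = 2, seed = 1)
#' @export
sample_lk <- function(L, K, scheme = c("random", "adjacent"), seed = NULL) {
  stopifnot(L >= 1)
  if (K < 0 || K > L - 1) stop("K must satisfy 0 <= K <= L - 1",
                               call. = FALSE)
  scheme <- match.arg(scheme)
  out <- with_seed(seed, {
    partners <- vapply(seq_len(L), function(i) {
      others <- if (K == 0L) integer(0)
      else if (scheme == "adjacent") ((i - 1L + seq_len(K)) %% L) + 1L
      else sample(setdiff(seq_len(L), i), K)
      as.integer(c(i, others))
    }, integer(K + 1L))
    partners <- matrix(partners, nrow = L, ncol = K + 1L, byrow = TRUE)
    contrib <- matrix(runif(2^(K + 1L) * L), nrow = 2^(K + 1L), ncol = L)
    list(partners = partners, contrib = contrib)
  })
  f <- cpp_lk_fitness(out$partners - 1L, out$contrib)
  lsc <- landscape(f)
  attr(lsc, "partners") <- out$partners
  lsc
}

#' Sample a holey (percolation) landscape
#'
#' Every genotype is independently viable (fitness 1) with probability `p`
#' or lethal (fitness 0). There is no notion of fitness rank; accessibility
#' becomes the percolation question of whether two antipodal genotypes are
#' joined by a shortest path of viable states (see
#' [count_lethal_free_paths()]). With `condition_endpoints_viable = TRUE`
#' the designated antipodal endpoints (all-zeros and all-ones) are forced
#' viable, the conditioning used when studying connecting paths.
#'
#' @param L number of loci.
#' @param p viability probability in `[0, 1]`.
#' @param seed integer seed.
#' @param condition_endpoints_viable force the all-zeros and all-ones
#'   genotypes to be viable.
#' @return A [landscape()] with fitness values in `{0, 1}`.
#' @examples
#' sample_holey(5, p = 0.6, seed = 1)
#' @export
sample_holey <- function(L, p, seed = NULL,
                         condition_endpoints_viable = FALSE) {
  stopifnot(L >= 1, p >= 0, p <= 1)
  f <- as.numeric(with_seed(seed, runif(2^L) < p))
  if (condition_endpoints_viable) f[c(1L, 2^L)] <- 1
  landscape(f)
}
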