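# Closed-form accessibility expectations and the two-parameter lethality
# model used in the empirical subgraph analysis.

#' Expected number of accessible paths in the House-of-Cards model
#'
#' By the order-statistics argument, each of the `L!` antipodal shortest
#' paths traverses L free i.i.d. fitness values (the endpoint is the global
#' maximum), exactly one of whose `L!` equally likely orderings is monotone,
#' so the expectation is 1 for every L. When the antipodal starting genotype
#' is additionally conditioned to be the global *minimum*, only `(L-1)!`
#' orderings of the interior values are free and the expectation becomes L.
#'
#' @param L number of loci.
#' @param conditioned condition the antipode of the maximum to be the global
#'   minimum.
#' @return Expected accessible-path count: 1, or L when conditioned.
#' @export
hoc_expected_paths <- function(L, conditioned = FALSE) {
  stopifnot(L >= 1)
  if (conditioned) L else 1
}

#' Expected number of connecting paths in the holey landscape
#'
#' With the two antipodal endpoints conditioned viable, a shortest path is
#' hole-free iff its `L - 1` interior genotypes are all viable, each
#' independently with probability p, giving `L! * p^(L-1)` expected
#' connecting paths. The factorial growth beats the exponential decay, so
#' the expectation diverges with L for any `p > 0`.
#'
#' @param L number of loci.
#' @param p viability probability in `[0, 1]`.
#' @return Expected number of hole-free antipodal shortest paths.
#' @export
holey_expected_paths <- function(L, p) {
  stopifnot(L >= 1, p >= 0, p <= 1)
  factorial(L) * p^(L - 1)
}

#' Single-path accessibility in the Rough Mount Fuji model, first order
#'
#' Probability that one fixed antipodal shortest path is selectively
#' accessible in the RMF model, expanded to first order in the slope c. The
#' path's L non-endpoint fitness values are i.i.d. noise plus a linear
#' drift of c per step (the endpoint is taken to be the global maximum);
#' relaxing each adjacent ordering constraint by c yields
#' \deqn{P \approx 1/L! + c \int \phi(x)^2 dx / (L-2)!}
#' where \eqn{\phi} is the noise density. At `c = 0` this is the
#' House-of-Cards value `1/L!`. The neglected terms are O(c^2), so the
#' approximation is quantitative only for small c.
#'
#' @param L number of loci (`>= 1`).
#' @param c small non-negative slope constant.
#' @param noise `"normal"`, `"gumbel"`, or a density function phi(x) to be
#'   squared and integrated numerically.
#' @return First-order accessibility probability of a fixed path.
#' @export
rmf_path_prob_first_order <- function(L, c, noise = "normal") {
  stopifnot(L >= 1, c >= 0)
  I <- if (is.function(noise)) {
    integrate(function(x) noise(x)^2, -Inf, Inf)$value
  } else {
    switch(match.arg(noise, c("normal", "gumbel")),
           normal = 1 / (2 * sqrt(pi)),  # int dnorm^2
           gumbel = 1 / 4)               # int (e^-x exp(-e^-x))^2
  }
  first <- if (L >= 2) c * I / factorial(L - 2) else 0
  1 / factorial(L) + first
}

#' Exact single-path accessibility for Gumbel-distributed RMF noise
#'
#' When the RMF noise is standard Gumbel the probability that a fixed
#' antipodal path is accessible has the closed product form
#' \deqn{P(L, c) = (1 - e^{-c})^L / \prod_{k=1}^{L} (1 - e^{-ck}).}
#' As `c -> 0` this reduces to the House-of-Cards value `1/L!`; for large L
#' the denominator approaches the constant \eqn{\prod_{k \ge 1}(1-e^{-ck})}
#' and P decays exponentially, with rate set by `-log(1 - e^{-c})`.
#' Evaluation is in log-space so large L is safe.
#'
#' @param L number of loci.
#' @param c non-negative slope constant (in units of the noise scale).
#' @return Exact accessibility probability of a fixed path, in
#'   `[1/L!, 1]` and increasing in c.
#' @export
rmf_path_prob_gumbel <- function(L, c) {
  stopifnot(L >= 1)
  if (c < 0) stop("c must be non-negative", call. = FALSE)
  if (c == 0) return(1 / factorial(L))
  lognum <- L * log(-expm1(-c))
  logden <- sum(log(-expm1(-c * seq_len(L))))
  exp(lognum - logden)
}

#' Two-parameter multiplicative lethality model
#'
#' Each mutation i independently causes lethality with probability `p_i`,
#' and mutations combine multiplicatively: a genotype carrying mutation set
#' S is viable with probability `prod_{i in S} (1 - p_i)`, independently
#' across genotypes. One focal locus (the lysine-deficiency-like high-risk
#' mutation) carries probability `p_focal`; the remaining `L0 - 1` loci
#' share a common `p_common`.
#'
#' @param p_common per-mutation lethality probability of the ordinary loci.
#' @param p_focal lethality probability of the focal locus.
#' @param L0 total number of loci (default 8).
#' @return An object of class `"lethality_model"`.
#' @export
lethality_model <- function(p_common, p_focal, L0 = 8L) {
  stopifnot(p_common >= 0, p_common <= 1, p_focal >= 0, p_focal <= 1,
            L0 >= 2)
  structure(list(p_common = p_common, p_focal = p_focal,
                 L0 = as.integer(L0)),
            class = "lethality_model")
}

#' @export
print.lethality_model <- function(x, ...) {
  cat(sprintf(
    "Two-parameter lethality model (L0 = %d): p_common = %.4g, p_focal = %.4g\n",
    x$L0, x$p_common, x$p_focal))
  invisible(x)
}

#' Expected number of viable subgraphs (VSGs)
#'
#' A subgraph of size L is viable if none of its `2^L` genotypes is lethal.
#' Under the lethality model a viable subgraph effectively cannot contain
#' the focal high-risk locus, so the expectation depends only on
#' `p_common`: the `L * 2^(L-1)` mutation slots of the subgraph's
#' mutation-carrying genotypes must all escape lethality,
#' \deqn{E[VSG] = C(L0 - 1, L) (1 - p)^{L 2^{L-1}}.}
#'
#' @param model a [lethality_model()].
#' @param L subgraph size, `2 <= L <= L0 - 1`.
#' @return Expected count of fully viable subgraphs of size L.
#' @export
expected_vsg <- function(model, L) {
  stopifnot(inherits(model, "lethality_model"), L >= 2, L <= model$L0 - 1)
  choose(model$L0 - 1, L) * (1 - model$p_common)^(L * 2^(L - 1))
}

#' Expected number of lethal-free paths per subgraph
#'
#' Expected number of shortest wildtype-to-L-fold-mutant paths containing no
#' lethal genotype, averaged over all `C(L0, L)` subgraphs of size L. A path
#' introduces its L mutations in some order; the mutation entering at step m
#' is present in `L - m + 1` of the path's genotypes, each of which must
#' independently escape lethality. Subgraphs avoiding the focal locus
#' contribute `L! (1-p)^{L(L+1)/2}`; in subgraphs containing it the focal
#' mutation enters at a uniformly distributed step, replacing the
#' corresponding `(1-p)` factors by `(1-p_focal)`.
#'
#' @param model a [lethality_model()].
#' @param L subgraph size, `1 <= L <= L0 - 1`.
#' @return Ensemble-average expected lethal-free path count per subgraph.
#' @export
expected_lethal_free <- function(model, L) {
  stopifnot(inherits(model, "lethality_model"), L >= 1, L <= model$L0 - 1)
  p <- model$p_common; pf <- model$p_focal; L0 <- model$L0
  total_slots <- L * (L + 1) / 2
  e_nofocal <- factorial(L) * (1 - p)^total_slots
  j <- seq_len(L)  # number of path genotypes carrying the focal mutation
  e_focal <- factorial(L) * mean((1 - p)^(total_slots - j) * (1 - pf)^j)
  (choose(L0 - 1, L) * e_nofocal + choose(L0 - 1, L - 1) * e_focal) /
    choose(L0, L)
}

#' Poisson statistics of missing genotypes
#'
#' If all G genotypes are equally likely to appear among `N_seg` sampled
#' segregants, a given genotype is missed with probability
#' `q = (1 - 1/G)^N_seg` and the number of missed genotypes is Poisson with
#' mean `lambda = G q`. Used to decide whether genotypes absent from an
#' empirical table can plausibly have been missed by chance (if not, they
#' are classified as non-viable). Computation is in log-space, so very
#' large `N_seg` does not underflow.
#'
#' @param G number of possible genotypes.
#' @param N_seg number of sampled segregants.
#' @param k integer; upper tail cut for the cumulative probability.
#' @return A list with `q` (per-genotype miss probability), `lambda`
#'   (Poisson mean) and `p_le_k` (probability that at most k genotypes were
#'   missed).
#' @examples
#' missed_genotype_stats(G = 256, N_seg = 2500, k = 1)
#' @export
missed_genotype_stats <- function(G, N_seg, k = 0L) {
  stopifnot(G >= 1, N_seg >= 0, k >= 0)
  q <- exp(N_seg * log1p(-1 / G))
  lambda <- G * q
  list(q = q, lambda = lambda, p_le_k = ppois(k, lambda))
}

#' Missing-genotype counts under heterogeneous detectability
#'
#' Conservative variant of [missed_genotype_stats()]: genotype detection
#' probabilities are drawn uniformly from `[lower, upper]` (normalized to
#' sum to one) rather than all equal to `1/G`, and `N_seg` segregants are
#' drawn multinomially. The default `upper = 2/G - lower` keeps the mean
#' detection probability at `1/G`. The default lower bound is a package
#' choice (a small fraction of `1/G`, standing in for the detectability of
#' the least fit observed strain); it is a parameter precisely because such
#' a choice is data-dependent.
#'
#' @param G number of possible genotypes.
#' @param N_seg number of sampled segregants.
#' @param lower,upper bounds of the detection-probability interval;
#'   `0 < lower <= upper` required.
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return Integer vector of length `reps`: number of genotypes never drawn
#'   in each replicate.
#' @export
simulate_heterogeneous_detection <- function(G, N_seg, lower = 0.1 / G,
                                             upper = 2 / G - lower,
                                             reps = 1000, seed = NULL) {
  stopifnot(G >= 1, N_seg >= 0, reps >= 1)
  if (!(lower > 0 && upper >= lower))
    stop("degenerate detection-probability range", call. = FALSE)
  with_seed(seed, vapply(seq_len(reps), function(r) {
    w <- runif(G, lower, upper)
    counts <- rmultinom(1L, N_seg, w / sum(w))
    sum(counts == 0L)
  }, integer(1)))
}
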