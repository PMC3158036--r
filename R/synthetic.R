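# Synthetic emulator of an A. niger-style 8-locus genotype-fitness table:
# multiplicative two-parameter lethality with one focal high-risk locus,
# correlated viable fitness (additive slope plus noise, rescaled to relative
# growth-rate units), and two-fold replicate measurement. Ground truth is
# known, so the full empirical pipeline is testable without any download.

aniger_locus_names <- c("fwnA1", "argH12", "pyrA5", "leuA1", "pheA1",
                        "lysD25", "oliC2", "crnB12")

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the structure of the classical eight-marker
#' *Aspergillus niger* segregant panel: eight loci of which the sixth
#' (lysD25-like) is far more likely to cause lethality than the rest, a
#' mildly sloped correlated fitness surface for the viable genotypes, and
#' two replicate measurements per strain. The synthetic locus labels reuse
#' the familiar marker names purely as mnemonics; the generated values are
#' synthetic throughout.
#'
#' @param L0 number of loci.
#' @param p_common per-mutation lethality probability of the ordinary loci.
#' @param p_focal lethality probability of the focal locus.
#' @param focal index of the focal locus.
#' @param c slope of the additive fitness component toward the wildtype
#'   optimum, in units of the noise scale (0 = uncorrelated).
#' @param noise_sd standard deviation of the per-genotype fitness noise.
#' @param replicate_sd standard deviation of a single replicate
#'   measurement, on the rescaled (relative growth rate) scale.
#' @param locus_names locus labels; defaults to the A. niger marker names
#'   when `L0 = 8`.
#' @param seed integer seed.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(L0 = 8L, p_common = 0.02, p_focal = 0.45,
                             focal = 6L, c = 0.3, noise_sd = 1,
                             replicate_sd = 0.02,
                             locus_names = NULL, seed = NULL) {
  stopifnot(L0 >= 2, p_common >= 0, p_common <= 1, p_focal >= 0,
            p_focal <= 1, focal >= 1, focal <= L0, c >= 0, noise_sd >= 0,
            replicate_sd >= 0)
  if (is.null(locus_names))
    locus_names <- if (L0 == 8L) aniger_locus_names
                   else paste0("locus", seq_len(L0))
  stopifnot(length(locus_names) == L0)
  structure(list(L0 = as.integer(L0), p_common = p_common,
                 p_focal = p_focal, focal = as.integer(focal), c = c,
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 locus_names = locus_names, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic genotype-fitness dataset
#'
#' Draws one dataset under a [synthetic_config()]:
#' \enumerate{
#'   \item each genotype is independently non-viable with probability
#'     `1 - prod(1 - p_i)` over its mutations (multiplicative lethality;
#'     the wildtype is always viable);
#'   \item viable genotypes receive a correlated fitness
#'     `-c * (mutation count) + noise`, affinely rescaled so the fittest
#'     viable strain has relative fitness 1 and the least fit 0.1 --
#'     mimicking growth rates expressed relative to the best strain, and
#'     preserving all accessibility structure (affine maps keep ranks);
#'   \item two replicate measurements add independent normal errors of
#'     scale `replicate_sd`; the reported mean fitness is their average;
#'   \item non-viable genotypes get fitness exactly 0 in both replicates
#'     and are flagged missing, as in the real table.
#' }
#'
#' @param cfg a [synthetic_config()].
#' @return An [empirical_dataset()] with replicate columns.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 1))
#' ds
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  L0 <- cfg$L0
  n <- 2^L0
  bm <- bit_matrix(L0)
  k_other <- rowSums(bm[, -cfg$focal, drop = FALSE])
  k_focal <- bm[, cfg$focal]
  p_viable <- (1 - cfg$p_common)^k_other * (1 - cfg$p_focal)^k_focal
  with_seed(cfg$seed, {
    viable <- runif(n) < p_viable
    raw <- -cfg$c * rowSums(bm) + cfg$noise_sd * rnorm(n)
    f <- numeric(n)
    vr <- raw[viable]
    f[viable] <- if (diff(range(vr)) == 0) 1
                 else 0.1 + 0.9 * (vr - min(vr)) / (max(vr) - min(vr))
    rep1 <- rep2 <- rep(NA_real_, n)
    rep1[viable] <- f[viable] + rnorm(sum(viable), 0, cfg$replicate_sd)
    rep2[viable] <- f[viable] + rnorm(sum(viable), 0, cfg$replicate_sd)
    mean_f <- numeric(n)
    mean_f[viable] <- pmax((rep1[viable] + rep2[viable]) / 2, 1e-6)
    rep1[!viable] <- rep2[!viable] <- 0
    empirical_dataset(cfg$locus_names, mean_f, missing = !viable,
                      rep1 = rep1, rep2 = rep2)
  })
}
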