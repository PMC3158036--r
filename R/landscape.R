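#' Fitness landscapes on the binary hypercube
#'
#' A landscape maps every one of the `2^L` genotypes to a finite,
#' non-negative fitness; a fitness of exactly 0 encodes a non-viable
#' (lethal) genotype. Fitness values are stored densely, indexed by the
#' integer genotype code (bit `i` = locus `i`, little-endian), so
#' `fitness[genotype_index(g) + 1]` is the fitness of `g`.
#'
#' @param fitness numeric vector of length `2^L`, all values finite and
#'   `>= 0`.
#' @param locus_names optional character vector of L locus labels.
#' @return An object of class `"landscape"` with fields `L`, `locus_names`
#'   and `fitness`.
#' @examples
#' lsc <- landscape(c(0.1, 0.2, 0.05, 0.3), locus_names = c("a", "b"))
#' lsc
#' @export
landscape <- function(fitness, locus_names = NULL) {
  fitness <- as.numeric(fitness)
  n <- length(fitness)
  L <- 0L
  while (2^L < n) L <- L + 1L
  if (2^L != n || n < 2L)
    stop("fitness must have length 2^L with L >= 1", call. = FALSE)
  if (anyNA(fitness) || any(!is.finite(fitness)) || any(fitness < 0))
    stop("fitness values must be finite and non-negative", call. = FALSE)
  if (is.null(locus_names)) locus_names <- paste0("locus", seq_len(L))
  if (length(locus_names) != L)
    stop("locus_names must have length L", call. = FALSE)
  structure(list(L = L, locus_names = as.character(locus_names),
                 fitness = fitness),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape on %d loci (%d genotypes)\n", x$L, 2^x$L))
  cat("  loci:", paste(x$locus_names, collapse = ", "), "\n")
  cat(sprintf("  viable: %d, non-viable: %d\n",
              sum(x$fitness > 0), sum(x$fitness == 0)))
  invisible(x)
}

# fitness lookup for a genotype given as bits
lsc_fitness <- function(lsc, g) lsc$fitness[genotype_index(g) + 1L]

# L x 2^L is wasteful; bit matrix rows = genotypes 0..2^L-1, cols = loci
bit_matrix <- function(L) {
  idx <- 0:(2^L - 1L)
  vapply(0:(L - 1L), function(b) as.integer((idx %/% 2^b) %% 2L),
         integer(2^L))
}

# indices (0-based) of the L single-mutant neighbors of every genotype:
# 2^L x L matrix, entry [g+1, b] = g XOR 2^(b-1)
neighbor_index <- function(L) {
  idx <- 0:(2^L - 1L)
  vapply(0:(L - 1L), function(b) bitwXor(idx, as.integer(2^b)),
         integer(2^L))
}

#' Global fitness maximum
#'
#' The genotype with the strictly largest fitness. The analyses here assume
#' that fitness values of neighboring genotypes can always be distinguished;
#' a tie for the maximum is therefore reported as an error rather than
#' silently broken, so that degenerate (e.g. empirical) inputs surface.
#'
#' @param lsc a [landscape()].
#' @return The maximal genotype as a 0/1 vector.
#' @export
global_maximum <- function(lsc) {
  stopifnot(inherits(lsc, "landscape"))
  top <- which(lsc$fitness == max(lsc$fitness))
  if (length(top) > 1L)
    stop("fitness tie: ", length(top),
         " genotypes share the maximal fitness", call. = FALSE)
  index_genotype(top - 1L, lsc$L)
}

#' Local fitness maxima
#'
#' All genotypes whose fitness strictly exceeds that of each of their L
#' single-mutant neighbors. Their number is the classical measure of
#' landscape ruggedness.
#'
#' @param lsc a [landscape()].
#' @return Integer matrix with one local maximum per row.
#' @export
local_maxima <- function(lsc) {
  stopifnot(inherits(lsc, "landscape"))
  nb <- neighbor_index(lsc$L)
  best_nb <- do.call(pmax, lapply(seq_len(lsc$L),
                                  function(b) lsc$fitness[nb[, b] + 1L]))
  which_max <- which(lsc$fitness > best_nb)
  t(vapply(which_max - 1L, index_genotype, integer(lsc$L), L = lsc$L))
}

#' Greedy (steepest-ascent) adaptive walk
#'
#' From `start`, repeatedly move to the fittest neighbor as long as it is
#' strictly fitter than the current genotype; the walk terminates at a local
#' maximum because fitness strictly increases at each step. A tie among the
#' best improving neighbors is reported as an error.
#'
#' @param lsc a [landscape()].
#' @param start starting genotype (0/1 vector).
#' @return Integer matrix whose rows are the visited genotypes, ending at a
#'   local maximum; a single row if `start` is itself a local maximum.
#' @export
greedy_walk <- function(lsc, start) {
  stopifnot(inherits(lsc, "landscape"))
  g <- check_genotype(start)
  if (length(g) != lsc$L) stop("start has wrong length", call. = FALSE)
  path <- list(g)
  repeat {
    nb <- neighbors(g)
    f_nb <- apply(nb, 1L, lsc_fitness, lsc = lsc)
    f_g <- lsc_fitness(lsc, g)
    if (max(f_nb) <= f_g) break
    best <- which(f_nb == max(f_nb))
    if (length(best) > 1L)
      stop("fitness tie among steepest-ascent neighbors", call. = FALSE)
    g <- nb[best, ]
    path[[length(path) + 1L]] <- g
  }
  do.call(rbind, path)
}

#' Basins of attraction of local maxima
#'
#' Maps every genotype to the local maximum reached by a greedy
#' steepest-ascent walk started from it. Basin sizes partition the `2^L`
#' genotypes among the local maxima.
#'
#' @param lsc a [landscape()].
#' @return An integer vector of length `2^L`: entry `g + 1` holds the
#'   0-based genotype index of the local maximum attracting genotype `g`.
#' @export
basins <- function(lsc) {
  stopifnot(inherits(lsc, "landscape"))
  L <- lsc$L
  n <- 2^L
  nb <- neighbor_index(L)
  f <- lsc$fitness
  # steepest-ascent successor of every genotype (0-based; self if maximum)
  f_nb <- vapply(seq_len(L), function(b) f[nb[, b] + 1L], numeric(n))
  best_f <- do.call(pmax, as.data.frame(f_nb))
  ties <- rowSums(f_nb == best_f) > 1L & best_f > f
  if (any(ties))
    stop("fitness tie among steepest-ascent neighbors of genotype ",
         which(ties)[1L] - 1L, call. = FALSE)
  succ <- 0:(n - 1L)
  improving <- best_f > f
  pick <- max.col(f_nb, ties.method = "first")
  succ[improving] <- nb[cbind(which(improving), pick[improving])]
  # iterate successor map to its fixed point (walk length is at most 2^L)
  dest <- succ
  repeat {
    nxt <- succ[dest + 1L]
    if (all(nxt == dest)) break
    dest <- nxt
  }
  dest
}

#' Restrict a landscape to a subgraph of loci
#'
#' The subgraph spanned by a subset of loci lets those loci vary while all
#' other loci are fixed to the wildtype (0) allele; fitness is inherited from
#' the parent landscape. This is the ensemble-building operation of the
#' empirical subgraph analysis.
#'
#' @param lsc a [landscape()].
#' @param loci integer vector of locus indices (1-based) to keep.
#' @return A [landscape()] on `length(loci)` loci.
#' @examples
#' lsc <- sample_hoc(4, seed = 1)
#' subgraph(lsc, c(1, 3))
#' @export
subgraph <- function(lsc, loci) {
  stopifnot(inherits(lsc, "landscape"))
  loci <- as.integer(loci)
  if (length(loci) < 1L || anyNA(loci) || any(loci < 1L | loci > lsc$L) ||
      anyDuplicated(loci))
    stop("loci must be a non-empty set of indices in 1..L", call. = FALSE)
  l <- length(loci)
  sub_idx <- as.integer(bit_matrix(l) %*% 2^(loci - 1L))  # 0-based parent idx
  landscape(lsc$fitness[sub_idx + 1L], locus_names = lsc$locus_names[loci])
}
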