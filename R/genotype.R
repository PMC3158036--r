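#' Genotypes on the binary hypercube
#'
#' A genotype is an ordered vector of L binary alleles, `1` marking the
#' presence and `0` the absence of the mutation at each locus. The set of all
#' `2^L` genotypes forms an L-dimensional hypercube under single point
#' mutations. Genotypes are also addressable as integers `0 .. 2^L - 1` with
#' bit `i` (little-endian) holding locus `i`; that indexing is used for dense
#' fitness storage in [landscape()] objects.
#'
#' @param bits integer vector of 0/1 alleles.
#' @param index integer genotype index in `0 .. 2^L - 1`.
#' @param L number of loci.
#' @return `genotype_index()` returns the 0-based integer index;
#'   `index_genotype()` returns the 0/1 allele vector.
#' @examples
#' genotype_index(c(1, 0, 1))      # 5
#' index_genotype(5, L = 3)        # c(1, 0, 1)
#' @export
genotype_index <- function(bits) {
  bits <- check_genotype(bits)
  sum(bits * 2^(seq_along(bits) - 1L))
}

#' @rdname genotype_index
#' @export
index_genotype <- function(index, L) {
  stopifnot(index >= 0, index < 2^L)
  as.integer((index %/% 2^(0:(L - 1L))) %% 2L)
}

check_genotype <- function(g) {
  g <- as.integer(g)
  if (length(g) < 1L || anyNA(g) || any(g != 0L & g != 1L))
    stop("a genotype must be a vector of 0/1 alleles", call. = FALSE)
  g
}

#' Hamming distance between two genotypes
#'
#' Number of loci at which two genotypes differ, i.e. the length of the
#' shortest mutational path connecting them.
#'
#' @param a,b genotypes (0/1 vectors) of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hamming_distance(c(0, 1, 0, 1), c(0, 1, 1, 0))  # 2
#' @export
hamming_distance <- function(a, b) {
  a <- check_genotype(a); b <- check_genotype(b)
  if (length(a) != length(b))
    stop("genotypes must have equal length", call. = FALSE)
  sum(a != b)
}

#' Antipodal genotype
#'
#' The genotype differing from `g` at every locus; the antipode of the global
#' fitness maximum is the canonical starting point for accessible-path
#' counts, being the genotype farthest from the optimum.
#'
#' @param g a genotype (0/1 vector).
#' @return The genotype with every allele flipped.
#' @examples
#' antipode(c(0, 0, 0, 0))  # 1 1 1 1
#' @export
antipode <- function(g) 1L - check_genotype(g)

#' Single-mutant neighbors of a genotype
#'
#' @param g a genotype (0/1 vector) of length L.
#' @return An `L x L` integer matrix, one neighbor per row, each at Hamming
#'   distance 1 from `g`.
#' @examples
#' neighbors(c(0, 0))
#' @export
neighbors <- function(g) {
  g <- check_genotype(g)
  L <- length(g)
  nb <- matrix(g, nrow = L, ncol = L, byrow = TRUE)
  diag(nb) <- 1L - diag(nb)
  nb
}

#' Enumerate all shortest paths between two genotypes
#'
#' Two genotypes at Hamming distance D are connected by exactly `D!` shortest
#' paths, one per order in which the D differing mutations can be introduced.
#' Enumeration grows factorially and is intended for D up to about 8.
#'
#' @param a,b genotypes (0/1 vectors) of equal length.
#' @return A list of `D!` paths; each path is a `(D+1) x L` integer matrix
#'   whose rows are consecutive genotypes from `a` to `b`.
#' @examples
#' length(enumerate_shortest_paths(c(0, 0, 0), c(1, 1, 1)))  # 3! = 6
#' @export
enumerate_shortest_paths <- function(a, b) {
  a <- check_genotype(a); b <- check_genotype(b)
  if (length(a) != length(b))
    stop("genotypes must have equal length", call. = FALSE)
  diff <- which(a != b)
  if (length(diff) == 0L)
    return(list(matrix(a, nrow = 1L)))
  lapply(permutations(length(diff)), function(ord) {
    path <- matrix(a, nrow = length(diff) + 1L, ncol = length(a),
                   byrow = TRUE)
    for (s in seq_along(ord)) {
      loci <- diff[ord[seq_len(s)]]
      path[s + 1L, loci] <- b[loci]
    }
    path
  })
}

# all permutations of 1..n as a list of integer vectors (n! of them)
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[p])
    }
  }
  out
}
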