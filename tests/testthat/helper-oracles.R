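# Independent oracles used to cross-check the package's counting routines.
# They deliberately avoid the package's DFS: paths are enumerated as explicit
# permutations of the differing loci and checked by direct comparison.

all_perms <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# D! x (D+1) matrix of 0-based genotype indices, one shortest path per row
path_index_matrix <- function(start, end) {
  D <- sum(start != end)
  s_idx <- sum(start * 2^(seq_along(start) - 1))
  if (D == 0L) return(matrix(s_idx, 1L, 1L))
  diffb <- which(start != end)
  delta <- (end[diffb] - start[diffb]) * 2^(diffb - 1)
  P <- do.call(rbind, all_perms(D))
  steps <- matrix(delta[P], nrow = nrow(P))
  cbind(s_idx, s_idx + t(apply(steps, 1L, cumsum)))
}

# brute-force path counts by exhaustive permutation enumeration
brute_count_accessible <- function(lsc, start, end) {
  idx <- path_index_matrix(start, end)
  f <- matrix(lsc$fitness[idx + 1L], nrow = nrow(idx))
  if (ncol(f) == 1L) return(1)
  sum(rowSums(f[, -1L, drop = FALSE] >
                f[, -ncol(f), drop = FALSE]) == ncol(f) - 1L)
}

brute_count_lethal_free <- function(lsc, start, end) {
  idx <- path_index_matrix(start, end)
  f <- matrix(lsc$fitness[idx + 1L], nrow = nrow(idx))
  sum(rowSums(f > 0) == ncol(f))
}

rgumbel <- function(n) -log(-log(runif(n)))

# exact ensemble expectation of lethal-free wildtype->L-mutant paths per
# subgraph under the multiplicative lethality model, by full enumeration of
# subgraphs and mutation orders (independent of the closed form)
enum_expected_lethal_free <- function(p_common, p_focal, L0, L, focal) {
  p_loc <- rep(p_common, L0)
  p_loc[focal] <- p_focal
  subsets <- combn(L0, L, simplify = FALSE)
  per_subgraph <- vapply(subsets, function(loci) {
    sum(vapply(all_perms(L), function(ord) {
      entered <- integer(0)
      prob <- 1
      for (m in seq_len(L)) {
        entered <- c(entered, loci[ord[m]])
        prob <- prob * prod(1 - p_loc[entered])
      }
      prob
    }, numeric(1)))
  }, numeric(1))
  mean(per_subgraph)
}

# exact expected number of fully viable focal-free subgraphs by enumerating
# each subgraph's mutation-carrying genotypes
enum_expected_vsg <- function(p_common, L0, L, focal) {
  subsets <- Filter(function(s) !(focal %in% s),
                    combn(L0, L, simplify = FALSE))
  sum(vapply(subsets, function(loci) {
    n_slots <- 0
    for (k in seq_len(L)) n_slots <- n_slots + k * choose(L, k)
    (1 - p_common)^n_slots
  }, numeric(1)))
}
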