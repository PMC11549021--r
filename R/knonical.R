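#' Symmetry under reverse complement
#'
#' A selection function is symmetric when it treats a k-mer and its reverse
#' complement identically -- the property required of any scheme applied to
#' double-stranded DNA. For a context-free scheme this means the k-mer set
#' is closed under reverse complement.
#'
#' @param phi a `kmer_set`.
#' @export
is_symmetric <- function(phi) {
  phi <- as_kmer_set(phi)
  all(rc_kmers(phi$ranks, phi$k, phi$sigma) %in% phi$ranks)
}

#' Canonicalized selection set
#'
#' The common practice of querying a scheme at the canonical k-mer
#' (`phi_c(m) = phi(min(m, rc(m)))`) is, as a set operation,
#' `(phi intersect C) union rc(phi intersect C)` where `C` is the canonical
#' half of the space. The result is always symmetric and of size close to
#' `|phi|`, but members of `phi` that are non-canonical are silently
#' dropped -- entire PCRs can lose coverage, so a decycling `phi` may have
#' a non-decycling `phi_c` (this is the mechanism behind sketching
#' deserts in canonical space).
#'
#' @param phi a `kmer_set`.
#' @return a symmetric `kmer_set`.
#' @export
canonicalize_set <- function(phi) {
  phi <- as_kmer_set(phi)
  n <- space_size(phi$k, phi$sigma)
  all_can <- canonical_kmers(0:(n - 1), phi$k, phi$sigma)
  kmer_set(which(all_can %in% phi$ranks) - 1, phi$k, phi$sigma)
}

#' Union (symmetrized) selection set
#'
#' `phi_u = phi union rc(phi)`: a k-mer is selected if it or its reverse
#' complement is. Always symmetric, always a superset of both `phi` and
#' `phi_c`, hence it never introduces new SCCs or deserts -- at the price
#' of up to doubling the set size (and so the density).
#'
#' @param phi a `kmer_set`.
#' @export
union_set <- function(phi) {
  phi <- as_kmer_set(phi)
  kmer_set(c(phi$ranks, rc_kmers(phi$ranks, phi$k, phi$sigma)),
           phi$k, phi$sigma)
}

#' Reverse-complement orbits of a k-mer set
#'
#' Partitions the members into orbits `{m, rc(m)}`; self-reverse-complement
#' k-mers form singleton orbits. Orbits are the removal units of
#' [greedy_sparsify()] and the variable units of the symmetric decycling
#' search.
#'
#' @param phi a `kmer_set` (or ranks via [kmer_set()]).
#' @return list of numeric vectors (length 1 or 2), ordered by minimum
#'   member rank.
#' @export
rc_orbits <- function(phi) {
  phi <- as_kmer_set(phi)
  r <- phi$ranks
  rc <- rc_kmers(r, phi$k, phi$sigma)
  key <- pmin(r, rc)
  split(r, key)
}

#' Greedy sparsification of a symmetric selection set
#'
#' Starting from a symmetric set (normally `phi_u`), visits the
#' reverse-complement orbits in a seeded random order and removes an orbit
#' whenever doing so does not enlarge the set of SCC nodes beyond
#' `baseline` (for a decycling input: whenever the set stays decycling).
#' With `protect_core = TRUE` (the sparse-canonicalization problem),
#' orbits intersecting `phi_c` of the original set are never removed, so
#' the output contains `phi_c`.
#'
#' @param phi_u a symmetric `kmer_set` (e.g. from [union_set()]).
#' @param seed integer seed for the removal order.
#' @param protect_core logical; protect the canonicalized core.
#' @param core optional `kmer_set`: the core to protect. Defaults to
#'   `canonicalize_set(phi_u)`, a superset of the original `phi_c`; pass
#'   `canonicalize_set(phi)` explicitly to protect exactly the original
#'   canonicalized core.
#' @param baseline optional numeric vector of node ranks allowed to remain
#'   in SCCs (default: the SCC nodes of `phi_u` itself, which is empty when
#'   `phi_u` is decycling).
#' @return a symmetric `kmer_set` subset of `phi_u`, with attributes
#'   `seed` and `removed_orbits`.
#' @export
greedy_sparsify <- function(phi_u, seed = 1L, protect_core = TRUE,
                            core = NULL, baseline = NULL) {
  phi_u <- as_kmer_set(phi_u)
  if (!is_symmetric(phi_u)) stop("greedy_sparsify input must be symmetric")
  if (is.null(baseline)) baseline <- unlist(scc_report(phi_u)$sccs)
  if (protect_core && is.null(core)) core <- canonicalize_set(phi_u)
  orbs <- rc_orbits(phi_u)
  ord <- with_seed(seed, sample.int(length(orbs)))
  cur <- phi_u$ranks
  removed <- 0L
  for (i in ord) {
    orb <- orbs[[i]]
    if (protect_core && any(orb %in% core$ranks)) next
    cand <- setdiff(cur, orb)
    scc_nodes <- unlist(scc_report(kmer_set(cand, phi_u$k, phi_u$sigma))$sccs)
    if (length(setdiff(scc_nodes, baseline)) == 0) {
      cur <- cand
      removed <- removed + 1L
    }
  }
  out <- kmer_set(cur, phi_u$k, phi_u$sigma)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "removed_orbits") <- removed
  out
}
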