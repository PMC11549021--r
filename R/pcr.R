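#' Pure cycling registers (PCRs)
#'
#' The rotation cycles of k-mers partition the nodes of the de Bruijn graph.
#' Every decycling set must take at least one node from each PCR; minimum
#' decycling sets take exactly one.
#'
#' @param k k-mer length.
#' @param sigma alphabet size.
#' @return a list of numeric vectors; each vector holds one PCR in cyclic
#'   order starting from its minimum-rank rotation (the necklace). The
#'   classes are ordered by necklace rank, so enumeration is deterministic.
#' @examples
#' length(pcr_classes(5, 2))   # 8
#' @export
pcr_classes <- function(k, sigma) {
  n <- space_size(k, sigma)
  seen <- logical(n)
  out <- vector("list", necklace_count(sigma, k))
  nxt <- 1L
  for (r0 in 0:(n - 1)) {
    if (seen[r0 + 1]) next
    cyc <- numeric(k)
    cyc[1] <- r0
    len <- 1L
    r <- rotate_kmers(r0, k, sigma)
    while (r != r0) {
      len <- len + 1L
      cyc[len] <- r
      r <- rotate_kmers(r, k, sigma)
    }
    cyc <- cyc[seq_len(len)]
    seen[cyc + 1] <- TRUE
    out[[nxt]] <- cyc
    nxt <- nxt + 1L
  }
  out
}

#' Reverse complement of a PCR
#'
#' The reverse complements of a PCR's members form a PCR of the same size,
#' traversed in the reversed cyclic order; it may be the same PCR (this is
#' exactly the case when the class contains a k-mer and its own reverse
#' complement).
#'
#' @param pcr numeric vector, one class from [pcr_classes()].
#' @inheritParams pcr_classes
#' @return numeric vector: the image PCR, in cyclic order starting from its
#'   necklace.
#' @export
rc_of_pcr <- function(pcr, k, sigma) {
  img <- rc_kmers(pcr, k, sigma)
  ## re-standardize: start at minimum, follow rotation order
  r0 <- min(img)
  cyc <- numeric(length(img))
  cyc[1] <- r0
  r <- rotate_kmers(r0, k, sigma)
  i <- 1L
  while (r != r0) {
    i <- i + 1L
    cyc[i] <- r
    r <- rotate_kmers(r, k, sigma)
  }
  stopifnot(setequal(cyc, img))
  cyc
}

#' Number of PCRs (necklace count)
#'
#' Closed form by Burnside's lemma:
#' `(1/k) * sum over d | k of EulerPhi(d) * sigma^(k/d)`.
#' Equals the cardinality of any minimum decycling set.
#'
#' @inheritParams pcr_classes
#' @return a single numeric.
#' @examples
#' necklace_count(2, 5)    # 8
#' necklace_count(4, 7)    # 2344
#' @export
necklace_count <- function(sigma, k) {
  divs <- which((k %% seq_len(k)) == 0)
  sum(vapply(divs, function(d) euler_phi(d) * sigma^(k / d), numeric(1))) / k
}

euler_phi <- function(n) {
  if (n == 1) return(1)
  p <- unique(prime_factors(n))
  n * prod(1 - 1 / p)
}

prime_factors <- function(n) {
  f <- numeric(0)
  d <- 2
  while (d * d <= n) {
    while (n %% d == 0) { f <- c(f, d); n <- n / d }
    d <- d + 1
  }
  if (n > 1) f <- c(f, n)
  f
}

#' Canonical / reverse-complement partition of the k-mer space
#'
#' `C` holds the canonical k-mers (`m <= rc(m)`), `Crc` their reverse
#' complements. Together they cover `Sigma^k`; the overlap is the set of
#' self-reverse-complement k-mers, non-empty only for even `k`.
#'
#' @inheritParams pcr_classes
#' @return list with `kmer_set`s `C` and `Crc`.
#' @export
canonical_partition <- function(k, sigma) {
  n <- space_size(k, sigma)
  all <- 0:(n - 1)
  rc <- rc_kmers(all, k, sigma)
  C <- all[all <= rc]
  list(C = kmer_set(C, k, sigma),
       Crc = kmer_set(rc_kmers(C, k, sigma), k, sigma))
}
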