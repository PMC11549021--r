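#' Minimum decycling sets from the complex embedding
#'
#' Both constructions here pick exactly one k-mer from each PCR using the
#' classic complex embedding: a k-mer `m = m0 m1 ... m(k-1)` is mapped to
#' the weight `W(m) = sum_j m_j * omega^j` with `omega = exp(2i*pi/k)`.
#' Rotating the k-mer left multiplies the weight by `omega^(-1)`, so within
#' a PCR of non-vanishing weight the embeddings of the rotations are evenly
#' spread on a circle, and exactly one rotation falls inside any half-open
#' angular sector of width `2*pi/k`.
#'
#' `mykkeltveit_set()` selects, from each non-vanishing PCR, the rotation
#' whose weight argument lies in the sector `(pi - 2*pi/k, pi]` -- the last
#' rotation in the upper half-plane before the embedding crosses the
#' negative real axis. Zero-weight PCRs (periodic k-mers and, for sigma = 4
#' and composite k, some primitive classes) are resolved as follows: odd
#' primitive period -> minimum-rank rotation; even primitive period ->
#' recurse on the primitive root class in the order-d de Bruijn graph;
#' primitive zero-weight classes -> first non-vanishing derivative weight
#' `sum_j j^p m_j omega^j`, same sector. These conventions were fixed so
#' that the construction is decycling across the supported range and
#' reproduces the published per-k statistics of the classic set (see the
#' methods vignette for the one known deviation, sigma=2, k=8).
#'
#' `champarnaud_set()` is a second, deterministic minimum decycling set:
#' one k-mer per PCR, decycling, and distinct from `mykkeltveit_set()`.
#' The historical construction it stands in for is based on Lyndon
#' decompositions; as that rotation rule could not be faithfully
#' reconstructed, this function implements a synthetic stand-in using the
#' opposite sector boundary (`[pi - 2*pi/k, pi)`) and fully recursive
#' zero-class handling. Its cardinality -- the number of PCRs -- is shared
#' by every minimum decycling set; path-length statistics specific to the
#' historical set are not reproduced.
#'
#' @param k k-mer length, `k >= 2`.
#' @param sigma alphabet size.
#' @return a `kmer_set` with exactly `necklace_count(sigma, k)` members.
#' @examples
#' length(mykkeltveit_set(5, 2))    # 8
#' is_decycling(mykkeltveit_set(5, 2))
#' @name decycling-sets
NULL

## shared machinery ---------------------------------------------------------

## pick one rotation of the class `cyc` (cyclic order irrelevant) using the
## sector anchored at pi. boundary: +1 => sector (pi-2pi/k, pi] (right-closed)
##                                 -1 => sector [pi-2pi/k, pi) (left-closed)
embedding_pick <- function(cyc, sigma, k, boundary, zero_rule) {
  if (length(cyc) == 1) return(cyc)
  D <- kmer_digits(cyc, k, sigma)
  w <- exp(2i * pi * (0:(k - 1)) / k)
  W <- as.complex(D %*% w)
  tol <- 1e-8
  sector_pick <- function(W) {
    ## t in [0,1): right-closed includes Arg = pi (t = 0);
    ## left-closed excludes it and includes t = 1 instead.
    t <- ((pi - Arg(W)) / (2 * pi / k)) %% k
    t[Mod(W) < tol] <- Inf
    cyc[which.min((t + boundary * 1e-9) %% k)]
  }
  if (any(Mod(W) > tol)) return(sector_pick(W))
  d <- length(cyc)                       # primitive period
  if (d == k) {
    ## primitive zero-weight class: derivative weights j^p m_j omega^j
    p <- 1
    repeat {
      W <- as.complex(D %*% ((0:(k - 1))^p * w))
      if (any(Mod(W) > tol)) break
      p <- p + 1
      if (p > k) stop("all derivative weights vanish (unexpected)")
    }
    return(sector_pick(W))
  }
  if (zero_rule == "parity" && d %% 2 == 1) return(min(cyc))
  ## recurse on the primitive root class in B_d
  roots <- cyc %/% sigma^(k - d)
  sub <- embedding_pick(sort(unique(roots)), sigma, d, boundary, zero_rule)
  cyc[which(roots == sub)]
}

embedding_mds <- function(k, sigma, boundary, zero_rule) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  cls <- pcr_classes(k, sigma)
  sel <- vapply(cls, embedding_pick, numeric(1),
                sigma = sigma, k = k, boundary = boundary,
                zero_rule = zero_rule)
  kmer_set(sel, k, sigma)
}

#' @rdname decycling-sets
#' @export
mykkeltveit_set <- function(k, sigma) {
  embedding_mds(k, sigma, boundary = +1, zero_rule = "parity")
}

#' @rdname decycling-sets
#' @export
champarnaud_set <- function(k, sigma) {
  embedding_mds(k, sigma, boundary = -1, zero_rule = "recursive")
}
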