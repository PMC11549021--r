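#' k-mer rank encoding
#'
#' k-mers over the alphabet `0..sigma-1` are stored as base-`sigma` integer
#' ranks with the FIRST character most significant, so that integer order on
#' ranks coincides with lexicographic order on strings. Ranks are numerics
#' (doubles); they are exact for every `sigma^k <= 2^53`, far beyond the
#' sizes this package materializes.
#'
#' @name kmer-encoding
NULL

## maximum number of k-mers that the package will materialize as a vector
.KS_MAX_SPACE <- 2^22

space_size <- function(k, sigma) {
  n <- sigma^k
  if (n > .KS_MAX_SPACE)
    stop("sigma^k = ", n, " exceeds the materialization guard (", .KS_MAX_SPACE, ")")
  n
}

check_ranks <- function(ranks, k, sigma) {
  if (any(is.na(ranks)) || any(ranks < 0) || any(ranks >= sigma^k) ||
      any(ranks != floor(ranks)))
    stop("invalid k-mer ranks for sigma=", sigma, ", k=", k)
  invisible(ranks)
}

## digits matrix: one row per rank, k columns, first character in column 1
kmer_digits <- function(ranks, k, sigma) {
  D <- matrix(0L, length(ranks), k)
  r <- ranks
  for (j in k:1) {
    D[, j] <- as.integer(r %% sigma)
    r <- r %/% sigma
  }
  D
}

digits_to_ranks <- function(D, sigma) {
  as.numeric(D %*% sigma^((ncol(D) - 1):0))
}

#' Convert k-mer strings to ranks
#'
#' @param x character vector of k-mer strings (glyphs for `sigma = 4`,
#'   digits otherwise; case-insensitive).
#' @param sigma alphabet size.
#' @return numeric vector of ranks in `[0, sigma^k)`.
#' @examples
#' encode_kmers(c("AAA", "TTT"), 4)  # 0 63
#' @export
encode_kmers <- function(x, sigma) {
  if (!length(x)) return(numeric(0))
  k <- unique(nchar(x))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  M <- matrix(glyphs_to_symbols(unlist(strsplit(x, "", fixed = TRUE)), sigma),
              nrow = length(x), ncol = k, byrow = TRUE)
  if (any(is.na(M))) stop("k-mer string contains a symbol outside the alphabet")
  digits_to_ranks(M, sigma)
}

#' Convert k-mer ranks to strings
#'
#' @param ranks numeric vector of ranks.
#' @param k k-mer length.
#' @param sigma alphabet size.
#' @return character vector.
#' @export
decode_kmers <- function(ranks, k, sigma) {
  if (!length(ranks)) return(character(0))
  check_ranks(ranks, k, sigma)
  D <- kmer_digits(ranks, k, sigma)
  G <- matrix(symbols_to_glyphs(D, sigma), nrow(D), ncol(D))
  apply(G, 1, paste, collapse = "")
}

#' Reverse complement of k-mers
#'
#' `rc(m)` reverses the symbol order and complements every symbol
#' (`a -> sigma-1-a`). It is an involution on the set of all k-mers.
#'
#' @inheritParams decode_kmers
#' @return numeric vector of the reverse-complement ranks.
#' @examples
#' decode_kmers(rc_kmers(encode_kmers("TTT", 4), 3, 4), 3, 4)  # "AAA"
#' @export
rc_kmers <- function(ranks, k, sigma) {
  if (!length(ranks)) return(numeric(0))
  check_ranks(ranks, k, sigma)
  D <- kmer_digits(ranks, k, sigma)
  digits_to_ranks((sigma - 1L) - D[, k:1, drop = FALSE], sigma)
}

#' Canonical representation of k-mers
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement; with rank encoding this is just
#' `pmin(rank, rc(rank))`. Idempotent.
#'
#' @inheritParams decode_kmers
#' @export
canonical_kmers <- function(ranks, k, sigma) {
  pmin(ranks, rc_kmers(ranks, k, sigma))
}

#' Left rotation of k-mers
#'
#' `rotate(m1 m2 ... mk) = m2 ... mk m1`. Applied `k` times it is the
#' identity; in the de Bruijn graph there is always an edge from a k-mer to
#' its rotation (the pure cycling register edge).
#'
#' @inheritParams decode_kmers
#' @export
rotate_kmers <- function(ranks, k, sigma) {
  check_ranks(ranks, k, sigma)
  (ranks %% sigma^(k - 1)) * sigma + ranks %/% sigma^(k - 1)
}

#' de Bruijn successors of k-mers
#'
#' The successors of `m` in the de Bruijn graph are the `sigma` k-mers whose
#' (k-1)-prefix equals the (k-1)-suffix of `m`; arithmetically
#' `(rank mod sigma^(k-1)) * sigma + a` for each symbol `a`. Homopolymers
#' are their own successor (self-loop).
#'
#' @inheritParams decode_kmers
#' @return numeric matrix with `length(ranks)` rows and `sigma` columns.
#' @export
successor_kmers <- function(ranks, k, sigma) {
  check_ranks(ranks, k, sigma)
  base <- (ranks %% sigma^(k - 1)) * sigma
  outer(base, 0:(sigma - 1), "+")
}
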