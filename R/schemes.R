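#' Orders on s-mers / k-mers
#'
#' Positional-minimum schemes compare substrings under a pre-determined
#' total order. `lex_order()` is the identity (plain lexicographic order);
#' `random_order()` is a seeded pseudo-random permutation of all
#' `sigma^length` ranks, reproducible from `(seed, sigma, length)`. The
#' seed is recorded in the object and propagated into every scheme built
#' from it.
#'
#' @param sigma alphabet size.
#' @param length substring length the order applies to.
#' @param seed integer seed for the permutation.
#' @return an object of class `kmer_order` with fields `key` (numeric
#'   vector; `key[rank + 1]` is the sort key of `rank`), `sigma`, `length`,
#'   `seed` (NA for lexicographic).
#' @rdname orders
#' @export
lex_order <- function(sigma, length) {
  n <- space_size(length, sigma)
  structure(list(key = seq_len(n) - 1, sigma = sigma, length = length,
                 seed = NA_integer_, kind = "lex"),
            class = "kmer_order")
}

#' @rdname orders
#' @export
random_order <- function(sigma, length, seed) {
  n <- space_size(length, sigma)
  key <- with_seed(seed, sample.int(n)) - 1
  structure(list(key = key, sigma = sigma, length = length,
                 seed = as.integer(seed), kind = "random"),
            class = "kmer_order")
}

order_keys <- function(ord, ranks) {
  if (!inherits(ord, "kmer_order")) stop("expected a kmer_order")
  ord$key[ranks + 1]
}

## for every k-mer rank, the 0-based offset of the LEFT-MOST minimal s-mer
## under `ord`. Vectorized over the whole k-mer space.
leftmost_min_smer_offset <- function(k, sigma, s, ord) {
  if (s < 1 || s > k) stop("need 1 <= s <= k")
  if (ord$sigma != sigma || ord$length != s)
    stop("order is for sigma=", ord$sigma, ", length=", ord$length)
  n <- space_size(k, sigma)
  D <- kmer_digits(0:(n - 1), k, sigma)
  pw <- sigma^((s - 1):0)
  nw <- k - s + 1
  K <- matrix(0, n, nw)
  for (o in seq_len(nw)) {
    sm <- as.numeric(D[, o:(o + s - 1), drop = FALSE] %*% pw)
    K[, o] <- order_keys(ord, sm)
  }
  ## left-most occurrence of the row minimum (ties broken by position only)
  max.col(-K, ties.method = "first") - 1L
}

#' Syncmer selection set
#'
#' A k-mer is selected iff the left-most occurrence of its minimal s-mer
#' (under `order`) starts exactly at offset `t` (0-based). Ties between
#' equal s-mers are always broken by the left-most position; a k-mer whose
#' minimal s-mer appears both before and at `t` is therefore NOT selected.
#' With `t = 0` the set is decycling (strong window guarantee); with
#' `0 < t <= s/2` only near-repetitive (sesqui-power) sequences escape
#' selection (relaxed guarantee); for `t >= s` there is no guarantee.
#'
#' @param k k-mer length.
#' @param sigma alphabet size.
#' @param s s-mer length, `1 <= s <= k`.
#' @param t offset in `0..(k-s)`.
#' @param order a `kmer_order` over s-mers; defaults to lexicographic.
#' @return a `kmer_set`; the scheme parameters (and order seed) are
#'   attached as attribute `scheme`.
#' @export
syncmer_set <- function(k, sigma, s, t, order = lex_order(sigma, s)) {
  if (t < 0 || t > k - s) stop("need 0 <= t <= k - s")
  off <- leftmost_min_smer_offset(k, sigma, s, order)
  out <- kmer_set(which(off == t) - 1, k, sigma)
  attr(out, "scheme") <- list(scheme = "syncmer", s = s, t = t,
                              seed = order$seed)
  out
}

#' Parameterized syncmer selection set
#'
#' Generalizes [syncmer_set()]: selected iff the left-most minimal s-mer
#' offset falls in `mask` (a set of offsets). `mask = t` reduces to the
#' plain syncmer; a mask containing 0 yields a decycling set; the full mask
#' `0..(k-s)` selects every k-mer.
#'
#' @inheritParams syncmer_set
#' @param mask integer vector of offsets, non-empty, each in `0..(k-s)`.
#' @export
parameterized_syncmer_set <- function(k, sigma, s, mask,
                                      order = lex_order(sigma, s)) {
  mask <- unique(as.integer(mask))
  if (!length(mask)) stop("mask must be non-empty")
  if (any(mask < 0 | mask > k - s)) stop("mask offsets must lie in 0..(k-s)")
  off <- leftmost_min_smer_offset(k, sigma, s, order)
  out <- kmer_set(which(off %in% mask) - 1, k, sigma)
  attr(out, "scheme") <- list(scheme = "psyncmer", s = s, mask = mask,
                              seed = order$seed)
  out
}

#' Fractional (hash-based) selection set
#'
#' Selects the `round(f * sigma^k)` k-mers whose image under a seeded
#' random permutation of the k-mer space comes first; the cardinality is
#' exact by construction. Such sets have no window guarantee.
#'
#' @inheritParams syncmer_set
#' @param f fraction in `(0, 1]`.
#' @param seed integer seed of the permutation.
#' @export
fractional_set <- function(k, sigma, f, seed = 1L) {
  if (f <= 0 || f > 1) stop("need 0 < f <= 1")
  n <- space_size(k, sigma)
  m <- round(f * n)
  key <- random_order(sigma, k, seed)$key
  out <- kmer_set(which(key < m) - 1, k, sigma)
  attr(out, "scheme") <- list(scheme = "fractional", f = f, seed = seed)
  out
}
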