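#' Sequences, sketches and sketching deserts
#'
#' Sequences are plain character strings over the alphabet glyphs
#' (`A,C,G,T` for sigma = 4, digits otherwise). Characters outside the
#' alphabet (e.g. `N`) are allowed on input: any k-mer window containing
#' one is never selected and does not reset desert accounting.
#'
#' @name sequence-sketch
NULL

seq_to_symbols <- function(x, sigma) {
  glyphs_to_symbols(strsplit(x, "", fixed = TRUE)[[1]], sigma)
}

#' Reverse complement of a sequence string
#' @param x a sequence string.
#' @param sigma alphabet size.
#' @export
rc_sequence <- function(x, sigma) {
  s <- rev(seq_to_symbols(x, sigma))
  if (any(is.na(s))) stop("rc_sequence: non-alphabet character")
  paste(symbols_to_glyphs((sigma - 1L) - s, sigma), collapse = "")
}

#' i.i.d. uniform random sequence
#'
#' @param length sequence length in bases.
#' @param sigma alphabet size.
#' @param seed integer seed; a fixed seed reproduces the sequence exactly.
#' @return a character string.
#' @export
random_sequence <- function(length, sigma, seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  s <- with_seed(seed, sample.int(sigma, length, replace = TRUE)) - 1L
  paste(symbols_to_glyphs(s, sigma), collapse = "")
}

## 0-based k-mer ranks along a sequence; NA where the window contains a
## non-alphabet symbol. Rolling update keeps this O(|S| k) worst case but
## vectorized via the digits matrix for typical lengths.
sequence_kmer_ranks <- function(x, k, sigma) {
  s <- seq_to_symbols(x, sigma)
  L <- length(s)
  if (L < k) return(numeric(0))
  nw <- L - k + 1
  bad <- is.na(s)
  sz <- s; sz[bad] <- 0L
  ## windowed rank via convolution with powers of sigma
  pw <- sigma^((k - 1):0)
  M <- matrix(0, nw, k)
  for (j in seq_len(k)) M[, j] <- sz[j:(j + nw - 1)]
  r <- as.numeric(M %*% pw)
  if (any(bad)) {
    badw <- as.logical(stats::filter(as.numeric(bad), rep(1, k),
                                     sides = 1)[k:L] > 0)
    r[badw] <- NA_real_
  }
  r
}

#' Selected positions of a sketch
#'
#' The sketch of a sequence under a context-free scheme is the set of
#' 0-based start offsets whose k-mer belongs to the selection set. Windows
#' containing non-alphabet symbols are never selected. Scanning is forward
#' strand only; double-strandedness is the selection set's responsibility
#' (use a symmetric set).
#'
#' @param x a sequence string.
#' @param phi a `kmer_set`.
#' @return increasing numeric vector of offsets in `[0, nchar(x) - k]`.
#' @export
sketch_positions <- function(x, phi) {
  phi <- as_kmer_set(phi)
  if (nchar(x) < phi$k) {
    warning("sequence shorter than k; empty sketch")
    return(numeric(0))
  }
  r <- sequence_kmer_ranks(x, phi$k, phi$sigma)
  which(!is.na(r) & r %in% phi$ranks) - 1
}

#' Observed sketch density
#'
#' Fraction of selected k-mer windows, `|positions| / (|S| - k + 1)`. For
#' i.i.d. uniform sequences its expectation equals [relative_size()] of the
#' scheme.
#'
#' @inheritParams sketch_positions
#' @export
sketch_density <- function(x, phi) {
  phi <- as_kmer_set(phi)
  nw <- nchar(x) - phi$k + 1
  if (nw < 1) stop("sequence shorter than k")
  length(sketch_positions(x, phi)) / nw
}

#' Sketching deserts of a sequence
#'
#' A desert is a maximal run of at least `L` consecutive bases containing
#' no *selected k-mer start*. Sequence ends count as boundaries, so an
#' unsampled prefix or suffix can be a desert; however, an interval must
#' contain at least one *possible* start (offset `<= |S| - k`) to count --
#' the final `k - 1` bases alone are never a desert (they extend a
#' preceding one). Intervals are 0-based, half-open. Runs of ambiguous
#' characters do not interrupt a desert; an interval consisting only of
#' non-alphabet characters is flagged.
#'
#' @param x a sequence string.
#' @param phi a `kmer_set`.
#' @param L minimum desert length in bases (default 50).
#' @param id optional sequence identifier carried into the report.
#' @return object of class `desert_report`: `id`, `length`, `positions`
#'   (selected offsets), `gaps` (distances between consecutive selected
#'   offsets), `deserts` (data.frame start/end/length/all_ambiguous),
#'   `cumulative_desert`, `L`.
#' @export
find_deserts <- function(x, phi, L = 50, id = "seq") {
  if (L < 1) stop("L must be >= 1")
  phi <- as_kmer_set(phi)
  n <- nchar(x)
  pos <- if (n >= phi$k) sketch_positions(x, phi) else numeric(0)
  ## base intervals free of selected starts, between/around selected offsets;
  ## an interval must contain a possible start position (<= n - k)
  b0 <- c(0, pos + 1)
  b1 <- c(pos, n)
  start <- b0
  end <- b1
  len <- end - start
  sel <- len >= L & (start <= n - phi$k | n < phi$k)
  des <- data.frame(start = start[sel], end = end[sel], length = len[sel])
  if (nrow(des)) {
    sym <- seq_to_symbols(x, phi$sigma)
    des$all_ambiguous <- vapply(seq_len(nrow(des)), function(i) {
      all(is.na(sym[(des$start[i] + 1):des$end[i]]))
    }, logical(1))
  } else des$all_ambiguous <- logical(0)
  structure(list(id = id, length = n, positions = pos,
                 gaps = if (length(pos) > 1) diff(pos) else numeric(0),
                 deserts = des, cumulative_desert = sum(des$length), L = L),
            class = "desert_report")
}

#' @export
print.desert_report <- function(x, ...) {
  cat(sprintf(
    "desert_report '%s': length %d, %d selected, %d desert(s) >= %d bases (%g total)\n",
    x$id, x$length, length(x$positions), nrow(x$deserts), x$L,
    x$cumulative_desert))
  invisible(x)
}

#' Adversarial sequence spelled by a surviving SCC
#'
#' When a selection set leaves an SCC in the de Bruijn graph, arbitrarily
#' long sequences exist that contain no selected k-mer; this generator
#' walks (seeded, uniformly at random) inside the largest surviving SCC and
#' spells out such a sequence -- a guaranteed sketching desert of any
#' requested length. Errors when `phi` is decycling.
#'
#' @param phi a `kmer_set` with at least one surviving SCC.
#' @param length requested sequence length (`>= k`).
#' @param seed integer seed for the walk.
#' @return a character string with `sketch_positions(result, phi)` empty.
#' @export
scc_walk_sequence <- function(phi, length, seed = 1L) {
  phi <- as_kmer_set(phi)
  if (length < phi$k) stop("length must be >= k")
  rep <- scc_report(phi)
  if (rep$count == 0)
    stop("phi is decycling: no unsampled sequence longer than the window bound exists")
  scc <- rep$sccs[[which.max(lengths(rep$sccs))]]
  k <- phi$k; sigma <- phi$sigma
  steps <- length - k
  path <- numeric(steps + 1)
  with_seed(seed, {
    cur <- scc[sample.int(length(scc), 1)]
    path[1] <- cur
    if (steps > 0) for (i in seq_len(steps)) {
      nxt <- successor_kmers(cur, k, sigma)
      nxt <- nxt[nxt %in% scc]
      cur <- if (length(nxt) == 1) nxt else nxt[sample.int(length(nxt), 1)]
      path[i + 1] <- cur
    }
  })
  first <- symbols_to_glyphs(kmer_digits(path[1], k, sigma)[1, ], sigma)
  rest <- if (steps > 0) symbols_to_glyphs(path[-1] %% sigma, sigma) else character(0)
  paste(c(first, rest), collapse = "")
}

#' Minimal FASTA reading / writing
#'
#' Thin wrappers over Biostrings' generic string sets so that sequences
#' over any alphabet (including the binary one) round-trip as plain text.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @rdname fasta-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @param x named character vector of sequences.
#' @rdname fasta-io
#' @export
write_fasta <- function(x, path) {
  b <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(b, path)
  invisible(path)
}
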