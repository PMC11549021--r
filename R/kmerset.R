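#' k-mer sets: the concrete form of a context-free selection function
#'
#' A context-free selection function over `Sigma^k` is fully described by
#' the set of k-mers it selects. `kmer_set` stores the member ranks (sorted,
#' unique) together with `(k, sigma)`; iteration order is increasing rank,
#' i.e. lexicographic.
#'
#' @param ranks numeric vector of member ranks (duplicates dropped).
#' @param k k-mer length.
#' @param sigma alphabet size.
#' @return an object of class `kmer_set`.
#' @examples
#' phi <- kmer_set(encode_kmers(c("ACG", "TTT"), 4), 3, 4)
#' length(phi); relative_size(phi)
#' @export
kmer_set <- function(ranks, k, sigma) {
  k <- as.integer(k); sigma <- as.integer(sigma)
  if (k < 1L) stop("k must be >= 1")
  alphabet(sigma)  # validates sigma
  ranks <- sort(unique(as.numeric(ranks)))
  if (length(ranks)) check_ranks(ranks, k, sigma)
  structure(list(ranks = ranks, k = k, sigma = sigma), class = "kmer_set")
}

as_kmer_set <- function(x) {
  if (!inherits(x, "kmer_set")) stop("expected a kmer_set")
  x
}

same_space <- function(a, b) {
  if (a$k != b$k || a$sigma != b$sigma)
    stop("kmer_set operands live in different (sigma, k) spaces")
  invisible(TRUE)
}

#' @export
length.kmer_set <- function(x) length(x$ranks)

#' @export
as.character.kmer_set <- function(x, ...) decode_kmers(x$ranks, x$k, x$sigma)

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: sigma=%d k=%d, %d of %g k-mers (%.4f%%)\n",
              x$sigma, x$k, length(x$ranks), x$sigma^x$k,
              100 * relative_size(x)))
  n <- min(length(x$ranks), 6L)
  if (n) cat(" ", paste(decode_kmers(x$ranks[seq_len(n)], x$k, x$sigma),
                        collapse = " "),
             if (length(x$ranks) > n) "..." else "", "\n")
  invisible(x)
}

#' Member ranks of a k-mer set
#' @param x a `kmer_set`.
#' @export
ks_members <- function(x) as_kmer_set(x)$ranks

#' Membership test
#' @param x a `kmer_set`.
#' @param ranks numeric vector of ranks to test.
#' @return logical vector.
#' @export
ks_contains <- function(x, ranks) {
  x <- as_kmer_set(x)
  ranks %in% x$ranks
}

#' Set algebra on k-mer sets
#'
#' Union, intersection, difference and complement of `kmer_set`s over the
#' same `(sigma, k)` space.
#'
#' @param a,b `kmer_set` objects.
#' @rdname ks-algebra
#' @export
ks_union <- function(a, b) {
  same_space(as_kmer_set(a), as_kmer_set(b))
  kmer_set(c(a$ranks, b$ranks), a$k, a$sigma)
}

#' @rdname ks-algebra
#' @export
ks_intersect <- function(a, b) {
  same_space(as_kmer_set(a), as_kmer_set(b))
  kmer_set(intersect(a$ranks, b$ranks), a$k, a$sigma)
}

#' @rdname ks-algebra
#' @export
ks_setdiff <- function(a, b) {
  same_space(as_kmer_set(a), as_kmer_set(b))
  kmer_set(setdiff(a$ranks, b$ranks), a$k, a$sigma)
}

#' @rdname ks-algebra
#' @export
ks_complement <- function(a) {
  a <- as_kmer_set(a)
  n <- space_size(a$k, a$sigma)
  kmer_set(setdiff(0:(n - 1), a$ranks), a$k, a$sigma)
}

#' Relative size of a k-mer set
#'
#' `|phi| / sigma^k`, which for a context-free scheme equals the expected
#' density of selected positions on a long i.i.d. uniform sequence.
#'
#' @param x a `kmer_set`.
#' @export
relative_size <- function(x) {
  x <- as_kmer_set(x)
  length(x$ranks) / x$sigma^x$k
}

#' Read / write the plain-text k-mer set format
#'
#' Format: first line `#sigma=<sigma> k=<k>`, then one k-mer string per line
#' (glyphs `A,C,G,T` for `sigma = 4`, digits otherwise; read is
#' case-insensitive, write is upper case). Round-trips bit-identically.
#'
#' @param path file path.
#' @rdname kmer-set-io
#' @export
read_kmer_set <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#sigma=\\d+ k=\\d+$", lines[1]))
    stop("malformed k-mer set file: missing '#sigma=<s> k=<k>' header")
  sigma <- as.integer(sub("^#sigma=(\\d+) k=\\d+$", "\\1", lines[1]))
  k <- as.integer(sub("^#sigma=\\d+ k=(\\d+)$", "\\1", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) && any(nchar(body) != k))
    stop("k-mer line length differs from header k=", k)
  ranks <- if (length(body)) encode_kmers(body, sigma) else numeric(0)
  kmer_set(ranks, k, sigma)
}

#' @param x a `kmer_set` to write.
#' @rdname kmer-set-io
#' @export
write_kmer_set <- function(x, path) {
  x <- as_kmer_set(x)
  tmp <- paste0(path, ".tmp")
  writeLines(c(sprintf("#sigma=%d k=%d", x$sigma, x$k), as.character(x)), tmp)
  file.rename(tmp, path)
  invisible(path)
}
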