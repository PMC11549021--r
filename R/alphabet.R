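#' Alphabet with complement structure
#'
#' An alphabet of even size `sigma` whose symbols are the integers
#' `0..sigma-1`, with the complement pairing `a -> sigma - 1 - a` (for DNA,
#' `A=0, C=1, G=2, T=3`, so `A<->T` and `C<->G`). The complement map is an
#' involution without fixed points, which is why `sigma` must be even.
#'
#' @param sigma integer number of symbols; must be even and >= 2.
#' @return an object of class `ks_alphabet` with elements `sigma`,
#'   `glyphs` (character vector used for printing; `A,C,G,T` when
#'   `sigma == 4`, decimal digits otherwise) and `complement`
#'   (integer vector such that `complement[a + 1]` is the complement of `a`).
#' @examples
#' ab <- alphabet(4)
#' ab$glyphs           # "A" "C" "G" "T"
#' ab$complement       # 3 2 1 0
#' @export
alphabet <- function(sigma) {
  sigma <- as.integer(sigma)
  if (length(sigma) != 1L || is.na(sigma) || sigma < 2L)
    stop("sigma must be a single integer >= 2")
  if (sigma %% 2L != 0L)
    stop("sigma must be even (complement must have no fixed point)")
  if (sigma > 10L)
    stop("alphabets larger than 10 symbols are not supported")
  glyphs <- if (sigma == 4L) c("A", "C", "G", "T") else as.character(0:(sigma - 1L))
  structure(
    list(sigma = sigma, glyphs = glyphs, complement = (sigma - 1L):0L),
    class = "ks_alphabet"
  )
}

## symbols (integers 0..sigma-1) from a glyph vector; NA for anything else
glyphs_to_symbols <- function(ch, sigma) {
  ab <- alphabet(sigma)
  m <- match(toupper(ch), ab$glyphs) - 1L
  m
}

symbols_to_glyphs <- function(x, sigma) {
  ab <- alphabet(sigma)
  ab$glyphs[x + 1L]
}
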