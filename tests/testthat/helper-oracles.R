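## Independent oracles: deliberately naive, string-based or matrix-based
## implementations that never share code with the package internals.

## reverse complement on glyph strings
oracle_rc <- function(x, sigma) {
  glyphs <- if (sigma == 4) c("A", "C", "G", "T") else as.character(0:(sigma - 1))
  ch <- rev(strsplit(x, "")[[1]])
  idx <- match(ch, glyphs) - 1
  paste(glyphs[(sigma - 1 - idx) + 1], collapse = "")
}

## all rotations of a string
oracle_rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i)
    paste0(substr(x, i, n), substr(x, 1, i - 1)), character(1))
}

## PCR partition by string rotation closure
oracle_pcr_count <- function(k, sigma) {
  all <- decode_kmers(0:(sigma^k - 1), k, sigma)
  seen <- character(0)
  count <- 0
  for (w in all) {
    if (w %in% seen) next
    seen <- c(seen, oracle_rotations(w))
    count <- count + 1
  }
  count
}

## dense adjacency matrix of B_k minus phi (by string overlap definition)
oracle_remaining_adjacency <- function(phi) {
  k <- phi$k; sigma <- phi$sigma
  keep <- setdiff(decode_kmers(0:(sigma^k - 1), k, sigma), as.character(phi))
  n <- length(keep)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (substr(keep[i], 2, k) == substr(keep[j], 1, k - 1)) A[i, j] <- 1
  }
  A
}

## nilpotency by dense matrix powers
oracle_nilpotent_index <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0)
  P <- diag(n)
  for (t in seq_len(n)) {
    P <- P %*% A
    if (all(P == 0)) return(t)
  }
  NA_integer_
}

## simulate absorption of uniform random walks; reports, per walk, the
## number of steps that land on an UNSELECTED k-mer (the quantity whose
## expectation is e' (sum_{j>=1} Atilde^j) p, i.e. absorption step - 1)
oracle_absorption_sim <- function(phi, n_walks, start = "remaining", seed = 42) {
  k <- phi$k; sigma <- phi$sigma
  n <- sigma^k
  member <- logical(n)
  member[ks_members(phi) + 1] <- TRUE
  set.seed(seed)
  starts <- if (start == "remaining") {
    sample(which(!member) - 1, n_walks, replace = TRUE)
  } else sample(0:(n - 1), n_walks, replace = TRUE)
  times <- integer(n_walks)
  for (i in seq_len(n_walks)) {
    cur <- starts[i]
    t <- 0
    while (!member[cur + 1]) {
      cur <- (cur %% sigma^(k - 1)) * sigma + sample.int(sigma, 1) - 1
      t <- t + 1
    }
    times[i] <- max(t - 1, 0)
  }
  times
}

## exhaustive minimum feedback vertex set of a small digraph (adjacency matrix)
oracle_mfvs_size <- function(A) {
  n <- nrow(A)
  has_cycle <- function(keep) {
    S <- A[keep, keep, drop = FALSE]
    m <- nrow(S)
    if (m == 0) return(FALSE)
    P <- S
    for (t in seq_len(m)) {
      if (any(diag(P) > 0)) return(TRUE)
      P <- P %*% S
    }
    FALSE
  }
  for (r in 0:n) {
    for (rem in if (r == 0) list(integer(0)) else
         asplit(utils::combn(n, r), 2)) {
      if (!has_cycle(setdiff(seq_len(n), rem))) return(r)
    }
  }
  n
}

## random small digraph
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(as.numeric(runif(n * n) < p), n, n)
  diag(A) <- 0
  A
}

expect_setequal_num <- function(a, b) expect_true(setequal(a, b))
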