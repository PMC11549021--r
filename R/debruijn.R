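#' de Bruijn graph analysis of a selection set
#'
#' For a context-free selection set `phi`, the sketching behaviour on
#' arbitrary sequences is governed by the subgraph of the de Bruijn graph
#' induced on the *unselected* k-mers, `B_k \ phi`. If that subgraph is a
#' DAG, `phi` is a decycling set and the longest remaining path bounds the
#' distance between selected k-mers on any sequence (strong window
#' guarantee). Surviving strongly connected components (SCCs) correspond to
#' arbitrarily long sequences with no selected k-mer.
#'
#' @name debruijn-analysis
NULL

## induced subgraph on Sigma^k \ phi; vertices carry their rank in $keep.
## Edges are generated arithmetically from ranks, never stored globally.
remainder_graph <- function(phi) {
  phi <- as_kmer_set(phi)
  k <- phi$k; sigma <- phi$sigma
  n <- space_size(k, sigma)
  keep <- setdiff(0:(n - 1), phi$ranks)
  g <- igraph::make_empty_graph(length(keep), directed = TRUE)
  if (length(keep)) {
    succ <- successor_kmers(keep, k, sigma)          # |keep| x sigma
    from <- rep(seq_along(keep), sigma)
    to <- match(as.vector(succ), keep)
    ok <- !is.na(to)
    g <- igraph::add_edges(g, rbind(from[ok], to[ok]))
  }
  list(g = g, keep = keep, k = k, sigma = sigma)
}

is_homopolymer <- function(ranks, k, sigma) {
  ranks %% ((sigma^k - 1) / (sigma - 1)) == 0 & ranks / ((sigma^k - 1) / (sigma - 1)) < sigma
}

#' Nontrivial strongly connected components of the remainder graph
#'
#' A reported SCC either has two or more nodes, or is a single homopolymer
#' node with its self-loop (the only self-loops in a de Bruijn graph).
#'
#' @param phi a `kmer_set`.
#' @return object of class `scc_report`: `count`, `sccs` (list of member
#'   rank vectors), `cumulative_size`, `cumulative_fraction`, and the
#'   `(k, sigma)` space.
#' @examples
#' scc_report(mykkeltveit_set(5, 2))$count   # 0: decycling
#' @export
scc_report <- function(phi) {
  phi <- as_kmer_set(phi)
  rg <- remainder_graph(phi)
  sccs <- list()
  if (length(rg$keep)) {
    comp <- igraph::components(rg$g, mode = "strong")
    for (ci in which(comp$csize >= 2)) {
      sccs[[length(sccs) + 1]] <- sort(rg$keep[comp$membership == ci])
    }
    ## singleton components count only with a self-loop (homopolymers)
    singles <- which(comp$csize == 1)
    if (length(singles)) {
      members <- comp$membership
      for (ci in singles) {
        v <- rg$keep[members == ci]
        if (is_homopolymer(v, rg$k, rg$sigma))
          sccs[[length(sccs) + 1]] <- v
      }
    }
    sccs <- sccs[order(vapply(sccs, min, numeric(1)))]
  }
  cum <- sum(lengths(sccs))
  structure(list(count = length(sccs), sccs = sccs, cumulative_size = cum,
                 cumulative_fraction = cum / phi$sigma^phi$k,
                 k = phi$k, sigma = phi$sigma),
            class = "scc_report")
}

#' @export
print.scc_report <- function(x, ...) {
  cat(sprintf("scc_report: sigma=%d k=%d, %d nontrivial SCC(s), %g nodes (%.4f%%)\n",
              x$sigma, x$k, x$count, x$cumulative_size,
              100 * x$cumulative_fraction))
  invisible(x)
}

#' Is a selection set decycling?
#'
#' TRUE iff the remainder graph has no nontrivial SCC, i.e. is a DAG.
#' A necessary condition is that `phi` hits every PCR; a missing PCR leaves
#' its rotation cycle intact.
#'
#' @param phi a `kmer_set`.
#' @export
is_decycling <- function(phi) {
  rg <- remainder_graph(as_kmer_set(phi))
  if (!length(rg$keep)) return(TRUE)
  ## is_dag() treats self-loops as cycles, matching our SCC convention
  igraph::is_dag(rg$g)
}

#' Longest path remaining after removal of a decycling set
#'
#' Counted in EDGES (a walk `v0 ... vt` has length `t`); an empty remainder
#' graph has longest path 0. By the nilpotency correspondence the nilpotent
#' index of the remaining adjacency matrix is `longest_path + 1`. Note that
#' a path of `t` edges visits `t + 1` k-mers, so tabulations that count the
#' k-mers on the path print `longest_path + 1`.
#'
#' @param phi a `kmer_set`; must be decycling.
#' @return integer number of edges.
#' @examples
#' longest_path(mykkeltveit_set(5, 2))   # 10 edges, i.e. 11 k-mers
#' @export
longest_path <- function(phi) {
  phi <- as_kmer_set(phi)
  rg <- remainder_graph(phi)
  if (!length(rg$keep)) return(0L)
  if (!igraph::is_dag(rg$g))
    stop("phi is not decycling: no window guarantee, longest path undefined")
  ord <- as.integer(igraph::topo_sort(rg$g))
  d <- integer(igraph::vcount(rg$g))
  preds <- igraph::as_adj_list(rg$g, mode = "in")
  for (v in ord) {
    p <- as.integer(preds[[v]])
    if (length(p)) d[v] <- max(d[p]) + 1L
  }
  max(d)
}

#' Nilpotency cross-check of the remaining adjacency matrix
#'
#' Iterates `v <- A v` starting from the all-ones vector; for a nonnegative
#' matrix, `A^t e = 0` for some `t <= n` iff `A` is nilpotent, and the
#' smallest such `t` is the nilpotent index -- one more than the longest
#' path when the graph is a DAG. This is an independent, matrix-only oracle
#' for [is_decycling()] / [longest_path()].
#'
#' @param phi a `kmer_set`; guarded to `sigma^k <= 2^16`.
#' @return list with `nilpotent` (logical) and `index` (integer or NA).
#' @export
nilpotency_check <- function(phi) {
  phi <- as_kmer_set(phi)
  n_all <- phi$sigma^phi$k
  if (n_all > 2^16) stop("nilpotency_check guard: sigma^k must be <= 2^16")
  rg <- remainder_graph(phi)
  n <- length(rg$keep)
  if (n == 0) return(list(nilpotent = TRUE, index = 0L))
  A <- adjacency_sparse(rg)
  v <- rep(1, n)
  for (t in seq_len(n)) {
    v <- as.numeric(A %*% v)
    if (all(v == 0)) return(list(nilpotent = TRUE, index = t))
  }
  list(nilpotent = FALSE, index = NA_integer_)
}

adjacency_sparse <- function(rg) {
  n <- length(rg$keep)
  succ <- successor_kmers(rg$keep, rg$k, rg$sigma)
  from <- rep(seq_len(n), rg$sigma)
  to <- match(as.vector(succ), rg$keep)
  ok <- !is.na(to)
  Matrix::sparseMatrix(i = from[ok], j = to[ok], x = 1, dims = c(n, n))
}

#' Expected absorption time of a random walk
#'
#' A uniform random walk on the de Bruijn graph (each of the `sigma`
#' outgoing edges equally likely) stops when it hits a selected k-mer. For a
#' decycling `phi`, the expected number of steps before absorption is
#' `E = e' (sum_{j=1}^{t} Atilde^j) p` with `Atilde = A / sigma` restricted
#' to the remaining nodes and `t` the nilpotent index; it is infinite when
#' `phi` is not decycling.
#'
#' Two start distributions are built in: `"remaining"` (uniform over
#' unselected k-mers, renormalized) and `"all"` (uniform over all `sigma^k`
#' k-mers, walks starting on a selected k-mer absorbed at time 0). A custom
#' probability vector over the remaining nodes (in increasing rank order)
#' may be given instead.
#'
#' @param phi a `kmer_set`; must be decycling.
#' @param start `"remaining"`, `"all"`, or a numeric vector.
#' @return a single numeric, the expected absorption time in steps.
#' @export
expected_absorption_time <- function(phi, start = c("remaining", "all")) {
  phi <- as_kmer_set(phi)
  rg <- remainder_graph(phi)
  n <- length(rg$keep)
  if (n == 0) return(0)
  if (!igraph::is_dag(rg$g))
    stop("phi is not decycling: expected absorption time is infinite")
  if (is.character(start)) {
    start <- match.arg(start)
    p <- switch(start,
                remaining = rep(1 / n, n),
                all = rep(1 / (rg$sigma^rg$k), n))
  } else {
    if (length(start) != n || any(start < 0))
      stop("custom start must be a nonnegative vector over the ", n,
           " remaining nodes")
    p <- start
  }
  At <- Matrix::t(adjacency_sparse(rg)) / rg$sigma
  v <- p
  total <- 0
  repeat {
    v <- as.numeric(At %*% v)
    s <- sum(v)
    if (s == 0) break
    total <- total + s
  }
  total
}

#' Classify the window guarantee of a selection set
#'
#' `strong` when `phi` is decycling (with window `w = longest_path + 1`,
#' the maximal possible distance between consecutive selected positions);
#' `relaxed` when the only surviving SCCs are the `sigma` homopolymer
#' self-loops (only low-entropy runs escape selection); `none` otherwise.
#'
#' @param phi a `kmer_set`.
#' @return list with `type` (one of `"strong"`, `"relaxed"`, `"none"`),
#'   `w` (for strong), and `scc` (the [scc_report()]).
#' @export
classify_window_guarantee <- function(phi) {
  rep <- scc_report(phi)
  if (rep$count == 0)
    return(list(type = "strong", w = longest_path(phi) + 1L, scc = rep))
  homopoly <- all(lengths(rep$sccs) == 1) &&
    all(is_homopolymer(unlist(rep$sccs), rep$k, rep$sigma))
  list(type = if (homopoly) "relaxed" else "none", w = NA_integer_, scc = rep)
}
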