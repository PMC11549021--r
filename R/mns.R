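#' Maximum nilpotent submatrix problems
#'
#' The exact design of symmetric, path-length-constrained decycling sets is
#' cast as a maximum-weight nilpotent-submatrix problem: choose a vertex
#' subset Gamma (the KEPT vertices) maximizing `sum of w over Gamma`
#' subject to the induced adjacency submatrix satisfying
#' `A_Gamma^(t+1) e = 0` -- equivalently, the induced subgraph is a DAG
#' with longest path at most `t` edges. The complement of a solution is a
#' minimum feedback vertex set with a path-length constraint; on the de
#' Bruijn graph with reverse-complement orbits identified it yields minimum
#' symmetric decycling sets.
#'
#' @param n number of vertices.
#' @param edges two-column matrix of directed edges (1-based vertex ids).
#' @param t path bound in edges (`t = n` means plain acyclicity).
#' @param w vertex weights (default all 1).
#' @param orbits list of integer vectors partitioning `1..n` into symmetry
#'   orbits (default: singletons, i.e. no symmetry).
#' @return object of class `nilpotent_problem`.
#' @export
nilpotent_problem <- function(n, edges, t = n, w = rep(1, n), orbits = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (length(edges) && (min(edges) < 1 || max(edges) > n))
    stop("edge endpoints out of range")
  if (length(w) != n || any(!is.finite(w))) stop("w must be n finite weights")
  if (is.null(orbits)) orbits <- as.list(seq_len(n))
  cover <- sort(unlist(orbits))
  if (!identical(cover, seq_len(n)))
    stop("orbits must partition the vertex set")
  if (t < 0 || t > n) stop("t must lie in [0, n]")
  structure(list(n = n, edges = edges, t = as.integer(t), w = as.numeric(w),
                 orbits = orbits),
            class = "nilpotent_problem")
}

#' Build the mixed-integer model for a nilpotent-submatrix problem
#'
#' Constructs the level-variable (vertex potential) encoding: one binary
#' keep-variable per symmetry orbit and one continuous level variable per
#' vertex with `0 <= level <= t`; for every edge `(i, j)`,
#' `level_j >= level_i + 1 - (t + 1) * (2 - x_i - x_j)` (big-M constant
#' exactly `t + 1`). A 0/1 assignment of the orbit variables is feasible
#' iff the kept subgraph has no walk longer than `t` edges -- the same
#' feasible set as the nilpotency condition `A_Gamma^(t+1) e = 0`.
#' The model is a plain data structure; [solve_mns()] solves it exactly.
#'
#' @param problem a [nilpotent_problem()].
#' @return object of class `mns_model` with fields `problem`, `n_binary`
#'   (one per orbit), `n_continuous`, `big_M`, `objective` (orbit weights),
#'   and `constraints` (data.frame `i`, `j`, big-M rows, one per edge).
#' @export
build_mns_model <- function(problem) {
  if (!inherits(problem, "nilpotent_problem")) stop("expected a nilpotent_problem")
  orbit_of <- integer(problem$n)
  for (oi in seq_along(problem$orbits)) orbit_of[problem$orbits[[oi]]] <- oi
  obj <- vapply(problem$orbits, function(o) sum(problem$w[o]), numeric(1))
  cons <- if (nrow(problem$edges)) {
    data.frame(i = problem$edges[, 1], j = problem$edges[, 2],
               xi = orbit_of[problem$edges[, 1]],
               xj = orbit_of[problem$edges[, 2]])
  } else data.frame(i = integer(0), j = integer(0), xi = integer(0),
                    xj = integer(0))
  structure(list(problem = problem, orbit_of = orbit_of,
                 n_binary = length(problem$orbits),
                 n_continuous = problem$n,
                 big_M = problem$t + 1, objective = obj,
                 constraints = cons),
            class = "mns_model")
}

## longest path (edges) of the subgraph induced on `keep` (logical over
## vertices); Inf when cyclic. Small graphs only -- used by the solver.
induced_longest_path <- function(n, edges, keep) {
  vs <- which(keep)
  if (!length(vs)) return(0)
  sel <- keep[edges[, 1]] & keep[edges[, 2]]
  e <- edges[sel, , drop = FALSE]
  idx <- match(e, vs)
  g <- igraph::make_empty_graph(length(vs), directed = TRUE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(idx[seq_len(nrow(e))],
                                               idx[-seq_len(nrow(e))]))
  if (!igraph::is_dag(g)) return(Inf)
  ord <- as.integer(igraph::topo_sort(g))
  d <- integer(length(vs))
  preds <- igraph::as_adj_list(g, mode = "in")
  for (v in ord) {
    p <- as.integer(preds[[v]])
    if (length(p)) d[v] <- max(d[p]) + 1L
  }
  max(d)
}

#' Solve a nilpotent-submatrix model exactly
#'
#' Branch-and-bound implicit enumeration over the orbit keep-variables.
#' Feasibility of (partial) assignments is checked on the kept subgraph via
#' the DAG/longest-path correspondence (the feasible region of the big-M
#' model, see [build_mns_model()]); keeping is monotone, so a partial
#' kept set that already violates the path bound prunes its subtree, and
#' the sum of still-undecided weights bounds the objective from above.
#' Designed for the problem sizes of this package's exact-design use case
#' (tens of orbits), not as a general MIP solver.
#'
#' @param model an `mns_model`.
#' @param verbose logical.
#' @return list with `keep` (logical over vertices), `objective`,
#'   `nodes_explored`.
#' @export
solve_mns <- function(model, verbose = FALSE) {
  if (!inherits(model, "mns_model")) stop("expected an mns_model")
  pr <- model$problem
  norb <- model$n_binary
  ## decide orbits in decreasing weight order (better bounds first)
  oord <- order(model$objective, decreasing = TRUE)
  best <- list(obj = -Inf, keep = rep(FALSE, norb))
  nodes <- 0L
  suffix_w <- rev(cumsum(rev(model$objective[oord])))
  rec <- function(pos, keepv, objv) {
    nodes <<- nodes + 1L
    if (pos > norb) {
      if (objv > best$obj) best <<- list(obj = objv, keep = keepv)
      return(invisible())
    }
    ub <- objv + suffix_w[pos]
    if (ub <= best$obj) return(invisible())
    oi <- oord[pos]
    ## branch 1: keep this orbit (check feasibility incrementally)
    keep2 <- keepv; keep2[oi] <- TRUE
    vkeep <- rep(FALSE, pr$n)
    vkeep[unlist(pr$orbits[keep2])] <- TRUE
    if (induced_longest_path(pr$n, pr$edges, vkeep) <= pr$t)
      rec(pos + 1, keep2, objv + model$objective[oi])
    ## branch 2: drop it
    rec(pos + 1, keepv, objv)
  }
  rec(1L, rep(FALSE, norb), 0)
  vkeep <- rep(FALSE, pr$n)
  vkeep[unlist(pr$orbits[best$keep])] <- TRUE
  if (verbose) message("solve_mns: ", nodes, " nodes")
  list(keep = vkeep, objective = best$obj, nodes_explored = nodes)
}

## ---------------------------------------------------------------------------

## all rc orbits of the full k-mer space
space_rc_orbits <- function(k, sigma) {
  n <- space_size(k, sigma)
  all <- 0:(n - 1)
  rc <- rc_kmers(all, k, sigma)
  key <- pmin(all, rc)
  unname(split(all, key))
}

debruijn_edges_1based <- function(k, sigma) {
  n <- space_size(k, sigma)
  all <- 0:(n - 1)
  succ <- successor_kmers(all, k, sigma)
  cbind(rep(all + 1, sigma), as.vector(succ) + 1)
}

#' Exact minimum symmetric decycling sets
#'
#' Lexicographic exact design over the de Bruijn graph with
#' reverse-complement symmetry: stage `"cardinality"` finds the minimum
#' number of k-mers in a reverse-complement-closed decycling set (one
#' binary variable per RC orbit, path bound `t = n`); stage `"path"` then
#' fixes that cardinality and minimizes the longest remaining path by
#' bisection on the path bound; stage `"expected"` finally minimizes the
#' expected absorption time (uniform over remaining nodes) among the
#' stage-2 optimal solutions, by enumeration.
#'
#' Every reported solution is independently re-verified with
#' [is_symmetric()], [is_decycling()] and [longest_path()] -- the solver's
#' answer is never trusted bare.
#'
#' @param k k-mer length (exact search; sigma = 2 and k <= 8 is the
#'   practical envelope, exponential beyond).
#' @param sigma alphabet size.
#' @param stages character vector, a prefix of
#'   `c("cardinality", "path", "expected")`.
#' @param verbose logical.
#' @return object of class `ilp_result`: `removed` (`kmer_set`),
#'   `cardinality`, `max_path` (edges; `NA` unless stage `"path"` ran),
#'   `expected_absorption`, `status`, `wall_time` (seconds), plus the
#'   search statistics.
#' @examples
#' \donttest{
#' r <- solve_symmetric_mds(5, 2)
#' r$cardinality   # 12
#' r$max_path      # 5 edges = 6 k-mers on the path
#' }
#' @export
solve_symmetric_mds <- function(k, sigma,
                                stages = c("cardinality", "path"),
                                verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  stages <- match.arg(stages, c("cardinality", "path", "expected"),
                      several.ok = TRUE)
  if ("expected" %in% stages && !"path" %in% stages)
    stop("stage 'expected' requires stage 'path'")
  n <- space_size(k, sigma)
  orbits1 <- lapply(space_rc_orbits(k, sigma), function(o) o + 1L)
  edges <- debruijn_edges_1based(k, sigma)

  ## stage 1: maximize kept weight == minimize removed k-mers
  pr <- nilpotent_problem(n, edges, t = n, orbits = orbits1)
  sol <- solve_mns(build_mns_model(pr), verbose = verbose)
  removed1 <- which(!sol$keep) - 1L
  card <- length(removed1)
  best_removed <- removed1
  max_path <- NA_integer_
  nodes <- sol$nodes_explored

  if ("path" %in% stages) {
    ## bisection on t: smallest t admitting a symmetric removal of
    ## cardinality `card` with remaining longest path <= t
    feas_removed <- best_removed
    lo <- 0L
    hi <- induced_longest_path(n, edges, !(seq_len(n) %in% (best_removed + 1L)))
    while (lo < hi) {
      mid <- as.integer(floor((lo + hi) / 2))
      prt <- nilpotent_problem(n, edges, t = mid, orbits = orbits1)
      solt <- solve_mns(build_mns_model(prt), verbose = verbose)
      nodes <- nodes + solt$nodes_explored
      if (sum(!solt$keep) <= card && is.finite(solt$objective)) {
        feas_removed <- which(!solt$keep) - 1L
        hi <- mid
      } else lo <- mid + 1L
    }
    best_removed <- feas_removed
    max_path <- lo
  }

  expected <- NA_real_
  phi <- kmer_set(best_removed, k, sigma)
  if ("expected" %in% stages) {
    cands <- enumerate_optimal_symmetric(k, sigma, card, max_path)
    exps <- vapply(cands, function(s)
      expected_absorption_time(kmer_set(s, k, sigma), "remaining"), numeric(1))
    phi <- kmer_set(cands[[which.min(exps)]], k, sigma)
    expected <- min(exps)
  } else if (!is.na(max_path)) {
    expected <- expected_absorption_time(phi, "remaining")
  }

  ## independent verification
  stopifnot(is_symmetric(phi), is_decycling(phi))
  lp <- longest_path(phi)
  if (!is.na(max_path)) stopifnot(lp <= max_path)

  structure(list(removed = phi, cardinality = length(phi),
                 max_path = if (is.na(max_path)) lp else max_path,
                 expected_absorption = expected,
                 status = "optimal", nodes_explored = nodes,
                 wall_time = proc.time()[["elapsed"]] - t0),
            class = "ilp_result")
}

#' @export
print.ilp_result <- function(x, ...) {
  cat(sprintf(
    "ilp_result: |removed| = %d, max remaining path = %s edges, E[absorption] = %s (%.2fs, %d nodes)\n",
    x$cardinality, format(x$max_path), format(x$expected_absorption),
    x$wall_time, x$nodes_explored))
  invisible(x)
}

## all symmetric decycling removal sets at given cardinality and path bound
enumerate_optimal_symmetric <- function(k, sigma, card, t) {
  orbs <- space_rc_orbits(k, sigma)
  sizes <- lengths(orbs)
  n <- space_size(k, sigma)
  edges <- debruijn_edges_1based(k, sigma)
  out <- list()
  rec <- function(idx, chosen, tot) {
    if (tot > card) return(invisible())
    if (idx > length(orbs)) {
      if (tot != card) return(invisible())
      rem <- unlist(orbs[chosen])
      keep <- !(seq_len(n) %in% (rem + 1L))
      if (induced_longest_path(n, edges, keep) <= t)
        out[[length(out) + 1L]] <<- rem
      return(invisible())
    }
    if (tot + sum(sizes[idx:length(orbs)]) < card) return(invisible())
    rec(idx + 1L, c(chosen, idx), tot + sizes[idx])
    rec(idx + 1L, chosen, tot)
  }
  rec(1L, integer(0), 0)
  out
}

#' Brute-force oracle for minimum symmetric decycling sets
#'
#' Exhaustive search over all subsets of reverse-complement orbits
#' (guarded to at most 20 orbits, i.e. 2^20 subsets): finds the minimum
#' cardinality of a symmetric decycling set and, among the
#' minimum-cardinality sets, the minimum longest remaining path. Entirely
#' independent of [solve_mns()]; used to cross-check it.
#'
#' @param k k-mer length.
#' @param sigma alphabet size.
#' @return list with `cardinality` (k-mers), `max_path` (edges),
#'   `n_orbits`, `n_optimal` (number of minimum-cardinality sets).
#' @export
brute_force_symmetric_mds <- function(k, sigma) {
  orbs <- space_rc_orbits(k, sigma)
  m <- length(orbs)
  if (m > 20) stop("brute force guard: more than 20 rc orbits")
  n <- space_size(k, sigma)
  edges <- debruijn_edges_1based(k, sigma)
  sizes <- lengths(orbs)
  best_card <- Inf
  best_sets <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))))
    card <- sum(sizes[sel])
    if (card > best_card) next
    rem <- unlist(orbs[sel])
    keep <- !(seq_len(n) %in% (rem + 1L))
    if (is.finite(induced_longest_path(n, edges, keep))) {
      if (card < best_card) {
        best_card <- card
        best_sets <- list(rem)
      } else best_sets[[length(best_sets) + 1L]] <- rem
    }
  }
  mps <- vapply(best_sets, function(rem) {
    keep <- !(seq_len(n) %in% (rem + 1L))
    induced_longest_path(n, edges, keep)
  }, numeric(1))
  list(cardinality = best_card, max_path = min(mps), n_orbits = m,
       n_optimal = length(best_sets))
}
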