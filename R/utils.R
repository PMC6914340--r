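#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed (kept < 2^31).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Solve a square linear assignment problem
#'
#' Minimizes `sum(cost[i, perm[i]])` over permutations by the Jonker-Volgenant
#' shortest augmenting path algorithm. Costs must be finite; use a large
#' penalty for forbidden assignments.
#'
#' @param cost square numeric matrix of finite costs.
#' @return integer vector `perm` with `perm[i]` the column assigned to row `i`.
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) stopf("assignment cost matrix must be square")
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stopf("assignment costs must be finite")
  # Potentials formulation; arrays carry a virtual column at index 1,
  # real column j lives at index j + 1.
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[jj] = row assigned to column jj (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (jj in 2:(n + 1)) {
        if (!used[jj]) {
          cur <- cost[i0, jj - 1L] - u[i0 + 1L] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in 1:(n + 1)) {
        if (used[jj]) {
          u[p[jj] + 1L] <- u[p[jj] + 1L] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  col_of <- integer(n)
  for (jj in 2:(n + 1)) if (p[jj] > 0L) col_of[p[jj]] <- jj - 1L
  col_of
}

#' Gated bipartite matching between two point sets
#'
#' Pairs rows of `xy1` with rows of `xy2` subject to a distance gate,
#' maximizing the number of pairs and, among maximum matchings, minimizing the
#' total (optionally squared) distance. Solved exactly via [solve_assignment()]
#' on an augmented square matrix in which leaving a point unmatched costs more
#' than any admissible pairing.
#'
#' @param xy1,xy2 two-column matrices of coordinates.
#' @param gate scalar or per-row-of-`xy1` vector of maximum admissible
#'   distances.
#' @param squared if `TRUE`, minimize total squared distance.
#' @return data.frame with columns `i`, `j`, `dist` (one row per pair).
#' @keywords internal
match_points <- function(xy1, xy2, gate, squared = FALSE) {
  m <- nrow(xy1); n <- nrow(xy2)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (m == 0L || n == 0L) return(empty)
  dx <- outer(xy1[, 1], xy2[, 1], "-")
  dy <- outer(xy1[, 2], xy2[, 2], "-")
  d <- sqrt(dx * dx + dy * dy)
  gate <- rep_len(gate, m)
  allowed <- d <= gate
  if (!any(allowed)) return(empty)
  # The optimal matching decomposes over connected components of the
  # admissible-pair graph; solve each (typically tiny) component exactly.
  edges <- which(allowed, arr.ind = TRUE)
  parent <- seq_len(m + n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges[r, 1]); rb <- find(m + edges[r, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots1 <- vapply(unique(edges[, 1]), find, 1L)
  comp_of_row <- integer(m)
  comp_of_row[unique(edges[, 1])] <- roots1
  comp_of_col <- integer(n)
  ucol <- unique(edges[, 2])
  comp_of_col[ucol] <- vapply(m + ucol, find, 1L)
  res <- vector("list", 0L)
  for (root in unique(roots1)) {
    ri <- which(comp_of_row == root)
    cj <- which(comp_of_col == root)
    sub <- match_points_exact(d[ri, cj, drop = FALSE],
                              allowed[ri, cj, drop = FALSE], squared)
    if (nrow(sub)) {
      sub$i <- ri[sub$i]; sub$j <- cj[sub$j]
      res[[length(res) + 1L]] <- sub
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$i), , drop = FALSE]
}

# Exact max-cardinality min-cost matching on a small dense component via the
# augmented-square assignment construction.
match_points_exact <- function(d, allowed, squared) {
  m <- nrow(d); n <- ncol(d)
  if (m == 1L && n == 1L) {
    return(data.frame(i = 1L, j = 1L, dist = d[1, 1]))
  }
  w <- if (squared) d * d else d
  big <- sum(w[allowed]) + max(w[allowed]) + 1
  huge <- big * (m + n + 1)
  k <- m + n
  cost <- matrix(huge, k, k)
  wgated <- w
  wgated[!allowed] <- huge
  cost[seq_len(m), seq_len(n)] <- wgated
  for (i in seq_len(m)) cost[i, n + i] <- big          # row i unmatched
  for (j in seq_len(n)) cost[m + j, j] <- big          # col j unmatched
  cost[(m + 1):k, (n + 1):k] <- 0                      # dummy-dummy free
  perm <- solve_assignment(cost)
  i_idx <- seq_len(m)
  j_idx <- perm[seq_len(m)]
  keep <- j_idx <= n
  keep[keep] <- allowed[cbind(i_idx[keep], j_idx[keep])]
  data.frame(i = i_idx[keep], j = j_idx[keep],
             dist = d[cbind(i_idx[keep], j_idx[keep])])
}

# Greedy gated matching: repeatedly take the closest admissible pair.
# Deterministic ties: smaller distance, then lower i, then lower j.
match_points_greedy <- function(xy1, xy2, gate) {
  m <- nrow(xy1); n <- nrow(xy2)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (m == 0L || n == 0L) return(empty)
  dx <- outer(xy1[, 1], xy2[, 1], "-")
  dy <- outer(xy1[, 2], xy2[, 2], "-")
  d <- sqrt(dx * dx + dy * dy)
  gate <- rep_len(gate, m)
  ok <- which(d <= gate, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(empty)
  dist <- d[ok]
  ord <- order(dist, ok[, 1], ok[, 2])
  ok <- ok[ord, , drop = FALSE]
  dist <- dist[ord]
  used1 <- rep(FALSE, m); used2 <- rep(FALSE, n)
  sel <- logical(nrow(ok))
  for (r in seq_len(nrow(ok))) {
    i <- ok[r, 1]; j <- ok[r, 2]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE; sel[r] <- TRUE
    }
  }
  data.frame(i = ok[sel, 1], j = ok[sel, 2], dist = dist[sel])
}

# Plain DBSCAN (Euclidean) for the small per-track point clouds used in
# immobile-particle detection. Returns integer cluster labels, 0 = noise.
dbscan_labels <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(xy))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neigh, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, neigh[[j]][labels[neigh[[j]]] == 0L])
      }
    }
  }
  labels
}
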