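# Exact solver for the balanced transportation problem, used as the Earth
# Mover's Distance engine. Transportation simplex: north-west-corner start,
# dual (u, v) pricing on the basis tree, Bland's smallest-index rule for
# entering and leaving variables so the pivoting cannot cycle even on the
# degenerate instances that colour histograms routinely produce.

#' Solve a balanced transportation problem exactly
#'
#' Minimises `sum(plan * cost)` over non-negative plans whose row sums equal
#' `supply` and column sums equal `demand`. Supplies and demands must
#' balance (equal totals).
#'
#' @param supply Non-negative numeric vector (length m), total mass > 0.
#' @param demand Non-negative numeric vector (length n), same total.
#' @param cost m x n numeric cost matrix.
#' @return List with `cost` (the optimal objective) and `plan` (an optimal
#'   m x n transport plan).
#' @export
solve_transport <- function(supply, demand, cost) {
  m <- length(supply); n <- length(demand)
  stopifnot(is.matrix(cost), nrow(cost) == m, ncol(cost) == n,
            all(supply >= 0), all(demand >= 0))
  total <- sum(supply)
  if (total <= 0) stop("total mass must be positive", call. = FALSE)
  if (abs(total - sum(demand)) > 1e-9 * max(1, total))
    stop("supply and demand are not balanced", call. = FALSE)

  if (m == 1L) return(list(cost = sum(demand * cost[1, ]),
                           plan = matrix(demand, 1L, n)))
  if (n == 1L) return(list(cost = sum(supply * cost[, 1]),
                           plan = matrix(supply, m, 1L)))

  a <- supply; b <- demand
  X <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  # north-west corner initial basic feasible solution (m + n - 1 cells,
  # including zero-flow cells under degeneracy)
  i <- 1L; j <- 1L
  while (i <= m && j <= n) {
    t <- min(a[i], b[j])
    X[i, j] <- t; basis[i, j] <- TRUE
    a[i] <- a[i] - t; b[j] <- b[j] - t
    if (i == m && j == n) break
    if (a[i] <= b[j] && i < m) i <- i + 1L else j <- j + 1L
  }

  eps <- 1e-12 * max(1, max(abs(cost)))
  for (iter in seq_len(10000L)) {
    # duals from the basis spanning tree (rows 1..m, cols m+1..m+n)
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    queue <- c(1L)  # node ids: rows 1..m, columns m + j
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      if (node <= m) {
        js <- which(basis[node, ] & is.na(v))
        v[js] <- cost[node, js] - u[node]
        queue <- c(queue, m + js)
      } else {
        jj <- node - m
        is <- which(basis[, jj] & is.na(u))
        u[is] <- cost[is, jj] - v[jj]
        queue <- c(queue, is)
      }
    }
    red <- cost - outer(u, v, "+")
    cand <- which(!basis & red < -eps)
    if (!length(cand)) break
    enter <- min(cand)  # Bland: smallest linear index
    ei <- (enter - 1L) %% m + 1L
    ej <- (enter - 1L) %/% m + 1L

    # unique path in the basis tree from row node ei to column node ej
    parent <- rep(0L, m + n)
    seen <- rep(FALSE, m + n); seen[ei] <- TRUE
    queue <- c(ei)
    while (length(queue) && !seen[m + ej]) {
      node <- queue[1]; queue <- queue[-1]
      nbrs <- if (node <= m) m + which(basis[node, ]) else which(basis[, node - m])
      nbrs <- nbrs[!seen[nbrs]]
      seen[nbrs] <- TRUE; parent[nbrs] <- node
      queue <- c(queue, nbrs)
    }
    path <- c(m + ej)
    while (path[1] != ei) path <- c(parent[path[1]], path)
    # cycle cells: entering cell then edges along the path; alternate signs
    cyc_i <- integer(0); cyc_j <- integer(0)
    for (k in seq_len(length(path) - 1L)) {
      n1 <- path[k]; n2 <- path[k + 1L]
      if (n1 <= m) { cyc_i <- c(cyc_i, n1); cyc_j <- c(cyc_j, n2 - m) }
      else { cyc_i <- c(cyc_i, n2); cyc_j <- c(cyc_j, n1 - m) }
    }
    # path edges alternate -, +, -, ... after the entering (+) cell
    signs <- rep_len(c(-1, 1), length(cyc_i))
    minus <- which(signs < 0)
    flows <- X[cbind(cyc_i[minus], cyc_j[minus])]
    theta <- min(flows)
    ties <- minus[flows == theta]
    lin <- cyc_i[ties] + (cyc_j[ties] - 1L) * m
    leave_k <- ties[which.min(lin)]  # Bland again on the leaving variable
    X[ei, ej] <- X[ei, ej] + theta
    X[cbind(cyc_i, cyc_j)] <- X[cbind(cyc_i, cyc_j)] + signs * theta
    basis[ei, ej] <- TRUE
    basis[cyc_i[leave_k], cyc_j[leave_k]] <- FALSE
    X[cyc_i[leave_k], cyc_j[leave_k]] <- 0
  }
  X[X < 0] <- 0
  list(cost = sum(X * cost), plan = X)
}
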