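#' Solve the linear sum assignment problem with a cost threshold
#'
#' Minimum-cost one-to-one matching of rows to columns of a cost matrix by
#' the Jonker–Volgenant-style shortest-augmenting-path algorithm (dual
#' potentials, no initialisation), the standard solver for linking
#' detections between time steps. Rectangular matrices are squared by
#' padding with the threshold cost, so leaving a detection unlinked (and
#' starting a new trajectory) competes fairly with an expensive link.
#' After solving, links whose cost exceeds the threshold are removed;
#' a link with cost exactly equal to the threshold is retained.
#'
#' @param cost Numeric matrix of non-negative finite costs (e.g. matching
#'   distances in pixels).
#' @param threshold Maximum retained link cost (default `Inf`).
#' @return Integer matrix with columns `row` and `col` (1-based indices of
#'   retained links); zero rows when nothing links.
#' @examples
#' solve_assignment(rbind(c(1, 2), c(2, 4)))        # anti-diagonal, total 4
#' solve_assignment(rbind(c(1, 50), c(50, 1)), 10)  # diagonal kept
#' @export
solve_assignment <- function(cost, threshold = Inf) {
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (length(cost) == 0) return(empty)
  cost <- as.matrix(cost)
  if (any(!is.finite(cost)) || any(cost < 0)) {
    stop("solve_assignment: costs must be finite and non-negative",
         call. = FALSE)
  }
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  pad <- if (is.finite(threshold)) threshold else max(cost) + 1
  a <- matrix(pad, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost
  col_of <- .lapjv_square(a)
  rows <- seq_len(nr)
  cols <- col_of[rows]
  keep <- cols <= nc
  keep[keep] <- cost[cbind(rows[keep], cols[keep])] <= threshold
  out <- cbind(row = rows[keep], col = cols[keep])
  if (nrow(out) == 0) empty else out
}

## Shortest augmenting path assignment on a square matrix; returns for each
## row its assigned column. Column n+1 acts as the virtual start column.
.lapjv_square <- function(a) {
  n <- nrow(a)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row currently assigned to column j
  way <- integer(n + 1)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- cols[!used[cols]]
      cur <- a[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- used
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[!usedj] <- minv[!usedj] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  col_of <- integer(n)
  col_of[p[cols]] <- cols
  col_of
}
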