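# Independent oracles used to cross-check the package's geometry and
# assignment code. They deliberately avoid the implementation's code paths:
# distances come from 1-D numerical minimization per segment, assignments
# from exhaustive permutation search.

# Distance from a point to a polyline by Brent minimization of the
# per-segment distance function (squared distance is quadratic in the
# segment parameter, hence unimodal).
oracle_point_to_polyline <- function(p, P) {
  V <- unclass(P)
  best <- Inf
  for (i in seq_len(nrow(V) - 1)) {
    a <- V[i, ]; b <- V[i + 1, ]
    f <- function(t) sqrt(sum((a + t * (b - a) - p)^2))
    best <- min(best, stats::optimize(f, c(0, 1), tol = 1e-12)$objective,
                f(0), f(1))
  }
  best
}

# Matching distance oracle: build the 4-element endpoint-distance multiset
# explicitly, sort, take the second element.
oracle_matching_distance <- function(Pa, Pb) {
  Va <- unclass(Pa); Vb <- unclass(Pb)
  d <- c(oracle_point_to_polyline(Va[1, ], Pb),
         oracle_point_to_polyline(Va[nrow(Va), ], Pb),
         oracle_point_to_polyline(Vb[1, ], Pa),
         oracle_point_to_polyline(Vb[nrow(Vb), ], Pa))
  sort(d)[2]
}

# All permutations of 1..n (recursive, no extra packages).
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- if (n == 1) matrix(1L, 1, 1) else {
      sub <- all_perms(n - 1)
      do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub)))
      }))
    }
    cache[[key]] <<- res
    res
  }
})

# Minimum total cost over all complete assignments of a square matrix.
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  vals <- matrix(cost[cbind(rep(seq_len(n), times = nrow(perms)),
                            as.vector(t(perms)))],
                 nrow = nrow(perms), byrow = TRUE)
  min(rowSums(vals))
}

# Random polyline with n vertices inside a box, consecutive vertices
# guaranteed distinct.
rand_polyline <- function(n = sample(2:5, 1), lim = 100) {
  repeat {
    x <- runif(n, 0, lim)
    y <- runif(n, 0, lim)
    if (all(rowSums(abs(diff(cbind(x, y)))) > 1e-6)) {
      return(polyline(x, y))
    }
  }
}
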