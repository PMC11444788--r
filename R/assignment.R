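# Minimum-cost bipartite assignment (the Hungarian problem), solved with the
# O(n^3) shortest-augmenting-path algorithm with dual potentials
# (Jonker-Volgenant style). Written here because the association step needs
# forbidden entries and rectangular matrices; tests verify optimality against
# permutation brute force.

# Solve the square assignment problem for cost matrix a (n x n, finite).
# Returns an integer vector: column assigned to each row.
lsap_square <- function(a) {
  n <- nrow(a)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials; index j + 1, column 0 virtual
  p <- integer(n + 1)    # p[j + 1]: row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign_col[p[j + 1]] <- j
  assign_col
}

#' Minimum-cost assignment with forbidden pairs
#'
#' Solves the rectangular assignment problem: each row is matched to at most
#' one column (and vice versa) so that the total cost of matched pairs is
#' minimal. Entries of `Inf` mark forbidden pairs and are never matched;
#' when rows outnumber columns (or vice versa) the surplus stays unmatched.
#'
#' @param cost Numeric cost matrix; `Inf` forbids a pairing.
#' @return Integer vector of length `nrow(cost)`: the column assigned to
#'   each row, or `NA` for unmatched rows.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) (max(abs(finite)) + 1) * (max(nr, nc) + 1) else 1
  n <- max(nr, nc)
  a <- matrix(big, n, n)  # padding: dummy rows/cols at the forbidden price
  a[seq_len(nr), seq_len(nc)] <- ifelse(is.finite(cost), cost, big)
  res <- lsap_square(a)
  out <- res[seq_len(nr)]
  out[out > nc] <- NA_integer_
  # a row "matched" to a forbidden entry is really unmatched
  for (i in seq_len(nr)) if (!is.na(out[i]) && !is.finite(cost[i, out[i]]))
    out[i] <- NA_integer_
  out
}
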