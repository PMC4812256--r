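# Independent reference implementations used as oracles. These deliberately
# use naive, loop-based formulations so they share no code path with the
# package internals they check.

# --- gromos clustering, brute force -----------------------------------------
# plain double-loop neighbour counting; returns the same fields as
# gromos_cluster() for exact comparison
gromos_oracle <- function(m, cutoff) {
  n <- nrow(m)
  avail <- seq_len(n)
  assignment <- integer(n)
  members <- list()
  cl <- 0L
  while (length(avail) > 0) {
    best <- NA_integer_; best_count <- -1L
    for (i in avail) {
      cnt <- 0L
      for (j in avail) if (j != i && m[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    grp <- best
    for (j in avail) if (j != best && m[best, j] <= cutoff) grp <- c(grp, j)
    grp <- sort(grp)
    cl <- cl + 1L
    members[[cl]] <- grp
    assignment[grp] <- cl
    avail <- setdiff(avail, grp)
  }
  sizes <- vapply(members, length, integer(1))
  ord <- order(-sizes, seq_len(cl))
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  centers <- integer(cl)
  for (k in seq_len(cl)) {
    grp <- members[[ord[k]]]
    best <- grp[1]; best_sum <- Inf
    for (i in grp) {
      s <- 0
      for (j in grp) s <- s + m[i, j]
      if (s < best_sum) { best_sum <- s; best <- i }
    }
    centers[k] <- best
  }
  list(assignment = relabel[assignment], centers = centers,
       populations = sizes[ord] / n)
}

random_rmsd_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# --- minimum RMSD by numerical search over rotations ------------------------
# coarse Euler-angle grid followed by Nelder-Mead refinement; never uses the
# SVD solution
euler_rot <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

grid_rmsd_oracle <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  score <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  step <- 30 * pi / 180
  grid <- seq(0, 2 * pi - step / 2, by = step)
  best <- c(0, 0, 0); best_val <- Inf
  for (a in grid) for (b in grid) for (c in grid) {
    v <- score(c(a, b, c))
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# --- signed dihedral via plane normals --------------------------------------
# cosine from the two plane normals, sign from the triple product
dihedral_oracle <- function(p) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(min(max(cosphi, -1), 1)) * 180 / pi
  s <- sum(cross(n1, n2) * b2)
  if (s > 0) -phi else phi
}
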