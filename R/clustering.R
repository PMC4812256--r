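# RMSD-matrix construction, gromos (neighbor-counting) clustering, medoid
# extraction and decomposition of cluster populations by ligand-state label.

#' Pairwise RMSD matrix of a trajectory
#'
#' Entry (i, j) is the RMSD between frames i and j over `sel`, after
#' least-squares fitting on the same selection when `fit = TRUE` (the
#' convention of the reference clustering tool).
#'
#' @param trj a [trajectory()] or [build_meta()] result.
#' @param sel atom selection (typically C-alpha atoms of a residue subset).
#' @param fit superpose each pair on `sel` before the RMSD (default `TRUE`).
#' @return A symmetric `n x n` matrix (nm) of class `rmsd_matrix`, with the
#'   selection provenance and fit flag as attributes.
#' @export
rmsd_matrix <- function(trj, sel = NULL, fit = TRUE) {
  idx <- resolve_selection(sel, trj$topology)
  n <- n_frames(trj)
  coords <- lapply(seq_len(n), function(f) {
    co <- frame_coords(trj, f)[idx, , drop = FALSE]
    sweep(co, 2, colMeans(co))                   # pre-centred
  })
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Pi <- coords[[i]]
    for (j in (i + 1):n) {
      Qj <- coords[[j]]
      if (fit) {
        sv <- svd(crossprod(Pi, Qj))
        d <- sign(det(sv$u %*% t(sv$v)))
        R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
        m[i, j] <- sqrt(mean(rowSums((Pi %*% R - Qj)^2)))
      } else {
        m[i, j] <- sqrt(mean(rowSums((Pi - Qj)^2)))
      }
      m[j, i] <- m[i, j]
    }
  }
  structure(m, class = c("rmsd_matrix", "matrix"),
            selection = attr(sel, "provenance") %||% "custom indices",
            fit = fit)
}

#' gromos conformational clustering
#'
#' The greedy neighbor-counting algorithm of Daura et al.: count, for every
#' unassigned frame, its unassigned neighbours within `cutoff`; the frame
#' with the most neighbours becomes a cluster centre and is removed together
#' with its neighbours; repeat until all frames are assigned. Ties on the
#' neighbour count are broken by the lowest frame index. Clusters are
#' numbered 1..K by decreasing size.
#'
#' @param matrix an [rmsd_matrix()] (any symmetric distance matrix works).
#' @param cutoff neighbour cutoff in nm (> 0), e.g. 0.35 nm for whole-protein
#'   or linker subsets and 0.15 nm for a compact beta-domain subset.
#' @return An object of class `cluster_result`: `assignment` (frame ->
#'   cluster id), `centers` (medoid frame per cluster, minimising the summed
#'   RMSD to members), `seeds` (the neighbour-richest frame that founded each
#'   cluster), `populations` (fractions, decreasing), `cutoff`.
#' @export
gromos_cluster <- function(matrix, cutoff) {
  stopifnot(cutoff > 0)
  m <- unclass(matrix)
  n <- nrow(m)
  adj <- m <= cutoff
  diag(adj) <- FALSE
  unassigned <- rep(TRUE, n)
  assignment <- integer(n)
  seeds <- integer(0)
  members <- list()
  cl <- 0L
  while (any(unassigned)) {
    cand <- which(unassigned)
    counts <- vapply(cand, function(i) sum(adj[i, cand]), integer(1))
    centre <- cand[which.max(counts)]          # first max = lowest index
    grp <- c(centre, cand[adj[centre, cand]])
    grp <- sort(unique(grp))
    cl <- cl + 1L
    assignment[grp] <- cl
    seeds[cl] <- centre
    members[[cl]] <- grp
    unassigned[grp] <- FALSE
  }
  sizes <- lengths(members)
  ord <- order(-sizes, seq_along(sizes))       # stable: ties keep formation order
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  assignment <- relabel[assignment]
  members <- members[ord]
  seeds <- seeds[ord]
  centers <- vapply(members, function(grp) {
    if (length(grp) == 1) return(grp)
    ssum <- rowSums(m[grp, grp, drop = FALSE])
    grp[which.min(ssum)]                       # medoid; ties -> lowest index
  }, integer(1))
  structure(list(assignment = assignment, centers = centers, seeds = seeds,
                 populations = as.vector(sizes[ord] / n), cutoff = cutoff,
                 n_frames = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("gromos clustering: %d clusters over %d frames (cutoff %.2f nm)\n",
              length(x$populations), x$n_frames, x$cutoff))
  print(data.frame(cluster = seq_along(x$populations),
                   population = round(x$populations, 3),
                   center = x$centers))
  invisible(x)
}

#' Decompose cluster populations by source label
#'
#' For each source label of a meta-trajectory (i.e. each ligand state), the
#' fraction of that label's frames falling in each of the top-k clusters,
#' plus a remainder bucket; each row sums to 1. This connects the common
#' conformations found on the concatenated ensemble back to the specific
#' ligand combinations that populate them.
#'
#' @param result a [gromos_cluster()] result.
#' @param labels per-frame source labels: a character vector or a
#'   [build_meta()] result (its `$source` is used).
#' @param top_k number of leading clusters reported individually (clamped,
#'   with a warning, to the number of clusters found).
#' @return A matrix of class `decomposition_table` (labels x clusters+other).
#' @export
decompose_by_label <- function(result, labels, top_k = 3) {
  if (inherits(labels, "meta_trj")) labels <- labels$source
  if (length(labels) != result$n_frames)
    stop("label count does not cover the clustered frames")
  k <- length(result$populations)
  if (top_k > k) {
    warning(sprintf("top_k = %d exceeds cluster count %d; clamped", top_k, k))
    top_k <- k
  }
  labs <- unique(labels)
  tab <- matrix(0, length(labs), top_k + 1L,
                dimnames = list(labs, c(paste0("cluster", seq_len(top_k)),
                                        "other")))
  for (li in seq_along(labs)) {
    sel <- labels == labs[li]
    a <- result$assignment[sel]
    for (cc in seq_len(top_k)) tab[li, cc] <- mean(a == cc)
    tab[li, top_k + 1L] <- mean(a > top_k)
  }
  structure(tab, class = c("decomposition_table", "matrix"))
}

#' Representative (medoid) frame of a cluster
#'
#' The cluster centre is the member frame minimising the summed RMSD to all
#' other members; it is exported as the cluster's representative
#' conformation.
#'
#' @param result a [gromos_cluster()] result.
#' @param cluster cluster id (1-based, by decreasing size).
#' @param trj the clustered [trajectory()] / [build_meta()] result.
#' @param file optional path; when given the frame is written as PDB.
#' @return A one-frame [trajectory()] (invisibly written to `file` if given).
#' @export
representative <- function(result, cluster, trj, file = NULL) {
  if (cluster < 1 || cluster > length(result$populations))
    stop("no such cluster: ", cluster)
  fr <- result$centers[cluster]
  out <- trajectory(trj$topology, trj$xyz[fr, , drop = FALSE])
  if (!is.null(file)) write_trajectory(out, file)
  out
}
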