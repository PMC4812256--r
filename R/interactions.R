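# Contact detection, hydrogen-bond detection, occupancy/persistence
# filtering, interface mapping and beta-strand content.

# per-frame minimum heavy-atom distance matrix (nm) between two residue sets
min_dist_matrix <- function(trj, frame, res_a, res_b) {
  top <- trj$topology
  co <- frame_coords(trj, frame)
  heavy <- top$element != "H"
  m <- matrix(Inf, length(res_a), length(res_b),
              dimnames = list(res_a, res_b))
  idx_a <- lapply(res_a, function(r) which(top$resno == r & heavy))
  idx_b <- lapply(res_b, function(r) which(top$resno == r & heavy))
  for (i in seq_along(res_a)) {
    ai <- idx_a[[i]]
    if (length(ai) == 0) next
    pa <- co[ai, , drop = FALSE]
    for (j in seq_along(res_b)) {
      bj <- idx_b[[j]]
      if (length(bj) == 0) next
      pb <- co[bj, , drop = FALSE]
      d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
      m[i, j] <- sqrt(max(min(d2), 0))
    }
  }
  m
}

new_interaction_series <- function(kind, pairs, present, cutoff) {
  structure(list(kind = kind, pairs = pairs, present = present,
                 cutoff = cutoff),
            class = "interaction_series")
}

#' @export
print.interaction_series <- function(x, ...) {
  cat(sprintf("%s series: %d pairs x %d frames, %d pairs ever present\n",
              x$kind, nrow(x$pairs), nrow(x$present),
              sum(colSums(x$present) > 0)))
  invisible(x)
}

#' Residue-residue contact series
#'
#' A pair of residues is in contact in a frame iff the minimum distance over
#' their heavy (non-hydrogen) atoms is at or below `cutoff`.
#'
#' @param trj a [trajectory()].
#' @param res_a,res_b disjoint residue-number vectors (e.g. linker residues
#'   versus the rest of the protein).
#' @param cutoff nm (default 0.45, a standard residue-contact convention).
#' @return An `interaction_series`: `pairs` (data.frame `res_a`, `res_b`),
#'   `present` (frames x pairs logical matrix).
#' @export
contact_series <- function(trj, res_a, res_b, cutoff = 0.45) {
  if (length(res_a) == 0 || length(res_b) == 0) stop("empty residue group")
  if (length(intersect(res_a, res_b)) > 0)
    stop("residue groups must be disjoint")
  n <- n_frames(trj)
  pairs <- expand.grid(res_a = res_a, res_b = res_b, KEEP.OUT.ATTRS = FALSE)
  present <- matrix(FALSE, n, nrow(pairs))
  for (f in seq_len(n)) {
    m <- min_dist_matrix(trj, f, res_a, res_b)
    present[f, ] <- as.vector(m <= cutoff)
  }
  new_interaction_series("contact", pairs, present, cutoff)
}

#' Hydrogen-bond series
#'
#' A donor/acceptor residue pair carries a hydrogen bond in a frame iff some
#' donor N atom and acceptor O atom are within `dist_cutoff` and, when
#' hydrogens are present on the donor, the hydrogen-donor-acceptor angle of
#' an attached hydrogen is at most `angle_cutoff`. Without hydrogens the
#' detection falls back to the donor-acceptor distance criterion alone and
#' the result is flagged (`hydrogen_free` attribute).
#'
#' @param trj a [trajectory()].
#' @param donors,acceptors residue-number vectors; donor atoms are the N
#'   atoms of the donor residues, acceptor atoms the O atoms of the
#'   acceptors.
#' @param dist_cutoff donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cutoff H-D-A angle cutoff, degrees (default 30).
#' @return An `interaction_series` with `kind = "hbond"`.
#' @export
hbond_series <- function(trj, donors, acceptors, dist_cutoff = 0.35,
                         angle_cutoff = 30) {
  top <- trj$topology
  d_atoms <- lapply(donors, function(r)
    which(top$resno == r & startsWith(top$elety, "N")))
  a_atoms <- lapply(acceptors, function(r)
    which(top$resno == r & startsWith(top$elety, "O")))
  if (all(lengths(d_atoms) == 0)) stop("no donor N atoms found")
  if (all(lengths(a_atoms) == 0)) stop("no acceptor O atoms found")
  h_all <- which(top$element == "H")
  hydrogen_free <- length(h_all) == 0
  n <- n_frames(trj)
  pairs <- expand.grid(res_a = donors, res_b = acceptors,
                       KEEP.OUT.ATTRS = FALSE)
  present <- matrix(FALSE, n, nrow(pairs))
  for (f in seq_len(n)) {
    co <- frame_coords(trj, f)
    for (p in seq_len(nrow(pairs))) {
      di <- d_atoms[[match(pairs$res_a[p], donors)]]
      ai <- a_atoms[[match(pairs$res_b[p], acceptors)]]
      if (length(di) == 0 || length(ai) == 0) next
      ok <- FALSE
      for (dd in di) {
        if (ok) break
        # hydrogens covalently attached to this donor (within 0.12 nm)
        hh <- if (hydrogen_free) integer(0) else
          h_all[sqrt(rowSums(sweep(co[h_all, , drop = FALSE], 2,
                                   co[dd, ])^2)) <= 0.12]
        for (aa in ai) {
          v_da <- co[aa, ] - co[dd, ]
          dist <- sqrt(sum(v_da^2))
          if (dist > dist_cutoff) next
          if (length(hh) == 0) { ok <- TRUE; break }
          ang <- vapply(hh, function(h) {
            v_dh <- co[h, ] - co[dd, ]
            cosang <- sum(v_dh * v_da) / (sqrt(sum(v_dh^2)) * dist)
            acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          }, numeric(1))
          if (min(ang) <= angle_cutoff) { ok <- TRUE; break }
        }
      }
      present[f, p] <- ok
    }
  }
  out <- new_interaction_series("hbond", pairs, present,
                                c(dist = dist_cutoff, angle = angle_cutoff))
  attr(out, "hydrogen_free") <- hydrogen_free
  out
}

#' Persistence filter: keep interactions above an occupancy threshold
#'
#' Occupancy is the fraction of analysed frames in which a pair is present.
#' Records with occupancy at or above `threshold` (and present in at least
#' one frame) are collected, occupancy reported exactly. The conventional
#' persistence threshold is 0.30 -- an interaction present for at least 30%
#' of the simulation time.
#'
#' @param series an `interaction_series` or a list of them.
#' @param threshold occupancy threshold in `[0, 1]` (default 0.30).
#' @return data.frame with `kind`, `res_a`, `res_b`, `occupancy`, sorted by
#'   decreasing occupancy.
#' @export
persistence_filter <- function(series, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (inherits(series, "interaction_series")) series <- list(series)
  out <- do.call(rbind, lapply(series, function(s) {
    occ <- colMeans(s$present)
    keep <- occ >= threshold & occ > 0
    data.frame(kind = rep(s$kind, sum(keep)), res_a = s$pairs$res_a[keep],
               res_b = s$pairs$res_b[keep], occupancy = occ[keep])
  }))
  out[order(-out$occupancy, out$res_a, out$res_b), , drop = FALSE]
}

#' Interface map from time-averaged minimum distances
#'
#' The per-pair minimum heavy-atom distance is averaged over the trajectory;
#' residues of one group are listed as interface members iff their average
#' distance to some residue of the other group is below `threshold`
#' (average-distance semantics, as returned by an averaged distance matrix
#' tool; `mode = "fraction"` instead reports the fraction of frames below
#' the threshold, for sensitivity checks).
#'
#' @param trj a [trajectory()].
#' @param group_a,group_b residue-number vectors (e.g. NBD and SBD residues).
#' @param threshold Angstrom (default 6).
#' @param mode `"average"` or `"fraction"`.
#' @return An object of class `interface_map`: `matrix` (group_a x group_b;
#'   Angstrom averages or frame fractions), `residues_a`, `residues_b` (the
#'   interface members of each side), `threshold`, `mode`.
#' @export
interface_map <- function(trj, group_a, group_b, threshold = 6,
                          mode = c("average", "fraction")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty residue group")
  n <- n_frames(trj)
  acc <- matrix(0, length(group_a), length(group_b),
                dimnames = list(group_a, group_b))
  for (f in seq_len(n)) {
    m <- min_dist_matrix(trj, f, group_a, group_b) * 10   # nm -> Angstrom
    acc <- acc + if (mode == "average") m else (m < threshold)
  }
  acc <- acc / n
  inside <- if (mode == "average") acc < threshold else acc >= 0.5
  structure(list(matrix = acc,
                 residues_a = group_a[rowSums(inside) > 0],
                 residues_b = group_b[colSums(inside) > 0],
                 threshold = threshold, mode = mode),
            class = "interface_map")
}

#' @export
print.interface_map <- function(x, ...) {
  cat(sprintf("interface map (%s < %g A): %d x %d residues in contact\n",
              x$mode, x$threshold, length(x$residues_a), length(x$residues_b)))
  invisible(x)
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); out <- matrix(FALSE, n, n)
  rs <- seq_len(n) + dr; cs <- seq_len(n) + dc
  okr <- rs >= 1 & rs <= n; okc <- cs >= 1 & cs <= n
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Beta-strand content of a residue range
#'
#' Per-frame strand assignment by a minimal backbone hydrogen-bond ladder
#' criterion: residues p and q (sequence separation >= `min_sep`) are
#' bridged in a frame iff an N(p)-O(q) or N(q)-O(p) distance is at or below
#' `cutoff`; a residue is assigned strand iff it sits on two consecutive
#' rungs of such a ladder, in parallel or antiparallel register. This is a
#' reduced DSSP-like criterion sufficient for strand fractions; it assumes
#' contiguous residue numbering. Content is the fraction of (residue, frame)
#' pairs assigned strand.
#'
#' @param trj a [trajectory()] with backbone N and O atoms in `range`.
#' @param range residue interval `c(first, last)` assessed (e.g. the linker).
#' @param cutoff N-O hydrogen-bond distance cutoff, nm (default 0.35).
#' @param min_sep minimum sequence separation of bridge partners (default 5,
#'   which excludes helical i,i+4 hydrogen bonds).
#' @return An object of class `strand_content`: `per_frame` (frames x range
#'   residues logical matrix), `content` scalar in `[0, 1]`.
#' @export
strand_content <- function(trj, range, cutoff = 0.35, min_sep = 5) {
  top <- trj$topology
  allres <- sort(unique(top$resno))
  n_idx <- vapply(allres, function(r) {
    i <- which(top$resno == r & top$elety == "N")
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  o_idx <- vapply(allres, function(r) {
    i <- which(top$resno == r & top$elety == "O")
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  in_range <- allres >= range[1] & allres <= range[2]
  if (any(is.na(n_idx[in_range])) || any(is.na(o_idx[in_range])))
    stop("backbone N/O atoms missing in the assessed range")
  R <- length(allres)
  sep_ok <- abs(outer(allres, allres, "-")) >= min_sep
  n <- n_frames(trj)
  flags <- matrix(FALSE, n, sum(in_range),
                  dimnames = list(NULL, allres[in_range]))
  for (f in seq_len(n)) {
    co <- frame_coords(trj, f)
    N <- co[ifelse(is.na(n_idx), 1L, n_idx), , drop = FALSE]
    O <- co[ifelse(is.na(o_idx), 1L, o_idx), , drop = FALSE]
    d2 <- outer(rowSums(N^2), rowSums(O^2), "+") - 2 * N %*% t(O)
    hb <- d2 <= cutoff^2
    hb[is.na(n_idx), ] <- FALSE
    hb[, is.na(o_idx)] <- FALSE
    bridged <- (hb | t(hb)) & sep_ok
    ladder <- bridged & (shift_mat(bridged, 1, -1) | shift_mat(bridged, -1, 1) |
                         shift_mat(bridged, 1, 1) | shift_mat(bridged, -1, -1))
    flags[f, ] <- rowSums(ladder[in_range, , drop = FALSE]) > 0
  }
  structure(list(range = range, per_frame = flags, content = mean(flags)),
            class = "strand_content")
}

#' @export
print.strand_content <- function(x, ...) {
  cat(sprintf("strand content of residues %d-%d: %.1f%% over %d frames\n",
              x$range[1], x$range[2], 100 * x$content, nrow(x$per_frame)))
  invisible(x)
}
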