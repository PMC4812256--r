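# Superposition, RMSD, centre-of-mass cloud statistics, residue-pair
# distance series and dihedral statistics.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the least-squares
#' deviation between two matched point sets (SVD solution, determinant +1
#' enforced). The transform maps mobile coordinates onto the reference:
#' `y = (x - centre_mobile) %*% rotation + centre_reference` for row vectors.
#'
#' @param mobile,reference numeric matrices (n x 3, nm) with n >= 3 matched,
#'   non-collinear points.
#' @return list with `rotation` (3 x 3, applied on the right to row vectors),
#'   `centre_mobile`, `centre_reference`, `rmsd` (nm) and `transform`, a
#'   function applying the fit to any m x 3 coordinate matrix.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("'mobile' and 'reference' must be matched n x 3 matrices")
  if (nrow(mobile) < 3) stop("at least 3 points required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  # degenerate (collinear or coincident) sets leave the rotation undetermined
  if (qr(P)$rank < 2 || qr(Q)$rank < 2)
    stop("degenerate point set: all points collinear or coincident")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  transform <- function(x) sweep(sweep(as.matrix(x), 2, cm) %*% R, 2, cr, "+")
  list(rotation = R, centre_mobile = cm, centre_reference = cr,
       rmsd = rmsd, transform = transform)
}

#' Centre of mass of a selection
#'
#' @param coords n x 3 coordinate matrix (nm) or a [trajectory()] (first
#'   frame used).
#' @param topology a [topology()] supplying masses (required for
#'   `weighting = "mass"` when `coords` is a bare matrix).
#' @param sel atom selection; `NULL` for all atoms.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return length-3 numeric vector (nm).
#' @export
com <- function(coords, topology = NULL, sel = NULL,
                weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (inherits(coords, "trj")) {
    topology <- coords$topology
    coords <- frame_coords(coords, 1)
  }
  idx <- if (is.null(topology)) {
    if (is.null(sel)) seq_len(nrow(coords)) else as.integer(sel)
  } else resolve_selection(sel, topology)
  x <- coords[idx, , drop = FALSE]
  if (nrow(x) == 0) stop("empty selection")
  w <- if (weighting == "mass") {
    if (is.null(topology)) stop("mass weighting requires a topology")
    topology$mass[idx]
  } else rep(1, nrow(x))
  if (sum(w) <= 0) stop("zero total mass in selection")
  colSums(x * w) / sum(w)
}

#' Centre-of-mass cloud of a mobile domain after fitting on an anchor domain
#'
#' Every retained frame of every run is superposed (Kabsch, on `fit_sel`)
#' onto the reference structure, then the centre of mass of `com_sel` is
#' recorded. This yields the spatial distribution of mobile-domain positions
#' in the anchor frame of reference -- the interdomain-arrangement statistic.
#' Runs are merged and per-point source labels preserved.
#'
#' @param runs list of [trajectory()] objects (or a single one).
#' @param fit_sel atom selection used for superposition (e.g. anchor-domain
#'   C-alpha atoms, DnaK residues 1-380).
#' @param com_sel atom selection whose centre of mass is tracked (e.g. all
#'   atoms of the mobile domain, DnaK residues 393-603).
#' @param reference one-frame [trajectory()] (or n x 3 matrix) to fit onto;
#'   its `com_sel` centre of mass is the reference point.
#' @param tail_ns optional tail window (ns) retained per run; `NULL` keeps
#'   all frames.
#' @param weighting COM weighting, `"mass"` or `"geometric"`.
#' @return An object of class `com_cloud`: `points` (n x 3, nm), `reference`
#'   (length 3, nm), `label` (character per point), `fit_rmsd` (nm per point).
#' @export
com_cloud <- function(runs, fit_sel, com_sel, reference, tail_ns = NULL,
                      weighting = "mass") {
  if (inherits(runs, "trj")) runs <- list(runs)
  if (!is.null(tail_ns)) {
    meta <- build_meta(runs, tail_ns)
    runs <- lapply(seq_len(nrow(meta$segments)), function(k) {
      s <- meta$segments[k, ]
      trj <- trajectory(meta$topology,
                        meta$xyz[s$start:s$end, , drop = FALSE])
      trj$label_str <- s$label
      trj
    })
  }
  top <- if (inherits(reference, "trj")) reference$topology else runs[[1]]$topology
  ref_xyz <- if (inherits(reference, "trj")) frame_coords(reference, 1)
             else as.matrix(reference)
  fit_idx <- resolve_selection(fit_sel, top)
  ref_point <- com(ref_xyz, top, com_sel, weighting)
  pts <- list(); labs <- character(); frmsd <- numeric()
  for (run in runs) {
    if (n_frames(run) == 0) stop("empty retained window in a run")
    lab <- run$label_str %||% format_label(run$label)
    for (f in seq_len(n_frames(run))) {
      co <- frame_coords(run, f)
      fit <- kabsch_fit(co[fit_idx, , drop = FALSE],
                        ref_xyz[fit_idx, , drop = FALSE])
      pts[[length(pts) + 1L]] <- com(fit$transform(co), top, com_sel, weighting)
      labs <- c(labs, lab)
      frmsd <- c(frmsd, fit$rmsd)
    }
  }
  structure(list(points = do.call(rbind, pts), reference = ref_point,
                 label = labs, fit_rmsd = frmsd),
            class = "com_cloud")
}

#' @export
print.com_cloud <- function(x, ...) {
  cat(sprintf("COM cloud: %d points, mean distance from start %.1f A\n",
              nrow(x$points),
              mean(sqrt(rowSums(sweep(x$points, 2, x$reference)^2))) * 10))
  invisible(x)
}

# histogram on bins centred at integer multiples of `width`, so a point mass
# at an integer distance reports that integer as the peak
make_distribution <- function(d, width) {
  hi <- max(d, 0)
  breaks <- seq(-width / 2, hi + width, by = width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  peak <- h$mids[which.max(h$counts)]   # ties resolve to the smaller distance
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 mean = mean(d), peak = peak, n = length(d)),
            class = "dist_distribution")
}

#' @export
print.dist_distribution <- function(x, ...) {
  cat(sprintf("distance distribution: n = %d, mean %.2f A, peak %.1f A\n",
              x$n, x$mean, x$peak))
  invisible(x)
}

#' Distribution of distances from the starting position
#'
#' Distances (in Angstrom) of every cloud point from the reference point,
#' histogrammed. The mean of this distribution measures the dynamic
#' flexibility of the interdomain arrangement.
#'
#' @param cloud a [com_cloud()].
#' @param width bin width in Angstrom (default 1).
#' @return A `dist_distribution`: breaks/counts/mids (Angstrom), `mean`,
#'   `peak` (centre of the modal bin, ties toward the smaller distance).
#' @export
distance_from_start <- function(cloud, width = 1) {
  stopifnot(inherits(cloud, "com_cloud"), nrow(cloud$points) >= 1)
  d <- sqrt(rowSums(sweep(cloud$points, 2, cloud$reference)^2)) * 10
  make_distribution(d, width)
}

#' Pair distance distribution of a point cloud
#'
#' All unordered point-pair distances (Angstrom), histogrammed; the peak is
#' the modal bin centre. For clouds above `max_points` points a seeded
#' uniform subsample is taken first, since exhaustive pairs are O(N^2).
#'
#' @param cloud a [com_cloud()] or an n x 3 point matrix (nm).
#' @param width bin width in Angstrom.
#' @param max_points subsampling threshold (default 5e4).
#' @param seed RNG seed for the subsample.
#' @return A `dist_distribution`.
#' @export
pair_distance_distribution <- function(cloud, width = 1, max_points = 5e4,
                                       seed = 1L) {
  pts <- if (inherits(cloud, "com_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 2) stop("at least 2 points required")
  if (nrow(pts) > max_points)
    pts <- pts[with_seed(seed, sort(sample.int(nrow(pts), max_points))), ]
  d <- as.vector(stats::dist(pts)) * 10
  make_distribution(d, width)
}

#' Per-frame distance between two residues
#'
#' @param trj a [trajectory()].
#' @param res_i,res_j residue numbers.
#' @param rule `"CA"` (C-alpha to C-alpha) or `"closest-heavy"` (minimum
#'   distance over non-hydrogen atoms).
#' @return list with `distance` (Angstrom per frame) and `mean`.
#' @export
residue_pair_distance_series <- function(trj, res_i, res_j,
                                         rule = c("CA", "closest-heavy")) {
  rule <- match.arg(rule)
  top <- trj$topology
  pick <- function(r) {
    if (rule == "CA") which(top$resno == r & top$elety == "CA")
    else which(top$resno == r & top$element != "H")
  }
  ai <- pick(res_i); aj <- pick(res_j)
  if (length(ai) == 0 || length(aj) == 0)
    stop(sprintf("no atoms for rule '%s' on residues %d/%d", rule, res_i, res_j))
  d <- vapply(seq_len(n_frames(trj)), function(f) {
    co <- frame_coords(trj, f)
    d2 <- outer(rowSums(co[ai, , drop = FALSE]^2),
                rowSums(co[aj, , drop = FALSE]^2), "+") -
      2 * co[ai, , drop = FALSE] %*% t(co[aj, , drop = FALSE])
    sqrt(max(min(d2), 0))
  }, numeric(1))
  d <- d * 10
  list(distance = d, mean = mean(d))
}

# signed dihedral (IUPAC convention) for one frame, atoms as rows of a 4 x 3
# matrix; degrees in (-180, 180]
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Circular mean of angles in degrees
#'
#' Mean direction of the resultant vector, in `(-180, 180]`; e.g. the
#' circular mean of +170 and -170 degrees is 180, not 0.
#' @param angles numeric vector, degrees; `NA`s dropped.
#' @return degrees.
#' @export
circular_mean <- function(angles) {
  a <- angles[!is.na(angles)] * pi / 180
  if (length(a) == 0) return(NA_real_)
  m <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  if (m <= -180) m + 360 else m
}

#' Circular variance of angles in degrees
#'
#' `1 - R` where `R` is the mean resultant length (0 = fully concentrated,
#' 1 = uniform).
#' @param angles numeric vector, degrees; `NA`s dropped.
#' @return numeric in `[0, 1]`.
#' @export
circular_variance <- function(angles) {
  a <- angles[!is.na(angles)] * pi / 180
  if (length(a) == 0) return(NA_real_)
  1 - sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' Dihedral angle series over a trajectory
#'
#' Signed dihedral (IUPAC convention) defined by four atoms, per frame, with
#' circular summary statistics. Hinge dihedrals such as the psi angle at the
#' helix-to-linker junction or the phi angle at the linker-to-domain junction
#' report on the local conformational state of the interdomain linker.
#'
#' @param trj a [trajectory()].
#' @param atoms four distinct atom indices.
#' @return An object of class `dihedral_series`: `angles` (degrees per frame,
#'   `NA` with a warning when three atoms are collinear in a frame),
#'   `circular_mean`, `circular_variance`.
#' @export
dihedral_series <- function(trj, atoms) {
  atoms <- as.integer(atoms)
  if (length(atoms) != 4 || anyDuplicated(atoms))
    stop("four distinct atom indices required")
  ang <- vapply(seq_len(n_frames(trj)), function(f) {
    dihedral_angle(frame_coords(trj, f)[atoms, , drop = FALSE])
  }, numeric(1))
  if (anyNA(ang)) warning("collinear atom triple in ", sum(is.na(ang)), " frame(s)")
  structure(list(angles = ang, circular_mean = circular_mean(ang),
                 circular_variance = circular_variance(ang)),
            class = "dihedral_series")
}

#' RMSD series against a reference or between two trajectories
#'
#' Per-frame RMSD over `sel` after least-squares fitting on `fit_sel`. With a
#' one-frame reference the series compares every frame to it; with a second
#' trajectory of matched length the comparison is frame-by-frame (replica
#' divergence).
#'
#' @param trj a [trajectory()].
#' @param reference a one-frame [trajectory()] / n x 3 matrix, or a second
#'   trajectory of the same length for pairwise mode.
#' @param sel selection the RMSD is computed over.
#' @param fit_sel selection used for fitting (defaults to `sel`).
#' @return numeric vector of per-frame RMSD (nm).
#' @export
rmsd_series <- function(trj, reference, sel = NULL, fit_sel = NULL) {
  if (is.null(fit_sel)) fit_sel <- sel
  idx <- resolve_selection(sel, trj$topology)
  fidx <- resolve_selection(fit_sel, trj$topology)
  pairwise <- inherits(reference, "trj") && n_frames(reference) > 1
  if (pairwise && n_frames(reference) != n_frames(trj))
    stop(sprintf("pairwise mode needs matched lengths (%d vs %d)",
                 n_frames(trj), n_frames(reference)))
  ref1 <- if (inherits(reference, "trj")) frame_coords(reference, 1)
          else as.matrix(reference)
  vapply(seq_len(n_frames(trj)), function(f) {
    co <- frame_coords(trj, f)
    rf <- if (pairwise) frame_coords(reference, f) else ref1
    fit <- kabsch_fit(co[fidx, , drop = FALSE], rf[fidx, , drop = FALSE])
    moved <- fit$transform(co[idx, , drop = FALSE])
    sqrt(mean(rowSums((moved - rf[idx, , drop = FALSE])^2)))
  }, numeric(1))
}
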