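# Distance-fluctuation (coordination) maps.

#' Distance-fluctuation map
#'
#' For every pair of selected residues i, j the temporal fluctuation of the
#' C-alpha pair distance `d_ij` is accumulated over the trajectory:
#' `A_ij = <d_ij^2> - <d_ij>^2` (the variance of the pair distance; the
#' standard deviation is available via `exponent = "sd"`). Low values mark
#' residue pairs whose distance barely fluctuates -- internally coordinated,
#' locally rigid blocks; matrix regions of low values identify sub-domains
#' that move together. Accumulation is streaming, so memory is O(selection^2)
#' and independent of the frame count.
#'
#' @param trj a [trajectory()] with >= 2 frames.
#' @param residues residue interval `c(first, last)`; `NULL` for all residues.
#' @param exponent `"variance"` (default) or `"sd"`.
#' @return A symmetric residue x residue matrix (nm^2, or nm for `"sd"`) of
#'   class `df_map`, dimnames = residue numbers.
#' @export
distance_fluctuation_map <- function(trj, residues = NULL,
                                     exponent = c("variance", "sd")) {
  exponent <- match.arg(exponent)
  if (n_frames(trj) < 2) stop("at least 2 frames required")
  top <- trj$topology
  if (is.null(residues)) residues <- residue_span(top)
  want <- residues[1]:residues[2]
  ca <- vapply(want, function(r) {
    i <- which(top$resno == r & top$elety == "CA")
    if (length(i) != 1) NA_integer_ else i
  }, integer(1))
  if (anyNA(ca))
    stop("missing CA for residues: ", paste(want[is.na(ca)], collapse = ", "))
  nr <- length(want)
  s1 <- matrix(0, nr, nr); s2 <- matrix(0, nr, nr)
  n <- n_frames(trj)
  # accumulate relative to the first frame's distances: the variance is
  # shift-invariant and this avoids catastrophic cancellation when the
  # fluctuations are tiny compared to the distances themselves
  d0 <- as.matrix(stats::dist(frame_coords(trj, 1)[ca, , drop = FALSE]))
  for (f in seq_len(n)) {
    d <- as.matrix(stats::dist(frame_coords(trj, f)[ca, , drop = FALSE])) - d0
    s1 <- s1 + d
    s2 <- s2 + d * d
  }
  A <- s2 / n - (s1 / n)^2
  A[A < 0] <- 0                      # guard against rounding
  diag(A) <- 0
  if (exponent == "sd") A <- sqrt(A)
  dimnames(A) <- list(want, want)
  structure(A, class = c("df_map", "matrix"),
            residues = want, exponent = exponent)
}

#' Difference of two distance-fluctuation maps
#'
#' Elementwise `a - b` over identical residue selections. Negative entries
#' mark pairs whose coordination increased (fluctuation decreased) in `a`
#' relative to `b` -- e.g. a ligand-induced rigidification of a loop.
#'
#' @param a,b [distance_fluctuation_map()] results on the same residues.
#' @return signed residue x residue matrix.
#' @export
df_difference <- function(a, b) {
  if (!identical(attr(a, "residues"), attr(b, "residues")))
    stop("maps computed over different residue selections")
  if (!identical(attr(a, "exponent"), attr(b, "exponent")))
    stop("maps computed with different exponents")
  unclass(a) - unclass(b)
}

#' Inter-block coordination score
#'
#' Mean distance-fluctuation over the rectangle of pairs with one residue in
#' each block; lower values mean the two blocks move as one rigid body (e.g.
#' increased coordination between the two lobes of the nucleotide-binding
#' domain upon linker docking).
#'
#' @param map a [distance_fluctuation_map()].
#' @param block_a,block_b residue intervals `c(first, last)` within the map.
#' @return scalar (nm^2, or nm for an `"sd"` map).
#' @export
coordination_score <- function(map, block_a, block_b) {
  res <- attr(map, "residues")
  ia <- which(res >= block_a[1] & res <= block_a[2])
  ib <- which(res >= block_b[1] & res <= block_b[2])
  if (length(ia) == 0 || length(ib) == 0)
    stop("empty block within the map's residue selection")
  mean(unclass(map)[ia, ib, drop = FALSE])
}
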