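#' Concatenate the equilibrated tails of several runs into a meta-trajectory
#'
#' Clustering a single concatenation of all runs, regardless of their ligand
#' state, lets cluster populations be decomposed afterwards by source label.
#' Each segment of the meta-trajectory is the final `tail_ns` of one run;
#' per-frame source labels are preserved.
#'
#' A frame belongs to the tail when its time exceeds `t_max - tail_ns * 1000`
#' ps, so a tail equal to the full run duration (last time minus first time
#' plus one frame interval) keeps every frame.
#'
#' @param trajectories list of [trajectory()] objects sharing one atom count.
#' @param tail_ns tail window length in ns; must not exceed any run duration.
#' @return An object of class `meta_trj` (also a `trj`): the concatenated
#'   frames, a per-frame `source` label vector, and a `segments` table.
#' @export
build_meta <- function(trajectories, tail_ns) {
  stopifnot(length(trajectories) >= 1)
  nat <- vapply(trajectories, function(t) n_atoms(t$topology), integer(1))
  if (length(unique(nat)) != 1)
    stop("trajectories differ in atom count: ",
         paste(unique(nat), collapse = ", "))
  tail_ps <- tail_ns * 1000
  pieces <- list()
  src <- character()
  seg <- data.frame(system = character(), replica = integer(),
                    label = character(), start = integer(), end = integer())
  pos <- 0L
  for (k in seq_along(trajectories)) {
    trj <- trajectories[[k]]
    tm <- trj$time
    dt <- if (length(tm) > 1) stats::median(diff(tm)) else 1
    duration <- max(tm) - min(tm) + dt
    if (tail_ps > duration + 1e-9)
      stop(sprintf("tail %g ns exceeds duration %g ns of run %d (%s)",
                   tail_ns, duration / 1000, k, format_label(trj$label)))
    keep <- which(tm > max(tm) - tail_ps)
    pieces[[k]] <- trj$xyz[keep, , drop = FALSE]
    lab <- format_label(trj$label)
    src <- c(src, rep(lab, length(keep)))
    seg <- rbind(seg, data.frame(
      system = if (is.null(trj$label)) NA_character_ else trj$label$system,
      replica = if (is.null(trj$label)) NA_integer_ else trj$label$replica,
      label = lab, start = pos + 1L, end = pos + length(keep)))
    pos <- pos + length(keep)
  }
  xyz <- do.call(rbind, pieces)
  out <- trajectory(trajectories[[1]]$topology, xyz,
                    time = seq_len(nrow(xyz)) - 1)
  out$source <- src
  out$segments <- seg
  class(out) <- c("meta_trj", "trj")
  out
}

#' @export
print.meta_trj <- function(x, ...) {
  cat(sprintf("meta-trajectory: %d frames from %d segments\n",
              n_frames(x), nrow(x$segments)))
  print(x$segments)
  invisible(x)
}
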