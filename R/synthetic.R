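# Synthetic two-domain hinge trajectories with exact ground truth.
#
# The generator emulates the architecture of an Hsp70-like chaperone: two
# compact lobes forming the anchor (NBD-like) domain, a flexible linker, and
# an appended (SBD-like) domain whose placement relative to the anchor is
# drawn per frame from a programmable state mixture. Every generator is a
# pure function of (parameters, seed) and emits its ground truth (state per
# frame, planted frames) alongside the trajectory.

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a toy two-domain architecture
#'
#' Residue counts of the four consecutive segments of the chain: two lobes
#' (together playing the role of the nucleotide-binding domain), a flexible
#' linker, and an appended domain (the substrate-binding domain). Residues
#' are numbered contiguously from 1.
#'
#' @param lobe_a,lobe_b,linker,appended residue counts (all >= 1).
#' @param spacing ideal consecutive C-alpha spacing in nm (default 0.38).
#' @return A list of class `toy_architecture` with the counts and the derived
#'   residue ranges of each segment.
#' @export
toy_architecture <- function(lobe_a = 50, lobe_b = 50, linker = 14,
                             appended = 100, spacing = 0.38) {
  stopifnot(lobe_a >= 1, lobe_b >= 1, linker >= 1, appended >= 1, spacing > 0)
  a <- lobe_a; b <- lobe_b; l <- linker; p <- appended
  structure(list(
    lobe_a = a, lobe_b = b, linker = l, appended = p, spacing = spacing,
    ranges = list(
      lobe_a   = c(1L, a),
      lobe_b   = c(a + 1L, a + b),
      linker   = c(a + b + 1L, a + b + l),
      appended = c(a + b + l + 1L, a + b + l + p)),
    n_residues = a + b + l + p),
    class = "toy_architecture")
}

# boustrophedon walk through an m^3 grid: consecutive points are always one
# grid step apart, giving a compact globule with exact chain spacing
serpentine <- function(n, spacing, origin) {
  m <- max(2L, ceiling(n^(1 / 3)))
  m2 <- m * m
  k <- seq_len(n) - 1L
  iz <- k %/% m2
  rem <- k %% m2
  rem <- ifelse(iz %% 2L == 1L, m2 - 1L - rem, rem)
  iy <- rem %/% m
  rx <- rem %% m
  ix <- ifelse(iy %% 2L == 1L, m - 1L - rx, rx)
  cbind(origin[1] + spacing * ix,
        origin[2] + spacing * iy,
        origin[3] + spacing * iz)
}

#' Build the reference structure of a toy two-domain protein
#'
#' Domains are placed as compact globules (deterministic boustrophedon walk
#' on a grid with the ideal C-alpha spacing), the linker as an extended
#' stretch, so that every pair of consecutive C-alpha atoms is exactly
#' `spacing` apart. With `backbone = TRUE` each residue additionally carries
#' N, C and O atoms (needed for hydrogen-bond and strand analyses).
#'
#' @param arch a [toy_architecture()].
#' @param backbone logical; add backbone N, C, O atoms per residue.
#' @return A one-frame [trajectory()] carrying the architecture in `$arch`.
#' @export
make_toy_structure <- function(arch, backbone = FALSE) {
  stopifnot(inherits(arch, "toy_architecture"))
  s <- arch$spacing
  ca <- matrix(0, arch$n_residues, 3)
  r <- arch$ranges
  blockA <- serpentine(arch$lobe_a, s, c(0, 0, 0))
  ca[r$lobe_a[1]:r$lobe_a[2], ] <- blockA
  endA <- blockA[nrow(blockA), ]
  blockB <- serpentine(arch$lobe_b, s, endA + c(s, 0, 0))
  ca[r$lobe_b[1]:r$lobe_b[2], ] <- blockB
  endB <- blockB[nrow(blockB), ]
  link <- cbind(endB[1] + s * seq_len(arch$linker), endB[2], endB[3])
  ca[r$linker[1]:r$linker[2], ] <- link
  endL <- link[nrow(link), ]
  blockP <- serpentine(arch$appended, s, endL + c(s, 0, 0))
  ca[r$appended[1]:r$appended[2], ] <- blockP

  if (backbone) {
    per <- c("N", "CA", "C", "O")
    nres <- arch$n_residues
    elety <- rep(per, nres)
    resno <- rep(seq_len(nres), each = 4L)
    off <- rbind(c(-0.12, 0.08, 0),   # N
                 c(0, 0, 0),          # CA
                 c(0.12, 0.08, 0),    # C
                 c(0.12, 0.20, 0))    # O
    coords <- ca[resno, ] + off[rep(1:4, nres), ]
  } else {
    elety <- rep("CA", arch$n_residues)
    resno <- seq_len(arch$n_residues)
    coords <- ca
  }
  top <- topology(elety = elety, resno = resno, resid = "ALA")
  trj <- trajectory(top, as.vector(t(coords)))
  trj$arch <- arch
  trj
}

#' Define a mixture of interdomain placement states
#'
#' Each state is a rigid placement of the appended domain (rotation about its
#' centroid plus a translation, both relative to the reference structure)
#' with a mixture weight. Per-frame states are drawn i.i.d. by default; a
#' two-state Markov chain with a stated switch probability is available to
#' probe robustness to time correlation.
#'
#' @param placements list of placements; each a list with `translation`
#'   (length-3, nm; default zero), `angle` (degrees; default 0) and `axis`
#'   (length-3; default z).
#' @param weights non-negative weights summing to 1.
#' @param model `"iid"` or `"markov"`.
#' @param switch_prob per-frame switch probability for the Markov model.
#' @return A list of class `state_mixture`.
#' @export
state_mixture <- function(placements, weights = NULL, model = c("iid", "markov"),
                          switch_prob = 0.1) {
  model <- match.arg(model)
  k <- length(placements)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stop("one weight per placement required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be >= 0 and sum to 1")
  placements <- lapply(placements, function(p) {
    list(translation = p$translation %||% c(0, 0, 0),
         angle = p$angle %||% 0,
         axis = p$axis %||% c(0, 0, 1))
  })
  structure(list(placements = placements, weights = weights,
                 model = model, switch_prob = switch_prob),
            class = "state_mixture")
}

#' Define the noise model of the synthetic generator
#'
#' Isotropic Gaussian displacement added independently to every atom in
#' every frame: `sigma_domain` (nm) for atoms inside the lobes and the
#' appended domain (low values emulate high internal coordination, i.e.
#' local rigidity), `sigma_linker` (nm) for linker residues.
#'
#' @param sigma_domain nm; scalar, or named vector with entries among
#'   `lobe_a`, `lobe_b`, `appended`.
#' @param sigma_linker nm.
#' @param seed integer RNG seed; the same seed gives bit-identical output.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma_domain = 0.02, sigma_linker = 0.05, seed = 1L) {
  if (any(sigma_domain < 0) || sigma_linker < 0) stop("sigma must be >= 0")
  structure(list(sigma_domain = sigma_domain, sigma_linker = sigma_linker,
                 seed = as.integer(seed)),
            class = "noise_model")
}

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Simulate a two-domain hinge trajectory
#'
#' Per frame: draw a state from the mixture, apply its rigid placement to the
#' appended domain, add Gaussian noise per atom. The per-frame state sequence
#' is returned as ground truth.
#'
#' @param structure reference structure from [make_toy_structure()].
#' @param mixture a [state_mixture()].
#' @param noise a [noise_model()].
#' @param n_frames number of frames (>= 1).
#' @param dt frame spacing in ps (default 100).
#' @param label optional [provenance_label()].
#' @return list with `trajectory` (a [trajectory()]) and `states` (integer
#'   state index per frame).
#' @export
simulate_hinge_trajectory <- function(structure, mixture, noise, n_frames,
                                      dt = 100, label = NULL) {
  stopifnot(inherits(structure, "trj"), !is.null(structure$arch),
            inherits(mixture, "state_mixture"), inherits(noise, "noise_model"),
            n_frames >= 1)
  arch <- structure$arch
  top <- structure$topology
  ref <- frame_coords(structure, 1)
  app_idx <- which(top$resno >= arch$ranges$appended[1] &
                   top$resno <= arch$ranges$appended[2])
  centre <- colMeans(ref[app_idx, , drop = FALSE])
  # per-atom noise sd
  sd_of <- function(domain) {
    s <- noise$sigma_domain
    if (length(s) > 1 && !is.null(names(s)) && domain %in% names(s)) s[[domain]]
    else s[[1]]
  }
  sigma <- numeric(nrow(top))
  for (d in c("lobe_a", "lobe_b", "appended")) {
    rg <- arch$ranges[[d]]
    sigma[top$resno >= rg[1] & top$resno <= rg[2]] <- sd_of(d)
  }
  rg <- arch$ranges$linker
  sigma[top$resno >= rg[1] & top$resno <= rg[2]] <- noise$sigma_linker

  k <- length(mixture$placements)
  placed <- lapply(mixture$placements, function(p) {
    R <- rotation_matrix(p$axis, p$angle)
    out <- ref
    moved <- sweep(ref[app_idx, , drop = FALSE], 2, centre) %*% t(R)
    out[app_idx, ] <- sweep(moved, 2, centre + p$translation, "+")
    out
  })

  with_seed(noise$seed, {
    if (mixture$model == "iid" || k == 1) {
      states <- sample.int(k, n_frames, replace = TRUE, prob = mixture$weights)
    } else {
      states <- integer(n_frames)
      states[1] <- sample.int(k, 1, prob = mixture$weights)
      for (f in 2:n_frames) {
        states[f] <- if (stats::runif(1) < mixture$switch_prob)
          sample(setdiff(seq_len(k), states[f - 1]), 1) else states[f - 1]
      }
    }
    xyz <- matrix(0, n_frames, 3 * nrow(top))
    for (f in seq_len(n_frames)) {
      co <- placed[[states[f]]]
      if (any(sigma > 0))
        co <- co + matrix(stats::rnorm(length(co), sd = rep(sigma, 3)),
                          ncol = 3)
      xyz[f, ] <- as.vector(t(co))
    }
    out <- trajectory(top, xyz, dt = dt, label = label)
    out$arch <- arch
    list(trajectory = out, states = states)
  })
}

#' Plant a hydrogen bond / contact with a programmable occupancy
#'
#' In a seeded uniformly random subset of `ceiling(f * n)` frames the
#' acceptor residue is rigidly moved so that its backbone O sits 0.28 nm from
#' the donor residue's backbone N (satisfying both the H-bond and the contact
#' criterion); in all other frames it is moved 1.2 nm away, violating the
#' distance criteria by a wide margin.
#'
#' @param trajectory a [trajectory()] whose topology carries backbone atoms.
#' @param donor,acceptor residue numbers.
#' @param occupancy target occupancy fraction in `[0, 1]`.
#' @param seed RNG seed for the frame subset.
#' @return list with `trajectory` and `planted_frames` (sorted indices).
#' @export
plant_interaction <- function(trajectory, donor, acceptor, occupancy, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  top <- trajectory$topology
  span <- residue_span(top)
  if (donor < span[1] || donor > span[2] || acceptor < span[1] ||
      acceptor > span[2])
    stop("donor/acceptor residue outside topology span")
  dN <- which(top$resno == donor & top$elety == "N")
  aO <- which(top$resno == acceptor & top$elety == "O")
  if (length(dN) != 1 || length(aO) != 1)
    stop("donor N / acceptor O backbone atoms required (build with backbone = TRUE)")
  acc_idx <- which(top$resno == acceptor)
  n <- n_frames(trajectory)
  kf <- ceiling(occupancy * n)
  planted <- if (kf > 0) with_seed(seed, sort(sample.int(n, kf))) else integer(0)
  for (f in seq_len(n)) {
    co <- frame_coords(trajectory, f)
    target <- co[dN, ] + if (f %in% planted) c(0.28, 0, 0) else c(1.2, 0, 0)
    shift <- target - co[aO, ]
    co[acc_idx, ] <- sweep(co[acc_idx, , drop = FALSE], 2, shift, "+")
    trajectory <- set_frame_coords(trajectory, f, co)
  }
  list(trajectory = trajectory, planted_frames = planted)
}

#' Plant beta-strand content over a residue range
#'
#' In a seeded random subset of `ceiling(f * n)` frames the range adopts an
#' ideal antiparallel strand geometry paired to a partner strand (backbone
#' N/O placed so every residue forms the two-rung hydrogen-bond ladder); in
#' the remaining frames both segments adopt helix-like geometry with no
#' inter-strand hydrogen bonds. The paired block is displaced far from the
#' rest of the chain in all frames so no accidental contacts interfere.
#'
#' @param trajectory a [trajectory()] with backbone atoms.
#' @param range residue interval `c(first, last)` to plant.
#' @param fraction fraction of frames in strand geometry, in `[0, 1]`.
#' @param partner partner-strand residue interval; defaults to the `length(range)`
#'   residues starting 5 after `range` (the minimum sequence separation the
#'   ladder criterion accepts).
#' @param seed RNG seed for the frame subset.
#' @return list with `trajectory` and `planted_frames`.
#' @export
plant_strand_segment <- function(trajectory, range, fraction, partner = NULL,
                                 seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, length(range) == 2)
  top <- trajectory$topology
  L <- range[2] - range[1] + 1L
  if (is.null(partner)) partner <- c(range[2] + 5L, range[2] + 4L + L)
  span <- residue_span(top)
  if (partner[2] > span[2]) stop("partner strand outside topology span")
  need <- c("N", "CA", "C", "O")
  for (rr in c(range[1]:range[2], partner[1]:partner[2])) {
    have <- top$elety[top$resno == rr]
    if (!all(need %in% have))
      stop("residue ", rr, " lacks backbone atoms (build with backbone = TRUE)")
  }
  n <- n_frames(trajectory)
  kf <- ceiling(fraction * n)
  planted <- if (kf > 0) with_seed(seed, sort(sample.int(n, kf))) else integer(0)

  base <- apply(matrix(trajectory$xyz[1, ], ncol = 3, byrow = TRUE), 2, max) + 10

  place_res <- function(co, resno_i, ca, nn, cc, oo) {
    idx <- function(e) which(top$resno == resno_i & top$elety == e)
    co[idx("CA"), ] <- ca; co[idx("N"), ] <- nn
    co[idx("C"), ] <- cc;  co[idx("O"), ] <- oo
    co
  }

  strand_geom <- function(co) {
    for (m in 0:(L - 1L)) {
      # strand 1: residues range[1]..range[2], left to right
      ca <- base + c(0.34 * m, 0, 0)
      co <- place_res(co, range[1] + m, ca, ca + c(-0.05, 0.16, 0),
                      ca + c(0.05, 0, 0), ca + c(0.05, 0.16, 0))
      # strand 2 antiparallel: residue partner[2]-m sits opposite residue range[1]+m
      ca2 <- base + c(0.34 * m, 0.45, 0)
      co <- place_res(co, partner[2] - m, ca2, ca2 + c(-0.05, -0.16, 0),
                      ca2 + c(0.05, 0, 0), ca2 + c(0.05, -0.16, 0))
    }
    co
  }
  helix_geom <- function(co) {
    helix <- function(k, origin) {
      th <- 100 * k * pi / 180
      origin + c(0.23 * cos(th), 0.23 * sin(th), 0.15 * k)
    }
    for (m in 0:(L - 1L)) {
      ca <- helix(m, base)
      co <- place_res(co, range[1] + m, ca, ca + c(0, 0, 0.05),
                      ca + c(0.03, 0, 0), ca + c(0, 0, -0.05))
      ca2 <- helix(m, base + c(5, 0, 0))
      co <- place_res(co, partner[1] + m, ca2, ca2 + c(0, 0, 0.05),
                      ca2 + c(0.03, 0, 0), ca2 + c(0, 0, -0.05))
    }
    co
  }

  for (f in seq_len(n)) {
    co <- frame_coords(trajectory, f)
    co <- if (f %in% planted) strand_geom(co) else helix_geom(co)
    trajectory <- set_frame_coords(trajectory, f, co)
  }
  list(trajectory = trajectory, planted_frames = planted)
}
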