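#' Build a molecular topology
#'
#' A topology is an ordered atom table shared by every frame of a trajectory.
#' Internally it is a `data.frame` with one row per atom and columns `elety`
#' (atom name), `element`, `mass` (amu), `resno` (1-based residue sequence
#' number), `resid` (residue name) and `chain`. Residue numbering must be
#' non-decreasing along the atom list, mirroring the residue intervals used
#' throughout the analyses (e.g. an NBD anchor 1-380, an SBD 393-603, a
#' linker 383-396 in DnaK numbering).
#'
#' @param elety character vector of atom names (PDB `elety`, e.g. "CA", "N").
#' @param resno integer vector of 1-based residue numbers, non-decreasing.
#' @param resid character vector of residue names (recycled if length 1).
#' @param chain chain identifier(s), recycled.
#' @param element optional element symbols; derived from `elety` when `NULL`.
#' @param mass optional atomic masses (amu); looked up from the element when
#'   `NULL`. Every atom must end up with a strictly positive mass.
#'
#' @return An object of class `topology` (a `data.frame`).
#' @export
topology <- function(elety, resno, resid = "ALA", chain = "A",
                     element = NULL, mass = NULL) {
  n <- length(elety)
  resno <- as.integer(resno)
  if (length(resno) != n)
    stop("'elety' and 'resno' must have equal length")
  if (is.unsorted(resno))
    stop("residue numbers must be non-decreasing along the atom list")
  if (is.null(element))
    element <- element_from_name(elety)
  if (is.null(mass))
    mass <- atomic_mass(element)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("every atom must have a finite mass > 0")
  top <- data.frame(
    elety = as.character(elety),
    element = as.character(element),
    mass = as.numeric(mass),
    resno = resno,
    resid = rep_len(as.character(resid), n),
    chain = rep_len(as.character(chain), n),
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  # flag residues with duplicated CA records: downstream Calpha lookups
  # require at most one CA per residue
  ca <- top$elety == "CA"
  if (anyDuplicated(top$resno[ca]))
    warning("residues with multiple CA atoms: ",
            paste(unique(top$resno[ca][duplicated(top$resno[ca])]),
                  collapse = ", "))
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues (%d-%d)\n",
              nrow(x), length(unique(x$resno)),
              min(x$resno), max(x$resno)))
  invisible(x)
}

# standard atomic masses (amu) for the elements found in protein systems
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, FE = 55.845, ZN = 65.38,
                    MG = 24.305, CA = 40.078, "NA" = 22.990, K = 39.098,
                    CL = 35.45)

# derive the element from a PDB atom name: strip digits/primes, then match
# known two-letter metals before falling back to the first letter
element_from_name <- function(elety) {
  core <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- c("FE", "ZN", "MG", "CL", "BR", "MN", "CU")
  vapply(core, function(s) {
    if (nchar(s) == 0) stop("atom name without letters")
    if (substr(s, 1, 2) %in% two) substr(s, 1, 2) else substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

atomic_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  if (any(is.na(m)))
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

n_atoms <- function(topology) nrow(topology)

residue_span <- function(topology) range(topology$resno)

#' Select atoms by residue range and atom-name filter
#'
#' Resolves a 1-based inclusive residue interval plus an atom-name filter to a
#' sorted, deduplicated set of atom indices. The provenance of the selection
#' (the expression that produced it) is kept as an attribute so derived
#' results remain traceable.
#'
#' @param topology a [topology()].
#' @param resno residue interval: a length-2 vector `c(first, last)`
#'   (1-based, inclusive) or a single residue number.
#' @param atoms `"all"`, or a character vector of atom names to keep
#'   (e.g. `"CA"` for the C-alpha subsets used in clustering and fitting).
#'
#' @return Integer vector of atom indices with class `atom_selection`.
#' @export
select_atoms <- function(topology, resno, atoms = "CA") {
  stopifnot(inherits(topology, "topology"))
  resno <- as.integer(resno)
  if (length(resno) == 1L) resno <- c(resno, resno)
  if (length(resno) != 2L) stop("'resno' must be a residue interval c(first, last)")
  if (resno[1] > resno[2])
    stop(sprintf("reversed residue range %d-%d", resno[1], resno[2]))
  span <- residue_span(topology)
  if (resno[1] < span[1] || resno[2] > span[2])
    stop(sprintf("residue range %d-%d outside topology span %d-%d",
                 resno[1], resno[2], span[1], span[2]))
  keep <- topology$resno >= resno[1] & topology$resno <= resno[2]
  if (!identical(atoms, "all"))
    keep <- keep & topology$elety %in% atoms
  idx <- sort(unique(which(keep)))
  if (length(idx) == 0L)
    warning(sprintf("empty selection: residues %d-%d, atoms %s",
                    resno[1], resno[2], paste(atoms, collapse = ",")))
  structure(idx,
            class = "atom_selection",
            provenance = sprintf("resno %d-%d; atoms %s", resno[1], resno[2],
                                 paste(atoms, collapse = ",")))
}

# normalise a selection argument: atom_selection, integer indices, or NULL
# (meaning all atoms)
resolve_selection <- function(sel, topology) {
  if (is.null(sel)) return(seq_len(n_atoms(topology)))
  idx <- as.integer(sel)
  if (any(idx < 1L) || any(idx > n_atoms(topology)))
    stop("selection indices outside topology")
  idx
}

#' Provenance label of a simulation run
#'
#' Records which system a trajectory belongs to: the ligand occupying each
#' binding site (e.g. `NBD = "ATP"`, `SBD = "NR"`) and the replica index.
#'
#' @param system system identifier (free text).
#' @param ligands named character vector mapping site to ligand.
#' @param replica integer replica index.
#' @param vocabulary optional list mapping site name to the allowed ligand
#'   names for this run set; tags are validated against it when given.
#' @return An object of class `provenance_label`.
#' @export
provenance_label <- function(system, ligands = character(), replica = 1L,
                             vocabulary = NULL) {
  ligands <- vapply(ligands, as.character, character(1))
  if (!is.null(vocabulary)) {
    for (site in names(ligands)) {
      allowed <- vocabulary[[site]]
      if (!is.null(allowed) && !(ligands[[site]] %in% allowed))
        stop(sprintf("ligand '%s' at site '%s' not in declared vocabulary",
                     ligands[[site]], site))
    }
  }
  structure(list(system = as.character(system), ligands = ligands,
                 replica = as.integer(replica)),
            class = "provenance_label")
}

#' Format a provenance label as the conventional state string
#'
#' Produces strings such as `"NBD(ATP)-SBD(NR)"` from the ligand tags.
#' @param label a [provenance_label()].
#' @return character scalar.
#' @export
format_label <- function(label) {
  if (is.null(label)) return("unlabelled")
  if (length(label$ligands) == 0) return(label$system)
  paste(sprintf("%s(%s)", names(label$ligands), unlist(label$ligands)),
        collapse = "-")
}

#' Construct a trajectory
#'
#' A trajectory couples one topology with an ordered set of frames. Frame
#' coordinates are stored as an `nframes x (3 * natoms)` matrix in nm
#' (bio3d `xyz` layout), with per-frame times in ps strictly increasing.
#'
#' @param topology a [topology()].
#' @param xyz numeric matrix `nframes x (3 * natoms)` of coordinates in nm
#'   (a plain length-3N vector is treated as a single frame).
#' @param time per-frame times in ps; synthesised from `dt` when `NULL`.
#' @param dt frame spacing in ps used to synthesise times (default 1 ps).
#' @param label optional [provenance_label()].
#' @return An object of class `trj`.
#' @export
trajectory <- function(topology, xyz, time = NULL, dt = 1, label = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop(sprintf("coordinate count (%d) does not match topology atoms (%d x 3)",
                 ncol(xyz), n_atoms(topology)))
  if (any(!is.finite(xyz)))
    stop("non-finite coordinates in trajectory")
  if (is.null(time)) time <- (seq_len(nrow(xyz)) - 1) * dt
  if (length(time) != nrow(xyz))
    stop("'time' length must equal frame count")
  if (nrow(xyz) > 1 && any(diff(time) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = unname(xyz),
                 time = as.numeric(time), label = label),
            class = "trj")
}

#' @export
print.trj <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %.1f-%.1f ps [%s]\n",
              n_frames(x), n_atoms(x$topology),
              min(x$time), max(x$time), format_label(x$label)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(trj) nrow(trj$xyz)

#' Coordinates of one frame as an n x 3 matrix
#' @param trj a [trajectory()].
#' @param frame frame index.
#' @param sel optional atom selection (indices or [select_atoms()] result).
#' @return numeric matrix (atoms x 3) in nm.
#' @export
frame_coords <- function(trj, frame, sel = NULL) {
  idx <- resolve_selection(sel, trj$topology)
  v <- trj$xyz[frame, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  m[idx, , drop = FALSE]
}

# replace coordinates of selected atoms in one frame
set_frame_coords <- function(trj, frame, coords, sel = NULL) {
  idx <- resolve_selection(sel, trj$topology)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  trj$xyz[frame, cols] <- as.vector(t(coords))
  trj
}

# column indices into the flat xyz layout for an atom selection
xyz_cols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

#' Extract a sub-trajectory of frames
#' @param trj a [trajectory()].
#' @param frames integer frame indices (in order).
#' @return a [trajectory()] restricted to those frames.
#' @export
subset_frames <- function(trj, frames) {
  trajectory(trj$topology, trj$xyz[frames, , drop = FALSE],
             time = trj$time[frames], label = trj$label)
}
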