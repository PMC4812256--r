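#' Read a structure (PDB, possibly multi-model)
#'
#' Parses a PDB file into a [topology()] plus one frame per MODEL record.
#' Coordinates are converted from Angstrom to nm. Atom order follows the
#' file. Protein residues lacking a C-alpha atom are flagged with a warning;
#' insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param dt frame spacing in ps assigned to multi-model files (default 1).
#' @param label optional [provenance_label()] attached to the result.
#' @return A [trajectory()] with one frame per model (single-model files give
#'   a one-frame trajectory whose first frame is the structure).
#' @export
read_structure <- function(path, dt = 1, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes present in ", path,
         "; renumber the structure before reading")
  top <- topology(elety = at$elety, resno = at$resno, resid = at$resid,
                  chain = ifelse(is.na(at$chain), "A", at$chain))
  protein <- top$resno[top$elety %in% c("N", "C", "O", "CB")]
  has_ca <- unique(top$resno[top$elety == "CA"])
  missing_ca <- setdiff(unique(protein), has_ca)
  if (length(missing_ca))
    warning("protein residues without CA: ",
            paste(missing_ca, collapse = ", "))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory(top, unclass(xyz) / 10, dt = dt, label = label)  # Angstrom -> nm
}

#' Read a trajectory file against a known topology
#'
#' Supported formats: DCD (read via bio3d; times synthesised from `dt` since
#' the format carries no reliable time metadata) and multi-model PDB. The
#' atom count in the file must equal the topology atom count.
#'
#' @param path trajectory file (`.dcd`, `.pdb`).
#' @param topology the [topology()] the frames belong to.
#' @param dt frame spacing in ps used to synthesise times.
#' @param label optional [provenance_label()].
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology, dt = 1, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    validate_dcd(path)
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) {
                      # the reader can leak its connection on failure
                      leaked <- showConnections()
                      for (k in rownames(leaked))
                        if (grepl(basename(path), leaked[k, "description"],
                                  fixed = TRUE))
                          close(getConnection(as.integer(k)))
                      stop("truncated or unreadable DCD file ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    xyz <- unclass(xyz) / 10
  } else if (ext %in% c("pdb", "ent")) {
    t2 <- read_structure(path, dt = dt)
    xyz <- t2$xyz
  } else {
    stop("unsupported trajectory format: .", ext,
         " (supported: dcd, multi-model pdb)")
  }
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop(sprintf("atom count mismatch: file has %d atoms, topology has %d",
                 ncol(xyz) %/% 3L, n_atoms(topology)))
  trajectory(topology, xyz, dt = dt, label = label)
}

# check that a native-endian DCD file has a consistent record structure, so
# a truncated file errors here rather than inside the block reader
validate_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  m1 <- readBin(con, "integer", 1, size = 4)
  if (length(m1) == 0) stop("truncated DCD file ", path, ": empty")
  if (m1 != 84) return(invisible(NULL))  # other endianness: defer to reader
  seek(con, 4 + 84 + 4)
  tlen <- readBin(con, "integer", 1, size = 4)
  if (length(tlen) == 0 || tlen < 4)
    stop("truncated DCD file ", path, ": bad title record")
  seek(con, 4 + 84 + 4 + 4 + tlen + 4)
  alen <- readBin(con, "integer", 1, size = 4)
  natoms <- readBin(con, "integer", 1, size = 4)
  if (length(alen) == 0 || length(natoms) == 0 || alen != 4 || natoms < 1)
    stop("truncated DCD file ", path, ": bad atom-count record")
  header <- (4 + 84 + 4) + (4 + tlen + 4) + (4 + 4 + 4)
  frame <- 3 * (4 + 4 * natoms + 4)
  body <- file.size(path) - header
  if (body < frame || body %% frame != 0)
    stop("truncated DCD file ", path, ": ", body,
         " body bytes are not a whole number of ", frame, "-byte frames")
  invisible(NULL)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' Coordinates are converted nm to Angstrom. One MODEL record per frame.
#'
#' @param trj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trj, path) {
  top <- trj$topology
  bio3d::write.pdb(file = path,
                   xyz = trj$xyz * 10,
                   resno = top$resno, resid = top$resid,
                   eleno = seq_len(nrow(top)), elety = top$elety,
                   chain = top$chain, elesy = top$element)
  invisible(path)
}

#' Read a run-set manifest
#'
#' The manifest is a YAML file declaring, per system, the ligand-state tags
#' and the trajectory files of each replica:
#'
#' ```yaml
#' vocabulary: {NBD: [ADP, ATP], SBD: [free, NR, Api88]}
#' reference: start.pdb
#' systems:
#'   - id: adp_free
#'     ligands: {NBD: ADP, SBD: free}
#'     runs:
#'       - {file: adp_free_r1.pdb, replica: 1, dt: 100}
#'       - {file: adp_free_r2.pdb, replica: 2, dt: 100}
#' ```
#'
#' File paths are resolved relative to the manifest location. The trajectory
#' output interval is not a property of the file formats used here, so every
#' run must declare `dt` (ps) explicitly.
#'
#' @param path manifest YAML file.
#' @return A list with `reference` (a one-frame [trajectory()]), `systems`
#'   (named list of lists of labelled [trajectory()] runs) and `vocabulary`.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  if (is.null(man$reference)) stop("manifest must declare a 'reference' structure")
  reference <- read_structure(resolve(man$reference))
  vocabulary <- man$vocabulary
  systems <- list()
  for (sys in man$systems) {
    runs <- lapply(sys$runs, function(r) {
      if (is.null(r$dt)) stop("run without dt in system ", sys$id)
      lab <- provenance_label(sys$id, ligands = unlist(sys$ligands),
                              replica = r$replica %||% 1L,
                              vocabulary = vocabulary)
      read_trajectory(resolve(r$file), reference$topology,
                      dt = r$dt, label = lab)
    })
    systems[[sys$id]] <- runs
  }
  list(reference = reference, systems = systems, vocabulary = vocabulary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
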