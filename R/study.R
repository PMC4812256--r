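#' Write a complete synthetic study (structures, runs, manifest) to disk
#'
#' Generates a self-contained run set emulating the design of a two-domain
#' ligand-state comparison: a "closed" system whose appended domain stays at
#' its reference placement (narrow interdomain distribution, as with ADP in
#' the nucleotide site) and an "open" system whose appended domain hops
#' between the reference placement and a displaced one (wide, multimodal
#' distribution, as with ATP). Two independent replicas per system are
#' written as multi-model PDB together with a YAML manifest, ready for
#' [analysis_config()] / [run_system()] / [run_meta()].
#'
#' @param dir output directory (created).
#' @param seed integer seed; replica seeds are derived from it.
#' @param n_frames frames per replica.
#' @param dt frame spacing, ps.
#' @param arch a [toy_architecture()].
#' @param sigma,sigma_linker noise widths, nm (see [noise_model()]).
#' @param offset displacement of the second state of the open system, nm.
#' @param open_weights mixture weights of the open system's two states.
#' @return list with `manifest` (path to `runs.yaml`), `truth` (per-run state
#'   sequences), `arch`, and `config_args`: ready-made residue presets for
#'   [analysis_config()] matched to the toy architecture.
#' @export
write_synthetic_study <- function(dir, seed = 1, n_frames = 60, dt = 100,
                                  arch = toy_architecture(30, 30, 10, 40),
                                  sigma = 0.02, sigma_linker = 0.05,
                                  offset = 2, open_weights = c(0.5, 0.5)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_toy_structure(arch, backbone = TRUE)
  write_trajectory(ref, file.path(dir, "reference.pdb"))
  mixtures <- list(
    closed_free = state_mixture(list(list(translation = c(0, 0, 0)))),
    open_free = state_mixture(list(list(translation = c(0, 0, 0)),
                                   list(translation = c(offset, 0, 0))),
                              open_weights))
  ligands <- list(closed_free = list(NBD = "ADP", SBD = "free"),
                  open_free = list(NBD = "ATP", SBD = "free"))
  truth <- list()
  systems <- list()
  k <- 0L
  for (sys in names(mixtures)) {
    runs <- list()
    for (rep_i in 1:2) {
      k <- k + 1L
      nm <- noise_model(sigma, sigma_linker, seed = seed * 100L + k)
      sim <- simulate_hinge_trajectory(ref, mixtures[[sys]], nm, n_frames,
                                       dt = dt)
      fname <- sprintf("%s_r%d.pdb", sys, rep_i)
      write_trajectory(sim$trajectory, file.path(dir, fname))
      truth[[sprintf("%s_r%d", sys, rep_i)]] <- sim$states
      runs[[rep_i]] <- list(file = fname, replica = rep_i, dt = dt)
    }
    systems[[length(systems) + 1L]] <- list(id = sys, ligands = ligands[[sys]],
                                            runs = runs)
  }
  manifest <- file.path(dir, "runs.yaml")
  yaml::write_yaml(list(
    vocabulary = list(NBD = c("ADP", "ATP"), SBD = c("free", "NR", "Api88")),
    reference = "reference.pdb",
    systems = systems), manifest)
  r <- arch$ranges
  config_args <- list(
    fit = r$lobe_a %+r% r$lobe_b,           # both lobes = anchor domain
    com = r$appended,
    linker = r$linker,
    subsets = list(hinge = list(range = c(max(1L, r$linker[1] - 5L),
                                          min(arch$n_residues,
                                              r$linker[2] + 20L)),
                                cutoff = 0.35)),
    coord_blocks = list(r$lobe_a, r$lobe_b),
    hinges = list(hinge_entry = seq(r$linker[1] - 2L, r$linker[1] + 1L),
                  hinge_exit = seq(r$linker[2] - 1L, r$linker[2] + 2L)),
    contact_partner = c(r$appended[1], min(r$appended[1] + 14L, r$appended[2])))
  list(manifest = manifest, truth = truth, arch = arch,
       config_args = config_args)
}

# union of two adjacent residue intervals
`%+r%` <- function(a, b) c(min(a[1], b[1]), max(a[2], b[2]))
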