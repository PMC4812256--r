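# Orchestration: per-system analyses and meta-trajectory clustering with
# ligand-state decomposition, driven by a run-set manifest.

#' Assemble an analysis configuration
#'
#' Collects every tunable of the workflow: the residue presets (anchor-domain
#' fit selection, mobile-domain COM selection, linker), the clustering
#' subsets with their cutoffs, the interaction cutoffs and the persistence
#' threshold, the equilibrated tail window, histogram bin width and the seed.
#' Defaults follow DnaK conventions (fit on residues 1-380, COM over
#' 393-603, linker 383-396, clustering subsets 373-393 and 393-433 at
#' 0.35 nm and 393-503 at 0.15 nm, interface threshold 6 A, persistence
#' 0.30, tail 90 ns); override them to match the topology being analysed.
#'
#' @param manifest path to a run-set manifest YAML (see [read_manifest()]),
#'   or an already-loaded manifest list.
#' @param fit,com,linker residue intervals `c(first, last)`.
#' @param subsets named list of `list(range = c(first, last), cutoff = nm)`
#'   clustering presets.
#' @param contact_cutoff,hbond_dist nm. @param hbond_angle degrees.
#' @param interface_threshold Angstrom. @param persistence occupancy fraction.
#' @param tail_ns analysed tail window per run, ns.
#' @param bin_width histogram bin width, Angstrom.
#' @param coord_blocks optional list of two residue intervals scored by
#'   [coordination_score()] (e.g. the two lobes of the anchor domain).
#' @param hinges optional named list of length-4 residue-number vectors; each
#'   defines a C-alpha pseudo-dihedral tracked per system.
#' @param contact_partner optional residue interval probed against the
#'   linker for contacts/H-bonds; `NULL` means every non-linker residue.
#' @param top_k clusters reported individually in decompositions.
#' @param seed integer seed for any subsampling.
#' @return A list of class `analysis_config` with `manifest` (loaded) and
#'   `params`.
#' @export
analysis_config <- function(manifest,
                            fit = c(1, 380), com = c(393, 603),
                            linker = c(383, 396),
                            subsets = list(
                              linker_nbd = list(range = c(373, 393), cutoff = 0.35),
                              linker_bsbd = list(range = c(393, 433), cutoff = 0.35),
                              bsbd = list(range = c(393, 503), cutoff = 0.15)),
                            contact_cutoff = 0.45, hbond_dist = 0.35,
                            hbond_angle = 30, interface_threshold = 6,
                            persistence = 0.30, tail_ns = 90, bin_width = 1,
                            coord_blocks = NULL, hinges = NULL,
                            contact_partner = NULL, top_k = 3, seed = 1L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  params <- list(fit = fit, com = com, linker = linker, subsets = subsets,
                 contact_cutoff = contact_cutoff, hbond_dist = hbond_dist,
                 hbond_angle = hbond_angle,
                 interface_threshold = interface_threshold,
                 persistence = persistence, tail_ns = tail_ns,
                 bin_width = bin_width, coord_blocks = coord_blocks,
                 hinges = hinges, contact_partner = contact_partner,
                 top_k = top_k, seed = as.integer(seed))
  structure(list(manifest = manifest, params = params,
                 hash = config_hash(params)),
            class = "analysis_config")
}

# stable hash of the parameter set, stamped into every report
config_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, null = "null",
                              digits = 12), f)
  unname(tools::md5sum(f))
}

tail_frames <- function(runs, tail_ns) {
  lapply(runs, function(run) {
    tm <- run$time
    dt <- if (length(tm) > 1) stats::median(diff(tm)) else 1
    keep <- which(tm > max(tm) - tail_ns * 1000)
    out <- subset_frames(run, keep)
    out
  })
}

#' Run all per-system analyses
#'
#' Executes the geometry, interactions and fluctuations stages on the
#' configured tail window of every replica of one system: COM cloud with
#' distance-from-start and pair-distance distributions (replicas merged),
#' persistent contacts and H-bonds of the linker (per replica and pooled),
#' interface map, distance-fluctuation map with optional inter-block
#' coordination score, strand content of the linker, and hinge dihedrals.
#' Deterministic given config and seed.
#'
#' @param config an [analysis_config()].
#' @param system_id system identifier present in the manifest.
#' @return A report list for the system.
#' @export
run_system <- function(config, system_id) {
  p <- config$params
  runs <- config$manifest$systems[[system_id]]
  if (is.null(runs) || length(runs) == 0)
    stop("no runs for system ", system_id)
  reference <- config$manifest$reference
  top <- reference$topology
  stage <- "setup"
  result <- tryCatch({
    stage <- "com_cloud"
    fit_sel <- select_atoms(top, p$fit, "CA")
    com_sel <- select_atoms(top, p$com, "all")
    cloud <- com_cloud(runs, fit_sel, com_sel, reference, tail_ns = p$tail_ns)
    dstart <- distance_from_start(cloud, p$bin_width)
    pdist <- pair_distance_distribution(cloud, p$bin_width, seed = p$seed)

    tails <- tail_frames(runs, p$tail_ns)
    pooled <- build_meta(runs, p$tail_ns)
    pooled_trj <- trajectory(top, pooled$xyz)

    stage <- "interactions"
    span <- residue_span(top)
    linker_res <- p$linker[1]:p$linker[2]
    partner_res <- if (is.null(p$contact_partner))
      setdiff(span[1]:span[2], linker_res)
    else setdiff(p$contact_partner[1]:p$contact_partner[2], linker_res)
    per_replica <- lapply(tails, function(tt) {
      cs <- contact_series(tt, partner_res, linker_res, p$contact_cutoff)
      hs <- tryCatch(
        hbond_series(tt, partner_res, linker_res, p$hbond_dist, p$hbond_angle),
        error = function(e) NULL)
      persistence_filter(Filter(Negate(is.null), list(cs, hs)), p$persistence)
    })
    pooled_cs <- contact_series(pooled_trj, partner_res, linker_res,
                                p$contact_cutoff)
    pooled_hs <- tryCatch(
      hbond_series(pooled_trj, partner_res, linker_res, p$hbond_dist,
                   p$hbond_angle),
      error = function(e) NULL)
    persistent <- persistence_filter(Filter(Negate(is.null),
                                            list(pooled_cs, pooled_hs)),
                                     p$persistence)
    iface <- interface_map(pooled_trj, partner_res, linker_res,
                           p$interface_threshold)

    stage <- "fluctuations"
    dfmap <- distance_fluctuation_map(pooled_trj)
    coord <- if (!is.null(p$coord_blocks))
      coordination_score(dfmap, p$coord_blocks[[1]], p$coord_blocks[[2]])
    else NULL

    stage <- "strand_content"
    strand <- tryCatch(strand_content(pooled_trj, p$linker),
                       error = function(e) NULL)

    stage <- "dihedrals"
    dihedrals <- NULL
    if (!is.null(p$hinges)) {
      dihedrals <- lapply(p$hinges, function(resnos) {
        atoms <- vapply(resnos, function(r)
          which(top$resno == r & top$elety == "CA")[1], integer(1))
        ds <- dihedral_series(pooled_trj, atoms)
        list(circular_mean = ds$circular_mean,
             circular_variance = ds$circular_variance)
      })
    }

    list(system = system_id,
         label = format_label(runs[[1]]$label),
         n_runs = length(runs),
         n_frames_analyzed = n_frames(pooled_trj),
         com = list(mean_distance_from_start = dstart$mean,
                    peak_distance_from_start = dstart$peak,
                    pair_distance_peak = pdist$peak,
                    pair_distance_mean = pdist$mean),
         cloud = cloud,
         distributions = list(from_start = dstart, pair = pdist),
         persistent_interactions = persistent,
         per_replica_interactions = per_replica,
         interface = list(residues_partner = iface$residues_a,
                          residues_linker = iface$residues_b),
         df_map = dfmap,
         coordination_score = coord,
         strand_content = if (is.null(strand)) NULL else strand$content,
         dihedrals = dihedrals,
         config_hash = config$hash)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed for system '%s': %s",
                 stage, system_id, conditionMessage(e)))
  })
  result
}

#' Meta-trajectory clustering with ligand-state decomposition
#'
#' Builds the meta-trajectory from the tails of every run of every system,
#' clusters each configured residue subset with the gromos method at its
#' cutoff, and decomposes cluster populations by source ligand state.
#'
#' @param config an [analysis_config()] whose manifest lists >= 2 systems
#'   (a single system degenerates to plain per-state populations).
#' @param representatives_dir optional directory; when given, the
#'   representative (medoid) frame of each top cluster of each subset is
#'   written there as PDB.
#' @return A report list: per subset, `populations`, `centers`,
#'   `decomposition` (label x cluster matrix) and `n_clusters`.
#' @export
run_meta <- function(config, representatives_dir = NULL) {
  p <- config$params
  runs <- unlist(config$manifest$systems, recursive = FALSE)
  if (length(runs) == 0) stop("manifest lists no runs")
  meta <- build_meta(runs, p$tail_ns)
  top <- meta$topology
  out <- list()
  for (nm in names(p$subsets)) {
    ss <- p$subsets[[nm]]
    sel <- select_atoms(top, ss$range, "CA")
    mat <- rmsd_matrix(meta, sel, fit = TRUE)
    cl <- gromos_cluster(mat, ss$cutoff)
    dec <- decompose_by_label(cl, meta, top_k = min(p$top_k,
                                                    length(cl$populations)))
    if (!is.null(representatives_dir)) {
      dir.create(representatives_dir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(min(p$top_k, length(cl$populations))))
        representative(cl, k, meta,
                       file.path(representatives_dir,
                                 sprintf("%s_cluster%d.pdb", nm, k)))
    }
    out[[nm]] <- list(range = ss$range, cutoff = ss$cutoff,
                      n_clusters = length(cl$populations),
                      populations = cl$populations,
                      centers = cl$centers,
                      decomposition = dec)
  }
  list(subsets = out, n_frames = n_frames(meta),
       labels = unique(meta$source), config_hash = config$hash)
}

# strip non-serialisable / bulky members down to plain numbers for the JSON
# report body
report_body <- function(report) {
  prune <- function(x) {
    if (inherits(x, "com_cloud")) return(NULL)
    if (inherits(x, "df_map"))
      return(list(mean = mean(x), max = max(x), n_residues = nrow(x)))
    if (inherits(x, "dist_distribution"))
      return(list(mean = x$mean, peak = x$peak, counts = as.vector(x$counts),
                  mids = as.vector(x$mids)))
    if (inherits(x, "decomposition_table") || inherits(x, "matrix"))
      return(as.data.frame(unclass(x)))
    if (is.list(x)) {
      out <- lapply(x, prune)
      return(out[!vapply(out, is.null, logical(1))])
    }
    x
  }
  prune(report)
}

#' Write a consolidated report to disk
#'
#' Serialises the report body as `report.json` (numbers only; clouds and
#' full matrices go to CSV side files) plus `dfmap_<system>.csv`,
#' `comcloud_<system>.csv`, `persistent_<system>.csv` and
#' `decomposition_<subset>.csv`, and a `MANIFEST.json` listing every file
#' with the config hash.
#'
#' @param reports named list: per-system reports from [run_system()] and
#'   optionally `meta` from [run_meta()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_report <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    files <<- c(files, name)
  }
  for (nm in setdiff(names(reports), "meta")) {
    rep <- reports[[nm]]
    if (!is.null(rep$cloud))
      emit(sprintf("comcloud_%s.csv", nm), function(pp) {
        d <- sqrt(rowSums(sweep(rep$cloud$points, 2, rep$cloud$reference)^2)) * 10
        utils::write.csv(data.frame(frame = seq_len(nrow(rep$cloud$points)),
                                    label = rep$cloud$label,
                                    x = rep$cloud$points[, 1],
                                    y = rep$cloud$points[, 2],
                                    z = rep$cloud$points[, 3],
                                    distance_from_start = d),
                         pp, row.names = FALSE)
      })
    if (!is.null(rep$df_map))
      emit(sprintf("dfmap_%s.csv", nm), function(pp)
        utils::write.csv(as.data.frame(unclass(rep$df_map)), pp))
    if (!is.null(rep$persistent_interactions))
      emit(sprintf("persistent_%s.csv", nm), function(pp)
        utils::write.csv(rep$persistent_interactions, pp, row.names = FALSE))
  }
  if (!is.null(reports$meta)) {
    for (sn in names(reports$meta$subsets))
      emit(sprintf("decomposition_%s.csv", sn), function(pp)
        utils::write.csv(as.data.frame(unclass(
          reports$meta$subsets[[sn]]$decomposition)), pp))
  }
  body <- report_body(reports)
  emit("report.json", function(pp)
    jsonlite::write_json(body, pp, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE))
  hash <- unlist(lapply(reports, function(r) r$config_hash))[1]
  jsonlite::write_json(list(files = files, config_hash = hash),
                       file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
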