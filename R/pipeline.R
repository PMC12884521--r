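# End-to-end driver reproducing the study's stage order: site definition ->
# conformational scan -> clash filter -> constrained minimisation ->
# deduplication -> two-layer scoring -> Boltzmann populations -> binding
# energy -> NCI -> hydrogen bonds -> (optional) spectrum. Stages exchange
# files (PDB/XYZ/TSV/cube), so any stage can be re-run independently, and a
# manifest records parameters, counts and checksums of every output.

#' Pipeline configuration
#'
#' @param toy A [toy_complex_spec()] to generate inputs synthetically, or
#'   `NULL` to read them from files.
#' @param pdb,ligand_code,radius,site_mode,ph PDB input mode: path to a
#'   complex PDB file and the site-extraction settings applied to it.
#' @param dihedrals Path to a TSV defining dihedral specs (columns `i, j,
#'   k, l, rotating` with `rotating` a comma-separated index list);
#'   required in PDB mode.
#' @param angle_step Dihedral scan increment, degrees.
#' @param translation_extent,translation_n Rigid translation grid: half
#'   width (Angstrom) and points per axis. `translation_n = 1` scans no
#'   translations.
#' @param clash_scale Clash-filter van der Waals scale.
#' @param dedup_rmsd Deduplication RMSD threshold, Angstrom.
#' @param temperature Boltzmann temperature, K.
#' @param nci_spacing,nci_padding NCI grid spacing (bohr) and padding
#'   (Angstrom).
#' @param transitions `NULL`, a path to a transitions TSV, or an integer:
#'   generate that many synthetic states (seeded) and post-process them.
#' @param seed Seed for all stochastic inputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(toy = toy_complex_spec(), pdb = NULL,
                            ligand_code = "VDX", radius = 6.0,
                            site_mode = "any_atom", ph = 7.4,
                            dihedrals = NULL, angle_step = 90,
                            translation_extent = 1.0, translation_n = 3,
                            clash_scale = 0.7, dedup_rmsd = 0.5,
                            temperature = 298.15, nci_spacing = 0.4,
                            nci_padding = 1.5, transitions = NULL,
                            seed = 1) {
  cfg <- list(toy = toy, pdb = pdb, ligand_code = ligand_code,
              radius = radius, site_mode = site_mode, ph = ph,
              dihedrals = dihedrals, angle_step = angle_step,
              translation_extent = translation_extent,
              translation_n = translation_n, clash_scale = clash_scale,
              dedup_rmsd = dedup_rmsd, temperature = temperature,
              nci_spacing = nci_spacing, nci_padding = nci_padding,
              transitions = transitions, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.read_dihedrals_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  lapply(seq_len(nrow(df)), function(r) {
    dihedral_spec(c(df$i[r], df$j[r], df$k[r], df$l[r]),
                  as.integer(strsplit(df$rotating[r], ",")[[1]]))
  })
}

.write_dihedrals_tsv <- function(specs, path) {
  df <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(i = s$atom_indices[1], j = s$atom_indices[2],
                   k = s$atom_indices[3], l = s$atom_indices[4],
                   rotating = paste(s$rotating_set, collapse = ","))
  }))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every stage in order, writing per-stage outputs and a
#' `manifest.json` (parameters, per-stage counts, file checksums) into
#' `dir`. Re-running with the same configuration reproduces every output
#' byte-for-byte; only the manifest's `created_at` field differs.
#'
#' @param config A [pipeline_config()].
#' @param dir Run directory; created if absent.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  # fail on missing inputs before any compute
  for (f in c(config$pdb, config$dihedrals,
              if (is.character(config$transitions)) config$transitions)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("configured input file does not exist: ", f, call. = FALSE)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, ...)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }

  ## stage 1: inputs / site definition -------------------------------------
  wells <- NULL
  if (!is.null(config$toy)) {
    toy <- make_toy_complex(config$toy)
    site <- toy$site
    ligand <- toy$ligand
    specs <- toy$dihedrals
    params <- toy$params
    wells <- toy$wells
    note("site", source = "synthetic", n_site_atoms = nrow(site),
         n_ligand_atoms = nrow(ligand))
  } else {
    if (is.null(config$pdb) || is.null(config$dihedrals)) {
      stop("file mode requires `pdb` and `dihedrals` paths", call. = FALSE)
    }
    full <- read_pdb(config$pdb, ligand_code = config$ligand_code)
    ligand <- full[full$fragment == "ligand", , drop = FALSE]
    site <- select_site(full, radius = config$radius,
                        mode = config$site_mode)
    site <- protonate(site, ph = config$ph)
    site <- cap_termini(site, reference = full)
    specs <- .read_dihedrals_tsv(config$dihedrals)
    params <- ff_params()
    note("site", source = config$pdb, n_site_atoms = nrow(site),
         n_ligand_atoms = nrow(ligand),
         n_residues = nrow(attr(site, "source_residues")))
  }
  write_pdb(site, pth("site.pdb"))
  write_xyz(ligand, pth("ligand.xyz"))
  .write_dihedrals_tsv(specs, pth("dihedrals.tsv"))
  readr::write_tsv(
    tibble::tibble(index = seq_len(nrow(site) + nrow(ligand)),
                   fragment = c(ligand$fragment, site$fragment),
                   charge = c(ligand$charge, site$charge)),
    pth("charges.tsv"))

  if (!is.null(wells)) readr::write_tsv(wells, pth("wells.tsv"))
  bonds <- cbind(seq_len(nrow(ligand) - 1), 2:nrow(ligand))
  high_backend <- ff_backend(params, bonds = bonds, hbonds = wells,
                             valence = TRUE, valence_ref = ligand,
                             name = "vacuum")
  low_backend <- ff_backend(
    ff_params(lj = params$lj, hb_depth = params$hb_depth,
              hb_r0 = params$hb_r0, dielectric = "distance_dependent"),
    bonds = bonds, hbonds = wells, valence = TRUE, valence_ref = ligand,
    name = "screened")

  ## stage 2: scan ----------------------------------------------------------
  translations <- if (config$translation_n > 1) {
    translation_grid(config$translation_extent, config$translation_n)
  } else {
    NULL
  }
  records <- enumerate_poses(ligand, specs, angle_step = config$angle_step,
                             translations = translations)
  note("scan", n_poses = nrow(records),
       n_dihedral_combos = (360 %/% config$angle_step)^length(specs),
       n_translations = if (is.null(translations)) 1L else nrow(translations))

  ## stage 3: clash filter ---------------------------------------------------
  records <- clash_filter(records, site, scale = config$clash_scale)
  note("clash_filter", n_survivors = nrow(records))

  ## stage 4: constrained minimisation ---------------------------------------
  records <- minimize_conformers(records, site, low_backend)
  readr::write_tsv(
    tibble::tibble(id = records$id, energy = records$energy,
                   tx = records$tx, ty = records$ty, tz = records$tz),
    pth("energies.tsv"))
  note("minimize", n_minimized = nrow(records), backend = low_backend$name)

  ## stage 5: deduplicate ----------------------------------------------------
  records <- deduplicate(records, rmsd_threshold = config$dedup_rmsd)
  write_xyz(records$pose, pth("distinct.xyz"))
  readr::write_tsv(
    tibble::tibble(id = records$id, energy = records$energy,
                   dihedrals = vapply(records$dihedrals, paste,
                                      "", collapse = ",")),
    pth("distinct.tsv"))
  note("deduplicate", n_distinct = nrow(records))

  ## stage 6: two-layer scoring ---------------------------------------------
  oniom <- lapply(records$pose, function(p) {
    oniom2_score(dplyr::bind_rows(p, site), high_backend, low_backend)
  })
  oniom_df <- dplyr::bind_rows(lapply(oniom, function(o) {
    tibble::tibble(e_high_model = o$e_high_model,
                   e_low_real = o$e_low_real,
                   e_low_model = o$e_low_model, e_oniom2 = o$e_oniom2)
  }))
  oniom_df <- dplyr::bind_cols(tibble::tibble(id = records$id), oniom_df)
  readr::write_tsv(oniom_df, pth("oniom.tsv"))
  note("oniom", n_scored = nrow(oniom_df),
       high = high_backend$name, low = low_backend$name)

  ## stage 7: populations ----------------------------------------------------
  dg <- oniom_df$e_oniom2 - min(oniom_df$e_oniom2)
  pops <- boltzmann_populations(dg, temperature = config$temperature,
                                ids = records$id)
  readr::write_tsv(
    tibble::tibble(id = pops$id, delta_g = pops$delta_g,
                   population = pops$population,
                   percent = round(pops$percent, 1)),
    pth("populations.tsv"))
  best <- which.min(oniom_df$e_oniom2)
  note("boltzmann", temperature = config$temperature,
       top_id = records$id[best],
       top_percent = round(max(pops$percent), 1))

  ## stage 8: binding energy --------------------------------------------------
  best_complex <- dplyr::bind_rows(records$pose[[best]], site)
  bind_res <- binding_energy_from_structures(best_complex, low_backend)
  readr::write_tsv(
    tibble::tibble(e_complex = bind_res$e_complex,
                   e_active_site = bind_res$e_active_site,
                   e_ligand = bind_res$e_ligand,
                   binding_energy = bind_res$binding_energy),
    pth("binding.tsv"))
  note("binding", binding_energy = bind_res$binding_energy)

  ## stage 9: NCI --------------------------------------------------------------
  grid <- nci_grid(best_complex, spacing = config$nci_spacing,
                   padding = config$nci_padding,
                   intermolecular_only = TRUE,
                   region = records$pose[[best]])
  scatter_export(grid, pth("nci-scatter.tsv"))
  nci_export_cubes(grid, best_complex, pth("nci"))
  note("nci", n_grid_points = prod(grid$dims),
       n_scatter_points = sum(grid$mask))

  ## stage 10: hydrogen bonds ---------------------------------------------------
  hb <- if (any(best_complex$element == "H")) {
    hbond_table(best_complex)
  } else {
    hbond_table(make_hbond_dimer())[0, ] # empty table, same schema
  }
  readr::write_tsv(hb, pth("hbonds.tsv"))
  note("hbonds", n_contacts = nrow(hb))

  ## stage 11: spectrum (optional) ---------------------------------------------
  if (!is.null(config$transitions)) {
    tt <- if (is.character(config$transitions)) {
      read_transitions(config$transitions)
    } else {
      make_transition_table(as.integer(config$transitions),
                            seed = config$seed)
    }
    spec <- normalize_spectrum(broaden(tt))
    readr::write_tsv(tibble::as_tibble(spec), pth("spectrum.tsv"))
    note("spectrum", n_transitions = nrow(tt),
         lambda_max = lambda_max(spec))
  }

  ## manifest -------------------------------------------------------------------
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(dir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "pocketconf",
    version = as.character(utils::packageVersion("pocketconf")),
    created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = config[setdiff(names(config), "toy")],
    toy_spec = if (!is.null(config$toy)) unclass(config$toy) else NULL,
    stages = log,
    files = checksums
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
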