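#' Synthetic study systems with known ground truth
#'
#' Builds a desk-scale helix/coil pair of prescribed-profile solvent
#' ensembles emulating the statistical structure of explicit-solvent
#' simulations of a coiled coil in a binary water/cosolvent box at
#' cosolvent mole fraction ~ 0.04 (~2.3 M), water at liquid density.
#' Two presets encode the two cosolvent archetypes:
#'
#' * `"tfe_like"` — side-chain-affine helix inducer: the cosolvent
#'   enhancement around the helix dimer (exposed side chains) is much
#'   stronger than around the coil, so the cosolvent term and the excess
#'   preferential solvation are positive.
#' * `"urea_like"` — backbone-affine denaturant: the enhancement around
#'   the coil (exposed backbone, doubled by the two-coil convention)
#'   dominates, so the excess preferential solvation is negative.
#'
#' In both presets water is hard-core excluded more strongly (after the
#' factor 2) by the two coils than by the dimer, so the water term is
#' negative — the excluded-volume effect that favours the coils.
#' The solvent is placed about a single reference atom (point mode) so
#' every KB integral has a closed form, stored in the ground truth.
#'
#' @param preset "tfe_like" or "urea_like".
#' @param conformation "helix_dimer" or "coil_monomer".
#' @param box box edge lengths (nm), default 6 nm cube.
#' @param n_frames frames (default 120).
#' @param seed RNG seed.
#' @param water_density bulk water density (molecules/nm^3, default 33.2).
#' @param cosolvent_density bulk cosolvent density (default 1.38
#'   molecules/nm^3, i.e. mole fraction 0.04, ~2.3 M).
#' @return As [place_solvent_prescribed()]: list with `trajectory` and
#'   `truth`.
#' @export
synthetic_system <- function(preset = c("tfe_like", "urea_like"),
                             conformation = c("helix_dimer",
                                              "coil_monomer"),
                             box = c(6, 6, 6), n_frames = 120L,
                             seed = 20231001L, water_density = 33.2,
                             cosolvent_density = 1.38) {
  preset <- match.arg(preset)
  conformation <- match.arg(conformation)
  profiles <- synthetic_profiles(preset, conformation)
  out <- place_solvent_prescribed(
    profiles = profiles,
    densities = c(water = water_density, cosolvent = cosolvent_density),
    box = box, n_frames = n_frames, seed = seed,
    conformation = conformation)
  # a single protein reference atom at the box centre anchors selections
  ref <- data.frame(name = "REF", element = "X", residue_name = "REF",
                    residue_index = 0L, chain_id = "R", species = "protein",
                    role = "main_chain", charge = 0, lj_sigma = 0,
                    lj_epsilon = 0, stringsAsFactors = FALSE)
  top0 <- as.data.frame(out$trajectory$topology)
  top0$atom_id <- NULL
  top0$molecule_id <- NULL
  top <- kb_topology(rbind(ref, top0))
  nf <- n_frames(out$trajectory)
  coords <- array(NA_real_, dim = c(nrow(top), 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- rbind(box / 2, out$trajectory$coords[, , f])
  out$trajectory <- kb_trajectory(top, coords, out$trajectory$box)
  out
}

#' @rdname synthetic_system
#' @return `synthetic_profiles()` returns the named list of
#'   [piecewise_profile()]s defining the preset (per monomer, before the
#'   coil multiplicity).
#' @export
synthetic_profiles <- function(preset, conformation) {
  helix <- conformation == "helix_dimer"
  water <- if (helix) piecewise_profile(c(0, 0.5), 0)
           else piecewise_profile(c(0, 0.42), 0)
  cosolvent <- if (preset == "tfe_like") {
    if (helix) piecewise_profile(c(0, 0.5, 1.1), c(0, 3.0))
    else piecewise_profile(c(0, 0.42, 1.0), c(0, 1.8))
  } else {
    if (helix) piecewise_profile(c(0, 0.5, 1.1), c(0, 1.3))
    else piecewise_profile(c(0, 0.42, 1.0), c(0, 1.8))
  }
  list(water = water, cosolvent = cosolvent)
}

#' Read and validate an analysis configuration
#'
#' YAML configuration for [run_pipeline()]. Either `mode: synthetic`
#' (fields `preset`, `box`, `n_frames`) or `mode: files` (fields
#' `helix_trajectory`, `coil_trajectory` pointing at columnar trajectory
#' files, optional `parameter_table`, `bulk_kb_table`). Common numeric
#' fields (defaults in parentheses): `bin_width` (0.02), `r_max` (2.5),
#' `cutoff` (1.0), `probe_radius` (0.14), `grid_spacing` (0.02),
#' `n_blocks` (5), `temperature` (300), `seed` (20231001), plus
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return Validated config list (class `analysis_config`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_analysis_config
#' @param config a config list.
#' @export
validate_config <- function(config) {
  defaults <- list(mode = "synthetic", preset = "tfe_like",
                   box = c(6, 6, 6), n_frames = 120L, bin_width = 0.02,
                   r_max = 1.8, cutoff = 1.0, probe_radius = 0.14,
                   grid_spacing = 0.02, n_blocks = 5L, temperature = 300,
                   seed = 20231001L, a33 = 1.0, out_dir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config$box <- rep_len(as.numeric(config$box), 3L)
  stopifnot(config$mode %in% c("synthetic", "files"),
            config$bin_width > 0, config$r_max > 0, config$cutoff > 0,
            config$probe_radius > 0, config$grid_spacing > 0,
            config$n_blocks >= 2L, config$temperature > 0)
  if (config$mode == "files") {
    for (k in c("helix_trajectory", "coil_trajectory")) {
      if (is.null(config[[k]])) stop("files mode requires ", k)
      if (!file.exists(config[[k]]))
        stop("input path does not exist: ", config[[k]])
    }
    for (k in c("parameter_table", "bulk_kb_table"))
      if (!is.null(config[[k]]) && !file.exists(config[[k]]))
        stop("input path does not exist: ", config[[k]])
  } else {
    config$preset <- match.arg(config$preset, c("tfe_like", "urea_like"))
  }
  structure(config, class = "analysis_config")
}

## cheap deterministic checksum of the config (hex), for the MANIFEST
.config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

#' Run the full trajectory-to-thermodynamics pipeline
#'
#' Stages: ingest or generate helix/coil ensembles; RDFs and running KB
#' integrals for the four protein-solvent pairs; excess preferential
#' solvation with cosolvent/water decomposition and five-block errors;
#' m-value and stability curve; probe-insertion excluded volumes and the
#' excluded-volume estimate of the water term; solvation-shell
#' orientation histogram; protein-cosolvent energy decomposition.
#' Results are written to `out_dir` as TSV/JSON plus `summary.json`, a
#' `MANIFEST` (versions, config hash, completion state, convention
#' flags) and `log.txt`. A stage failure aborts with the stage name;
#' partial outputs are kept and the MANIFEST records the aborted stage.
#' Reruns with the same seed produce identical numbers.
#'
#' @param config an `analysis_config` (list or [read_analysis_config()]
#'   result).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  cat("kbsolv pipeline\n", file = logf)
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                            append = TRUE)
  note("config hash: %s", .config_hash(config))
  note("conventions: rdf=pair-count site-averaged; coil multiplicity=2;")
  note("  linkage: delta_gamma = m*beta*rho3/a33 (small a33 amplifies);")
  note("  axis=principal direction of main-chain atoms, slab=instantaneous extent;")
  note("  LJ combining=Lorentz-Berthelot; Coulomb=real-space cutoff, no Ewald;")
  note("  plateau=mean over trailing window, constant extrapolation beyond trust radius")

  stages_done <- character(0)
  manifest <- function(state) {
    writeLines(c(sprintf("kbsolv %s",
                         as.character(utils::packageVersion("kbsolv"))),
                 sprintf("config_hash %s", .config_hash(config)),
                 sprintf("seed %d", as.integer(config$seed)),
                 sprintf("state %s", state),
                 paste("stages_completed", paste(stages_done,
                                                 collapse = ","))),
               file.path(config$out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest(paste0("aborted_at:", name))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    note("stage %s: done", name)
    res
  }

  ## -- ingest / generate -------------------------------------------------
  dat <- stage("ingest", {
    if (config$mode == "synthetic") {
      h <- synthetic_system(config$preset, "helix_dimer", config$box,
                            config$n_frames, seed = config$seed)
      c_ <- synthetic_system(config$preset, "coil_monomer", config$box,
                             config$n_frames, seed = config$seed + 1L)
      list(helix = h$trajectory, coil = c_$trajectory,
           truth = list(helix = h$truth, coil = c_$truth))
    } else {
      h <- read_columnar_trajectory(config$helix_trajectory)
      c_ <- read_columnar_trajectory(config$coil_trajectory)
      if (!is.null(config$parameter_table)) {
        tab <- read_parameter_table(config$parameter_table)
        h <- kb_trajectory(apply_parameters(h$topology, tab, strict = FALSE),
                           h$coords, h$box)
        c_ <- kb_trajectory(apply_parameters(c_$topology, tab,
                                             strict = FALSE),
                            c_$coords, c_$box)
      }
      list(helix = h, coil = c_, truth = NULL)
    }
  })

  sel <- function(traj, what) {
    top <- traj$topology
    switch(what, protein = which(top$species == "protein"),
           water = which(top$species == "water"),
           cosolvent = which(top$species == "cosolvent"))
  }
  dens <- function(conf, species) {
    if (!is.null(dat$truth)) dat$truth[[conf]]$densities[[species]]
    else NULL
  }

  ## -- rdf + kb ----------------------------------------------------------
  profs <- stage("rdf", {
    mk <- function(traj, conf, species)
      rdf_atomset(traj, sel(traj, "protein"), sel(traj, species),
                  bin_width = config$bin_width, r_max = config$r_max,
                  bulk_density = dens(conf, species),
                  conformation = if (conf == "helix") "helix_dimer"
                                 else "coil_monomer")
    p <- list(p23h = mk(dat$helix, "helix", "cosolvent"),
              p21h = mk(dat$helix, "helix", "water"),
              p23c = mk(dat$coil, "coil", "cosolvent"),
              p21c = mk(dat$coil, "coil", "water"))
    for (nm in names(p))
      write_profile_tsv(p[[nm]], file.path(config$out_dir,
                                           paste0("rdf_", nm, ".tsv")))
    p
  })
  kbs <- stage("kb", {
    k <- lapply(profs, function(p) plateau_estimate(kb_running_integral(p)))
    for (nm in names(k))
      write_profile_tsv(k[[nm]], file.path(config$out_dir,
                                           paste0("kb_", nm, ".tsv")))
    k
  })

  ## -- preferential binding ---------------------------------------------
  rho3 <- if (!is.null(dat$truth)) dat$truth$helix$densities[["cosolvent"]]
          else composition(dat$helix$topology,
                           box = dat$helix$box[1, ])$rho3
  pbp <- stage("pbp", {
    r <- preferential_binding(profs$p23h, profs$p21h, profs$p23c,
                              profs$p21c, rho3, n_blocks = config$n_blocks)
    jsonlite::write_json(
      list(gamma23_helix = r$gamma23_helix, gamma23_coil = r$gamma23_coil,
           delta_gamma = r$delta_gamma, cosolvent_term = r$cosolvent_term,
           water_term = r$water_term, rho3 = r$rho3,
           block_sd = as.list(r$block_sd), n_blocks = r$n_blocks),
      file.path(config$out_dir, "pbp.json"), auto_unbox = TRUE,
      digits = NA)
    r
  })

  ## -- thermodynamic linkage ---------------------------------------------
  thermo <- stage("thermo", {
    a33 <- if (!is.null(config$bulk_kb_table))
      read_bulk_kb_table(config$bulk_kb_table) else config$a33
    conc <- molarity_from_density(rho3)
    a33_here <- .a33_at(a33, conc)
    m <- m_value(pbp, a33 = a33_here, temperature = config$temperature,
                 rho3_molar = conc)
    sm <- delta_g_curve(0, m, c_grid = seq(0, 4, by = 0.25))
    proj <- project_delta_gamma(m, a33 = a33,
                                temperature = config$temperature,
                                c_grid = seq(0, min(4, conc * 2),
                                             by = 0.25))
    utils::write.table(proj, file.path(config$out_dir,
                                       "delta_gamma_projection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(m_value = m, a33 = a33_here, conc_M = conc, stability = sm,
         projection = proj)
  })

  ## -- excluded volume ----------------------------------------------------
  vol <- stage("volume", {
    solute_traj <- function(conf) {
      traj <- dat[[conf]]
      prot <- sel(traj, "protein")
      if (config$mode == "synthetic") {
        # bead solutes carry the geometry in synthetic mode
        s <- make_solute(if (conf == "helix") "helix_dimer"
                         else "coil_monomer",
                         n_residues = 8L, seed = config$seed)
        kb_trajectory(kb_topology(.solute_topology(s)),
                      sweep(s$coords, 2L, config$box / 2, "+"), config$box)
      } else {
        kb_trajectory(kb_topology(as.data.frame(traj$topology[prot, ])),
                      traj$coords[prot, , , drop = FALSE], traj$box)
      }
    }
    vh <- v21_trajectory(solute_traj("helix"), "helix_dimer",
                         probe_radius = config$probe_radius,
                         grid_spacing = config$grid_spacing,
                         n_blocks = config$n_blocks)
    vc <- v21_trajectory(solute_traj("coil"), "coil_monomer",
                         probe_radius = config$probe_radius,
                         grid_spacing = config$grid_spacing,
                         n_blocks = config$n_blocks)
    wt <- water_term_from_volumes(vh, vc, rho3)
    cmp <- compare_water_term(wt, pbp)
    jsonlite::write_json(c(wt[c("v21_h", "v21_c", "water_term_approx")],
                           cmp["water_term"], cmp["difference"]),
                         file.path(config$out_dir, "excluded_volume.json"),
                         auto_unbox = TRUE, digits = NA)
    list(helix = vh, coil = vc, water_term = wt, comparison = cmp)
  })

  ## -- orientation ---------------------------------------------------------
  orient <- stage("orient", {
    traj <- if (config$mode == "synthetic") {
      law <- orientation_shells(c(0, 0.75, 1.65),
                                list(orientation_point(1),
                                     orientation_density(function(x)
                                       (1 - x) / 2)))
      s <- make_solute("helix_dimer", n_residues = 8L, seed = config$seed)
      place_solvent_oriented(law, density = 1.38, box = config$box,
                             n_frames = min(40L, config$n_frames),
                             seed = config$seed + 2L, solute = s)$trajectory
    } else dat$helix
    top <- traj$topology
    tail_name <- if (is.null(config$tail_name)) "C1" else config$tail_name
    head_name <- if (is.null(config$head_name)) "O" else config$head_name
    tails <- which(top$species == "cosolvent" & top$name == tail_name)
    heads <- which(top$species == "cosolvent" & top$name == head_name)
    if (!length(tails) || length(tails) != length(heads)) {
      note("stage orient: no orientation pair (%s -> %s); skipped",
           tail_name, head_name)
      NULL
    } else {
      oh <- orientation_histogram(traj, tails, heads,
                                  reference = "centroid",
                                  solute_atoms = which(top$species ==
                                                       "protein"))
      write_orientation_tsv(oh, file.path(config$out_dir,
                                          "orientation.tsv"))
      oh
    }
  })

  ## -- energy decomposition ------------------------------------------------
  energy <- stage("energy", {
    traj <- if (config$mode == "synthetic") {
      # charged bead system: cosolvent sees the side chains of the dimer
      s <- make_solute("helix_dimer", n_residues = 8L, seed = config$seed)
      sys <- place_solvent_prescribed(
        profiles = list(cosolvent = piecewise_profile(c(0, 0.4, 1.4),
                                                      c(0, 1.5))),
        densities = c(cosolvent = 1.38), box = config$box,
        n_frames = min(20L, config$n_frames), seed = config$seed + 3L,
        solute = s)$trajectory
      top <- sys$topology
      top$charge[top$species == "cosolvent"] <- -0.1
      top$charge[top$role == "side_chain"] <- 0.2
      top$lj_sigma[top$species == "protein"] <- 0.33
      top$lj_epsilon[top$species == "protein"] <- 0.1
      kb_trajectory(top, sys$coords, sys$box)
    } else dat$helix
    ed <- decompose_energy(traj, cutoff = config$cutoff,
                           n_blocks = config$n_blocks)
    write_energy_tsv(ed, file.path(config$out_dir, "energy.tsv"))
    ed
  })

  ## -- summary --------------------------------------------------------------
  summary <- list(
    mode = config$mode,
    preset = if (config$mode == "synthetic") config$preset else NULL,
    rho3 = rho3, conc_M = thermo$conc_M,
    gamma23_helix = pbp$gamma23_helix, gamma23_coil = pbp$gamma23_coil,
    delta_gamma = pbp$delta_gamma, cosolvent_term = pbp$cosolvent_term,
    water_term = pbp$water_term, block_sd = as.list(pbp$block_sd),
    m_value = thermo$m_value, a33 = thermo$a33,
    v21_helix = vol$helix$v21, v21_coil = vol$coil$v21,
    water_term_approx = vol$water_term$water_term_approx,
    energy_total = energy$mean["total", "total"],
    G = as.list(pbp$G))
  if (!is.null(dat$truth)) {
    tr <- dat$truth
    summary$truth <- list(
      G23h = tr$helix$analytic_G[["cosolvent"]],
      G21h = tr$helix$analytic_G[["water"]],
      G23c = 2 * tr$coil$analytic_G[["cosolvent"]],
      G21c = 2 * tr$coil$analytic_G[["water"]])
    summary$delta_gamma_truth <- with(summary$truth,
                                      rho3 * (G23h - G23c) +
                                      rho3 * (G21c - G21h))
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest("complete")
  invisible(summary)
}
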