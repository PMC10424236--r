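# Pipeline orchestration: build -> sample -> wham -> analyze, fully
# reproducible from (config, seed). The master seed splits into per-window
# seeds as seed + window_index (1-based), a documented rule that is stable
# across versions.

empty_ion_inventory <- function() {
  structure(list(counterion_valence = 1L, n_counterions = 0L, n_coions = 0L,
                 coion_valence = -1L, residue = 0L),
            class = "ion_inventory")
}

build_molecule_from_config <- function(sys) {
  switch(sys$topology,
    linear = build_linear_duplex_model(sys$n_bp, sys$rise_nm),
    ring   = build_minicircle_model(sys$n_bp, sys$rise_nm),
    bead   = molecule_model(matrix(0, 1, 3), -2, "linear"))
}

#' Assemble the system described by a run configuration
#'
#' Builds the molecule pair, composes the ion inventory (unless
#' `system.explicit_ions` is off, as in the two-bead oracle preset) and
#' places everything in the box at the requested centre-of-mass separation.
#'
#' @param cfg A `run_config`.
#' @param com_separation Initial COM separation, nm.
#' @param seed Integer placement seed.
#' @return A `system_state`.
#' @export
build_system <- function(cfg, com_separation, seed = 1L) {
  stopifnot(inherits(cfg, "run_config"))
  sys <- cfg$system
  a <- build_molecule_from_config(sys)
  b <- build_molecule_from_config(sys)
  box <- simulation_box(sys$box_edge_nm)
  inv <- if (isTRUE(sys$explicit_ions)) {
    compose_ion_inventory(sum(a$charges) + sum(b$charges),
                          sys$counterion_valence, sys$salt_molar, box)
  } else {
    empty_ion_inventory()
  }
  place_pair_and_ions(a, b, inv, box, com_separation, seed = seed)
}

config_forcefield <- function(cfg) do.call(forcefield_params, cfg$forcefield)

config_schedule <- function(cfg) {
  sa <- cfg$sampling
  make_schedule(sa$r_min, sa$r_max, sa$spacing, sa$force_k)
}

config_bin_edges <- function(cfg) {
  seq(cfg$wham$bin_min, cfg$wham$bin_max, by = cfg$wham$bin_width)
}

#' Run the full pipeline
#'
#' Executes build, per-window umbrella sampling, WHAM reconstruction and —
#' when frames are recorded (`sampling.frame_stride > 0`) — the
#' conformational/ionic analyses, writing every artifact under `out_dir`:
#' the serialized configuration, initial structures (PDB/XYZ), per-window
#' series files, the effective-potential TSV with overlap diagnostics,
#' analysis tables and a JSON summary, plus a manifest listing every
#' artifact with its MD5 checksum. A failed stage leaves a manifest that
#' records partial completion before the error is rethrown.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; overrides `cfg$sampling$seed` when non-NULL.
#' @param quiet Suppress progress messages.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, seed = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) cfg$sampling$seed <- as.integer(seed)
  seed <- as.integer(cfg$sampling$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("dnapairpmf")),
                   seed = seed, stages = character(0), files = list())
  add_file <- function(path) {
    manifest$files[[length(manifest$files) + 1]] <<-
      list(path = sub(paste0("^", out_dir, "/?"), "", path),
           md5 = unname(tools::md5sum(path)))
  }
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(flush_manifest())

  save_config(cfg, file.path(out_dir, "config.yaml"))
  add_file(file.path(out_dir, "config.yaml"))

  ff <- config_forcefield(cfg)
  sched <- config_schedule(cfg)
  centers <- vapply(sched$windows, function(w) w$center, 0)

  # ---- build -------------------------------------------------------------
  say("build: %s pair, %d windows", cfg$system$topology,
      length(sched$windows))
  state0 <- build_system(cfg, centers[1], seed = seed)
  dir.create(file.path(out_dir, "structures"), showWarnings = FALSE)
  p_pdb <- file.path(out_dir, "structures", "initial.pdb")
  p_xyz <- file.path(out_dir, "structures", "initial.xyz")
  write_pdb(state0, p_pdb)
  write_xyz(system_positions(state0), p_xyz, box = state0$box,
            labels = c(rep("A", state0$molecule_a$n_bp),
                       rep("B", state0$molecule_b$n_bp),
                       rep("I", length(state0$ion_charges))))
  add_file(p_pdb); add_file(p_xyz)
  manifest$stages <- c(manifest$stages, "build")

  # ---- sample ------------------------------------------------------------
  dir.create(file.path(out_dir, "windows"), showWarnings = FALSE)
  sa <- cfg$sampling
  records <- vector("list", length(sched$windows))
  list_lines <- character(0)
  for (i in seq_along(sched$windows)) {
    w <- sched$windows[[i]]
    wi_seed <- seed + i
    st <- build_system(cfg, w$center, seed = wi_seed)
    records[[i]] <- run_window(st, ff, w,
                               n_equil_sweeps = sa$n_equil_sweeps,
                               n_prod_sweeps = sa$n_prod_sweeps,
                               sample_stride = sa$sample_stride,
                               seed = wi_seed,
                               frame_stride = sa$frame_stride)
    fn <- sprintf("window_%03d.tsv", i)
    fp <- file.path(out_dir, "windows", fn)
    write_window_series(records[[i]], fp)
    add_file(fp)
    list_lines <- c(list_lines,
                    sprintf("%s %s %s", fn, fmt_num(w$center),
                            fmt_num(w$force_k)))
    if (sa$frame_stride > 0) {
      fx <- file.path(out_dir, "windows", sprintf("window_%03d.xyz", i))
      write_xyz(records[[i]]$frames, fx, box = st$box)
      add_file(fx)
    }
    say("sample: window %d/%d (center %.2f nm, %d samples)", i,
        length(sched$windows), w$center, length(records[[i]]$rc_series))
  }
  meta_path <- file.path(out_dir, "windows", "metadata.list")
  writeLines(list_lines, meta_path)
  add_file(meta_path)
  manifest$stages <- c(manifest$stages, "sample")

  # ---- wham --------------------------------------------------------------
  say("wham: reconstructing V_eff(r)")
  edges <- config_bin_edges(cfg)
  hists <- lapply(records, histogram_window, bin_edges = edges)
  sol <- solve_wham(hists, temperature = cfg$forcefield$temperature,
                    tol = cfg$wham$tol, max_iter = cfg$wham$max_iter)
  prof <- pmf_from_density(sol$density, sol$bin_centers,
                           reference_r = cfg$wham$reference_r,
                           temperature = cfg$forcefield$temperature)
  p_pmf <- file.path(out_dir, "pmf.tsv")
  write_pmf_tsv(prof, p_pmf); add_file(p_pmf)
  if (length(hists) >= 2) {
    ov <- overlap_diagnostic(hists)
    p_ov <- file.path(out_dir, "overlap.tsv")
    utils::write.table(ov, p_ov, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(p_ov)
  }
  manifest$stages <- c(manifest$stages, "wham")

  # ---- analyze -----------------------------------------------------------
  summary_json <- list()
  if (sa$frame_stride > 0) {
    say("analyze: orientation, RMSF, g(r)")
    dir.create(file.path(out_dir, "analysis"), showWarnings = FALSE)
    mode <- if (cfg$system$topology == "ring") "smallest" else "largest"
    orient <- do.call(rbind, lapply(records, function(rec) {
      if (length(rec$frames) == 0) return(NULL)
      orientation_samples(rec, mode = mode)
    }))
    if (!is.null(orient) && nrow(orient) >= 2) {
      p_or <- file.path(out_dir, "analysis", "orientation.tsv")
      utils::write.table(orient, p_or, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(p_or)
      kde <- tryCatch(
        kde2d_field(orient$r, orient$theta,
                    grid_r = seq(min(centers) - 0.2, max(centers) + 0.2,
                                 length.out = cfg$analysis$kde_n_r),
                    grid_theta = seq(0, 90,
                                     length.out = cfg$analysis$kde_n_theta)),
        error = function(e) NULL)
      if (!is.null(kde)) {
        kg <- expand.grid(r = kde$grid_r, theta = kde$grid_theta)
        kg$density <- as.vector(kde$density)
        p_kde <- file.path(out_dir, "analysis", "kde.tsv")
        utils::write.table(kg, p_kde, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        add_file(p_kde)
      }
    }
    rec1 <- records[[1]]
    nA <- rec1$n_dna[1]; nB <- rec1$n_dna[2]
    if (length(rec1$frames) >= 2 && nA >= 3) {
      ref <- build_system(cfg, centers[1], seed = seed + 1L)
      rp <- rmsf_profile(rec1$frames, system_positions(ref),
                         selection = seq_len(nA))
      p_rmsf <- file.path(out_dir, "analysis", "rmsf.tsv")
      utils::write.table(rp, p_rmsf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(p_rmsf)
    }
    n_ion <- length(rec1$final_state$ion_charges)
    if (n_ion > 0 && length(rec1$frames) >= 1) {
      qs <- system_charges(rec1$final_state)
      dna_idx <- seq_len(nA + nB)
      cat_idx <- which(qs > 0)
      curve <- rdf(rec1$frames, dna_idx, cat_idx,
                   bin_width = cfg$analysis$rdf_bin_width,
                   r_max = cfg$analysis$rdf_r_max,
                   box = rec1$final_state$box)
      p_rdf <- file.path(out_dir, "analysis", "rdf_cation_dna.tsv")
      utils::write.table(curve, p_rdf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(p_rdf)
      rs <- first_shell_radius(curve)
      summary_json$cation_dna_first_shell_radius_nm <- rs
      summary_json$cation_dna_coordination <- coordination_number(curve, rs)
    }
    summary_json$n_windows <- length(records)
    summary_json$n_frames <- sum(vapply(records,
                                        function(r) length(r$frames), 0L))
    p_sum <- file.path(out_dir, "analysis", "summary.json")
    jsonlite::write_json(summary_json, p_sum, auto_unbox = TRUE, digits = NA)
    add_file(p_sum)
    manifest$stages <- c(manifest$stages, "analyze")
  }

  log_path <- file.path(out_dir, "log.txt")
  writeLines(c(
    sprintf("dnapairpmf %s", manifest$package_version),
    sprintf("R %s", as.character(getRversion())),
    sprintf("master seed %d (per-window seeds seed + window index)", seed),
    sprintf("stages: %s", paste(manifest$stages, collapse = ", "))),
    log_path)
  add_file(log_path)
  flush_manifest()
  invisible(manifest)
}
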