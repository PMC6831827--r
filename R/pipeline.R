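#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]:
#' sequence source (`NULL` for the packaged fixture), region annotations,
#' build parameters, analysis toggles, an optional measured-data path,
#' simulation and refinement settings, output directory and the global
#' seed. Stage seeds are derived from the global seed by fixed offsets so
#' stages are independently reproducible.
#'
#' @param seed Global seed.
#' @param out_dir Output directory for artifacts (`NULL`: nothing written).
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sequence_fasta = NULL,        # NULL -> packaged fixture
    construct = c(22L, 187L),
    regions = jip_regions(),
    build = list(crick = crick_params(register_phase = "f"),
                 bundle = bundle_geometry()),
    analysis = list(guinier = TRUE, kratky = TRUE, pr = TRUE, mass = TRUE,
                    hydro = TRUE),
    data_path = NULL,             # measured 3-column ASCII curve, if any
    data_q_unit = "A^-1",
    simulate = list(enabled = TRUE, snr = 100, floor_frac = 0.01,
                    n_points = 500),
    refine = list(enabled = FALSE, population = 16, generations = 25,
                  n_runs = 2, mutation_deg = 10),
    ensemble = list(enabled = FALSE, n_pool = 300, n_select = 20,
                    n_cycles = 20, n_runs = 5)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks file existence, range consistency and (when data are supplied)
#' unit plausibility. Returns a tibble of diagnostics; an empty tibble
#' means the configuration is clean.
#'
#' @param cfg A [default_config()]-style list.
#' @return Tibble with columns `level` ("error"/"warning") and `message`.
#' @export
validate_config <- function(cfg) {
  out <- list()
  note <- function(level, msg) out[[length(out) + 1]] <<- tibble(level = level, message = msg)
  if (!is.null(cfg$sequence_fasta) && !file.exists(cfg$sequence_fasta)) {
    note("error", sprintf("sequence FASTA not found: %s", cfg$sequence_fasta))
  }
  if (!is.null(cfg$data_path) && !file.exists(cfg$data_path)) {
    note("error", sprintf("data file not found: %s", cfg$data_path))
  }
  reg <- cfg$regions
  if (!is.null(reg)) {
    bad <- reg$start > reg$end
    if (any(bad)) {
      note("error", sprintf("inverted region(s): %s",
                            paste(reg$name[bad], collapse = ", ")))
    }
  }
  rigid <- list(c(26, 66), c(78, 176))
  flex <- list(c(19, 25), c(67, 77), c(177, 187))
  cov <- c(unlist(lapply(rigid, function(r) r[1]:r[2])),
           unlist(lapply(flex, function(r) r[1]:r[2])))
  if (anyDuplicated(cov)) note("error", "rigid/flexible ranges overlap")
  if (!is.null(cfg$data_path) && file.exists(cfg$data_path)) {
    cur <- tryCatch(read_saxs(cfg$data_path, q_unit = cfg$data_q_unit),
                    error = function(e) NULL)
    if (is.null(cur)) {
      note("error", sprintf("cannot parse data file %s", cfg$data_path))
    } else {
      g <- tryCatch(guinier_fit(cur), error = function(e) NULL)
      if (!is.null(g) && (g$rg < 10 || g$rg > 1000)) {
        note("warning", sprintf(
          "implausible Guinier Rg %.3g A: check q units (nm^-1 input needs data_q_unit = 'nm^-1')",
          g$rg))
      }
    }
  }
  if (length(out) == 0) {
    tibble(level = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Run the full modelling and SAXS analysis pipeline
#'
#' Build -> predict -> compare -> (optionally) refine -> report, as one
#' deterministic run: assembles the RH1-LZI dimer model, measures its
#' dimensions, predicts hydrodynamics, obtains a scattering curve (a
#' packaged-fixture simulation or a measured file), runs Guinier /
#' dimensionless Kratky / P(r) / Porod-mass analyses, scores the model
#' against the curve and, if enabled, refines it and characterizes linker
#' flexibility by ensemble selection. Artifacts (PDB, curves, TSV tables)
#' are written under `cfg$out_dir` when set.
#'
#' @param cfg A [default_config()]-style configuration.
#' @return A `run_report` list; numeric entries carry units in their
#'   names.
#' @export
run_pipeline <- function(cfg = default_config()) {
  diags <- validate_config(cfg)
  if (any(diags$level == "error")) {
    abort(paste("invalid config:", paste(diags$message, collapse = "; ")))
  }
  report <- list(seed = cfg$seed, stages = character())
  stage <- function(nm) report$stages <<- c(report$stages, nm)

  # --- build ---
  seqs <- if (is.null(cfg$sequence_fasta)) {
    fixture_sequences()$jip3
  } else {
    read_fasta(cfg$sequence_fasta)[[1]]
  }
  construct <- construct_record(seqs, cfg$construct[1], cfg$construct[2])
  model <- assemble_rh1_lzi_dimer(construct, cfg$build$crick, cfg$build$bundle)
  stage("build")
  report$model <- list(
    n_centers = nrow(model),
    max_extent_a = max_extent(model),
    lzi_axial_length_a = axial_length(model, 74, 177),
    bundle_axial_length_a = axial_length(model, 26, 73),
    thickness_a = model_thickness(model),
    rg_coord_a = model_rg(model),
    symmetry_rmsd_a = dimer_symmetry_rmsd(model)
  )

  # --- hydrodynamics ---
  if (isTRUE(cfg$analysis$hydro)) {
    h <- hydro_predict(model)
    report$hydro <- list(rg_a = h$rg_a, rh_nm = h$rh_nm, s_sved = h$s_sved,
                         f_ratio = h$f_ratio, mass_kda = h$mass_kda)
    stage("hydro")
  }

  # --- data: measured or simulated ---
  curve <- NULL
  if (!is.null(cfg$data_path)) {
    curve <- read_saxs(cfg$data_path, q_unit = cfg$data_q_unit)
    stage("read_data")
  } else if (isTRUE(cfg$simulate$enabled)) {
    curve <- simulate_curve(
      model, instrument_setup(n_points = cfg$simulate$n_points),
      noise_model(snr = cfg$simulate$snr, floor_frac = cfg$simulate$floor_frac),
      seed = cfg$seed + 101L)
    stage("simulate")
  }

  if (!is.null(curve)) {
    g <- guinier_fit(curve)
    if (isTRUE(cfg$analysis$guinier)) {
      report$guinier <- list(rg_a = g$rg, i0 = g$i0, qmin = g$qmin,
                             qmax = g$qmax, qrg_max = g$qrg_max, r2 = g$r2)
      stage("guinier")
    }
    if (isTRUE(cfg$analysis$kratky)) {
      k <- dimensionless_kratky(curve, rg = g$rg, i0 = g$i0)
      pk <- kratky_peak(k)
      report$kratky <- list(peak_qrg = pk$qrg, peak_height = pk$height)
      stage("kratky")
    }
    if (isTRUE(cfg$analysis$pr)) {
      prs <- pr_from_structure(model)
      report$pr_model <- pr_summary(prs)
      ift <- ift_pr(curve, dmax = max_extent(model) + 10)
      report$pr_data <- c(pr_summary(ift), list(chi2 = attr(ift, "chi2")))
      stage("pr")
    }
    if (isTRUE(cfg$analysis$mass)) {
      mw <- porod_mow_mass(curve, g)
      report$mass <- list(mass_kda = mw$mass_kda,
                          apparent_volume_a3 = mw$apparent_volume,
                          q_m = mw$q_m)
      stage("mass")
    }
    mcurve <- debye_intensity(model, curve$q, form_factor = "sphere")
    fit0 <- chi2_fit(curve, mcurve)
    report$fit <- list(chi2_initial = fit0$chi2, scale = fit0$scale)
    stage("fit")

    if (isTRUE(cfg$refine$enabled)) {
      rs <- refinement_settings(population = cfg$refine$population,
                                generations = cfg$refine$generations,
                                mutation_deg = cfg$refine$mutation_deg,
                                seed = cfg$seed + 201L,
                                n_runs = cfg$refine$n_runs)
      rr <- refine_against_saxs(model, curve, settings = rs)
      report$refine <- list(chi2_initial = rr$chi2_initial,
                            chi2_final = rr$chi2_final,
                            rg_best_a = rr$rg_best,
                            hinge_deg = rr$runs$hinge_deg[rr$runs$run == rr$winner_run])
      model_refined <- rr$best
      stage("refine")
    } else model_refined <- NULL

    if (isTRUE(cfg$ensemble$enabled)) {
      pool <- generate_pool(model, n = cfg$ensemble$n_pool,
                            seed = cfg$seed + 301L)
      es <- ensemble_settings(n_select = cfg$ensemble$n_select,
                              n_cycles = cfg$ensemble$n_cycles,
                              n_runs = cfg$ensemble$n_runs,
                              seed = cfg$seed + 401L)
      sel <- select_ensemble(pool, curve, es)
      report$ensemble <- list(chi2 = sel$chi2,
                              mean_rg_selected_a = sel$mean_rg_selected,
                              mean_rg_pool_a = sel$mean_rg_pool)
      stage("ensemble")
    }
  }

  # --- artifacts ---
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb(model, file.path(cfg$out_dir, "rh1_lzi_model.pdb"))
    if (!is.null(curve)) {
      write_saxs(curve, file.path(cfg$out_dir, "curve.dat"),
                 comment = sprintf("# seed %d", cfg$seed))
    }
    if (exists("model_refined") && !is.null(model_refined)) {
      write_pdb(model_refined, file.path(cfg$out_dir, "rh1_lzi_refined.pdb"))
    }
    flat <- report_flat(report)
    utils::write.table(flat, file.path(cfg$out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(report, class = "run_report")
}

report_flat <- function(report) {
  rows <- list()
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(v)) walk(v, key)
      else if (is.numeric(v) && length(v) == 1) {
        rows[[length(rows) + 1]] <<- tibble(key = key, value = v)
      }
    }
  }
  walk(report[setdiff(names(report), "stages")], "")
  dplyr::bind_rows(rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(x$stages, collapse = " -> "), "\n")
  flat <- report_flat(x)
  for (i in seq_len(nrow(flat))) {
    cat(sprintf("  %-28s %.6g\n", flat$key[i], flat$value[i]))
  }
  invisible(x)
}

#' Flatten a run report to a tibble
#' @param x A `run_report`.
#' @param ... Unused.
#' @return Tibble with `key` and `value` columns.
#' @exportS3Method tibble::as_tibble
as_tibble.run_report <- function(x, ...) report_flat(x)
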