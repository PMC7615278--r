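#' Configuration for the full analysis
#'
#' Collects every tunable of the pipeline with defaults equal to the module
#' defaults, so a report can name exactly what was applied. With no
#' structure file the pipeline runs on the synthetic crystal stand-in
#' generated from `seed`.
#'
#' @param structure_file optional PDB/mmCIF path providing the dimers.
#' @param dimer1_chains,dimer2_chains length-2 chain ids of the two dimers
#'   (used with `structure_file`).
#' @param tem_image optional `fl_density` micrograph; if `NULL` a synthetic
#'   lattice image is generated from the model itself.
#' @param seed integer seed for every stochastic stage.
#' @param probe,n_points SASA parameters.
#' @param burial_threshold Angstrom^2 for counting a buried residue.
#' @param salt_bridge_cutoff,hbond_cutoff,stacking_cutoff contact cutoffs
#'   (Angstrom).
#' @param reject_cutoff iterative superposition trim cutoff (Angstrom).
#' @param clash_cutoff Angstrom.
#' @param row_shift_nm lattice row translation (default 3.9).
#' @param pixel_size,sigma density projection parameters (nm, Angstrom).
#' @param n_orders reciprocal orders kept in lattice averaging.
#' @param image_cells synthetic micrograph size in cells per axis.
#' @param image_noise_sd synthetic micrograph noise (fraction of motif max).
#' @param with_trajectory also run the trajectory stage (default `TRUE`).
#' @param output_dir optional directory for the JSON report and the lattice
#'   PDB model.
#' @return A list of class `fl_config`.
#' @export
run_config <- function(structure_file = NULL,
                       dimer1_chains = c("A", "B"),
                       dimer2_chains = c("A", "B"),
                       tem_image = NULL,
                       seed = 1,
                       probe = 1.4, n_points = 960,
                       burial_threshold = 1.0,
                       salt_bridge_cutoff = 4.0,
                       hbond_cutoff = 3.5,
                       stacking_cutoff = 6.0,
                       reject_cutoff = 3.5,
                       clash_cutoff = 2.5,
                       row_shift_nm = 3.9,
                       pixel_size = 0.2, sigma = 4.0,
                       n_orders = 3,
                       image_cells = c(12, 12),
                       image_noise_sd = 1.0,
                       with_trajectory = TRUE,
                       output_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "fl_config"
  cfg
}

#' Run the full interface-to-lattice analysis
#'
#' Executes the stages in order: structure input (file or synthetic
#' stand-in), dimer interface characterization, two-fold transform
#' extraction, zigzag/lattice construction with clash check and cell
#' measurement, density projection, lattice-image averaging and model
#' scoring, and (optionally) the synthetic trajectory + PMF stage. Any
#' stage failure aborts with the stage name; results computed so far are
#' attached to the error condition.
#'
#' @param config an `fl_config` from [run_config()].
#' @return A list of class `fl_report` with one element per stage plus
#'   `parameters` (the config) and `correlation` (the final score).
#' @export
run_full_analysis <- function(config = run_config()) {
  results <- list(parameters = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  results$input <- stage("input", {
    if (!is.null(config$structure_file)) {
      st <- read_structure(config$structure_file)
      list(dimer1 = select_atoms(st, chain = config$dimer1_chains),
           dimer2 = select_atoms(st, chain = config$dimer2_chains),
           monomer = select_atoms(st, chain = config$dimer1_chains[1]),
           synthetic = FALSE)
    } else {
      cs <- make_crystal_standin(seed = config$seed)
      c(cs, list(synthetic = TRUE))
    }
  })

  ch1 <- if (results$input$synthetic) c("A", "B") else config$dimer1_chains
  ch2 <- if (results$input$synthetic) c("A", "B") else config$dimer2_chains

  results$interface <- stage("interface", {
    list(dimer1 = interface_report(results$input$dimer1, ch1[1], ch1[2],
                                   burial_threshold = config$burial_threshold,
                                   probe = config$probe,
                                   n_points = config$n_points),
         dimer2 = interface_report(results$input$dimer2, ch2[1], ch2[2],
                                   burial_threshold = config$burial_threshold,
                                   probe = config$probe,
                                   n_points = config$n_points))
  })

  results$lattice <- stage("lattice", {
    t1 <- extract_dimer_transform(results$input$dimer1, ch1[1], ch1[2])
    t2 <- extract_dimer_transform(results$input$dimer2, ch2[1], ch2[2])
    # both two-fold operations must act on one shared reference monomer
    # (the stand-in dimers are built around the same monomer placement;
    # dimers read from a file are aligned first, as in building a trimer)
    if (!results$input$synthetic) {
      u <- iterative_superpose(results$input$dimer2, ch2[1],
                               results$input$dimer1, ch1[1],
                               reject_cutoff = config$reject_cutoff)
      t2 <- conjugate_dimer_transform(t2, u$transform)
    }
    mono <- results$input$monomer
    mono$chain <- "A"
    zz <- build_zigzag(mono, t1, t2, n_copies = 4)
    trimer <- build_zigzag(mono, t1, t2, n_copies = 3)
    clashes <- detect_clashes(trimer, cutoff = config$clash_cutoff)
    lat <- build_lattice(zz, default_row_shift(zz, b_nm = config$row_shift_nm),
                         n_rows = 2)
    cell <- measure_unit_cell(lat)
    list(t1 = t1, t2 = t2, zigzag = zz, trimer_clashes = clashes,
         lattice = lat, cell = cell)
  })

  results$density <- stage("density", {
    lat <- results$lattice$lattice
    proj <- project_density(lat, plane_normal = lat$plane_normal,
                            pixel_size = config$pixel_size,
                            sigma = config$sigma)
    motif <- fold_to_cell(proj, c(lat$cell_a, lat$cell_b), n_tiles = 2)
    list(projection = proj, model_patch = motif)
  })

  results$tem <- stage("tem", {
    lat <- results$lattice$lattice
    cell <- c(lat$cell_a, lat$cell_b)
    img <- config$tem_image %||%
      make_lattice_image(results$density$projection, cell,
                         n_cells = config$image_cells,
                         noise_sd = config$image_noise_sd,
                         seed = config$seed + 10)
    peaks <- find_reciprocal_peaks(img, expected_cell = cell,
                                   n_orders = config$n_orders)
    avg <- average_unit_cell(img, peaks)
    score <- score_model(avg, results$density$model_patch)
    list(image = img, peaks = peaks, cell_average = avg, score = score)
  })
  results$correlation <- results$tem$score

  if (isTRUE(config$with_trajectory)) {
    results$trajectory <- stage("trajectory", {
      tr <- make_trajectory(n_frames = 5000, seed = config$seed + 20)
      truth <- tr$truth
      occ <- contact_occupancy(tr$frames, attr(truth, "contact_i"),
                               attr(truth, "contact_j"),
                               cutoff = config$salt_bridge_cutoff)
      ori <- orientation_series(tr$frames, tail_sel = 1L, head_sel = 2L)
      sep <- separation_series(tr$frames, attr(truth, "sel_a"),
                               attr(truth, "sel_b"))
      ev <- detect_dissociation(sep, baseline_window = 200)
      pmf <- make_pmf(depth = 10, width = 0.3)
      dg <- delta_g_bind(pmf, r_bound_max = 0.3 - 0.005)
      list(occupancy = occ, orientation = ori, separation = sep,
           dissociation_frame = ev, pmf = pmf, delta_g = dg)
    })
  }

  class(results) <- "fl_report"
  if (!is.null(config$output_dir)) write_report(results, config$output_dir)
  results
}

#' @export
print.fl_report <- function(x, ...) {
  cat("<analysis report>\n")
  cat(sprintf("  interface: dimer1 %.0f A^2 (%d/%d buried), dimer2 %.0f A^2 (%d/%d)\n",
              x$interface$dimer1$buried_area_avg,
              x$interface$dimer1$buried_count[1], x$interface$dimer1$buried_count[2],
              x$interface$dimer2$buried_area_avg,
              x$interface$dimer2$buried_count[1], x$interface$dimer2$buried_count[2]))
  cat(sprintf("  lattice: repeat %.2f nm, cell %.2f x %.2f nm (%.1f deg), %d clashes\n",
              x$lattice$zigzag$repeat_length, x$lattice$cell$a, x$lattice$cell$b,
              x$lattice$cell$angle, nrow(x$lattice$trimer_clashes)))
  cat(sprintf("  correlation vs lattice image: r = %.3f\n", x$correlation$r))
  if (!is.null(x$trajectory))
    cat(sprintf("  trajectory: occupancy %.3f, dG %.2f +/- %.2f kcal/mol\n",
                x$trajectory$occupancy, x$trajectory$delta_g$dg,
                x$trajectory$delta_g$dg_err))
  invisible(x)
}

#' Summarize a report as one tibble row
#' @param x an `fl_report`.
#' @param ... unused.
#' @export
glance.fl_report <- function(x, ...) {
  tibble::tibble(
    dimer1_buried_area = x$interface$dimer1$buried_area_avg,
    dimer2_buried_area = x$interface$dimer2$buried_area_avg,
    repeat_nm = x$lattice$zigzag$repeat_length,
    cell_a_nm = x$lattice$cell$a,
    cell_b_nm = x$lattice$cell$b,
    cell_angle_deg = x$lattice$cell$angle,
    n_trimer_clashes = nrow(x$lattice$trimer_clashes),
    correlation_r = x$correlation$r,
    occupancy = if (!is.null(x$trajectory)) x$trajectory$occupancy else NA_real_,
    delta_g = if (!is.null(x$trajectory)) x$trajectory$delta_g$dg else NA_real_)
}

# JSON + PDB outputs; every applied parameter is named in the report.
write_report <- function(results, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- results$parameters
  pars$tem_image <- NULL
  pars <- pars[!vapply(pars, is.null, logical(1))]
  out <- list(parameters = pars,
              summary = as.list(glance(results)),
              interface = list(
                dimer1 = as.list(glance(results$interface$dimer1)),
                dimer2 = as.list(glance(results$interface$dimer2))),
              correlation = as.list(glance(results$correlation)))
  jsonlite::write_json(out, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_structure(expand_lattice(results$lattice$lattice),
                  file.path(output_dir, "lattice_model.pdb"))
  invisible(output_dir)
}
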