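# Configuration-driven end-to-end analysis producing a tidy observable
# report (thickness, diffusion, packing, potential difference, order
# parameters, chain distances), plus a multi-system comparison.

default_observables <- c("density", "thickness", "packing", "diffusion",
                         "order", "potential", "distances", "rdf")

#' Run the full bilayer analysis
#'
#' Executes the enabled observables in dependency order over one
#' trajectory and collects every result, with its uncertainty and the
#' method/convention that produced it, into one report. Stages fail
#' independently: an error in one observable is recorded and the rest
#' still run.
#'
#' @param x A [bl_trajectory], or a config: a named list (or YAML path)
#'   with entries `structure`, `trajectory`, `species_map` (file paths),
#'   and optionally `window` (ps), `observables`, `bin_width`,
#'   `smooth_window`, `n_blocks`, `fit_window`, `dv_convention`,
#'   `rdf_dr`, `pairs`, `rdf_selections`, `system`, `output_dir`.
#' @param observables Character subset of
#'   `r paste(default_observables, collapse = ", ")`.
#' @param system Label for the analysed system.
#' @param bin_width Profile bin width, nm (default 0.05).
#' @param smooth_window Peak-finding smoothing window, bins (default 5).
#' @param n_blocks Blocks for uncertainties (default 5).
#' @param fit_window MSD fit window as fractions of max lag.
#' @param dv_convention Potential-difference convention (see
#'   [potential_difference()]).
#' @param rdf_dr RDF bin width, nm (default 0.002).
#' @param rdf_mode RDF mode (default `"lateral"`: layered selections such
#'   as headgroups call for per-leaflet in-plane correlations).
#' @param pairs Intramolecular pair list (see
#'   [intramolecular_distances()]); default pairs built from the chain
#'   roles present.
#' @param rdf_selections Named character vector of selection expressions
#'   for intermolecular RDFs (default head/terminal/unsaturated labels).
#' @param output_dir If non-NULL, write the report JSON and TSV tables
#'   there.
#' @return A `bl_report`.
#' @export
run_bilayer_analysis <- function(x, observables = default_observables,
                                 system = "system", bin_width = 0.05,
                                 smooth_window = 5, n_blocks = 5,
                                 fit_window = c(0.1, 0.5),
                                 dv_convention = "center_vs_bulk",
                                 rdf_dr = 0.002, rdf_mode = "lateral",
                                 pairs = NULL,
                                 rdf_selections = NULL, output_dir = NULL) {
  if (!inherits(x, "bl_trajectory")) {
    cfg <- if (is.character(x)) yaml::read_yaml(x) else x
    for (p in c("structure", "trajectory", "species_map")) {
      if (is.null(cfg[[p]])) rlang::abort(paste0("config lacks '", p, "'"))
      if (!file.exists(cfg[[p]])) {
        rlang::abort(paste0("config file does not exist: ", cfg[[p]]))
      }
    }
    call_args <- cfg[intersect(names(cfg),
                               setdiff(names(formals(run_bilayer_analysis)),
                                       "x"))]
    # arguments given explicitly in this call override the config file
    supplied <- as.list(match.call())[-(1:2)]
    supplied <- lapply(supplied, eval, envir = parent.frame())
    call_args <- utils::modifyList(call_args, supplied)
    st <- read_structure(cfg$structure, cfg$species_map)
    traj <- load_trajectory(st$topology, cfg$trajectory,
                            window = if (!is.null(cfg$window))
                              as.numeric(cfg$window))
    return(do.call(run_bilayer_analysis, c(list(x = traj), call_args)))
  }

  bad <- setdiff(observables, default_observables)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown observable(s): ", paste(bad, collapse = ", ")))
  }
  traj <- assign_leaflets(x)
  atoms <- traj$topology$atoms

  values <- tibble::tibble(observable = character(), value = numeric(),
                           stderr = numeric(), unit = character(),
                           method = character())
  add_value <- function(obs, value, stderr, unit, method) {
    values <<- dplyr::bind_rows(values, tibble::tibble(
      observable = obs, value = value, stderr = stderr, unit = unit,
      method = method))
  }
  report <- list(system = system, errors = character(),
                 settings = list(bin_width = bin_width,
                                 smooth_window = smooth_window,
                                 n_blocks = n_blocks,
                                 fit_window = fit_window,
                                 dv_convention = dv_convention,
                                 rdf_dr = rdf_dr,
                                 window_ps = traj$window))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors <<- c(report$errors,
                          paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  profiles <- list()
  if ("density" %in% observables) {
    stage("density", {
      profiles$head_number <- z_profile(traj, role == "head",
                                        bin_width = bin_width)
      profiles$tail_number <- z_profile(traj, role %in% c("sn1", "sn2"),
                                        bin_width = bin_width)
    })
  }
  if ("thickness" %in% observables) {
    stage("thickness", {
      th <- bilayer_thickness(traj, bin_width = bin_width,
                              smooth_window = smooth_window,
                              n_blocks = n_blocks)
      add_value("thickness", th$thickness, th$uncertainty, "nm",
                "headgroup density peak-to-peak")
      report$thickness <- th
    })
  }
  if ("packing" %in% observables) {
    stage("packing", {
      pk <- packing_density(traj, n_blocks = n_blocks)
      add_value("packing_density", pk$packing_density, pk$uncertainty,
                "nm^-2", "1 / area per lipid")
      add_value("area_per_lipid", pk$apl, NA_real_, "nm^2",
                "<lx ly> / n_leaflet")
      report$packing <- pk
    })
  }
  if ("diffusion" %in% observables) {
    stage("diffusion", {
      tracks <- unwrap_lateral(traj)
      msd <- lateral_msd(tracks)
      dc <- diffusion_coefficient(msd, fit_window = fit_window)
      add_value("diffusion_coefficient", dc$d_cm2_s / 1e-7,
                dc$uncertainty / 1e-7, "1e-7 cm^2/s",
                "Einstein relation, lateral MSD slope / 4")
      report$msd <- msd
      report$diffusion <- dc
    })
  }
  if ("order" %in% observables) {
    stage("order", {
      report$s_cd <- structure(
        dplyr::bind_rows(scd_profile(traj, "sn1", n_blocks = n_blocks),
                         scd_profile(traj, "sn2", n_blocks = n_blocks)),
        class = c("bl_order_profile", class(tibble::tibble())))
    })
  }
  if ("potential" %in% observables) {
    stage("potential", {
      chg <- z_profile(traj, bin_width = bin_width, quantity = "charge")
      pot <- electrostatic_potential(chg)
      dv <- potential_difference(pot, dv_convention)
      add_value("potential_difference", dv, NA_real_, "V", dv_convention)
      profiles$charge <- chg
      profiles$potential <- pot$profile
      report$potential <- pot
    })
  }
  if ("distances" %in% observables) {
    stage("distances", {
      if (is.null(pairs)) pairs <- default_pairs(atoms)
      report$intra <- intramolecular_distances(traj, pairs,
                                               n_blocks = n_blocks)
    })
  }
  if ("rdf" %in% observables) {
    stage("rdf", {
      if (is.null(rdf_selections)) {
        rdf_selections <- default_rdf_selections(atoms)
      }
      peaks <- purrr::imap_dfr(rdf_selections, function(expr_str, nm) {
        sel <- rlang::parse_expr(expr_str)
        r <- rlang::inject(rdf(traj, !!sel, !!sel, dr = rdf_dr,
                               mode = rdf_mode))
        tibble::tibble(selection = nm,
                       first_peak_nm = first_peak_distance(r, smooth_window))
      })
      report$rdf_peaks <- peaks
    })
  }

  report$values <- values
  report$profiles <- profiles
  report <- structure(report, class = "bl_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

default_pairs <- function(atoms) {
  chain <- atoms[atoms$role %in% c("sn1", "sn2"), ]
  if (nrow(chain) == 0) return(list())
  m <- max(chain$carbon, na.rm = TRUE)
  p <- list(terminal_terminal = list(list(role = "sn1", carbon = m),
                                     list(role = "sn2", carbon = m)))
  if (any(atoms$label == "unsaturated")) {
    ku <- unique(chain$carbon[chain$label == "unsaturated"])[1]
    p$unsat_unsat <- list(list(role = "sn1", carbon = ku),
                          list(role = "sn2", carbon = ku))
  }
  p
}

default_rdf_selections <- function(atoms) {
  sels <- c(head = 'role == "head"')
  if (any(atoms$label == "terminal")) {
    sels <- c(sels, terminal = 'label == "terminal"')
  }
  if (any(atoms$label == "unsaturated")) {
    sels <- c(sels, unsaturated = 'label == "unsaturated"')
  }
  sels
}

#' @export
print.bl_report <- function(x, ...) {
  cat("<bl_report> system:", x$system, "\n")
  print(x$values)
  if (length(x$errors) > 0) {
    cat("stage errors:\n")
    for (e in x$errors) cat(" -", e, "\n")
  }
  invisible(x)
}

#' Write a report to disk (JSON + TSV tables)
#'
#' @param report A `bl_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(system = report$system,
              settings = report$settings,
              values = report$values,
              errors = report$errors)
  if (!is.null(report$s_cd)) out$s_cd <- as.data.frame(report$s_cd)
  if (!is.null(report$intra)) out$intra <- as.data.frame(report$intra)
  if (!is.null(report$rdf_peaks)) out$rdf_peaks <- as.data.frame(report$rdf_peaks)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$values, file.path(dir, "observables.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$s_cd)) {
    write_order_tsv(report$s_cd, file.path(dir, "s_cd.tsv"))
  }
  if (!is.null(report$msd)) {
    write_msd_tsv(report$msd, file.path(dir, "msd.tsv"))
  }
  for (nm in names(report$profiles)) {
    write_profile_tsv(report$profiles[[nm]],
                      file.path(dir, paste0("profile_", nm, ".tsv")))
  }
  invisible(dir)
}

#' Read a report back from JSON
#' @param path `report.json` file.
#' @return A `bl_report` (tables only; profile objects are not restored).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$values <- tibble::as_tibble(raw$values)
  structure(raw, class = "bl_report")
}

#' Compare observable reports across systems
#'
#' Ranks systems per observable and flags whether each gap to the
#' next-ranked system exceeds the combined standard errors — an
#' uncertainty-aware ordering of, e.g., a thicker/tighter-packed system
#' over another.
#'
#' @param reports List of `bl_report` objects (>= 2), optionally named.
#' @return A tibble: `observable`, `system`, `value`, `stderr`, `rank`,
#'   `gap_to_next`, `significant`.
#' @export
compare_systems <- function(reports) {
  if (length(reports) < 2) rlang::abort("need at least 2 reports to compare")
  nms <- names(reports)
  if (is.null(nms)) nms <- vapply(reports, function(r) r$system, character(1))
  tall <- purrr::map2_dfr(reports, nms, function(r, nm) {
    dplyr::mutate(r$values, system = nm)
  })
  obs_sets <- lapply(reports, function(r) r$values$observable)
  common <- Reduce(intersect, obs_sets)
  if (length(unique(lapply(obs_sets, sort))) > 1) {
    rlang::warn("reports carry different observable sets; comparing the intersection")
  }
  tall |>
    dplyr::filter(.data$observable %in% common) |>
    dplyr::group_by(.data$observable) |>
    dplyr::arrange(dplyr::desc(.data$value), .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      gap_to_next = .data$value - dplyr::lead(.data$value),
      significant = .data$gap_to_next >
        sqrt(.data$stderr^2 + dplyr::lead(.data$stderr)^2)) |>
    dplyr::ungroup() |>
    dplyr::select("observable", "system", "value", "stderr", "rank",
                  "gap_to_next", "significant")
}
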