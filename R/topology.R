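#' Build a bilayer topology from an atom table
#'
#' A topology couples a per-atom table (roles, charges, lipid membership)
#' with a per-lipid table (species, leaflet). Atom roles follow the usual
#' bilayer bookkeeping: `"head"` for headgroup atoms, `"sn1"`/`"sn2"` with a
#' 1-based `carbon` index for acyl-chain carbons, `"other"` for everything
#' else (linkers, solvent). The optional `label` column carries free-form
#' selector tags such as `"N1"`, `"unsaturated"` or `"terminal"` used by the
#' distance analyses.
#'
#' @param atoms A data frame with columns `atom_id` (0-based integer),
#'   `name`, `lipid_id` (integer, `NA` for solvent), `species`, `role`
#'   (one of `"head"`, `"sn1"`, `"sn2"`, `"other"`), `carbon` (integer or
#'   `NA`), `charge` (elementary-charge units) and optionally `label` and
#'   `mass`.
#' @param check Validate invariants (chain contiguity, lipid neutrality).
#' @return An object of class `bl_topology`: a list with tibbles `atoms`
#'   and `lipids` (columns `lipid_id`, `species`, `leaflet`).
#' @export
bl_topology <- function(atoms, check = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom_id", "name", "lipid_id", "species", "role", "charge")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    rlang::abort(paste0("atom table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"carbon" %in% names(atoms)) atoms$carbon <- NA_integer_
  if (!"label" %in% names(atoms)) atoms$label <- atoms$name
  if (!"mass" %in% names(atoms)) atoms$mass <- 1
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$lipid_id <- as.integer(atoms$lipid_id)
  atoms$carbon <- as.integer(atoms$carbon)

  bad_role <- setdiff(unique(atoms$role), c("head", "sn1", "sn2", "other"))
  if (length(bad_role) > 0) {
    rlang::abort(paste0("unknown atom role(s): ", paste(bad_role, collapse = ", ")))
  }

  lipids <- atoms |>
    dplyr::filter(!is.na(.data$lipid_id)) |>
    dplyr::distinct(.data$lipid_id, .data$species) |>
    dplyr::arrange(.data$lipid_id) |>
    dplyr::mutate(leaflet = "unassigned")
  if (anyDuplicated(lipids$lipid_id) > 0) {
    rlang::abort("a lipid_id maps to more than one species")
  }

  if (check) {
    check_chain_indices(atoms)
    check_lipid_neutrality(atoms)
  }

  structure(list(atoms = atoms, lipids = lipids), class = "bl_topology")
}

check_chain_indices <- function(atoms) {
  chains <- atoms |>
    dplyr::filter(.data$role %in% c("sn1", "sn2"), !is.na(.data$lipid_id))
  if (nrow(chains) == 0) return(invisible(TRUE))
  bad <- chains |>
    dplyr::group_by(.data$lipid_id, .data$role) |>
    dplyr::summarise(
      ok = all(diff(.data$carbon) == 1) && .data$carbon[1] >= 1 &&
        !anyNA(.data$carbon),
      .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    rlang::abort(paste0(
      "chain carbon indices not strictly increasing and contiguous for lipid ",
      bad$lipid_id[1], " (", bad$role[1], ")"))
  }
  invisible(TRUE)
}

check_lipid_neutrality <- function(atoms, tol = 1e-6) {
  q <- atoms |>
    dplyr::filter(!is.na(.data$lipid_id)) |>
    dplyr::group_by(.data$lipid_id) |>
    dplyr::summarise(q = sum(.data$charge), .groups = "drop") |>
    dplyr::filter(abs(.data$q) > tol)
  if (nrow(q) > 0) {
    rlang::abort(paste0("lipid ", q$lipid_id[1], " has net charge ",
                        format(q$q[1]), " e (must be 0 within 1e-6)"))
  }
  invisible(TRUE)
}

#' @export
print.bl_topology <- function(x, ...) {
  cat("<bl_topology> ", nrow(x$atoms), " atoms, ", nrow(x$lipids),
      " lipids (", sum(x$lipids$leaflet == "upper"), " upper / ",
      sum(x$lipids$leaflet == "lower"), " lower / ",
      sum(x$lipids$leaflet == "unassigned"), " unassigned)\n", sep = "")
  invisible(x)
}

#' Read a species map
#'
#' The species map assigns a role, partial charge and optional selector
#' label to every (residue name, atom name) pair, and lists solvent residue
#' names. It is a YAML (or JSON) document of the form:
#'
#' ```yaml
#' solvent: [SOL]
#' residues:
#'   SYNL:
#'     HEAD: {role: head, charge: -0.07, label: N1}
#'     C01A: {role: sn1, carbon: 1, charge: 0.035}
#' ```
#'
#' @param path Path to the YAML/JSON file, or an equivalent named list.
#' @return A list with elements `residues` and `solvent`, class
#'   `bl_species_map`.
#' @export
read_species_map <- function(path) {
  map <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(map$residues)) rlang::abort("species map lacks a 'residues' block")
  if (is.null(map$solvent)) map$solvent <- character(0)
  structure(map, class = "bl_species_map")
}

#' Look up one atom in a species map
#' @noRd
species_map_entry <- function(map, resname, atomname) {
  res <- map$residues[[resname]]
  if (is.null(res)) {
    if (resname %in% map$solvent) {
      return(list(role = "other", charge = 0, carbon = NA_integer_,
                  label = atomname, mass = 1, solvent = TRUE))
    }
    rlang::abort(paste0("residue '", resname, "' not in species map"))
  }
  at <- res[[atomname]]
  if (is.null(at)) {
    rlang::abort(paste0("atom '", atomname, "' of residue '", resname,
                        "' not in species map"))
  }
  list(role = at$role %||% "other",
       charge = at$charge %||% 0,
       carbon = as.integer(at$carbon %||% NA_integer_),
       label = at$label %||% atomname,
       mass = at$mass %||% 1,
       solvent = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
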