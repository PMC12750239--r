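#' Construct a trajectory from in-memory frames
#'
#' A trajectory is an ordered sequence of coordinate frames over one
#' topology, with an analysis window selecting the frames that enter every
#' observable (the usual practice of analysing only the equilibrated tail
#' of a run).
#'
#' @param topology A [bl_topology].
#' @param frames List of frames; each frame is a list with `time` (ps),
#'   `xyz` (N x 3 matrix, nm) and `box` (length-3 numeric, nm).
#' @param window Optional `c(t_start, t_end)` in ps; defaults to the full
#'   time range.
#' @return A `bl_trajectory` object.
#' @export
bl_trajectory <- function(topology, frames, window = NULL) {
  stopifnot(inherits(topology, "bl_topology"))
  if (length(frames) == 0) rlang::abort("trajectory has no frames")
  n_atoms <- nrow(topology$atoms)
  times <- vapply(frames, function(f) as.numeric(f$time), numeric(1))
  for (f in frames) {
    if (nrow(f$xyz) != n_atoms) {
      rlang::abort(sprintf("frame atom count (%d) != topology atom count (%d)",
                           nrow(f$xyz), n_atoms))
    }
    if (!all(is.finite(f$xyz))) rlang::abort("non-finite coordinates in frame")
    if (length(f$box) != 3 || any(f$box <= 0)) {
      rlang::abort("box must be three positive lengths (orthorhombic)")
    }
  }
  if (any(diff(times) <= 0)) {
    rlang::abort("frame times must be strictly increasing (duplicate or non-monotone time stamp)")
  }
  if (is.null(window)) window <- range(times)
  if (window[1] < times[1] || window[2] > times[length(times)]) {
    rlang::abort("analysis window outside the trajectory time range")
  }
  structure(list(topology = topology, frames = frames, window = window),
            class = "bl_trajectory")
}

#' @export
print.bl_trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat("<bl_trajectory> ", length(x$frames), " frames (t = ",
      times[1], " .. ", times[length(times)], " ps), ",
      nrow(x$topology$atoms), " atoms; analysis window [",
      x$window[1], ", ", x$window[2], "] ps\n", sep = "")
  invisible(x)
}

#' Frame time stamps of a trajectory
#' @param traj A [bl_trajectory].
#' @return Numeric vector of frame times (ps).
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, function(f) as.numeric(f$time), numeric(1))
}

#' Restrict the analysis window of a trajectory
#'
#' @param traj A [bl_trajectory].
#' @param t_start,t_end Window bounds in ps.
#' @return The trajectory with the new window.
#' @export
set_window <- function(traj, t_start, t_end) {
  times <- frame_times(traj)
  if (t_start > t_end) rlang::abort("t_start > t_end")
  if (!any(times >= t_start & times <= t_end)) {
    rlang::abort("no frames inside the requested window")
  }
  traj$window <- c(t_start, t_end)
  traj
}

#' Frames inside the analysis window
#' @param traj A [bl_trajectory].
#' @return The list of frames whose times fall in the analysis window.
#' @export
analysis_frames <- function(traj) {
  times <- frame_times(traj)
  keep <- times >= traj$window[1] & times <= traj$window[2]
  if (!any(keep)) rlang::abort("zero frames in analysis window")
  traj$frames[keep]
}

#' Mean box over the analysis window
#' @noRd
mean_box <- function(traj) {
  boxes <- vapply(analysis_frames(traj), function(f) f$box, numeric(3))
  rowMeans(boxes)
}

#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between points under the minimum-image convention:
#' each Cartesian component of the separation is wrapped to the nearest
#' periodic image before the norm is taken.
#'
#' @param a,b Numeric vectors of length 3, or N x 3 matrices (row-wise
#'   pairs).
#' @param box Length-3 box vector (nm).
#' @return Distance(s) in nm.
#' @export
min_image_distance <- function(a, b, box) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    d <- a - b
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    return(sqrt(rowSums(d^2)))
  }
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

#' Minimum-image displacement vectors (matrix form)
#' @noRd
min_image_disp <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Assign lipids to leaflets
#'
#' The bilayer midplane is taken as the mean z of all lipid atoms in the
#' first frame of the analysis window; a lipid whose head atoms sit above
#' the midplane is `"upper"`, otherwise `"lower"`. Lipids without any
#' head-role atom stay `"unassigned"` with a warning.
#'
#' @param traj A [bl_trajectory].
#' @return The trajectory with leaflet labels filled in on its topology.
#' @export
assign_leaflets <- function(traj) {
  atoms <- traj$topology$atoms
  frame <- analysis_frames(traj)[[1]]
  lipid_rows <- !is.na(atoms$lipid_id)
  midplane <- mean(frame$xyz[lipid_rows, 3])

  head_rows <- which(atoms$role == "head" & lipid_rows)
  head_z <- tapply(frame$xyz[head_rows, 3], atoms$lipid_id[head_rows], mean)

  lipids <- traj$topology$lipids
  lab <- ifelse(head_z[as.character(lipids$lipid_id)] > midplane,
                "upper", "lower")
  lab[is.na(lab)] <- "unassigned"
  if (any(lab == "unassigned")) {
    rlang::warn(sprintf("%d lipid(s) have no head atom; leaflet left unassigned",
                        sum(lab == "unassigned")))
  }
  assigned <- lab[lab != "unassigned"]
  if (length(assigned) > 0 && length(unique(assigned)) == 1) {
    rlang::warn(paste0("all lipids assigned to the ", assigned[1],
                       " leaflet; structure may not be a bilayer"))
  }
  traj$topology$lipids$leaflet <- as.vector(lab)
  traj
}

#' Evaluate an atom-selection expression against a topology
#' @noRd
select_atoms <- function(topology, sel_quo) {
  if (rlang::quo_is_null(sel_quo)) return(seq_len(nrow(topology$atoms)))
  keep <- rlang::eval_tidy(sel_quo, data = topology$atoms)
  if (!is.logical(keep)) rlang::abort("selection must evaluate to a logical vector")
  which(keep & !is.na(keep))
}
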