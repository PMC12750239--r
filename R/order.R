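#' Deuterium order parameter profile of an acyl chain
#'
#' For every interior chain carbon n (both neighbors present), the order
#' parameter is
#' \deqn{S_{CD}(n) = \tfrac{1}{2}\langle 3\cos^2\theta - 1\rangle}
#' where theta is the angle between the membrane normal (z) and the
#' vector from carbon n-1 to carbon n+1 (minimum-image). The angular
#' bracket averages over lipids within each frame first; the per-carbon
#' uncertainty is then a block estimate over the per-frame means, which
#' respects the correlation of lipids within a frame.
#'
#' S is reported exactly as defined — 1 for a segment along the normal,
#' -0.5 in-plane, 0 isotropic; no sign flip or absolute value is applied.
#'
#' @param traj A [bl_trajectory].
#' @param chain `"sn1"` or `"sn2"`.
#' @param species Optional species name; default analyses every lipid
#'   that has the requested chain.
#' @param n_blocks Blocks for the uncertainty estimate (default 5).
#' @return A `bl_order_profile`: tibble with columns `chain`,
#'   `carbon_index`, `s_cd`, `stderr`.
#' @export
scd_profile <- function(traj, chain = c("sn1", "sn2"), species = NULL,
                        n_blocks = 5) {
  chain <- match.arg(chain)
  atoms <- traj$topology$atoms
  rows <- which(atoms$role == chain & !is.na(atoms$lipid_id))
  if (!is.null(species)) rows <- rows[atoms$species[rows] == species]
  if (length(rows) == 0) rlang::abort(paste0("no ", chain, " chain atoms found"))

  by_lipid <- split(rows, atoms$lipid_id[rows])
  by_lipid <- lapply(by_lipid, function(ix) ix[order(atoms$carbon[ix])])
  m <- unique(vapply(by_lipid, length, integer(1)))
  if (length(m) != 1) {
    rlang::abort("lipids have differing chain lengths; analyse one species at a time")
  }
  if (m < 3) rlang::abort("chain has fewer than 3 carbons; S_CD undefined")

  # index matrices: lipids x carbon, for the n-1 and n+1 atoms of each
  # interior carbon n = 2..m-1
  idx <- do.call(rbind, by_lipid)
  interior <- 2:(m - 1)
  prev_idx <- idx[, interior - 1, drop = FALSE]
  next_idx <- idx[, interior + 1, drop = FALSE]

  frames <- analysis_frames(traj)
  per_frame <- matrix(NA_real_, nrow = length(frames), ncol = length(interior))
  for (fi in seq_along(frames)) {
    f <- frames[[fi]]
    d <- f$xyz[as.vector(next_idx), , drop = FALSE] -
      f$xyz[as.vector(prev_idx), , drop = FALSE]
    d <- min_image_disp(d, f$box)
    cos2 <- d[, 3]^2 / rowSums(d^2)
    s <- 0.5 * (3 * cos2 - 1)
    per_frame[fi, ] <- colMeans(matrix(s, nrow = nrow(idx)))
  }

  est <- apply(per_frame, 2, function(col) {
    nb <- min(n_blocks, length(col))
    if (nb >= 2) unlist(block_error(col, nb)) else c(mean = mean(col), stderr = NA_real_)
  })

  structure(tibble::tibble(chain = chain, carbon_index = interior,
                           s_cd = est["mean", ], stderr = est["stderr", ]),
            class = c("bl_order_profile", class(tibble::tibble())))
}

#' Export an order-parameter profile as TSV
#'
#' @param profile A `bl_order_profile` (or several row-bound together).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_order_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
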