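#' Generate a synthetic parcellation of the voxel grid
#'
#' Partitions the 3-D grid into `n_regions` spatially contiguous rectangular
#' parcels by recursive bisection (always splitting the longest axis, with the
#' number of regions divided proportionally between the two halves), then
#' groups consecutive regions into `n_networks` networks of near-equal size.
#' The construction is deterministic given the configuration. When seven
#' networks are requested they receive the canonical resting-state names, and
#' six regions are tagged with the theory-driven region-of-interest labels
#' (bilateral amygdala, anterior insula, dACC) so the theory battery can be run
#' verbatim on synthetic data.
#'
#' @param config a [sim_config()] (only `grid_shape`, `n_regions`,
#'   `n_networks` are used).
#' @return an object of class `brain_atlas` with fields `region` (region id
#'   per voxel, aligned to the voxel order of generated maps), `network`
#'   (network id per region), `region_names`, `network_names`, `coords`,
#'   `grid`.
#' @export
generate_atlas <- function(config) {
  config <- as_sim_config(config)
  dims <- config$grid_shape
  R <- config$n_regions
  K <- config$n_networks
  if (prod(dims) < R) {
    abort(sprintf("Grid with %d voxels cannot hold %d regions.",
                  prod(dims), R))
  }
  if (R < K) abort("`n_regions` must be at least `n_networks`.")

  # region label array by recursive bisection of index boxes
  lab <- array(0L, dim = dims)
  next_id <- 1L
  assign_box <- function(lo, hi, k) {
    if (k == 1L) {
      lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- next_id
      next_id <<- next_id + 1L
      return(invisible())
    }
    len <- hi - lo + 1L
    ax <- which.max(len)
    k1 <- k %/% 2L
    k2 <- k - k1
    # split position proportional to region counts, at least one slab each
    cut <- lo[ax] - 1L + max(1L, min(len[ax] - 1L, round(len[ax] * k1 / k)))
    lo2 <- lo; hi1 <- hi
    hi1[ax] <- cut; lo2[ax] <- cut + 1L
    n1 <- prod(hi1 - lo + 1L); n2 <- prod(hi - lo2 + 1L)
    if (n1 < k1 || n2 < k2) {
      # rebalance counts to what the halves can hold
      k1 <- max(1L, min(k - 1L, round(k * n1 / (n1 + n2))))
      if (n1 < k1) k1 <- n1
      if (n2 < k - k1) k1 <- k - n2
      k2 <- k - k1
    }
    assign_box(lo, hi1, k1)
    assign_box(lo2, hi, k2)
  }
  assign_box(c(1L, 1L, 1L), as.integer(dims), R)

  coords <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1L,
                                  y = seq_len(dims[2]) - 1L,
                                  z = seq_len(dims[3]) - 1L))
  storage.mode(coords) <- "integer"
  region <- as.integer(lab)          # column-major, matches expand.grid order

  # networks: consecutive region ids, sizes differing by at most one
  network <- as.integer(cut(seq_len(R), breaks = K, labels = FALSE))

  yeo <- c("limbic", "ventral_attention", "dorsal_attention",
           "frontoparietal", "default_mode", "visual", "somatomotor")
  network_names <- if (K == 7L) yeo else sprintf("network_%02d", seq_len(K))
  region_names <- sprintf("region_%03d", seq_len(R))

  roi <- c("amygdala_L", "amygdala_R", "anterior_insula_L",
           "anterior_insula_R", "dACC_L", "dACC_R")
  host <- c(1L, 1L, 2L, 2L, 3L, 3L)   # limbic, ventral attention, dorsal attn
  slot <- c(1L, 2L, 1L, 2L, 1L, 2L)
  for (i in seq_along(roi)) {
    if (host[i] > K) next
    members <- which(network == host[i])
    if (length(members) >= slot[i]) region_names[members[slot[i]]] <- roi[i]
  }

  structure(
    list(region = region, network = network, region_names = region_names,
         network_names = network_names, coords = coords,
         grid = as.integer(dims)),
    class = "brain_atlas"
  )
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas: %d voxels, %d regions, %d networks on %s>\n",
              length(x$region), length(x$region_names),
              length(x$network_names), paste(x$grid, collapse = "x")))
  invisible(x)
}

#' @method tidy brain_atlas
#' @export
tidy.brain_atlas <- function(x, ...) {
  tibble(
    region = seq_along(x$region_names),
    region_name = x$region_names,
    network = x$network,
    network_name = x$network_names[x$network],
    n_voxels = as.integer(tabulate(x$region, nbins = length(x$region_names)))
  )
}

check_atlas_alignment <- function(maps, atlas) {
  if (length(atlas$region) != n_voxels(maps)) {
    abort(sprintf(
      "Atlas covers %d voxels but maps have %d: voxel spaces do not match.",
      length(atlas$region), n_voxels(maps)))
  }
}

#' Aggregate voxel maps to region or network averages
#'
#' The value of a unit is the unweighted mean of its member voxels, so the
#' network average equals the voxel-count-weighted mean of its member-region
#' averages.
#'
#' @param maps [brain_maps()] or matrix, aligned with the atlas voxel space.
#' @param atlas a `brain_atlas`.
#' @param level `"region"` or `"network"`.
#' @return numeric matrix, observations by units, with unit names as columns.
#' @export
aggregate_maps <- function(maps, atlas, level = c("region", "network")) {
  level <- match.arg(level)
  check_atlas_alignment(maps, atlas)
  x <- map_matrix(maps)
  group <- switch(level,
                  region = atlas$region,
                  network = atlas$network[atlas$region])
  nm <- switch(level, region = atlas$region_names,
               network = atlas$network_names)
  sums <- t(rowsum(t(x), group = group))
  counts <- tabulate(group, nbins = length(nm))
  present <- which(counts > 0)
  out <- sweep(sums, 2L, counts[present], "/")
  colnames(out) <- nm[present]
  out
}

resolve_unit <- function(atlas, unit, level) {
  nm <- switch(level, region = atlas$region_names,
               network = atlas$network_names)
  if (is.character(unit)) {
    id <- match(unit, nm)
    if (is.na(id)) abort(sprintf("Unknown %s '%s'.", level, unit))
  } else {
    id <- as.integer(unit)
    if (is.na(id) || id < 1L || id > length(nm)) {
      abort(sprintf("%s id %s out of range.", level, unit))
    }
  }
  id
}

unit_voxels <- function(atlas, unit, level = c("region", "network")) {
  level <- match.arg(level)
  id <- resolve_unit(atlas, unit, level)
  if (level == "region") {
    atlas$region == id
  } else {
    atlas$network[atlas$region] == id
  }
}

#' Virtually lesion a region or network
#'
#' Removes every voxel of the named unit from the maps (and from the atlas via
#' [lesion_atlas()]), so that downstream models can be retrained and
#' re-evaluated on the reduced voxel space.
#'
#' @param maps [brain_maps()] or matrix aligned with the atlas.
#' @param atlas a `brain_atlas`.
#' @param unit region/network name or id.
#' @param level `"region"` or `"network"`.
#' @return maps with the unit's voxels removed.
#' @export
lesion <- function(maps, atlas, unit, level = c("region", "network")) {
  level <- match.arg(level)
  check_atlas_alignment(maps, atlas)
  drop <- unit_voxels(atlas, unit, level)
  if (all(drop)) abort("Lesion would remove every voxel.")
  apply_gray_mask(maps, !drop)
}

#' Restrict an atlas to the voxels kept after a lesion
#' @inheritParams lesion
#' @return a `brain_atlas` on the reduced voxel space (the removed unit keeps
#'   its id but owns no voxels).
#' @export
lesion_atlas <- function(atlas, unit, level = c("region", "network")) {
  level <- match.arg(level)
  drop <- unit_voxels(atlas, unit, level)
  if (all(drop)) abort("Lesion would remove every voxel.")
  atlas$region <- atlas$region[!drop]
  atlas$coords <- atlas$coords[!drop, , drop = FALSE]
  atlas
}
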