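# Readers and writers for the standard on-disk formats: 4-D NIfTI stacks for
# maps, 3-D NIfTI for weight images and integer atlas labels (with a JSON
# lookup sidecar), CSV for tables, YAML for simulation configurations.

maps_to_array <- function(maps) {
  dims <- maps$grid
  n <- n_obs(maps)
  arr <- array(0, dim = c(dims, n))
  lin <- 1 + maps$coords[, 1] + dims[1] * (maps$coords[, 2] +
                                             dims[2] * maps$coords[, 3])
  vol <- prod(dims)
  for (i in seq_len(n)) {
    arr[lin + (i - 1) * vol] <- maps$data[i, ]
  }
  arr
}

#' Write and read brain maps as a 4-D NIfTI stack
#'
#' Observations are stacked along the 4th axis; per-observation metadata go
#' to a CSV sidecar and provenance to a JSON sidecar next to the image.
#' Voxel coordinates are 0-based grid indices; the affine is pass-through
#' (identity on write).
#'
#' @param maps a [brain_maps()] object.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `read_brain_maps` returns a [brain_maps()]; the writer returns
#'   `path` invisibly.
#' @export
write_brain_maps <- function(maps, path) {
  RNifti::writeNifti(RNifti::asNifti(maps_to_array(maps)), path)
  if (!is.null(maps$obs)) {
    write.csv(maps$obs, paste0(path, ".obs.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(provenance = maps$provenance),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_brain_maps
#' @export
read_brain_maps <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  dims <- dim(arr)[1:3]
  n <- dim(arr)[4]
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1L,
                                  y = seq_len(dims[2]) - 1L,
                                  z = seq_len(dims[3]) - 1L))
  data <- t(matrix(arr, prod(dims), n))
  obs_path <- paste0(path, ".obs.csv")
  obs <- if (file.exists(obs_path)) as_tibble(read.csv(obs_path))
  side_path <- paste0(path, ".json")
  prov <- if (file.exists(side_path)) {
    unlist(jsonlite::read_json(side_path)$provenance) %||% character()
  } else character()
  brain_maps(data, coords = coords, obs = obs, grid = dims,
             provenance = prov)
}

#' Write and read an atlas as integer-labelled NIfTI plus JSON lookup
#' @param atlas a `brain_atlas`.
#' @param path output `.nii` path; the lookup goes to `<path>.json`.
#' @return `read_atlas` returns a `brain_atlas`; the writer returns `path`
#'   invisibly.
#' @export
write_atlas <- function(atlas, path) {
  arr <- array(0L, dim = atlas$grid)
  lin <- 1 + atlas$coords[, 1] + atlas$grid[1] *
    (atlas$coords[, 2] + atlas$grid[2] * atlas$coords[, 3])
  arr[lin] <- atlas$region
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(
    list(region_names = atlas$region_names,
         network_names = atlas$network_names,
         network_of_region = atlas$network),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  dims <- dim(arr)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1L,
                                  y = seq_len(dims[2]) - 1L,
                                  z = seq_len(dims[3]) - 1L))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(region = as.integer(arr), network = as.integer(meta$network_of_region),
         region_names = meta$region_names, network_names = meta$network_names,
         coords = coords, grid = as.integer(dims)),
    class = "brain_atlas"
  )
}

#' Write and read a signature weight image
#' @param sig a `signature_map`.
#' @param grid integer(3) grid dimensions for reshaping the weight vector.
#' @param path output `.nii` path.
#' @return `read_signature` returns a `signature_map`; the writer returns
#'   `path` invisibly.
#' @export
write_signature <- function(sig, grid, path) {
  arr <- array(sig$weights, dim = grid)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(list(name = sig$name), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta_path <- paste0(path, ".json")
  nm <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$name
  } else "signature"
  structure(list(name = nm, weights = as.numeric(arr)),
            class = "signature_map")
}

#' Write a synthetic cohort to a directory
#'
#' Contrast and trial maps go to 4-D NIfTI stacks, traits and ratings to CSV,
#' the configuration to YAML, the atlas to NIfTI + JSON, and the ground truth
#' (pattern weight images, latent scores) to a sidecar subdirectory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sim_config(cohort$config, file.path(dir, "config.yaml"))
  write_atlas(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  write_brain_maps(cohort$trial_maps, file.path(dir, "trial_maps.nii.gz"))
  for (nm in names(cohort$contrasts)) {
    write_brain_maps(cohort$contrasts[[nm]],
                     file.path(dir, paste0("contrast_", nm, ".nii.gz")))
  }
  write.csv(cohort$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(cohort$ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  grid <- cohort$config$grid_shape
  write_signature(structure(list(name = "true_state_pattern",
                                 weights = cohort$truth$w_state),
                            class = "signature_map"),
                  grid, file.path(tdir, "w_state.nii.gz"))
  write_signature(structure(list(name = "true_trait_pattern",
                                 weights = cohort$truth$w_trait),
                            class = "signature_map"),
                  grid, file.path(tdir, "w_trait.nii.gz"))
  write.csv(cohort$truth$latent, file.path(tdir, "latent.csv"),
            row.names = FALSE)
  invisible(dir)
}
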