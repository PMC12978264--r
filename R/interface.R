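#' Produce parameter maps from a diffusion-weighted volume
#'
#' Runs a trained estimator voxelwise over a 4D NIfTI volume with an
#' FSL-style gradient table aligned to the 4th axis. Each voxel's graph
#' is built from the volume's own protocol, so any acquisition scheme
#' with at least one b0 works without retraining. Estimates are clipped
#' to \[0, 1\] at export; voxels outside the mask are 0. The input affine
#' and orientation are passed through untouched.
#'
#' @param dwi path to a 4D NIfTI volume, or an `niftiImage`/array
#' @param bval_path,bvec_path FSL gradient table paths (b in s/mm^2 on
#'   disk)
#' @param model a trained `gnn_model` (or any object with a `predict`
#'   method returning an n x 3 matrix)
#' @param mask optional 3D binary mask (path, image or array)
#' @param out_prefix if non-NULL, writes `<prefix>_ndi.nii.gz`,
#'   `<prefix>_odi.nii.gz`, `<prefix>_fwf.nii.gz` and a run manifest
#' @param chunk_size voxels per prediction chunk
#' @return named list of three 3D arrays (ndi, odi, fwf), invisibly also
#'   written to disk when `out_prefix` is given
#' @export
predict_maps <- function(dwi, bval_path, bvec_path, model, mask = NULL,
                         out_prefix = NULL, chunk_size = 2000) {
  img <- if (is.character(dwi)) RNifti::readNifti(dwi) else dwi
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("dwi must be a 4D volume")
  proto <- read_gradient_table(bval_path, bvec_path)
  if (dim(arr)[4] != proto$n) {
    stop(sprintf("volume has %d frames but gradient table %d entries",
                 dim(arr)[4], proto$n))
  }
  if (length(proto$b0_indices) == 0) stop("gradient table contains no b = 0 entry")
  dims <- dim(arr)[1:3]
  if (is.null(mask)) {
    mask_arr <- array(TRUE, dims)
  } else {
    mask_arr <- as.array(if (is.character(mask)) RNifti::readNifti(mask) else mask) > 0
    if (!all(dim(mask_arr) == dims)) stop("mask dimensions do not match the volume")
  }
  vox_idx <- which(mask_arr)
  maps <- lapply(1:3, function(i) array(0, dims))
  names(maps) <- c("ndi", "odi", "fwf")
  flat <- matrix(arr, prod(dims), dim(arr)[4])
  usable <- vox_idx[apply(flat[vox_idx, , drop = FALSE] > 0, 1, all)]
  for (start in seq_len(max(0, ceiling(length(usable) / chunk_size))) * chunk_size -
       chunk_size + 1) {
    idx <- usable[start:min(start + chunk_size - 1, length(usable))]
    voxels <- lapply(idx, function(i) voxel_data(proto, flat[i, ]))
    est <- pmin(pmax(predict(model, voxels), 0), 1)
    for (j in 1:3) maps[[j]][idx] <- est[, j]
  }
  if (!is.null(out_prefix)) {
    paths <- character(0)
    for (nm in names(maps)) {
      path <- paste0(out_prefix, "_", nm, ".nii.gz")
      out_img <- RNifti::asNifti(maps[[nm]], reference = img)
      RNifti::writeNifti(out_img, path)
      paths <- c(paths, path)
    }
    write_manifest(paste0(out_prefix, "_manifest.json"),
                   command = "predict",
                   inputs = list(bval = bval_path, bvec = bvec_path),
                   outputs = as.list(paths),
                   n_voxels = length(usable))
  }
  maps
}

#' Write a run manifest
#'
#' Every artefact-producing command records a small JSON manifest:
#' package version, timestamp, seeds/configuration and output paths, so
#' a run can be reproduced from its manifest.
#'
#' @param path output JSON path
#' @param ... named fields to record
#' @return invisibly, the path
#' @export
write_manifest <- function(path, ...) {
  payload <- c(list(package = "noddigraph",
                    version = as.character(utils::packageVersion("noddigraph")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
               list(...))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a simulated dataset to disk
#'
#' Writes each protocol as an FSL bval/bvec pair, the voxel signals and
#' ground truth as columnar CSV tables, and a manifest. The layout is
#' one `protocol_<id>.bval/.bvec` pair plus a long-format `signals.csv`
#' (example, measurement, signal) and `truth.csv`.
#'
#' @param dataset a [build_training_set()] result
#' @param dir output directory (created if missing)
#' @param seed seed recorded in the manifest
#' @return invisibly, the directory
#' @export
export_dataset <- function(dataset, dir, seed = NA) {
  stopifnot(inherits(dataset, "training_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$examples)
  truth <- dataset$params
  truth$voxel <- seq_len(nrow(truth))
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sig_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- dataset$examples[[i]]
    g <- t(ex$q)
    nrm <- sqrt(pmax(rowSums(g^2), 1e-300))
    g <- g / nrm
    g[ex$b == 0, ] <- 0
    proto <- protocol(ex$b, g)
    write_gradient_table(proto,
                         file.path(dir, sprintf("protocol_%05d.bval", i)),
                         file.path(dir, sprintf("protocol_%05d.bvec", i)))
    sig_rows[[i]] <- data.frame(example = i,
                                voxel = (i - 1) %/% dataset$protocols_per_voxel + 1,
                                measurement = seq_along(ex$s), signal = ex$s)
  }
  write.csv(do.call(rbind, sig_rows), file.path(dir, "signals.csv"),
            row.names = FALSE)
  write_manifest(file.path(dir, "manifest.json"), command = "simulate",
                 n_examples = n, n_voxels = dataset$n_voxels,
                 protocols_per_voxel = dataset$protocols_per_voxel,
                 seed = seed, outputs = list("truth.csv", "signals.csv"))
  invisible(dir)
}
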