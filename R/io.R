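# Readers and writers: NIfTI BOLD volumes and masks (via RNifti),
# BIDS-style tab-separated events tables, JSON sidecars.

## Smallest near-cubic 3D grid holding n voxels; voxels are flattened in
## column-major (x fastest) order.
.voxelGridDims <- function(n) {
  s <- ceiling(n^(1 / 3))
  d1 <- s
  d2 <- ceiling(sqrt(n / d1))
  d3 <- ceiling(n / (d1 * d2))
  c(d1, d2, d3)
}

#' Write a BoldRun as a 4D NIfTI volume with a JSON sidecar
#'
#' Voxels are reshaped into a small near-cubic 3D grid (padded voxels are
#' zero) and the sidecar records the repetition time, run index, voxel
#' count and any ground-truth annotation.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param path output .nii or .nii.gz path; the sidecar is written next
#'   to it with extension .json.
#' @param groundTruth optional list stored verbatim in the sidecar (e.g.
#'   simulated phi, omega, voxel kinds).
#' @return The NIfTI path, invisibly.
#' @export
writeBoldRun <- function(run, path, groundTruth = NULL) {
  dims <- .voxelGridDims(nVoxels(run))
  arr <- array(0, dim = c(dims, nScans(run)))
  flat <- prod(dims)
  for (tcol in seq_len(nScans(run))) {
    v <- numeric(flat)
    v[seq_len(nVoxels(run))] <- boldData(run)[, tcol]
    arr[, , , tcol] <- array(v, dim = dims)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, repetitionTime(run))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(RepetitionTime = repetitionTime(run), RunIndex = runIndex(run),
         NVoxels = nVoxels(run), GridDims = dims,
         GroundTruth = groundTruth),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a BoldRun written by \code{\link{writeBoldRun}}
#'
#' @param path NIfTI path (sidecar expected next to it).
#' @return A \linkS4class{BoldRun}; the sidecar (if present) is attached
#'   as the \code{"sidecar"} attribute.
#' @export
readBoldRun <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stopf("expected a 4D NIfTI volume")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  nv <- if (!is.null(meta$NVoxels)) meta$NVoxels else prod(dim(arr)[1:3])
  tr <- if (!is.null(meta$RepetitionTime)) meta$RepetitionTime
        else RNifti::pixdim(img)[4]
  ri <- if (!is.null(meta$RunIndex)) meta$RunIndex else 1L
  nt <- dim(arr)[4]
  dat <- matrix(arr, nrow = prod(dim(arr)[1:3]), ncol = nt)[seq_len(nv), ,
                                                            drop = FALSE]
  out <- boldRun(dat, tr = tr, runIndex = ri)
  attr(out, "sidecar") <- meta
  out
}

#' Write a per-voxel statistic map as 3D NIfTI
#'
#' @param values per-voxel statistic vector (flattening order of
#'   \code{\link{writeBoldRun}}).
#' @param path output path.
#' @param dims optional 3D grid dims; default the near-cubic grid.
#' @return The path, invisibly.
#' @export
writeStatMap <- function(values, path, dims = NULL) {
  if (is.null(dims)) dims <- .voxelGridDims(length(values))
  v <- numeric(prod(dims))
  v[seq_along(values)] <- values
  RNifti::writeNifti(RNifti::asNifti(array(v, dim = dims)), path)
  invisible(path)
}

#' Read an ROI mask into a voxel index set
#'
#' @param path NIfTI mask path (nonzero voxels are in the ROI).
#' @return integer indices in the flattening order of
#'   \code{\link{writeBoldRun}}.
#' @export
readMask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  which(as.vector(arr) != 0)
}

#' Write a trial table as a tab-separated events file
#'
#' BIDS-events-like layout: onset and duration are the leading columns.
#'
#' @param trials trial table.
#' @param path output .tsv path.
#' @return The path, invisibly.
#' @export
writeEvents <- function(trials, path) {
  validateTrialTable(trials)
  lead <- intersect(c("onset", "duration"), names(trials))
  rest <- setdiff(names(trials), lead)
  utils::write.table(trials[c(lead, rest)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated events file into a trial table
#'
#' @param path .tsv path.
#' @return A validated trial table.
#' @export
readEvents <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateTrialTable(tab)
  tab
}
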