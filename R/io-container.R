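# Single-file binary array container: the package's native on-disk format
# for voxel-grid datasets, trajectories and model checkpoints.
#
# Layout: 8-byte magic "MDAFFIN1", 8-byte little-endian header length,
# JSON header (array names/dims + free-form metadata), then the numeric
# payloads as IEEE little-endian doubles in header order. Strings and
# small tables travel in the JSON header; only numeric arrays go in the
# payload.

container_magic <- charToRaw("MDAFFIN1")

#' Write named numeric arrays plus metadata to a single file
#'
#' @param path Output file path.
#' @param arrays Named list of numeric arrays/vectors/matrices.
#' @param meta Named list of JSON-serializable metadata (attributes,
#'   string vectors, nested lists).
#' @return `path`, invisibly.
#' @export
write_array_container <- function(path, arrays, meta = list()) {
  assert_that(length(arrays) == 0 || !is.null(names(arrays)),
              "arrays must be a named list")
  entries <- purrr::imap(arrays, function(a, nm) {
    list(name = nm, dims = if (is.null(dim(a))) length(a) else dim(a))
  })
  header <- jsonlite::toJSON(
    list(arrays = unname(entries), meta = meta),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(container_magic, con)
  writeBin(as.numeric(length(hraw)), con, size = 8, endian = "little")
  writeBin(hraw, con)
  for (a in arrays) {
    writeBin(as.numeric(a), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a container written by [write_array_container()]
#'
#' @param path File path.
#' @return List with elements `arrays` (named list of numeric arrays)
#'   and `meta`.
#' @export
read_array_container <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(container_magic))
  assert_that(identical(magic, container_magic),
              sprintf("'%s' is not an mdaffinity array container", path))
  hlen <- readBin(con, "numeric", 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(
    rawToChar(readBin(con, "raw", hlen)),
    simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE
  )
  arrays <- list()
  for (entry in header$arrays) {
    dims <- as.integer(unlist(entry$dims))
    vals <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
    arrays[[entry$name]] <- if (length(dims) > 1) array(vals, dims) else vals
  }
  list(arrays = arrays, meta = header$meta)
}

# ---- grid datasets -----------------------------------------------------

normalize_split <- function(split) {
  # accept a list of voxel_grid / voxel_sequence, or a ready-made list
  if (!is.null(split$grids)) return(split)
  assert_that(length(split) > 0, "empty split")
  first <- split[[1]]
  assert_that(inherits(first, "voxel_grid") || inherits(first, "voxel_sequence"),
              "split must contain voxel_grid or voxel_sequence objects")
  dims <- dim(first$values)
  flat <- vapply(split, function(g) {
    assert_that(identical(dim(g$values), dims), "heterogeneous grid shapes in split")
    as.numeric(g$values)
  }, numeric(prod(dims)))
  arr <- aperm(array(flat, c(dims, length(split))), c(length(dims) + 1, seq_along(dims)))
  labels <- vapply(split, function(g) g$label_pk %||% NA_real_, numeric(1))
  list(grids = arr, labels = labels,
       complex_ids = names(split) %||% as.character(seq_along(split)),
       edge_A = first$edge_A, resolution_A = first$resolution_A,
       channels = first$channels, centering = first$centering)
}

#' Write a voxel-grid dataset to disk
#'
#' One split per group; each split stores a `grids` array (`(N, C, D, D,
#' D)` for single frames, `(N, T, C, D, D, D)` for sequences), a `labels`
#' vector and `complex_ids`, with dataset-level attributes `edge_A`,
#' `resolution_A`, `channels` and `centering`. Round trips are bit-exact.
#'
#' @param splits Named list of splits (e.g. `train`, `val`, `test`). Each
#'   split is either a list with elements `grids`, `labels`,
#'   `complex_ids`, or a named list of [voxel_grid()] /
#'   [voxel_sequence()] objects.
#' @param path Output file.
#' @param edge_A,resolution_A,centering Dataset attributes; taken from
#'   the grids when omitted.
#' @return `path`, invisibly.
#' @export
write_grid_dataset <- function(splits, path, edge_A = NULL,
                               resolution_A = NULL, centering = NULL) {
  splits <- purrr::map(splits, normalize_split)
  first <- splits[[1]]
  edge_A <- edge_A %||% first$edge_A
  resolution_A <- resolution_A %||% first$resolution_A
  centering <- centering %||% first$centering
  assert_that(!is.null(resolution_A), "resolution_A attribute required")
  arrays <- list()
  meta_splits <- list()
  for (nm in names(splits)) {
    s <- splits[[nm]]
    arrays[[paste0(nm, "/grids")]] <- s$grids
    arrays[[paste0(nm, "/labels")]] <- as.numeric(s$labels)
    meta_splits[[nm]] <- list(complex_ids = as.character(s$complex_ids))
  }
  write_array_container(path, arrays, meta = list(
    kind = "grid_dataset",
    edge_A = edge_A, resolution_A = resolution_A,
    channels = feature_channels(), centering = centering,
    splits = meta_splits
  ))
}

#' Read a voxel-grid dataset
#'
#' @param path File written by [write_grid_dataset()].
#' @param channels Expected channel names; a mismatch with the stored
#'   names is an error.
#' @return Named list of splits, each with `grids`, `labels`,
#'   `complex_ids`, plus attributes `edge_A`, `resolution_A`, `channels`,
#'   `centering`.
#' @export
read_grid_dataset <- function(path, channels = feature_channels()) {
  raw <- read_array_container(path)
  meta <- raw$meta
  assert_that(identical(meta$kind, "grid_dataset"),
              sprintf("'%s' is not a grid dataset", path))
  assert_that(!is.null(meta$resolution_A),
              sprintf("'%s': missing resolution_A attribute", path))
  stored <- unlist(meta$channels)
  assert_that(identical(stored, channels),
              sprintf("channel mismatch: stored [%s] vs expected [%s]",
                      paste(stored, collapse = ","), paste(channels, collapse = ",")))
  out <- list()
  for (nm in names(meta$splits)) {
    out[[nm]] <- list(
      grids = raw$arrays[[paste0(nm, "/grids")]],
      labels = raw$arrays[[paste0(nm, "/labels")]],
      complex_ids = unlist(meta$splits[[nm]]$complex_ids)
    )
  }
  attr(out, "edge_A") <- meta$edge_A
  attr(out, "resolution_A") <- meta$resolution_A
  attr(out, "channels") <- stored
  attr(out, "centering") <- meta$centering
  out
}

# ---- trajectory containers ---------------------------------------------

#' Write a trajectory to a single-file container
#'
#' Stores the `(T, n_atoms, 3)` coordinate array plus the full atom
#' roster and provenance, so [read_trajectory()] reconstructs the object
#' exactly.
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_array_container(
    path,
    arrays = list(coords = traj$coords),
    meta = list(
      kind = "trajectory",
      complex_id = traj$complex_id,
      replicate_id = traj$replicate_id,
      label_pk = traj$label_pk,
      frame_index = traj$frame_index,
      atoms = as.list(traj$atoms)
    )
  )
}

read_trajectory_container <- function(path) {
  raw <- read_array_container(path)
  meta <- raw$meta
  assert_that(identical(meta$kind, "trajectory"),
              sprintf("'%s' is not a trajectory container", path))
  atoms <- tibble::as_tibble(purrr::map(meta$atoms, unlist))
  coords <- raw$arrays$coords
  trajectory(atoms, coords, meta$complex_id, meta$replicate_id,
             meta$label_pk %||% NA_real_,
             frame_index = as.integer(unlist(meta$frame_index)))
}
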