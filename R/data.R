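#' Extract square regions of interest from a frame
#'
#' Copies `tile` x `tile` sub-arrays centred on the requested pixel
#' coordinates.  Coordinates are `(x, y)` with x the column and y the row
#' of the frame matrix (so a 1388 x 1040 pixel camera frame is a matrix
#' with 1040 rows and 1388 columns).  Centres closer than `tile/2` to an
#' edge are rejected.
#'
#' @param frame Numeric matrix.
#' @param centers List of `c(x, y)` pixel coordinates.
#' @param tile Even tile side in pixels (default 256).
#' @return List of `tile` x `tile` matrices, one per accepted centre.
#' @export
extract_rois <- function(frame, centers, tile = 256) {
  stopifnot(is.matrix(frame), tile %% 2 == 0, tile > 0)
  half <- tile %/% 2
  lapply(centers, function(ctr) {
    x <- ctr[1]; y <- ctr[2]
    rows <- (y - half + 1):(y + half)
    cols <- (x - half + 1):(x + half)
    if (min(rows) < 1 || max(rows) > nrow(frame) ||
        min(cols) < 1 || max(cols) > ncol(frame)) {
      stop(sprintf(
        "ROI centred at (x = %d, y = %d) with tile %d exceeds the %d x %d frame",
        x, y, tile, ncol(frame), nrow(frame)), call. = FALSE)
    }
    frame[rows, cols]
  })
}

#' Normalize a tile to \[-1, 1\]
#'
#' Min-max normalization with the record needed to invert it.  Constant
#' tiles map to all zeros (and invert back exactly via the record).
#'
#' @param tile Numeric matrix.
#' @return List with `tile` (normalized matrix) and `norm`
#'   (`c(min, max)`).
#' @export
normalize_tile <- function(tile) {
  rng <- range(tile)
  out <- if (diff(rng) > 0) 2 * (tile - rng[1]) / diff(rng) - 1 else tile * 0
  list(tile = out, norm = rng)
}

#' @rdname normalize_tile
#' @param norm The `c(min, max)` record.
#' @return `denormalize_tile()`: the matrix on its original scale.
#' @export
denormalize_tile <- function(tile, norm) {
  if (diff(range(norm)) == 0) {
    return(matrix(norm[1], nrow(tile), ncol(tile)))
  }
  (tile + 1) / 2 * (norm[2] - norm[1]) + norm[1]
}

#' Build the paired intensity/phase training set
#'
#' Pairs every selected defocused frame of each stack with that stack's
#' single conventional-TIE phase map (one phase target per object,
#' whatever the defocus of the input frame - this is what teaches the
#' model to be defocus-robust), normalizes both tiles to \[-1, 1\] with
#' per-tile records, and splits the pairs into train/validation/test sets
#' that are disjoint by source object, so no cell or bead field appears
#' in two splits.
#'
#' When the requested split sizes are not attainable with whole objects,
#' objects are allocated proportionally and each split is then trimmed
#' (seeded subsampling) to the exact requested size.
#'
#' @param stacks List of [intensity_stack()]s.
#' @param phases List of [phase_map()]s, one per stack (the ground truth
#'   target of every frame of that stack).
#' @param z_selection `"all"` or a numeric vector of z planes to keep.
#' @param split_sizes `c(train, validation, test)` pair counts; `NULL`
#'   keeps everything in `train`.
#' @param seed Integer seed controlling the split.
#' @return A tibble of class `qpi_pairs` with columns `source_id`,
#'   `z_um`, `split`, `intensity` and `phase` (list columns of normalized
#'   tiles), `i_norm` and `p_norm` (list columns of `c(min, max)`
#'   records).
#' @export
build_pairs <- function(stacks, phases, z_selection = "all",
                        split_sizes = NULL, seed = 1L) {
  if (length(stacks) != length(phases)) {
    stop("need exactly one phase map per stack", call. = FALSE)
  }
  rows <- purrr::imap(stacks, function(st, si) {
    id <- if (!is.null(st$source_id)) st$source_id else paste0("obj", si)
    keep <- if (identical(z_selection, "all")) {
      seq_along(st$z_um)
    } else {
      which(st$z_um %in% z_selection)
    }
    ph <- normalize_tile(phases[[si]]$phase_rad)
    purrr::map(keep, function(i) {
      it <- normalize_tile(st$frames[[i]])
      tibble::tibble(source_id = id, z_um = st$z_um[i],
                     intensity = list(it$tile), phase = list(ph$tile),
                     i_norm = list(it$norm), p_norm = list(ph$norm))
    }) |> dplyr::bind_rows()
  })
  pairs <- dplyr::bind_rows(rows)

  if (is.null(split_sizes)) {
    pairs$split <- "train"
  } else {
    stopifnot(length(split_sizes) == 3)
    if (sum(split_sizes) > nrow(pairs)) {
      stop(sprintf("requested %d pairs but only %d are available",
                   sum(split_sizes), nrow(pairs)), call. = FALSE)
    }
    pairs <- with_seed(as.integer(seed), assign_splits(pairs, split_sizes))
  }
  pairs <- dplyr::relocate(pairs, "source_id", "z_um", "split")
  class(pairs) <- c("qpi_pairs", class(pairs))
  pairs
}

# Allocate whole source objects to splits proportionally to the requested
# sizes, then trim each split to its exact size; called inside with_seed.
assign_splits <- function(pairs, split_sizes) {
  names(split_sizes) <- c("train", "validation", "test")
  ids <- unique(pairs$source_id)
  ids <- sample(ids)
  per_id <- table(pairs$source_id)[ids]
  target <- split_sizes
  alloc <- setNames(rep("unused", length(ids)), ids)
  got <- c(train = 0, validation = 0, test = 0)
  for (id in ids) {
    need <- target - got
    open <- need > 0
    if (!any(open)) break
    frac <- ifelse(open, need / pmax(target, 1), -Inf)
    pick <- names(target)[which.max(frac)]
    alloc[id] <- pick
    got[pick] <- got[pick] + per_id[[id]]
  }
  pairs$split <- unname(alloc[pairs$source_id])
  trimmed <- lapply(names(target), function(sp) {
    sub <- pairs[pairs$split == sp, ]
    if (nrow(sub) > target[[sp]]) {
      sub <- sub[sort(sample(nrow(sub), target[[sp]])), ]
    } else if (nrow(sub) < target[[sp]]) {
      stop(sprintf(
        "cannot fill the %s split with whole objects (%d of %d pairs)",
        sp, nrow(sub), target[[sp]]), call. = FALSE)
    }
    sub
  })
  dplyr::bind_rows(trimmed)
}

#' Split accessors
#'
#' @param pairs A `qpi_pairs` tibble from [build_pairs()].
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @return The subset tibble.
#' @export
pairs_split <- function(pairs, split) {
  pairs[pairs$split == split, ]
}

#' Write / read an intensity stack on disk
#'
#' Frames are stored as a multi-page 32-bit float TIFF next to a YAML
#' sidecar carrying the z positions, pitch, wavelength and the
#' normalization scale used to fit the frames into \[0, 1\].
#'
#' @param stack An [intensity_stack()].
#' @param path Path of the `.tiff` file; the sidecar gets the extension
#'   `.yaml`.
#' @return `write_stack()`: `path`, invisibly.  `read_stack()`: an
#'   [intensity_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "intensity_stack"))
  scale <- max(vapply(stack$frames, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(stack$frames, function(f) f / scale), path,
                  bits.per.sample = 32L)
  meta <- list(z_positions_um = as.numeric(stack$z_um),
               pitch_um = stack$pitch_um,
               wavelength_um = stack$config$wavelength_um,
               medium_index = stack$config$medium_index,
               scale = scale,
               source_id = stack$source_id)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".yaml", path)

#' @rdname write_stack
#' @param config Optional [optical_config()] overriding the sidecar
#'   values.
#' @export
read_stack <- function(path, config = NULL) {
  meta <- yaml::read_yaml(sidecar_path(path))
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) as.matrix(f) * meta$scale)
  if (is.null(config)) {
    config <- optical_config(wavelength_um = meta$wavelength_um,
                             medium_index = meta$medium_index)
  }
  intensity_stack(frames, meta$z_positions_um, meta$pitch_um, config,
                  source_id = meta$source_id)
}

#' Write / read a phase map on disk
#'
#' The phase is stored as a 32-bit float TIFF in \[0, 1\] with the
#' (min, max) radian range in a YAML sidecar, plus the record needed to
#' recover radians exactly.
#'
#' @param phase A [phase_map()].
#' @param path Path of the `.tiff` file.
#' @return `write_phase()`: `path`, invisibly.  `read_phase()`: a
#'   [phase_map()].
#' @export
write_phase <- function(phase, path) {
  stopifnot(inherits(phase, "phase_map"))
  rng <- range(phase$phase_rad)
  img <- if (diff(rng) > 0) (phase$phase_rad - rng[1]) / diff(rng) else
    phase$phase_rad * 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  yaml::write_yaml(list(min_rad = rng[1], max_rad = rng[2],
                        pitch_um = phase$pitch_um), sidecar_path(path))
  invisible(path)
}

#' @rdname write_phase
#' @export
read_phase <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  img <- as.matrix(tiff::readTIFF(path))
  phi <- meta$min_rad + img * (meta$max_rad - meta$min_rad)
  phase_map(phi, meta$pitch_um, normalization = c(meta$min_rad,
                                                  meta$max_rad))
}
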