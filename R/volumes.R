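# ---- domain types: volumes, frame schedules, atlases, cohorts -------------

#' Construct a frame schedule
#'
#' A frame schedule records the start and end time (in seconds) of every
#' frame of a dynamic PET acquisition. Frames must be non-overlapping and in
#' temporal order; gaps between frames are allowed.
#'
#' @param starts numeric vector of frame start times, seconds.
#' @param ends numeric vector of frame end times, seconds.
#' @return A `frame_schedule` object (a data frame with columns `start_s`,
#'   `end_s`).
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) == 0)
    stop("'starts' and 'ends' must be nonempty vectors of equal length")
  if (any(!is.finite(starts)) || any(!is.finite(ends)))
    stop("frame times must be finite")
  if (any(ends <= starts))
    stop("every frame end must exceed its start")
  if (is.unsorted(starts, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("frames must not overlap")
  structure(data.frame(start_s = starts, end_s = ends),
            class = c("frame_schedule", "data.frame"))
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`.
#' @export
frame_durations <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  x$end_s - x$start_s
}

#' @rdname frame_schedule
#' @export
frame_midpoints <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  (x$start_s + x$end_s) / 2
}

#' Default dynamic PET frame schedule
#'
#' A 55-minute schedule with fine early frames (6 x 10 s, 4 x 30 s,
#' 4 x 60 s, 4 x 120 s, 8 x 300 s), suitable for early-frame perfusion
#' windows and reference-tissue kinetic modelling.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(10, 6), rep(30, 4), rep(60, 4), rep(120, 4), rep(300, 8))
  ends <- cumsum(dur)
  frame_schedule(ends - dur, ends)
}

#' Construct a dynamic (4D) image
#'
#' @param data 4D numeric array, voxel x frame (last dimension is time).
#' @param schedule a [frame_schedule()]; its length must equal the number of
#'   frames.
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(data, schedule) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, frame)")
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule")
  if (dim(data)[4] != nrow(schedule))
    stop(sprintf("number of frames (%d) does not match schedule length (%d)",
                 dim(data)[4], nrow(schedule)))
  structure(list(data = data, schedule = schedule), class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %d x %d x %d voxels, %d frames, %.0f-%.0f s\n",
              d[1], d[2], d[3], d[4],
              x$schedule$start_s[1], x$schedule$end_s[nrow(x$schedule)]))
  invisible(x)
}

#' Construct an atlas definition
#'
#' An atlas is an integer label volume (0 = outside any region) together
#' with region names and a region-to-lobe combination map.
#'
#' @param labels 3D integer array of region labels, 0 outside.
#' @param region_names named character vector mapping label (as character)
#'   to region name.
#' @param lobe_map named character vector mapping region name to lobe name.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An `atlas_def` object.
#' @export
atlas_definition <- function(labels, region_names, lobe_map,
                             voxel_size = c(2, 2, 2)) {
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  labs <- sort(unique(as.integer(labels[labels != 0])))
  missing_names <- setdiff(as.character(labs), names(region_names))
  if (length(missing_names))
    stop("labels without a region name: ", paste(missing_names, collapse = ", "))
  unmapped <- setdiff(unname(region_names[as.character(labs)]), names(lobe_map))
  if (length(unmapped))
    stop("regions without a lobe assignment: ", paste(unmapped, collapse = ", "))
  structure(list(labels = labels, region_names = region_names,
                 lobe_map = lobe_map, voxel_size = as.numeric(voxel_size)),
            class = "atlas_def")
}

#' @export
print.atlas_def <- function(x, ...) {
  cat(sprintf("Atlas: %s grid, %d regions, %d lobes\n",
              paste(dim(x$labels), collapse = " x "),
              length(x$region_names),
              length(unique(x$lobe_map))))
  invisible(x)
}

#' Construct a subject cohort
#'
#' @param images list of 3D arrays on a shared grid.
#' @param subject_id character vector of subject identifiers.
#' @param group character vector of group labels, drawn from
#'   `c("AD", "MCI+", "MCI-", "HC")`.
#' @param mask logical 3D array, the analysis brain mask.
#' @param voxel_size numeric length-3, mm.
#' @return A `pet_cohort` object.
#' @export
pet_cohort <- function(images, subject_id, group, mask,
                       voxel_size = c(2, 2, 2)) {
  if (!is.list(images) || length(images) == 0)
    stop("'images' must be a nonempty list of 3D arrays")
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all cohort images must share one grid")
  if (!identical(dim(mask), dims[[1]]))
    stop("mask grid does not match image grid")
  if (length(subject_id) != length(images) || length(group) != length(images))
    stop("subject_id and group must have one entry per image")
  bad <- setdiff(unique(group), c("AD", "MCI+", "MCI-", "HC"))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  structure(list(images = images, subject_id = as.character(subject_id),
                 group = as.character(group), mask = mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  tab <- table(factor(x$group, levels = c("AD", "MCI+", "MCI-", "HC")))
  cat(sprintf("PET cohort: %d subjects (%s), grid %s, %d mask voxels\n",
              length(x$images),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Apply a brain mask to a volume
#'
#' Voxels outside the mask are set to zero. Masking is idempotent.
#'
#' @param img 3D array.
#' @param mask logical 3D array of the same dimensions.
#' @return The masked array.
#' @export
apply_mask <- function(img, mask) {
  if (!identical(dim(img), dim(mask))) stop("mask grid mismatch")
  img[!mask] <- 0
  img
}

# ---- NIfTI and tabular I/O ------------------------------------------------

#' Read and write image volumes (NIfTI)
#'
#' `read_volume()` reads a 3D NIfTI image into a plain array with a
#' `voxel_size` attribute; `write_volume()` writes one. `read_dynamic()` and
#' `write_dynamic()` are the 4D analogues and require a frame schedule
#' (stored as a two-column CSV sidecar `start_s,end_s`).
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return `read_volume()`: 3D array with attribute `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 4L)
    stop("file is 4D; use read_dynamic() with a frame schedule: ", path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1:3]
  out
}

#' @rdname read_volume
#' @param img 3D array.
#' @param voxel_size numeric length-3 voxel size in mm (defaults to the
#'   array's `voxel_size` attribute, else 2 mm isotropic).
#' @export
write_volume <- function(img, path, voxel_size = NULL) {
  if (length(dim(img)) != 3L) stop("'img' must be a 3D array")
  vs <- voxel_size
  if (is.null(vs)) vs <- attr(img, "voxel_size")
  if (is.null(vs)) vs <- c(2, 2, 2)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "pixdim") <- vs
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' @rdname read_volume
#' @param schedule a [frame_schedule()], or a path to a schedule CSV.
#' @export
read_dynamic <- function(path, schedule) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(schedule) || is.null(schedule))
    stop("4D data require frame timing: supply 'schedule' ",
         "(a frame_schedule or path to a start_s,end_s CSV)")
  if (is.character(schedule)) schedule <- read_frame_schedule(schedule)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 3L)
    stop("expected a 4D dynamic image, found a 3D volume: ", path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D dynamic image: ", path)
  dynamic_image(array(as.numeric(img), dim = dim(img)), schedule)
}

#' @rdname read_volume
#' @param dyn a [dynamic_image()].
#' @param schedule_path where to write the schedule CSV sidecar (optional).
#' @export
write_dynamic <- function(dyn, path, schedule_path = NULL,
                          voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(dyn, "dynamic_image"))
  arr <- dyn$data
  attr(arr, "pixdim") <- c(voxel_size, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  if (!is.null(schedule_path)) write_frame_schedule(dyn$schedule, schedule_path)
  invisible(path)
}

#' Read and write frame-schedule CSV files
#'
#' @param path CSV with columns `start_s`, `end_s`.
#' @return A [frame_schedule()].
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(tab)))
    stop("schedule CSV must have columns start_s, end_s")
  frame_schedule(tab$start_s, tab$end_s)
}

#' @rdname read_frame_schedule
#' @param schedule a [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  utils::write.csv(data.frame(start_s = schedule$start_s,
                              end_s = schedule$end_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' Load a region-to-lobe combination table
#'
#' Reads a two-column table (`region`, `lobe`) describing how atlas regions
#' are combined into larger lobe volumes of interest.
#'
#' @param path CSV path with columns `region` and `lobe`.
#' @param atlas_regions optional character vector of atlas region names; any
#'   atlas region absent from the table is reported via a warning.
#' @return Named character vector: region name -> lobe name.
#' @export
load_region_combination <- function(path, atlas_regions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, colClasses = "character")
  if (!all(c("region", "lobe") %in% names(tab)))
    stop("region combination CSV must have columns 'region' and 'lobe'")
  if (nrow(tab) == 0) {
    warning("empty region combination table")
    return(stats::setNames(character(0), character(0)))
  }
  conflict <- tapply(tab$lobe, tab$region, function(l) length(unique(l)) > 1)
  if (any(conflict))
    stop("region(s) mapped to conflicting lobes: ",
         paste(names(conflict)[conflict], collapse = ", "))
  tab <- tab[!duplicated(tab$region), ]
  lobe_map <- stats::setNames(tab$lobe, tab$region)
  if (!is.null(atlas_regions)) {
    unlisted <- setdiff(atlas_regions, names(lobe_map))
    if (length(unlisted))
      warning("atlas regions absent from the combination table: ",
              paste(unlisted, collapse = ", "))
  }
  lobe_map
}

#' Write or read a cohort manifest
#'
#' The manifest CSV (`subject_id,group,path`) points at per-subject NIfTI
#' volumes on a shared grid.
#'
#' @param cohort a [pet_cohort()].
#' @param dir directory to write NIfTIs + manifest into.
#' @return `write_cohort()`: the manifest path. `read_cohort()`: a
#'   [pet_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subject_id, ".nii.gz"))
  for (i in seq_along(cohort$images))
    write_volume(cohort$images[[i]], paths[i], voxel_size = cohort$voxel_size)
  write_volume(array(as.numeric(cohort$mask), dim = dim(cohort$mask)),
               file.path(dir, "mask.nii.gz"), voxel_size = cohort$voxel_size)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(subject_id = cohort$subject_id,
                              group = cohort$group,
                              path = basename(paths)),
                   manifest, row.names = FALSE)
  manifest
}

#' @rdname write_cohort
#' @param manifest_path manifest CSV path.
#' @param mask_path NIfTI brain mask path.
#' @export
read_cohort <- function(manifest_path, mask_path) {
  tab <- utils::read.csv(manifest_path, colClasses = "character")
  if (!all(c("subject_id", "group", "path") %in% names(tab)))
    stop("manifest must have columns subject_id, group, path")
  base <- dirname(manifest_path)
  paths <- ifelse(file.exists(tab$path), tab$path, file.path(base, tab$path))
  images <- lapply(paths, read_volume)
  maskv <- read_volume(mask_path)
  vs <- attr(images[[1]], "voxel_size")
  if (is.null(vs)) vs <- c(2, 2, 2)
  pet_cohort(images, tab$subject_id, tab$group,
             array(maskv != 0, dim = dim(maskv)), voxel_size = vs)
}
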