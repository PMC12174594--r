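#' Write a scene to disk
#'
#' Writes the intensity image as an 8-bit grayscale PNG, the stratification
#' and lesion masks as single-channel PNGs carrying the literal labels
#' \{0, 1, 2\}, and the annotations (normalized fovea abscissa plus the three
#' per-column boundary rows recovered from the mask) as JSON.
#'
#' @param scene a `retinal_scene`.
#' @param dir output directory (created if missing).
#' @param id scan identifier used as file-name stem.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_scene <- function(scene, dir, id) {
  stopifnot(inherits(scene, "retinal_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, paste0(id, "_image.png")),
             strat = file.path(dir, paste0(id, "_strat.png")),
             lesion = file.path(dir, paste0(id, "_lesion.png")),
             annot = file.path(dir, paste0(id, "_annot.json")))
  png::writePNG(scene$image, paths[["image"]])
  png::writePNG(scene$strat_mask / 255, paths[["strat"]])
  png::writePNG(scene$lesion_mask / 255, paths[["lesion"]])
  b <- mask_boundaries(scene$strat_mask)
  jsonlite::write_json(list(fovea_x = scene$fovea_x,
                            ilm = b$ilm, rpe = b$rpe, choroid = b$choroid),
                       paths[["annot"]], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory containing the files.
#' @param id scan identifier.
#' @return A `retinal_scene` (truth recomputed from the masks on disk).
#' @export
read_scene <- function(dir, id) {
  read_mask <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  }
  image <- png::readPNG(file.path(dir, paste0(id, "_image.png")))
  if (length(dim(image)) == 3L) image <- image[, , 1L]
  annot <- jsonlite::read_json(file.path(dir, paste0(id, "_annot.json")),
                               simplifyVector = TRUE)
  new_retinal_scene(image,
                    read_mask(file.path(dir, paste0(id, "_strat.png"))),
                    read_mask(file.path(dir, paste0(id, "_lesion.png"))),
                    annot$fovea_x)
}

#' Write a cohort to a directory tree
#'
#' One subdirectory per pair (`pair_001`, ...) holding the pre, real post, and
#' predicted post scenes, plus `manifest.csv` at the top level with the truth
#' measurements and ground-truth trend labels.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oct_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- c("pre", "post_real", "post_predicted")
  for (i in seq_along(cohort$pairs)) {
    sub <- file.path(dir, sprintf("pair_%03d", i))
    for (role in roles) write_scene(cohort$pairs[[i]][[role]], sub, role)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$truth, manifest, row.names = FALSE)
  invisible(manifest)
}
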