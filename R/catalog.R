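#' Load a structure catalog from JSON
#'
#' The file holds \code{{"structures": [{"id", "name", "category",
#' "penalty", "is_goal"}, ...]}}. Validation enforces unique ids, exactly
#' one goal (tumor) structure, and non-negative penalties.
#'
#' @param path path to a catalog JSON file.
#' @return A \linkS4class{StructureCatalog}.
#' @seealso [writeCatalog()], [defaultCatalog()]
#' @export
loadCatalog <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$structures))
    stop("catalog document must contain a 'structures' array")
  df <- as.data.frame(doc$structures)
  need <- c("id", "name", "category", "penalty")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalog entries missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(df$is_goal)) df$is_goal <- df$category == "tumor"
  StructureCatalog(df)
}

#' Write a structure catalog to JSON
#'
#' @param catalog a \linkS4class{StructureCatalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  jsonlite::write_json(list(structures = structures(catalog)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default structure catalog of transcortical surgical landmarks
#'
#' One entry per avoid-structure class encountered in transcortical
#' approaches -- major arteries, deep and superficial veins, dural sinuses,
#' white-matter tracts, eloquent gyri and deep nuclei -- plus the tumor as
#' the goal. Penalty magnitudes are package defaults expressing the usual
#' clinical hierarchy (arteries and sinuses worst, superficial veins least);
#' they are fully overridable through a catalog file.
#'
#' @return A \linkS4class{StructureCatalog}.
#' @examples
#' defaultCatalog()
#' @export
defaultCatalog <- function() {
  StructureCatalog(data.frame(
    id = 1:12,
    name = c(
      "tumor",
      "internal carotid artery and main branches",
      "basilar artery and main branches",
      "superior sagittal sinus and other main sinuses",
      "vein of Labbe (inferior anastomotic vein)",
      "superior anastomotic vein (Trolard)",
      "superficial sylvian vein",
      "corticospinal tract",
      "arcuate and superior longitudinal fasciculus",
      "precentral and postcentral gyri",
      "Broca and Wernicke areas",
      "caudate and lenticular nuclei, thalamus"),
    category = c("tumor", "artery", "artery", "sinus", "vein", "vein",
                 "vein", "tract", "tract", "eloquent_cortex",
                 "eloquent_cortex", "nucleus"),
    penalty = c(0, 100, 100, 100, 40, 40, 40, 80, 80, 80, 80, 60),
    is_goal = c(TRUE, rep(FALSE, 11))))
}

#' Per-id penalty lookup table
#'
#' @param catalog a \linkS4class{StructureCatalog}.
#' @return numeric vector such that \code{lut[id]} is the structure's
#'   penalty; the goal id maps to 0 (reward, not penalty).
#' @export
penaltyLUT <- function(catalog) {
  df <- structures(catalog)
  lut <- numeric(max(df$id))
  lut[df$id] <- df$penalty
  lut[df$id[df$is_goal]] <- 0
  lut
}

#' Validate a label map against a catalog
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param catalog a \linkS4class{StructureCatalog}.
#' @return TRUE invisibly, or an error naming the uncatalogued label.
#' @export
validateLabels <- function(labelmap, catalog) {
  ids <- sort(unique(as.integer(labels3d(labelmap))))
  ids <- ids[ids != 0L]
  bad <- setdiff(ids, structures(catalog)$id)
  if (length(bad))
    stop("label map contains uncatalogued label(s): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Extract the tumor goal region from a label map
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param catalog a \linkS4class{StructureCatalog}.
#' @return A \linkS4class{GoalRegion}; its canonical \code{goalPoint} is
#'   the tumor voxel nearest the tumor centroid (ties broken
#'   lexicographically).
#' @export
goalRegion <- function(labelmap, catalog) {
  gid <- goalId(catalog)
  vox <- which(labels3d(labelmap) == gid, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("empty tumor region: no voxel carries the goal label")
  colnames(vox) <- NULL
  vox <- vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
  ctr <- colMeans(vox)
  d2 <- (vox[, 1] - ctr[1])^2 + (vox[, 2] - ctr[2])^2 + (vox[, 3] - ctr[3])^2
  gp <- vox[which.min(d2), ]
  new("GoalRegion", voxels = vox, goalPoint = as.integer(gp),
      label = as.integer(gid))
}
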