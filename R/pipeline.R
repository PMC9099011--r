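# End-to-end two-stage pipeline: Stage-1 staged reduction per cell
# dimension, Stage-2 environment construction per the mode rule, training,
# and extraction of the best nonlinear trajectory, with all artifacts
# written to a self-describing run directory.

.readPipelineConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  config
}

.writeLinearPaths <- function(paths, path) {
  doc <- lapply(paths, function(p) list(
    face = p@face, u = p@u, v = p@v, n = p@n,
    entry = as.integer(p@entry), goal_point = as.integer(p@goalPoint),
    penalty = p@penalty, length_voxels = p@lengthVoxels,
    center_line = unname(apply(p@centerLine, 1, as.integer,
                               simplify = FALSE))))
  jsonlite::write_json(list(indexing = "1-based", paths = doc), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full two-stage planning pipeline
#'
#' Loads (or generates) the volume, labels and catalog, derives the head
#' mask, runs the Stage-1 funnel for every configured cell dimension, then
#' builds the Stage-2 environment per the mode rule (narrow dimensions
#' contribute entry points, wide ones the corridor environment), trains
#' the Q-learning agent and extracts the best nonlinear trajectory. All
#' outputs land in \code{outDir}: per-dimension linear path lists, the
#' ranked starts, the best trajectory JSON, a NIfTI overlay and a run
#' manifest recording seed and configuration. Reruns with identical
#' configuration and seed write byte-identical trajectory files.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \code{phantom} (arguments to [phantomSpec()]) or \code{volume} /
#'   \code{labels} (NIfTI paths or a DICOM directory), optional
#'   \code{catalog} (path; default [defaultCatalog()]), optional
#'   \code{planner} (arguments to [plannerConfig()]) and \code{q}
#'   (arguments to [qConfig()]).
#' @param outDir run directory (created).
#' @return list with \code{linearPaths} (per cell dimension), \code{env},
#'   \code{qtable}, \code{ranking}, \code{best}
#'   (\linkS4class{TrajectoryResult}) and the output file paths.
#' @export
runPipeline <- function(config, outDir) {
  config <- .readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  pcfg <- do.call(plannerConfig, as.list(config$planner))
  qcfg <- do.call(qConfig, as.list(config$q))

  if (!is.null(config$phantom)) {
    spec <- do.call(phantomSpec, as.list(config$phantom))
    ph <- generatePhantom(spec)
    volume <- ph$volume; labelmap <- ph$labels
    catalog <- if (is.null(config$catalog)) ph$catalog else loadCatalog(config$catalog)
    mask <- ph$headMask
  } else {
    if (is.null(config$volume) || is.null(config$labels))
      stop("config must provide either 'phantom' or 'volume' + 'labels'")
    volume <- if (dir.exists(config$volume)) readDicomSeries(config$volume)
              else readNiftiVolume(config$volume)
    labelmap <- readNiftiLabels(config$labels)
    catalog <- if (is.null(config$catalog)) defaultCatalog()
               else loadCatalog(config$catalog)
    mask <- headMask(volume)
  }
  validateLabels(labelmap, catalog)
  dims <- dim(labelmap)
  goal <- goalRegion(labelmap, catalog)

  linearPaths <- list()
  files <- list()
  for (n in pcfg@cellDims) {
    windows <- enumerateEntryWindows(dims, n)
    message(sprintf("[stage1] n=%d: %d candidate windows", n, nrow(windows)))
    paths <- stagedReduction(windows, goal, labelmap, catalog, mask, pcfg)
    message(sprintf("[stage1] n=%d: kept %d paths, best penalty %.4g",
                    n, length(paths), paths[[1]]@penalty))
    key <- sprintf("n%02d", n)
    linearPaths[[key]] <- paths
    f <- file.path(outDir, sprintf("linear_paths_%s.json", key))
    .writeLinearPaths(paths, f)
    files[[paste0("linear_", key)]] <- f
  }
  allPaths <- do.call(c, unname(linearPaths))
  if (length(allPaths) == 0L) stop("Stage 1 produced no linear paths")

  env <- buildEnvironment(allPaths, labelmap, catalog, mask, pcfg, qcfg)
  message(sprintf("[stage2] environment: %d nodes, %d start states",
                  nodeCount(env), nrow(startStates(env))))
  tr <- train(env, qcfg)
  message(sprintf("[stage2] trained %d episodes; %.1f%% reached the goal",
                  qcfg@episodes, 100 * mean(tr$stats$cause == "goal")))
  ranking <- rankStarts(tr$qtable, env, gamma = qcfg@gamma)
  f <- file.path(outDir, "ranked_starts.json")
  jsonlite::write_json(ranking, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files$ranking <- f

  # a usable trajectory must end in the tumor, not in a penalized structure
  rankedPaths <- attr(ranking, "paths")
  reachesGoal <- vapply(rankedPaths, function(p) {
    if (is.null(p)) return(FALSE)
    last <- p@path[nrow(p@path), ]
    env@reward[last[1], last[2], last[3]] > 0
  }, TRUE)
  if (!any(reachesGoal))
    stop("Stage 2 extraction failed for every start state")
  best <- rankedPaths[[which(reachesGoal)[1]]]
  f <- file.path(outDir, "best_trajectory.json")
  writeTrajectory(best, f, labelmap)
  files$best <- f
  f <- file.path(outDir, "overlay.nii.gz")
  burnOverlay(volume, pathCoords(best), f, "nifti")
  files$overlay <- f

  manifest <- list(package_version = as.character(utils::packageVersion("CorticoPath")),
                   r_version = R.version.string,
                   seed = qcfg@seed, config = config,
                   dims = dims, n_nodes = nodeCount(env),
                   n_starts = nrow(startStates(env)))
  f <- file.path(outDir, "run_info.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$manifest <- f

  list(linearPaths = linearPaths, env = env, qtable = tr$qtable,
       stats = tr$stats, ranking = ranking, best = best, files = files)
}
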