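#' Pipeline run configuration
#'
#' Collects every stage parameter of the branch-to-phenotype pipeline in
#' one serializable object.  A run's configuration plus its seed fully
#' determine its outputs.
#'
#' @param input path to the labeled input cloud (n x 4/5 matrix, PLY or
#'   PCD); may be `NULL` when the cloud is passed directly to
#'   [run_pipeline()].
#' @param out_dir output directory of the run.
#' @param sor_k,sor_std statistical outlier removal parameters
#'   ([remove_outliers()]).
#' @param voxel voxel size in meters ([voxel_thin()]); `0` disables
#'   thinning.
#' @param fps_m farthest-point-sample size ([farthest_point_sample()]);
#'   `0` disables sampling.  Preprocessing for phenotype estimation keeps
#'   the full density; FPS and normalization serve the fixed-size network
#'   input path and are off by default.
#' @param cube_side normalization cube side ([normalize_cloud()]); `0`
#'   disables normalization (measurements are always taken in original
#'   coordinates).
#' @param radius mean-shift bandwidth in meters ([mean_shift_segment()]).
#' @param min_points_cluster minimum cluster size before dissolution.
#' @param mls_radius,mls_order MLS smoothing parameters ([mls_smooth()]).
#' @param k_midrib midrib-walk neighbourhood size.
#' @param mu triangulation edge-length bound.
#' @param min_points_leaf minimum points for phenotype estimation.
#' @param seed integer seed funnelling all randomness of the run.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(input = NULL, out_dir = "run",
                            sor_k = 16L, sor_std = 1.0,
                            voxel = 0.003, fps_m = 0L, cube_side = 0,
                            radius = 0.045, min_points_cluster = 10L,
                            mls_radius = 0.012, mls_order = 2L,
                            k_midrib = 8L, mu = 3.0,
                            min_points_leaf = 30L, seed = 1L) {
  structure(list(input = input, out_dir = out_dir,
                 sor_k = as.integer(sor_k), sor_std = sor_std,
                 voxel = voxel, fps_m = as.integer(fps_m),
                 cube_side = cube_side, radius = radius,
                 min_points_cluster = as.integer(min_points_cluster),
                 mls_radius = mls_radius, mls_order = as.integer(mls_order),
                 k_midrib = as.integer(k_midrib), mu = mu,
                 min_points_leaf = as.integer(min_points_leaf),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' YAML round trip: a written configuration reloads to an equal object.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  invisible(x)
}

#' Run the full branch-to-phenotype pipeline
#'
#' Stages: read the labeled branch cloud, statistical outlier removal,
#' voxel thinning, optional FPS + cube normalization (recorded and
#' inverted, so all measurements are in original meters), mean-shift
#' single-leaf segmentation, per-leaf phenotype estimation, and — when the
#' input carries ground-truth instance ids — segmentation evaluation.
#' Stage outputs, a phenotype CSV, an evaluation JSON and a log with
#' per-stage point counts are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param cloud optional [leaf_cloud()]; when missing, `config$input` is
#'   read.
#' @return Invisibly, a list with `cloud` (instance-labeled),
#'   `phenotypes` (the [phenotype_leaves()] data frame), `evaluation`
#'   (an `instance_report` or `NULL`) and `paths` (named output files).
#' @export
run_pipeline <- function(config, cloud = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cloud)) {
    if (is.null(config$input)) stop("no input cloud given")
    if (!file.exists(config$input))
      stop("input file not found: ", config$input)
    cloud <- read_cloud(config$input)
  }
  if (is.null(cloud$semantic))
    stop("pipeline input needs semantic labels (x y z label [instance])")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("input points: %d", n_points(cloud)))
  truth_inst <- cloud$instance

  work <- remove_outliers(cloud, k = config$sor_k,
                          std_ratio = config$sor_std)
  log_lines <- c(log_lines, sprintf("after SOR (k=%d, std=%.2f): %d",
                                    config$sor_k, config$sor_std,
                                    n_points(work)))
  if (config$voxel > 0) {
    work <- voxel_thin(work, voxel = config$voxel)
    log_lines <- c(log_lines, sprintf("after voxel thinning (%.4f m): %d",
                                      config$voxel, n_points(work)))
  }
  if (config$fps_m > 0) {
    sampled <- farthest_point_sample(work, m = config$fps_m,
                                     seed = config$seed)
    log_lines <- c(log_lines, sprintf("FPS sample: %d", n_points(sampled)))
    if (config$cube_side > 0) {
      nrm <- normalize_cloud(sampled, cube_side = config$cube_side)
      write_cloud(nrm$cloud, file.path(config$out_dir, "normalized.txt"))
      log_lines <- c(log_lines,
                     sprintf("normalized into %.1f m cube (scale %.6f)",
                             config$cube_side, nrm$transform$scale))
    }
    write_cloud(sampled, file.path(config$out_dir, "sampled.txt"))
  }
  write_cloud(work, file.path(config$out_dir, "preprocessed.txt"))

  seg <- mean_shift_segment(work, radius = config$radius,
                            min_points = config$min_points_cluster)
  inst_cloud <- apply_instances(work, seg)
  write_cloud(inst_cloud, file.path(config$out_dir, "instanced.txt"))
  log_lines <- c(log_lines,
                 sprintf("mean shift (radius %.3f m): %d instance(s)",
                         config$radius, nrow(seg$centers)))

  phen <- phenotype_leaves(inst_cloud, mls_radius = config$mls_radius,
                           mls_order = config$mls_order,
                           k = config$k_midrib, mu = config$mu,
                           min_points = config$min_points_leaf)
  csv_path <- file.path(config$out_dir, "phenotypes.csv")
  utils::write.csv(phen, csv_path, row.names = FALSE)
  log_lines <- c(log_lines, sprintf("phenotypes: %d ok of %d",
                                    sum(phen$status == "ok"), nrow(phen)))

  evaluation <- NULL
  if (!is.null(truth_inst) && any(truth_inst >= 0L)) {
    # evaluate on the preprocessed points, whose truth ids survived thinning
    tr <- instance_sets(work)
    pr <- instance_sets(inst_cloud)
    evaluation <- instance_pr(tr, pr)
    eval_path <- file.path(config$out_dir, "evaluation.json")
    jsonlite::write_json(list(instance = list(
      precision = evaluation$precision, recall = evaluation$recall,
      mcov = evaluation$mcov, n_true = evaluation$n_true,
      n_pred = evaluation$n_pred)), eval_path, auto_unbox = TRUE,
      digits = NA)
    log_lines <- c(log_lines,
                   sprintf("evaluation: precision %.3f recall %.3f mCov %.3f",
                           evaluation$precision, evaluation$recall,
                           evaluation$mcov))
  }
  writeLines(log_lines, logf)
  invisible(list(cloud = inst_cloud, phenotypes = phen,
                 evaluation = evaluation,
                 paths = c(preprocessed = file.path(config$out_dir,
                                                    "preprocessed.txt"),
                           instanced = file.path(config$out_dir,
                                                 "instanced.txt"),
                           phenotypes = csv_path, log = logf)))
}
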