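#' Configure an end-to-end pipeline run
#'
#' Either point the pipeline at existing data (`volumes`, `mask`,
#' `subjects` paths) or supply a `synthetic` [cohort_config()] to generate
#' and analyze a fixture cohort. Referenced files must exist at
#' configuration time; feature names are validated up front so a typo fails
#' before any computation.
#'
#' @param output_dir directory for all artifacts (created on run).
#' @param volumes character vector of per-subject NIfTI paths (ignored when
#'   `synthetic` is given).
#' @param mask path to the brain-mask NIfTI.
#' @param subjects path to the subject table CSV (see
#'   [read_subject_table()]).
#' @param synthetic optional [cohort_config()]; when given, fixtures are
#'   generated under `output_dir/fixtures` and then analyzed.
#' @param glcm a [glcm_params()].
#' @param features texture features to analyze.
#' @param q_level FDR level for the voxel-wise maps.
#' @param min_cluster_size strict cluster-size threshold (kept if
#'   size > min_cluster_size).
#' @param connectivity 6, 18 or 26.
#' @param seed integer seed (used only by the synthetic branch).
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            volumes = NULL, mask = NULL, subjects = NULL,
                            synthetic = NULL,
                            glcm = glcm_params(),
                            features = TEXTURE_FEATURES,
                            q_level = 0.05,
                            min_cluster_size = 10,
                            connectivity = 26,
                            seed = 1,
                            log_level = "info") {
  check_features(features)
  stopifnot(inherits(glcm, "glcm_params"), q_level > 0, q_level < 1,
            min_cluster_size >= 0, connectivity %in% c(6, 18, 26))
  log_level <- match.arg(log_level, c("info", "debug", "quiet"))
  if (is.null(synthetic)) {
    if (is.null(volumes) || is.null(mask) || is.null(subjects))
      stop("either a synthetic cohort_config or volumes+mask+subjects paths are required")
    missing_files <- c(volumes, mask, subjects)[!file.exists(c(volumes, mask, subjects))]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  } else stopifnot(inherits(synthetic, "cohort_config"))
  structure(list(output_dir = output_dir, volumes = volumes, mask = mask,
                 subjects = subjects, synthetic = synthetic, glcm = glcm,
                 features = features, q_level = q_level,
                 min_cluster_size = min_cluster_size,
                 connectivity = connectivity, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round-trip of a [pipeline_config()]; `read_pipeline_config()`
#' reconstructs the nested [glcm_params()] and [cohort_config()] objects so
#' that write-then-read returns an equivalent configuration.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$glcm <- x$glcm[c("n_levels", "radius", "distance", "smoothing")]
  if (!is.null(x$synthetic)) {
    syn <- unclass(x$synthetic)
    syn$roi_specs <- lapply(syn$roi_specs, unclass)
    x$synthetic <- syn
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  glcm <- do.call(glcm_params, x$glcm)
  synthetic <- NULL
  if (!is.null(x$synthetic)) {
    rois <- lapply(x$synthetic$roi_specs, function(s) do.call(roi_spec, s))
    syn <- x$synthetic
    syn$roi_specs <- rois
    synthetic <- do.call(cohort_config, syn)
  }
  pipeline_config(output_dir = x$output_dir,
                  volumes = unlist(x$volumes), mask = x$mask,
                  subjects = x$subjects, synthetic = synthetic,
                  glcm = glcm, features = unlist(x$features),
                  q_level = x$q_level, min_cluster_size = x$min_cluster_size,
                  connectivity = x$connectivity, seed = x$seed,
                  log_level = x$log_level)
}

#' Read and validate a subject table
#'
#' Requires columns `subject_id`, `group` (binary 0/1), `age_years`, `sex`;
#' clinical columns (`duration_months`, `alsfrs`, `fi_left`, `fi_right`)
#' are optional and may contain missing values, which are flagged with a
#' warning but kept.
#'
#' @param path CSV file path.
#' @return Data frame of typed subject records.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age_years", "sex")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("subject table lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  if (!all(tab$group %in% c(0, 1))) stop("group must be binary 0/1")
  if (anyNA(tab$group) || anyNA(tab$age_years) || anyNA(tab$sex))
    stop("group, age_years and sex must be complete")
  for (cc in intersect(c("duration_months", "alsfrs", "fi_left", "fi_right"), names(tab))) {
    n_na <- sum(is.na(tab[[cc]]) & tab$group == 1)
    if (n_na > 0)
      warning(n_na, " patient row(s) with missing ", cc)
  }
  tab
}

#' Check that volumes and mask share one grid
#'
#' Asserts identical voxel dimensions and affines (within `tol` mm,
#' default 1e-4) across all files.
#'
#' @param volume_paths character vector of NIfTI paths.
#' @param mask_path NIfTI mask path used as the reference grid.
#' @param tol mm tolerance on affine entries.
#' @return Invisibly, a data frame (file, dims, max affine deviation);
#'   mismatches raise an error naming the offending files.
#' @export
validate_geometry <- function(volume_paths, mask_path, tol = 1e-4) {
  ref_hdr <- RNifti::niftiHeader(mask_path)
  ref_dim <- ref_hdr$dim[2:4]
  ref_aff <- RNifti::xform(ref_hdr)
  rows <- lapply(volume_paths, function(p) {
    h <- RNifti::niftiHeader(p)
    data.frame(file = p,
               dims = paste(h$dim[2:4], collapse = "x"),
               dim_ok = all(h$dim[2:4] == ref_dim),
               affine_dev = max(abs(RNifti::xform(h) - ref_aff)))
  })
  report <- do.call(rbind, rows)
  bad <- report[!report$dim_ok | report$affine_dev > tol, ]
  if (nrow(bad))
    stop("geometry mismatch against mask grid (", paste(ref_dim, collapse = "x"),
         "): ", paste(basename(bad$file), collapse = ", "))
  invisible(report)
}

plog <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$log_level]] >= lv[[level]]) message("[", level, "] ", ...)
}

#' Run the whole analysis pipeline
#'
#' Sequences the full method: (synthetic fixture generation or input
#' loading) -> geometry validation -> per-subject texture maps (cached to
#' disk) -> per-feature voxel-wise GLM with FDR correction -> cluster
#' extraction -> region means, ROC and clinical correlations -> region
#' report. All artifacts are written under `config$output_dir`, and a JSON
#' manifest records the configuration, package version, per-file MD5 hashes
#' and timestamps; with a fixed configuration and seed the output hashes
#' are reproducible.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- stage: inputs -------------------------------------------------------
  inp <- resolve_inputs(config)
  vol_paths <- inp$volumes
  mask_path <- inp$mask
  subj_path <- inp$subjects
  subjects <- read_subject_table(subj_path)
  ids_from_files <- sub("_T1w\\.nii(\\.gz)?$", "", basename(vol_paths))
  if (length(vol_paths) != nrow(subjects) ||
      !setequal(ids_from_files, subjects$subject_id)) {
    only_csv <- setdiff(subjects$subject_id, ids_from_files)
    only_vol <- setdiff(ids_from_files, subjects$subject_id)
    stop("subject table and volumes disagree; only in CSV: ",
         paste(only_csv, collapse = ", "), "; only as volumes: ",
         paste(only_vol, collapse = ", "))
  }
  vol_paths <- vol_paths[match(subjects$subject_id, ids_from_files)]
  validate_geometry(vol_paths, mask_path)
  plog(config, "info", "stage inputs: ", nrow(subjects), " subjects validated")

  ma <- read_mask_and_affine(mask_path)
  mask <- ma$mask
  affine <- ma$affine
  volumes <- lapply(vol_paths, function(p) {
    v <- RNifti::readNifti(p)
    array(as.vector(v), dim = dim(v))
  })
  names(volumes) <- subjects$subject_id

  # --- stage: texture ------------------------------------------------------
  plog(config, "info", "stage texture: ", length(config$features),
       " features x ", length(volumes), " subjects")
  maps <- cohort_texture_maps(volumes, mask, config$features, config$glcm,
                              verbose = config$log_level == "debug")
  map_dir <- file.path(out, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  map_paths <- character()
  for (sid in names(maps))
    for (f in config$features) {
      p <- file.path(map_dir, paste0(sid, "_", f, ".nii.gz"))
      write_nifti_volume(maps[[sid]][[f]], affine, p)
      map_paths <- c(map_paths, p)
    }
  sidecar <- file.path(map_dir, "glcm_params.json")
  jsonlite::write_json(config$glcm[c("n_levels", "radius", "distance", "smoothing")],
                       sidecar, auto_unbox = TRUE, digits = NA)

  # --- stage: statistics + regions -----------------------------------------
  res <- analyze_maps(maps, subjects, mask, affine, config, out)

  manifest_path <- file.path(out, "manifest.json")
  all_out <- c(vol_paths, mask_path, subj_path, map_paths, sidecar,
               res$stat_paths, res$table_paths)
  cfg_file <- file.path(out, "config.yaml")
  write_pipeline_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(packageVersion("texmap3d")),
    seed = config$seed,
    config = cfg_file,
    n_subjects = nrow(subjects),
    stat_maps = basename(res$stat_paths),
    n_clusters = res$n_clusters,
    hashes = as.list(unname(Map(function(p, h) list(file = basename(p), md5 = unname(h)),
                                all_out, tools::md5sum(all_out)))),
    finished = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  plog(config, "info", "pipeline finished: ", res$n_clusters, " cluster(s), manifest at ",
       manifest_path)
  invisible(manifest)
}

# Resolve input paths, generating synthetic fixtures on first use.
resolve_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    fixdir <- file.path(config$output_dir, "fixtures")
    if (!file.exists(file.path(fixdir, "subjects.csv"))) {
      plog(config, "info", "stage simulate: writing synthetic fixtures")
      syn <- config$synthetic
      syn$seed <- config$seed
      write_fixture_set(fixdir, syn)
    }
    list(volumes = sort(list.files(fixdir, pattern = "_T1w\\.nii(\\.gz)?$",
                                   full.names = TRUE)),
         mask = file.path(fixdir, "brain_mask.nii.gz"),
         subjects = file.path(fixdir, "subjects.csv"))
  } else {
    list(volumes = config$volumes, mask = config$mask,
         subjects = config$subjects)
  }
}

read_mask_and_affine <- function(mask_path) {
  mask_img <- RNifti::readNifti(mask_path)
  list(mask = array(as.vector(mask_img) > 0.5, dim = dim(mask_img)),
       affine = matrix(as.numeric(RNifti::xform(mask_img)), 4, 4))
}

# Texture stage only: compute per-subject maps and cache them under
# <output_dir>/maps (one NIfTI per subject and feature + params sidecar).
run_texture_stage <- function(config) {
  inp <- resolve_inputs(config)
  subjects <- read_subject_table(inp$subjects)
  validate_geometry(inp$volumes, inp$mask)
  ma <- read_mask_and_affine(inp$mask)
  volumes <- lapply(inp$volumes, function(p) {
    v <- RNifti::readNifti(p)
    array(as.vector(v), dim = dim(v))
  })
  names(volumes) <- sub("_T1w\\.nii(\\.gz)?$", "", basename(inp$volumes))
  maps <- cohort_texture_maps(volumes, ma$mask, config$features, config$glcm,
                              verbose = config$log_level == "debug")
  map_dir <- file.path(config$output_dir, "maps")
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (sid in names(maps))
    for (f in config$features) {
      p <- file.path(map_dir, paste0(sid, "_", f, ".nii.gz"))
      write_nifti_volume(maps[[sid]][[f]], ma$affine, p)
      paths <- c(paths, p)
    }
  jsonlite::write_json(config$glcm[c("n_levels", "radius", "distance", "smoothing")],
                       file.path(map_dir, "glcm_params.json"),
                       auto_unbox = TRUE, digits = NA)
  plog(config, "info", "stage texture: cached ", length(paths), " maps in ", map_dir)
  invisible(list(maps = paths, subjects = subjects))
}

# Statistics stage from cached maps written by run_texture_stage().
run_analyze_stage <- function(config) {
  inp <- resolve_inputs(config)
  subjects <- read_subject_table(inp$subjects)
  ma <- read_mask_and_affine(inp$mask)
  map_dir <- file.path(config$output_dir, "maps")
  maps <- lapply(subjects$subject_id, function(sid) {
    per_feature <- lapply(config$features, function(f) {
      p <- file.path(map_dir, paste0(sid, "_", f, ".nii.gz"))
      if (!file.exists(p)) stop("cached map missing: ", p,
                                " (run the texture stage first)")
      v <- RNifti::readNifti(p)
      array(as.vector(v), dim = dim(v))
    })
    names(per_feature) <- config$features
    per_feature
  })
  names(maps) <- subjects$subject_id
  analyze_maps(maps, subjects, ma$mask, ma$affine, config, config$output_dir)
}

# Statistics, cluster and region stages over in-memory texture maps.
analyze_maps <- function(maps, subjects, mask, affine, config, out) {
  design <- build_design_matrix(subjects)
  stat_dir <- file.path(out, "stats")
  dir.create(stat_dir, showWarnings = FALSE)
  stat_paths <- character()
  cluster_rows <- list()
  region_rows <- list()
  n_clusters <- 0L

  for (f in config$features) {
    fmaps <- lapply(maps, `[[`, f)
    sm <- fit_voxelwise_glm(fmaps, design)
    fdr <- fdr_correct(sm$p, config$q_level)
    plog(config, "info", "stage analyze [", f, "]: ", sm$n_valid,
         " voxels tested, ", fdr$n_significant, " significant at q<=",
         config$q_level)
    for (nm in c("F", "p")) {
      pth <- file.path(stat_dir, paste0(f, "_", nm, ".nii.gz"))
      write_nifti_volume(sm[[nm]], affine, pth)
      stat_paths <- c(stat_paths, pth)
    }
    qp <- file.path(stat_dir, paste0(f, "_q.nii.gz"))
    write_nifti_volume(fdr$q, affine, qp)
    stat_paths <- c(stat_paths, qp)

    clusters <- extract_clusters(fdr$sig_mask, sm$F, affine,
                                 min_size = config$min_cluster_size,
                                 connectivity = config$connectivity,
                                 group_coef = sm$group_coef)
    n_clusters <- n_clusters + length(clusters)
    ct <- cluster_table(clusters, fdr$q)
    if (nrow(ct)) {
      ct <- cbind(feature = f, ct)
      cluster_rows[[f]] <- ct
    }
    for (cl in clusters)
      region_rows[[paste(f, cl$id)]] <-
        region_report_row(maps, subjects, cl, f)
  }

  tab_dir <- file.path(out, "tables")
  dir.create(tab_dir, showWarnings = FALSE)
  cl_path <- file.path(tab_dir, "clusters.csv")
  rg_path <- file.path(tab_dir, "region_report.csv")
  cl_tab <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    cbind(feature = character(), cluster_table(list()))
  write.csv(cl_tab, cl_path, row.names = FALSE)
  rg_tab <- if (length(region_rows)) do.call(rbind, region_rows) else
    region_report_row(NULL, NULL, NULL, NULL)[0, ]
  write.csv(rg_tab, rg_path, row.names = FALSE)

  list(stat_paths = stat_paths, table_paths = c(cl_path, rg_path),
       n_clusters = n_clusters, clusters = cl_tab, region_report = rg_tab)
}

# One region-report row: group summary, ROC, clinical correlations
# (duration/ALSFRS/tapping over patients only).
region_report_row <- function(maps, subjects, cluster, feature) {
  cols <- c("cluster_id", "feature", "size_voxels", "mean_control",
            "sd_control", "mean_patient", "sd_patient", "auc", "cutoff",
            "sensitivity_pct", "specificity_pct", "r_duration", "p_duration",
            "r_tapping", "p_tapping", "r_alsfrs", "p_alsfrs")
  if (is.null(cluster)) {
    empty <- as.data.frame(setNames(rep(list(numeric()), length(cols)), cols))
    return(empty)
  }
  fmaps <- lapply(maps, `[[`, feature)
  rs <- region_means(fmaps, cluster, group = subjects$group)
  roc <- roc_analysis(rs)
  pat <- subjects$group == 1
  corr <- function(measure) {
    tryCatch({
      cr <- clinical_correlation(rs$values, measure, subset = pat)
      c(cr$r, cr$p)
    }, error = function(e) c(NA_real_, NA_real_))
  }
  getcol <- function(nm) if (nm %in% names(subjects)) subjects[[nm]]
                         else rep(NA_real_, nrow(subjects))
  tapping <- (getcol("fi_left") + getcol("fi_right")) / 2
  cd <- corr(getcol("duration_months"))
  ctap <- corr(tapping)
  ca <- corr(getcol("alsfrs"))
  data.frame(cluster_id = cluster$id, feature = feature,
             size_voxels = cluster$size,
             mean_control = mean(rs$values[!pat], na.rm = TRUE),
             sd_control = sd(rs$values[!pat], na.rm = TRUE),
             mean_patient = mean(rs$values[pat], na.rm = TRUE),
             sd_patient = sd(rs$values[pat], na.rm = TRUE),
             auc = roc$auc, cutoff = roc$cutoff,
             sensitivity_pct = roc$sensitivity_pct,
             specificity_pct = roc$specificity_pct,
             r_duration = cd[1], p_duration = cd[2],
             r_tapping = ctap[1], p_tapping = ctap[2],
             r_alsfrs = ca[1], p_alsfrs = ca[2])
}
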