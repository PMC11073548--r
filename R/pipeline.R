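#' Run the full topological inference pipeline
#'
#' Ties the package together: ingest (feature table + group manifest, or a
#' directory of networks + manifest), optional leave-one-out jackknife,
#' birth-death decomposition, Betti curves on a shared threshold grid,
#' pairwise topological distances, group-difference inference, and artifact
#' output. Every run is reproducible from its configuration plus seed.
#'
#' @param config A configuration list or path to a YAML file with fields:
#' \describe{
#'   \item{features / networks}{Exactly one of: `features` (path to a
#'     subject-by-node table; subjects are jackknifed into per-subject
#'     networks per group) or `networks` (directory of matrix files).}
#'   \item{manifest}{Two-column file mapping subject or file names to the two
#'     group labels. Required.}
#'   \item{out_dir}{Output directory (created if needed). Required.}
#'   \item{method}{`"permutation"` (default), `"transposition"` or `"z"`.}
#'   \item{distance}{`"combined"` (default), `"d0"` or `"d1"`.}
#'   \item{w0, w1}{Combined-distance weights (default 1, 1).}
#'   \item{n_resamples}{Resamples for the resampling tests (default 2000).}
#'   \item{full_perm_interval}{Transposition refresh interval (default 1000).}
#'   \item{grid_points, grid_mode}{Betti threshold grid (default 100,
#'     `"uniform"`); the grid spans the pooled weight range of all networks.}
#'   \item{seed}{Integer seed recorded in every output (default 1).}
#' }
#' @return Invisibly, a list with the test `report`, the `distances`
#'   (`grouped_dist`), the per-network `betti` curves, the shared `grid`, and
#'   the output file `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_config(config)
  t0 <- Sys.time()
  log_lines <- c(sprintf("topofilt %s | R %s.%s",
                         as.character(utils::packageVersion("topofilt")),
                         R.version$major, R.version$minor),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("started: %s", format(t0)))
  set.seed(cfg$seed)

  groups <- run_stage("ingest", ingest_groups(cfg))
  log_lines <- c(log_lines, sprintf("ingest: %d + %d networks (%s)",
                                    length(groups$g1), length(groups$g2),
                                    paste(groups$names, collapse = " vs ")))

  nets <- c(groups$g1, groups$g2)
  grid <- run_stage("betti", {
    allw <- unlist(lapply(nets, function(x) edge_list(x)$w))
    lo <- min(allw); hi <- max(allw)
    delta <- max(hi - lo, .Machine$double.eps) * 1e-3
    if (cfg$grid_mode == "exact") sort(unique(allw))
    else seq(lo - delta, hi, length.out = cfg$grid_points)
  })
  betti <- run_stage("betti", lapply(nets, betti_curves, thresholds = grid))

  gd <- run_stage("distances",
                  pairwise_distances(groups$g1, groups$g2,
                                     w0 = cfg$w0, w1 = cfg$w1,
                                     group_names = groups$names))
  Dmat <- dist_matrix(gd, cfg$distance)
  report <- run_stage("inference", switch(
    cfg$method,
    permutation = permutation_test(Dmat, gd$labels,
                                   n_perms = cfg$n_resamples,
                                   seed = cfg$seed),
    transposition = transposition_test(Dmat, gd$labels,
                                       n_transpositions = cfg$n_resamples,
                                       full_perm_interval =
                                         cfg$full_perm_interval,
                                       seed = cfg$seed),
    z = z_test(Dmat, gd$labels)))

  paths <- run_stage("write", {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(cfg$out_dir, "betti"), showWarnings = FALSE)
    dir.create(file.path(cfg$out_dir, "diagrams"), showWarnings = FALSE)
    ids <- sprintf("%s_%02d", as.character(gd$labels),
                   c(seq_along(groups$g1), seq_along(groups$g2)))
    for (k in seq_along(nets)) {
      write_betti(betti[[k]],
                  file.path(cfg$out_dir, "betti", paste0(ids[k], ".tsv")))
      write_decomposition(birth_death_decompose(nets[[k]]),
                          file.path(cfg$out_dir, "diagrams", ids[k]))
    }
    dpath <- file.path(cfg$out_dir, "distances.tsv")
    write_distance_matrix(gd, dpath, which = cfg$distance)
    rpath <- file.path(cfg$out_dir, "report.json")
    write_report(report, rpath)
    yaml::write_yaml(cfg[setdiff(names(cfg), "config")],
                     file.path(cfg$out_dir, "run_config.yaml"))
    list(report = rpath, distances = dpath, out_dir = cfg$out_dir)
  })

  log_lines <- c(log_lines,
                 sprintf("inference: %s on %s distance, p = %.6g",
                         cfg$method, cfg$distance, report$p_value),
                 sprintf("finished: %s (%.2f s)", format(Sys.time()),
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  invisible(list(report = report, distances = gd, betti = betti,
                 grid = grid, paths = paths))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_topofilt(sprintf("stage '%s': %s", name, conditionMessage(e)),
                   "topofilt_pipeline")
  })
}

pipeline_config <- function(config) {
  if (!is.list(config)) {
    abort_topofilt("`config` must be a list or a YAML file path",
                   "topofilt_invalid_parameter")
  }
  get_or <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  cfg <- list(
    features = config$features,
    networks = config$networks,
    manifest = config$manifest,
    out_dir = config$out_dir,
    method = match.arg(get_or("method", "permutation"),
                       c("permutation", "transposition", "z")),
    distance = match.arg(get_or("distance", "combined"),
                         c("combined", "d0", "d1")),
    w0 = get_or("w0", 1), w1 = get_or("w1", 1),
    n_resamples = get_or("n_resamples", 2000L),
    full_perm_interval = get_or("full_perm_interval", 1000L),
    grid_points = get_or("grid_points", 100L),
    grid_mode = match.arg(get_or("grid_mode", "uniform"),
                          c("uniform", "exact")),
    seed = as.integer(get_or("seed", 1L)))
  if (is.null(cfg$out_dir)) {
    abort_topofilt("config: `out_dir` is required", "topofilt_invalid_parameter")
  }
  if (is.null(cfg$features) == is.null(cfg$networks)) {
    abort_topofilt("config: exactly one of `features` or `networks` required",
                   "topofilt_invalid_parameter")
  }
  if (is.null(cfg$manifest)) {
    abort_topofilt("config: `manifest` is required",
                   "topofilt_invalid_parameter")
  }
  for (p in c(cfg$features, cfg$networks, cfg$manifest)) {
    if (!file.exists(p)) {
      abort_topofilt(sprintf("config: path does not exist: %s", p),
                     "topofilt_invalid_parameter")
    }
  }
  check_distance_weights(cfg$w0, cfg$w1)
  cfg
}

ingest_groups <- function(cfg) {
  mf <- read_manifest(cfg$manifest)
  lev <- unique(mf$group)
  if (length(lev) != 2L) {
    abort_topofilt("manifest must define exactly two groups",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(cfg$features)) {
    tab <- read_feature_table(cfg$features)
    missing <- setdiff(tab$subjects, mf$id)
    if (length(missing) > 0L) {
      abort_topofilt(sprintf("subjects missing from manifest: %s",
                             paste(missing, collapse = ", ")),
                     "topofilt_invalid_parameter")
    }
    grp <- mf$group[match(tab$subjects, mf$id)]
    pick <- function(g) {
      keep <- grp == g
      feature_table(tab$values[keep, , drop = FALSE],
                    subjects = tab$subjects[keep], node_ids = tab$node_ids)
    }
    list(g1 = jackknife_networks(pick(lev[1L])),
         g2 = jackknife_networks(pick(lev[2L])),
         names = lev)
  } else {
    nets <- read_networks(cfg$networks, manifest = cfg$manifest)
    list(g1 = nets$networks[nets$labels == lev[1L]],
         g2 = nets$networks[nets$labels == lev[2L]],
         names = lev)
  }
}
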