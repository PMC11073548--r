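#' Read a weighted network from delimited text
#'
#' Reads a square `q x q` weight matrix from a comma- (`.csv`) or
#' whitespace/tab-delimited file. Entries must be numeric and finite (a `NaN`
#' or missing cell is a format error naming the offending position).
#' Asymmetries up to `tol` are averaged away with a warning; anything larger
#' is an error.
#'
#' @param path File to read.
#' @param sep Field separator; guessed from the extension when `NULL`
#'   (`","` for `.csv`, whitespace otherwise).
#' @param labels_path Optional text file with one node label per line.
#' @param diagonal `"strict"` (nonzero diagonal is an error, default) or
#'   `"zero"` (diagonal is overwritten with 0, as for correlation matrices
#'   stored with unit diagonal).
#' @param tol Symmetry tolerance (default `1e-8`).
#' @return A [weighted_network()].
#' @export
read_network <- function(path, sep = NULL, labels_path = NULL,
                         diagonal = c("strict", "zero"), tol = 1e-8) {
  diagonal <- match.arg(diagonal)
  mat <- read_numeric_matrix(path, sep)
  labels <- if (!is.null(labels_path)) readLines(labels_path) else NULL
  validate_network_matrix(mat, path, diagonal = diagonal, tol = tol,
                          node_labels = labels)
}

read_numeric_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    abort_topofilt(sprintf("file not found: %s", path), "topofilt_format")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  }
  df <- read.table(path, sep = sep, header = FALSE,
                   stringsAsFactors = FALSE)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    abort_topofilt(sprintf("%s: non-numeric entries in column %d",
                           path, which(bad)[1L]), "topofilt_format")
  }
  as.matrix(df)
}

validate_network_matrix <- function(mat, where, diagonal = "strict",
                                    tol = 1e-8, node_labels = NULL) {
  dimnames(mat) <- NULL
  if (nrow(mat) != ncol(mat)) {
    abort_topofilt(sprintf("%s: matrix is %d x %d, not square",
                           where, nrow(mat), ncol(mat)), "topofilt_format")
  }
  if (any(!is.finite(mat))) {
    pos <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    abort_topofilt(sprintf("%s: non-finite value at row %d, column %d",
                           where, pos[1L], pos[2L]), "topofilt_format")
  }
  asym <- max(abs(mat - t(mat)))
  if (asym > tol) {
    abort_topofilt(sprintf(
      "%s: matrix asymmetric beyond tolerance (max asymmetry %.3g)",
      where, asym), "topofilt_format")
  }
  if (asym > 0) {
    warn_topofilt(sprintf("%s: symmetrized (max asymmetry %.3g)", where,
                          asym))
    mat <- (mat + t(mat)) / 2
  }
  if (diagonal == "zero") diag(mat) <- 0
  weighted_network(mat, node_labels = node_labels)
}

#' Read a collection of networks
#'
#' Either a directory of per-network delimited matrices (optionally paired
#' with a two-column manifest mapping file names to group labels) or a single
#' "stacked" file of `m` vertically concatenated `q x q` blocks.
#'
#' @param path Directory of matrix files, or a single file when `q` is given.
#' @param manifest Optional manifest file with two whitespace/comma separated
#'   columns: file name (relative to `path`) and group label. Determines both
#'   the ordering and the labels.
#' @param q Block size for stacked single-file input.
#' @inheritParams read_network
#' @return List with `networks` (list of [weighted_network()]), `labels`
#'   (factor or `NULL`) and `files`.
#' @export
read_networks <- function(path, manifest = NULL, q = NULL, sep = NULL,
                          diagonal = c("strict", "zero"), tol = 1e-8) {
  diagonal <- match.arg(diagonal)
  if (!is.null(q)) {
    mat <- read_numeric_matrix(path, sep)
    if (nrow(mat) %% q != 0L || ncol(mat) != q) {
      abort_topofilt(sprintf(
        "%s: stacked input must be (m*q) x q with q = %d", path, q),
        "topofilt_format")
    }
    m <- nrow(mat) %/% q
    nets <- lapply(seq_len(m), function(k) {
      validate_network_matrix(mat[((k - 1L) * q + 1L):(k * q), , drop = FALSE],
                              sprintf("%s [block %d]", path, k),
                              diagonal = diagonal, tol = tol)
    })
    return(list(networks = nets, labels = NULL, files = rep(path, m)))
  }
  if (!dir.exists(path)) {
    abort_topofilt(sprintf("directory not found: %s", path),
                   "topofilt_format")
  }
  labels <- NULL
  if (!is.null(manifest)) {
    mf <- read_manifest(manifest)
    files <- file.path(path, mf$id)
    labels <- factor(mf$group)
  } else {
    files <- sort(list.files(path, pattern = "\\.(csv|tsv|txt)$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      abort_topofilt(sprintf("no matrix files (*.csv|tsv|txt) in %s", path),
                     "topofilt_format")
    }
  }
  nets <- lapply(files, read_network, sep = sep, diagonal = diagonal,
                 tol = tol)
  list(networks = nets, labels = labels, files = files)
}

#' Read a two-column manifest (identifier, group label)
#'
#' @param path Manifest file; comma- or whitespace-separated, no header.
#' @return Data frame with columns `id` and `group`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_topofilt(sprintf("manifest not found: %s", path), "topofilt_format")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- read.table(path, sep = sep, header = FALSE,
                   stringsAsFactors = FALSE, col.names = c("id", "group"))
  if (ncol(df) != 2L || nrow(df) == 0L) {
    abort_topofilt(sprintf("%s: manifest needs two columns (id, group)",
                           path), "topofilt_format")
  }
  df
}

#' Read a subject-by-node feature table
#'
#' Expects a header row of node identifiers and a first column of subject
#' identifiers.
#'
#' @param path Delimited text file.
#' @param sep Separator (guessed from extension when `NULL`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    abort_topofilt(sprintf("file not found: %s", path), "topofilt_format")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  }
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    abort_topofilt(sprintf("%s: non-numeric feature column '%s'",
                           path, names(df)[bad][1L]), "topofilt_format")
  }
  feature_table(as.matrix(df), subjects = rownames(df),
                node_ids = colnames(df))
}

fmt_num <- function(x) sprintf("%.17g", x)

write_delim_matrix <- function(mat, path, sep) {
  lines <- apply(mat, 1L, function(r) paste(fmt_num(r), collapse = sep))
  writeLines(lines, path)
}

#' Write a weighted network to delimited text
#'
#' Weights are printed with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param net A [weighted_network()].
#' @param path Output file; `.csv` gets commas, anything else tabs.
#' @export
write_network <- function(net, path) {
  net <- as_weighted_network(net)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write_delim_matrix(net$weights, path, sep)
  invisible(path)
}

#' Write a birth-death decomposition as two-column text
#'
#' Creates `<prefix>_births.tsv` and `<prefix>_deaths.tsv`, each with columns
#' `index` and `value` (ascending).
#'
#' @param bd A [birth_death_decompose()] result.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_decomposition <- function(bd, prefix) {
  stopifnot(inherits(bd, "birth_death"))
  paths <- paste0(prefix, c("_births.tsv", "_deaths.tsv"))
  for (k in 1:2) {
    v <- if (k == 1) bd$births else bd$deaths
    writeLines(c("index\tvalue",
                 sprintf("%d\t%s", seq_along(v), fmt_num(v))), paths[k])
  }
  invisible(paths)
}

#' Write Betti curves as three-column text
#'
#' Columns: `threshold`, `beta0`, `beta1`.
#'
#' @param bc A [betti_curves()] result.
#' @param path Output file.
#' @export
write_betti <- function(bc, path) {
  stopifnot(inherits(bc, "betti_curve"))
  writeLines(c("threshold\tbeta0\tbeta1",
               sprintf("%s\t%d\t%d", fmt_num(bc$thresholds), bc$beta0,
                       bc$beta1)), path)
  invisible(path)
}

#' Write a grouped distance matrix
#'
#' The matrix file starts with a one-line `#` header naming the groups and
#' sizes; the labels go to a sidecar file `<path>.labels`.
#'
#' @param gd A `grouped_dist`.
#' @param path Output file.
#' @param which Which component to write (see [dist_matrix()]).
#' @export
write_distance_matrix <- function(gd, path, which = "combined") {
  D <- dist_matrix(gd, which)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lev <- levels(gd$labels)
  header <- sprintf("# %s=%d%s%s=%d", lev[1L], gd$m, sep, lev[2L], gd$n)
  lines <- apply(D, 1L, function(r) paste(fmt_num(r), collapse = sep))
  writeLines(c(header, lines), path)
  writeLines(as.character(gd$labels), paste0(path, ".labels"))
  invisible(path)
}

#' Serialize a test report to JSON
#'
#' Writes the statistic, p-value, settings, seed and a summary of the null
#' trace (count, mean, sd, quantiles) of a [permutation_test()],
#' [transposition_test()] or [z_test()] report.
#'
#' @param report A `topo_ratio_test` or `topo_z_test`.
#' @param path Output `.json` file.
#' @param null_trace_path Optional file to receive the full null trace as
#'   one value per line.
#' @export
write_report <- function(report, path, null_trace_path = NULL) {
  if (inherits(report, "topo_ratio_test")) {
    nv <- report$null_values
    qs <- quantile(nv, c(0, 0.025, 0.5, 0.975, 1), names = FALSE)
    obj <- list(
      test = "ratio",
      method = report$method,
      statistic = report$statistic,
      p_value = report$p_value,
      settings = list(n_resamples = report$n_resamples,
                      full_perm_interval = report$full_perm_interval,
                      m = report$m, n = report$n),
      seed = report$seed,
      null_summary = list(count = length(nv), mean = mean(nv), sd = sd(nv),
                          quantiles = list(q0 = qs[1], q025 = qs[2],
                                           q50 = qs[3], q975 = qs[4],
                                           q100 = qs[5])))
    if (!is.null(null_trace_path)) {
      writeLines(fmt_num(nv), null_trace_path)
    }
  } else if (inherits(report, "topo_z_test")) {
    obj <- list(
      test = "z",
      statistic = report$z,
      p_value = report$p_value,
      moments = list(mean_within = report$mean_within,
                     mean_between = report$mean_between,
                     var_within = report$var_within,
                     var_between = report$var_between),
      settings = list(m = report$m, n = report$n))
  } else {
    abort_topofilt("unsupported report object", "topofilt_invalid_parameter")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
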