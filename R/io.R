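#' Read nuclei centroids from a delimited text file
#'
#' Expects a comma-separated file with a header and columns `id`, `x`,
#' `y` and optionally `z`; the dimensionality is inferred from the
#' presence of `z` (a constant-zero `z` column still yields a 3D set
#' unless `force_2d` is given). Extra columns are ignored.
#'
#' @param path path to the CSV file.
#' @param force_2d drop the `z` column and parse as 2D.
#' @return A [centroid_set()].
#' @export
read_centroids <- function(path, force_2d = FALSE) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df))) {
    stop(
      "centroid file must have columns id,x,y[,z]; missing: ",
      paste(setdiff(need, names(df)), collapse = ", ")
    )
  }
  has_z <- "z" %in% names(df)
  cols <- if (has_z && !force_2d) c("x", "y", "z") else c("x", "y")
  if (has_z && force_2d && length(unique(df$z)) > 1L) {
    warning("force_2d dropped a non-constant z column")
  }
  for (cl in c("id", cols)) {
    if (!is.numeric(df[[cl]])) stop("non-numeric values in column '", cl, "'")
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate centroid id(s): ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  centroid_set(as.matrix(df[cols]), ids = df$id)
}

#' Write nuclei centroids to CSV
#'
#' Coordinates are written with 15 significant digits so that a
#' write/read round trip reproduces them to full double precision.
#'
#' @param centroids a [centroid_set()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(inherits(centroids, "centroid_set"))
  cols <- c("x", "y", "z")[seq_len(centroids$dim)]
  df <- data.frame(id = centroids$ids)
  for (k in seq_len(centroids$dim)) {
    df[[cols[k]]] <- sprintf("%.15g", centroids$coords[, k])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge list from CSV
#'
#' Expects a header and columns `i`, `j` (extra columns ignored).
#'
#' @param path path to the CSV file.
#' @return 2-column integer matrix of unordered, deduplicated edges.
#' @export
read_edges <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("i", "j") %in% names(df))) {
    stop("edge file must have columns i,j")
  }
  normalize_edges(as.matrix(df[c("i", "j")]))
}

#' Write an edge list to CSV
#'
#' @param edges 2-column matrix/data frame of id pairs.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_edges <- function(edges, path) {
  e <- normalize_edges(edges)
  utils::write.csv(as.data.frame(e), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the result files of an inference run
#'
#' Writes (a) the annotated candidate-edge table `edges.csv` with columns
#' `i,j,r,theta,kept`; (b) a machine-readable run summary `summary.json`
#' (selected thresholds, edge counts, fraction of candidate links removed,
#' filter mode, seed, package version); (c) optionally `metrics.json` when
#' ground truth was available; (d) optionally a GraphML file of the kept
#' graph for interchange with graph tools.
#'
#' @param graph a [filter_edges()] result.
#' @param thresholds the `nf_thresholds` used (defaults to those stored in
#'   `graph`).
#' @param metrics optional `metrics_report` to write alongside.
#' @param outdir output directory (created if missing).
#' @param seed optional integer recorded in the summary.
#' @param graphml logical; also export `neighbors.graphml`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(graph, thresholds = NULL, metrics = NULL,
                          outdir = ".", seed = NULL, graphml = FALSE) {
  stopifnot(inherits(graph, "neighbor_graph"))
  th <- if (is.null(thresholds)) graph$thresholds else {
    thresholds[c("r_star", "theta_star", "efficiency", "mode")]
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(outdir, "edges.csv"))
  e <- graph$edges
  df <- data.frame(
    i = e$i, j = e$j,
    r = sprintf("%.15g", e$r), theta = sprintf("%.15g", e$theta),
    kept = ifelse(e$kept, "true", "false")
  )
  utils::write.csv(df, paths["edges"], row.names = FALSE, quote = FALSE)

  summary <- list(
    r_star = th$r_star,
    theta_star = th$theta_star,
    efficiency = th$efficiency,
    mode = th$mode,
    n_nodes = length(graph$nodes),
    n_candidate_edges = nrow(e),
    n_kept_edges = sum(e$kept),
    fraction_removed = graph$fraction_removed,
    ground_truth = if (is.null(metrics)) "no ground truth" else "evaluated",
    seed = if (is.null(seed)) NULL else as.integer(seed),
    package_version = as.character(utils::packageVersion("cellneighbors"))
  )
  paths["summary"] <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(metrics)) {
    stopifnot(inherits(metrics, "metrics_report"))
    paths["metrics"] <- file.path(outdir, "metrics.json")
    jsonlite::write_json(
      list(
        TPR = metrics$TPR, PPV = metrics$PPV, JI = metrics$JI,
        F1 = metrics$F1, MCC = metrics$MCC,
        TP = metrics$counts$TP, FP = metrics$counts$FP,
        FN = metrics$counts$FN, TN = metrics$counts$TN,
        n_nodes = metrics$counts$n_nodes
      ),
      paths["metrics"],
      auto_unbox = TRUE, digits = NA, na = "string"
    )
  }
  if (graphml) {
    paths["graphml"] <- file.path(outdir, "neighbors.graphml")
    ke <- kept_edges(graph)
    g <- igraph::graph_from_data_frame(
      as.data.frame(matrix(as.character(ke), ncol = 2, dimnames = list(NULL, c("i", "j")))),
      directed = FALSE,
      vertices = data.frame(name = as.character(graph$nodes))
    )
    igraph::write_graph(g, paths["graphml"], format = "graphml")
  }
  invisible(paths)
}

#' Export an efficiency surface as a delimited table
#'
#' Long-format CSV with one row per grid cell and columns
#' `r`, `theta`, `F`, `L`, `E`, suitable for plotting the surface.
#'
#' @param surface an [efficiency_surface()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "efficiency_surface"))
  grid <- expand.grid(r = surface$r, theta = surface$theta)
  df <- data.frame(
    r = grid$r, theta = grid$theta,
    F = as.vector(surface$F), L = as.vector(surface$L), E = as.vector(surface$E)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
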