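#' Write an ensemble to disk
#'
#' Two plain-text formats: a frame table CSV (`frame,label,x,y,z`, full
#' double precision) and a multi-model PDB (one `MODEL` block per frame,
#' one CA pseudo-atom per point, fixed 3-decimal coordinate precision).
#' Chain-qualified labels `"A:12"` map to PDB chain A, residue 12.
#'
#' @param traj an `EnsembleTrajectory`.
#' @param path output file.
#' @param format `"csv"` or `"pdb"` (default: by file extension).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(traj, path, format = c("auto", "csv", "pdb")) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  f <- n_frames(traj)
  n <- length(traj$labels)
  if (format == "csv") {
    df <- data.frame(frame = rep(seq_len(f), each = n),
                     label = rep(traj$labels, times = f),
                     x = as.vector(t(matrix(traj$coords[, , 1], nrow = f))),
                     y = as.vector(t(matrix(traj$coords[, , 2], nrow = f))),
                     z = as.vector(t(matrix(traj$coords[, , 3], nrow = f))))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    sub <- node_subunit(traj$labels)
    chain <- ifelse(is.na(sub), "A", substr(sub, 1, 1))
    resno <- suppressWarnings(as.integer(sub("^.*:", "", traj$labels)))
    resno[is.na(resno)] <- seq_len(n)[is.na(resno)]
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(f)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      for (p in seq_len(n)) {
        writeLines(sprintf(
          "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          p, chain[p], resno[p],
          traj$coords[k, p, 1], traj$coords[k, p, 2], traj$coords[k, p, 3]), con)
      }
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Load an ensemble from disk
#'
#' Reads a frame-table CSV or a multi-model PDB back into an
#' `EnsembleTrajectory`. PDB reading goes through
#' `bio3d::read.pdb(multi = TRUE)`; frames must all carry the same atoms,
#' and an inconsistent frame is reported by number.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, or `"pdb"`.
#' @return an `EnsembleTrajectory` (with `seed = NULL`).
#' @export
load_ensemble <- function(path, format = c("auto", "csv", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  if (format == "csv") {
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop_("parse error in %s: %s", path,
                                             conditionMessage(e)))
    need <- c("frame", "label", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop_("%s: expected columns %s", path, paste(need, collapse = ", "))
    frames <- sort(unique(df$frame))
    labels <- df$label[df$frame == frames[1]]
    coords <- array(NA_real_, dim = c(length(frames), length(labels), 3))
    for (k in seq_along(frames)) {
      sub <- df[df$frame == frames[k], ]
      if (!identical(as.character(sub$label), as.character(labels)))
        stop_("frame %s has a different label set than frame %s",
              frames[k], frames[1])
      coords[k, , ] <- as.matrix(sub[, c("x", "y", "z")])
    }
    ensemble_trajectory(coords, as.character(labels))
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop_("parse error in %s: %s", path,
                                              conditionMessage(e)))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n <- nrow(pdb$atom)
    labels <- paste0(pdb$atom$chain, ":", pdb$atom$resno)
    f <- nrow(xyz)
    coords <- array(NA_real_, dim = c(f, n, 3))
    for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, 3 * n, by = 3), drop = FALSE]
    ensemble_trajectory(coords, labels)
  }
}

#' Correlation-matrix TSV round trip
#'
#' Writes/reads a `CorrelationMatrix` as TSV with a label header row and a
#' label first column.
#'
#' @param cm a `CorrelationMatrix`.
#' @param path file path.
#' @return `write_correlation_matrix()` returns `path` invisibly;
#'   `read_correlation_matrix()` returns a `CorrelationMatrix`.
#' @export
write_correlation_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "CorrelationMatrix"))
  df <- data.frame(label = cm$labels, cm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @export
read_correlation_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  correlation_matrix(m, labels = labels)
}

#' Export a residue graph
#'
#' Writes the graph as GraphML (via igraph, edge attributes preserved) and
#' as a flat edge-list TSV (`node_i`, `node_j`, `occupancy`,
#' `correlation`, `length`, plus `usage`/`in_spm` when an SPM result is
#' supplied).
#'
#' @param graph a `ResidueGraph`.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @param spm optional `SpmResult` whose usages annotate the edges.
#' @return invisible list of written paths.
#' @export
export_graph <- function(graph, graphml_path = NULL, edges_path = NULL, spm = NULL) {
  edges <- if (is.null(spm)) graph$edges else spm$edges
  if (!is.null(graphml_path)) {
    ig <- as_igraph(graph, spm = spm)
    igraph::write_graph(ig, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    out <- edges
    names(out)[names(out) == "i"] <- "node_i"
    names(out)[names(out) == "j"] <- "node_j"
    utils::write.table(out, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(graphml = graphml_path, edges = edges_path))
}

#' Convert a residue graph to igraph
#'
#' @param graph a `ResidueGraph`.
#' @param spm optional `SpmResult` contributing `usage`/`in_spm` edge
#'   attributes.
#' @return an igraph object with `weight` set to the edge length.
#' @export
as_igraph <- function(graph, spm = NULL) {
  edges <- if (is.null(spm)) graph$edges else spm$edges
  d <- edges
  names(d)[1:2] <- c("from", "to")
  d$weight <- d$length
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Distance-series CSV round trip
#'
#' @param series a `DistanceSeries`.
#' @param path file path.
#' @return path / `DistanceSeries`.
#' @export
write_distance_series <- function(series, path) {
  stopifnot(inherits(series, "DistanceSeries"))
  df <- data.frame(frame = seq_along(series$distances),
                   distance_A = series$distances)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_series
#' @param point_a,point_b labels for the reconstructed series.
#' @export
read_distance_series <- function(path, point_a = "a", point_b = "b") {
  df <- read.csv(path)
  distance_series(df$distance_A, point_a, point_b)
}

#' Write a node-weakening table as CSV (sorted by |delta CPL|)
#'
#' @param tbl a `NodeWeakeningTable`.
#' @param path file path.
#' @export
write_node_weakening <- function(tbl, path) {
  stopifnot(inherits(tbl, "NodeWeakeningTable"))
  write.csv(cbind(tbl$table, baseline_cpl = tbl$baseline_cpl), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a DFI profile as two-column CSV
#'
#' @param profile a `DFIProfile`.
#' @param path file path.
#' @export
write_dfi <- function(profile, path) {
  stopifnot(inherits(profile, "DFIProfile"))
  write.csv(data.frame(residue = names(profile$dfi), dfi = unname(profile$dfi)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a kinetic fit report as JSON
#'
#' Serializes the fitted parameters, their asymptotic standard errors and
#' the residual sum of squares.
#'
#' @param fit a `MichaelisFit`, `MeltingFit`, `BindingFit` or `HillFit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  pars <- switch(class(fit)[1],
                 MichaelisFit = list(k_cat = fit$k_cat, K_M = fit$K_M),
                 MeltingFit = list(T_m = fit$T_m, c = fit$c, LL = fit$LL, UL = fit$UL),
                 BindingFit = list(V_max = fit$V_max, K_D_app = fit$K_D_app, G = fit$G),
                 HillFit = list(V_max = fit$V_max, K_half = fit$K_half, h = fit$h,
                                form = fit$form),
                 stop_("unsupported fit class: %s", class(fit)[1]))
  jsonlite::write_json(list(model = class(fit)[1], parameters = pars,
                            std_errors = as.list(fit$se), rss = fit$rss),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
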