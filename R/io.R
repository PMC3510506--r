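# TSV dialect: tab-separated, '#'-prefixed comment/header lines allowed,
# '.' decimal, no quoting; gene identifiers are opaque strings.

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample-based expression data as TSV
#'
#' Writes a genes x samples matrix TSV (first column `gene`) and a sidecar
#' annotation TSV (`sample_id`, `stage`) mapping each sample column to its
#' stage.
#'
#' @param data A [staged_expression()].
#' @param matrix_path,annotation_path Output file paths.
#' @export
write_staged_expression <- function(data, matrix_path, annotation_path) {
  all_mat <- do.call(cbind, data$matrices)
  if (is.null(colnames(all_mat)))
    colnames(all_mat) <- paste0(
      rep(data$stage_labels, vapply(data$matrices, ncol, 0L)), "_",
      unlist(lapply(data$matrices, function(m) seq_len(ncol(m)))))
  df <- data.frame(gene = data$gene_ids, all_mat, check.names = FALSE)
  write_tsv_plain(df, matrix_path)
  ann <- data.frame(
    sample_id = colnames(all_mat),
    stage = rep(data$stage_labels, vapply(data$matrices, ncol, 0L)))
  write_tsv_plain(ann, annotation_path)
  invisible(matrix_path)
}

#' Read sample-based expression data from TSV
#'
#' @param matrix_path Genes x samples TSV with a `gene` first column.
#' @param annotation_path Annotation TSV with columns `sample_id`, `stage`;
#'   stage order is the order of first appearance.
#' @return A [staged_expression()].
#' @export
read_staged_expression <- function(matrix_path, annotation_path) {
  df <- read_tsv_plain(matrix_path)
  ann <- read_tsv_plain(annotation_path)
  gene_ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- gene_ids
  missing <- setdiff(colnames(mat), ann$sample_id)
  if (length(missing))
    stop("samples missing from annotation: ",
         paste(missing, collapse = ", "))
  stages <- unique(ann$stage)
  mats <- lapply(stages, function(st) {
    ids <- ann$sample_id[ann$stage == st]
    mat[, intersect(colnames(mat), ids), drop = FALSE]
  })
  staged_expression(mats, as.character(stages), gene_ids)
}

#' Write a time course as TSV
#'
#' First column `time`, then one column per gene; the stage of each
#' timepoint goes to the sidecar annotation TSV (`sample_id`, `stage`).
#'
#' @param tc A `time_course`.
#' @param matrix_path,annotation_path Output file paths.
#' @export
write_time_course <- function(tc, matrix_path, annotation_path) {
  df <- data.frame(time = tc$times, t(tc$values), check.names = FALSE)
  write_tsv_plain(df, matrix_path)
  ann <- data.frame(sample_id = paste0("t", seq_along(tc$times)),
                    stage = tc$stage_labels[tc$stage_of_timepoint])
  write_tsv_plain(ann, annotation_path)
  invisible(matrix_path)
}

#' Read a time course from TSV
#'
#' @param matrix_path TSV with a `time` first column and one column per gene.
#' @param annotation_path Annotation TSV (`sample_id`, `stage`), one row per
#'   timepoint in time order.
#' @return A `time_course`.
#' @export
read_time_course <- function(matrix_path, annotation_path) {
  df <- read_tsv_plain(matrix_path)
  if (colnames(df)[1L] != "time")
    stop("time-course matrix must have a 'time' first column")
  ann <- read_tsv_plain(annotation_path)
  stages <- unique(ann$stage)
  structure(list(times = df$time,
                 values = t(as.matrix(df[, -1L, drop = FALSE])),
                 stage_of_timepoint = match(ann$stage, stages),
                 stage_labels = as.character(stages),
                 gene_ids = colnames(df)[-1L]),
            class = "time_course")
}

#' Write ground-truth or inferred networks as an edge-list TSV
#'
#' Columns: stage, regulator, target, strength (ground truth) or stage,
#' regulator, target, coefficient, confidence (inference output).
#'
#' @param x A [kinetic_network()] or [stage_networks()].
#' @param path Output file path.
#' @export
write_edges <- function(x, path) {
  if (inherits(x, "kinetic_network")) {
    rows <- lapply(seq_len(x$n_stages), function(s) {
      e <- true_edges(x, s)
      if (nrow(e)) cbind(stage = x$stages[[s]]$label, e)
    })
    df <- do.call(rbind, rows)
  } else if (inherits(x, "stage_networks")) {
    rows <- lapply(seq_along(x$stage_labels), function(s) {
      co <- x$coefficients[[s]]; conf <- x$confidence[[s]]
      idx <- which(co != 0 | conf != 0, arr.ind = TRUE)
      idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
      if (nrow(idx) == 0L) return(NULL)
      data.frame(stage = x$stage_labels[s],
                 regulator = x$gene_ids[idx[, 2L]],
                 target = x$gene_ids[idx[, 1L]],
                 coefficient = co[idx], confidence = conf[idx],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else stop("unsupported object")
  write_tsv_plain(df, path)
}

#' Read an edge-list TSV
#'
#' @param path TSV with at least columns regulator and target (optionally
#'   stage, strength/coefficient, confidence).
#' @return Data frame of edges.
#' @export
read_edges <- function(path) read_tsv_plain(path)

#' Export per-stage networks in SIF format
#'
#' One SIF file per stage (`<prefix>_<stage>.sif`), rows
#' `regulator<TAB>activates|inhibits<TAB>target` according to the
#' coefficient sign, restricted to the thresholded edge set.
#'
#' @param nets A [stage_networks()].
#' @param prefix Output path prefix.
#' @param mode,value Passed to [threshold_network()] (default: confidence
#'   >= 0.5).
#' @return Paths written, invisibly.
#' @export
write_sif <- function(nets, prefix, mode = "confidence", value = 0.5) {
  lst <- threshold_network(nets, mode, value)
  paths <- character(0)
  for (s in names(lst)) {
    df <- lst[[s]]
    out <- data.frame(regulator = df$regulator,
                      relation = ifelse(df$coefficient >= 0, "activates",
                                        "inhibits"),
                      target = df$target)
    path <- paste0(prefix, "_", s, ".sif")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a configuration file into DCM/fraction/baseline configs
#'
#' JSON or YAML (by extension) with optional top-level blocks `dcm`,
#' `fractions` and `baseline`, whose fields mirror [dcm_config()],
#' [fraction_config()] and [baseline_config()] argument-for-argument.
#'
#' @param path Config file path.
#' @return List with elements `dcm`, `fractions`, `baseline`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(fields, ctor) do.call(ctor, as.list(fields))
  list(dcm = build(raw$dcm %||% list(), dcm_config),
       fractions = build(raw$fractions %||% list(), fraction_config),
       baseline = build(raw$baseline %||% list(), baseline_config))
}

#' Write a run manifest
#'
#' Records the command, resolved configuration, seed and input/output paths
#' of a run as JSON next to its outputs, so identical manifests imply
#' identical outputs.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param seed Integer seed of the run.
#' @param config List of resolved configuration values.
#' @param inputs,outputs Character vectors of paths.
#' @export
write_manifest <- function(path, command, seed, config = list(),
                           inputs = character(0), outputs = character(0)) {
  manifest <- list(command = command, seed = seed, config = config,
                   inputs = inputs, outputs = outputs,
                   started = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
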