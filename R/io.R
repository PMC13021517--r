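#' Write a synthetic atlas to disk
#'
#' Writes the counts as a MatrixMarket sparse matrix plus tab-separated
#' cell and gene tables and the generating ontology as an edge-list TSV —
#' the on-disk interchange format consumed by the pipeline commands.
#'
#' @param atlas a `synthetic_atlas`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.mtx"),
             cells = file.path(dir, "cells.tsv"),
             genes = file.path(dir, "genes.tsv"),
             ontology = file.path(dir, "ontology.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(atlas$counts, sparse = TRUE),
                              "generalMatrix"), paths["counts"])
  utils::write.table(atlas$cells, paths["cells"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = atlas$genes), paths["genes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ontology_edgelist(atlas$dag, paths["ontology"])
  invisible(paths)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param dir directory containing `counts.mtx`, `cells.tsv`, `genes.tsv`
#'   and `ontology.tsv`.
#' @return a `synthetic_atlas` (without simulation-only fields such as the
#'   leaf programs).
#' @export
read_atlas <- function(dir) {
  need <- file.path(dir, c("counts.mtx", "cells.tsv", "genes.tsv",
                           "ontology.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop("missing atlas file(s): ", paste(missing, collapse = ", "))
  }
  counts <- as.matrix(Matrix::readMM(need[1]))
  cells <- utils::read.delim(need[2], stringsAsFactors = FALSE)
  genes <- utils::read.delim(need[3], stringsAsFactors = FALSE)$gene_id
  dag <- load_ontology(need[4], format = "edgelist")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cells$cell_id, genes)
  bad <- setdiff(unique(cells$observed_label), dag$nodes)
  if (length(bad) > 0L) {
    stop("label(s) in data absent from ontology: ", paste(bad, collapse = ", "))
  }
  structure(list(counts = counts, cells = cells, genes = genes,
                 programs = NULL, dag = dag, config = NULL),
            class = "synthetic_atlas")
}

#' Write an evaluation report as JSON + per-class TSV
#'
#' @param report list from [evaluate_predictions()].
#' @param path JSON output path; the per-class table is written next to it
#'   with suffix `_per_class.tsv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(macro_f1 = report$macro_f1,
              included_classes = report$included_classes,
              per_class = report$per_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  utils::write.table(report$per_class,
                     sub("\\.json$", "_per_class.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an evaluation report JSON
#' @param path path written by [write_report()].
#' @return list with `macro_f1`, `included_classes`, `per_class`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Save a fitted classifier checkpoint
#'
#' Self-describing plain-JSON checkpoint: architecture spec, weights,
#' training configuration, the ontology node ordering the logits align to,
#' and a hash of the configuration for provenance.
#'
#' @param model an `hce_classifier`.
#' @param node_order character vector of ontology node ids in class order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, node_order, path) {
  stopifnot(inherits(model, "hce_classifier"))
  ck <- list(
    spec = unclass(model$spec),
    config = unclass(model$config),
    node_order = node_order,
    params = lapply(model$params, function(p)
      list(W = as.numeric(p$W), dim = dim(p$W), b = p$b)),
    config_hash = config_hash(c(unclass(model$spec), unclass(model$config)))
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier checkpoint
#' @param path path written by [save_checkpoint()].
#' @return list with `model` (an `hce_classifier`) and `node_order`.
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  spec <- structure(ck$spec, class = "classifier_spec")
  spec$hidden_dims <- as.integer(spec$hidden_dims)
  cfg <- structure(ck$config, class = "train_config")
  params <- lapply(ck$params, function(p)
    list(W = matrix(p$W, p$dim[1], p$dim[2]), b = as.numeric(p$b)))
  model <- structure(list(params = params, spec = spec, config = cfg,
                          history = NULL),
                     class = "hce_classifier")
  list(model = model, node_order = as.character(ck$node_order),
       config_hash = ck$config_hash)
}

#' Deterministic hash of a configuration object
#'
#' Serialises the object to canonical JSON and returns a compact checksum,
#' used to stamp output files so runs with identical configuration are
#' identifiable.
#'
#' @param x any JSON-serialisable list.
#' @return character scalar.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  raw <- utf8ToInt(as.character(s))
  # polynomial rolling checksum; exact in double precision (h < 2^31)
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
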