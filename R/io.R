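#' On-disk artifacts
#'
#' Spikes travel as TSV (`population`, `neuron_id`, `time_ms`; 1-based
#' neuron ids within each population, 0-based cluster indexing wherever
#' clusters appear — stated in every header).  Weights and topology travel
#' as one Matrix Market file per connection class (rows = targets,
#' columns = sources, explicit entries mark existing edges even at weight
#' zero) plus a JSON sidecar holding sizes, cluster labels, bounds, the
#' normalization targets `K`, plastic flags and the creating config hash.
#' Metrics travel as JSON.
#'
#' @name io
NULL

SPIKE_HEADER <- "# neuroclock spikes v1; neuron_id 1-based within population; times ms"

#' Write a spike record as TSV
#' @param spikes data.frame `population`, `neuron`, `t_ms`.
#' @param path output path.
#' @param cfg optional `clock_config` whose hash is recorded.
#' @return `path` invisibly.
#' @export
write_spikes <- function(spikes, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SPIKE_HEADER, con)
  if (!is.null(cfg)) writeLines(paste0("# config_hash=", config_hash(cfg)), con)
  df <- data.frame(population = spikes$population,
                   neuron_id = spikes$neuron,
                   time_ms = sprintf("%.17g", spikes$t_ms))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike record TSV
#' @param path file written by [write_spikes()].
#' @return data.frame `population`, `neuron`, `t_ms`.
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("character", "integer", "numeric"),
                          stringsAsFactors = FALSE)
  data.frame(population = df$population, neuron = df$neuron_id,
             t_ms = df$time_ms, stringsAsFactors = FALSE)
}

#' Write topology and weights as Matrix Market + JSON sidecar
#'
#' One `<class>.mtx` coordinate file per connection class (explicit
#' entries preserve zero-weight edges) and a `meta.json` sidecar.
#'
#' @param topology a `network_topology`.
#' @param synapses a `synapse_state`.
#' @param dir output directory (created if missing).
#' @param cfg optional config for the recorded hash.
#' @return `dir` invisibly.
#' @export
write_weights <- function(topology, synapses, dir, cfg = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nsz <- c(E = topology$N_E, I = topology$N_I, R = topology$N_R,
           S = topology$N_R, H = topology$N_R)
  for (cl in names(topology$edges)) {
    e <- topology$edges[[cl]]
    pops <- class_populations(cl)
    M <- Matrix::sparseMatrix(
      i = as.integer(e[, "tgt"]), j = as.integer(e[, "src"]),
      x = as.numeric(synapses$W[[cl]]),
      dims = c(nsz[[pops$target]], nsz[[pops$source]]), repr = "T")
    Matrix::writeMM(M, file.path(dir, paste0(cl, ".mtx")))
  }
  meta <- list(
    format = "neuroclock-weights-v1",
    indexing = "mtx entries 1-based per Matrix Market; cluster labels 0-based",
    N_E = topology$N_E, N_I = topology$N_I, N_C = topology$N_C,
    N_R = topology$N_R,
    cluster_label = topology$cluster_label,
    delay = topology$delay,
    bounds = synapses$bounds,
    plastic = as.list(synapses$plastic),
    K = synapses$K,
    frozen = synapses$frozen,
    config_hash = if (is.null(cfg)) NULL else config_hash(cfg))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a weights container written by [write_weights()]
#'
#' @param dir directory holding `<class>.mtx` files and `meta.json`.
#' @return list `topology` (a `network_topology`), `synapses`
#'   (a `synapse_state`); edge order within each class follows the stored
#'   coordinate order.
#' @export
read_weights <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  mtx_files <- list.files(dir, pattern = "\\.mtx$")
  edges <- list(); W <- list()
  for (f in mtx_files) {
    cl <- sub("\\.mtx$", "", f)
    M <- methods::as(Matrix::readMM(file.path(dir, f)), "TsparseMatrix")
    edges[[cl]] <- cbind(src = as.integer(M@j + 1L), tgt = as.integer(M@i + 1L))
    W[[cl]] <- as.numeric(M@x)
  }
  order_cls <- intersect(c("EE", "IE", "EI", "II", "RE", "RS", "RH", "HR"),
                         names(edges))
  edges <- edges[order_cls]; W <- W[order_cls]
  plastic <- unlist(meta$plastic)
  topo <- structure(list(
    N_E = meta$N_E, N_I = meta$N_I, N_C = meta$N_C, N_R = meta$N_R,
    cluster_label = as.integer(meta$cluster_label),
    edges = edges,
    delay = as.list(meta$delay), seed = NA_integer_),
    class = "network_topology")
  bounds <- lapply(meta$bounds, as.numeric)
  syn <- structure(list(W = W, bounds = bounds,
                        plastic = plastic[names(edges)],
                        K = as.numeric(meta$K),
                        frozen = isTRUE(meta$frozen)),
                   class = "synapse_state")
  list(topology = topo, synapses = syn)
}

#' Write analysis metrics as JSON
#' @param metrics a named list (e.g. flattened `clock_metrics`).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read metrics JSON written by [write_metrics()]
#' @param path file path.
#' @return a list.
#' @export
read_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
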