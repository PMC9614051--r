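#' Assign excitatory neurons to clusters
#'
#' Divides `N_E` excitatory neurons uniformly into `N_C` clusters of equal
#' size.  Labels are assigned to contiguous index blocks in ascending order,
#' so the block structure of learned weight matrices is visible in raw
#' matrix order.  Labels are 0-based, matching the package-wide indexing
#' convention for clusters.
#'
#' @param N_E number of excitatory neurons.
#' @param N_C number of clusters; must divide `N_E` exactly.
#' @return integer vector of length `N_E` with values in `0:(N_C-1)`.
#' @examples
#' table(assign_clusters(2400, 30))  # 80 neurons per cluster
#' @export
assign_clusters <- function(N_E, N_C) {
  N_E <- as.integer(N_E); N_C <- as.integer(N_C)
  if (N_E <= 0L || N_C <= 0L) {
    stop("N_E and N_C must be positive", call. = FALSE)
  }
  if (N_E %% N_C != 0L) {
    stop(sprintf("N_E (%d) is not divisible by N_C (%d); cluster sizes must be equal",
                 N_E, N_C), call. = FALSE)
  }
  rep(0:(N_C - 1L), each = N_E %/% N_C)
}

# Directed Erdos-Renyi edge set between populations of size n_src, n_tgt.
# Autapses (src == tgt when same_pop) are excluded; at most one edge per
# ordered pair by construction.  Returns a 2-column integer matrix
# (src, tgt), 1-based within each population.
random_edges <- function(n_src, n_tgt, p, same_pop = FALSE) {
  if (p < 0 || p > 1) stop("connection probability outside [0, 1]", call. = FALSE)
  if (p == 0 || n_src == 0L || n_tgt == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("src", "tgt"))))
  }
  # sample per source column to bound memory at full scale
  out <- vector("list", n_src)
  for (s in seq_len(n_src)) {
    tg <- if (p == 1) seq_len(n_tgt) else which(stats::runif(n_tgt) < p)
    if (same_pop) tg <- tg[tg != s]
    if (length(tg)) out[[s]] <- cbind(src = rep.int(s, length(tg)), tgt = tg)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(0), ncol = 2,
                              dimnames = list(NULL, c("src", "tgt")))
  m
}

#' Build the two-subnetwork topology
#'
#' Constructs the random recurrent connectivity of the RNN (classes EE,
#' IE, EI, II; each ordered pair connected independently with probability
#' `p`, excluding autapses and multapses) and the deterministic read-out
#' wiring: all-to-all plastic connections from every excitatory RNN neuron
#' to every read-out neuron (RE), plus exactly one supervisor (RS) and one
#' interneuron (RH) afferent per read-out neuron; each read-out neuron in
#' turn excites its own interneuron (HR), closing a per-element feedback
#' inhibition loop.  There are no connections between read-out neurons.
#'
#' Class names follow the target<-source convention: `"EI"` is inhibitory
#' onto excitatory.
#'
#' @param cfg a [clock_config()].
#' @param seed topology seed; defaults to `cfg$seeds$topology`.
#' @return an object of class `network_topology`: sizes, 0-based cluster
#'   labels, per-class edge matrices (`src`, `tgt`, 1-based within
#'   population), and per-class delays (ms).
#' @export
build_connectivity <- function(cfg, seed = cfg$seeds$topology) {
  nw <- cfg$network
  set.seed(seed)
  edges <- list(
    EE = random_edges(nw$N_E, nw$N_E, cfg$network$p$EE, same_pop = TRUE),
    IE = random_edges(nw$N_E, nw$N_I, cfg$network$p$IE),
    EI = random_edges(nw$N_I, nw$N_E, cfg$network$p$EI),
    II = random_edges(nw$N_I, nw$N_I, cfg$network$p$II, same_pop = TRUE),
    RE = cbind(src = rep(seq_len(nw$N_E), times = nw$N_R),
               tgt = rep(seq_len(nw$N_R), each = nw$N_E)),
    RS = cbind(src = seq_len(nw$N_R), tgt = seq_len(nw$N_R)),
    RH = cbind(src = seq_len(nw$N_R), tgt = seq_len(nw$N_R)),
    HR = cbind(src = seq_len(nw$N_R), tgt = seq_len(nw$N_R))
  )
  structure(list(
    N_E = nw$N_E, N_I = nw$N_I, N_C = nw$N_C, N_R = nw$N_R,
    cluster_label = assign_clusters(nw$N_E, nw$N_C),
    edges = edges,
    delay = cfg$plasticity$delay,
    seed = seed
  ), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d E (%d clusters), %d I, %d R/S/H\n",
              x$N_E, x$N_C, x$N_I, x$N_R))
  for (cl in names(x$edges)) {
    cat(sprintf("  %s: %d edges\n", cl, nrow(x$edges[[cl]])))
  }
  invisible(x)
}

# source/target population of a connection class (target<-source naming)
class_populations <- function(class) {
  map <- list(EE = c("E", "E"), IE = c("E", "I"), EI = c("I", "E"),
              II = c("I", "I"), RE = c("E", "R"), RS = c("S", "R"),
              RH = c("H", "R"), HR = c("R", "H"))
  m <- map[[class]]
  if (is.null(m)) stop("unknown connection class: ", class, call. = FALSE)
  list(source = m[1], target = m[2])
}

#' Initialize synaptic weights
#'
#' Gives every existing edge of a connection class the same scalar initial
#' weight (the pre-training state in which the network sits in the E-I
#' balanced regime), records the plastic classes' bounds, and computes the
#' per-neuron normalization target `K_i` as the realized sum of initial
#' incoming EE weights of excitatory neuron `i`.  `K` is computed once here
#' and never mutated afterwards.
#'
#' @param topology a `network_topology`.
#' @param cfg the [clock_config()] used to build it.
#' @return an object of class `synapse_state`: per-class weight vectors
#'   aligned with `topology$edges`, bounds, plastic flags, the `K` vector,
#'   and a `frozen` flag (all-plasticity-off switch used during replay).
#' @export
init_weights <- function(topology, cfg) {
  plastic <- c(EE = TRUE, IE = FALSE, EI = TRUE, II = FALSE,
               RE = TRUE, RS = FALSE, RH = FALSE, HR = FALSE)
  W <- list(); bounds <- list()
  for (cl in names(topology$edges)) {
    w0 <- cfg$weights$init[[cl]]
    if (is.null(w0)) stop("no initial weight configured for class ", cl, call. = FALSE)
    if (plastic[[cl]]) {
      b <- cfg$weights$bounds[[cl]]
      if (is.null(b)) stop("no bounds configured for plastic class ", cl, call. = FALSE)
      if (w0 < b[1] || w0 > b[2]) {
        stop(sprintf("initial weight %g for plastic class %s outside bounds [%g, %g]",
                     w0, cl, b[1], b[2]), call. = FALSE)
      }
      bounds[[cl]] <- b
    }
    W[[cl]] <- rep(w0, nrow(topology$edges[[cl]]))
  }
  K <- numeric(topology$N_E)
  ee <- topology$edges$EE
  if (nrow(ee)) {
    sums <- tapply(W$EE, ee[, "tgt"], sum)
    K[as.integer(names(sums))] <- as.numeric(sums)
  }
  structure(list(W = W, bounds = bounds, plastic = plastic,
                 K = K, frozen = FALSE), class = "synapse_state")
}

#' @export
print.synapse_state <- function(x, ...) {
  cat("<synapse_state>", if (x$frozen) "(frozen)" else "", "\n")
  for (cl in names(x$W)) {
    tag <- if (isTRUE(x$plastic[[cl]])) "plastic" else "static"
    cat(sprintf("  %s: %d weights, mean %.4g [%s]\n",
                cl, length(x$W[[cl]]),
                if (length(x$W[[cl]])) mean(x$W[[cl]]) else NA, tag))
  }
  invisible(x)
}

#' Dense weight matrix of one connection class
#'
#' @param topology a `network_topology`.
#' @param synapses a `synapse_state`.
#' @param class connection class name (target<-source).
#' @return a base dense matrix, rows = targets, columns = sources;
#'   nonexistent edges are exactly zero.
#' @export
weight_matrix <- function(topology, synapses, class = "EE") {
  pops <- class_populations(class)
  nsz <- c(E = topology$N_E, I = topology$N_I, R = topology$N_R,
           S = topology$N_R, H = topology$N_R)
  e <- topology$edges[[class]]
  M <- matrix(0, nrow = nsz[[pops$target]], ncol = nsz[[pops$source]])
  if (nrow(e)) M[cbind(e[, "tgt"], e[, "src"])] <- synapses$W[[class]]
  M
}

#' Signed full RNN weight matrix
#'
#' Assembles the (N_E + N_I) square matrix over all RNN neurons with
#' excitatory source columns entered positively and inhibitory source
#' columns negatively — the convention under which the E-I balance shows up
#' as a conjugate eigenvalue pair with large negative real part.
#'
#' @inheritParams weight_matrix
#' @return a dense square matrix of dimension `N_E + N_I`.
#' @export
full_weight_matrix <- function(topology, synapses) {
  nE <- topology$N_E; nI <- topology$N_I
  M <- matrix(0, nE + nI, nE + nI)
  M[seq_len(nE), seq_len(nE)] <- weight_matrix(topology, synapses, "EE")
  M[nE + seq_len(nI), seq_len(nE)] <- weight_matrix(topology, synapses, "IE")
  M[seq_len(nE), nE + seq_len(nI)] <- -weight_matrix(topology, synapses, "EI")
  M[nE + seq_len(nI), nE + seq_len(nI)] <- -weight_matrix(topology, synapses, "II")
  M
}
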