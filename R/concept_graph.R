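# Patient-specific concept co-occurrence graphs and a GraphSAGE-mean
# encoder.
#
# Nodes are clinical concept ids matched by a longest-first dictionary
# matcher; edges accumulate same-note co-occurrence plus consecutive-note
# temporal adjacency. Diagnostic concepts named by the mask policy never
# enter a graph. The encoder is mean-aggregation GraphSAGE with
# deterministic neighbour sampling keyed by (patient, node), so node
# insertion order never changes the pooled embedding.

#' Extract clinical concepts from a note
#'
#' Longest-match, case-insensitive, non-overlapping dictionary matching of
#' concept phrases. Matches are attributed to the section they occur in.
#'
#' @param note A [note()] object.
#' @param lexicon Concept lexicon data.frame (see [read_concept_lexicon()]).
#' @param policy Optional [mask_policy()]; matches whose concept id is
#'   diagnostic are dropped and counted in the `n_masked` attribute.
#' @return Data frame with `concept_id`, `phrase`, `section`.
#' @export
extract_concepts <- function(note, lexicon = read_concept_lexicon(),
                             policy = NULL) {
  if (nrow(lexicon) == 0) stopf("empty concept dictionary")
  phrases <- lexicon$phrase[order(-nchar(lexicon$phrase))]
  re <- paste0("(?<![A-Za-z])(",
               paste(gsub("([][{}()+*^$|\\\\?./'])", "\\\\\\1", phrases),
                     collapse = "|"),
               ")(?![A-Za-z])")
  secs <- if (length(note$sections)) note$sections else list(other = note$text)
  hits <- list()
  for (sec in names(secs)) {
    text <- secs[[sec]]
    m <- gregexpr(re, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    ph <- tolower(regmatches(text, list(m))[[1]])
    hits[[length(hits) + 1L]] <- data.frame(
      concept_id = lexicon$concept_id[match(ph, lexicon$phrase)],
      phrase = ph, section = sec, stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(concept_id = character(0), phrase = character(0),
               section = character(0))
  n_masked <- 0L
  if (!is.null(policy)) {
    drop <- out$concept_id %in% policy$concept_ids
    n_masked <- sum(drop)
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_masked") <- n_masked
  out
}

#' Build a patient concept co-occurrence graph
#'
#' One node per distinct concept over the patient's notes. Edge weight =
#' number of notes where both concepts appear + number of consecutive-note
#' pairs where one appears in each. When more than `max_nodes` concepts
#' occur, the most frequent are kept (ties broken lexicographically).
#' Node features carry normalized mention frequency and per-section
#' relative frequency.
#'
#' @param record A patient record.
#' @param lexicon Concept lexicon.
#' @param policy Optional [mask_policy()] applied during extraction.
#' @param max_nodes Node cap (default 200).
#' @return A `concept_graph`: list with `patient_id`, `nodes` (data.frame),
#'   `edges` (data.frame `a`, `b`, `weight`).
#' @export
build_patient_graph <- function(record, lexicon = read_concept_lexicon(),
                                policy = NULL, max_nodes = 200L) {
  per_note <- lapply(record$notes, extract_concepts, lexicon = lexicon,
                     policy = policy)
  all_hits <- do.call(rbind, per_note)
  if (is.null(all_hits) || nrow(all_hits) == 0) {
    return(structure(list(patient_id = record$patient_id,
                          nodes = data.frame(concept_id = character(0)),
                          edges = data.frame(a = character(0), b = character(0),
                                             weight = numeric(0))),
                     class = "concept_graph"))
  }
  freq <- sort(table(all_hits$concept_id), decreasing = TRUE)
  keep <- names(freq)[order(-as.numeric(freq), names(freq))]
  keep <- head(keep, max_nodes)

  note_sets <- lapply(per_note, function(h) intersect(unique(h$concept_id), keep))
  # same-note co-occurrence + consecutive-note temporal adjacency
  acc <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(a, b, w = 1) {
    if (a == b) return(invisible())
    key <- if (a < b) paste0(a, "\t", b) else paste0(b, "\t", a)
    acc[[key]] <- (acc[[key]] %||% 0) + w
  }
  for (s in note_sets) {
    if (length(s) >= 2) {
      cmb <- utils::combn(sort(s), 2)
      for (i in seq_len(ncol(cmb))) bump(cmb[1, i], cmb[2, i])
    }
  }
  if (length(note_sets) >= 2) {
    for (t in seq_len(length(note_sets) - 1L)) {
      for (a in note_sets[[t]]) for (b in note_sets[[t + 1L]]) bump(a, b)
    }
  }
  keys <- ls(acc)
  edges <- if (length(keys)) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    data.frame(a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2),
               weight = vapply(keys, function(k) acc[[k]], numeric(1)),
               row.names = NULL)
  } else {
    data.frame(a = character(0), b = character(0), weight = numeric(0))
  }

  sec_names <- c(SECTION_NAMES, "other")
  kept_hits <- all_hits[all_hits$concept_id %in% keep, ]
  nodes <- do.call(rbind, lapply(sort(keep), function(cid) {
    h <- kept_hits[kept_hits$concept_id == cid, ]
    secs <- table(factor(h$section, levels = sec_names))
    d <- data.frame(concept_id = cid, freq = nrow(h) / nrow(kept_hits))
    for (s in sec_names) d[[paste0("sec_", s)]] <- as.numeric(secs[[s]]) / nrow(h)
    d
  }))
  deg <- table(factor(c(edges$a, edges$b), levels = nodes$concept_id))
  nodes$degree <- as.numeric(deg[nodes$concept_id])
  rownames(nodes) <- NULL
  structure(list(patient_id = record$patient_id, nodes = nodes, edges = edges),
            class = "concept_graph")
}

#' GraphSAGE encoder parameters
#'
#' Three mean-aggregation layers with a neighbourhood sample cap of 10 and
#' a 200-node graph cap by default.
#'
#' @param dim_in Input feature dimension (raw node features are padded).
#' @param dim_hidden Hidden/output dimension.
#' @param n_layers Number of message-passing layers.
#' @param neighborhood Neighbour sample size per node.
#' @param max_nodes Node cap.
#' @param seed Integer seed for Xavier weight initialization.
#' @return A `graph_encoder_params` list with weight matrices `W`.
#' @export
graph_encoder_params <- function(dim_in = 16L, dim_hidden = 32L, n_layers = 3L,
                                 neighborhood = 10L, max_nodes = 200L,
                                 seed = 1L) {
  stopifnot(neighborhood >= 1, n_layers >= 1)
  W <- withr::with_seed(seed, {
    dims <- c(dim_in, rep(dim_hidden, n_layers))
    lapply(seq_len(n_layers), function(k) xavier_matrix(dims[k], dims[k + 1]))
  })
  structure(list(W = W, dim_in = dim_in, dim_hidden = dim_hidden,
                 n_layers = n_layers, neighborhood = neighborhood,
                 max_nodes = max_nodes, activation = relu),
            class = "graph_encoder_params")
}

# Adjacency list (neighbour index vectors) from an edge data.frame.
graph_adjacency <- function(graph) {
  ids <- graph$nodes$concept_id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[i]; b <- graph$edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unique(x)))
}

# Deterministic neighbour sample of size <= `size`, keyed by patient and
# node ids so results are independent of node insertion order.
sample_neighbors <- function(neighbors, size, patient_id, node_id) {
  if (length(neighbors) <= size) return(neighbors)
  withr::with_seed(derive_seed(hash31(patient_id), node_id), {
    sort(resample(neighbors, size))
  })
}

#' One GraphSAGE message-passing step
#'
#' Updates every node state as
#' `h_v <- act(W_k' * mean({h_v} union {h_u : u in sampled N(v)}))`.
#'
#' @param h Numeric matrix of node states (rows named by concept id).
#' @param graph A `concept_graph`.
#' @param params [graph_encoder_params()].
#' @param k Layer index (selects `params$W[[k]]`).
#' @param activation Override activation (default from params).
#' @return Updated node-state matrix.
#' @export
graphsage_layer <- function(h, graph, params, k, activation = NULL) {
  act <- activation %||% params$activation
  W <- params$W[[k]]
  if (ncol(h) != nrow(W)) stopf("node state dim %d != layer input dim %d",
                                ncol(h), nrow(W))
  adj <- graph_adjacency(graph)
  ids <- rownames(h)
  out <- t(vapply(ids, function(v) {
    nb <- sample_neighbors(adj[[v]] %||% character(0), params$neighborhood,
                           graph$patient_id, v)
    agg <- colMeans(h[c(v, nb), , drop = FALSE])
    act(as.numeric(crossprod(W, agg)))
  }, numeric(ncol(W))))
  rownames(out) <- ids
  out
}

#' Mean pooling of node states to a patient embedding
#'
#' @param h Node-state matrix (possibly zero rows).
#' @param dim Output dimension used for the empty-graph zero vector.
#' @return Numeric vector; attribute `no_concepts` flags an empty graph.
#' @export
graph_pool <- function(h, dim = NULL) {
  if (is.null(dim)) dim <- ncol(h)
  if (is.null(nrow(h)) || nrow(h) == 0) {
    return(structure(numeric(dim), no_concepts = TRUE))
  }
  structure(colMeans(h), no_concepts = FALSE)
}

# Raw node features: normalized frequency, per-section proportions, degree
# (scaled), zero-padded to the encoder input dimension.
node_features <- function(graph, dim_in) {
  n <- nrow(graph$nodes)
  if (n == 0) return(matrix(numeric(0), 0, dim_in))
  base <- as.matrix(graph$nodes[, c("freq", paste0("sec_", c(SECTION_NAMES, "other")),
                                    "degree")])
  base[, "degree"] <- base[, "degree"] / max(1, max(base[, "degree"]))
  m <- cbind(base, matrix(0, n, dim_in - ncol(base)))
  rownames(m) <- graph$nodes$concept_id
  m
}

#' Encode a patient graph to its pooled embedding
#'
#' @param graph A `concept_graph`.
#' @param params [graph_encoder_params()].
#' @return Patient-level graph embedding `g_p` (length `dim_hidden`).
#' @export
encode_graph <- function(graph, params) {
  h <- node_features(graph, params$dim_in)
  if (nrow(h) == 0) return(graph_pool(h, dim = params$dim_hidden))
  for (k in seq_len(params$n_layers)) {
    h <- graphsage_layer(h, graph, params, k)
  }
  graph_pool(h)
}

#' Export a patient graph as edge-list and node TSV files
#'
#' @param graph A `concept_graph`.
#' @param dir Output directory.
#' @return Invisibly the written paths.
#' @export
write_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, paste0(graph$patient_id, "_edges.tsv"))
  np <- file.path(dir, paste0(graph$patient_id, "_nodes.tsv"))
  utils::write.table(graph$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ep, np))
}
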