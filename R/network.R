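#' Build the clonal similarity network
#'
#' Vertices are unique V(D)J nucleotide sequences (records are collapsed:
#' duplicate counts summed, isotypes unioned). Edges connect vertices of
#' equal length at Hamming distance exactly 1 (single-nucleotide, non-indel
#' differences). Clusters — clones — are the connected components.
#'
#' @param airr `data.table` of annotated records (needs `sequence`,
#'   `c_call`, `duplicate_count`; `v_call`, `j_call`, `junction_aa`,
#'   `n_mut_total` are carried through when present).
#' @return A `ClonalNetwork`: list with `vertices` (`data.table`: vertex_id,
#'   sequence, duplicate_count, isotypes (list column of raw labels),
#'   cluster_id, plus carried columns), `edges` (vertex-id pairs), and
#'   `graph` (igraph object).
#' @export
build_network <- function(airr) {
  dt <- data.table::as.data.table(airr)
  if (nrow(dt) == 0L) stop("empty input")
  carry <- intersect(c("v_call", "j_call", "junction_aa", "n_mut_total"),
                     names(dt))
  vert <- dt[, c(list(duplicate_count = sum(duplicate_count),
                      isotypes = list(sort(unique(c_call)))),
                 lapply(.SD, data.table::first)),
             by = sequence, .SDcols = carry]
  vert[, vertex_id := seq_len(nrow(vert))]
  # Hamming-1 edges, enumerated within equal-length buckets
  lens <- nchar(vert$sequence)
  edge_list <- list()
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) < 2L) next
    e <- hamming1_edges_cpp(vert$sequence[idx])
    if (nrow(e) > 0L)
      edge_list[[length(edge_list) + 1L]] <-
        data.table::data.table(from = idx[e[, 1L]], to = idx[e[, 2L]])
  }
  edges <- if (length(edge_list)) data.table::rbindlist(edge_list)
           else data.table::data.table(from = integer(0), to = integer(0))
  g <- igraph::make_empty_graph(n = nrow(vert), directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  comp <- igraph::components(g)$membership
  # stable cluster ids: numbered in order of first vertex appearance
  relabel <- match(comp, unique(comp))
  vert[, cluster_id := relabel]
  structure(list(vertices = vert, edges = edges, graph = g),
            class = "ClonalNetwork")
}

#' @export
print.ClonalNetwork <- function(x, ...) {
  cat(sprintf("ClonalNetwork: %d vertices, %d edges, %d clusters, %d reads\n",
              nrow(x$vertices), nrow(x$edges),
              length(unique(x$vertices$cluster_id)),
              sum(x$vertices$duplicate_count)))
  invisible(x)
}

#' Identify the largest cluster
#'
#' @param net A `ClonalNetwork`.
#' @param by `"reads"` (total duplicate count, default) or `"vertices"`.
#' @return The cluster id (integer). Ties resolve to the smallest cluster id
#'   with a warning.
#' @export
largest_cluster <- function(net, by = c("reads", "vertices")) {
  by <- match.arg(by)
  if (nrow(net$vertices) == 0L) stop("empty network")
  sz <- net$vertices[, .(size = if (by == "reads") sum(duplicate_count)
                                else .N), by = cluster_id]
  mx <- max(sz$size)
  winners <- sort(sz$cluster_id[sz$size == mx])
  if (length(winners) > 1L)
    warning("tie for largest cluster (", length(winners),
            " clusters of size ", mx, "); returning smallest cluster id")
  winners[1L]
}

#' Summarise clones (clusters) of a network
#'
#' One row per cluster: vertex and read counts, read-fraction of the sample,
#' the raw isotype set, the number of grouped isotype classes (IgM, IgD,
#' IgG3, IgG1/2, IgG4, IgA1/2, IgE), an IgM/IgD-status label at the
#' reporting granularity used for clone-level comparisons, and the mean
#' number of V-region mutations from germline over member unique sequences.
#'
#' @param net A `ClonalNetwork` built from records carrying `n_mut_total`.
#' @return `data.table` with `cluster_id`, `n_vertices`, `clone_reads`,
#'   `clone_size_fraction`, `isotype_set` (collapsed string),
#'   `n_isotype_classes`, `isotype_class_group`, `mean_mut_from_germline`.
#' @export
clone_summaries <- function(net) {
  total <- sum(net$vertices$duplicate_count)
  out <- net$vertices[, {
    raw <- sort(unique(unlist(isotypes)))
    cls <- sort(unique(group_isotypes(raw, scheme = "class")))
    k <- length(cls)
    md <- any(cls %in% c("IgM", "IgD"))
    grp <- if (k == 1L) "1 isotype"
      else if (k == 2L && identical(cls, sort(c("IgM", "IgD"))))
        "2 isotypes IgM+IgD+"
      else if (k == 2L && !md) "2 isotypes IgM-IgD-"
      else if (k == 2L) "2 isotypes mixed"
      else if (md) ">2 isotypes IgM+IgD+"
      else ">2 isotypes IgM-IgD-"
    list(n_vertices = .N, clone_reads = sum(duplicate_count),
         clone_size_fraction = sum(duplicate_count) / total,
         isotype_set = paste(raw, collapse = ","),
         n_isotype_classes = k, isotype_class_group = grp,
         mean_mut_from_germline = if ("n_mut_total" %in% names(.SD))
           mean(n_mut_total) else NA_real_)
  }, by = cluster_id]
  out[]
}

#' Mutational distance of cluster members from the dominant sequence
#'
#' The dominant sequence is the member vertex with the highest read count.
#' Distances are nucleotide mismatches within the aligned V region (the
#' prefix covered by the dominant vertex's germline V) between each member
#' and the dominant sequence.
#'
#' @param net A `ClonalNetwork` whose vertices carry `v_call`.
#' @param cluster_id Cluster to analyse.
#' @param germline A `GermlineSet` (for the V-region length).
#' @return `data.table` with `vertex_id`, `sequence`, `isotype_set`,
#'   `duplicate_count`, `distance`.
#' @export
mutations_from_dominant <- function(net, cluster_id, germline) {
  mem <- net$vertices[net$vertices$cluster_id == cluster_id, ]
  if (nrow(mem) == 0L) stop("no such cluster: ", cluster_id)
  dom <- which.max(mem$duplicate_count)
  v_len <- nchar(germline$v$seq[match(mem$v_call[dom], germline$v$name)])
  if (is.na(v_len)) v_len <- min(nchar(mem$sequence))
  data.table::data.table(
    vertex_id = mem$vertex_id,
    sequence = mem$sequence,
    isotype_set = vapply(mem$isotypes, paste, character(1), collapse = ","),
    duplicate_count = mem$duplicate_count,
    distance = mismatch_to_ref_cpp(mem$sequence, mem$sequence[dom],
                                   min(v_len, min(nchar(mem$sequence)))))
}

#' Write network tables (vertices and edge list) to TSV
#'
#' @param net A `ClonalNetwork`.
#' @param vertices_path,edges_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_network_tsv <- function(net, vertices_path, edges_path) {
  v <- data.table::copy(net$vertices)
  v[, isotypes := vapply(isotypes, paste, character(1), collapse = ",")]
  data.table::fwrite(v, vertices_path, sep = "\t")
  data.table::fwrite(net$edges, edges_path, sep = "\t")
  invisible(c(vertices_path, edges_path))
}
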