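#' Build specificity groups over a repertoire
#'
#' Re-implementation of GLIPH-style amino-acid similarity grouping.
#' Clonotypes are connected when they share an enriched local motif (see
#' [motif_enrichment()]) or when their CDR3s are near-identical (global
#' link, Hamming distance <= `hamming_max` over trimmed cores of
#' equal-length CDR3s). Specificity groups are the connected components of
#' this similarity graph. A group is *significant* when it holds an
#' enriched motif shared by at least two members, or a global edge whose
#' shared core pattern passes the same enrichment test against the
#' reference; this is the "statistically significantly enriched cluster"
#' notion used for the antigen-drive call.
#'
#' @param sample A `tcr_repertoire`. Extra query CDR3s (clonotypes that
#'   should participate in grouping without being part of the sampled
#'   repertoire, e.g. re-inserted leukemic clones in the exclusion mode)
#'   can be supplied via `query`.
#' @param reference A `tcr_repertoire`, CDR3 character vector or
#'   [index_reference()] object (>= 100 distinct CDR3s).
#' @param config A [pipeline_config()].
#' @param query Optional data.frame with columns `key`, `cdr3_aa`,
#'   `leukemic` of query clonotypes appended to the graph.
#' @return Object of class `tcrdrive_groups`: list with
#'   \describe{
#'     \item{`nodes`}{data.frame `key`, `cdr3_aa`, `frequency`, `leukemic`,
#'       `group_id`.}
#'     \item{`groups`}{data.frame `group_id`, `n_members`, `n_motifs`,
#'       `n_global_edges`, `significant`, `contains_leukemic`, `members`
#'       (";"-separated keys), `motifs` (";"-separated enriched motifs
#'       shared by >= 2 members).}
#'     \item{`motifs`}{the full [motif_enrichment()] table.}
#'     \item{`edges`}{data.frame `from`, `to`, `evidence` ("motif" or
#'       "global").}
#'   }
#'   Group ids are deterministic: groups sorted by size (descending), ties
#'   broken by the lexicographically smallest member key.
#' @export
build_specificity_groups <- function(sample, reference, config = NULL,
                                     query = NULL) {
  config <- as_config(config)
  validate_repertoire(sample)
  ref <- as_reference_index(reference, config)

  nodes <- data.frame(key = sample$clonotypes$key,
                      cdr3_aa = sample$clonotypes$cdr3_aa,
                      frequency = sample$clonotypes$frequency,
                      leukemic = sample$clonotypes$leukemic,
                      stringsAsFactors = FALSE)
  if (!is.null(query) && nrow(query) > 0L) {
    nodes <- rbind(nodes, data.frame(key = query$key,
                                     cdr3_aa = query$cdr3_aa,
                                     frequency = NA_real_,
                                     leukemic = query$leukemic %||% NA,
                                     stringsAsFactors = FALSE))
  }
  if (anyDuplicated(nodes$key))
    stop_tcrdrive("validation_error", "duplicate keys across sample and query nodes")

  # Enrichment is computed over the distinct CDR3s of all participating
  # clonotypes (sample + query).
  enr <- motif_enrichment(nodes$cdr3_aa, ref, config)
  enriched <- enr[enr$enriched, , drop = FALSE]

  cores <- trim_core(nodes$cdr3_aa, config$cdr3_trim)

  # Bipartite trick: motif vertices connect every clonotype containing an
  # enriched motif; connected components over clonotype vertices are then
  # identical to components of the clique-expanded graph, without
  # materialising O(m^2) clique edges.
  n <- nrow(nodes)
  motif_edges <- NULL
  if (nrow(enriched) > 0L) {
    hits <- lapply(seq_len(n), function(i) {
      km <- unique(unlist(lapply(config$motif_lengths,
                                 function(k) kmers_of(cores[i], k)),
                          use.names = FALSE))
      intersect(km, enriched$motif)
    })
    motif_edges <- data.frame(
      node = rep.int(seq_len(n), lengths(hits)),
      motif = unlist(hits, use.names = FALSE),
      stringsAsFactors = FALSE)
  }

  gp <- global_pairs(nodes$cdr3_aa, config)

  motif_ids <- unique(motif_edges$motif)
  g <- igraph::make_empty_graph(n = n + length(motif_ids), directed = FALSE)
  if (!is.null(motif_edges) && nrow(motif_edges) > 0L) {
    mi <- n + match(motif_edges$motif, motif_ids)
    g <- igraph::add_edges(g, rbind(motif_edges$node, mi))
  }
  if (nrow(gp) > 0L) g <- igraph::add_edges(g, rbind(gp$i, gp$j))
  comp <- igraph::components(g)$membership[seq_len(n)]

  # Deterministic group ids: size desc, then smallest member key.
  sizes <- table(comp)
  smallest <- tapply(nodes$key, comp, function(k) min(k))
  ord <- order_stable(-as.integer(sizes[as.character(names(smallest))]),
                      as.character(smallest))
  relabel <- stats::setNames(seq_along(ord), names(smallest)[ord])
  group_id <- as.integer(relabel[as.character(comp)])
  nodes$group_id <- group_id

  leuk <- !is.na(nodes$leukemic) & nodes$leukemic
  group_rows <- lapply(sort(unique(group_id)), function(gid) {
    members <- which(group_id == gid)
    mm <- if (!is.null(motif_edges) && nrow(motif_edges) > 0L) {
      tabm <- table(motif_edges$motif[motif_edges$node %in% members])
      names(tabm)[tabm >= 2L]  # enriched motifs shared by >= 2 members
    } else character()
    n_global <- if (nrow(gp) > 0L) sum(gp$i %in% members & gp$j %in% members)
                else 0L
    sig <- length(mm) > 0L
    if (!sig && n_global > 0L) {
      ge <- gp[gp$i %in% members & gp$j %in% members, , drop = FALSE]
      for (r in seq_len(nrow(ge))) {
        if (global_edge_significant(cores[ge$i[r]], cores[ge$j[r]],
                                    cores, ref, config)) {
          sig <- TRUE
          break
        }
      }
    }
    data.frame(group_id = gid, n_members = length(members),
               n_motifs = length(mm), n_global_edges = as.integer(n_global),
               significant = sig,
               contains_leukemic = any(leuk[members]),
               members = paste(sort(nodes$key[members]), collapse = ";"),
               motifs = paste(sort(mm), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, group_rows)

  edges <- data.frame(from = character(), to = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  if (!is.null(motif_edges) && nrow(motif_edges) > 0L) {
    # expand motif co-membership into clonotype pairs for reporting
    by_motif <- split(motif_edges$node, motif_edges$motif)
    pair_list <- lapply(by_motif, function(mem) {
      mem <- sort(unique(mem))
      if (length(mem) < 2L) return(NULL)
      cmb <- utils::combn(mem, 2L)
      data.frame(from = nodes$key[cmb[1, ]], to = nodes$key[cmb[2, ]],
                 evidence = "motif", stringsAsFactors = FALSE)
    })
    pair_df <- do.call(rbind, pair_list)
    if (!is.null(pair_df)) edges <- rbind(edges, unique(pair_df))
  }
  if (nrow(gp) > 0L) {
    edges <- rbind(edges, data.frame(from = nodes$key[gp$i],
                                     to = nodes$key[gp$j],
                                     evidence = "global",
                                     stringsAsFactors = FALSE))
  }

  structure(list(nodes = nodes, groups = groups, motifs = enr, edges = edges),
            class = "tcrdrive_groups")
}

#' @export
print.tcrdrive_groups <- function(x, ...) {
  sig <- x$groups[x$groups$significant & x$groups$n_members >= 2L, , drop = FALSE]
  cat(sprintf("specificity grouping: %d clonotypes, %d groups (%d significant with >= 2 members), %d enriched motifs\n",
              nrow(x$nodes), nrow(x$groups), nrow(sig), sum(x$motifs$enriched)))
  invisible(x)
}

#' Write a specificity network to GraphML
#'
#' Nodes carry `frequency` and `leukemic` attributes; edges carry the
#' `evidence` attribute ("motif" or "global").
#'
#' @param groups A `tcrdrive_groups` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_groups_graphml <- function(groups, path) {
  nodes <- groups$nodes
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes$key
  igraph::V(g)$frequency <- ifelse(is.na(nodes$frequency), -1, nodes$frequency)
  igraph::V(g)$leukemic <- !is.na(nodes$leukemic) & nodes$leukemic
  if (nrow(groups$edges) > 0L) {
    idx <- rbind(match(groups$edges$from, nodes$key),
                 match(groups$edges$to, nodes$key))
    g <- igraph::add_edges(g, idx, evidence = groups$edges$evidence)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
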