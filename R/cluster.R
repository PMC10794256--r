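# Greedy similarity clustering at a threshold (equivalent to connected
# components of the >= threshold graph, i.e. single linkage) and candidate
# status assignment against a reference panel.

#' Clustering configuration
#'
#' @param threshold Similarity threshold in (0, 1]; members join a cluster
#'   when they reach at least this similarity to any current member
#'   (default 0.8). Ties at exactly the threshold are inclusive.
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  structure(list(threshold = threshold), class = "cluster_config")
}

#' Greedy single-linkage clustering of a similarity table
#'
#' Groups ids into a cluster whenever one member has similarity at or above
#' the threshold with any other member; the result equals the connected
#' components of the threshold graph and is independent of input order.
#'
#' @param table Similarity table from [all_pairs()] (columns `id_a`, `id_b`,
#'   `similarity`).
#' @param config A [cluster_config()].
#' @param ids Optional character vector of all ids (so that ids with no
#'   table row still appear as singletons).
#' @return List of character vectors (cluster member ids), ordered by first
#'   member; singletons included.
#' @export
cluster_greedy <- function(table, config = cluster_config(), ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(table$id_a, table$id_b)))
  edges <- table[table$similarity >= config$threshold, c("id_a", "id_b")]
  adj <- split(c(edges$id_b, edges$id_a), c(edges$id_a, edges$id_b))
  seen <- setNames(rep(FALSE, length(ids)), ids)
  clusters <- list()
  for (id in ids) {
    if (seen[[id]]) next
    queue <- id
    members <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (isTRUE(seen[[v]])) next
      seen[[v]] <- TRUE
      members <- c(members, v)
      queue <- c(queue, setdiff(unique(adj[[v]]), members))
    }
    clusters[[length(clusters) + 1]] <- sort(members)
  }
  clusters
}

#' Assign hit / clustered / orphan status to candidates
#'
#' A candidate is a *hit* when it has a direct similarity at or above the
#' threshold to at least one reference; otherwise *clustered* when it
#' reaches the threshold against another candidate; otherwise *orphan*.
#' Candidates that share a cluster with a reference only through transitive
#' links (no direct edge) stay *clustered* but are flagged
#' `in_reference_cluster`.
#'
#' @param table Similarity table from [all_pairs()].
#' @param clusters Cluster list from [cluster_greedy()].
#' @param reference_ids Character vector of reference ids (disjoint from
#'   candidate ids).
#' @param config A [cluster_config()].
#' @return Object of class `cluster_assignment`: list with `clusters`,
#'   `status` (`data.frame`: `candidate_id`, `status`, `best_reference`,
#'   `best_similarity`, `in_reference_cluster`), and `hit_pairs`.
#' @export
assign_status <- function(table, clusters, reference_ids,
                          config = cluster_config()) {
  all_ids <- unique(c(table$id_a, table$id_b))
  cand_ids <- setdiff(all_ids, reference_ids)
  if (length(intersect(cand_ids, reference_ids)))
    stop("reference ids must be disjoint from candidate ids")
  long <- rbind(
    data.frame(a = table$id_a, b = table$id_b, s = table$similarity),
    data.frame(a = table$id_b, b = table$id_a, s = table$similarity))
  status <- data.frame(candidate_id = cand_ids, status = "orphan",
                       best_reference = NA_character_,
                       best_similarity = NA_real_,
                       in_reference_cluster = FALSE,
                       stringsAsFactors = FALSE)
  hit_pairs <- list()
  for (k in seq_along(cand_ids)) {
    id <- cand_ids[k]
    mine <- long[long$a == id, ]
    to_ref <- mine[mine$b %in% reference_ids, ]
    if (nrow(to_ref)) {
      best <- to_ref[which.max(to_ref$s), ]
      status$best_reference[k] <- best$b
      status$best_similarity[k] <- best$s
    }
    if (nrow(to_ref) && any(to_ref$s >= config$threshold)) {
      status$status[k] <- "hit"
      hits <- to_ref[to_ref$s >= config$threshold, ]
      hit_pairs[[length(hit_pairs) + 1]] <- data.frame(
        candidate = id, reference = hits$b, similarity = hits$s,
        stringsAsFactors = FALSE)
    } else {
      to_cand <- mine[!mine$b %in% reference_ids, ]
      if (nrow(to_cand) && any(to_cand$s >= config$threshold))
        status$status[k] <- "clustered"
    }
    cl <- Find(function(cl) id %in% cl, clusters)
    status$in_reference_cluster[k] <- status$status[k] != "hit" &&
      !is.null(cl) && length(intersect(cl, reference_ids)) > 0
  }
  structure(list(clusters = clusters, status = status,
                 hit_pairs = if (length(hit_pairs))
                   do.call(rbind, hit_pairs)
                 else data.frame(candidate = character(),
                                 reference = character(),
                                 similarity = numeric())),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(factor(x$status$status, c("hit", "clustered", "orphan")))
  cat(sprintf("<cluster_assignment> %d clusters; %d hit, %d clustered, %d orphan\n",
              length(x$clusters), tab[["hit"]], tab[["clustered"]],
              tab[["orphan"]]))
  invisible(x)
}

#' Group ids sharing token-identical BDAs
#'
#' @param bdas List of [bda()] objects.
#' @return List with `groups` (list of id vectors keyed by the shared token
#'   sequence) and `shared_count` (number of ids whose BDA is shared with at
#'   least one other id).
#' @export
collapse_identical <- function(bdas) {
  keys <- vapply(bdas, function(b) paste(b$tokens, collapse = "\r"),
                 character(1))
  ids <- vapply(bdas, `[[`, character(1), "bgc_id")
  groups <- split(ids, keys)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  names(groups) <- vapply(groups, function(g)
    paste(bdas[[match(g[1], ids)]]$tokens, collapse = ","), character(1))
  list(groups = groups,
       shared_count = sum(lengths(groups)[lengths(groups) >= 2]))
}

#' Write cluster membership and status tables
#'
#' @param assignment A `cluster_assignment`.
#' @param reference_ids Reference ids (to mark member roles).
#' @param clusters_path,status_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cluster_tables <- function(assignment, reference_ids,
                                 clusters_path, status_path) {
  rows <- do.call(rbind, lapply(seq_along(assignment$clusters), function(i)
    data.frame(cluster_id = i, member_id = assignment$clusters[[i]],
               role = ifelse(assignment$clusters[[i]] %in% reference_ids,
                             "reference", "candidate"),
               stringsAsFactors = FALSE)))
  write.table(rows, clusters_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(assignment$status, status_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(clusters_path, status_path))
}
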