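# Domain-frequency composition per BGC class: mean count of each domain per
# cluster, grouped by class and role.

#' Domain frequencies per class and role
#'
#' The frequency of a domain in a group is its total count across the
#' group's BGCs divided by the group size, i.e. the mean number of times the
#' domain appears per BGC. Domains absent from a group are omitted
#' (implicitly zero).
#'
#' @param records List of [bgc_record()] objects with resolved domain calls.
#' @param complete_only Drop contig-edge records before counting (default
#'   `FALSE`; the frequencies include edge records).
#' @param normalize Normalize labels through [normalize_domain_label()]
#'   before counting (default `TRUE`).
#' @return `data.frame` with columns `bgc_class`, `role`, `domain`,
#'   `frequency`, `n_bgcs`.
#' @export
domain_frequencies <- function(records, complete_only = FALSE,
                               normalize = TRUE) {
  if (complete_only)
    records <- Filter(function(r) !isTRUE(r$contig_edge), records)
  if (!length(records)) stop("no records in group (empty input)")
  key <- vapply(records, function(r) paste(r$bgc_class, r$role, sep = "\r"),
                character(1))
  out <- lapply(split(records, key), function(grp) {
    labels <- unlist(lapply(grp, function(r) r$domains$label))
    if (normalize) labels <- normalize_domain_label(labels)
    counts <- table(labels)
    n <- length(grp)
    if (!length(counts)) return(NULL)
    data.frame(bgc_class = grp[[1]]$bgc_class, role = grp[[1]]$role,
               domain = names(counts),
               frequency = as.numeric(counts) / n, n_bgcs = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top-k domains per class/role group
#'
#' @param table Output of [domain_frequencies()].
#' @param k Number of domains to keep per group (default 10); groups with
#'   fewer domains return all of them. Ties at the cut are broken
#'   lexicographically by domain label.
#' @return Ranked `data.frame` with an added `rank` column.
#' @export
top_domains <- function(table, k = 10) {
  if (!nrow(table)) stop("empty composition table")
  key <- paste(table$bgc_class, table$role, sep = "\r")
  out <- lapply(split(table, key), function(grp) {
    ord <- order(-grp$frequency, grp$domain)
    grp <- grp[head(ord, k), ]
    grp$rank <- seq_len(nrow(grp))
    grp
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
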