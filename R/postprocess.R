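# Post-processing rules for detected BGC regions: product-to-class mapping,
# qualifier-precedence resolution, region trimming, contig-edge flagging,
# short-contig filtering, and BDA construction.

#' Filtering configuration
#'
#' @param min_contig_length Minimum contig length in bp; regions on shorter
#'   contigs are discarded (default 10000, i.e. "shorter than 10 kb" is
#'   removed strictly).
#' @param edge_margin Width in bp of the contig-end margins used to flag
#'   potentially incomplete detections (default 20000).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_contig_length = 10000, edge_margin = 20000) {
  stopifnot(min_contig_length > 0, edge_margin > 0)
  structure(list(min_contig_length = min_contig_length,
                 edge_margin = edge_margin), class = "filter_config")
}

#' Map antiSMASH product subclasses to a BGC class
#'
#' `NRPS`/`NRPS-like` products map to the NRPS class, `T1PKS`/`T2PKS` to
#' modular PKS, `T3PKS` to type III PKS, `terpene` to TPS; anything else is
#' `other`. Mixed products resolve by priority NRPS > modular_PKS >
#' typeIII_PKS > TPS > other, except that an iterative-ketosynthase label in
#' `domain_labels` forces modular_PKS (hybrid clusters driven by an iterative
#' KS behave as single-module PKSs).
#'
#' @param subclasses Nonempty character vector of product labels.
#' @param domain_labels Optional character vector of canonical domain labels
#'   used for the iterative-KS override.
#' @return A single class string.
#' @examples
#' map_product_to_class("NRPS-like")
#' map_product_to_class(c("NRPS", "T1PKS"), domain_labels = "Itr_KS")
#' @export
map_product_to_class <- function(subclasses, domain_labels = character()) {
  stopifnot(length(subclasses) >= 1)
  per <- vapply(subclasses, function(s) {
    switch(s,
           "NRPS" = , "NRPS-like" = "NRPS",
           "T1PKS" = , "T2PKS" = "modular_PKS",
           "T3PKS" = "typeIII_PKS",
           "terpene" = "TPS",
           "other")
  }, character(1))
  if ("Itr_KS" %in% normalize_domain_label(domain_labels) &&
      any(per %in% c("NRPS", "modular_PKS")))
    return("modular_PKS")
  prio <- c("NRPS", "modular_PKS", "typeIII_PKS", "TPS", "other")
  prio[min(match(per, prio))]
}

#' Resolve NRPS_PKS vs sec_met_domain qualifier precedence
#'
#' antiSMASH can annotate the same CDS with both `NRPS_PKS` and
#' `sec_met_domain` qualifiers. At loci carrying both kinds, modular classes
#' (NRPS, modular PKS) keep the `NRPS_PKS` calls while non-modular classes
#' (type III PKS, TPS, other) keep the `sec_met_domain` calls; loci with only
#' one kind keep whatever exists.
#'
#' @param calls Domain-call `data.frame` (see [bgc_record()]).
#' @param bgc_class Class of the record the calls belong to.
#' @return Filtered domain-call `data.frame`.
#' @export
resolve_feature_precedence <- function(calls, bgc_class) {
  if (!nrow(calls)) return(calls)
  preferred <- if (bgc_class %in% c("NRPS", "modular_PKS"))
    "NRPS_PKS" else "sec_met_domain"
  keep <- unlist(lapply(split(seq_len(nrow(calls)), calls$cds_id), function(i) {
    kinds <- unique(calls$source_feature[i])
    if (length(kinds) > 1) i[calls$source_feature[i] == preferred] else i
  }), use.names = FALSE)
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim a BGC region to its domain-bearing CDSs
#'
#' Region bounds become the minimum start / maximum end over CDSs that carry
#' at least one biosynthetic domain call. Records without any domain call are
#' left untrimmed and flagged `"no_domains"`.
#'
#' @param record A [bgc_record()].
#' @return The trimmed record.
#' @export
trim_region <- function(record) {
  if (!nrow(record$domains)) {
    record$flags <- union(record$flags, "no_domains")
    return(record)
  }
  ids <- unique(record$domains$cds_id)
  cds <- record$cds[record$cds$cds_id %in% ids, , drop = FALSE]
  if (!nrow(cds)) cds <- record$domains  # fall back to domain coordinates
  record$region_start <- min(cds$start)
  record$region_end <- max(cds$end)
  validate_bgc_record(record)
}

#' Flag regions overlapping a contig-end margin
#'
#' A region is at the contig edge when it overlaps the first or last
#' `edge_margin` bp of its contig (closed at the contig ends, half-open
#' toward the interior).
#'
#' @param record A [bgc_record()] with known `contig_length`.
#' @param config A [filter_config()].
#' @return The record with `contig_edge` set.
#' @export
flag_contig_edge <- function(record, config = filter_config()) {
  if (is.na(record$contig_length))
    stop(record$bgc_id, ": contig_length is required to flag contig edges")
  record$contig_edge <-
    record$region_start < config$edge_margin ||
    record$region_end > record$contig_length - config$edge_margin
  record
}

#' Remove records detected on short contigs
#'
#' @param records List of [bgc_record()] objects.
#' @param config A [filter_config()]; records with
#'   `contig_length < min_contig_length` are removed.
#' @return List with elements `kept` and `removed`; together they partition
#'   the input in order.
#' @export
filter_short_contigs <- function(records, config = filter_config()) {
  short <- vapply(records, function(r) {
    if (is.na(r$contig_length))
      stop(r$bgc_id, ": contig_length is required for filtering")
    r$contig_length < config$min_contig_length
  }, logical(1))
  list(kept = records[!short], removed = records[short])
}

#' Build the biosynthetic domain architecture of a record
#'
#' Tokens follow assembly-line order: CDSs sorted by genomic start, and
#' within each CDS domains in translation order (genomic order on the plus
#' strand, reverse genomic order on the minus strand). Labels are normalized
#' to the canonical vocabulary.
#'
#' @param record A [bgc_record()] with resolved domain calls.
#' @param aliases Alias table passed to [normalize_domain_label()].
#' @return A [bda()].
#' @export
build_bda <- function(record, aliases = domain_aliases()) {
  d <- record$domains
  if (!nrow(d)) {
    if (record$bgc_class %in% c("NRPS", "modular_PKS"))
      stop(record$bgc_id, ": modular-class record has no domain calls")
    return(bda(record$bgc_id, character(0)))
  }
  cds_start <- tapply(d$start, d$cds_id, min)
  cds_order <- rank(cds_start[d$cds_id], ties.method = "min")
  within <- ifelse(d$strand == "-", -d$start, d$start)
  ord <- order(cds_order, within, d$rank_in_cds)
  bda(record$bgc_id, normalize_domain_label(d$label[ord], aliases))
}
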