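# BGC record container. Coordinates are 0-based half-open everywhere inside
# the package; conversion to/from GenBank's 1-based closed intervals happens
# only in the GenBank reader/writer.

#' Construct a BGC record
#'
#' A `bgc_record` holds one detected (candidate) or characterized (reference)
#' biosynthetic gene cluster: its class, trimmed region coordinates, contig
#' metadata, the CDS layout and the ordered biosynthetic domain calls.
#'
#' @param bgc_id,contig_id Identifiers.
#' @param contig_length Contig length in bp (`NA` allowed for references).
#' @param bgc_class One of `"NRPS"`, `"modular_PKS"`, `"typeIII_PKS"`,
#'   `"TPS"`, `"other"`.
#' @param subclass Character vector of product subclasses (e.g. `"NRPS-like"`,
#'   `"T1PKS"`).
#' @param region_start,region_end Region bounds, 0-based half-open.
#' @param contig_edge Logical; whether the region overlaps a contig-end
#'   margin (`NA` until [flag_contig_edge()] has run).
#' @param role `"candidate"` or `"reference"`.
#' @param domains `data.frame` with columns `label`, `cds_id`, `strand`,
#'   `start`, `end`, `source_feature`, `rank_in_cds`.
#' @param cds `data.frame` with columns `cds_id`, `start`, `end`, `strand`.
#' @param evidence,chem_acts Character vectors (reference records only).
#' @param organism Organism name or `"unknown"`.
#' @param flags Character vector of processing flags (e.g. `"no_domains"`).
#' @return An object of class `bgc_record`.
#' @export
bgc_record <- function(bgc_id, contig_id = bgc_id, contig_length = NA_real_,
                       bgc_class = "other", subclass = character(),
                       region_start, region_end, contig_edge = NA,
                       role = c("candidate", "reference"),
                       domains = empty_domain_calls(), cds = empty_cds_table(),
                       evidence = character(), chem_acts = character(),
                       organism = "unknown", flags = character()) {
  role <- match.arg(role)
  rec <- structure(
    list(bgc_id = as.character(bgc_id), contig_id = as.character(contig_id),
         contig_length = as.numeric(contig_length),
         bgc_class = as.character(bgc_class), subclass = as.character(subclass),
         region_start = as.numeric(region_start),
         region_end = as.numeric(region_end),
         contig_edge = contig_edge, role = role,
         domains = as_domain_calls(domains), cds = as_cds_table(cds),
         evidence = as.character(evidence), chem_acts = as.character(chem_acts),
         organism = as.character(organism), flags = as.character(flags)),
    class = "bgc_record")
  validate_bgc_record(rec)
}

bgc_classes <- function() c("NRPS", "modular_PKS", "typeIII_PKS", "TPS", "other")

#' @export
print.bgc_record <- function(x, ...) {
  cat(sprintf("<bgc_record> %s [%s, %s] %s:%d-%d (%d domains, %d CDS)%s\n",
              x$bgc_id, x$bgc_class, x$role, x$contig_id,
              x$region_start, x$region_end, nrow(x$domains), nrow(x$cds),
              if (isTRUE(x$contig_edge)) " [contig edge]" else ""))
  invisible(x)
}

empty_domain_calls <- function() {
  data.frame(label = character(), cds_id = character(), strand = character(),
             start = numeric(), end = numeric(), source_feature = character(),
             rank_in_cds = integer(), stringsAsFactors = FALSE)
}

empty_cds_table <- function() {
  data.frame(cds_id = character(), start = numeric(), end = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

as_domain_calls <- function(d) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  need <- names(empty_domain_calls())
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("domain calls missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, need]
  if (nrow(d)) {
    stopifnot(all(d$start < d$end), all(nzchar(d$label)),
              all(d$rank_in_cds >= 0), all(d$strand %in% c("+", "-")))
  }
  d
}

as_cds_table <- function(d) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  need <- names(empty_cds_table())
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cds table missing column(s): ", paste(miss, collapse = ", "))
  d[, need]
}

validate_bgc_record <- function(rec) {
  if (!rec$bgc_class %in% bgc_classes())
    stop("unknown bgc_class: ", rec$bgc_class)
  if (!is.na(rec$region_start) && rec$region_start >= rec$region_end)
    stop(rec$bgc_id, ": region_start must be < region_end")
  if (nrow(rec$domains) && !is.na(rec$region_start)) {
    if (any(rec$domains$start < rec$region_start) ||
        any(rec$domains$end > rec$region_end))
      stop(rec$bgc_id, ": region bounds must cover every domain call")
  }
  rec
}

#' Summarize a list of BGC records as a table
#'
#' @param records List of [bgc_record()] objects.
#' @return `data.frame` with one row per record (columns `bgc_id`,
#'   `contig_id`, `contig_length`, `class`, `subclass`, `start`, `end`,
#'   `contig_edge`, `role`, `n_domains`).
#' @export
bgc_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(bgc_id = r$bgc_id, contig_id = r$contig_id,
               contig_length = r$contig_length, class = r$bgc_class,
               subclass = paste(r$subclass, collapse = ","),
               start = r$region_start, end = r$region_end,
               contig_edge = r$contig_edge, role = r$role,
               n_domains = nrow(r$domains), stringsAsFactors = FALSE)
  }))
}

#' Write / read the BGC summary table
#'
#' @param records List of [bgc_record()] objects.
#' @param path Output TSV path.
#' @return `write_bgc_table()` returns `path` invisibly.
#' @export
write_bgc_table <- function(records, path) {
  write.table(bgc_table(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a BDA (biosynthetic domain architecture)
#'
#' @param bgc_id Identifier of the source cluster.
#' @param tokens Ordered character vector of canonical domain labels.
#' @return Object of class `bda`.
#' @export
bda <- function(bgc_id, tokens) {
  tokens <- as.character(tokens)
  if (any(!nzchar(tokens))) stop("empty BDA token")
  structure(list(bgc_id = as.character(bgc_id), tokens = tokens),
            class = "bda")
}

as_bda <- function(x, bgc_id = "bda") {
  if (inherits(x, "bda")) return(x)
  if (is.character(x)) return(bda(bgc_id, x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a BDA")
}

#' @export
print.bda <- function(x, ...) {
  cat(sprintf("<bda> %s: %s\n", x$bgc_id, paste(x$tokens, collapse = "-")))
  invisible(x)
}

#' Write / read BDA token sequences as TSV
#'
#' One line per BDA: the BGC identifier, a tab, and the comma-joined tokens.
#'
#' @param bdas List of [bda()] objects.
#' @param path TSV path.
#' @return `read_bda_tsv()` returns a named list of [bda()] objects.
#' @export
write_bda_tsv <- function(bdas, path) {
  lines <- vapply(bdas, function(b)
    paste0(b$bgc_id, "\t", paste(b$tokens, collapse = ",")), character(1))
  writeLines(c("bgc_id\ttokens", lines), path)
  invisible(path)
}

#' @rdname write_bda_tsv
#' @export
read_bda_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- lapply(seq_len(nrow(d)), function(i)
    bda(d$bgc_id[i], strsplit(d$tokens[i], ",", fixed = TRUE)[[1]]))
  names(out) <- d$bgc_id
  out
}
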