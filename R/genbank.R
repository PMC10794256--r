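# Reader for the antiSMASH region dialect of GenBank flat files. Only the
# features this package consumes are interpreted: `region` features carrying
# `/product` qualifiers and CDS features carrying `/NRPS_PKS` and/or
# `/sec_met_domain` qualifiers. GenBank 1-based closed coordinates are
# converted to the package's 0-based half-open convention on the way in.

#' Parse antiSMASH-dialect GenBank text into BGC records
#'
#' One [bgc_record()] is produced per `region` feature. Domain calls are
#' extracted from `NRPS_PKS` qualifiers (`"Domain: <label> (<aa_start>-<aa_end>). ..."`,
#' protein coordinates converted to genomic) and from `sec_met_domain`
#' qualifiers (`"<label> (E-value: ...)"`, assigned the CDS coordinates).
#' Both qualifier kinds are retained; call [resolve_feature_precedence()]
#' afterwards to apply class-dependent precedence. Regions without a
#' `product` qualifier are classed `"other"` with a warning; regions without
#' any biosynthetic domain get an empty domain table and the `"no_domains"`
#' flag.
#'
#' @param text Either a path to a GenBank file or a character vector of
#'   GenBank lines.
#' @param classify Logical; when `TRUE` (default) the record class is set
#'   with [map_product_to_class()] from the product qualifiers.
#' @return List of [bgc_record()] objects (`role = "candidate"`).
#' @export
parse_antismash_genbank <- function(text, classify = TRUE) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  ends <- grep("^//\\s*$", lines)
  starts <- c(1, head(ends, -1) + 1)
  if (!length(ends)) { starts <- 1; ends <- length(lines) }
  out <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    chunk <- chunk[!grepl("^//\\s*$", chunk)]
    if (!any(nzchar(trimws(chunk)))) next
    out <- c(out, parse_genbank_record(chunk, offset = starts[k] - 1,
                                       classify = classify))
  }
  out
}

parse_genbank_record <- function(lines, offset = 0, classify = TRUE) {
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc))
    stop("malformed GenBank: no LOCUS line in record starting at line ",
         offset + 1)
  loc <- strsplit(trimws(lines[iloc[1]]), "[[:space:]]+")[[1]]
  contig_id <- loc[2]
  len_i <- which(loc == "bp")
  contig_length <- suppressWarnings(as.numeric(loc[if (length(len_i)) len_i[1] - 1 else 3]))
  if (is.na(contig_length))
    stop("malformed GenBank: cannot read sequence length from line ",
         offset + iloc[1])
  ifeat <- grep("^FEATURES", lines)
  if (!length(ifeat)) return(list())
  iend <- grep("^(ORIGIN|CONTIG)", lines)
  iend <- if (length(iend)) min(iend[iend > ifeat[1]]) - 1 else length(lines)
  feats <- parse_feature_block(lines[(ifeat[1] + 1):iend], offset + ifeat[1])

  regions <- Filter(function(f) f$key == "region", feats)
  cdss <- Filter(function(f) f$key == "CDS", feats)
  lapply(seq_along(regions), function(ri) {
    reg <- regions[[ri]]
    number <- reg$qualifiers[["region_number"]]
    rid <- paste0(contig_id, "_", if (length(number)) number[1] else ri)
    products <- reg$qualifiers[["product"]]
    if (is.null(products)) {
      warning(rid, ": region has no product qualifier; classed as \"other\"")
      products <- character(0)
    }
    inside <- Filter(function(f) f$start < reg$end && f$end > reg$start, cdss)
    cds_tab <- empty_cds_table()
    calls <- empty_domain_calls()
    for (ci in seq_along(inside)) {
      f <- inside[[ci]]
      cid <- c(f$qualifiers[["locus_tag"]], f$qualifiers[["protein_id"]],
               paste0(rid, "_cds", ci))[1]
      cds_tab <- rbind(cds_tab, data.frame(
        cds_id = cid, start = f$start, end = f$end, strand = f$strand,
        stringsAsFactors = FALSE))
      calls <- rbind(calls, extract_domain_calls(f, cid))
    }
    flags <- if (nrow(calls)) character() else "no_domains"
    cls <- if (classify && length(products))
      map_product_to_class(products, domain_labels = calls$label) else "other"
    bgc_record(bgc_id = rid, contig_id = contig_id,
               contig_length = contig_length, bgc_class = cls,
               subclass = products, region_start = reg$start,
               region_end = reg$end, role = "candidate",
               domains = calls, cds = cds_tab, flags = flags)
  })
}

# Parse the FEATURES block into a list of (key, start, end, strand,
# qualifiers). Qualifiers are a named list of character vectors; repeated
# qualifiers accumulate.
parse_feature_block <- function(lines, line_offset = 0) {
  feats <- list()
  cur <- NULL
  qname <- NULL
  flush <- function() if (!is.null(cur)) feats[[length(feats) + 1]] <<- cur
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (grepl("^ {5}\\S", line)) {                      # feature header
      flush()
      m <- regmatches(line, regexec("^ {5}(\\S+)\\s+(\\S.*)$", line))[[1]]
      if (length(m) < 3)
        stop("malformed GenBank feature at line ", line_offset + i)
      loc <- parse_gb_location(m[3], line_offset + i)
      cur <- c(list(key = m[2]), loc, list(qualifiers = list()))
      qname <- NULL
    } else if (grepl("^\\s+/", line)) {                 # qualifier start
      if (is.null(cur))
        stop("malformed GenBank: qualifier before any feature at line ",
             line_offset + i)
      m <- regmatches(trimws(line),
                      regexec("^/([A-Za-z0-9_]+)(=(.*))?$", trimws(line)))[[1]]
      qname <- m[2]
      val <- if (nchar(m[4])) m[4] else ""
      cur$qualifiers[[qname]] <- c(cur$qualifiers[[qname]], val)
    } else if (!is.null(qname)) {                       # continuation
      n <- length(cur$qualifiers[[qname]])
      cur$qualifiers[[qname]][n] <-
        paste(cur$qualifiers[[qname]][n], trimws(line))
    }
  }
  flush()
  lapply(feats, function(f) {
    f$qualifiers <- lapply(f$qualifiers, function(v) gsub("^\"|\"$", "", v))
    f
  })
}

# "123..456", "complement(123..456)", "join(..)"; returns 0-based half-open.
parse_gb_location <- function(loc, lineno) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- suppressWarnings(as.numeric(
    regmatches(loc, gregexpr("[0-9]+", loc))[[1]]))
  if (length(nums) < 2 || any(is.na(nums)))
    stop("malformed GenBank location at line ", lineno, ": ", loc)
  list(start = min(nums) - 1, end = max(nums), strand = strand)
}

extract_domain_calls <- function(feat, cds_id) {
  calls <- empty_domain_calls()
  rank <- 0L
  add <- function(label, start, end, source) {
    calls[nrow(calls) + 1L, ] <<- list(label, cds_id, feat$strand,
                                       start, end, source, rank)
    rank <<- rank + 1L
  }
  for (v in feat$qualifiers[["NRPS_PKS"]]) {
    m <- regmatches(v, regexec("^Domain:\\s*(\\S+)\\s*\\((\\d+)-(\\d+)\\)", v))[[1]]
    if (length(m) < 4) next                     # "type: ..." and other values
    aa <- as.numeric(m[3:4])
    if (feat$strand == "+") {
      g <- c(feat$start + 3 * (aa[1] - 1), feat$start + 3 * aa[2])
    } else {
      g <- c(feat$end - 3 * aa[2], feat$end - 3 * (aa[1] - 1))
    }
    g <- pmin(pmax(g, feat$start), feat$end)
    add(m[2], g[1], g[2], "NRPS_PKS")
  }
  for (v in feat$qualifiers[["sec_met_domain"]]) {
    label <- trimws(sub("\\s*\\(.*$", "", v))
    if (nzchar(label)) add(label, feat$start, feat$end, "sec_met_domain")
  }
  calls
}
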