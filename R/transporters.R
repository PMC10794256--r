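# Transporter-gene context around complete BGCs: genes are assigned to the
# 5' proximate flank, the cluster region, or the 3' proximate flank; each
# region is tiled into 1 kb windows; per-family window frequencies feed a
# rank-sum enrichment test per family and region.

#' Region configuration for the transporter scan
#'
#' @param proximate_margin Width in bp of the 5' and 3' flanks (default
#'   20000).
#' @param window Window width in bp for frequency averaging (default 1000).
#' @return Object of class `region_config`.
#' @export
region_config <- function(proximate_margin = 20000, window = 1000) {
  stopifnot(proximate_margin > 0, window > 0, window <= proximate_margin)
  structure(list(proximate_margin = proximate_margin, window = window),
            class = "region_config")
}

#' Read a transporter annotation table
#'
#' @param path TSV with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `tcdb_family`, `tcdb_superfamily`.
#' @return Validated `data.frame`.
#' @export
read_transporter_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validate_transporter_table(d)
}

validate_transporter_table <- function(d) {
  need <- c("gene_id", "contig_id", "start", "end", "tcdb_family",
            "tcdb_superfamily")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("transporter table missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$start >= d$end)) stop("transporter gene with start >= end")
  bad <- !grepl("^[0-9]+(\\.[A-Za-z0-9]+)+$", d$tcdb_family)
  if (any(bad))
    stop("tcdb_family not a dotted TCDB code: ",
         paste(unique(d$tcdb_family[bad]), collapse = ", "))
  d
}

# Region spans of one complete BGC: 0-based half-open, clipped at contig
# bounds; disjoint by construction.
region_spans <- function(bgc, config = region_config()) {
  rs <- bgc$region_start; re <- bgc$region_end
  list(
    `5prime` = c(max(0, rs - config$proximate_margin), rs),
    in_cluster = c(rs, re),
    `3prime` = c(re, min(bgc$contig_length, re + config$proximate_margin)))
}

#' Assign transporter genes around one BGC to regions
#'
#' Genes overlapping the cluster region are `in_cluster`; genes overlapping
#' the 20 kb flank upstream/downstream are `5prime` / `3prime` (overlap
#' priority: in_cluster first, then 5prime, then 3prime); genes outside all
#' three spans are dropped. Only complete (non-contig-edge) BGCs are valid
#' input.
#'
#' @param bgc A [bgc_record()] with `contig_edge == FALSE`.
#' @param annotations Transporter `data.frame` (see
#'   [read_transporter_tsv()]).
#' @param config A [region_config()].
#' @return The annotations overlapping any region, with an added `region`
#'   column.
#' @export
assign_regions <- function(bgc, annotations, config = region_config()) {
  if (!isFALSE(bgc$contig_edge))
    stop(bgc$bgc_id,
         ": transporter context requires complete (non-edge) BGCs")
  ann <- annotations[annotations$contig_id == bgc$contig_id, , drop = FALSE]
  spans <- region_spans(bgc, config)
  region <- rep(NA_character_, nrow(ann))
  for (nm in c("in_cluster", "5prime", "3prime")) {
    sp <- spans[[nm]]
    hit <- is.na(region) & ann$start < sp[2] & ann$end > sp[1]
    region[hit] <- nm
  }
  out <- ann[!is.na(region), , drop = FALSE]
  out$region <- region[!is.na(region)]
  rownames(out) <- NULL
  out
}

# Tile a span [s, e) into non-overlapping windows of `window` bp (final
# partial window keeps its actual width) and compute per-family per-window
# frequency in genes per kb: count of genes whose start lies in the window,
# divided by the window width in kb.
window_table <- function(span, annotations, config = region_config(),
                         families = NULL) {
  s <- span[1]; e <- span[2]
  if (e - s < 1) stop("region span must be at least 1 bp")
  starts <- seq(s, e - 1e-9, by = config$window)
  ends <- pmin(starts + config$window, e)
  width_kb <- (ends - starts) / 1000
  if (is.null(families)) families <- sort(unique(annotations$tcdb_family))
  out <- data.frame(win_start = starts, win_end = ends, width_kb = width_kb)
  inside <- annotations$start >= s & annotations$start < e
  idx <- floor((annotations$start[inside] - s) / config$window) + 1
  counts <- table(factor(idx, levels = seq_along(starts)),
                  factor(annotations$tcdb_family[inside], levels = families))
  for (k in seq_along(families))
    out[[families[k]]] <- as.numeric(counts[, k]) / width_kb
  out
}

#' Mean windowed frequency of each transporter family in a span
#'
#' @param span Numeric length-2 vector `(start, end)`, 0-based half-open.
#' @param annotations Transporter genes inside the span.
#' @param config A [region_config()].
#' @param families Families to report (default: those present).
#' @return Named numeric vector: mean over windows of genes-per-kb.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2"), contig_id = "c",
#'                   start = c(1500, 7200), end = c(2000, 7700),
#'                   tcdb_family = "3.A.1", tcdb_superfamily = "ABC")
#' windowed_frequency(c(0, 10000), ann)  # 2 genes over 10 windows -> 0.2
#' @export
windowed_frequency <- function(span, annotations, config = region_config(),
                               families = NULL) {
  wt <- window_table(span, annotations, config, families)
  fam_cols <- setdiff(names(wt), c("win_start", "win_end", "width_kb"))
  if (!length(fam_cols)) return(setNames(numeric(0), character(0)))
  # mean over windows, the partial terminal window weighted by its width
  vapply(fam_cols, function(f) weighted.mean(wt[[f]], wt$width_kb),
         numeric(1))
}

#' Wilcoxon rank-sum (Mann-Whitney) test with exact small-sample enumeration
#'
#' Midranks handle ties. When `length(x) + length(y) <= exact_limit` the
#' two-sided p-value is computed by complete enumeration of group
#' assignments; otherwise the tie-corrected normal approximation with
#' continuity correction is used. When every value is identical the
#' p-value is 1.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact_limit Enumeration threshold on the combined sample size
#'   (default 10).
#' @return List with `statistic` (the Mann-Whitney U of `x`) and `p_value`
#'   (two-sided).
#' @export
rank_sum_test <- function(x, y, exact_limit = 10) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  U <- u_of(seq_len(nx))
  if (length(unique(pooled)) == 1) return(list(statistic = U, p_value = 1))
  if (n <= exact_limit) {
    r <- rank(pooled)
    us <- apply(combn(n, nx), 2, function(idx)
      sum(r[idx]) - nx * (nx + 1) / 2)
    p <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
    return(list(statistic = U, p_value = p))
  }
  r <- rank(pooled)
  ties <- table(r)
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p_value = 1))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  list(statistic = U, p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Transporter-family enrichment scan per BGC class and region
#'
#' For each class, pools the 1 kb windows of every complete BGC's three
#' regions, keeps the `top_n` most abundant TCDB families (by assigned gene
#' count), and for each family and region compares that family's window
#' frequencies in the region against its frequencies in all other windows
#' of the class with [rank_sum_test()]. A family is flagged `enriched` in a
#' region at `p < alpha` (raw p-values, no multiplicity correction) and
#' `exclusive` when all of its genes fall in that single region.
#'
#' @param records List of complete candidate [bgc_record()] objects.
#' @param annotations Transporter `data.frame`.
#' @param config A [region_config()].
#' @param top_n Families per class to test (default 10; `Inf` for all).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()]
#'   applied within class.
#' @return `data.frame` with columns `bgc_class`, `region`, `tcdb_family`,
#'   `mean_frequency`, `n_windows`, `p_value`, `enriched`, `exclusive`.
#' @export
enrichment_scan <- function(records, annotations, config = region_config(),
                            top_n = 10, alpha = 0.05, p_adjust = "none") {
  records <- Filter(function(r) !isTRUE(r$contig_edge), records)
  if (!length(records)) stop("no complete (non-edge) BGCs to scan")
  classes <- unique(vapply(records, `[[`, character(1), "bgc_class"))
  out <- list()
  for (cls in classes) {
    recs <- Filter(function(r) r$bgc_class == cls, records)
    assigned <- list(); windows <- list()
    for (r in recs) {
      ann <- assign_regions(r, annotations, config)
      assigned[[length(assigned) + 1]] <- ann
      spans <- region_spans(r, config)
      for (nm in names(spans)) {
        reg_nm <- if (nm == "in_cluster") "in_cluster" else nm
        wt <- window_table(spans[[nm]], ann[ann$region == reg_nm, , drop = FALSE],
                           config, families = unique(annotations$tcdb_family))
        wt$region <- reg_nm
        windows[[length(windows) + 1]] <- wt
      }
    }
    assigned <- do.call(rbind, assigned)
    if (!nrow(assigned)) next
    win <- do.call(rbind, windows)
    fam_counts <- sort(table(assigned$tcdb_family), decreasing = TRUE)
    fams <- names(fam_counts)
    if (is.finite(top_n)) {
      ord <- order(-as.numeric(fam_counts), names(fam_counts))
      fams <- names(fam_counts)[head(ord, top_n)]
    }
    for (f in fams) {
      fam_regions <- unique(assigned$region[assigned$tcdb_family == f])
      for (reg in c("5prime", "in_cluster", "3prime")) {
        in_reg <- win$region == reg
        x <- win[[f]][in_reg]; y <- win[[f]][!in_reg]
        if (!length(x) || !length(y)) next
        t <- rank_sum_test(x, y)
        out[[length(out) + 1]] <- data.frame(
          bgc_class = cls, region = reg, tcdb_family = f,
          mean_frequency = mean(x), n_windows = length(x),
          p_value = t$p_value,
          exclusive = identical(fam_regions, reg),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(bgc_class = character(), region = character(),
                      tcdb_family = character(), mean_frequency = numeric(),
                      n_windows = integer(), p_value = numeric(),
                      enriched = logical(), exclusive = logical()))
  res <- do.call(rbind, out)
  if (p_adjust != "none") {
    for (cls in unique(res$bgc_class)) {
      i <- res$bgc_class == cls
      res$p_value[i] <- stats::p.adjust(res$p_value[i], method = p_adjust)
    }
  }
  res$enriched <- res$p_value < alpha
  rownames(res) <- NULL
  res[, c("bgc_class", "region", "tcdb_family", "mean_frequency",
          "n_windows", "p_value", "enriched", "exclusive")]
}
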