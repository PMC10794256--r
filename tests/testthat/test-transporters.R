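ann_row <- function(id, start, end, fam = "3.A.1", contig = "tctg01") {
  data.frame(gene_id = id, contig_id = contig, start = start, end = end,
             tcdb_family = fam, tcdb_superfamily = sub("^(\\d+\\.[A-Za-z0-9]+).*", "\\1", fam),
             stringsAsFactors = FALSE)
}

test_that("genes are assigned to regions with in-cluster priority", {
  bgc <- transporter_test_records(1)[[1]]       # region [30000, 40000), 100 kb
  ann <- rbind(ann_row("g_up", 25000, 25400),          # 5 kb upstream
               ann_row("g_straddle", 29800, 30200),    # straddles region start
               ann_row("g_in", 35000, 35400),
               ann_row("g_down", 41000, 41400),
               ann_row("g_far", 65000, 65400))         # 25 kb downstream
  res <- assign_regions(bgc, ann)
  reg <- setNames(res$region, res$gene_id)
  expect_equal(reg[["g_up"]], "5prime")
  expect_equal(reg[["g_straddle"]], "in_cluster")
  expect_equal(reg[["g_in"]], "in_cluster")
  expect_equal(reg[["g_down"]], "3prime")
  expect_false("g_far" %in% res$gene_id)
  # contig-edge records are rejected
  edge <- bgc
  edge$contig_edge <- TRUE
  expect_error(assign_regions(edge, ann), "complete")
})

test_that("region spans are disjoint and clipped at contig bounds", {
  bgc <- transporter_test_records(1)[[1]]
  bgc$region_start <- 15000; bgc$region_end <- 95000
  spans <- bdalign:::region_spans(bgc, region_config())
  expect_equal(spans$`5prime`, c(0, 15000))       # clipped at the 5' end
  expect_equal(spans$`3prime`, c(95000, 1e5))     # clipped at the 3' end
  expect_equal(spans$in_cluster, c(15000, 95000))
  ends <- do.call(rbind, spans)
  expect_true(all(ends[, 1] < ends[, 2]))
})

test_that("windowed frequency is genes per kb averaged over 1 kb windows", {
  ann <- rbind(ann_row("a", 1500, 1900), ann_row("b", 7200, 7600))
  f <- windowed_frequency(c(0, 10000), ann)
  expect_equal(unname(f["3.A.1"]), 0.2)
  # empty region reports 0 for requested families
  f0 <- windowed_frequency(c(0, 5000), ann[0, ], families = c("3.A.1", "2.A.6"))
  expect_equal(unname(f0), c(0, 0))
  # 10.5 kb span: partial terminal window weighted by its width
  ann2 <- rbind(ann_row("a", 200, 600), ann_row("b", 10100, 10400))
  f2 <- windowed_frequency(c(0, 10500), ann2)
  # oracle: 10 full windows (one with freq 1) + one 0.5 kb window with
  # freq 1/0.5; weighted mean = (1*1 + 2*0.5) / 10.5
  expect_equal(unname(f2["3.A.1"]), (1 + 2 * 0.5) / 10.5)
  # doubling the genes doubles the mean frequency
  ann3 <- rbind(ann2, ann_row("c", 210, 610), ann_row("d", 10110, 10410))
  f3 <- windowed_frequency(c(0, 10500), ann3)
  expect_equal(unname(f3["3.A.1"]), 2 * unname(f2["3.A.1"]))
})

test_that("rank-sum test matches enumeration, conventions, and wilcox.test", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)       # 2/20 arrangements as extreme
  expect_equal(rank_sum_test(c(2, 2), c(2, 2))$p_value, 1)
  # exact branch agrees with wilcox.test where both are exact (no ties)
  set.seed(61)
  for (rep in 1:20) {
    x <- sample(1:100, 4); y <- sample(101:200, 5)
    ours <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  # normal approximation agrees with enumeration at n = 10: within 0.01 in
  # the significance-relevant tail for untied samples, more loosely under
  # heavy ties and in the centre of the distribution
  set.seed(62)
  for (rep in 1:50) {
    x <- runif(5); y <- runif(5)
    exact <- rank_sum_test(x, y)$p_value
    approx <- rank_sum_test(x, y, exact_limit = 0)$p_value
    if (exact <= 0.1) expect_lt(abs(exact - approx), 0.01)
    expect_lt(abs(exact - approx), 0.1)
    xt <- rpois(5, 2); yt <- rpois(5, 2)
    exact_t <- rank_sum_test(xt, yt)$p_value
    approx_t <- rank_sum_test(xt, yt, exact_limit = 0)$p_value
    if (exact_t <= 0.1) expect_lt(abs(exact_t - approx_t), 0.05)
  }
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("enrichment scan flags constructed effects and exclusivity", {
  recs <- transporter_test_records(8)
  fams <- c("3.A.1", "3.A.16", "8.A.23", "2.A.6", "1.B.14")
  ann <- generate_transporter_layout(recs, fams, density = 0.3,
                                     mode = "enriched",
                                     enriched_families = "3.A.1",
                                     enrich_factor = 5, seed = 91)
  # a family present only inside clusters is flagged exclusive
  ann_exc <- rbind(ann, do.call(rbind, lapply(seq_along(recs), function(i)
    ann_row(paste0("exc", i), 32000, 32400, fam = "9.B.99",
            contig = recs[[i]]$contig_id))))
  res <- enrichment_scan(recs, ann_exc, top_n = Inf)
  inc <- res[res$region == "in_cluster", ]
  expect_true(inc$enriched[inc$tcdb_family == "3.A.1"])
  expect_true(inc$exclusive[inc$tcdb_family == "9.B.99"])
  expect_false(any(res$exclusive[res$tcdb_family == "3.A.1"]))
  # the boosted family has the highest in-cluster mean frequency
  expect_equal(inc$tcdb_family[which.max(inc$mean_frequency)], "3.A.1")
  expect_true(all(res$mean_frequency >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("transporter TSV validation catches schema problems", {
  ann <- ann_row("g", 100, 500)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_transporter_tsv(path)$gene_id, "g")
  bad <- ann; bad$tcdb_family <- "not a code"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_transporter_tsv(path2), "TCDB")
  expect_error(validate_transporter_table(ann_row("g", 700, 600)),
               "start")
})
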