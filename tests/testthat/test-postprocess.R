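make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(label = r[[1]], cds_id = r[[2]], strand = r[[3]],
               start = as.numeric(r[[4]]), end = as.numeric(r[[5]]),
               source_feature = r[[6]],
               rank_in_cds = as.integer(r[[7]]), stringsAsFactors = FALSE)))
}

test_that("product labels map to classes with the documented priority", {
  expect_equal(map_product_to_class("NRPS-like"), "NRPS")
  expect_equal(map_product_to_class("T3PKS"), "typeIII_PKS")
  expect_equal(map_product_to_class("lanthipeptide"), "other")
  expect_equal(map_product_to_class(c("terpene", "T1PKS")), "modular_PKS")
  expect_equal(map_product_to_class(c("NRPS", "T1PKS")), "NRPS")
  # an iterative-KS domain forces hybrids into the modular PKS class
  expect_equal(map_product_to_class(c("NRPS", "T1PKS"),
                                    domain_labels = "Itr_KS"), "modular_PKS")
})

test_that("feature precedence keeps the class-preferred qualifier kind", {
  calls <- make_calls(
    list("Cond_LCL", "c1", "+", 100, 400, "NRPS_PKS", 0),
    list("Condensation", "c1", "+", 50, 500, "sec_met_domain", 1),
    list("AMP_binding", "c2", "+", 900, 1200, "sec_met_domain", 0))
  nrps <- resolve_feature_precedence(calls, "NRPS")
  expect_equal(nrps$label, c("Cond_LCL", "AMP_binding"))  # c2 has no conflict
  tps <- resolve_feature_precedence(calls, "TPS")
  expect_equal(tps$label, c("Condensation", "AMP_binding"))
  expect_equal(resolve_feature_precedence(empty_calls <- calls[0, ], "NRPS"),
               empty_calls)
})

test_that("trimming shrinks the region to domain-bearing CDSs", {
  rec <- bgc_record("b1", "c1", 1e5, "NRPS", "NRPS", 0, 50000,
                    domains = make_calls(
                      list("Cond_LCL", "x1", "+", 12500, 13400, "NRPS_PKS", 0)),
                    cds = data.frame(cds_id = c("x1", "x2"),
                                     start = c(12000, 40000),
                                     end = c(30000, 48000),
                                     strand = "+", stringsAsFactors = FALSE))
  tr <- trim_region(rec)
  expect_equal(c(tr$region_start, tr$region_end), c(12000, 30000))
  # all CDSs domain-bearing: unchanged
  rec2 <- rec
  rec2$cds <- rec2$cds[1, ]
  rec2$region_start <- 12000; rec2$region_end <- 30000
  tr2 <- trim_region(rec2)
  expect_equal(c(tr2$region_start, tr2$region_end), c(12000, 30000))
  # no domains: unchanged + flagged
  rec3 <- bgc_record("b3", "c1", 1e5, "other", "x", 0, 50000)
  tr3 <- trim_region(rec3)
  expect_equal(c(tr3$region_start, tr3$region_end), c(0, 50000))
  expect_true("no_domains" %in% tr3$flags)
})

test_that("contig-edge flagging uses the 20 kb margins", {
  mk <- function(s, e, len) bgc_record("b", "c", len, "other", "x", s, e)
  expect_true(flag_contig_edge(mk(0, 5000, 1e5))$contig_edge)
  expect_false(flag_contig_edge(mk(30000, 50000, 1e5))$contig_edge)
  # on a 60 kb contig the 3' margin starts at 40 kb
  expect_true(flag_contig_edge(mk(30000, 50000, 6e4))$contig_edge)
  rec <- mk(0, 5000, NA)
  expect_error(flag_contig_edge(rec), "contig_length")
})

test_that("short-contig filtering is a strict, order-preserving partition", {
  mk <- function(id, len) bgc_record(id, "c", len, "other", "x", 0, 5000)
  recs <- list(mk("a", 9999), mk("b", 10000), mk("c", 250000), mk("d", 500))
  parts <- filter_short_contigs(recs)
  expect_equal(vapply(parts$kept, `[[`, character(1), "bgc_id"), c("b", "c"))
  expect_equal(vapply(parts$removed, `[[`, character(1), "bgc_id"), c("a", "d"))
  expect_equal(length(parts$kept) + length(parts$removed), length(recs))
  empty <- filter_short_contigs(list())
  expect_equal(lengths(empty), c(kept = 0L, removed = 0L))
})

test_that("filter, trim and edge-flag are idempotent", {
  bdas <- list(generate_bda("NRPS", 2, bgc_id = "idem"))
  rec <- simulate_bgc_records(bdas, seed = 3)[[1]]
  once <- flag_contig_edge(trim_region(rec))
  twice <- flag_contig_edge(trim_region(once))
  expect_equal(twice, once)
  f1 <- filter_short_contigs(list(once))
  f2 <- filter_short_contigs(f1$kept)
  expect_equal(f2$kept, f1$kept)
})

test_that("BDA tokens follow genomic CDS order and translation order within CDS", {
  rec <- bgc_record("b", "c", 1e5, "NRPS", "NRPS", 0, 10000,
                    domains = make_calls(
                      list("TE", "g2", "+", 5000, 5900, "NRPS_PKS", 0),
                      list("Cond_LCL", "g1", "+", 1000, 1900, "NRPS_PKS", 0),
                      list("AMP_binding", "g1", "+", 1900, 2800, "NRPS_PKS", 1),
                      list("PCP", "g1", "+", 2800, 3700, "NRPS_PKS", 2)))
  expect_equal(build_bda(rec)$tokens, c("Cond_LCL", "AMP_binding", "PCP", "TE"))
  # minus-strand CDS whose genomic-order domains read PCP, A, C emits C, A, PCP
  rev_rec <- bgc_record("b2", "c", 1e5, "NRPS", "NRPS", 0, 10000,
                        domains = make_calls(
                          list("PCP", "g1", "-", 1000, 1900, "NRPS_PKS", 2),
                          list("AMP_binding", "g1", "-", 1900, 2800, "NRPS_PKS", 1),
                          list("Cond_LCL", "g1", "-", 2800, 3700, "NRPS_PKS", 0)))
  expect_equal(build_bda(rev_rec)$tokens, c("Cond_LCL", "AMP_binding", "PCP"))
  # labels are normalized on the way out
  alias_rec <- bgc_record("b3", "c", 1e5, "NRPS", "NRPS", 0, 10000,
                          domains = make_calls(
                            list("Condensation(LCL)", "g1", "+", 100, 1000, "NRPS_PKS", 0),
                            list("PP-binding", "g1", "+", 1000, 1900, "NRPS_PKS", 1)))
  expect_equal(build_bda(alias_rec)$tokens, c("Cond_LCL", "PP_bind"))
  # modular-class record without domains is an error
  empty_rec <- bgc_record("b4", "c", 1e5, "NRPS", "NRPS", 0, 10000)
  expect_error(build_bda(empty_rec), "no domain calls")
})

test_that("the worked Discussion candidate reconstructs to its 6-token BDA", {
  # candidate cluster: two CDSs carrying an elongation module each, the
  # first with a PP-binding carrier, the second with a peptidyl carrier
  rec <- bgc_record("MesVir_RPFO01000156.1_1", "RPFO01000156.1", 1e5,
                    "NRPS", "NRPS", 0, 20000,
                    domains = make_calls(
                      list("Condensation(LCL)", "g1", "+", 1000, 1900, "NRPS_PKS", 0),
                      list("AMP-binding", "g1", "+", 1900, 2800, "NRPS_PKS", 1),
                      list("PP-binding", "g1", "+", 2800, 3700, "NRPS_PKS", 2),
                      list("Condensation(LCL)", "g2", "+", 5000, 5900, "NRPS_PKS", 0),
                      list("AMP-binding", "g2", "+", 5900, 6800, "NRPS_PKS", 1),
                      list("PCP", "g2", "+", 6800, 7700, "NRPS_PKS", 2)))
  expect_equal(build_bda(rec)$tokens, worked_example_bdas()$candidate$tokens)
})

test_that("BDA TSV round-trips", {
  bdas <- list(generate_bda("NRPS", 2, bgc_id = "w1"),
               generate_bda("modular_PKS", 1, bgc_id = "w2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bda_tsv(bdas, path)
  back <- read_bda_tsv(path)
  expect_equal(lapply(back, `[[`, "tokens"),
               setNames(lapply(bdas, `[[`, "tokens"), c("w1", "w2")))
})
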