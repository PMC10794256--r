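# Shared fixtures and independent oracles used across the suite.

# Toy matrix mirroring the modular-NRPS homology structure: condensation
# subtypes mutually homologous, carrier proteins mutually homologous.
toy_nrps_matrix <- function() {
  homology_matrix(list(
    c("Cond_Starter", "Cond_DCL", "Cond_LCL", "Cond_Dual"),
    "AMP_binding",
    c("PCP", "ACP", "PP_bind"),
    "TE"))
}

# The two architectures printed for the candidate/reference worked example.
worked_example_bdas <- function() {
  list(candidate = bda("MesVir_RPFO01000156.1_1",
                       c("Cond_LCL", "AMP_binding", "PP_bind",
                         "Cond_LCL", "AMP_binding", "PCP")),
       reference = bda("BGC0001873",
                       c("Cond_Starter", "AMP_binding", "PCP",
                         "Cond_DCL", "AMP_binding", "PP_bind", "TE")))
}

random_tokens <- function(n, alphabet = rownames(toy_nrps_matrix())) {
  sample(alphabet, n, replace = TRUE)
}

# Independent alignment oracle: enumerate every monotone set of matched
# index pairs (sorted row subset paired with sorted column subset), score it
# as the sum of pair scores minus gap_cost per unmatched token, and take the
# maximum. No dynamic programming involved.
brute_force_align_score <- function(ta, tb, m, gap_cost = 0) {
  n1 <- length(ta); n2 <- length(tb)
  best <- -gap_cost * (n1 + n2)            # the all-gap alignment
  for (k in seq_len(min(n1, n2))) {
    rows <- combn(n1, k); cols <- combn(n2, k)
    for (i in seq_len(ncol(rows))) for (j in seq_len(ncol(cols))) {
      sc <- sum(m[cbind(ta[rows[, i]], tb[cols[, j]])]) -
        gap_cost * (n1 + n2 - 2 * k)
      if (sc > best) best <- sc
    }
  }
  best
}

# Same enumeration for profile columns with column_score entries.
brute_force_coemission <- function(h1, h2, gap_cost = 0) {
  n1 <- nrow(h1$emissions); n2 <- nrow(h2$emissions)
  cs <- function(i, j) column_score(h1$emissions[i, ], h2$emissions[j, ],
                                    h1$background)
  best <- -gap_cost * (n1 + n2)
  for (k in seq_len(min(n1, n2))) {
    rows <- combn(n1, k); cols <- combn(n2, k)
    for (i in seq_len(ncol(rows))) for (j in seq_len(ncol(cols))) {
      sc <- sum(vapply(seq_len(k), function(q)
        cs(rows[q, i], cols[q, j]), numeric(1))) -
        gap_cost * (n1 + n2 - 2 * k)
      if (sc > best) best <- sc
    }
  }
  max(best, 0)
}

# Independent connected-components oracle (union-find with path
# compression), for checking the greedy clustering.
union_find_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$id_a[k]); rb <- find(edges$id_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# Ten complete candidate records with round 10 kb cluster regions centred on
# 100 kb contigs, used for the transporter scans (all windows full width).
transporter_test_records <- function(n = 10, class = "NRPS") {
  lapply(seq_len(n), function(i) {
    bgc_record(bgc_id = sprintf("%s_bgc%02d", class, i),
               contig_id = sprintf("tctg%02d", i), contig_length = 1e5,
               bgc_class = class, subclass = class,
               region_start = 30000, region_end = 40000,
               contig_edge = FALSE, role = "candidate")
  })
}

# Canonicalize a similarity table: orient each pair lexicographically and
# sort rows, so tables from differently ordered inputs compare equal.
sort_pair_table <- function(tab) {
  swap <- tab$id_a > tab$id_b
  tmp <- tab$id_a[swap]
  tab$id_a[swap] <- tab$id_b[swap]
  tab$id_b[swap] <- tmp
  tab <- tab[order(tab$id_a, tab$id_b), ]
  rownames(tab) <- NULL
  tab
}
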