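point_mass <- function(letter, n = 20) { e <- rep(0, n); e[letter] <- 1; e }
pm_profile <- function(label, letters)
  profile_hmm(label, do.call(rbind, lapply(letters, point_mass)))

test_that("column scores match their closed forms", {
  a <- point_mass(1); b <- point_mass(2)
  expect_equal(column_score(a, a), log(20))
  expect_equal(column_score(a, b), -Inf)
  u <- rep(1 / 20, 20)
  expect_equal(column_score(u, a), 0)
  expect_equal(column_score(u, runif_dist <- {x <- runif(20); x / sum(x)}), 0)
})

test_that("raw co-emission matches closed forms and brute-force enumeration", {
  h <- pm_profile("h", c(1, 2, 3))
  expect_equal(raw_coemission(h, h), 3 * log(20))
  # profiles with no positively scoring column pair floor at 0
  g <- pm_profile("g", c(4, 5))
  expect_equal(raw_coemission(h, g), 0)
  # 2-column vs 3-column sharing 2 columns equals exhaustive enumeration
  p2 <- pm_profile("p2", c(1, 3))
  expect_equal(raw_coemission(h, p2), brute_force_coemission(h, p2))
  expect_equal(raw_coemission(h, p2), 2 * log(20))
  # random soft profiles, with and without gap costs, up to 4 columns
  set.seed(42)
  for (rep in 1:25) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    soft <- function(k) {
      e <- matrix(runif(k * 20), k)
      e / rowSums(e)
    }
    h1 <- profile_hmm("a", soft(n1)); h2 <- profile_hmm("b", soft(n2))
    for (gp in c(0, 0.3))
      expect_equal(raw_coemission(h1, h2, gp),
                   brute_force_coemission(h1, h2, gp), tolerance = 1e-10)
  }
})

test_that("normalized co-emission is 1 on self, 0 on unrelated, exact on half-shared", {
  h <- pm_profile("h", c(1, 2, 3, 4))
  expect_equal(normalized_coemission(h, h), 1)
  g <- pm_profile("g", c(5, 6))
  expect_equal(normalized_coemission(h, g), 0)
  # profiles sharing half their columns: raw12 = 2 log20, selfs 4 and 4
  p <- pm_profile("p", c(1, 2, 7, 8))
  expect_equal(normalized_coemission(h, p),
               (2 * log(20)) / sqrt(4 * log(20) * 4 * log(20)))
  # degenerate profile: uniform columns self-score 0
  u <- profile_hmm("u", matrix(1 / 20, 2, 20))
  expect_error(normalized_coemission(u, h), "degenerate")
})

test_that("normalization is scale-free under column duplication", {
  set.seed(7)
  fam <- generate_phmm_family(c("x", "y"), length = 5, divergence = 0.4,
                              seed = 7, purity = 0.9)
  v1 <- normalized_coemission(fam[[1]], fam[[2]])
  dup <- function(h) profile_hmm(h$label,
                                 h$emissions[rep(seq_len(nrow(h$emissions)),
                                                 each = 2), ])
  v2 <- normalized_coemission(dup(fam[[1]]), dup(fam[[2]]))
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("replacing a shared column with an unrelated one never increases similarity", {
  base_letters <- c(1, 2, 3, 4, 5)
  h1 <- pm_profile("a", base_letters)
  for (pos in 1:5) {
    mod <- base_letters
    mod[pos] <- 10 + pos                      # unrelated letter
    h2 <- pm_profile("b", mod)
    expect_lte(normalized_coemission(h1, h2), normalized_coemission(h1, h1))
    # degrading a second column cannot increase it further
    mod2 <- mod
    mod2[(pos %% 5) + 1] <- 15 + pos
    h3 <- pm_profile("c", mod2)
    expect_lte(normalized_coemission(h1, h3), normalized_coemission(h1, h2))
  }
})

test_that("scoring matrix has block structure, unit diagonal and symmetry", {
  fam1 <- generate_phmm_family(c("A1", "A2"), length = 6, divergence = 0.1,
                               seed = 1, letters = 1:6)
  out <- generate_phmm_family("B1", length = 6, divergence = 0,
                              seed = 2, letters = 11:16)
  m <- build_scoring_matrix(c(fam1, out))
  expect_gt(m["A1", "A2"], 0)
  expect_equal(m["A1", "B1"], -1)
  expect_equal(m["A2", "B1"], -1)
  expect_equal(diag(m), setNames(rep(1, 3), c("A1", "A2", "B1")))
  expect_equal(m, t(m) |> structure(class = class(m)))
  # single profile
  one <- build_scoring_matrix(generate_phmm_family("solo", seed = 3))
  expect_equal(unname(one[1, 1]), 1)
  expect_equal(dim(one), c(1, 1))
  # duplicate labels error
  expect_error(build_scoring_matrix(c(fam1, fam1)), "duplicate")
})

test_that("matrix symmetry and diagonal hold over random profile sets", {
  for (seed in 1:5) {
    hmms <- vocabulary_hmms(seed = seed)[c(1:4, 8:10)]
    m <- build_scoring_matrix(hmms)
    expect_silent(bdalign:::validate_scoring_matrix(m))
  }
})

test_that("a carrier-protein family built from one ancestor is mutually homologous", {
  fam <- generate_phmm_family(c("PCP", "ACP", "PP_bind"), length = 10,
                              divergence = 0.2, seed = 9, letters = 1:4)
  m <- build_scoring_matrix(fam)
  off <- m[row(m) != col(m)]
  expect_true(all(off > 0))
})

test_that("HMMER3 text profiles parse and round-trip", {
  txt <- c(
    "HMMER3/f [toy]",
    "NAME  toy2",
    "LENG  2",
    "ALPH  amino",
    paste(c("HMM", bdalign:::AA_ALPHABET), collapse = "   "),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste(c("      1", sprintf("%.5f", -log(point_mass(1) * 0.9998 + 1e-5))),
          collapse = "  "),
    paste(rep("2.99573", 20), collapse = "  "),
    paste(rep("0.00000", 7), collapse = "  "),
    paste(c("      2", ifelse(point_mass(3) > 0, "0.00000", "*")),
          collapse = "  "),
    paste(rep("2.99573", 20), collapse = "  "),
    paste(rep("0.00000", 7), collapse = "  "),
    "//")
  h <- read_hmmer3(txt)
  expect_equal(h$label, "toy2")
  expect_equal(nrow(h$emissions), 2)
  expect_equal(rowSums(h$emissions), c(1, 1))
  # '*' means emission probability exactly 0
  expect_equal(unname(h$emissions[2, ]), point_mass(3))
  expect_error(read_hmmer3("not a profile"), "HMMER3")

  hmms <- vocabulary_hmms(seed = 4)[1:5]
  path <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hmms, path)
  back <- read_hmmer3(path, all = TRUE)
  expect_length(back, 5)
  for (k in 1:5) {
    expect_equal(back[[k]]$label, hmms[[k]]$label)
    expect_equal(back[[k]]$emissions, hmms[[k]]$emissions, tolerance = 1e-9)
  }
})

test_that("scoring-matrix TSV round-trips at 12 significant digits", {
  m <- build_scoring_matrix(vocabulary_hmms(seed = 6)[1:6])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_equal(rownames(back), rownames(m))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-11)
  # a second write/read cycle is bit-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
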