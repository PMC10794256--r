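# Domain-domain homology scoring from profile-HMM comparison. The score is a
# match-column log-odds co-emission: columns of the two profiles are aligned
# by a monotone DP and each aligned pair contributes
# log( sum_a e1(a) e2(a) / bg(a) ). Self-normalization by the geometric mean
# of the self-scores maps the raw score to (0, 1]; pairs with zero
# co-emission are floored to -1 in the scoring matrix so that non-homologous
# domains are never rewarded during BDA alignment.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a profile HMM (match-state emissions only)
#'
#' @param label Domain symbol.
#' @param emissions Numeric matrix, one row per match column, one column per
#'   alphabet letter; each row must sum to 1 (tolerance 1e-9).
#' @param background Background emission distribution (default uniform).
#' @param alphabet Character vector of letters (default the 20 amino acids).
#' @return Object of class `profile_hmm`.
#' @export
profile_hmm <- function(label, emissions, background = NULL,
                        alphabet = AA_ALPHABET) {
  emissions <- as.matrix(emissions)
  if (nrow(emissions) < 1) stop(label, ": profile needs at least one column")
  if (ncol(emissions) != length(alphabet))
    stop(label, ": emission width does not match alphabet size")
  if (is.null(background)) background <- rep(1 / length(alphabet), length(alphabet))
  if (any(abs(rowSums(emissions) - 1) > 1e-9))
    stop(label, ": emission columns must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop(label, ": background must sum to 1")
  colnames(emissions) <- alphabet
  structure(list(label = as.character(label), emissions = emissions,
                 background = as.numeric(background), alphabet = alphabet),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s: %d match columns over %d letters\n",
              x$label, nrow(x$emissions), length(x$alphabet)))
  invisible(x)
}

#' Log-odds co-emission score of two emission distributions
#'
#' `log( sum_a e1(a) e2(a) / bg(a) )`: positive when the two columns
#' co-emit more than expected under the background, 0 when either column is
#' uninformative (e.g. equal to a uniform background), `-Inf` when they
#' cannot co-emit any letter.
#'
#' @param e1,e2 Emission distributions (numeric vectors summing to 1).
#' @param background Background distribution.
#' @return Scalar score (may be `-Inf`).
#' @export
column_score <- function(e1, e2, background = rep(1 / length(e1), length(e1))) {
  log(sum(e1 * e2 / background))
}

#' Raw co-emission score of two profiles
#'
#' Maximum over monotone column alignments of the summed [column_score()]
#' of aligned column pairs, minus `gap_cost` per unaligned column, floored
#' at 0. Computed by a deterministic dynamic program.
#'
#' @param h1,h2 [profile_hmm()] objects over the same alphabet.
#' @param gap_cost Non-negative cost per unaligned column (default 0).
#' @return Scalar raw score, `>= 0`.
#' @export
raw_coemission <- function(h1, h2, gap_cost = 0) {
  stopifnot(gap_cost >= 0)
  n1 <- nrow(h1$emissions); n2 <- nrow(h2$emissions)
  bg <- h1$background
  # pairwise column scores; -Inf allowed
  cs <- log(tcrossprod(sweep(h1$emissions, 2, bg, "/"), h2$emissions))
  S <- matrix(0, n1 + 1, n2 + 1)
  S[1, ] <- -gap_cost * (0:n2)
  S[, 1] <- -gap_cost * (0:n1)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      S[i + 1, j + 1] <- max(S[i, j] + cs[i, j],
                             S[i, j + 1] - gap_cost,
                             S[i + 1, j] - gap_cost)
    }
  }
  res <- max(S[n1 + 1, n2 + 1], 0)
  if (res < 1e-9) res <- 0     # guard against accumulated rounding noise
  res
}

#' Normalized co-emission similarity of two profiles
#'
#' `raw(h1, h2) / sqrt(raw(h1, h1) * raw(h2, h2))`, clipped to `[0, 1]`.
#' Equals 1 when the profiles are identical and 0 when they share no
#' positively co-emitting columns.
#'
#' @inheritParams raw_coemission
#' @param norm `"geometric"` (default) divides by the geometric mean of the
#'   self-scores; `"max"` divides by the larger self-score.
#' @return Similarity in `[0, 1]`.
#' @export
normalized_coemission <- function(h1, h2, gap_cost = 0,
                                  norm = c("geometric", "max")) {
  norm <- match.arg(norm)
  s11 <- raw_coemission(h1, h1, gap_cost)
  s22 <- raw_coemission(h2, h2, gap_cost)
  if (s11 <= 0) stop("degenerate profile (self-score 0): ", h1$label)
  if (s22 <= 0) stop("degenerate profile (self-score 0): ", h2$label)
  s12 <- raw_coemission(h1, h2, gap_cost)
  denom <- if (norm == "geometric") sqrt(s11 * s22) else max(s11, s22)
  min(max(s12 / denom, 0), 1)
}

#' Build the domain-to-domain scoring matrix from profiles
#'
#' Off-diagonal entries are the normalized co-emission similarity when it
#' exceeds `epsilon`, and -1 otherwise (zero-co-emission pairs are penalized
#' so they are never aligned); the diagonal is exactly 1.
#'
#' @param hmms List of [profile_hmm()] objects with unique labels.
#' @param gap_cost,norm Passed to [normalized_coemission()].
#' @param epsilon Entries `<= epsilon` become -1 (default 0).
#' @return A symmetric numeric matrix with label dimnames, class
#'   `bda_scoring_matrix`.
#' @export
build_scoring_matrix <- function(hmms, gap_cost = 0,
                                 norm = c("geometric", "max"), epsilon = 0) {
  norm <- match.arg(norm)
  labels <- vapply(hmms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate profile labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(labels)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- normalized_coemission(hmms[[i]], hmms[[j]], gap_cost, norm)
      m[i, j] <- m[j, i] <- if (v > epsilon) v else -1
    }
  }
  structure(m, class = c("bda_scoring_matrix", "matrix", "array"))
}

#' Block scoring matrix from homology groups
#'
#' Convenience constructor: every pair of labels inside one group scores
#' `within`, every cross-group pair scores `across`, and the diagonal is 1.
#'
#' @param groups List of character vectors of labels (disjoint).
#' @param within,across Scores for within-group and cross-group pairs.
#' @return A `bda_scoring_matrix`.
#' @examples
#' homology_matrix(list(c("PCP", "ACP"), "TE"))
#' @export
homology_matrix <- function(groups, within = 1, across = -1) {
  labels <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(labels)) stop("labels appear in more than one group")
  grp <- rep(seq_along(groups), lengths(groups))
  m <- ifelse(outer(grp, grp, "=="), within, across)
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("bda_scoring_matrix", "matrix", "array"))
}

validate_scoring_matrix <- function(m) {
  if (is.null(dimnames(m)[[1]]) || nrow(m) != ncol(m))
    stop("scoring matrix must be square with label dimnames")
  if (!isTRUE(all.equal(unname(m), unname(t(m)), tolerance = 1e-9)))
    stop("scoring matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-9))
    stop("scoring matrix diagonal must be exactly 1")
  off <- m[row(m) != col(m)]
  if (any(off != -1 & (off <= 0 | off > 1)))
    stop("off-diagonal entries must lie in {-1} union (0, 1]")
  invisible(m)
}

#' Write / read a scoring matrix as TSV
#'
#' Values are written with 12 significant digits; writing and re-reading
#' reproduces the matrix at that precision.
#'
#' @param m A `bda_scoring_matrix`.
#' @param path TSV path (header row and first column carry the labels).
#' @return `read_matrix()` returns the matrix.
#' @export
write_matrix <- function(m, path) {
  labels <- rownames(m)
  body <- apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = "\t"))
  writeLines(c(paste(c("label", labels), collapse = "\t"),
               paste(labels, body, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(d)
  dimnames(m) <- list(rownames(d), colnames(d))
  m <- structure(m, class = c("bda_scoring_matrix", "matrix", "array"))
  validate_scoring_matrix(m)
  m
}

#' Read a HMMER3 text profile
#'
#' Parses the match-state emission lines of a HMMER3 `.hmm` file into
#' probabilities (stored values are negative natural-log probabilities; `*`
#' means probability 0). The `COMPO` line, when present, supplies the
#' background distribution; insert and transition parameters are parsed past
#' but ignored. Rows are renormalized to sum exactly to 1 (files store 5
#' decimals).
#'
#' @param text Path to a `.hmm` file or a character vector of its lines.
#' @return A [profile_hmm()] (the first profile in the file), or a list of
#'   profiles when `all = TRUE`.
#' @param all Return every profile in the file as a list.
#' @export
read_hmmer3 <- function(text, all = FALSE) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    stop("not a HMMER3 text profile (header line missing)")
  profiles <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^HMMER3", lines[i])) { i <- i + 1; next }
    name <- NULL; alphabet <- NULL; background <- NULL; rows <- list()
    i <- i + 1
    while (i <= length(lines) && !grepl("^//", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (!length(tok)) { i <- i + 1; next }
      if (tok[1] == "NAME") {
        name <- tok[2]
      } else if (tok[1] == "HMM") {
        alphabet <- tok[-1]
        i <- i + 1                                   # transition header line
      } else if (tok[1] == "COMPO") {
        background <- hmmer3_probs(tok[-1], length(alphabet))
        i <- i + 2                                   # insert + begin lines
      } else if (grepl("^[0-9]+$", tok[1]) && !is.null(alphabet)) {
        rows[[length(rows) + 1]] <- hmmer3_probs(tok[1 + seq_along(alphabet)],
                                                 length(alphabet))
        i <- i + 2                                   # insert + transition lines
      }
      i <- i + 1
    }
    if (is.null(alphabet) || !length(rows))
      stop("HMMER3 profile ", if (is.null(name)) "(unnamed)" else name,
           ": no match emission lines found")
    em <- do.call(rbind, rows)
    em <- em / rowSums(em)
    if (!is.null(background)) background <- background / sum(background)
    profiles[[length(profiles) + 1]] <-
      profile_hmm(if (is.null(name)) "profile" else name, em,
                  background = background, alphabet = alphabet)
    i <- i + 1
  }
  if (!length(profiles)) stop("no profiles found")
  if (all) profiles else profiles[[1]]
}

hmmer3_probs <- function(fields, n) {
  fields <- fields[seq_len(n)]
  p <- ifelse(fields == "*", 0, exp(-suppressWarnings(as.numeric(fields))))
  if (any(is.na(p))) stop("malformed HMMER3 emission line")
  p
}
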