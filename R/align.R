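# Exact global alignment of domain-label sequences (BDAs) under a custom
# scoring matrix with zero gap penalties. With gap cost 0 the DP never gains
# from pairing two domains whose matrix entry is negative, so the default
# traceback produces no "misaligned" (-1) columns; similarity is M/N over
# the reported traceback.

#' Globally align two BDAs
#'
#' Needleman-Wunsch on domain tokens with linear gap cost 0 (end gaps free
#' by construction). Ties in the traceback are broken deterministically:
#' prefer the diagonal when the pair score is positive, otherwise prefer the
#' up gap, then the left gap — this maximizes the number of matched columns
#' without ever admitting a negatively scoring pair.
#'
#' @param a,b [bda()] objects (or character vectors of tokens).
#' @param m Scoring matrix (labels x labels; see [build_scoring_matrix()] or
#'   [homology_matrix()]).
#' @param gap_cost Linear gap cost (default 0, the intended model).
#' @param unknown Policy for tokens absent from the matrix: `"error"`
#'   (default) or `"mismatch"` (treated as scoring -1 against everything,
#'   including themselves).
#' @return Object of class `bda_alignment` with elements `pairs` (two-column
#'   matrix of token indices, `NA` for gaps), `rows` (two gapped token
#'   vectors), `score`, `N`, `M`, `misaligned`, `similarity`.
#' @examples
#' m <- homology_matrix(list(c("C", "Cs"), "A", c("PCP", "PP")))
#' align_pair(c("C", "A", "PCP"), c("Cs", "A", "PP"), m)$similarity
#' @export
align_pair <- function(a, b, m, gap_cost = 0,
                       unknown = c("error", "mismatch")) {
  unknown <- match.arg(unknown)
  a <- as_bda(a, "a"); b <- as_bda(b, "b")
  ta <- a$tokens; tb <- b$tokens
  if (!length(ta) || !length(tb)) stop("cannot align an empty BDA")
  labels <- rownames(m)
  score_of <- function(x, y) {
    if (x %in% labels && y %in% labels) return(m[x, y])
    if (unknown == "error") {
      bad <- setdiff(c(x, y), labels)
      stop("token(s) not in scoring matrix: ", paste(bad, collapse = ", "))
    }
    -1
  }
  n1 <- length(ta); n2 <- length(tb)
  s <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    s[i, j] <- score_of(ta[i], tb[j])

  S <- matrix(0, n1 + 1, n2 + 1)
  S[1, ] <- -gap_cost * (0:n2)
  S[, 1] <- -gap_cost * (0:n1)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    S[i + 1, j + 1] <- max(S[i, j] + s[i, j],
                           S[i, j + 1] - gap_cost,
                           S[i + 1, j] - gap_cost)

  tol <- 1e-9
  i <- n1; j <- n2
  pairs <- matrix(NA_integer_, 0, 2)
  while (i > 0 || j > 0) {
    cur <- S[i + 1, j + 1]
    if (i > 0 && j > 0 && s[i, j] > 0 &&
        abs(S[i, j] + s[i, j] - cur) < tol) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    } else if (i > 0 && abs(S[i, j + 1] - gap_cost - cur) < tol) {
      pairs <- rbind(c(i, NA), pairs); i <- i - 1
    } else if (j > 0 && abs(S[i + 1, j] - gap_cost - cur) < tol) {
      pairs <- rbind(c(NA, j), pairs); j <- j - 1
    } else {                                  # diagonal is the only optimum
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    }
  }
  matched <- !is.na(pairs[, 1]) & !is.na(pairs[, 2])
  N <- nrow(pairs)
  M <- sum(matched)
  mis <- sum(matched & apply(pairs, 1, function(p)
    if (!anyNA(p)) score_of(ta[p[1]], tb[p[2]]) == -1 else FALSE))
  rows <- list(ifelse(is.na(pairs[, 1]), "-", ta[pairs[, 1]]),
               ifelse(is.na(pairs[, 2]), "-", tb[pairs[, 2]]))
  structure(list(id_a = a$bgc_id, id_b = b$bgc_id, pairs = pairs,
                 rows = rows, score = S[n1 + 1, n2 + 1], N = N, M = M,
                 misaligned = mis, similarity = M / N),
            class = "bda_alignment")
}

#' @export
print.bda_alignment <- function(x, ...) {
  cat(sprintf("<bda_alignment> %s vs %s: M=%d N=%d similarity=%.3f score=%.3f\n",
              x$id_a, x$id_b, x$M, x$N, x$similarity, x$score))
  cat(" ", paste(x$rows[[1]], collapse = " "), "\n")
  cat(" ", paste(x$rows[[2]], collapse = " "), "\n")
  invisible(x)
}

#' Count misaligned columns of an alignment
#'
#' A misaligned column pairs two domains whose scoring-matrix entry is -1
#' (zero co-emission probability).
#'
#' @param alignment A `bda_alignment` from [align_pair()].
#' @param m The scoring matrix the alignment was computed with.
#' @return List with `count` and `rate` (count / M; 0 when M = 0).
#' @export
count_misaligned <- function(alignment, m) {
  p <- alignment$pairs
  matched <- !is.na(p[, 1]) & !is.na(p[, 2])
  ra <- alignment$rows[[1]]; rb <- alignment$rows[[2]]
  labels <- rownames(m)
  cnt <- sum(vapply(which(matched), function(k) {
    if (ra[k] %in% labels && rb[k] %in% labels) m[ra[k], rb[k]] == -1
    else TRUE                            # unknown tokens score -1 by policy
  }, logical(1)))
  M <- sum(matched)
  list(count = cnt, rate = if (M > 0) cnt / M else 0)
}

#' Pairwise BDA similarity table
#'
#' Aligns every unordered candidate pair and every candidate-reference pair
#' (reference-reference pairs are not compared, matching how candidates are
#' prioritized against a fixed reference panel). Callers should pass
#' class-homogeneous input.
#'
#' @param bdas List of candidate [bda()] objects.
#' @param m Scoring matrix.
#' @param refs Optional list of reference [bda()] objects.
#' @param ... Passed to [align_pair()].
#' @return `data.frame` with columns `id_a`, `id_b`, `similarity`, `M`, `N`,
#'   `misaligned`.
#' @export
all_pairs <- function(bdas, m, refs = NULL, ...) {
  ids <- vapply(bdas, `[[`, character(1), "bgc_id")
  names(bdas) <- ids
  rows <- list()
  add <- function(x, y) {
    al <- align_pair(x, y, m, ...)
    rows[[length(rows) + 1]] <<- data.frame(
      id_a = al$id_a, id_b = al$id_b, similarity = al$similarity,
      M = al$M, N = al$N, misaligned = al$misaligned,
      stringsAsFactors = FALSE)
  }
  n <- length(bdas)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) add(bdas[[i]], bdas[[j]])
  for (r in refs) for (b in bdas) add(b, r)
  if (!length(rows)) return(data.frame(
    id_a = character(), id_b = character(), similarity = numeric(),
    M = integer(), N = integer(), misaligned = integer(),
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Progressive multiple alignment of a BDA cluster
#'
#' Re-aligns the members of a cluster for visualization: sequences join a
#' growing profile in order of decreasing pairwise similarity to a member
#' already in the profile, each addition using the same zero-gap-cost DP
#' with column scores taken as the maximum over the profile column's tokens.
#' Removing gaps from any output row recovers the corresponding input BDA.
#'
#' @param bdas List of two or more [bda()] objects.
#' @param m Scoring matrix.
#' @return Named list of gapped token vectors, all of equal length.
#' @export
align_cluster <- function(bdas, m) {
  if (length(bdas) < 2) stop("align_cluster needs at least two BDAs")
  ids <- vapply(bdas, `[[`, character(1), "bgc_id")
  names(bdas) <- ids
  sim <- all_pairs(bdas, m)
  # order of inclusion: best pair first, then nearest neighbour to the set
  ord <- order(-sim$similarity, sim$id_a, sim$id_b)
  sim <- sim[ord, ]
  included <- c(sim$id_a[1], sim$id_b[1])
  while (length(included) < length(bdas)) {
    cand <- sim[xor(sim$id_a %in% included, sim$id_b %in% included), ]
    nxt <- cand[1, ]
    included <- c(included,
                  if (nxt$id_a %in% included) nxt$id_b else nxt$id_a)
  }
  # profile: matrix rows = aligned members, entries are tokens or "-"
  prof <- matrix(bdas[[included[1]]]$tokens, nrow = 1,
                 dimnames = list(included[1], NULL))
  for (id in included[-1]) prof <- profile_add(prof, bdas[[id]], m)
  prof <- prof[ids, , drop = FALSE]
  setNames(lapply(seq_len(nrow(prof)), function(i) unname(prof[i, ])),
           rownames(prof))
}

profile_add <- function(prof, b, m) {
  tb <- b$tokens
  np <- ncol(prof); nb <- length(tb)
  labels <- rownames(m)
  colscore <- function(j, t) {
    toks <- setdiff(prof[, j], "-")
    max(vapply(toks, function(u)
      if (u %in% labels && t %in% labels) m[u, t] else -1, numeric(1)))
  }
  s <- matrix(0, np, nb)
  for (i in seq_len(np)) for (j in seq_len(nb)) s[i, j] <- colscore(i, tb[j])
  S <- matrix(0, np + 1, nb + 1)
  for (i in seq_len(np)) for (j in seq_len(nb))
    S[i + 1, j + 1] <- max(S[i, j] + s[i, j], S[i, j + 1], S[i + 1, j])
  tol <- 1e-9
  i <- np; j <- nb
  newprof <- matrix(character(0), nrow = nrow(prof), ncol = 0)
  newrow <- character(0)
  while (i > 0 || j > 0) {
    cur <- S[i + 1, j + 1]
    if (i > 0 && j > 0 && s[i, j] > 0 && abs(S[i, j] + s[i, j] - cur) < tol) {
      newprof <- cbind(prof[, i], newprof); newrow <- c(tb[j], newrow)
      i <- i - 1; j <- j - 1
    } else if (i > 0 && abs(S[i, j + 1] - cur) < tol) {
      newprof <- cbind(prof[, i], newprof); newrow <- c("-", newrow)
      i <- i - 1
    } else if (j > 0 && abs(S[i + 1, j] - cur) < tol) {
      newprof <- cbind(rep("-", nrow(prof)), newprof)
      newrow <- c(tb[j], newrow)
      j <- j - 1
    } else {
      newprof <- cbind(prof[, i], newprof); newrow <- c(tb[j], newrow)
      i <- i - 1; j <- j - 1
    }
  }
  out <- rbind(newprof, newrow)
  rownames(out) <- c(rownames(prof), b$bgc_id)
  out
}
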