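#' SAM-style moderated difference statistic
#'
#' Per-gene `d = (mean_case - mean_control) / (s + s0)` with `s` the pooled
#' standard error `sqrt((1/n1 + 1/n0) * pooled within-class variance)` and
#' `s0` the exchangeability (fudge) constant damping the statistics of
#' low-variance genes. `s0 = "auto"` uses the median of the per-gene `s`.
#' With `s0 = 0` the statistic is the ordinary pooled-variance t.
#'
#' @param matrix features x samples matrix.
#' @param labels binary labels (cases = 1).
#' @param s0 non-negative constant or `"auto"`.
#' @return list with `d` (named numeric), `s`, and the `s0` used.
#' @export
samStatistic <- function(matrix, labels, s0 = "auto") {
  y <- as_binary01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2)
    stop("each class needs >= 2 samples for a within-class variance")
  m1 <- rowMeans(matrix[, y == 1, drop = FALSE])
  m0 <- rowMeans(matrix[, y == 0, drop = FALSE])
  ss <- rowSums((matrix[, y == 1, drop = FALSE] - m1)^2) +
        rowSums((matrix[, y == 0, drop = FALSE] - m0)^2)
  s <- sqrt((1 / n1 + 1 / n0) * ss / (n1 + n0 - 2))
  if (identical(s0, "auto")) s0 <- stats::median(s)
  d <- (m1 - m0) / (s + s0)
  list(d = d, s = s, s0 = s0)
}

#' Permutation false-discovery rates for SAM statistics
#'
#' For each candidate threshold t (the observed |d| values), the FDR is the
#' median permuted count of `|d_perm| >= t` divided by the observed count;
#' a gene's q-value is the minimum FDR over the thresholds it passes
#' (`t <= |d|`), so q is non-increasing in |d|. Label permutations keep the
#' fudge constant fixed at its observed value; when the number of distinct
#' case assignments is at most `nPermutations` they are enumerated
#' exhaustively (flagged in the output).
#'
#' @param matrix features x samples matrix.
#' @param labels binary labels.
#' @param nPermutations permutations requested.
#' @param s0 passed to [samStatistic()].
#' @param seed RNG seed for sampled permutations.
#' @return list with `q` (named, `[0,1]`), `d`, `s0`, `exhaustive`, and the
#'   permutation count used.
#' @export
samPermutationFdr <- function(matrix, labels, nPermutations = 200,
                              s0 = "auto", seed = 1) {
  stopifnot(nPermutations >= 1)
  y <- as_binary01(labels)
  n <- length(y); n1 <- sum(y == 1)
  obs <- samStatistic(matrix, y, s0)
  s0v <- obs$s0
  absd <- abs(obs$d)

  nDistinct <- choose(n, n1)
  exhaustive <- is.finite(nDistinct) && nDistinct <= nPermutations
  perms <- if (exhaustive) {
    cmb <- utils::combn(n, n1)
    lapply(seq_len(ncol(cmb)), function(j) {
      p <- integer(n); p[cmb[, j]] <- 1L; p
    })
  } else {
    set.seed(seed)
    lapply(seq_len(nPermutations), function(i) sample(y))
  }

  thr <- sort(unique(absd))
  obsCount <- vapply(thr, function(t) sum(absd >= t), integer(1))
  permCounts <- vapply(perms, function(p) {
    pd <- abs(samStatistic(matrix, p, s0v)$d)
    vapply(thr, function(t) sum(pd >= t), integer(1))
  }, integer(length(thr)))
  if (length(thr) == 1) permCounts <- matrix(permCounts, nrow = 1)
  medPerm <- apply(permCounts, 1, stats::median)
  fdr <- pmin(medPerm / pmax(obsCount, 1), 1)
  ## min FDR over the thresholds a gene passes (t <= |d|)
  q <- cummin(fdr)[findInterval(absd, thr)]
  names(q) <- names(obs$d)
  list(q = q, d = obs$d, s0 = s0v, exhaustive = exhaustive,
       nPermutations = length(perms))
}

#' Rank-rank hypergeometric overlap map
#'
#' Threshold-free concordance between two ranked gene lists over the same
#' universe: for every pair of list-head sizes (i, j) on a step grid, the
#' overlap k of the top-i of A with the top-j of B is scored by the
#' hypergeometric tail, `-log10 P(X >= k)` for over-enrichment and
#' `+log10 P(X <= k)` (a negative value) for depletion. Reverse both lists
#' to examine the tail-tail (concordant-down) corner.
#'
#' @param listA,listB character vectors: the same gene universe ranked by a
#'   signed score, strongest first; no duplicates.
#' @param step grid step (default `ceiling(N/100)`).
#' @return list of class `RRHOMap`: `logp` (signed matrix), `thresholds`,
#'   `step`, `N`, and the input lists.
#' @export
rrhoMap <- function(listA, listB, step = NULL) {
  if (anyDuplicated(listA) || anyDuplicated(listB))
    stop("ranked lists must not contain duplicates")
  if (!setequal(listA, listB) || length(listA) != length(listB))
    stop("lists must rank the same gene universe")
  N <- length(listA)
  if (is.null(step)) step <- ceiling(N / 100)
  nthr <- ceiling(N / step)
  thr <- pmin(seq_len(nthr) * step, N)

  rA <- match(listA, listA)            # 1..N
  rB <- match(listA, listB)
  ## 2D histogram of (grid cell of rank A, grid cell of rank B), then
  ## cumulative sums give overlap(top-i, top-j)
  cellA <- findInterval(rA, thr + 1L) + 1L
  cellB <- findInterval(rB, thr + 1L) + 1L
  H <- matrix(0L, nthr, nthr)
  for (g in seq_len(N)) H[cellA[g], cellB[g]] <- H[cellA[g], cellB[g]] + 1L
  ov <- apply(apply(H, 2, cumsum), 1, cumsum)  # transposed double-cumsum
  ov <- t(ov)

  logp <- matrix(0, nthr, nthr,
                 dimnames = list(paste0("A", thr), paste0("B", thr)))
  for (a in seq_len(nthr)) {
    i <- thr[a]
    for (b in seq_len(nthr)) {
      j <- thr[b]
      k <- ov[a, b]
      expct <- i * j / N
      if (k >= expct) {
        p <- stats::phyper(k - 1, i, N - i, j, lower.tail = FALSE)
        logp[a, b] <- -log10(max(p, .Machine$double.xmin))
      } else {
        p <- stats::phyper(k, i, N - i, j)
        logp[a, b] <- log10(max(p, .Machine$double.xmin))
      }
    }
  }
  structure(list(logp = logp, thresholds = thr, step = step, N = N,
                 listA = listA, listB = listB),
            class = "RRHOMap")
}

#' @export
print.RRHOMap <- function(x, ...) {
  cat("RRHOMap:", x$N, "genes, step", x$step, "->", nrow(x$logp), "x",
      ncol(x$logp), "grid; max -log10 p =", round(max(x$logp), 2), "\n")
  invisible(x)
}

#' Most significant concordant enrichment zone of an RRHO map
#'
#' Returns the intersection gene set at the most over-enriched cell of the
#' head-head corner (both thresholds at most half the universe, where
#' concordant top-ranked signal lives), with its coordinates and p-value.
#' When no corner cell is over-enriched the zone is empty.
#'
#' @param map an `RRHOMap`.
#' @return list with `genes`, `i`, `j`, `logp`.
#' @export
rrhoEnrichmentZone <- function(map) {
  corner <- map$thresholds <= ceiling(map$N / 2)
  sub <- map$logp[corner, corner, drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)
  ## earliest (most head-ward) cell among ties
  best <- best[order(best[, 1] + best[, 2], best[, 1]), , drop = FALSE][1, ]
  val <- sub[best[1], best[2]]
  if (val <= 0)
    return(list(genes = character(), i = NA_integer_, j = NA_integer_,
                logp = val))
  i <- map$thresholds[best[1]]; j <- map$thresholds[best[2]]
  list(genes = intersect(utils::head(map$listA, i),
                         utils::head(map$listB, j)),
       i = i, j = j, logp = val)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a query
#' list against an expressed-gene background, by the exact hypergeometric
#' upper tail `P(X >= overlap)`; Benjamini-Hochberg correction is applied
#' across the collection. Sets are intersected with the background before
#' testing and the query must be contained in the background.
#'
#' @param query character vector of genes of interest.
#' @param collection named list of gene sets.
#' @param background character vector, the expressed-gene universe.
#' @return data.frame: set, overlap, set_size, query_size, background_size,
#'   p, q.
#' @export
oraHypergeometric <- function(query, collection, background) {
  query <- unique(query); background <- unique(background)
  if (length(setdiff(query, background)))
    stop("query contains genes outside the background universe")
  N <- length(background)
  K <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), background)
    ov <- length(intersect(set, query))
    p <- stats::phyper(ov - 1, length(set), N - length(set), K,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               query_size = K, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
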