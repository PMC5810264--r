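# Cluster-based permutation test (CBPT) over channels x time.
#
# The test exploits the spatio-temporal correlation of real EEG effects:
# sample-level paired t-statistics are thresholded, suprathreshold points of
# equal sign are clustered over sensor adjacency and +/-1-sample temporal
# adjacency, each cluster's mass is the sum of its t-values, and observed
# masses are referred to the permutation distribution of the maximum
# absolute cluster mass obtained by flipping condition labels within
# participants. One Monte-Carlo test for the whole channel x time space
# controls the family-wise error rate while retaining sensitivity.

#' CBPT configuration
#'
#' @param alpha Significance level for the cluster decision (default 0.05:
#'   clusters beyond the 95th percentile of the max-statistic null).
#' @param cluster_forming_p Two-tailed p threshold forming clusters from the
#'   sample-level t map (default 0.05).
#' @param n_permutations Number of random label permutations (default 1000).
#'   If `n_permutations >= 2^n_participants` the test falls back to exact
#'   full enumeration of all sign patterns.
#' @param seed RNG seed for the permutation draw (`NULL` = leave RNG alone).
#' @return A list of class `cbpt_config`.
#' @export
cbpt_config <- function(alpha = 0.05, cluster_forming_p = 0.05,
                        n_permutations = 1000, seed = NULL) {
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  stopifnot_scalar_number(cluster_forming_p, "cluster_forming_p")
  if (cluster_forming_p <= 0 || cluster_forming_p >= 1)
    abort("`cluster_forming_p` must be in (0, 1).")
  stopifnot_scalar_number(n_permutations, "n_permutations", positive = TRUE)
  structure(list(alpha = alpha, cluster_forming_p = cluster_forming_p,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "cbpt_config")
}

#' Channel adjacency from sensor positions
#'
#' Channels are neighbors iff their Euclidean distance is positive and at
#' most `max_dist` (same units as the montage coordinates). Only scalp
#' channels are considered.
#'
#' @param layout A [read_montage()] layout.
#' @param max_dist Neighbor distance threshold (> 0).
#' @return Object of class `adjacency`: symmetric logical channel x channel
#'   matrix with zero diagonal, attribute `max_dist`. Scalp channels without
#'   any neighbor trigger a warning (the test still runs; such channels can
#'   only form single-channel clusters).
#' @export
build_adjacency <- function(layout, max_dist) {
  stopifnot_scalar_number(max_dist, "max_dist", positive = TRUE)
  scalp <- layout[layout$type == "scalp", , drop = FALSE]
  pos <- as.matrix(scalp[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(pos))
  A <- D > 0 & D <= max_dist
  diag(A) <- FALSE
  dimnames(A) <- list(scalp$label, scalp$label)
  lonely <- scalp$label[rowSums(A) == 0]
  if (length(lonely) > 0)
    warn(sprintf("channel(s) without neighbors at max_dist = %g: %s",
                 max_dist, paste(lonely, collapse = ", ")))
  structure(A, class = c("adjacency", "matrix"), max_dist = max_dist)
}

#' Paired t map over channels and samples
#'
#' Computes, at every (channel, sample) point, the paired t statistic of the
#' per-participant difference `avgA - avgB`, plus the two-tailed critical
#' value at `cluster_forming_p` with `n - 1` degrees of freedom.
#'
#' Points with zero variance across participants get `t = +/-Inf` carrying
#' the sign of the mean difference (suprathreshold by construction) or 0 if
#' the mean difference is also zero; this only arises in degenerate
#' synthetic data.
#'
#' @param avgA,avgB 3-D arrays participants x channels x samples (matched
#'   shapes, >= 3 participants).
#' @param cluster_forming_p Two-tailed threshold p.
#' @return List with `t` (channels x samples matrix), `t_crit`, `df`.
#' @export
paired_tmap <- function(avgA, avgB, cluster_forming_p = 0.05) {
  if (!identical(dim(avgA), dim(avgB)))
    abort("avgA and avgB must have identical dimensions.")
  n <- dim(avgA)[1]
  if (n < 3) abort("paired t map needs at least 3 participants (df >= 2).")
  D <- avgA - avgB
  Dm <- matrix(D, nrow = n)                 # participants x (ch*sample)
  m <- colMeans(Dm)
  s <- sqrt(pmax(colSums(Dm^2) - n * m^2, 0) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)),
              ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)))
  tmap <- matrix(t, nrow = dim(avgA)[2], ncol = dim(avgA)[3],
                 dimnames = list(dimnames(avgA)[[2]], NULL))
  list(t = tmap, t_crit = qt(1 - cluster_forming_p / 2, df = n - 1), df = n - 1)
}

#' Form same-sign spatio-temporal clusters from a thresholded t map
#'
#' Connected components of the suprathreshold set (`|t| > t_crit`), where
#' two points are connected iff they carry t values of the same sign and are
#' either the same channel at consecutive samples or adjacent channels at
#' the same sample. Cluster mass is the sum of member t values.
#'
#' @param t_map Channels x samples t matrix (rownames = channel labels).
#' @param t_crit Cluster-forming threshold (absolute t).
#' @param adjacency An [build_adjacency()] matrix covering the t map's
#'   channels.
#' @return List of clusters, each a list with `members` (two-column matrix
#'   `channel`, `sample` of integer indices), `sign` (+1/-1), `mass`.
#'   Empty list if nothing is suprathreshold.
#' @export
form_clusters <- function(t_map, t_crit, adjacency) {
  ch_labels <- rownames(t_map)
  adj_idx <- match(ch_labels, rownames(adjacency))
  if (anyNA(adj_idx))
    abort(sprintf("adjacency lacks channel(s): %s",
                  paste(ch_labels[is.na(adj_idx)], collapse = ", ")))
  A <- unclass(adjacency)[adj_idx, adj_idx, drop = FALSE]
  neighbors <- lapply(seq_len(nrow(A)), function(i) which(A[i, ]))

  supra <- which(abs(t_map) > t_crit, arr.ind = TRUE)
  if (nrow(supra) == 0L) return(list())
  n_ch <- nrow(t_map)
  keys <- (supra[, 2] - 1L) * n_ch + supra[, 1]   # linear index into t_map
  lookup <- new.env(hash = TRUE, size = length(keys))
  for (k in seq_along(keys)) assign(as.character(keys[k]), k, envir = lookup)
  sgn <- sign(t_map[keys])

  visited <- logical(length(keys))
  clusters <- list()
  for (start in seq_along(keys)) {
    if (visited[start]) next
    stack <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(stack) > 0) {
      k <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, k)
      ch <- supra[k, 1]; sm <- supra[k, 2]
      cand_keys <- c(
        if (sm > 1) (sm - 2L) * n_ch + ch,                 # t - 1
        if (sm < ncol(t_map)) sm * n_ch + ch,              # t + 1
        (sm - 1L) * n_ch + neighbors[[ch]])                # spatial neighbors
      for (ck in cand_keys) {
        j <- lookup[[as.character(ck)]]
        if (!is.null(j) && !visited[j] && sgn[j] == sgn[start]) {
          visited[j] <- TRUE
          stack <- c(stack, j)
        }
      }
    }
    tvals <- t_map[keys[members]]
    mass <- sum(tvals[is.finite(tvals)]) +
      sum(sign(tvals[!is.finite(tvals)])) * 0  # infinite members contribute
    if (any(!is.finite(tvals))) mass <- sign(sgn[start]) * Inf
    clusters[[length(clusters) + 1L]] <- list(
      members = cbind(channel = supra[members, 1], sample = supra[members, 2]),
      sign = as.integer(sgn[start]),
      mass = mass)
  }
  clusters
}

# t maps for a batch of sign-flip permutations, computed jointly:
# squares are flip-invariant, so only the means depend on the signs.
perm_tmaps <- function(Dm, S) {
  n <- ncol(S)
  M <- S %*% Dm / n                                   # perms x points
  ss <- matrix(colSums(Dm^2), nrow = nrow(S), ncol = ncol(Dm), byrow = TRUE)
  V <- pmax(ss - n * M^2, 0) / (n - 1)
  T <- M / sqrt(V / n)
  T[V == 0] <- sign(M[V == 0]) * Inf
  T[V == 0 & M == 0] <- 0
  T
}

max_cluster_mass <- function(t_map, t_crit, adjacency) {
  cl <- form_clusters(t_map, t_crit, adjacency)
  if (length(cl) == 0L) return(0)
  max(vapply(cl, function(x) abs(x$mass), numeric(1)))
}

#' Permutation null distribution of the maximum cluster mass
#'
#' For a paired design, flipping the A/B labels of a participant is
#' equivalent to flipping the sign of that participant's difference wave.
#' Each permutation draws independent +/-1 signs per participant, recomputes
#' the t map and its clusters, and records the maximum absolute cluster
#' mass (0 when no cluster forms). If `n_permutations >= 2^n` all sign
#' patterns are enumerated instead (exact test).
#'
#' @param avgA,avgB 3-D arrays participants x channels x samples.
#' @param config A [cbpt_config()].
#' @param adjacency An [build_adjacency()] matrix.
#' @return Numeric vector of max-|mass| values; attribute `exhaustive`
#'   is `TRUE` when all `2^n` sign patterns were enumerated.
#' @export
permutation_null <- function(avgA, avgB, config, adjacency) {
  stopifnot(inherits(config, "cbpt_config"))
  n <- dim(avgA)[1]
  D <- avgA - avgB
  Dm <- matrix(D, nrow = n)
  exhaustive <- n <= 25 && config$n_permutations >= 2^n
  S <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
  } else {
    with_seed(config$seed,
              matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
                     ncol = n))
  }
  T <- perm_tmaps(Dm, S)
  t_crit <- qt(1 - config$cluster_forming_p / 2, df = n - 1)
  null <- vapply(seq_len(nrow(S)), function(i) {
    tm <- matrix(T[i, ], nrow = dim(avgA)[2],
                 dimnames = list(dimnames(avgA)[[2]], NULL))
    max_cluster_mass(tm, t_crit, adjacency)
  }, numeric(1))
  attr(null, "exhaustive") <- exhaustive
  null
}

#' Cluster-based permutation test for a paired two-condition comparison
#'
#' Runs the full test: paired t map, sign-separated spatio-temporal
#' clustering, max-statistic permutation null, and the Monte-Carlo p value
#' `p = (1 + #{null >= |mass|}) / (n_permutations + 1)` per cluster (plain
#' proportion under exact enumeration). A cluster is significant iff
#' `p <= alpha`.
#'
#' @param avgA,avgB 3-D arrays participants x channels x samples (e.g. from
#'   [cond_avg()]); channel dimnames required and must be covered by the
#'   layout.
#' @param layout A [read_montage()] layout.
#' @param config A [cbpt_config()].
#' @param max_dist Neighbor distance threshold passed to
#'   [build_adjacency()].
#' @param time_ms Optional per-sample times (ms) used to report cluster
#'   extents; defaults to sample indices.
#' @return Object of class `cbpt_result`: a tibble with one row per cluster
#'   (sorted by |mass| descending): `cluster`, `sign`, `mass`, `n_members`,
#'   `p_mc`, `significant`, `t_start_ms`/`t_end_ms`, `channels`
#'   (list-column), `members` (list-column of index matrices). Attributes:
#'   `null` (permutation distribution), `t_map`, `t_crit`, `mask` (logical
#'   channels x samples significance mask), `time_ms`, `config`.
#' @export
cbpt_test <- function(avgA, avgB, layout, config = cbpt_config(),
                      max_dist = 0.06, time_ms = NULL) {
  adjacency <- build_adjacency(layout, max_dist)
  tm <- paired_tmap(avgA, avgB, config$cluster_forming_p)
  clusters <- form_clusters(tm$t, tm$t_crit, adjacency)
  null <- permutation_null(avgA, avgB, config, adjacency)
  exhaustive <- isTRUE(attr(null, "exhaustive"))

  n_ch <- nrow(tm$t); n_samp <- ncol(tm$t)
  ch_labels <- rownames(tm$t)
  if (is.null(time_ms)) time_ms <- seq_len(n_samp)

  rows <- purrr::map(clusters, function(cl) {
    p_mc <- if (exhaustive) mean(null >= abs(cl$mass))
    else (1 + sum(null >= abs(cl$mass))) / (length(null) + 1)
    smp <- cl$members[, "sample"]
    tibble(sign = cl$sign, mass = cl$mass, n_members = nrow(cl$members),
           p_mc = p_mc, significant = p_mc <= config$alpha,
           t_start_ms = min(time_ms[smp]), t_end_ms = max(time_ms[smp]),
           channels = list(sort(unique(ch_labels[cl$members[, "channel"]]))),
           members = list(cl$members))
  })
  res <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(sign = integer(), mass = numeric(), n_members = integer(),
           p_mc = numeric(), significant = logical(),
           t_start_ms = numeric(), t_end_ms = numeric(),
           channels = list(), members = list())
  res <- res[order(-abs(res$mass)), , drop = FALSE]
  res <- dplyr::bind_cols(tibble(cluster = seq_len(nrow(res))), res)

  mask <- matrix(FALSE, n_ch, n_samp, dimnames = list(ch_labels, NULL))
  for (i in seq_len(nrow(res))) {
    if (res$significant[i]) mask[res$members[[i]]] <- TRUE
  }
  structure(res, class = c("cbpt_result", class(res)),
            null = null, t_map = tm$t, t_crit = tm$t_crit, mask = mask,
            time_ms = time_ms, config = config, exhaustive = exhaustive)
}

#' @export
print.cbpt_result <- function(x, ...) {
  cat(sprintf("<cbpt_result> %d cluster(s), %d significant at alpha = %g (%s null, %d draws)\n",
              nrow(x), sum(x$significant), attr(x, "config")$alpha,
              if (isTRUE(attr(x, "exhaustive"))) "exhaustive" else "Monte-Carlo",
              length(attr(x, "null"))))
  if (nrow(x) > 0)
    print(as_tibble(x)[, c("cluster", "sign", "mass", "n_members", "p_mc",
                           "significant", "t_start_ms", "t_end_ms")])
  invisible(x)
}

#' Write a cluster table to CSV
#'
#' Flat export of a [cbpt_test()] result: one row per cluster with sign,
#' mass, Monte-Carlo p, time range and a semicolon-joined channel list.
#'
#' @param x A `cbpt_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  stopifnot(inherits(x, "cbpt_result"))
  flat <- as_tibble(x)[, c("cluster", "sign", "mass", "n_members", "p_mc",
                           "significant", "t_start_ms", "t_end_ms")]
  flat$channels <- vapply(x$channels, paste, character(1), collapse = ";")
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
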