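# Shared fixtures and independent oracles, built in code.

roi_n2 <- c("FC1", "FC2", "C1", "Cz", "C2")
roi_p3 <- c("CP3", "CP1", "CPz", "CP2", "CP4", "P3", "Pz", "P4",
            "PO3", "POz", "PO4")
desk_channels <- union(roi_n2, roi_p3)

pkg_layout <- read_montage(default_montage_path())

# A minimal layout tibble from explicit coordinates.
make_layout <- function(labels, pos, type = "scalp") {
  tibble::tibble(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 type = type)
}

# Hand-made trial store with known contents.
make_store <- function(amplitudes, meta, time_ms = NULL, fs = 500) {
  d <- dim(amplitudes)
  if (is.null(time_ms)) time_ms <- (seq_len(d[2]) - 1) * 1000 / fs
  labels <- paste0("ch", seq_len(d[1]))
  trial_store(amplitudes, time_ms, labels, meta, sampling_rate = fs)
}

random_store <- function(n_ch = 3, n_samp = 12, n_trials = 20,
                         n_participants = 2, seed = 1) {
  set.seed(seed)
  meta <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", seq_len(n_participants)),
                         each = n_trials / n_participants),
    trial_index = rep(seq_len(n_trials / n_participants), n_participants),
    condition = factor(sample(c("a", "b"), n_trials, replace = TRUE),
                       c("a", "b")),
    rt_ms = runif(n_trials, 300, 900))
  make_store(array(rnorm(n_ch * n_samp * n_trials), c(n_ch, n_samp, n_trials)),
             meta)
}

# Independent connected-components oracle: iterative label propagation over
# an explicit edge list (a different algorithm from the package's stack
# flood fill).
bfs_cluster_oracle <- function(t_map, t_crit, adjacency) {
  supra <- which(abs(t_map) > t_crit, arr.ind = TRUE)
  n <- nrow(supra)
  if (n == 0) return(list())
  A <- unclass(adjacency)[match(rownames(t_map), rownames(adjacency)),
                          match(rownames(t_map), rownames(adjacency)),
                          drop = FALSE]
  sgn <- sign(t_map[cbind(supra[, 1], supra[, 2])])
  labels <- seq_len(n)
  connected <- function(i, j) {
    if (sgn[i] != sgn[j]) return(FALSE)
    ci <- supra[i, 1]; si <- supra[i, 2]
    cj <- supra[j, 1]; sj <- supra[j, 2]
    (ci == cj && abs(si - sj) == 1) || (si == sj && A[ci, cj])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && connected(i, j) && labels[j] != labels[i]) {
        new <- min(labels[i], labels[j])
        if (labels[i] != new || labels[j] != new) {
          labels[labels == labels[i] | labels == labels[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    list(members = cbind(channel = supra[idx, 1], sample = supra[idx, 2]),
         sign = as.integer(sgn[idx[1]]),
         mass = sum(t_map[cbind(supra[idx, 1], supra[idx, 2])]))
  })
}

# Canonical form for comparing cluster partitions from different algorithms.
cluster_signature <- function(clusters, n_ch) {
  sort(vapply(clusters, function(cl) {
    keys <- sort((cl$members[, "sample"] - 1) * n_ch + cl$members[, "channel"])
    paste0(cl$sign, ":", paste(keys, collapse = ","), "@",
           signif(cl$mass, 12))
  }, character(1)))
}
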