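# Small fixtures built in code; all randomness goes through withr::local_seed
# or explicit generator seeds so tests are reproducible.

# short clean synthetic record (default: 10 s, strict 60 bpm)
tiny_synth <- function(duration = 10, mean_hr = 60, rr_sd = 0, seed = 7,
                       ...) {
  generate_ecg(synth_config(duration = duration, mean_hr = mean_hr,
                            rr_sd = rr_sd, seed = seed, ...))
}

# reduced-size network configuration for fast training tests
tiny_unet_config <- function(input_length = 64L, in_channels = 2L, ...) {
  unet_config(input_length = input_length, in_channels = in_channels, ...)
}

# labelled segment set holding one window duplicated n times
duplicated_window_set <- function(window, mask, n, fs = 500) {
  vcgrpeak:::new_segment_set(
    nrow(window), nrow(window), rep(0L, n),
    rep(list(window), n), rep(list(mask), n),
    rep("dup", n), fs
  )
}

# naive triple-loop matrix product oracle (independent of %*%)
naive_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      s <- 0
      for (k in seq_len(ncol(A))) s <- s + A[i, k] * B[k, j]
      out[i, j] <- s
    }
  }
  out
}

# exhaustive 1-D clustering oracle: minimal within-cluster sum of squares
# over all contiguous partitions of the sorted values into k groups
best_partition_centroids <- function(x, k) {
  x <- sort(unique(x))
  n <- length(x)
  stopifnot(k <= n)
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  best_cent <- NULL
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, j], n)
    ss <- 0
    cent <- numeric(k)
    for (g in seq_len(k)) {
      seg <- x[(bounds[g] + 1L):bounds[g + 1L]]
      cent[g] <- mean(seg)
      ss <- ss + sum((seg - cent[g])^2)
    }
    if (ss < best - 1e-12) {
      best <- ss
      best_cent <- cent
    }
  }
  best_cent
}

# brute-force consensus peak oracle: every strictly-above-threshold sample
# follows the steepest-ascent rule step by step; peaks with enough followers
# are kept (re-derived here independently of the package implementation)
oracle_extract_peaks <- function(v, threshold = 0.5, min_support = 5L) {
  n <- length(v)
  cand <- which(v > threshold)
  terminals <- integer(0)
  for (s in cand) {
    repeat {
      left <- if (s > 1L) v[s - 1L] else -Inf
      right <- if (s < n) v[s + 1L] else -Inf
      if (max(left, right) > v[s]) {
        s <- if (left >= right) s - 1L else s + 1L
      } else if (left == v[s]) {
        s <- s - 1L
      } else {
        break
      }
    }
    terminals <- c(terminals, s)
  }
  tab <- table(terminals)
  sort(as.integer(names(tab)[tab >= min_support])) - 1L
}

# exhaustive optimal one-to-one matching: maximum number of pairs within
# tolerance, found by recursion over annotations (instances <= 10 beats)
oracle_max_matching <- function(ann, det, fs, tolerance_ms = 75) {
  tol <- tolerance_ms / 1000
  compatible <- lapply(seq_along(ann), function(i) {
    which(abs(ann[i] - det) / fs <= tol)
  })
  recurse <- function(i, used) {
    if (i > length(ann)) return(0L)
    best <- recurse(i + 1L, used) # leave annotation i unmatched
    for (j in compatible[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, logical(length(det)))
}
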