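# Shared fixtures and small utilities for the test suite. Everything is
# generated in code; no stored data.

# sup-norm between two belief states on the same grid
supnorm <- function(b1, b2) max(abs(belief_density(b1) - belief_density(b2)))

# total variation between two discrete distributions given as named vectors
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pp <- as.numeric(p[match(keys, names(p))]); pp[is.na(pp)] <- 0
  qq <- as.numeric(q[match(keys, names(q))]); qq[is.na(qq)] <- 0
  0.5 * sum(abs(pp - qq))
}

# canonical string key of a partition
partition_key <- function(row_groups, change_points) {
  paste(paste(row_groups, collapse = ","),
        paste(change_points, collapse = ","), sep = "|")
}

# empirical distribution of partitions in a trace, as a named vector
trace_partition_probs <- function(trace) {
  key <- vapply(seq_len(nrow(trace$row_groups)), function(t) {
    partition_key(trace$row_groups[t, ], trace$change_points[[t]])
  }, character(1))
  tab <- table(key)
  stats::setNames(as.numeric(tab) / length(key), names(tab))
}

# the frozen block-means layout used for clustering recovery: >= 5 sigma
# separation within every segment, asymmetric row and column profiles
recovery_means <- function() {
  matrix(c(0, 6, 12, 11, 5, 17, 7, 13, 1), 3, 3)
}

# restrict a belief state to a subset of its grid indices (renormalized)
restrict_belief <- function(belief, idx) {
  belief_state(belief$support[idx], belief$log_density[idx])
}
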