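# Independent brute-force oracles used to verify the fast implementations.

# O(n^2) union-find over pairwise inclusive-coordinate overlap (half-open
# internal coords: a and b overlap iff a$start < b$end and b$start < a$end,
# same chromosome). Returns the merged regions as a sorted tibble.
brute_force_merge <- function(records) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          records$chrom[i] == records$chrom[j] &&
          records$start[i] < records$end[j] &&
          records$start[j] < records$end[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = records$chrom[idx[1]],
               start = min(records$start[idx]),
               end = max(records$end[idx]),
               n_records = length(idx))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

random_interval_set <- function(n, n_chrom = 3, max_pos = 5000,
                                max_span = 400) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + sample.int(max_span, n, replace = TRUE),
    sample_id = paste0("s", sample.int(4, n, replace = TRUE))
  )
}
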