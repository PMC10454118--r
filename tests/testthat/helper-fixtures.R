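# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the package's own code paths (brute-force rotation, hand-merged interval
# unions, edit-distance identity via adist/pairwiseAlignment).

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# substitute a fraction of positions with a different base
mutate_subs <- function(s, frac) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), round(frac * length(v)))
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  v[idx] <- vapply(v[idx], other, "")
  paste(v, collapse = "")
}

# brute-force canonical rotation: enumerate every rotation of s and of its
# reverse complement, take the lexicographic minimum
brute_canonical <- function(s) {
  rots <- function(x) {
    v <- strsplit(x, "")[[1]]
    vapply(seq_along(v), function(i)
      paste(c(v[i:length(v)], v[seq_len(i - 1)]), collapse = ""), "")
  }
  min(c(rots(s), rots(revcomp(s))))
}

# independent interval-union length: sort and merge with a plain loop
oracle_union_len <- function(starts, ends) {
  if (!length(starts)) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce + 1) ce <- max(ce, ends[i])
    else { tot <- tot + ce - cs + 1; cs <- starts[i]; ce <- ends[i] }
  }
  tot + ce - cs + 1
}

# edit-distance-based global identity for the clustering oracle
oracle_identity <- function(a, b) {
  1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

# greedy clustering with the exact identity oracle: same contract as
# greedy_cluster (longest-first, first passing representative, length guard)
# but none of its code
oracle_greedy_cluster <- function(seqs, threshold = 0.90,
                                  max_ratio = 1.25) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    found <- 0L
    for (r in reps) {
      if (nchar(seqs[r]) > max_ratio * nchar(seqs[i])) next
      if (oracle_identity(seqs[r], seqs[i]) >= threshold) { found <- r; break }
    }
    if (found) assign[i] <- found
    else { reps <- c(reps, i); assign[i] <- i }
  }
  stats::setNames(names(seqs)[assign], names(seqs))
}

# small shared toy genome for placement/annotation tests
small_genome <- function(seed = 11, lengths = c(chrA = 3e5, chrB = 2e5)) {
  sim_genome(lengths, seed = seed)
}

# partition of a clustering data frame as a canonical string, for comparing
# partitions irrespective of cluster labels
partition_key <- function(member_ids, cluster_ids) {
  groups <- split(member_ids, cluster_ids)
  groups <- vapply(groups, function(g) paste(sort(g), collapse = "+"), "")
  paste(sort(unname(groups)), collapse = " | ")
}
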