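# Greedy incremental clustering of circle sequences at a sequence-identity
# threshold, with identity estimated by k-mer containment. Mirrors the
# longest-first greedy contract of classical sequence clusterers: each
# sequence joins the first existing cluster whose representative passes the
# identity criterion, otherwise founds a new cluster.

#' k-mer containment identity estimate
#'
#' Fraction of the shorter sequence's distinct k-mers present in the longer
#' sequence's k-mer set. Under iid substitutions at identity `i`, a k-mer
#' survives in both sequences with probability about `i^k`, so a containment
#' cutoff of `identity^k` corresponds to a sequence-identity threshold (the
#' calibration is verified empirically in the test suite). Both sequences are
#' expected to be canonical-rotated (see [canonical_rotation()]) so the
#' estimate is rotation- and strand-invariant.
#'
#' @param a the longer sequence (character scalar).
#' @param b the shorter sequence; must be longer than `k`.
#' @param k k-mer size (default 12).
#' @return containment fraction in `[0, 1]`.
#' @export
kmer_identity <- function(a, b, k = 12) {
  if (nchar(b) <= k) stop("`b` must be longer than k")
  ka <- unique(kmer_codes(a, k))
  kb <- unique(kmer_codes(b, k))
  ka <- ka[!is.na(ka)]
  kb <- kb[!is.na(kb)]
  if (!length(kb)) return(0)
  mean(kb %in% ka)
}

# Scrambled order of a k-mer code, used for bottom-s sketches so the sketch
# is an effectively random sample of the k-mer space.
kmer_hash <- function(code) (code * 48271) %% 2147483647

# Longest run of TRUE in a logical vector treated as circular (a run may
# wrap from the end to the start).
longest_circular_run <- function(x) {
  if (!length(x)) return(0L)
  if (all(x)) return(length(x))
  r <- rle(x)
  best <- max(c(0L, r$lengths[r$values]))
  if (r$values[1] && r$values[length(r$values)])
    best <- max(best, r$lengths[1] + r$lengths[length(r$values)])
  best
}

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are sorted by length (descending, ties by id ascending) and each
#' joins the first existing cluster whose representative (its longest member,
#' the founder) passes three criteria: k-mer containment at least
#' `identity_threshold ^ k`; representative/member length ratio at most
#' `max_length_ratio` (containment is asymmetric; the guard stops a long
#' sequence absorbing short unrelated ones); and no circularly contiguous
#' block of the member longer than `1 - identity_threshold` of its length is
#' absent from the representative. The block guard separates genuine
#' sequence divergence (missing k-mers scattered along the sequence) from
#' mere partial overlap of two circles excised from neighbouring loci, whose
#' missing k-mers form one long block — so the criterion matches
#' identity-over-the-shorter-sequence semantics rather than raw containment.
#' Candidate representatives are prefiltered through a
#' bottom-`sketch_size` min-hash sketch of their k-mer sets, so unrelated
#' pairs are never compared in full. Output is deterministic and invariant
#' to input order.
#'
#' @param circles named character vector or DNAStringSet of canonical-rotated
#'   circle sequences.
#' @param identity_threshold sequence-identity threshold (default 0.90).
#' @param k k-mer size for the containment estimate (default 12).
#' @param max_length_ratio representative/member length cap (default 1.25).
#' @param sketch_size bottom-sketch size for candidate prefiltering.
#' @return data frame with one row per input sequence: `cluster_id`,
#'   `member_id`, `representative_id`, `identity` (estimated identity to the
#'   representative; 1 for the representative itself), `is_representative`.
#' @export
greedy_cluster <- function(circles, identity_threshold = 0.90, k = 12,
                           max_length_ratio = 1.25, sketch_size = 64) {
  seqs <- if (is.character(circles)) circles else as.character(circles)
  if (!length(seqs)) {
    return(data.frame(cluster_id = character(), member_id = character(),
                      representative_id = character(), identity = numeric(),
                      is_representative = logical(), stringsAsFactors = FALSE))
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%05d", seq_along(seqs))
  stopifnot(!anyDuplicated(ids), all(nchar(seqs) > k))

  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]
  ids <- ids[ord]
  lens <- nchar(seqs)
  cutoff <- identity_threshold^k

  rep_codes <- list()   # distinct k-mer codes per representative
  rep_len <- numeric(0)
  rep_id <- character(0)
  sketch_index <- new.env(hash = TRUE, parent = emptyenv())

  assign_cluster <- integer(length(seqs))
  member_identity <- numeric(length(seqs))

  max_gap <- (1 - identity_threshold)  # fraction of member length

  for (i in seq_along(seqs)) {
    kb_all <- kmer_codes(seqs[i], k)
    kb <- unique(kb_all[!is.na(kb_all)])
    sketch <- sort(kmer_hash(kb))[seq_len(min(sketch_size, length(kb)))]

    cand <- integer(0)
    for (h in as.character(sketch)) {
      if (exists(h, envir = sketch_index, inherits = FALSE))
        cand <- c(cand, get(h, envir = sketch_index, inherits = FALSE))
    }
    cand <- sort(unique(cand))
    cand <- cand[rep_len[cand] <= max_length_ratio * lens[i]]

    joined <- 0L
    for (ci in cand) {
      containment <- mean(kb %in% rep_codes[[ci]])
      if (containment < cutoff) next
      # longest circular run of member positions absent from the rep
      miss <- !(kb_all %in% rep_codes[[ci]])
      run <- longest_circular_run(miss)
      if (run > max_gap * lens[i] + k) next
      joined <- ci
      member_identity[i] <- containment^(1 / k)
      break
    }
    if (joined > 0L) {
      assign_cluster[i] <- joined
    } else {
      ci <- length(rep_id) + 1L
      rep_codes[[ci]] <- kb
      rep_len[ci] <- lens[i]
      rep_id[ci] <- ids[i]
      for (h in as.character(sketch)) {
        prev <- if (exists(h, envir = sketch_index, inherits = FALSE))
          get(h, envir = sketch_index, inherits = FALSE) else integer(0)
        assign(h, c(prev, ci), envir = sketch_index)
      }
      assign_cluster[i] <- ci
      member_identity[i] <- 1
    }
  }

  data.frame(cluster_id = sprintf("cluster_%05d", assign_cluster),
             member_id = ids,
             representative_id = rep_id[assign_cluster],
             identity = member_identity,
             is_representative = ids == rep_id[assign_cluster],
             stringsAsFactors = FALSE)
}
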