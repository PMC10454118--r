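# Deconcatenation of RCA concatemer reads: detect the monomer period from
# k-mer recurrence spacing, build an error-corrected monomer consensus across
# the tandem copies, and flag circularity from copy number, period support and
# junction consistency.

#' Detect the tandem monomer period of a concatemer read
#'
#' The monomer length of a rolling-circle concatemer shows up as the dominant
#' spacing between recurrences of shared k-mers along the read. Spacings are
#' collected from consecutive occurrences of each k-mer, merged into clusters
#' within a +/-2 percent tolerance, and the best-supported cluster gives the
#' period. Reads without tandem structure yield almost no recurrent k-mers and
#' return `NULL`.
#'
#' @param read DNA string (character scalar), at least `2 * min_period` long.
#' @param k k-mer size, 8..21 (default 15).
#' @param min_period smallest monomer length considered, bp (default 200).
#' @param min_period_score minimum fraction of recurrence votes the dominant
#'   spacing must carry (default 0.8).
#' @param min_votes minimum number of recurrence votes overall (default 5).
#' @return `NULL`, or a list with `period` (bp), `score` (fraction of votes on
#'   the dominant spacing) and `n_votes`.
#' @export
find_monomer_period <- function(read, k = 15, min_period = 200,
                                min_period_score = 0.8, min_votes = 5) {
  stopifnot(k >= 8, k <= 21)
  n <- nchar(read)
  if (n < 2 * min_period) return(NULL)
  codes <- kmer_codes(read, k)
  pos <- which(!is.na(codes))
  codes <- codes[pos]
  if (length(codes) < 2) return(NULL)
  o <- order(codes, pos)
  codes <- codes[o]
  pos <- pos[o]
  gaps <- diff(pos)[diff(codes) == 0]
  gaps <- gaps[gaps >= floor(0.95 * min_period)]
  if (length(gaps) < min_votes) return(NULL)
  g <- sort(gaps)
  # single-linkage clusters: break where adjacent sorted gaps differ by more
  # than 2% (at least 3 bp, so indel jitter never splits short periods)
  brk <- diff(g) > pmax(0.02 * g[-length(g)], 3)
  cl <- cumsum(c(1L, as.integer(brk)))
  sizes <- tabulate(cl)
  best <- which.max(sizes)
  score <- sizes[best] / length(g)
  if (score < min_period_score) return(NULL)
  list(period = round(stats::median(g[cl == best])),
       score = score, n_votes = length(g))
}

# Build the monomer consensus across the full tandem copies of a read.
# Copy 1 is the backbone; the other copies are mapped onto it through chains
# of shared unique k-mer anchors, columns are resolved by majority vote (ties
# kept from the backbone), and with 3+ copies backbone indels are repaired
# where the other copies' offset tracks jump in unison.
consensus_monomer <- function(read, period, anchor_k = 12) {
  n <- nchar(read)
  L1 <- round(period)
  m <- floor(n / period + 0.02)
  if (m < 2) return(substr(read, 1L, min(L1, n)))
  starts <- round((seq_len(m) - 1) * period) + 1L
  copies <- substring(read, starts, pmin(starts + L1 - 1L, n))
  copies <- copies[nchar(copies) >= 0.98 * L1]
  m <- length(copies)
  if (m < 2) return(copies[1])

  backbone <- copies[1]
  c1 <- strsplit(backbone, "", fixed = TRUE)[[1]]
  L1 <- length(c1)
  cod1 <- kmer_codes(backbone, anchor_k)
  u1 <- which(!(duplicated(cod1) | duplicated(cod1, fromLast = TRUE)) &
                !is.na(cod1))

  letters_by_copy <- vector("list", m)
  letters_by_copy[[1]] <- c1
  offsets <- vector("list", m)
  offsets[[1]] <- rep(0L, L1)
  for (j in 2:m) {
    cj <- strsplit(copies[j], "", fixed = TRUE)[[1]]
    letters_by_copy[[j]] <- cj
    codj <- kmer_codes(copies[j], anchor_k)
    uj <- which(!(duplicated(codj) | duplicated(codj, fromLast = TRUE)) &
                  !is.na(codj))
    mi <- match(cod1[u1], codj[uj])
    ok <- !is.na(mi)
    a1 <- u1[ok]
    aj <- uj[mi[ok]]
    if (length(a1) >= 3) {
      off <- aj - a1
      keep <- abs(off - stats::median(off)) <= pmax(30, 0.02 * L1)
      a1 <- a1[keep]; aj <- aj[keep]
      if (length(a1) > 1) {
        mono <- c(TRUE, diff(aj) > 0)
        a1 <- a1[mono]; aj <- aj[mono]
      }
    }
    offsets[[j]] <- if (length(a1) >= 3) {
      (aj - a1)[pmax(findInterval(seq_len(L1), a1), 1L)]
    } else rep(0L, L1)
  }

  # repair backbone indels when a strict majority of the other copies' offset
  # tracks jump together (-1: backbone insertion, +1: backbone deletion)
  del_col <- logical(L1)
  ins_before <- integer(0)
  if (m >= 3) {
    need <- max(2L, floor((m - 1) / 2) + 1L)
    D <- vapply(2:m, function(j) diff(offsets[[j]]), numeric(L1 - 1L))
    negs <- rowSums(D == -1)
    poss <- rowSums(D == 1)
    del_col[which(negs >= need & poss == 0) + 1L] <- TRUE
    ins_before <- which(poss >= need & negs == 0) + 1L
  }

  votes <- matrix(NA_character_, L1, m)
  votes[, 1] <- c1
  for (j in 2:m) {
    idx <- seq_len(L1) + offsets[[j]]
    v <- rep(NA_character_, L1)
    inr <- idx >= 1L & idx <= length(letters_by_copy[[j]])
    v[inr] <- letters_by_copy[[j]][idx[inr]]
    votes[, j] <- v
  }
  cnt <- vapply(DNA_BASES, function(b) rowSums(votes == b, na.rm = TRUE),
                numeric(L1))
  mx <- pmax(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
  bb_cnt <- cnt[cbind(seq_len(L1), match(c1, DNA_BASES))]
  cons <- ifelse(bb_cnt >= mx, c1, DNA_BASES[max.col(cnt, ties.method = "first")])

  pieces <- cons
  pieces[del_col] <- ""
  for (i in ins_before) {
    letters <- vapply(2:m, function(j) {
      p <- i - 1L + offsets[[j]][i - 1L] + 1L
      if (p >= 1L && p <= length(letters_by_copy[[j]]))
        letters_by_copy[[j]][p] else NA_character_
    }, "")
    tab <- table(letters)
    if (length(tab))
      pieces[i] <- paste0(names(tab)[which.max(tab)], pieces[i])
  }
  paste(pieces, collapse = "")
}

#' Collapse a concatemer read to a circle candidate
#'
#' Given the monomer period, extracts the full tandem copies, builds a
#' majority-vote consensus monomer (anchor-aligned to tolerate indels), and
#' flags circularity: the read must span at least `min_copies` copies (so a
#' full junction was observed), carry a dominant period, and its copy-boundary
#' k-mers must be consistent with the monomer treated as circular.
#'
#' @param read DNA string (character scalar).
#' @param period result of [find_monomer_period()] (list or numeric period),
#'   or `NULL`, in which case the read is passed through uncollapsed with
#'   `circular = FALSE`.
#' @param read_id identifier recorded in the candidate.
#' @param min_copies minimum copy number for a circular call (default 1.5).
#' @param min_period_score minimum period support for a circular call.
#' @param junction_frac minimum fraction of copy boundaries at which the
#'   junction must be confirmed, i.e. at which a k-mer from the monomer start
#'   re-occurs in the read window around the boundary (default 0.5: a
#'   majority of observed junctions; a true tandem confirms nearly all
#'   boundaries even at a 1 percent error rate, a non-tandem read none).
#' @param junction_k k-mer size for the junction check (default 12).
#' @return a one-row data frame (`read_id`, `copy_number`, `circular`,
#'   `period`, `period_score`, `junction_score`) with the consensus monomer in
#'   the `monomer` column.
#' @export
deconcat_read <- function(read, period, read_id = "read",
                          min_copies = 1.5, min_period_score = 0.8,
                          junction_frac = 0.5, junction_k = 12) {
  if (is.numeric(period)) period <- list(period = period, score = 1)
  if (is.null(period) || is.null(period$period)) {
    return(data.frame(read_id = read_id, monomer = read, copy_number = 1,
                      circular = FALSE, period = NA_real_, period_score = 0,
                      junction_score = NA_real_, stringsAsFactors = FALSE))
  }
  p <- period$period
  n <- nchar(read)
  copy_number <- n / p
  monomer <- consensus_monomer(read, p)

  # junction consistency: at each copy boundary the monomer start must
  # re-occur — some k-mer from the (error-corrected) monomer's first bases is
  # found in the read window around the boundary. Checking start recurrence
  # rather than the monomer's own wrap sequence keeps the call robust to the
  # +/- few bp uncertainty of the consensus length.
  jscore <- NA_real_
  if (copy_number >= min_copies) {
    probe <- kmer_codes(substr(monomer, 1L, 3L * junction_k - 5L), junction_k)
    probe <- probe[!is.na(probe)]
    half <- 50L
    bounds <- round(p * seq_len(floor(copy_number)))
    bounds <- bounds[bounds - half >= 1 & bounds + half <= n]
    if (length(bounds) && length(probe)) {
      hit <- vapply(bounds, function(b) {
        wk <- kmer_codes(substr(read, b - half, b + half), junction_k)
        any(probe %in% wk)
      }, logical(1))
      jscore <- mean(hit)
    } else {
      jscore <- 1  # boundaries only at the read ends; nothing to contradict
    }
  }
  circular <- isTRUE(copy_number >= min_copies &&
                       period$score >= min_period_score &&
                       !is.na(jscore) && jscore >= junction_frac)
  data.frame(read_id = read_id, monomer = monomer, copy_number = copy_number,
             circular = circular, period = p, period_score = period$score,
             junction_score = jscore, stringsAsFactors = FALSE)
}

#' Deconcatenate a set of reads
#'
#' Runs [find_monomer_period()] and [deconcat_read()] over a read set.
#'
#' @param reads named DNAStringSet or character vector of reads.
#' @param k k-mer size for period detection.
#' @inheritParams deconcat_read
#' @inheritParams find_monomer_period
#' @return data frame with one row per read (see [deconcat_read()]).
#' @export
deconcat_reads <- function(reads, k = 15, min_period = 200,
                           min_period_score = 0.8, min_copies = 1.5,
                           junction_frac = 0.6) {
  rd <- if (is.character(reads)) reads else as.character(reads)
  ids <- names(rd)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(rd))
  ids <- sub(" .*", "", ids)
  out <- vector("list", length(rd))
  for (i in seq_along(rd)) {
    per <- find_monomer_period(rd[i], k = k, min_period = min_period,
                               min_period_score = min_period_score)
    out[[i]] <- deconcat_read(rd[i], per, read_id = ids[i],
                              min_copies = min_copies,
                              min_period_score = min_period_score,
                              junction_frac = junction_frac)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Canonical rotation of a circular sequence
#'
#' Circles have no defined start or strand, so identity comparisons use the
#' lexicographically smallest string among all rotations of the sequence and
#' of its reverse complement. Idempotent.
#'
#' @param seq DNA string over A/C/G/T (character scalar).
#' @return the canonical rotation (character scalar).
#' @examples
#' canonical_rotation("GTAC")  # "ACGT"
#' @export
canonical_rotation <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters")
  a <- least_rotation(seq)
  b <- least_rotation(revcomp_chr(seq))
  if (a <= b) a else b
}

# Lexicographically least rotation by iterative candidate filtering on the
# doubled string. Random sequences resolve in O(n log n); fully periodic
# strings (worst case) fall back to the first candidate, which is then
# equivalent to every other survivor.
least_rotation <- function(s) {
  n <- nchar(s)
  v <- strsplit(strrep(s, 2L), "", fixed = TRUE)[[1]]
  cand <- seq_len(n)
  d <- 0L
  while (length(cand) > 1L && d < n) {
    ch <- v[cand + d]
    cand <- cand[ch == min(ch)]
    d <- d + 1L
  }
  paste(v[cand[1]:(cand[1] + n - 1L)], collapse = "")
}
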