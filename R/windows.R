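# Best-hit genomic placement of circles (seed-and-vote toy aligner), binning
# of placements into consecutive fixed-width genome windows, per-condition
# Z-scores, and biogenesis hotspot calls.

#' Partition a genome into consecutive fixed-width windows
#'
#' Per chromosome, emits windows `[0, width)`, `[width, 2*width)`, ... with
#' the final window truncated at the chromosome end. Coordinates in the
#' returned table are 0-based half-open (BED convention).
#'
#' @param genome a `toy_genome`, a DNAStringSet, or a named numeric vector of
#'   chromosome lengths.
#' @param width window width in bp (default 500000).
#' @return data frame with `chrom`, `start0`, `end0`, `window_id`.
#' @examples
#' make_windows(c(chrA = 1234567))  # 3 windows, last [1000000, 1234567)
#' @export
make_windows <- function(genome, width = 500000) {
  stopifnot(width > 0)
  lens <- if (is.numeric(genome)) genome
          else Biostrings::width(as_genome_seqs(genome))
  if (is.null(names(lens)) && is.numeric(genome) && length(lens))
    names(lens) <- paste0("chr", seq_along(lens))
  if (methods::is(genome, "DNAStringSet") || inherits(genome, "toy_genome"))
    names(lens) <- names(as_genome_seqs(genome))
  out <- lapply(names(lens), function(ch) {
    n <- ceiling(lens[[ch]] / width)
    if (n == 0) return(NULL)
    s <- (seq_len(n) - 1) * width
    data.frame(chrom = ch, start0 = s,
               end0 = pmin(s + width, lens[[ch]]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), window_id = character(),
                      stringsAsFactors = FALSE))
  res$window_id <- sprintf("%s:%d-%d", res$chrom, res$start0, res$end0)
  rownames(res) <- NULL
  res
}

#' Place circles on a genome with a seed-and-vote aligner
#'
#' Evenly spaced k-mer seeds from each circle (both strands) are matched
#' exactly against the genome with [Biostrings::matchPDict()]; the locus
#' gathering the most seed hits within a circle-length window wins. Ties are
#' broken toward the lexicographically lowest chromosome and lowest start.
#' Circles gathering fewer than `min_votes` seed hits are reported unplaced.
#' Placement is strand-agnostic and tolerant of the arbitrary rotation of a
#' deconcatenated monomer.
#'
#' @param circles named character vector or DNAStringSet.
#' @param genome a `toy_genome` or named DNAStringSet.
#' @param k seed k-mer size (default 15).
#' @param n_seeds number of seeds per circle and strand (default 32).
#' @param min_votes minimum agreeing seeds to accept a placement (default 5).
#' @return data frame with `circle_id`, `placed`, `chrom`, `start0`, `end0`
#'   (0-based half-open), `strand`, `votes`; unplaced circles carry NA
#'   coordinates.
#' @export
locate_circles <- function(circles, genome, k = 15, n_seeds = 32,
                           min_votes = 5) {
  seqs <- if (is.character(circles)) circles else as.character(circles)
  gseqs <- as_genome_seqs(genome)
  if (!length(gseqs)) stop("empty genome index")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("circle_%05d", seq_along(seqs))
  n <- length(seqs)
  out <- data.frame(circle_id = ids, placed = FALSE, chrom = NA_character_,
                    start0 = NA_integer_, end0 = NA_integer_,
                    strand = NA_character_, votes = 0L,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  glens <- stats::setNames(Biostrings::width(gseqs), names(gseqs))
  chroms <- sort(names(gseqs))
  L <- nchar(seqs)

  # one batch of seeds across all circles and both strands, matched with a
  # single PDict per chromosome
  acc <- vector("list", 2L * n)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  for (strand in c("+", "-")) {
    src <- if (strand == "+") seqs else rc
    for (i in seq_len(n)) {
      if (nchar(src[i]) < k) next
      offs <- unique(round(seq(1, nchar(src[i]) - k + 1,
                               length.out = n_seeds)))
      sd <- unique(substring(src[i], offs, offs + k - 1))
      sd <- sd[!grepl("[^ACGT]", sd)]
      acc[[(if (strand == "+") 0L else n) + i]] <-
        list(sd = sd, i = rep(i, length(sd)),
             strand = rep(strand, length(sd)))
    }
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) return(out)
  seed_str <- unlist(lapply(acc, `[[`, "sd"), use.names = FALSE)
  seed_circle <- unlist(lapply(acc, `[[`, "i"), use.names = FALSE)
  seed_strand <- unlist(lapply(acc, `[[`, "strand"), use.names = FALSE)
  if (!length(seed_str)) return(out)
  uniq <- unique(seed_str)
  pat_of_seed <- match(seed_str, uniq)
  owners_by_pat <- split(seq_along(seed_str), pat_of_seed)
  pd <- Biostrings::PDict(uniq)

  best <- data.frame(votes = rep(0L, n), chrom = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     strand = NA_character_, stringsAsFactors = FALSE)
  for (ch in chroms) {
    mi <- Biostrings::startIndex(Biostrings::matchPDict(pd, gseqs[[ch]]))
    hit_len <- lengths(mi)
    if (!sum(hit_len)) next
    hit_pat <- rep(seq_along(mi), hit_len)
    hit_pos <- unlist(mi, use.names = FALSE)
    own <- owners_by_pat[as.character(hit_pat)]
    own_len <- lengths(own)
    owner <- unlist(own, use.names = FALSE)
    pos <- rep(hit_pos, own_len)
    key <- paste0(seed_circle[owner], seed_strand[owner])
    by_grp <- split(pos, key)
    for (g in names(by_grp)) {
      p <- sort(by_grp[[g]])
      if (length(p) < min_votes) next
      ci <- as.integer(sub("[+-]$", "", g))
      strand <- substring(g, nchar(g))
      W <- L[ci] + max(20, round(0.05 * L[ci]))
      cnt <- findInterval(p + W, p) - seq_along(p) + 1L
      votes <- max(cnt)
      i0 <- which.max(cnt)
      lo <- p[i0]
      hi <- max(p[p <= lo + W]) + k - 1L
      better <- votes > best$votes[ci] ||
        (votes == best$votes[ci] && best$votes[ci] > 0L &&
           (ch < best$chrom[ci] ||
              (ch == best$chrom[ci] && lo < best$start[ci])))
      if (better) {
        best$votes[ci] <- votes
        best$chrom[ci] <- ch
        best$start[ci] <- lo
        best$end[ci] <- min(hi, glens[[ch]])
        best$strand[ci] <- strand
      }
    }
  }
  placed <- best$votes >= min_votes
  out$placed <- placed
  out$chrom[placed] <- best$chrom[placed]
  out$start0[placed] <- best$start[placed] - 1L
  out$end0[placed] <- best$end[placed]
  out$strand[placed] <- best$strand[placed]
  out$votes <- best$votes
  out
}

#' Z-score of a window count
#'
#' `(count - mean) / sd`, reported rounded half away from zero.
#'
#' @param count window count.
#' @param mean,sd per-condition window-count mean and (population) SD.
#' @param digits decimal places for the report (default 2); `NULL` for the
#'   raw value.
#' @return numeric Z-score.
#' @examples
#' window_zscore(185, 1.97, 4.42)  # 41.41
#' @export
window_zscore <- function(count, mean, sd, digits = 2) {
  z <- (count - mean) / sd
  if (is.null(digits)) z else round_half_away(z, digits)
}

#' Bin circle placements into genome windows and score them
#'
#' Each placed circle is assigned to the window containing its hit midpoint
#' (unique assignment, so window counts sum to the number of placed circles).
#' The per-window mean and population standard deviation are computed over
#' all windows, zeros included, and each window gets
#' `z = (count - mean) / sd`. `pct_with_genes` is the percentage of binned
#' circles carrying at least one gene.
#'
#' @param hits data frame from [locate_circles()].
#' @param windows data frame from [make_windows()].
#' @param gene_flags optional named logical: does each circle carry a gene?
#' @param condition optional condition label carried into the result.
#' @return an `ecc_window_table`: a list with `windows` (the window table,
#'   with raw `z` and `pct_with_genes` columns), `mean`, `sd`, `n_placed`,
#'   `n_unplaced`, `condition`. If `sd` is 0 all `z` are NA.
#' @export
bin_and_score <- function(hits, windows, gene_flags = NULL, condition = NA) {
  placed <- hits[hits$placed, , drop = FALSE]
  width <- max(windows$end0 - windows$start0)
  wt <- windows
  wt$count <- 0L
  wt$count_with_genes <- 0L
  if (nrow(placed)) {
    mid <- floor((placed$start0 + placed$end0) / 2)
    key <- sprintf("%s:%d", placed$chrom, floor(mid / width))
    wkey <- sprintf("%s:%d", wt$chrom, floor(wt$start0 / width))
    wi <- match(key, wkey)
    if (anyNA(wi)) stop("hit midpoint outside the window tiling")
    tab <- table(wi)
    wt$count[as.integer(names(tab))] <- as.integer(tab)
    if (!is.null(gene_flags)) {
      gf <- gene_flags[placed$circle_id]
      gf[is.na(gf)] <- FALSE
      tab2 <- table(wi[gf])
      wt$count_with_genes[as.integer(names(tab2))] <- as.integer(tab2)
    }
  }
  mu <- mean(wt$count)
  sdev <- sqrt(mean((wt$count - mu)^2))  # population SD over all windows
  wt$pct_with_genes <- pct_round(wt$count_with_genes, wt$count)
  wt$z <- if (sdev > 0) (wt$count - mu) / sdev else NA_real_
  structure(list(windows = wt, mean = mu, sd = sdev,
                 n_placed = nrow(placed),
                 n_unplaced = sum(!hits$placed), condition = condition),
            class = "ecc_window_table")
}

#' @export
print.ecc_window_table <- function(x, ...) {
  cat(sprintf(
    "ecc_window_table: %d windows, %d circles binned (mean %.2f +/- %.2f)\n",
    nrow(x$windows), x$n_placed, x$mean, x$sd))
  invisible(x)
}

#' Call eccDNA biogenesis hotspots
#'
#' Windows with a Z-score at or above `z_min` are called hotspots, ranked by
#' count (descending, ties by chromosome then start). Also returns the top-N
#' windows by count formatted like a hotspot report (counts, gene-bearing
#' counts and percentages, Z-scores rounded to the printed precision).
#'
#' @param table an `ecc_window_table` from [bin_and_score()].
#' @param z_min hotspot Z-score threshold (default 2).
#' @param top_n rows in the top-window report (default 15).
#' @return list with `hotspots` (data frame with `rank`) and `top` (top-N
#'   report data frame). Both are empty when the window SD is 0 (all `z`
#'   undefined).
#' @export
call_hotspots <- function(table, z_min = 2, top_n = 15) {
  wt <- table$windows
  fmt <- function(df) {
    data.frame(chrom = df$chrom, start0 = df$start0, end0 = df$end0,
               count = df$count, count_with_genes = df$count_with_genes,
               pct_with_genes = df$pct_with_genes,
               z = round_half_away(df$z, 2), stringsAsFactors = FALSE)
  }
  if (all(is.na(wt$z))) {
    empty <- fmt(wt[0, , drop = FALSE])
    return(list(hotspots = cbind(empty, rank = integer(0)), top = empty))
  }
  ord <- order(-wt$count, wt$chrom, wt$start0)
  hs <- wt[ord, , drop = FALSE]
  hs <- hs[hs$z >= z_min, , drop = FALSE]
  hotspots <- fmt(hs)
  if (nrow(hotspots)) hotspots$rank <- seq_len(nrow(hotspots))
  else hotspots$rank <- integer(0)
  top <- fmt(wt[ord, , drop = FALSE][seq_len(min(top_n, nrow(wt))), ,
                                     drop = FALSE])
  list(hotspots = hotspots, top = top)
}
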