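# Synthetic-data generator: toy genome with annotated features, eccDNA
# populations with planted biogenesis hotspots, RCA concatemer reads, and
# TMM expression tables with planted dosage (and optional DE) effects.

# Default repeat-class composition, as percent of genome bases. The class mix
# follows the relative interspersed/tandem repeat abundances typical of a
# rodent genome (SINE/LINE/LTR-dominated, ~38% of bases masked overall).
REPEAT_CLASS_PCT <- c(
  SINE = 7.49, LINE = 14.6, LTR = 9.94, DNA = 1.08, unclassified = 0.61,
  smallRNA = 0.11, satellite = 1.82, simple = 2.09, low_complexity = 0.26
)

REPEAT_CLASS_LEN <- list(
  SINE = c(150, 300), LINE = c(1000, 6000), LTR = c(300, 1500),
  DNA = c(100, 800), unclassified = c(100, 1000), smallRNA = c(70, 150),
  satellite = c(200, 2000), simple = c(20, 120), low_complexity = c(20, 150)
)

INTERSPERSED_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "unclassified")

#' Simulate a toy reference genome with feature annotations
#'
#' Generates random chromosome sequences at a target GC fraction and a feature
#' set of non-overlapping genes, tRNAs, rDNA genes and origins of replication
#' (ORIs), plus possibly-overlapping repeat intervals whose union covers a
#' configurable fraction of the genome. A stand-in for a real reference genome
#' plus its annotation databases at desk scale.
#'
#' @param chrom_lengths named (or unnamed, then chr1..chrN) integer vector of
#'   chromosome lengths in bp; each must be >= 50 kb.
#' @param gc target GC fraction in (0, 1); realized GC is within ~0.02 for
#'   chromosomes of 100 kb and above.
#' @param repeat_fraction target fraction of genome bases covered by the union
#'   of repeat intervals (default 0.38).
#' @param genes_per_mb,trnas_per_mb feature densities.
#' @param gene_length,trna_length,rdna_length,ori_length length ranges in bp.
#' @param n_rdna,n_ori total counts genome-wide.
#' @param seed integer seed; identical arguments and seed give byte-identical
#'   FASTA/BED output.
#' @return an object of class `toy_genome`: a list with `genome` (a named
#'   [Biostrings::DNAStringSet]) and `features` (a [GenomicRanges::GRanges]
#'   with metadata columns `kind` — one of `gene`, `tRNA`, `rDNA`, `ORI`, or
#'   `repeat:<class>` — and `id`, unique within kind).
#' @export
sim_genome <- function(chrom_lengths, gc = 0.405, repeat_fraction = 0.38,
                       genes_per_mb = 30, gene_length = c(500, 2500),
                       trnas_per_mb = 20, trna_length = c(70, 90),
                       n_rdna = 3, rdna_length = c(1500, 3000),
                       n_ori = 4, ori_length = c(300, 800),
                       seed = 1) {
  stopifnot(all(chrom_lengths >= 5e4), gc > 0, gc < 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  stopifnot(!anyDuplicated(names(chrom_lengths)))
  chrom_lengths <- round(chrom_lengths)
  total <- sum(chrom_lengths)

  with_seed(seed, {
    seqs <- vapply(chrom_lengths, random_dna, "", gc = gc)

    occupied <- lapply(chrom_lengths, function(...) IRanges::IRanges())
    rows <- list()
    place_nonoverlapping <- function(kind, n, len_range) {
      placed <- 0L
      attempts <- 0L
      while (placed < n && attempts < 60L * n) {
        attempts <- attempts + 1L
        chrom <- sample(names(chrom_lengths), 1L, prob = chrom_lengths)
        len <- sample(len_range[1]:len_range[2], 1L)
        if (len >= chrom_lengths[[chrom]]) next
        start <- sample.int(chrom_lengths[[chrom]] - len, 1L)
        ir <- IRanges::IRanges(start, start + len - 1L)
        if (IRanges::countOverlaps(ir, occupied[[chrom]]) > 0L) next
        occupied[[chrom]] <<- c(occupied[[chrom]], ir)
        placed <- placed + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = chrom, start = start, end = start + len - 1L,
          strand = sample(c("+", "-"), 1L),
          kind = kind, id = sprintf("%s_%04d", sub(":.*", "", kind), placed),
          stringsAsFactors = FALSE)
      }
      if (placed < n)
        warning(sprintf("placed %d of %d requested %s features", placed, n, kind))
    }
    place_nonoverlapping("gene", round(genes_per_mb * total / 1e6), gene_length)
    place_nonoverlapping("tRNA", round(trnas_per_mb * total / 1e6), trna_length)
    place_nonoverlapping("rDNA", n_rdna, rdna_length)
    place_nonoverlapping("ORI", n_ori, ori_length)

    # Repeat intervals: overlap allowed, class drawn by base-pair weight,
    # drawn until the interval union reaches the target coverage.
    target <- repeat_fraction * total
    cls_prob <- REPEAT_CLASS_PCT / sum(REPEAT_CLASS_PCT)
    rep_rows <- list()
    rep_by_chrom <- lapply(chrom_lengths, function(...) IRanges::IRanges())
    cur_union <- 0
    draw_repeats <- function(nb) {
      cls <- sample(names(cls_prob), nb, replace = TRUE, prob = cls_prob)
      for (cl in cls) {
        lr <- REPEAT_CLASS_LEN[[cl]]
        len <- sample(lr[1]:lr[2], 1L)
        chrom <- sample(names(chrom_lengths), 1L, prob = chrom_lengths)
        if (len >= chrom_lengths[[chrom]]) next
        start <- sample.int(chrom_lengths[[chrom]] - len, 1L)
        rep_by_chrom[[chrom]] <<- c(rep_by_chrom[[chrom]],
                                    IRanges::IRanges(start, start + len - 1L))
        rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
          chrom = chrom, start = start, end = start + len - 1L,
          strand = sample(c("+", "-"), 1L),
          kind = paste0("repeat:", cl), id = NA_character_,
          stringsAsFactors = FALSE)
      }
      cur_union <<- sum(vapply(rep_by_chrom, function(ir)
        sum(IRanges::width(IRanges::reduce(ir))), numeric(1)))
    }
    if (target > 0) {
      # halve the remaining gap per round (mean interval ~1.7 kb), then close
      # it with single draws so the overshoot is at most one interval
      repeat {
        gap <- target - cur_union
        if (gap <= 0) break
        draw_repeats(min(200L, max(1L, floor(gap / 3500))))
      }
    }

    feat <- do.call(rbind, c(rows, rep_rows))
    if (is.null(feat)) {
      gr <- GenomicRanges::GRanges()
    } else {
      # unique ids within kind for repeats
      is_rep <- is.na(feat$id)
      feat$id[is_rep] <- sprintf("rep_%05d", seq_len(sum(is_rep)))
      gr <- GenomicRanges::GRanges(
        feat$chrom, IRanges::IRanges(feat$start, feat$end),
        strand = feat$strand,
        seqlengths = chrom_lengths)
      S4Vectors::mcols(gr)$kind <- feat$kind
      S4Vectors::mcols(gr)$id <- feat$id
      gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    }

    structure(
      list(genome = Biostrings::DNAStringSet(seqs),
           features = gr,
           params = list(gc = gc, repeat_fraction = repeat_fraction,
                         seed = seed)),
      class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosome(s), %s bp, %d features\n",
              length(x$genome),
              format(sum(Biostrings::width(x$genome)), big.mark = ","),
              length(x$features)))
  invisible(x)
}

#' Simulate an eccDNA population with planted biogenesis hotspots
#'
#' Circle source midpoints are drawn from a mixture: with probability
#' `p_hotspot` from the supplied weighted hotspot windows, otherwise uniformly
#' along the genome. Lengths are truncated-normal with a 200 bp floor; the
#' circle sequence is the genomic substring on a uniformly chosen strand.
#'
#' @param genome a `toy_genome` or named [Biostrings::DNAStringSet].
#' @param features optional [GenomicRanges::GRanges] of annotations (taken
#'   from the `toy_genome` if omitted); used to record carried features.
#' @param n_circles number of circles (0 gives an empty population).
#' @param hotspot_windows data frame with columns `chrom`, `start0`, `end0`
#'   (0-based half-open, e.g. rows of [make_windows()]) and optionally
#'   `weight`; `NULL` disables hotspot planting.
#' @param p_hotspot probability a circle originates in a hotspot window.
#' @param length_mean,length_sd truncated-normal length parameters in bp.
#' @param min_length lower truncation bound (default 200 bp).
#' @param seed integer seed.
#' @return list with `seqs` (named DNAStringSet of circle sequences) and
#'   `truth` (data frame: `circle_id`, `chrom`, `start0`, `end0`, `strand`,
#'   `length`, `hotspot_window` — the planted window id or NA — and
#'   comma-separated `carried_features` / `carried_genes` fully contained in
#'   the source interval).
#' @export
sim_ecc_population <- function(genome, features = NULL, n_circles,
                               hotspot_windows = NULL, p_hotspot = 0.5,
                               length_mean = 4905, length_sd = 1500,
                               min_length = 200, seed = 1) {
  stopifnot(length_mean > 0, length_sd >= 0, p_hotspot >= 0, p_hotspot <= 1)
  seqs <- as_genome_seqs(genome)
  if (is.null(features) && inherits(genome, "toy_genome"))
    features <- genome$features
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))

  empty <- list(
    seqs = Biostrings::DNAStringSet(),
    truth = data.frame(circle_id = character(), chrom = character(),
                       start0 = integer(), end0 = integer(),
                       strand = character(), length = integer(),
                       hotspot_window = character(),
                       carried_features = character(),
                       carried_genes = character(),
                       stringsAsFactors = FALSE))
  if (n_circles == 0) return(empty)

  use_hot <- !is.null(hotspot_windows) && nrow(hotspot_windows) > 0
  if (use_hot) {
    w <- if ("weight" %in% names(hotspot_windows)) hotspot_windows$weight
         else rep(1, nrow(hotspot_windows))
    stopifnot(all(w >= 0), any(w > 0))
    bad <- hotspot_windows$end0 > lens[hotspot_windows$chrom]
    if (any(bad))
      stop("hotspot window(s) extend beyond their chromosome: ",
           paste(hotspot_windows$chrom[bad], collapse = ", "),
           " (chromosome shorter than the requested window)")
  }

  with_seed(seed, {
    n <- n_circles
    from_hot <- if (use_hot) stats::runif(n) < p_hotspot else rep(FALSE, n)
    chrom <- character(n)
    mid <- numeric(n)
    hot_id <- rep(NA_character_, n)
    if (any(from_hot)) {
      wi <- sample.int(nrow(hotspot_windows), sum(from_hot), replace = TRUE,
                       prob = w)
      chrom[from_hot] <- hotspot_windows$chrom[wi]
      mid[from_hot] <- floor(stats::runif(sum(from_hot),
                                          hotspot_windows$start0[wi],
                                          hotspot_windows$end0[wi]))
      hot_id[from_hot] <- sprintf("%s:%d-%d", hotspot_windows$chrom[wi],
                                  hotspot_windows$start0[wi],
                                  hotspot_windows$end0[wi])
    }
    if (any(!from_hot)) {
      ci <- sample(names(lens), sum(!from_hot), replace = TRUE, prob = lens)
      chrom[!from_hot] <- ci
      mid[!from_hot] <- floor(stats::runif(sum(!from_hot), 0, lens[ci]))
    }
    len <- round(stats::rnorm(n, length_mean, length_sd))
    while (any(len < min_length))
      len[len < min_length] <- round(stats::rnorm(sum(len < min_length),
                                                  length_mean, length_sd))
    len <- pmin(len, lens[chrom])
    start0 <- pmax(0, pmin(round(mid - len / 2), lens[chrom] - len))
    end0 <- start0 + len
    strand <- sample(c("+", "-"), n, replace = TRUE)

    circle_seq <- substring(as.character(seqs[chrom]), start0 + 1, end0)
    neg <- strand == "-"
    if (any(neg))
      circle_seq[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(circle_seq[neg])))
    ids <- sprintf("circle_%05d", seq_len(n))

    carried <- rep("", n)
    carried_genes <- rep("", n)
    if (!is.null(features) && length(features)) {
      nonrep <- features[!startsWith(S4Vectors::mcols(features)$kind, "repeat:")]
      src <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
      ov <- GenomicRanges::findOverlaps(nonrep, src, type = "within",
                                        ignore.strand = TRUE)
      if (length(ov)) {
        ids_by_circle <- split(S4Vectors::mcols(nonrep)$id[S4Vectors::queryHits(ov)],
                               S4Vectors::subjectHits(ov))
        kinds_by_circle <- split(S4Vectors::mcols(nonrep)$kind[S4Vectors::queryHits(ov)],
                                 S4Vectors::subjectHits(ov))
        for (s in names(ids_by_circle)) {
          i <- as.integer(s)
          carried[i] <- paste(ids_by_circle[[s]], collapse = ",")
          g <- ids_by_circle[[s]][kinds_by_circle[[s]] == "gene"]
          carried_genes[i] <- paste(g, collapse = ",")
        }
      }
    }

    out_seqs <- Biostrings::DNAStringSet(stats::setNames(circle_seq, ids))
    list(seqs = out_seqs,
         truth = data.frame(circle_id = ids, chrom = chrom,
                            start0 = as.integer(start0),
                            end0 = as.integer(end0),
                            strand = strand, length = as.integer(len),
                            hotspot_window = hot_id,
                            carried_features = carried,
                            carried_genes = carried_genes,
                            stringsAsFactors = FALSE))
  })
}

# Apply iid substitution/insertion/deletion errors to one sequence.
mutate_seq <- function(s, rate, mix = c(sub = 8, ins = 1, del = 1)) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  idx <- which(stats::runif(n) < rate)
  if (!length(idx)) return(s)
  type <- sample(c("sub", "ins", "del"), length(idx), replace = TRUE,
                 prob = mix)
  piece <- v
  subs <- idx[type == "sub"]
  if (length(subs)) {
    cur <- match(v[subs], DNA_BASES)
    piece[subs] <- DNA_BASES[((cur - 1L + sample.int(3L, length(subs),
                                                     replace = TRUE)) %% 4L) + 1L]
  }
  ins <- idx[type == "ins"]
  if (length(ins))
    piece[ins] <- paste0(piece[ins],
                         sample(DNA_BASES, length(ins), replace = TRUE))
  piece[idx[type == "del"]] <- ""
  paste(piece, collapse = "")
}

#' Simulate rolling-circle-amplification concatemer reads
#'
#' Each read is its circle's monomer repeated `c` times (`c` uniform in
#' `[copy_min, copy_max]`, fractional tail allowed), starting at a uniform
#' random rotation, with iid substitution/insertion/deletion errors. The read
#' header carries the source circle id and copy number for truth lookup.
#'
#' @param circles named DNAStringSet or character vector of circle monomers.
#' @param copy_min,copy_max copy-number range, `1 <= copy_min <= copy_max`.
#' @param error_rate per-base error probability in `[0, 0.1)`.
#' @param error_mix relative weights of substitution, insertion and deletion
#'   events (default 8:1:1).
#' @param seed integer seed. Structural draws (copies, rotations) are made
#'   before any error draws, so the same seed with `error_rate = 0` yields the
#'   error-free counterparts of the same reads.
#' @return a named DNAStringSet; names are
#'   `read_<n> circle=<circle_id> copies=<c>`.
#' @export
sim_concatemer_reads <- function(circles, copy_min = 1.5, copy_max = 8,
                                 error_rate = 0.01,
                                 error_mix = c(sub = 8, ins = 1, del = 1),
                                 seed = 1) {
  stopifnot(copy_min >= 1, copy_min <= copy_max,
            error_rate >= 0, error_rate < 0.1)
  mono <- if (is.character(circles)) circles else as.character(circles)
  ids <- names(mono)
  if (is.null(ids)) ids <- sprintf("circle_%05d", seq_along(mono))
  n <- length(mono)
  if (n == 0) return(Biostrings::DNAStringSet())
  with_seed(seed, {
    L <- nchar(mono)
    copies <- stats::runif(n, copy_min, copy_max)
    rot <- floor(stats::runif(n, 0, L))
    reads <- character(n)
    for (i in seq_len(n)) {
      rotated <- paste0(substr(mono[i], rot[i] + 1L, L[i]),
                        substr(mono[i], 1L, rot[i]))
      read_len <- round(copies[i] * L[i])
      tandem <- strrep(rotated, ceiling(copies[i]) + 1L)
      reads[i] <- mutate_seq(substr(tandem, 1L, read_len), error_rate,
                             error_mix)
    }
    names(reads) <- sprintf("read_%05d circle=%s copies=%.3f",
                            seq_len(n), ids, copies)
    Biostrings::DNAStringSet(reads)
  })
}

#' Simulate a TMM expression table with planted dosage effects
#'
#' Emulates the correlation structure the integration rules are designed to
#' detect: a chosen fraction of genes that sit on eccDNA in exactly one
#' condition receive a multiplicative abundance boost (`planted_fold`) in that
#' condition only; all entries then get log-normal noise; a configurable
#' fraction of genes is kept below the low-expression floor (TMM < 2) in all
#' conditions to exercise the filter. Optionally plants differentially
#' expressed genes (|log2FC| >= 2) in the second condition, with a smaller
#' subset persisting into the final condition, to give the DE-thresholding and
#' net-change operations end-to-end signal.
#'
#' @param gene_ids character vector of all gene ids (the expression universe).
#' @param presence named list, one character vector of eccDNA-carried gene ids
#'   per condition; all must appear in `gene_ids`.
#' @param dosage_fraction fraction of single-condition-exclusive eccDNA genes
#'   that receive the planted fold.
#' @param planted_fold multiplicative boost, must be >= 1.2.
#' @param noise_cv coefficient of variation of the log-normal noise.
#' @param low_expr_fraction fraction of genes held below TMM 2 everywhere.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline parameters for
#'   expressed genes (resampled to stay above TMM 2.5).
#' @param de_fraction,de_log2fc_range,net_de_fraction optional planted DE:
#'   `de_fraction` of non-dosage genes get +/- log2FC drawn from
#'   `de_log2fc_range` in condition 2; `net_de_fraction` get it in the final
#'   condition (a net change versus baseline). Both default to 0.
#' @param conditions condition names; defaults to `names(presence)`.
#' @param seed integer seed.
#' @return list with `tmm` (gene x condition numeric matrix) and `truth`
#'   (data frame: `gene_id`, `baseline`, `low_expr`, `dosage_gene`,
#'   `boosted_condition`, `planted_fold`, `de_condition`, `de_log2fc`).
#' @export
sim_expression_table <- function(gene_ids, presence, dosage_fraction = 0.5,
                                 planted_fold = 1.5, noise_cv = 0.05,
                                 low_expr_fraction = 0.1,
                                 baseline_log_mean = log(20),
                                 baseline_log_sd = 1,
                                 de_fraction = 0, de_log2fc_range = c(2.2, 5),
                                 net_de_fraction = 0,
                                 conditions = names(presence), seed = 1) {
  stopifnot(planted_fold >= 1.2, length(conditions) >= 2,
            noise_cv >= 0, dosage_fraction >= 0, dosage_fraction <= 1)
  missing_genes <- setdiff(unique(unlist(presence)), gene_ids)
  if (length(missing_genes))
    stop("presence refers to gene(s) absent from the feature set: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  n <- length(gene_ids)
  C <- length(conditions)

  with_seed(seed, {
    low <- rep(FALSE, n)
    low[sample.int(n, round(low_expr_fraction * n))] <- TRUE
    baseline <- numeric(n)
    baseline[low] <- stats::runif(sum(low), 0.2, 1.5)
    hi <- which(!low)
    b <- stats::rlnorm(length(hi), baseline_log_mean, baseline_log_sd)
    while (any(b < 2.5))
      b[b < 2.5] <- stats::rlnorm(sum(b < 2.5), baseline_log_mean,
                                  baseline_log_sd)
    baseline[hi] <- b

    tmm <- matrix(baseline, n, C, dimnames = list(gene_ids, conditions))

    in_cond <- vapply(presence[conditions], function(s) gene_ids %in% s,
                      logical(n))
    n_present <- rowSums(in_cond)
    exclusive <- which(n_present == 1L)
    excl_cond <- rep(NA_character_, n)
    excl_cond[exclusive] <- conditions[max.col(in_cond[exclusive, , drop = FALSE])]

    dosage <- rep(FALSE, n)
    if (length(exclusive) && dosage_fraction > 0) {
      pick <- sample(exclusive, round(dosage_fraction * length(exclusive)))
      dosage[pick] <- TRUE
      for (i in pick) tmm[i, excl_cond[i]] <- tmm[i, excl_cond[i]] * planted_fold
    }

    de_cond <- rep(NA_character_, n)
    de_fc <- rep(NA_real_, n)
    plant_de <- function(frac, cond_idx, pool) {
      if (frac <= 0 || !length(pool)) return(integer(0))
      pick <- sample(pool, min(length(pool), round(frac * n)))
      sgn <- rep_len(c(1, -1), length(pick))
      fc <- sgn * stats::runif(length(pick), de_log2fc_range[1],
                               de_log2fc_range[2])
      tmm[pick, cond_idx] <<- tmm[pick, cond_idx] * 2^fc
      de_cond[pick] <<- conditions[cond_idx]
      de_fc[pick] <<- fc
      pick
    }
    pool <- setdiff(which(!dosage & !low), integer(0))
    used <- plant_de(de_fraction, 2L, pool)
    if (C >= 3) plant_de(net_de_fraction, C, setdiff(pool, used))

    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      tmm <- tmm * matrix(stats::rlnorm(n * C, -sdlog^2 / 2, sdlog), n, C)
    }

    list(tmm = tmm,
         truth = data.frame(gene_id = gene_ids, baseline = baseline,
                            low_expr = low, dosage_gene = dosage,
                            boosted_condition = ifelse(dosage, excl_cond, NA),
                            planted_fold = ifelse(dosage, planted_fold, NA),
                            de_condition = de_cond, de_log2fc = de_fc,
                            stringsAsFactors = FALSE))
  })
}
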