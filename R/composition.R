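# Structural annotation of circles (feature transfer through the genomic
# hit, sequence-level rDNA/ORI homology calls, GC and repeat accounting) and
# the per-condition composition summary.

#' GC content of a DNA sequence
#'
#' `(#G + #C) / length`. Ambiguous bases count in the denominator only; a
#' sequence with no unambiguous base is rejected.
#'
#' @param seq DNA string (character scalar or DNAString).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(seq) {
  s <- if (is.character(seq)) Biostrings::DNAString(seq) else seq
  n <- length(s)
  if (n == 0) stop("empty sequence")
  fr <- Biostrings::letterFrequency(s, DNA_BASES)
  if (sum(fr) == 0) stop("sequence has no unambiguous bases")
  unname((fr[["C"]] + fr[["G"]]) / n)
}

#' Homology calls against a sequence database
#'
#' Local-alignment screen of a circle against a database of reference
#' sequences (e.g. origins of replication or rDNA genes). A database entry
#' matches when its best local alignment on the circle (either strand) reaches
#' `min_identity` over at least `min_coverage` of the entry's length. Entries
#' sharing no exact k-mer with the circle are skipped without alignment.
#'
#' @param circle DNA string (character scalar).
#' @param db named character vector or DNAStringSet of database sequences,
#'   each at least 100 bp.
#' @param min_identity identity threshold (default 0.95).
#' @param min_coverage minimum aligned fraction of the database entry
#'   (default 0.8).
#' @param prefilter_k k-mer size of the exact-match prefilter. An entry is
#'   aligned only when at least `min_coverage / 2` of its k-mers occur in the
#'   circle: a true match at the identity threshold shares well over half of
#'   its k-mers, while sub-coverage overlaps are skipped cheaply.
#' @return character vector of matching database ids (empty for an empty db).
#' @export
homology_call <- function(circle, db, min_identity = 0.95,
                          min_coverage = 0.8, prefilter_k = 12) {
  dbs <- if (is.character(db)) db else as.character(db)
  if (!length(dbs)) return(character(0))
  stopifnot(all(nchar(dbs) >= 100))
  ids <- names(dbs)
  if (is.null(ids)) ids <- sprintf("db_%04d", seq_along(dbs))
  strands <- c(circle, revcomp_chr(circle))
  ckmers <- unique(c(kmer_codes(strands[1], prefilter_k),
                     kmer_codes(strands[2], prefilter_k)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  hits <- character(0)
  for (i in seq_along(dbs)) {
    dk <- kmer_codes(dbs[i], prefilter_k)
    dk <- dk[!is.na(dk)]
    if (mean(dk %in% ckmers) < min_coverage / 2) next
    for (s in strands) {
      aln <- Biostrings::pairwiseAlignment(
        dbs[i], s, type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      pr <- Biostrings::pattern(aln)
      cov <- (Biostrings::end(pr) - Biostrings::start(pr) + 1) / nchar(dbs[i])
      ident <- Biostrings::pid(aln, type = "PID1") / 100
      if (ident >= min_identity && cov >= min_coverage) {
        hits <- c(hits, ids[i])
        break
      }
    }
  }
  hits
}

#' Annotate circles with reference features through their genomic hits
#'
#' Transfers annotations from the reference feature set onto each circle via
#' its best genomic placement: genes and tRNAs must be fully contained in the
#' hit interval; repeat intervals are intersected with the hit and accounted
#' per class (element count and base pairs, plus the per-circle union of
#' masked bases across classes). rDNA and ORI status come from the sequence-
#' level homology rule ([homology_call()]), not from interval transfer. GC is
#' computed from the circle sequence itself, so unplaced circles still get GC
#' (with empty annotations otherwise).
#'
#' @param circles named character vector or DNAStringSet.
#' @param hits data frame from [locate_circles()] covering these circles.
#' @param features [GenomicRanges::GRanges] with `kind` and `id` metadata
#'   (kinds `gene`, `tRNA`, and `repeat:<class>` are used here).
#' @param ori_db,rdna_db optional homology databases (see [homology_call()]).
#' @param min_identity identity threshold of the homology rule (default 0.95).
#' @return list with `records` (one row per circle: `circle_id`, `length`,
#'   `gc`, `placed`, `n_genes`, `gene_ids`, `n_trnas`, `trna_ids`, `rdna`,
#'   `ori`, `repeat_masked_bp`) and `repeat_classes` (long data frame:
#'   `circle_id`, `class`, `n_elements`, `bp`).
#' @export
annotate_circles <- function(circles, hits, features, ori_db = NULL,
                             rdna_db = NULL, min_identity = 0.95) {
  seqs <- if (is.character(circles)) circles else as.character(circles)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("circle_%05d", seq_along(seqs))
  hits <- hits[match(ids, hits$circle_id), , drop = FALSE]
  stopifnot(!anyNA(hits$circle_id))
  n <- length(seqs)

  gc <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
  rec <- data.frame(circle_id = ids, length = nchar(seqs), gc = gc,
                    placed = hits$placed, n_genes = 0L, gene_ids = "",
                    n_trnas = 0L, trna_ids = "", rdna = FALSE, ori = FALSE,
                    repeat_masked_bp = 0L, stringsAsFactors = FALSE)
  rep_classes <- data.frame(circle_id = character(), class = character(),
                            n_elements = integer(), bp = integer(),
                            stringsAsFactors = FALSE)

  pl <- which(hits$placed)
  if (length(pl) && length(features)) {
    hg <- GenomicRanges::GRanges(hits$chrom[pl],
                                 IRanges::IRanges(hits$start0[pl] + 1,
                                                  hits$end0[pl]))
    kind <- S4Vectors::mcols(features)$kind
    fid <- S4Vectors::mcols(features)$id

    transfer <- function(sel_kind, count_col, id_col) {
      sub <- features[kind == sel_kind]
      ov <- GenomicRanges::findOverlaps(sub, hg, type = "within",
                                        ignore.strand = TRUE)
      if (length(ov)) {
        byc <- split(S4Vectors::mcols(sub)$id[S4Vectors::queryHits(ov)],
                     S4Vectors::subjectHits(ov))
        for (s in names(byc)) {
          i <- pl[as.integer(s)]
          rec[[count_col]][i] <<- length(byc[[s]])
          rec[[id_col]][i] <<- paste(sort(byc[[s]]), collapse = ",")
        }
      }
    }
    transfer("gene", "n_genes", "gene_ids")
    transfer("tRNA", "n_trnas", "trna_ids")

    is_rep <- startsWith(kind, "repeat:")
    if (any(is_rep)) {
      rg <- features[is_rep]
      rcls <- sub("^repeat:", "", kind[is_rep])
      ov <- GenomicRanges::findOverlaps(rg, hg, ignore.strand = TRUE)
      if (length(ov)) {
        q <- S4Vectors::queryHits(ov)
        s <- S4Vectors::subjectHits(ov)
        inter <- GenomicRanges::pintersect(rg[q], hg[s], ignore.strand = TRUE)
        w <- GenomicRanges::width(inter)
        key <- paste(s, rcls[q], sep = "\r")
        agg_n <- tapply(rep(1L, length(key)), key, sum)
        agg_bp <- tapply(w, key, sum)
        parts <- strsplit(names(agg_n), "\r", fixed = TRUE)
        rep_classes <- data.frame(
          circle_id = ids[pl[as.integer(vapply(parts, `[`, "", 1))]],
          class = vapply(parts, `[`, "", 2),
          n_elements = as.integer(agg_n), bp = as.integer(agg_bp),
          stringsAsFactors = FALSE)
        # per-circle union of masked bases across all classes
        st <- GenomicRanges::start(inter)
        en <- GenomicRanges::end(inter)
        for (si in unique(s)) {
          sel <- s == si
          rec$repeat_masked_bp[pl[si]] <- union_width(st[sel], en[sel])
        }
      }
    }
  }

  screen <- function(dbset, col) {
    if (is.null(dbset) || !length(dbset)) return()
    for (i in seq_len(n)) {
      if (length(homology_call(seqs[i], dbset, min_identity = min_identity)))
        rec[[col]][i] <<- TRUE
    }
  }
  screen(ori_db, "ori")
  screen(rdna_db, "rdna")

  rownames(rec) <- NULL
  list(records = rec, repeat_classes = rep_classes)
}

#' Total interspersed-repeat base pairs
#'
#' Sum of the SINE, LINE, LTR, DNA-element and unclassified class totals (the
#' tandem/simple/low-complexity/satellite/small-RNA classes are excluded, as
#' in standard repeat-masking reports).
#'
#' @param class_bp named numeric vector of per-class base-pair totals.
#' @return total interspersed-repeat bp.
#' @export
interspersed_repeat_total <- function(class_bp) {
  sum(class_bp[names(class_bp) %in% INTERSPERSED_CLASSES])
}

#' Per-condition structural composition summary
#'
#' Computes the standard per-condition summary of a clustered eccDNA
#' population: sequence counts before and after clustering, length maximum
#' and mean, pooled GC percentage, repeat-masked bases and fraction,
#' gene-/tRNA-bearing counts with percentages (over clustered sequences),
#' rDNA and ORI counts, and a per-repeat-class table (element count, bp,
#' percent of total pooled bases) with the interspersed-repeat total.
#'
#' @param annotation result of [annotate_circles()] for the clustered
#'   (post-collapse) circles of one condition.
#' @param n_raw number of circle sequences before clustering.
#' @param condition condition label.
#' @return an `ecc_composition` list; see Details for the fields.
#' @export
summarize_condition <- function(annotation, n_raw, condition = NA) {
  rec <- annotation$records
  rcl <- annotation$repeat_classes
  n <- nrow(rec)
  total_bp <- sum(rec$length)
  by_class <- if (nrow(rcl)) {
    data.frame(class = sort(unique(rcl$class)), stringsAsFactors = FALSE)
  } else data.frame(class = character(), stringsAsFactors = FALSE)
  if (nrow(by_class)) {
    by_class$n_elements <- vapply(by_class$class, function(cl)
      sum(as.numeric(rcl$n_elements[rcl$class == cl])), numeric(1))
    by_class$bp <- vapply(by_class$class, function(cl)
      sum(as.numeric(rcl$bp[rcl$class == cl])), numeric(1))
    by_class$pct_total_bases <- round_half_away(
      if (total_bp > 0) 100 * by_class$bp / total_bp else rep(0, nrow(by_class)), 2)
  } else {
    by_class$n_elements <- integer(0)
    by_class$bp <- integer(0)
    by_class$pct_total_bases <- numeric(0)
  }
  class_bp <- stats::setNames(by_class$bp, by_class$class)
  masked <- sum(rec$repeat_masked_bp)
  structure(list(
    condition = condition,
    n_sequences = n_raw,
    n_clustered = n,
    max_len = if (n) max(rec$length) else 0L,
    mean_len = if (n) round_half_away(mean(rec$length), 0) else 0,
    repeat_bp = masked,
    repeat_pct = pct_round(masked, total_bp),
    gc_pct = if (total_bp > 0)
      round_half_away(100 * sum(rec$gc * rec$length) / total_bp, 1) else 0,
    n_with_genes = sum(rec$n_genes > 0),
    pct_with_genes = pct_round(sum(rec$n_genes > 0), n),
    n_with_rdna = sum(rec$rdna),
    n_with_trna = sum(rec$n_trnas > 0),
    pct_with_trna = pct_round(sum(rec$n_trnas > 0), n),
    n_ori_ge95 = sum(rec$ori),
    repeat_class_table = by_class,
    interspersed_bp = interspersed_repeat_total(class_bp),
    interspersed_pct = pct_round(interspersed_repeat_total(class_bp), total_bp),
    total_bases = total_bp), class = "ecc_composition")
}

#' @export
print.ecc_composition <- function(x, ...) {
  cat(sprintf(
    paste0("ecc_composition [%s]: %d sequences -> %d clustered, mean length ",
           "%s bp, GC %.1f%%, %d (%s%%) with genes, %d (%s%%) with tRNA, ",
           "%d rDNA, %d ORI\n"),
    x$condition, x$n_sequences, x$n_clustered,
    format(x$mean_len, big.mark = ","), x$gc_pct,
    x$n_with_genes, x$pct_with_genes, x$n_with_trna, x$pct_with_trna,
    x$n_with_rdna, x$n_ori_ge95))
  invisible(x)
}

#' One-row data frame view of a composition summary
#'
#' @param x an `ecc_composition`.
#' @param ... unused.
#' @return one-row data frame of the scalar fields.
#' @method as.data.frame ecc_composition
#' @export
as.data.frame.ecc_composition <- function(x, ...) {
  data.frame(condition = x$condition, n_sequences = x$n_sequences,
             n_clustered = x$n_clustered, max_len = x$max_len,
             mean_len = x$mean_len, repeat_bp = x$repeat_bp,
             repeat_pct = x$repeat_pct, gc_pct = x$gc_pct,
             n_with_genes = x$n_with_genes,
             pct_with_genes = x$pct_with_genes,
             n_with_rdna = x$n_with_rdna, n_with_trna = x$n_with_trna,
             pct_with_trna = x$pct_with_trna, n_ori_ge95 = x$n_ori_ge95,
             interspersed_bp = x$interspersed_bp,
             interspersed_pct = x$interspersed_pct,
             total_bases = x$total_bases, stringsAsFactors = FALSE)
}
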