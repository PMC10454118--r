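# Integration of eccDNA gene content with expression: cross-condition set
# overlaps, the fold-change correlation rule for eccDNA-exclusive genes, and
# log2 fold-change thresholding including the endpoint ("net change") view.

#' Venn region counts for per-condition gene sets
#'
#' Counts every non-empty intersection region of the given sets, the union,
#' and the number of elements present in more than one set.
#'
#' @param gene_sets named list (>= 2 elements) of character vectors.
#' @return list with `regions` (named counts; names join set names with `&`
#'   for elements exclusive to exactly that combination), `union`,
#'   `multiple` (elements in 2+ sets), `per_set` (set sizes).
#' @examples
#' venn_counts(list(A = c("1", "2"), B = c("2", "3"), C = "3"))
#' @export
venn_counts <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2, !is.null(names(gene_sets)))
  sets <- lapply(gene_sets, unique)
  conds <- names(sets)
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, conds))
  combos <- unlist(lapply(seq_along(conds), function(m)
    utils::combn(conds, m, paste, collapse = "&", simplify = FALSE)))
  regions <- stats::setNames(integer(length(combos)), combos)
  if (length(all_genes)) {
    key <- apply(memb, 1, function(r) paste(conds[r], collapse = "&"))
    tab <- table(key)
    regions[names(tab)] <- as.integer(tab)
  }
  list(regions = regions,
       union = length(all_genes),
       multiple = if (length(all_genes)) sum(rowSums(memb) >= 2) else 0L,
       per_set = vapply(sets, length, integer(1)))
}

#' Fold difference between two abundances
#'
#' Symmetric fold `max(a, b) / min(a, b)`, reported to two decimals, so a
#' decrease and an increase of the same size give the same fold.
#'
#' @param tmm_a,tmm_b positive abundances (e.g. TMM values).
#' @return fold >= 1, rounded to 2 decimals; NA with a warning when either
#'   value is not positive.
#' @examples
#' fold_difference(9.11, 7.76)  # 1.17
#' @export
fold_difference <- function(tmm_a, tmm_b) {
  out <- numeric(length(tmm_a))
  bad <- !(tmm_a > 0 & tmm_b > 0)
  if (any(bad)) {
    warning("non-positive abundance: fold undefined for ", sum(bad),
            " gene(s)")
    out[bad] <- NA_real_
  }
  ok <- !bad
  out[ok] <- round_half_away(pmax(tmm_a[ok], tmm_b[ok]) /
                               pmin(tmm_a[ok], tmm_b[ok]), 2)
  out
}

#' Correlate eccDNA gene presence with transcript abundance
#'
#' A gene passes when (i) it sits on eccDNA in exactly one condition, (ii) its
#' abundance in that condition is at least `min_fold` times its abundance in
#' the other conditions, and (iii) it is not lowly expressed (TMM below
#' `low_expr_floor` in every condition). With `compare = "all"` (default) the
#' fold criterion must hold against every other condition; `compare = "any"`
#' relaxes it to at least one. For genes exclusive to the baseline
#' (first-listed) condition the criterion reads as a reduction in the later
#' conditions relative to baseline; `baseline_compare = "next"` restricts
#' that comparison to the immediately following condition only.
#'
#' @param presence named list of per-condition eccDNA gene-id vectors.
#' @param tmm gene x condition numeric matrix (rownames are gene ids) whose
#'   columns cover the presence conditions.
#' @param min_fold fold threshold (default 1.2).
#' @param low_expr_floor TMM floor (default 2).
#' @param compare `"all"` or `"any"` (see above).
#' @param baseline_compare `"all"` or `"next"` (see above).
#' @return data frame with one row per gene in the union of the presence
#'   sets: `gene_id`, `n_conditions_present`, `exclusive_condition`,
#'   `min_fold_vs_others`, `max_tmm`, `passes`, `reason` for excluded genes.
#' @export
correlate_ecc_expression <- function(presence, tmm, min_fold = 1.2,
                                     low_expr_floor = 2,
                                     compare = c("all", "any"),
                                     baseline_compare = c("all", "next")) {
  compare <- match.arg(compare)
  baseline_compare <- match.arg(baseline_compare)
  conds <- names(presence)
  stopifnot(length(conds) >= 2, all(conds %in% colnames(tmm)))
  genes <- sort(unique(unlist(presence)))
  eps <- 1e-9

  out <- data.frame(gene_id = genes,
                    n_conditions_present = 0L,
                    exclusive_condition = NA_character_,
                    min_fold_vs_others = NA_real_,
                    max_tmm = NA_real_,
                    passes = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  missing <- !(genes %in% rownames(tmm))
  if (any(missing)) {
    warning(sum(missing), " eccDNA gene(s) absent from the expression ",
            "matrix were excluded")
    out$reason[missing] <- "absent_from_expression"
  }
  for (i in which(!missing)) {
    g <- genes[i]
    pres <- vapply(presence, function(s) g %in% s, logical(1))
    out$n_conditions_present[i] <- sum(pres)
    vals <- tmm[g, conds]
    out$max_tmm[i] <- max(vals)
    if (any(vals <= 0)) {
      warning("gene ", g, " has a non-positive TMM value; excluded")
      out$reason[i] <- "non_positive_tmm"
      next
    }
    if (sum(pres) != 1L) {
      out$reason[i] <- if (sum(pres) == 0) "not_present" else "not_exclusive"
      next
    }
    cexc <- conds[pres]
    out$exclusive_condition[i] <- cexc
    if (all(vals < low_expr_floor)) {
      out$reason[i] <- "low_expression"
      next
    }
    others <- setdiff(conds, cexc)
    if (cexc == conds[1] && baseline_compare == "next")
      others <- conds[2]
    folds <- vals[cexc] / vals[others]
    out$min_fold_vs_others[i] <- min(folds)
    ok <- if (compare == "all") all(folds >= min_fold - eps)
          else any(folds >= min_fold - eps)
    if (ok) out$passes[i] <- TRUE else out$reason[i] <- "below_fold"
  }
  out
}

#' Classify genes by log2 fold change
#'
#' Thresholds a per-gene log2 fold-change table into up- and downregulated
#' sets: `up` when log2FC >= `threshold`, `down` when <= `-threshold`,
#' otherwise `none`. Non-finite values are rejected per gene with a warning.
#'
#' @param log2fc named numeric vector (names are gene ids), or a data frame
#'   whose first two columns are gene id and log2FC.
#' @param threshold log2FC magnitude threshold (default 2).
#' @return data frame `gene_id`, `log2fc`, `direction` (`up`/`down`/`none`);
#'   rejected genes are dropped.
#' @examples
#' de_classify(c(Rras = 3.06, Brca1 = -2.71, x = -1.99))
#' @export
de_classify <- function(log2fc, threshold = 2) {
  if (is.data.frame(log2fc))
    log2fc <- stats::setNames(log2fc[[2]], log2fc[[1]])
  bad <- !is.finite(log2fc)
  if (any(bad)) {
    warning("dropped ", sum(bad), " gene(s) with non-finite log2FC: ",
            paste(utils::head(names(log2fc)[bad], 5), collapse = ", "))
    log2fc <- log2fc[!bad]
  }
  direction <- ifelse(log2fc >= threshold, "up",
                      ifelse(log2fc <= -threshold, "down", "none"))
  data.frame(gene_id = names(log2fc), log2fc = unname(log2fc),
             direction = direction, stringsAsFactors = FALSE)
}

#' Net differential expression between endpoint and baseline
#'
#' Applies the log2FC threshold to an endpoint-versus-baseline contrast and
#' reports the net-change gene set split by direction.
#'
#' @param log2fc endpoint-vs-baseline log2FC table (see [de_classify()]).
#' @param threshold log2FC magnitude threshold (default 2).
#' @return list with `genes` (all passing), `up`, `down`, `n_up`, `n_down`.
#' @export
net_change <- function(log2fc, threshold = 2) {
  d <- de_classify(log2fc, threshold)
  up <- d$gene_id[d$direction == "up"]
  down <- d$gene_id[d$direction == "down"]
  list(genes = c(up, down), up = up, down = down,
       n_up = length(up), n_down = length(down))
}
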