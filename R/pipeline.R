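# End-to-end orchestration: simulate inputs (optional), deconcatenate reads,
# cluster circles, place and bin them, summarize composition, and integrate
# with expression — one condition at a time, with a machine-readable report.

#' Default pipeline configuration
#'
#' Study-condition defaults: a three-chromosome 15-Mb toy genome at GC 0.405
#' with 38 percent repeat coverage (30 windows at the 500-kbp width, enough
#' for hotspot Z-scores to be meaningful); three lactate-adaptation
#' conditions with 1000 circles each at mean lengths 4905 / 4976 / 5515 bp;
#' three planted hotspot windows shared across conditions with half of all
#' circles arising from them; concatemer reads at 1.5-8 copies and 1 percent
#' error; TMM tables with 1.5-fold dosage planting at 5 percent noise.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(chrom_lengths = c(chr1 = 6e6, chr2 = 5e6, chr3 = 4e6),
                  gc = 0.405, repeat_fraction = 0.38),
    circles = list(
      n = c(unadapted = 1000, lactate_30mM = 1000, lactate_60mM = 1000),
      length_mean = c(unadapted = 4905, lactate_30mM = 4976,
                      lactate_60mM = 5515),
      length_sd = 1500, p_hotspot = 0.5, n_hotspot_windows = 3),
    reads = list(copy_min = 1.5, copy_max = 8, error_rate = 0.01),
    expression = list(dosage_fraction = 0.5, planted_fold = 1.5,
                      noise_cv = 0.05, low_expr_fraction = 0.1,
                      de_fraction = 0.05, net_de_fraction = 0.01),
    params = list(k_period = 15, min_copies = 1.5, min_period_score = 0.8,
                  junction_frac = 0.6, identity = 0.90, width = 5e5,
                  z_min = 2, top_n = 15, min_fold = 1.2, floor = 2,
                  min_votes = 5))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  for (nm in c("chrom_lengths"))
    if (!is.null(cfg$genome[[nm]])) cfg$genome[[nm]] <- unlist(cfg$genome[[nm]])
  for (nm in c("n", "length_mean"))
    if (!is.null(cfg$circles[[nm]])) cfg$circles[[nm]] <- unlist(cfg$circles[[nm]])
  cfg
}

#' Run the full synthetic-to-integration pipeline
#'
#' Executes simulate -> deconcatenate -> cluster -> place/bin/hotspots ->
#' composition -> expression integration for every condition, writing all
#' intermediates under `out_dir` and returning a run report whose counts are
#' internally consistent (clusters <= circular candidates; window counts sum
#' to placed circles). A failure in one condition is recorded in the report
#' without aborting the others; setting `config$expression` to `NULL` skips
#' the integration stage with a note.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed optional master-seed override.
#' @return the run report (list), invisibly; also written as
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("eccpipe_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- if (is.null(config)) default_pipeline_config()
         else utils::modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  conds <- names(cfg$circles$n)
  report <- list(seed = cfg$seed, parameters = p, conditions = list(),
                 notes = character(0))

  # --- simulate the shared reference -------------------------------------
  tg <- sim_genome(cfg$genome$chrom_lengths, gc = cfg$genome$gc,
                   repeat_fraction = cfg$genome$repeat_fraction,
                   seed = cfg$seed + 11L)
  write_genome_fasta(tg, file.path(out_dir, "genome.fasta"))
  write_features_bed(tg$features, file.path(out_dir, "features.bed"))
  write_features_gff3(tg$features, file.path(out_dir, "features.gff3"))
  windows <- make_windows(tg, width = p$width)

  full <- windows[windows$end0 - windows$start0 == p$width, , drop = FALSE]
  hot <- with_seed(cfg$seed + 7L, {
    full[sample.int(nrow(full), min(cfg$circles$n_hotspot_windows,
                                    nrow(full))), , drop = FALSE]
  })
  hot$weight <- 1
  write_tsv_file(hot, file.path(out_dir, "planted_hotspots.tsv"))

  # homology databases: the reference ORI and rDNA sequences themselves
  kind <- S4Vectors::mcols(tg$features)$kind
  extract_db <- function(sel) {
    sub <- tg$features[kind == sel]
    if (!length(sub)) return(NULL)
    ch <- as.character(GenomicRanges::seqnames(sub))
    s <- substring(as.character(tg$genome)[ch],
                   GenomicRanges::start(sub), GenomicRanges::end(sub))
    neg <- as.character(GenomicRanges::strand(sub)) == "-"
    if (any(neg))
      s[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[neg])))
    stats::setNames(s, S4Vectors::mcols(sub)$id)
  }
  ori_db <- extract_db("ORI")
  rdna_db <- extract_db("rDNA")

  gene_ids <- S4Vectors::mcols(tg$features)$id[kind == "gene"]
  truth_presence <- list()
  observed_presence <- list()
  summaries <- list()

  # --- per-condition stages ----------------------------------------------
  for (i in seq_along(conds)) {
    cond <- conds[i]
    res <- tryCatch({
      pop <- sim_ecc_population(
        tg, n_circles = cfg$circles$n[[cond]], hotspot_windows = hot,
        p_hotspot = cfg$circles$p_hotspot,
        length_mean = cfg$circles$length_mean[[cond]],
        length_sd = cfg$circles$length_sd, seed = cfg$seed + 100L + i)
      write_tsv_file(pop$truth, file.path(out_dir,
                                          sprintf("truth_%s.tsv", cond)))
      g <- strsplit(pop$truth$carried_genes[nzchar(pop$truth$carried_genes)],
                    ",", fixed = TRUE)
      truth_presence[[cond]] <- unique(unlist(g))

      reads <- sim_concatemer_reads(pop$seqs, copy_min = cfg$reads$copy_min,
                                    copy_max = cfg$reads$copy_max,
                                    error_rate = cfg$reads$error_rate,
                                    seed = cfg$seed + 200L + i)
      Biostrings::writeXStringSet(reads,
                                  file.path(out_dir,
                                            sprintf("reads_%s.fasta", cond)))

      dec <- deconcat_reads(reads, k = p$k_period,
                            min_period_score = p$min_period_score,
                            min_copies = p$min_copies,
                            junction_frac = p$junction_frac)
      dec$monomer_length <- nchar(dec$monomer)
      write_tsv_file(dec[, setdiff(names(dec), "monomer")],
                     file.path(out_dir, sprintf("deconcat_%s.tsv", cond)))
      circ <- dec[dec$circular, , drop = FALSE]
      monomers <- vapply(circ$monomer, canonical_rotation, "",
                         USE.NAMES = FALSE)
      names(monomers) <- circ$read_id

      cl <- greedy_cluster(monomers, identity_threshold = p$identity)
      write_tsv_file(cl, file.path(out_dir,
                                   sprintf("clusters_%s.tsv", cond)))
      reps <- monomers[cl$member_id[cl$is_representative]]
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(reps),
        file.path(out_dir, sprintf("circles_%s.fasta", cond)))

      hits <- locate_circles(reps, tg, min_votes = p$min_votes)
      write_tsv_file(hits, file.path(out_dir,
                                     sprintf("hits_%s.tsv", cond)))

      ann <- annotate_circles(reps, hits, tg$features,
                              ori_db = ori_db, rdna_db = rdna_db)
      write_tsv_file(ann$records,
                     file.path(out_dir, sprintf("annotation_%s.tsv", cond)))

      gene_flags <- stats::setNames(ann$records$n_genes > 0,
                                    ann$records$circle_id)
      wt <- bin_and_score(hits, windows, gene_flags, condition = cond)
      wtab <- wt$windows
      wtab$z <- round_half_away(wtab$z, 2)
      write_tsv_file(wtab, file.path(out_dir,
                                     sprintf("windows_%s.tsv", cond)))
      hs <- call_hotspots(wt, z_min = p$z_min, top_n = p$top_n)
      write_tsv_file(hs$top, file.path(out_dir,
                                       sprintf("top_windows_%s.tsv", cond)))

      comp <- summarize_condition(ann, n_raw = nrow(circ), condition = cond)
      summaries[[cond]] <- comp
      write_tsv_file(as.data.frame(comp),
                     file.path(out_dir, sprintf("composition_%s.tsv", cond)))
      write_tsv_file(comp$repeat_class_table,
                     file.path(out_dir,
                               sprintf("repeat_classes_%s.tsv", cond)))

      obs_genes <- unique(unlist(strsplit(
        ann$records$gene_ids[nzchar(ann$records$gene_ids)], ",",
        fixed = TRUE)))
      observed_presence[[cond]] <- if (is.null(obs_genes)) character(0)
                                   else obs_genes

      list(ok = TRUE,
           n_circles_simulated = length(pop$seqs),
           n_reads = length(reads),
           n_circular = nrow(circ),
           n_clusters = length(reps),
           n_placed = sum(hits$placed),
           n_unplaced = sum(!hits$placed),
           n_windows = nrow(windows),
           window_mean = wt$mean, window_sd = wt$sd,
           n_hotspots = nrow(hs$hotspots),
           top_window_count = if (nrow(hs$top)) hs$top$count[1] else 0L,
           top_window_z = if (nrow(hs$top)) hs$top$z[1] else NA_real_,
           n_genes_on_ecc = length(observed_presence[[cond]]),
           composition = as.data.frame(comp))
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    report$conditions[[cond]] <- res
  }

  # --- integration ---------------------------------------------------------
  ok_conds <- conds[vapply(report$conditions, function(x) isTRUE(x$ok),
                           logical(1))]
  if (is.null(cfg$expression)) {
    report$notes <- c(report$notes, "integrate skipped: no expression input")
  } else if (length(ok_conds) >= 2) {
    ex <- cfg$expression
    expr <- sim_expression_table(
      gene_ids, truth_presence[ok_conds],
      dosage_fraction = ex$dosage_fraction, planted_fold = ex$planted_fold,
      noise_cv = ex$noise_cv, low_expr_fraction = ex$low_expr_fraction,
      de_fraction = ex$de_fraction %||% 0,
      net_de_fraction = ex$net_de_fraction %||% 0,
      seed = cfg$seed + 53L)
    write_expression_tsv(expr$tmm, file.path(out_dir, "tmm.tsv"))
    write_tsv_file(expr$truth, file.path(out_dir, "expression_truth.tsv"))

    pres_df <- do.call(rbind, lapply(ok_conds, function(cd)
      if (length(observed_presence[[cd]]))
        data.frame(condition = cd, gene_id = observed_presence[[cd]],
                   stringsAsFactors = FALSE) else NULL))
    if (!is.null(pres_df))
      write_tsv_file(pres_df, file.path(out_dir, "presence.tsv"))

    vn <- venn_counts(observed_presence[ok_conds])
    corr <- correlate_ecc_expression(observed_presence[ok_conds], expr$tmm,
                                     min_fold = p$min_fold,
                                     low_expr_floor = p$floor)
    write_tsv_file(corr, file.path(out_dir, "correlation.tsv"))

    contrasts <- list()
    if (length(ok_conds) >= 2) {
      lfc <- function(a, b) log2(expr$tmm[, a] / expr$tmm[, b])
      for (j in 2:length(ok_conds)) {
        nm <- paste0(ok_conds[j], "_vs_", ok_conds[j - 1])
        d <- de_classify(lfc(ok_conds[j], ok_conds[j - 1]))
        write_tsv_file(d, file.path(out_dir, paste0("de_", nm, ".tsv")))
        contrasts[[nm]] <- list(n_up = sum(d$direction == "up"),
                                n_down = sum(d$direction == "down"))
      }
      nc <- net_change(lfc(ok_conds[length(ok_conds)], ok_conds[1]))
      contrasts[[paste0(ok_conds[length(ok_conds)], "_vs_", ok_conds[1],
                        "_net")]] <- list(n_up = nc$n_up, n_down = nc$n_down)
    }
    report$integration <- list(
      presence_sizes = vapply(observed_presence[ok_conds], length,
                              integer(1)),
      venn = list(union = vn$union, multiple = vn$multiple,
                  regions = as.list(vn$regions)),
      n_correlated = sum(corr$passes),
      contrasts = contrasts)
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  report$out_dir <- out_dir
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
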