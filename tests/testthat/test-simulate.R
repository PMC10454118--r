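# Synthetic-data generator: determinism, calibration of planted signal, and
# conservation invariants.

test_that("genome simulation is deterministic and hits its GC target", {
  tg1 <- sim_genome(c(chr1 = 2e5, chr2 = 1e5), gc = 0.405, seed = 42)
  tg2 <- sim_genome(c(chr1 = 2e5, chr2 = 1e5), gc = 0.405, seed = 42)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(tg1, f1); write_genome_fasta(tg2, f2)
  expect_identical(readLines(f1), readLines(f2))
  b1 <- tempfile(fileext = ".bed"); b2 <- tempfile(fileext = ".bed")
  write_features_bed(tg1$features, b1); write_features_bed(tg2$features, b2)
  expect_identical(readLines(b1), readLines(b2))

  gc <- Biostrings::letterFrequency(tg1$genome, "GC") /
    Biostrings::width(tg1$genome)
  expect_true(all(abs(gc - 0.405) <= 0.02))

  tg3 <- sim_genome(c(chr1 = 2e5, chr2 = 1e5), gc = 0.405, seed = 43)
  expect_false(identical(as.character(tg1$genome), as.character(tg3$genome)))
})

test_that("emitted repeat intervals cover the requested genome fraction", {
  tg <- sim_genome(c(chr1 = 4e5, chr2 = 2e5), repeat_fraction = 0.38,
                   seed = 7)
  kind <- S4Vectors::mcols(tg$features)$kind
  rep_gr <- tg$features[startsWith(kind, "repeat:")]
  cov <- sum(vapply(names(tg$genome), function(ch) {
    sub <- rep_gr[GenomicRanges::seqnames(rep_gr) == ch]
    oracle_union_len(GenomicRanges::start(sub), GenomicRanges::end(sub))
  }, numeric(1)))
  expect_equal(cov / sum(Biostrings::width(tg$genome)), 0.38,
               tolerance = 0.02 / 0.38)
  cls <- sub("^repeat:", "", kind[startsWith(kind, "repeat:")])
  expect_true(all(cls %in% c("SINE", "LINE", "LTR", "DNA", "simple",
                             "low_complexity", "satellite", "smallRNA",
                             "unclassified")))
})

test_that("genome feature ids are unique within kind and inside bounds", {
  tg <- small_genome()
  mc <- S4Vectors::mcols(tg$features)
  for (k in unique(mc$kind)) {
    ids <- mc$id[mc$kind == k]
    expect_false(anyDuplicated(ids) > 0)
  }
  lens <- stats::setNames(Biostrings::width(tg$genome), names(tg$genome))
  expect_true(all(GenomicRanges::start(tg$features) >= 1))
  expect_true(all(GenomicRanges::end(tg$features) <=
                    lens[as.character(GenomicRanges::seqnames(tg$features))]))
})

test_that("eccDNA population respects the hotspot mixture and length model", {
  tg <- small_genome()
  w <- make_windows(tg, width = 1e5)
  hot <- w[2, ]; hot$weight <- 1
  pop <- sim_ecc_population(tg, n_circles = 1000, hotspot_windows = hot,
                            p_hotspot = 0.5, length_mean = 4905,
                            length_sd = 1500, seed = 3)
  # planted fraction: binomial(1000, 0.5)
  expect_equal(mean(!is.na(pop$truth$hotspot_window)), 0.5,
               tolerance = 0.05 / 0.5)
  # planted circles have their midpoint in the hotspot window
  planted <- pop$truth[!is.na(pop$truth$hotspot_window), ]
  mid <- (planted$start0 + planted$end0) / 2
  expect_true(all(planted$chrom == hot$chrom &
                    mid >= hot$start0 & mid < hot$end0))
  # length model: sample mean within 100 bp of 4905 at n=1000
  expect_lt(abs(mean(pop$truth$length) - 4905), 100)
  expect_true(all(pop$truth$length >= 200))

  pop2 <- sim_ecc_population(tg, n_circles = 50, hotspot_windows = hot,
                             p_hotspot = 1, seed = 4)
  expect_true(all(!is.na(pop2$truth$hotspot_window)))

  pop0 <- sim_ecc_population(tg, n_circles = 0, seed = 5)
  expect_equal(nrow(pop0$truth), 0)
  expect_equal(length(pop0$seqs), 0)
})

test_that("population truth conserves coordinates and carried features", {
  tg <- small_genome()
  lens <- stats::setNames(Biostrings::width(tg$genome), names(tg$genome))
  mc <- S4Vectors::mcols(tg$features)
  for (seed in 1:3) {
    pop <- sim_ecc_population(tg, n_circles = 100, p_hotspot = 0,
                              seed = seed)
    tr <- pop$truth
    expect_true(all(tr$start0 >= 0 & tr$end0 <= lens[tr$chrom]))
    expect_true(all(tr$end0 - tr$start0 == tr$length))
    expect_equal(unname(Biostrings::width(pop$seqs)), tr$length)
    # every carried feature is fully contained in the source interval
    for (i in which(nzchar(tr$carried_features))) {
      fids <- strsplit(tr$carried_features[i], ",")[[1]]
      f <- tg$features[mc$id %in% fids]
      expect_true(all(as.character(GenomicRanges::seqnames(f)) == tr$chrom[i] &
                        GenomicRanges::start(f) >= tr$start0[i] + 1 &
                        GenomicRanges::end(f) <= tr$end0[i]))
    }
    # circle sequence matches the genome substring (up to strand)
    j <- which(tr$strand == "+")[1]
    expect_identical(as.character(pop$seqs[[j]]),
                     substr(as.character(tg$genome[[tr$chrom[j]]]),
                            tr$start0[j] + 1, tr$end0[j]))
    j <- which(tr$strand == "-")[1]
    expect_identical(as.character(pop$seqs[[j]]),
                     revcomp(substr(as.character(tg$genome[[tr$chrom[j]]]),
                                    tr$start0[j] + 1, tr$end0[j])))
  }
})

test_that("hotspot windows that do not fit their chromosome are rejected", {
  tg <- small_genome()
  bad <- data.frame(chrom = "chrB", start0 = 0, end0 = 5e5, weight = 1)
  expect_error(sim_ecc_population(tg, n_circles = 10, hotspot_windows = bad,
                                  seed = 1),
               "shorter than the requested window")
})

test_that("error-free concatemer reads are exact tandem rotations", {
  mono <- c(m1 = "ACGTACGTAA")
  reads <- sim_concatemer_reads(mono, copy_min = 2, copy_max = 2,
                                error_rate = 0, seed = 1)
  r <- as.character(reads[[1]])
  expect_equal(nchar(r), 20)
  # a rotation of the doubled monomer: read occurs in monomer repeated 3x
  expect_true(grepl(r, strrep(mono, 3), fixed = TRUE))

  set.seed(42)
  monos <- stats::setNames(vapply(1:20, function(i) rand_dna(500), ""),
                           sprintf("c%02d", 1:20))
  reads <- sim_concatemer_reads(monos, copy_min = 1.5, copy_max = 8,
                                error_rate = 0, seed = 2)
  expect_true(all(Biostrings::width(reads) >= 1.5 * 500))
  copies <- as.numeric(sub(".*copies=", "", names(reads)))
  # header copies are printed to 3 decimals, so lengths agree to +/-1 bp
  expect_true(all(abs(Biostrings::width(reads) - copies * 500) <= 1))
})

test_that("read errors land at the requested rate", {
  set.seed(7)
  mono <- c(m = rand_dna(5000))
  noisy <- sim_concatemer_reads(mono, copy_min = 3, copy_max = 3,
                                error_rate = 0.01, seed = 9)
  clean <- sim_concatemer_reads(mono, copy_min = 3, copy_max = 3,
                                error_rate = 0, seed = 9)
  d <- utils::adist(as.character(noisy[[1]]), as.character(clean[[1]]))[1, 1]
  expect_equal(d / Biostrings::width(clean)[1], 0.01, tolerance = 0.3)
})

test_that("expression planting passes the fold rule exactly without noise", {
  genes <- sprintf("gene_%03d", 1:60)
  presence <- list(unadapted = genes[1:10], mid = genes[21:30],
                   high = genes[41:50])
  ex <- sim_expression_table(genes, presence, dosage_fraction = 1,
                             planted_fold = 1.5, noise_cv = 0,
                             low_expr_fraction = 0, seed = 1)
  planted <- ex$truth$gene_id[ex$truth$dosage_gene]
  expect_equal(sort(planted), sort(unname(unlist(presence))))
  corr <- correlate_ecc_expression(presence, ex$tmm, min_fold = 1.2,
                                   low_expr_floor = 2)
  expect_true(all(corr$passes[corr$gene_id %in% planted]))
  # boosted condition is the exclusive one, boosted exactly 1.5x
  for (i in which(ex$truth$dosage_gene)[1:5]) {
    g <- ex$truth$gene_id[i]
    b <- ex$truth$boosted_condition[i]
    expect_equal(ex$tmm[g, b] / ex$truth$baseline[i], 1.5)
  }
})

test_that("low-expression genes stay under the floor in every condition", {
  genes <- sprintf("g%03d", 1:200)
  presence <- list(a = genes[1:5], b = genes[6:10])
  ex <- sim_expression_table(genes, presence, dosage_fraction = 0,
                             noise_cv = 0.05, low_expr_fraction = 0.1,
                             seed = 2)
  low <- ex$truth$low_expr
  expect_equal(sum(low), 20)
  expect_true(all(ex$tmm[low, ] < 2))
  expect_true(all(apply(ex$tmm[!low, ], 1, max) >= 2))
})

test_that("expression generation rejects presence genes outside the universe", {
  expect_error(
    sim_expression_table(c("g1", "g2"), list(a = "g1", b = "gX"), seed = 1),
    "absent from the feature set")
})

test_that("identical seeds give byte-identical expression TSVs", {
  genes <- sprintf("g%02d", 1:30)
  presence <- list(a = genes[1:5], b = genes[6:10])
  f1 <- tempfile(); f2 <- tempfile()
  write_expression_tsv(sim_expression_table(genes, presence, seed = 5)$tmm, f1)
  write_expression_tsv(sim_expression_table(genes, presence, seed = 5)$tmm, f2)
  expect_identical(readLines(f1), readLines(f2))
})
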