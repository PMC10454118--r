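# Feature transfer, homology screening, GC, and the per-condition summary.

make_feature_set <- function() {
  gr <- GenomicRanges::GRanges(
    "chrA",
    IRanges::IRanges(start = c(2001, 6001, 9001, 1001, 3001),
                     end = c(4000, 6500, 9200, 1500, 3800)),
    strand = "+")
  S4Vectors::mcols(gr)$kind <- c("gene", "gene", "tRNA",
                                 "repeat:SINE", "repeat:LINE")
  S4Vectors::mcols(gr)$id <- c("gene_0001", "gene_0002", "tRNA_0001",
                               "rep_00001", "rep_00002")
  gr
}

hit_row <- function(id, start0, end0, placed = TRUE) {
  data.frame(circle_id = id, placed = placed,
             chrom = if (placed) "chrA" else NA, start0 = start0, end0 = end0,
             strand = "+", votes = 30, stringsAsFactors = FALSE)
}

test_that("gene transfer requires full containment in the hit", {
  set.seed(1)
  feats <- make_feature_set()
  circ <- c(full = rand_dna(4000), half = rand_dna(2500))
  hits <- rbind(hit_row("full", 1000, 5000),   # covers gene_0001 fully
                hit_row("half", 2500, 5000))   # only half of gene_0001
  ann <- annotate_circles(circ, hits, feats)
  expect_equal(ann$records$gene_ids, c("gene_0001", ""))
  expect_equal(ann$records$n_genes, c(1L, 0L))
})

test_that("repeat masking is accounted per class and as a union", {
  set.seed(2)
  feats <- make_feature_set()
  circ <- c(a = rand_dna(4000))
  ann <- annotate_circles(circ, hit_row("a", 1000, 5000), feats)
  # SINE [1001,1500] -> 500 bp; LINE [3001,3800] -> 800 bp (within hit)
  rc <- ann$repeat_classes
  expect_setequal(rc$class, c("SINE", "LINE"))
  expect_equal(rc$bp[rc$class == "SINE"], 500L)
  expect_equal(rc$bp[rc$class == "LINE"], 800L)
  expect_equal(ann$records$repeat_masked_bp, 1300L)
  expect_equal(ann$records$repeat_masked_bp,
               oracle_union_len(c(1001, 3001), c(1500, 3800)))
})

test_that("planted repeat coverage on circles matches an interval oracle", {
  tg <- small_genome()
  pop <- sim_ecc_population(tg, n_circles = 120, p_hotspot = 0, seed = 3)
  hits <- data.frame(circle_id = pop$truth$circle_id, placed = TRUE,
                     chrom = pop$truth$chrom, start0 = pop$truth$start0,
                     end0 = pop$truth$end0, strand = "+", votes = 32,
                     stringsAsFactors = FALSE)
  ann <- annotate_circles(pop$seqs, hits, tg$features)
  frac <- sum(ann$records$repeat_masked_bp) / sum(ann$records$length)
  # pooled circle repeat content reflects the genome-wide planted fraction
  expect_equal(frac, 0.38, tolerance = 0.05 / 0.38)
  # per-circle oracle check on a few circles
  kind <- S4Vectors::mcols(tg$features)$kind
  rep_gr <- tg$features[startsWith(kind, "repeat:")]
  for (i in c(1, 50, 120)) {
    sub <- rep_gr[as.character(GenomicRanges::seqnames(rep_gr)) ==
                    pop$truth$chrom[i]]
    st <- pmax(GenomicRanges::start(sub), pop$truth$start0[i] + 1)
    en <- pmin(GenomicRanges::end(sub), pop$truth$end0[i])
    keep <- st <= en
    expect_equal(ann$records$repeat_masked_bp[i],
                 oracle_union_len(st[keep], en[keep]))
  }
})

test_that("unplaced circles keep GC but carry empty annotations", {
  set.seed(4)
  circ <- c(u = rand_dna(1000))
  ann <- annotate_circles(circ, hit_row("u", NA, NA, placed = FALSE),
                          make_feature_set())
  expect_false(is.na(ann$records$gc))
  expect_equal(ann$records$n_genes, 0L)
  expect_equal(ann$records$repeat_masked_bp, 0L)
})

test_that("homology calls respect the identity threshold", {
  set.seed(5)
  circ <- rand_dna(5000)
  entry <- substr(circ, 2001, 2500)  # planted verbatim, 500 bp
  expect_equal(homology_call(circ, c(ori1 = entry)), "ori1")
  # on the reverse complement strand too
  expect_equal(homology_call(revcomp(circ), c(ori1 = entry)), "ori1")
  # 10% substitutions: below the 95% identity rule
  expect_length(homology_call(circ, c(ori1 = mutate_subs(entry, 0.10))), 0)
  # 3% substitutions: ~0.97 identity, still a match
  e3 <- mutate_subs(entry, 0.03)
  expect_equal(homology_call(circ, c(ori1 = e3)), "ori1")
  # oracle: substitution-only mutation leaves per-base identity 1 - 0.03
  expect_equal(mean(strsplit(e3, "")[[1]] == strsplit(entry, "")[[1]]),
               0.97, tolerance = 0.01)
  expect_length(homology_call(circ, character(0)), 0)
  # unrelated database entry
  expect_length(homology_call(circ, c(x = rand_dna(500))), 0)
})

test_that("gc_content counts G and C over the full length", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ANGC"), 0.5)  # ambiguous base in denominator only
  expect_error(gc_content("NNN"), "unambiguous")
  expect_error(gc_content(""), "empty")
})

test_that("a synthetic condition pool lands on the genome GC target", {
  tg <- small_genome()
  pop <- sim_ecc_population(tg, n_circles = 150, p_hotspot = 0, seed = 6)
  gc <- vapply(as.character(pop$seqs), gc_content, numeric(1))
  len <- pop$truth$length
  pooled <- 100 * sum(gc * len) / sum(len)
  expect_equal(pooled, 40.5, tolerance = 0.5 / 40.5)
})

test_that("summary percentages follow the printed-precision convention", {
  # 233 gene-bearing of 4511 clustered -> 5.2%; 800 of 8109 tRNA -> 9.9%
  rec <- data.frame(circle_id = sprintf("c%04d", 1:4511),
                    length = 5000, gc = 0.4, placed = TRUE,
                    n_genes = rep(c(1L, 0L), c(233, 4511 - 233)),
                    gene_ids = "", n_trnas = 0L, trna_ids = "",
                    rdna = FALSE, ori = FALSE, repeat_masked_bp = 0L,
                    stringsAsFactors = FALSE)
  s <- summarize_condition(list(records = rec,
                                repeat_classes = data.frame(
                                  circle_id = character(), class = character(),
                                  n_elements = integer(), bp = integer())),
                           n_raw = 4563, condition = "x")
  expect_equal(s$pct_with_genes, 5.2)
  expect_equal(s$n_sequences, 4563)
  expect_equal(s$n_clustered, 4511)
  expect_equal(pct_round(800, 8109), 9.9)
})

test_that("interspersed repeat totals sum the interspersed classes", {
  bp <- c(SINE = 2994270, LINE = 5818281, LTR = 3972926, DNA = 431383,
          unclassified = 244548, simple = 836271, satellite = 727205,
          low_complexity = 105297, smallRNA = 41990)
  expect_equal(interspersed_repeat_total(bp), 13461408)
  # the summary carries the same accounting
  rcl <- data.frame(circle_id = "c1", class = names(bp),
                    n_elements = 1L, bp = unname(bp),
                    stringsAsFactors = FALSE)
  rec <- data.frame(circle_id = "c1", length = 40000000, gc = 0.4,
                    placed = TRUE, n_genes = 0L, gene_ids = "", n_trnas = 0L,
                    trna_ids = "", rdna = FALSE, ori = FALSE,
                    repeat_masked_bp = 15159445L, stringsAsFactors = FALSE)
  s <- summarize_condition(list(records = rec, repeat_classes = rcl),
                           n_raw = 1)
  expect_equal(s$interspersed_bp, 13461408)
})

test_that("summaries are monotone in gene-bearing records and round-trip", {
  set.seed(7)
  tg <- small_genome()
  pop <- sim_ecc_population(tg, n_circles = 40, p_hotspot = 0, seed = 8)
  hits <- data.frame(circle_id = pop$truth$circle_id, placed = TRUE,
                     chrom = pop$truth$chrom, start0 = pop$truth$start0,
                     end0 = pop$truth$end0, strand = "+", votes = 32,
                     stringsAsFactors = FALSE)
  ann <- annotate_circles(pop$seqs, hits, tg$features)
  s1 <- summarize_condition(ann, n_raw = 40, condition = "c")
  # add one gene-bearing record: count never decreases
  extra <- ann$records[1, ]
  extra$circle_id <- "extra"; extra$n_genes <- 1L
  ann2 <- list(records = rbind(ann$records, extra),
               repeat_classes = ann$repeat_classes)
  s2 <- summarize_condition(ann2, n_raw = 41, condition = "c")
  expect_gte(s2$n_with_genes, s1$n_with_genes)
  # round-trip through serialized records
  f <- tempfile()
  utils::write.table(ann$records, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rec2 <- utils::read.delim(f, stringsAsFactors = FALSE)
  rec2$gene_ids[is.na(rec2$gene_ids)] <- ""
  rec2$trna_ids[is.na(rec2$trna_ids)] <- ""
  s3 <- summarize_condition(list(records = rec2,
                                 repeat_classes = ann$repeat_classes),
                            n_raw = 40, condition = "c")
  expect_equal(as.data.frame(s3), as.data.frame(s1))
})

test_that("empty record sets give an all-zero summary", {
  s <- summarize_condition(
    list(records = data.frame(circle_id = character(), length = integer(),
                              gc = numeric(), placed = logical(),
                              n_genes = integer(), gene_ids = character(),
                              n_trnas = integer(), trna_ids = character(),
                              rdna = logical(), ori = logical(),
                              repeat_masked_bp = integer()),
         repeat_classes = data.frame(circle_id = character(),
                                     class = character(),
                                     n_elements = integer(),
                                     bp = integer())),
    n_raw = 0, condition = "empty")
  expect_equal(s$n_clustered, 0)
  expect_equal(s$pct_with_genes, 0)
  expect_equal(s$interspersed_bp, 0)
})
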