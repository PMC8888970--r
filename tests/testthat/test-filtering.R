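# ann with controlled same-chromosome gaps for the distance boundary:
# L ends at 2000; R10k starts at 12000 (gap exactly 10,000), R9999 at 11999
gap_ann <- function() {
  genes <- data.frame(
    gene_id = c("L", "R10k", "R9999", "Far", "Far2"),
    gene_name = c("L", "R10k", "R9999", "Far", "Far2"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(1000L, 12000L, 11999L, 1000L, 20000L),
    end = c(2000L, 13000L, 12999L, 2000L, 21000L),
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE
  )
  tx <- data.frame(transcript_id = paste0(genes$gene_id, ".t1"),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                   chrom = genes$chrom, start = genes$start, end = genes$end,
                   strand = "+", exon_number = 1L, stringsAsFactors = FALSE)
  genome_annotation(genes, tx, ex)
}

mk_cand <- function(gene_a, gene_b, chrom_a, chrom_b, n_total = 2L,
                    n_split = 1L) {
  data.frame(gene_a = gene_a, gene_b = gene_b, chrom_a = chrom_a,
             pos_a = 1500L, chrom_b = chrom_b, pos_b = 1500L,
             n_discordant = n_total - n_split, n_split = n_split,
             n_total = n_total, orientation = "unknown", filter_flags = "",
             stringsAsFactors = FALSE)
}

test_that("chromosome whitelist admits 1-22/X/Y and rejects other contigs", {
  cfg <- wes_config()
  expect_true(filter_chromosome(mk_cand("A", "B", "chr15", "chr17"), cfg))
  expect_true(filter_chromosome(mk_cand("A", "B", "15", "X"), cfg))
  expect_false(filter_chromosome(mk_cand("A", "B", "chrM", "chr17"), cfg))
  expect_false(filter_chromosome(mk_cand("A", "B", "GL000220.1", "chr1"), cfg))
})

test_that("biotype filter requires protein-coding on both sides", {
  ann <- tiny_ann()
  cfg <- wes_config()
  both <- mk_cand("A", "B", "chr15", "chr17")
  linc <- mk_cand("A", "C", "chr15", "chr15")
  expect_true(filter_biotype(both, ann, cfg))
  expect_false(filter_biotype(linc, ann, cfg))

  # biotype "unknown" fails by default, passes under assume_coding
  ann$genes$biotype[ann$genes$gene_id == "B"] <- "unknown"
  ann2 <- genome_annotation(ann$genes, ann$transcripts, ann$exons)
  expect_false(filter_biotype(both, ann2, cfg))
  expect_true(filter_biotype(both, ann2, wes_config(assume_coding = TRUE)))
  expect_true(filter_biotype(linc, ann, wes_config(require_protein_coding = FALSE)))
})

test_that("distance filter: 10 kb inclusive boundary, interchromosomal free", {
  ann <- gap_ann()
  cfg <- wes_config()
  expect_false(filter_distance(mk_cand("L", "R9999", "chr1", "chr1"), ann, cfg))
  expect_true(filter_distance(mk_cand("L", "R10k", "chr1", "chr1"), ann, cfg))
  expect_true(filter_distance(mk_cand("L", "Far", "chr1", "chr2"), ann, cfg))
})

test_that("support filter boundary sits at min_support", {
  expect_true(filter_support(mk_cand("A", "B", "chr1", "chr2", n_total = 1L,
                                     n_split = 0L), wes_config()))
  expect_false(filter_support(mk_cand("A", "B", "chr1", "chr2", n_total = 0L,
                                      n_split = 0L), wes_config()))
  expect_false(filter_support(mk_cand("A", "B", "chr1", "chr2", n_total = 2L),
                              wes_config(min_support = 3L)))
})

test_that("split-read gene count is capped at two", {
  cfg <- wes_config()
  s2 <- mk_split_row("s", "A", "B")
  s3 <- mk_split_row("s", "A", "B", n_genes = 3L)
  s1 <- mk_split_row("s", "A", "A", n_genes = 1L)
  expect_true(filter_split_gene_count(s2, cfg))
  expect_false(filter_split_gene_count(s3, cfg))
  expect_true(filter_split_gene_count(s1, cfg))
  expect_equal(nrow(filter_splits(rbind(s2, s3), cfg)), 1L)
})

test_that("overlapping split mates need strictly more than 20 non-overlapping bases", {
  cfg <- wes_config()
  mk <- function(pos, end, read_index) {
    s <- mk_split_row("rp", "A", "B", read_index = read_index)
    s$pos_p <- pos; s$end_p <- end
    s
  }
  # footprints [1000,1099] vs [1021,1099]: union 100, intersection 79 -> 21
  expect_true(filter_split_pair_overlap(mk(1000L, 1099L, 1L),
                                        mk(1021L, 1099L, 2L), cfg))
  # [1000,1099] vs [1020,1099]: non-overlap exactly 20 -> fail
  expect_false(filter_split_pair_overlap(mk(1000L, 1099L, 1L),
                                         mk(1020L, 1099L, 2L), cfg))
  # disjoint footprints: rule not applicable
  expect_true(filter_split_pair_overlap(mk(1000L, 1099L, 1L),
                                        mk(1200L, 1299L, 2L), cfg))
  expect_error(filter_split_pair_overlap(mk(1000L, 1099L, 1L),
                                         mk_split_row("other", "A", "B"), cfg),
               "different read names")
})

test_that("cascade flags every failed filter and admits the rest", {
  ann <- gap_ann()
  cfg <- wes_config()
  # six candidates: 2 fail distance, 1 fails biotype, 3 pass (manual oracle)
  g <- ann$genes
  g$biotype[g$gene_id == "Far"] <- "lincRNA"
  ann <- genome_annotation(g, ann$transcripts, ann$exons)
  cands <- rbind(
    mk_cand("L", "R9999", "chr1", "chr1"),     # distance
    mk_cand("R10k", "R9999", "chr1", "chr1"),  # distance (overlapping spans)
    mk_cand("L", "Far", "chr1", "chr2"),       # biotype
    mk_cand("L", "R10k", "chr1", "chr1"),      # pass
    mk_cand("L", "Far2", "chr1", "chr2"),      # pass
    mk_cand("R10k", "Far2", "chr1", "chr2")    # pass
  )
  res <- apply_filters(cands, ann, NULL, cfg)
  expect_equal(nrow(res$passed), 3L)
  expect_setequal(res$passed$gene_b, c("R10k", "Far2"))
  expect_true(all(nzchar(res$rejected$filter_flags)))
  expect_true(all(grepl("distance",
                        res$rejected$filter_flags[res$rejected$gene_b == "R9999"])))

  # idempotence: filtering the passed set changes nothing
  again <- apply_filters(res$passed, ann, NULL, cfg)
  expect_equal(again$passed, res$passed)
  expect_equal(nrow(again$rejected), 0L)
})

test_that("candidate-level filters are order-independent pure predicates", {
  ann <- gap_ann()
  cfg <- wes_config()
  cands <- rbind(
    mk_cand("L", "R9999", "chr1", "chr1"),
    mk_cand("L", "R10k", "chr1", "chr1"),
    mk_cand("L", "Far", "chr1", "chr2"),
    mk_cand("L", "Far", "chrM", "chr2"),
    mk_cand("L", "R10k", "chr1", "chr1", n_total = 0L, n_split = 0L)
  )
  preds <- list(
    function(d) filter_chromosome(d, cfg),
    function(d) filter_biotype(d, ann, cfg),
    function(d) filter_distance(d, ann, cfg),
    function(d) filter_support(d, cfg)
  )
  ref_pass <- apply_filters(cands, ann, NULL, cfg)$passed
  key <- function(d) paste(d$gene_a, d$gene_b, d$chrom_a, d$n_total)
  set.seed(33)
  for (i in 1:5) {
    d <- cands
    for (p in sample(preds)) d <- d[p(d), , drop = FALSE]
    expect_setequal(key(d), key(ref_pass))
  }
})

test_that("tightening thresholds never grows the pass set", {
  ann <- gap_ann()
  cands <- rbind(
    mk_cand("L", "R10k", "chr1", "chr1", n_total = 1L, n_split = 0L),
    mk_cand("L", "Far", "chr1", "chr2", n_total = 3L),
    mk_cand("R10k", "Far", "chr1", "chr2", n_total = 2L)
  )
  key <- function(d) paste(d$gene_a, d$gene_b)
  prev <- NULL
  for (ms in c(1L, 2L, 3L, 4L)) {
    pass <- apply_filters(cands, ann, NULL, wes_config(min_support = ms))$passed
    if (!is.null(prev)) expect_true(all(key(pass) %in% prev))
    prev <- key(pass)
  }
  full <- apply_filters(cands, ann, NULL, wes_config())$passed
  shrunk <- apply_filters(cands, ann, NULL,
                          wes_config(allowed_chroms = c("1")))$passed
  expect_true(all(key(shrunk) %in% key(full)))
})
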