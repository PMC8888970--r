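random_tx <- function(n, len, seed) {
  set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
  names(out) <- sprintf("tx%d", seq_len(n))
  out
}

# minimal annotation assigning each transcript to its own gene (or a given map)
tx_ann <- function(tx_gene) {
  genes <- data.frame(
    gene_id = unique(tx_gene), gene_name = unique(tx_gene),
    chrom = "chr1",
    start = 1000L + 50000L * (seq_along(unique(tx_gene)) - 1L),
    end = 2000L + 50000L * (seq_along(unique(tx_gene)) - 1L),
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE
  )
  tx <- data.frame(transcript_id = names(tx_gene), gene_id = unname(tx_gene),
                   stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                   chrom = "chr1",
                   start = genes$start[match(tx$gene_id, genes$gene_id)],
                   end = genes$end[match(tx$gene_id, genes$gene_id)],
                   strand = "+", exon_number = 1L, stringsAsFactors = FALSE)
  genome_annotation(genes, tx, ex)
}

test_that("read simulation is uniform, exact-count and seed-deterministic", {
  txs <- random_tx(3, 600, seed = 1)
  r1 <- simulate_reads(txs, n_per_tx = 100, read_len = 100, seed = 5)
  expect_equal(nrow(r1), 300L)
  expect_equal(unname(table(r1$origin)["tx2"]), 100L)
  expect_true(all(nchar(r1$seq) == 100L))
  r2 <- simulate_reads(txs, n_per_tx = 100, read_len = 100, seed = 5)
  expect_identical(r1, r2)

  # single placement: transcript exactly read-length long
  one <- c(solo = substr(txs[[1]], 1, 100))
  rs <- simulate_reads(one, n_per_tx = 1, read_len = 100, seed = 2)
  expect_identical(rs$seq, unname(one))

  # short transcripts are skipped with a warning
  expect_warning(
    rshort <- simulate_reads(c(txs, tiny = "ACGT"), 10, 100, seed = 3),
    "shorter than read length")
  expect_false("tiny" %in% rshort$origin)
})

test_that("identical transcripts share all reads; unrelated share none", {
  txs <- random_tx(2, 2000, seed = 7)
  dup <- c(txs, tx3 = unname(txs[1]))
  reads <- simulate_reads(dup, n_per_tx = 200, read_len = 100, seed = 8)
  m <- map_simulated(reads, dup)
  expect_equal(unname(diag(m$counts)), rep(200L, 3L))  # self-consistency
  expect_equal(m$counts["tx1", "tx3"], 200L)
  expect_equal(m$counts["tx3", "tx1"], 200L)
  # independent random 2 kb sequences: no 100-mer collisions
  expect_equal(m$counts["tx1", "tx2"], 0L)
  expect_equal(m$counts["tx2", "tx1"], 0L)
})

test_that("sharing counts match exhaustive placement enumeration", {
  set.seed(17)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  txs <- c(full = base, half = substr(base, 1, 500))
  read_len <- 100L

  # oracle: enumerate every start position and test substring occurrence
  enum_counts <- function(origin, target) {
    L <- nchar(txs[[origin]])
    starts <- seq_len(L - read_len + 1L)
    hits <- vapply(starts, function(s) {
      grepl(substr(txs[[origin]], s, s + read_len - 1L), txs[[target]],
            fixed = TRUE)
    }, TRUE)
    sum(hits)
  }
  all_reads <- do.call(rbind, lapply(names(txs), function(id) {
    L <- nchar(txs[[id]])
    starts <- seq_len(L - read_len + 1L)
    data.frame(origin = id, start = starts,
               seq = substring(txs[[id]], starts, starts + read_len - 1L),
               stringsAsFactors = FALSE)
  }))
  m <- map_simulated(all_reads, txs)
  for (i in names(txs)) {
    for (j in names(txs)) {
      expect_equal(m$counts[i, j], enum_counts(i, j),
                   info = paste(i, "->", j))
    }
  }
  # the prefix half shares exactly its internal placements with the full
  expect_equal(m$counts["half", "full"], 401L)  # 500 - 100 + 1
})

test_that("paralog derivation thresholds, symmetry and monotonicity", {
  set.seed(23)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  tail3 <- paste(sample(c("A", "C", "G", "T"), 350, TRUE), collapse = "")
  txs <- c(g1.t1 = base,
           g2.t1 = paste0(substr(base, 1, 650), tail3),
           g3.t1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                         collapse = ""))
  ann <- tx_ann(c(g1.t1 = "g1", g2.t1 = "g2", g3.t1 = "g3"))
  # exhaustive placements: sharing fraction = 551/901 ~ 0.61 for g1<->g2
  all_reads <- do.call(rbind, lapply(names(txs), function(id) {
    starts <- seq_len(nchar(txs[[id]]) - 99L)
    data.frame(origin = id, start = starts,
               seq = substring(txs[[id]], starts, starts + 99L),
               stringsAsFactors = FALSE)
  }))
  m <- map_simulated(all_reads, txs)
  expect_equal(m$counts["g2.t1", "g1.t1"], 551L)

  p50 <- derive_paralogs(m, ann, share_frac = 0.5)
  p90 <- derive_paralogs(m, ann, share_frac = 0.9)
  expect_equal(nrow(p50), 1L)
  expect_identical(p50$gene_a, "g1")
  expect_identical(p50$gene_b, "g2")
  expect_equal(nrow(p90), 0L)

  # monotone in the threshold: stricter never adds pairs
  key <- function(p) paste(p$gene_a, p$gene_b)
  expect_true(all(key(p90) %in% key(p50)))

  # symmetric closure: transposed matrix gives the same pairs
  mt <- m
  mt$counts <- t(m$counts)
  expect_equal(derive_paralogs(mt, ann, 0.5), p50)

  # absolute-count alternative
  pmin5 <- derive_paralogs(m, ann, min_shared_reads = 5L)
  expect_true(all(key(p50) %in% key(pmin5)))
  expect_error(derive_paralogs(m, ann, share_frac = 0), "share_frac")
  expect_error(derive_paralogs(m, ann, share_frac = 1.5), "share_frac")
})

test_that("a duplicated gene pair is flagged paralogous; unrelated pairs are not", {
  ref <- make_toy_reference(n_genes = 4, duplicate_pair = TRUE, seed = 31)
  cfg <- wes_config(sim_reads_per_tx = 500)
  p <- detect_paralogs(ref$tx_seq, ref$ann, cfg)
  key <- paste(p$gene_a, p$gene_b)
  expect_true("G01 G04" %in% key)
  expect_false("G01 G02" %in% key)

  cands <- data.frame(gene_a = c("G01", "G01"), gene_b = c("G04", "G02"),
                      chrom_a = "chr1", pos_a = 1L, chrom_b = "chr2",
                      pos_b = 1L, n_discordant = 1L, n_split = 1L,
                      n_total = 2L, orientation = "unknown",
                      filter_flags = "", stringsAsFactors = FALSE)
  flagged <- filter_paralog_candidates(cands, p)
  expect_identical(flagged$filter_flags, c("paralog", ""))
  none <- filter_paralog_candidates(cands, p[0L, ])
  expect_identical(none$filter_flags, c("", ""))
  expect_equal(sum(is_paralog_pair(cands, p)), 1L)

  # paralog table round-trips through its TSV cache
  tsv <- tempfile(fileext = ".tsv")
  write_paralogs(p, tsv)
  expect_equal(read_paralogs(tsv), p)
})

test_that("the simulation pipeline is deterministic end-to-end", {
  ref <- make_toy_reference(n_genes = 3, duplicate_pair = TRUE, seed = 13)
  cfg <- wes_config(sim_reads_per_tx = 200, seed = 77)
  expect_identical(detect_paralogs(ref$tx_seq, ref$ann, cfg),
                   detect_paralogs(ref$tx_seq, ref$ann, cfg))
})
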