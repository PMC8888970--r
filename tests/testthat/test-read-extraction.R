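test_that("pairs with any mate below the MAPQ gate are excluded entirely", {
  ann <- tiny_ann()
  recs <- rbind(
    sam_pair("lowq", "chr15", 1500, "chr17", 2000, mapq2 = 29L),
    sam_pair("okq", "chr15", 1500, "chr17", 2000, mapq2 = 30L)
  )
  ev <- scan_alignments(write_tiny_sam(recs), ann, wes_config())
  expect_identical(ev$pairs$read_name, "okq")
  expect_equal(nrow(ev$splits), 0L)
})

test_that("pair classification separates discordant, concordant, unassigned", {
  ann <- tiny_ann()
  cfg <- wes_config()
  inA <- seg("r", "chr15", 1500, "100M")
  inB <- seg("r", "chr17", 2000, "100M", read_index = 2L)
  inA2 <- seg("r", "chr15", 2500, "100M", read_index = 2L)
  nowhere <- seg("r", "chr15", 10000, "100M", read_index = 2L)
  expect_identical(classify_pair(inA, inB, ann, cfg), "discordant")
  expect_identical(classify_pair(inA, inA2, ann, cfg), "concordant")
  expect_identical(classify_pair(inA, nowhere, ann, cfg), "unassigned")
  other <- seg("other", "chr17", 2000, "100M", read_index = 2L)
  expect_error(classify_pair(inA, other, ann, cfg), "different read names")

  # concordant proper pairs produce no evidence at scan level
  ev <- scan_alignments(
    write_tiny_sam(sam_pair("conc", "chr15", 1200, "chr15", 1450)),
    ann, cfg)
  expect_equal(nrow(ev$pairs), 0L)
  expect_equal(nrow(ev$splits), 0L)
})

test_that("a planted discordant pair and split read are both recovered", {
  ann <- tiny_ann()
  recs <- rbind(
    sam_pair("disc1", "chr15", 1500, "chr17", 2000),
    sam_split("split1", "chr15", 1000, "chr17", 2000, m = 60L, s = 40L)
  )
  ev <- scan_alignments(write_tiny_sam(recs), ann, wes_config())
  expect_equal(nrow(ev$pairs), 1L)
  expect_equal(nrow(ev$splits), 1L)
  # junction at the clip boundary: 60M ending at 1000+59; partner start 2000
  expect_equal(ev$splits$junction_p, 1059L)
  expect_equal(ev$splits$junction_s, 2000L)
  expect_identical(ev$splits$genes_p[[1]], "A")
  expect_identical(ev$splits$genes_s[[1]], "B")
})

test_that("clips below threshold or without a partner segment are not splits", {
  ann <- tiny_ann()
  cfg <- wes_config()
  # 95M5S: clip below min_clip_len even with a supplementary present
  below <- rbind(
    seg("r1", "chr15", 1000, "95M5S",
        sa = "SA:Z:chr17,2000,+,95S5M,60,0;"),
    seg("r1", "chr17", 2000, "95S5M", supp = TRUE)
  )
  expect_null(detect_split(below, ann, cfg))
  # long clip but no supplementary segment anywhere
  lonely <- seg("r2", "chr15", 1000, "60M40S")
  expect_null(detect_split(lonely, ann, cfg))
  # supplementary below MAPQ disqualifies the split
  lowq <- rbind(
    seg("r3", "chr15", 1000, "60M40S"),
    seg("r3", "chr17", 2000, "60S40M", supp = TRUE, mapq = 29L)
  )
  expect_null(detect_split(lowq, ann, cfg))
  # SA tag alone (no supplementary record) is sufficient
  sa_only <- seg("r4", "chr15", 1000, "60M40S",
                 sa = "SA:Z:chr17,2000,+,60S40M,60,0;")
  sr <- detect_split(sa_only, ann, cfg)
  expect_equal(sr$junction_p, 1059L)
  expect_equal(sr$junction_s, 2000L)
})

test_that("duplicates are dropped and mixed evidence counts once, as split", {
  ann <- tiny_ann()
  cfg <- wes_config()
  # five-read fixture, tallies enumerated by hand:
  #  r1: split (mate1) AND discordant pair for (A,B)  -> 1 split unit
  #  r2: discordant only                              -> 1 discordant unit
  #  r3: split only                                   -> 1 split unit
  #  r4: duplicate-flagged copy of a discordant pair  -> dropped
  #  r5: concordant                                   -> nothing
  r1_split <- sam_split("r1", "chr15", 1000, "chr17", 2000)
  r1_split$rnext <- "chr17"; r1_split$pnext <- 2500L
  r1_mate <- sam_record("r1", 0x1 + 0x80 + 0x10, "chr17", 2500, 60L, "100M",
                        rnext = "chr15", pnext = 1000L)
  recs <- rbind(
    r1_split, r1_mate,
    sam_pair("r2", "chr15", 1500, "chr17", 2200),
    sam_split("r3", "chr15", 1100, "chr17", 2100),
    sam_pair("r4", "chr15", 1500, "chr17", 2200, dup = TRUE),
    sam_pair("r5", "chr15", 1200, "chr15", 1500)
  )
  ev <- scan_alignments(write_tiny_sam(recs), ann, cfg)
  dd <- dedup_evidence(ev$pairs, ev$splits)
  feqs <- merge_feqs(lapply(seq_len(nrow(dd$pairs)), function(i)
    build_feq(dd$pairs[i, ], ann)))
  cand <- candidates_from_evidence(feqs, dd$splits, ann)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_split, 2L)       # r1 (once, as split) + r3
  expect_equal(cand$n_discordant, 1L)  # r2 only; r4 dropped as duplicate
  expect_equal(cand$n_total, 3L)

  # two distinct read names on the same gene pair stay two units
  ev2 <- scan_alignments(write_tiny_sam(rbind(
    sam_pair("x1", "chr15", 1500, "chr17", 2000),
    sam_pair("x2", "chr15", 1600, "chr17", 2100)
  )), ann, cfg)
  expect_equal(nrow(ev2$pairs), 2L)
})

test_that("fusion-free synthetic alignments yield zero evidence", {
  ref <- make_toy_reference(n_genes = 4, seed = 5)
  pl <- plant_fusion_reads(ref, fusion_spec("G01", "G02", 5900, 5900,
                                            fraction = 0),
                           coverage = 30, seed = 6)
  ev <- scan_alignments(pl$sam, ref$ann, wes_config())
  expect_equal(nrow(ev$pairs), 0L)
  expect_equal(nrow(ev$splits), 0L)
})

test_that("no emitted evidence contains a segment below the MAPQ gate", {
  ref <- make_toy_reference(n_genes = 4, seed = 8)
  pl <- plant_fusion_reads(ref, fusion_spec("G01", "G02", 5900, 5900,
                                            fraction = 0.5),
                           coverage = 40, seed = 9)
  cfg <- wes_config()
  ev <- scan_alignments(pl$sam, ref$ann, cfg)
  expect_gt(nrow(ev$pairs), 0L)
  expect_gt(nrow(ev$splits), 0L)
  expect_true(all(ev$pairs$mapq1 >= cfg$min_mapq))
  expect_true(all(ev$pairs$mapq2 >= cfg$min_mapq))
  expect_true(all(ev$splits$mapq_min >= cfg$min_mapq))
})

test_that("classification is independent of record order", {
  ref <- make_toy_reference(n_genes = 4, seed = 8)
  pl <- plant_fusion_reads(ref, fusion_spec("G01", "G02", 5900, 5900,
                                            fraction = 0.5),
                           coverage = 20, seed = 10)
  lines <- readLines(pl$sam)
  hdr <- startsWith(lines, "@")
  set.seed(99)
  shuffled <- tempfile(fileext = ".sam")
  writeLines(c(lines[hdr], sample(lines[!hdr])), shuffled)
  ev1 <- scan_alignments(pl$sam, ref$ann, wes_config())
  ev2 <- scan_alignments(shuffled, ref$ann, wes_config())
  expect_setequal(ev1$pairs$read_name, ev2$pairs$read_name)
  expect_setequal(paste(ev1$splits$read_name, ev1$splits$read_index),
                  paste(ev2$splits$read_name, ev2$splits$read_index))
})
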