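# Synthetic ground-truth data: a toy multi-gene reference with GTF and
# spliced transcript sequences, a planted-fusion paired-end read simulator
# that writes standards-conformant SAM (soft-clipped primaries plus
# supplementary records with reciprocal SA tags at the junction), and a
# per-pair subsampler for coverage titration. Everything is deterministic
# under a seed, and every read carries a ground-truth label, so pipeline
# sensitivity is measurable without any external data.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy reference: genome, annotation and transcript sequences
#'
#' Builds random-sequence chromosomes carrying non-overlapping multi-exon
#' protein-coding genes laid out round-robin across chromosomes with large
#' intergenic gaps. Each gene gets `n_tx_per_gene` transcripts: the first
#' uses all exons, later ones each skip one internal exon. With
#' `duplicate_pair = TRUE` the last gene's span is overwritten with the
#' first gene's sequence, producing an exact paralog pair for testing the
#' paralog filter.
#'
#' @param n_genes Number of genes (>= 2).
#' @param gene_len Approximate gene span in bp; exons and introns are
#'   equal-sized slices of it.
#' @param n_tx_per_gene Transcripts per gene (<= `n_exons`).
#' @param n_exons Exons per gene.
#' @param intergenic Gap between adjacent genes on a chromosome (bp).
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param duplicate_pair If `TRUE`, the last gene duplicates the first.
#' @param seed Integer seed.
#' @return Object of class `toy_reference`: `genome` (named character),
#'   `ann` ([genome_annotation]), `tx_seq` (named character of spliced
#'   transcripts).
#' @export
make_toy_reference <- function(n_genes = 4L, gene_len = 2100L,
                               n_tx_per_gene = 2L, n_exons = 4L,
                               intergenic = 20000L, n_chroms = 2L,
                               duplicate_pair = FALSE, seed = 1L) {
  n_genes <- as.integer(n_genes)
  gene_len <- as.integer(gene_len)
  n_tx_per_gene <- as.integer(n_tx_per_gene)
  n_exons <- as.integer(n_exons)
  intergenic <- as.integer(intergenic)
  n_chroms <- as.integer(n_chroms)
  if (n_genes < 2L) stop("n_genes must be >= 2", call. = FALSE)
  if (n_tx_per_gene < 1L || n_tx_per_gene > n_exons) {
    stop("n_tx_per_gene must be between 1 and n_exons", call. = FALSE)
  }
  exon_len <- gene_len %/% (2L * n_exons - 1L)
  if (exon_len < 1L) stop("gene_len too small for requested exon count",
                          call. = FALSE)
  if (intergenic < 0L) stop("intergenic must be >= 0 (genes may not overlap)",
                            call. = FALSE)
  span <- n_exons * exon_len + (n_exons - 1L) * exon_len
  set.seed(seed)

  chroms <- paste0("chr", seq_len(n_chroms))
  gene_chrom <- chroms[((seq_len(n_genes) - 1L) %% n_chroms) + 1L]
  slot <- (seq_len(n_genes) - 1L) %/% n_chroms
  gene_start <- 5000L + slot * (span + intergenic)
  gene_end <- gene_start + span - 1L
  gene_id <- sprintf("G%02d", seq_len(n_genes))

  chrom_len <- vapply(chroms, function(ch) {
    max(gene_end[gene_chrom == ch]) + 5000L
  }, integer(1L))
  genome <- vapply(chrom_len, .random_dna, "")
  names(genome) <- chroms

  if (duplicate_pair) {
    # last gene becomes an exact sequence copy of the first
    src <- substring(genome[gene_chrom[1L]], gene_start[1L], gene_end[1L])
    g <- genome[gene_chrom[n_genes]]
    genome[gene_chrom[n_genes]] <- paste0(
      substring(g, 1L, gene_start[n_genes] - 1L), src,
      substring(g, gene_end[n_genes] + 1L, nchar(g)))
  }

  genes <- data.frame(
    gene_id = gene_id, gene_name = sprintf("GENE%d", seq_len(n_genes)),
    chrom = gene_chrom, start = gene_start, end = gene_end,
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE
  )

  ex_rows <- list(); tx_rows <- list(); tx_seq <- character()
  for (i in seq_len(n_genes)) {
    ex_start <- gene_start[i] + (seq_len(n_exons) - 1L) * 2L * exon_len
    ex_end <- ex_start + exon_len - 1L
    for (k in seq_len(n_tx_per_gene)) {
      use <- if (k == 1L) seq_len(n_exons) else setdiff(seq_len(n_exons), k)
      tx_id <- sprintf("%s.t%d", gene_id[i], k)
      tx_rows[[length(tx_rows) + 1L]] <-
        data.frame(transcript_id = tx_id, gene_id = gene_id[i],
                   stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        transcript_id = tx_id, gene_id = gene_id[i],
        chrom = gene_chrom[i], start = ex_start[use], end = ex_end[use],
        strand = "+", exon_number = seq_along(use), stringsAsFactors = FALSE
      )
      tx_seq[tx_id] <- paste(substring(genome[gene_chrom[i]],
                                       ex_start[use], ex_end[use]),
                             collapse = "")
    }
  }

  ann <- genome_annotation(genes, do.call(rbind, tx_rows),
                           do.call(rbind, ex_rows))
  structure(list(genome = genome, ann = ann, tx_seq = tx_seq,
                 exon_len = exon_len, seed = seed),
            class = "toy_reference")
}

#' Write a toy reference to disk
#'
#' Emits `genome.fa`, `annotation.gtf` and `transcripts.fa` under `dir`.
#'
#' @param ref A `toy_reference`.
#' @param dir Output directory (created if missing).
#' @return Named list of the three paths.
#' @export
write_toy_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "toy_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  tx_fa <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome), genome_fa)
  write_gtf(ref$ann, gtf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$tx_seq), tx_fa)
  list(genome = genome_fa, gtf = gtf, tx_fasta = tx_fa)
}

#' Describe a fusion to plant
#'
#' @param gene_a,gene_b Partner gene ids (as in the toy reference).
#' @param break_a,break_b 1-based breakpoint coordinates; each must fall
#'   inside its gene span.
#' @param fraction Fraction of read pairs drawn from the fused allele
#'   (tumor fraction), in `[0, 1]`.
#' @param orientation `"a_up"` (gene A donates the upstream side) or
#'   `"b_up"`.
#' @return Object of class `fusion_spec`.
#' @export
fusion_spec <- function(gene_a, gene_b, break_a, break_b,
                        fraction = 0.5, orientation = "a_up") {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]",
                                         call. = FALSE)
  if (!orientation %in% c("a_up", "b_up")) {
    stop("orientation must be 'a_up' or 'b_up'", call. = FALSE)
  }
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 break_a = as.integer(break_a), break_b = as.integer(break_b),
                 fraction = fraction, orientation = orientation),
            class = "fusion_spec")
}

# records for all fragments of one allele; parts = list of 1 or 2
# list(chrom, ref_start, len) segments making up the allele sequence
.frag_records <- function(aseq, parts, n_frags, read_len, insert_mean,
                          insert_sd, prefix, proper) {
  alen <- nchar(aseq)
  J <- if (length(parts) == 2L) parts[[1L]]$len else NA_integer_
  if (n_frags == 0L) {
    return(list(records = NULL, truth = NULL))
  }
  flen <- pmin(alen, pmax(2L * read_len,
                          as.integer(round(stats::rnorm(n_frags, insert_mean,
                                                        insert_sd)))))
  fs <- as.integer(floor(stats::runif(n_frags) * (alen - flen + 1))) + 1L
  fe <- fs + flen - 1L
  qname <- sprintf("%s%06d", prefix, seq_len(n_frags))

  map_chrom <- function(p) {
    if (length(parts) == 1L) rep(parts[[1L]]$chrom, length(p))
    else ifelse(p <= J, parts[[1L]]$chrom, parts[[2L]]$chrom)
  }
  map_pos <- function(p) {
    if (length(parts) == 1L) parts[[1L]]$ref_start + p - 1L
    else ifelse(p <= J, parts[[1L]]$ref_start + p - 1L,
                parts[[2L]]$ref_start + (p - J) - 1L)
  }

  mate_info <- function(rs, re) {
    cross <- !is.na(J) & rs <= J & re > J
    oL <- ifelse(cross, J - rs + 1L, NA_integer_)
    oR <- ifelse(cross, re - J, NA_integer_)
    prim_on_a <- cross & oL >= oR
    prim_chrom <- ifelse(!cross, map_chrom(rs),
                         ifelse(prim_on_a, parts[[1L]]$chrom,
                                parts[[2L]]$chrom))
    prim_pos <- ifelse(!cross, map_pos(rs),
                       ifelse(prim_on_a, map_pos(rs), parts[[2L]]$ref_start))
    side <- ifelse(cross, "X", ifelse(is.na(J) | re <= J, "A", "B"))
    list(rs = rs, re = re, cross = cross, oL = oL, oR = oR,
         prim_on_a = prim_on_a, prim_chrom = prim_chrom,
         prim_pos = as.integer(prim_pos), side = side)
  }
  m1 <- mate_info(fs, fs + read_len - 1L)
  m2 <- mate_info(fe - read_len + 1L, fe)

  build <- function(m, other, ridx) {
    n <- length(m$rs)
    base <- FLAG_PAIRED +
      (if (ridx == 1L) FLAG_READ1 + FLAG_MATE_REVERSE
       else FLAG_READ2 + FLAG_REVERSE) +
      (if (proper) FLAG_PROPER else 0L)
    strand <- if (ridx == 2L) "-" else "+"
    seqs <- substring(aseq, m$rs, m$re)
    recs <- list()
    # single-record reads
    s <- which(!m$cross)
    if (length(s) > 0L) {
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qname[s], flag = base, chrom = map_chrom(m$rs)[s],
        pos = as.integer(map_pos(m$rs))[s], mapq = 60L,
        cigar = paste0(read_len, "M"),
        rnext = other$prim_chrom[s], pnext = other$prim_pos[s], tlen = 0L,
        seq = seqs[s], qual = strrep("I", read_len), tags = "",
        stringsAsFactors = FALSE)
    }
    # junction-crossing reads: two records with reciprocal SA tags
    x <- which(m$cross)
    if (length(x) > 0L) {
      cigA <- paste0(m$oL[x], "M", m$oR[x], "S")
      cigB <- paste0(m$oL[x], "S", m$oR[x], "M")
      posA <- as.integer(map_pos(m$rs))[x]
      posB <- rep(parts[[2L]]$ref_start, length(x))
      chA <- rep(parts[[1L]]$chrom, length(x))
      chB <- rep(parts[[2L]]$chrom, length(x))
      saA <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", chB, posB, strand, cigB)
      saB <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", chA, posA, strand, cigA)
      pa <- m$prim_on_a[x]
      flagA <- ifelse(pa, base, base + FLAG_SUPPLEMENTARY)
      flagB <- ifelse(pa, base + FLAG_SUPPLEMENTARY, base)
      recs[[length(recs) + 1L]] <- data.frame(
        qname = rep(qname[x], 2L),
        flag = as.integer(c(flagA, flagB)),
        chrom = c(chA, chB), pos = c(posA, posB), mapq = 60L,
        cigar = c(cigA, cigB),
        rnext = rep(other$prim_chrom[x], 2L),
        pnext = rep(other$prim_pos[x], 2L), tlen = 0L,
        seq = rep(seqs[x], 2L), qual = strrep("I", read_len),
        tags = c(saA, saB), stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
  }

  records <- rbind(build(m1, m2, 1L), build(m2, m1, 2L))

  straddle <- m1$side != m2$side | m1$side == "X" | m2$side == "X"
  label_of <- function(m) {
    out <- rep("background", length(m$rs))
    if (is.na(J)) return(out)
    out[straddle] <- "fusion-spanning-pair"
    out[m$cross] <- "fusion-split"
    out
  }
  truth <- data.frame(
    read_name = rep(qname, 2L),
    mate = rep(c(1L, 2L), each = n_frags),
    label = c(label_of(m1), label_of(m2)),
    overhang = c(ifelse(m1$cross, pmin(m1$oL, m1$oR), NA_integer_),
                 ifelse(m2$cross, pmin(m2$oL, m2$oR), NA_integer_)),
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Plant a fusion and simulate paired-end reads over it
#'
#' Draws paired-end fragments from the two wild-type gene regions and from
#' the fused allele (the two partner regions joined at the breakpoints), in
#' proportion to the tumor fraction, at the requested mean coverage over the
#' captured regions. Reads crossing the junction are written as a
#' soft-clipped primary record plus a supplementary record on the partner
#' chromosome, with reciprocal `SA` tags; mate fields and flags are
#' consistent throughout. Every read gets a ground-truth label
#' (`background`, `fusion-spanning-pair` or `fusion-split`).
#'
#' @param ref A `toy_reference`.
#' @param spec A [fusion_spec()].
#' @param coverage Mean fold-coverage over the captured regions (> 0).
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment-size distribution (truncated normal,
#'   lower bound `2 * read_len`).
#' @param flank Captured flank around each gene span (bp).
#' @param seed Integer seed.
#' @param out Output SAM path.
#' @return `list(sam, truth, n_fragments)`; `truth` has one row per read
#'   with its label and, for junction-crossing reads, the shorter overhang.
#' @export
plant_fusion_reads <- function(ref, spec, coverage, read_len = 100L,
                               insert_mean = 350, insert_sd = 50,
                               flank = 500L, seed = 1L,
                               out = tempfile(fileext = ".sam")) {
  stopifnot(inherits(ref, "toy_reference"), inherits(spec, "fusion_spec"))
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  genes <- ref$ann$genes
  ga <- genes[genes$gene_id == spec$gene_a, , drop = FALSE]
  gb <- genes[genes$gene_id == spec$gene_b, , drop = FALSE]
  if (nrow(ga) != 1L || nrow(gb) != 1L) {
    stop("fusion partners not found in reference", call. = FALSE)
  }
  if (spec$break_a < ga$start || spec$break_a > ga$end ||
      spec$break_b < gb$start || spec$break_b > gb$end) {
    stop("breakpoints must fall inside the gene spans", call. = FALSE)
  }
  chrom_len <- nchar(ref$genome)
  ra <- c(max(1L, ga$start - flank), min(chrom_len[[ga$chrom]], ga$end + flank))
  rb <- c(max(1L, gb$start - flank), min(chrom_len[[gb$chrom]], gb$end + flank))
  seq_a <- substring(ref$genome[[ga$chrom]], ra[1L], ra[2L])
  seq_b <- substring(ref$genome[[gb$chrom]], rb[1L], rb[2L])
  len_a <- nchar(seq_a); len_b <- nchar(seq_b)
  L <- len_a + len_b

  # fused allele: upstream region up to its breakpoint + downstream region
  # from its breakpoint on
  if (spec$orientation == "a_up") {
    up <- list(chrom = ga$chrom, ref_start = ra[1L],
               len = spec$break_a - ra[1L] + 1L,
               seq = substring(seq_a, 1L, spec$break_a - ra[1L] + 1L))
    dn <- list(chrom = gb$chrom, ref_start = spec$break_b,
               len = rb[2L] - spec$break_b + 1L,
               seq = substring(seq_b, spec$break_b - rb[1L] + 1L, len_b))
  } else {
    up <- list(chrom = gb$chrom, ref_start = rb[1L],
               len = spec$break_b - rb[1L] + 1L,
               seq = substring(seq_b, 1L, spec$break_b - rb[1L] + 1L))
    dn <- list(chrom = ga$chrom, ref_start = spec$break_a,
               len = ra[2L] - spec$break_a + 1L,
               seq = substring(seq_a, spec$break_a - ra[1L] + 1L, len_a))
  }
  fused_seq <- paste0(up$seq, dn$seq)

  n_total <- max(1L, as.integer(round(coverage * L / (2 * read_len))))
  n_fused <- as.integer(round(spec$fraction * n_total))
  n_wt <- n_total - n_fused
  n_wt_a <- as.integer(round(n_wt * len_a / L))
  n_wt_b <- n_wt - n_wt_a

  set.seed(seed)
  pieces <- list(
    .frag_records(seq_a, list(list(chrom = ga$chrom, ref_start = ra[1L],
                                   len = len_a)),
                  n_wt_a, read_len, insert_mean, insert_sd, "wtA", TRUE),
    .frag_records(seq_b, list(list(chrom = gb$chrom, ref_start = rb[1L],
                                   len = len_b)),
                  n_wt_b, read_len, insert_mean, insert_sd, "wtB", TRUE),
    .frag_records(fused_seq, list(up[c("chrom", "ref_start", "len")],
                                  dn[c("chrom", "ref_start", "len")]),
                  n_fused, read_len, insert_mean, insert_sd, "fu", FALSE)
  )
  records <- do.call(rbind, lapply(pieces, `[[`, "records"))
  truth <- do.call(rbind, lapply(pieces, `[[`, "truth"))
  if (is.null(records)) records <- sam_record("x", 4L, "*", 0L, 0L, "*")[0L, ]
  write_sam(records, chrom_len, out)
  list(sam = out, truth = truth, n_fragments = n_total,
       junction = list(chrom_a = ga$chrom, break_a = spec$break_a,
                       chrom_b = gb$chrom, break_b = spec$break_b))
}

#' Subsample alignments by read pair
#'
#' Keeps or drops whole read pairs (primary and supplementary records move
#' together) with probability `fraction`. The decision is a per-read-name
#' uniform draw under `seed`, so the kept set at a smaller fraction is a
#' subset of the kept set at a larger fraction under the same seed — the
#' nesting a coverage-titration ladder needs.
#'
#' @param sam Input SAM path.
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param out Output SAM path.
#' @return `out`, invisibly.
#' @export
subsample_alignments <- function(sam, fraction, seed = 1L,
                                 out = tempfile(fileext = ".sam")) {
  if (fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]", call. = FALSE)
  }
  lines <- readLines(sam, warn = FALSE)
  hdr <- startsWith(lines, "@")
  qn <- sub("\t.*", "", lines[!hdr])
  uq <- sort(unique(qn))
  set.seed(seed)
  u <- stats::runif(length(uq))
  keep <- uq[u <= fraction]
  writeLines(c(lines[hdr], lines[!hdr][qn %in% keep]), out)
  invisible(out)
}

#' Coverage-sensitivity curve on a planted fusion
#'
#' For each replicate, plants the fusion at the base coverage, subsamples it
#' along the fraction ladder (nested within a replicate), runs the full
#' detection pipeline on each subsample, and records whether the planted
#' pair is called and with how much support.
#'
#' @param ref A `toy_reference`.
#' @param spec A [fusion_spec()].
#' @param fractions Numeric vector of subsampling fractions.
#' @param n_replicates Replicates per fraction.
#' @param cfg A [wes_config].
#' @param coverage Base coverage before subsampling.
#' @param seed Integer seed.
#' @return data.frame `(replicate, fraction, coverage, detected, n_support,
#'   n_split)`.
#' @export
sensitivity_curve <- function(ref, spec, fractions, n_replicates = 3L,
                              cfg = wes_config(), coverage = 150,
                              seed = 1L) {
  key <- .canon_pair(spec$gene_a, spec$gene_b)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + 1000L * r
    planted <- plant_fusion_reads(ref, spec, coverage = coverage,
                                  read_len = cfg$read_len, seed = rep_seed)
    for (f in sort(fractions, decreasing = TRUE)) {
      sub <- subsample_alignments(planted$sam, f, seed = rep_seed)
      res <- run_pipeline(sub, ref$ann, cfg)
      calls <- res$calls
      hit <- .canon_pair(calls$gene_a, calls$gene_b) == key
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, fraction = f, coverage = coverage * f,
        detected = any(hit),
        n_support = if (any(hit)) calls$n_total[hit][1L] else 0L,
        n_split = if (any(hit)) calls$n_split[hit][1L] else 0L
      )
      unlink(sub)
    }
    unlink(planted$sam)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
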