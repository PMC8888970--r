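# In-code fixtures shared across the suite: a small hand-laid annotation
# mimicking an inter-chromosomal fusion geometry (a 2-transcript gene and a
# 3-transcript gene on different chromosomes, a non-coding gene, and a
# mitochondrial gene), plus constructors for alignment segment rows and SAM
# files.

tiny_ann <- function() {
  genes <- data.frame(
    gene_id = c("A", "B", "C", "M"),
    gene_name = c("GENEA", "GENEB", "GENEC", "GENEM"),
    chrom = c("chr15", "chr17", "chr15", "chrM"),
    start = c(1000L, 1000L, 20000L, 100L),
    end = c(3000L, 4000L, 22000L, 1000L),
    strand = "+",
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "protein_coding"),
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    transcript_id = c("A.t1", "A.t2", "B.t1", "B.t2", "B.t3", "C.t1", "M.t1"),
    gene_id = c("A", "A", "B", "B", "B", "C", "M"),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    transcript_id = transcripts$transcript_id,
    gene_id = transcripts$gene_id,
    chrom = genes$chrom[match(transcripts$gene_id, genes$gene_id)],
    start = genes$start[match(transcripts$gene_id, genes$gene_id)],
    end = genes$end[match(transcripts$gene_id, genes$gene_id)],
    strand = "+",
    exon_number = 1L,
    stringsAsFactors = FALSE
  )
  genome_annotation(genes, transcripts, exons)
}

tiny_seqlens <- function() {
  c(chr15 = 30000L, chr17 = 10000L, chrM = 2000L)
}

# one alignment-segment row in the read_alignments() layout
seg <- function(read_name, chrom, pos, cigar, mapq = 60L, read_index = 1L,
                reverse = FALSE, supp = FALSE, dup = FALSE,
                sa = NA_character_) {
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  data.frame(read_name = read_name, flag = 0L, chrom = chrom,
             pos = as.integer(pos), end = as.integer(pos) + refw - 1L,
             mapq = as.integer(mapq), cigar = cigar,
             mate_chrom = NA_character_, mate_pos = NA_integer_,
             sa_tag = sa, is_reverse = reverse, is_supplementary = supp,
             is_duplicate = dup, read_index = as.integer(read_index),
             stringsAsFactors = FALSE)
}

# a full paired-end read pair as two SAM records
sam_pair <- function(qname, chrom1, pos1, chrom2, pos2, mapq1 = 60L,
                     mapq2 = 60L, cigar1 = "100M", cigar2 = "100M",
                     dup = FALSE) {
  f1 <- 0x1 + 0x40 + 0x20 + if (dup) 0x400 else 0
  f2 <- 0x1 + 0x80 + 0x10 + if (dup) 0x400 else 0
  rbind(
    sam_record(qname, f1, chrom1, pos1, mapq1, cigar1, rnext = chrom2,
               pnext = pos2),
    sam_record(qname, f2, chrom2, pos2, mapq2, cigar2, rnext = chrom1,
               pnext = pos1)
  )
}

# a split read: soft-clipped primary + supplementary with reciprocal SA tags
sam_split <- function(qname, chrom_p, pos_p, chrom_s, pos_s, m = 60L,
                      s = 40L, mapq = 60L, read_index = 1L) {
  base <- 0x1 + if (read_index == 1L) 0x40 else 0x80
  cig_p <- sprintf("%dM%dS", m, s)
  cig_s <- sprintf("%dS%dM", m, s)
  sa_p <- sprintf("SA:Z:%s,%d,+,%s,%d,0;", chrom_s, pos_s, cig_s, mapq)
  sa_s <- sprintf("SA:Z:%s,%d,+,%s,%d,0;", chrom_p, pos_p, cig_p, mapq)
  rbind(
    sam_record(qname, base, chrom_p, pos_p, mapq, cig_p, rnext = chrom_p,
               pnext = pos_p, tags = sa_p),
    sam_record(qname, base + 0x800, chrom_s, pos_s, mapq, cig_s,
               rnext = chrom_p, pnext = pos_p, tags = sa_s)
  )
}

write_tiny_sam <- function(records, path = tempfile(fileext = ".sam")) {
  write_sam(records, tiny_seqlens(), path)
  path
}

# discordant-pair evidence row (scan_alignments layout) for feq tests
mk_pair_row <- function(read_name, ann, genes1, genes2, chrom1, pos1,
                        chrom2, pos2, width = 100L) {
  df <- data.frame(read_name = read_name, chrom1 = chrom1, pos1 = pos1,
                   end1 = pos1 + width - 1L, mapq1 = 60L, chrom2 = chrom2,
                   pos2 = pos2, end2 = pos2 + width - 1L, mapq2 = 60L,
                   stringsAsFactors = FALSE)
  df$genes1 <- list(genes1)
  df$genes2 <- list(genes2)
  tx_of <- function(gs) {
    unlist(lapply(gs, function(g) transcripts_of(ann, g)), use.names = FALSE)
  }
  df$txs1 <- list(tx_of(genes1))
  df$txs2 <- list(tx_of(genes2))
  df
}

# split-read evidence row (detect_split layout)
mk_split_row <- function(read_name, genes_p, genes_s, chrom_p = "chr15",
                         junction_p = 1059L, chrom_s = "chr17",
                         junction_s = 2000L, read_index = 1L,
                         clip_side = "right", n_genes = NULL) {
  df <- data.frame(read_name = read_name, read_index = read_index,
                   chrom_p = chrom_p, pos_p = junction_p - 59L,
                   end_p = junction_p, clip_side = clip_side,
                   junction_p = junction_p, chrom_s = chrom_s,
                   pos_s = junction_s, end_s = junction_s + 39L,
                   junction_s = junction_s, mapq_min = 60L,
                   n_genes = if (is.null(n_genes)) {
                     length(unique(c(genes_p, genes_s)))
                   } else n_genes,
                   stringsAsFactors = FALSE)
  df$genes_p <- list(genes_p)
  df$genes_s <- list(genes_s)
  df
}
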