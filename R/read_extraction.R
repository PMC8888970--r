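# Evidence extraction: stream alignment segments, apply the MAPQ gate, and
# classify read pairs into discordant-pair or split-read fusion evidence.
#
# Discordance is defined by gene-assignment disjointness (mates overlapping
# disjoint gene sets), not by the aligner's proper-pair flag: the flag depends
# on insert-size calibration while the fusion definition is gene-centric.

.canon_pair <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "\r")
}

.cross_pair_keys <- function(genes_a, genes_b) {
  if (length(genes_a) == 0L || length(genes_b) == 0L) return(character())
  grid <- expand.grid(a = genes_a, b = genes_b, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  unique(.canon_pair(grid$a, grid$b))
}

# gene_id sets overlapped by each segment row (gene span, introns included)
.segment_gene_sets <- function(seg, ann) {
  n <- nrow(seg)
  out <- rep(list(character()), n)
  if (n == 0L || nrow(ann$genes) == 0L) return(out)
  ok <- !is.na(seg$pos) & !is.na(seg$end) & seg$chrom %in% ann$genes$chrom
  if (!any(ok)) return(out)
  q <- GenomicRanges::GRanges(seg$chrom[ok],
                              IRanges::IRanges(seg$pos[ok], seg$end[ok]))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, ann$gene_gr))
  ids <- S4Vectors::mcols(ann$gene_gr)$gene_id[S4Vectors::subjectHits(hits)]
  sets <- split(ids, factor(S4Vectors::queryHits(hits), levels = seq_len(sum(ok))))
  out[ok] <- lapply(sets, function(x) sort(unique(x)))
  out
}

# transcript ids whose span overlaps each segment row
.segment_tx_sets <- function(seg, ann) {
  n <- nrow(seg)
  out <- rep(list(character()), n)
  if (n == 0L || length(ann$tx_gr) == 0L) return(out)
  tx_chroms <- as.character(GenomicRanges::seqnames(ann$tx_gr))
  ok <- !is.na(seg$pos) & !is.na(seg$end) & seg$chrom %in% tx_chroms
  if (!any(ok)) return(out)
  q <- GenomicRanges::GRanges(seg$chrom[ok],
                              IRanges::IRanges(seg$pos[ok], seg$end[ok]))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, ann$tx_gr))
  ids <- S4Vectors::mcols(ann$tx_gr)$transcript_id[S4Vectors::subjectHits(hits)]
  sets <- split(ids, factor(S4Vectors::queryHits(hits), levels = seq_len(sum(ok))))
  out[ok] <- lapply(sets, function(x) sort(unique(x)))
  out
}

#' Classify a primary read pair
#'
#' A pair is `"discordant"` when both mates pass the MAPQ gate, each overlaps
#' at least one gene, and the two gene sets are disjoint; `"concordant"` when
#' the gene sets intersect; `"unassigned"` when either mate fails MAPQ or
#' overlaps no gene.
#'
#' @param seg_r1,seg_r2 One-row segment data.frames (as from
#'   [read_alignments()]) holding the primary alignment of each mate; both
#'   must share a read name.
#' @param ann A [genome_annotation].
#' @param cfg A [wes_config].
#' @return One of `"discordant"`, `"concordant"`, `"unassigned"`.
#' @export
classify_pair <- function(seg_r1, seg_r2, ann, cfg = wes_config()) {
  if (!identical(seg_r1$read_name, seg_r2$read_name)) {
    stop("segments belong to different read names", call. = FALSE)
  }
  if (seg_r1$mapq < cfg$min_mapq || seg_r2$mapq < cfg$min_mapq) {
    return("unassigned")
  }
  g1 <- .segment_gene_sets(seg_r1, ann)[[1L]]
  g2 <- .segment_gene_sets(seg_r2, ann)[[1L]]
  if (length(g1) == 0L || length(g2) == 0L) return("unassigned")
  if (length(intersect(g1, g2)) > 0L) return("concordant")
  "discordant"
}

#' Detect a split read among the segments of one physical read
#'
#' A read is split-read evidence when its primary alignment carries a
#' soft-clip of at least `min_clip_len` bases and a supplementary alignment
#' (a separate record or one synthesized from the `SA` tag) places the
#' clipped part elsewhere, every used segment passes the MAPQ gate, and the
#' segments together touch at least two distinct genes. The junction is
#' estimated as the clip boundary on the primary segment and the facing end
#' of the supplementary segment.
#'
#' @param segs data.frame of segments for one `(read_name, read_index)`
#'   (primary plus any supplementary records).
#' @param ann A [genome_annotation].
#' @param cfg A [wes_config].
#' @return A one-row data.frame describing the split read, or `NULL`.
#' @export
detect_split <- function(segs, ann, cfg = wes_config()) {
  prim <- segs[!segs$is_supplementary, , drop = FALSE]
  if (nrow(prim) == 0L) return(NULL)
  prim <- prim[1L, , drop = FALSE]
  if (is.na(prim$cigar) || prim$mapq < cfg$min_mapq) return(NULL)
  cl <- .clip_lens(prim$cigar)
  if (max(cl) < cfg$min_clip_len) return(NULL)

  supp <- segs[segs$is_supplementary, , drop = FALSE]
  if (nrow(supp) == 0L && !is.na(prim$sa_tag) && nzchar(prim$sa_tag)) {
    sa <- .parse_sa(prim$sa_tag)
    if (nrow(sa) > 0L) {
      supp <- data.frame(
        read_name = prim$read_name, flag = NA_integer_,
        chrom = sa$chrom, pos = sa$pos,
        end = sa$pos +
          GenomicAlignments::cigarWidthAlongReferenceSpace(sa$cigar) - 1L,
        mapq = sa$mapq, cigar = sa$cigar,
        mate_chrom = NA_character_, mate_pos = NA_integer_,
        sa_tag = NA_character_, is_reverse = sa$strand == "-",
        is_supplementary = TRUE, is_duplicate = FALSE,
        read_index = prim$read_index, stringsAsFactors = FALSE
      )
    }
  }
  supp <- supp[!is.na(supp$mapq) & supp$mapq >= cfg$min_mapq, , drop = FALSE]
  if (nrow(supp) == 0L) return(NULL)

  clip_side <- if (cl[2L] >= cl[1L]) "right" else "left"
  junction_p <- if (clip_side == "right") prim$end else prim$pos
  s <- supp[which.max(supp$mapq), , drop = FALSE]
  junction_s <- if (clip_side == "right") s$pos else s$end

  genes_p <- .segment_gene_sets(prim, ann)[[1L]]
  genes_supp_all <- .segment_gene_sets(supp, ann)
  genes_s <- genes_supp_all[[which.max(supp$mapq)]]
  n_genes <- length(unique(c(genes_p, unlist(genes_supp_all))))
  if (length(unique(c(genes_p, genes_s))) < 2L) return(NULL)

  out <- data.frame(
    read_name = prim$read_name, read_index = prim$read_index,
    chrom_p = prim$chrom, pos_p = prim$pos, end_p = prim$end,
    clip_side = clip_side, junction_p = junction_p,
    chrom_s = s$chrom, pos_s = s$pos, end_s = s$end,
    junction_s = junction_s,
    mapq_min = min(prim$mapq, s$mapq),
    n_genes = n_genes,
    stringsAsFactors = FALSE
  )
  out$genes_p <- list(genes_p)
  out$genes_s <- list(genes_s)
  out
}

.empty_pairs <- function() {
  df <- data.frame(read_name = character(),
                   chrom1 = character(), pos1 = integer(), end1 = integer(),
                   mapq1 = integer(),
                   chrom2 = character(), pos2 = integer(), end2 = integer(),
                   mapq2 = integer(), stringsAsFactors = FALSE)
  df$genes1 <- list(); df$genes2 <- list()
  df$txs1 <- list(); df$txs2 <- list()
  df
}

.empty_splits <- function() {
  df <- data.frame(read_name = character(), read_index = integer(),
                   chrom_p = character(), pos_p = integer(), end_p = integer(),
                   clip_side = character(), junction_p = integer(),
                   chrom_s = character(), pos_s = integer(), end_s = integer(),
                   junction_s = integer(), mapq_min = integer(),
                   n_genes = integer(), stringsAsFactors = FALSE)
  df$genes_p <- list(); df$genes_s <- list()
  df
}

#' Extract discordant-pair and split-read evidence from an alignment file
#'
#' Scans all mapped records, drops duplicate-flagged records (unless
#' `keep_duplicates`), applies the MAPQ gate to every segment, and returns
#' the two evidence tables. Concordant pairs (both mates within the same
#' gene, no informative clip) produce nothing.
#'
#' @param bam Path to a coordinate-sorted SAM or BAM file.
#' @param ann A [genome_annotation].
#' @param cfg A [wes_config].
#' @return `list(pairs = <discordant pairs>, splits = <split reads>)`.
#' @export
scan_alignments <- function(bam, ann, cfg = wes_config()) {
  segs <- read_alignments(bam)
  if (!cfg$keep_duplicates) {
    segs <- segs[!segs$is_duplicate, , drop = FALSE]
  }

  # --- split-read detection, per physical read ---------------------------
  splits <- .empty_splits()
  if (nrow(segs) > 0L) {
    maxclip <- rep(0L, nrow(segs))
    okc <- !is.na(segs$cigar)
    if (any(okc)) {
      cl <- .clip_lens(segs$cigar[okc])
      maxclip[okc] <- pmax(cl[, 1L], cl[, 2L])
    }
    key <- paste(segs$read_name, segs$read_index, sep = "\r")
    has_supp <- tapply(segs$is_supplementary, key, any)
    has_clip <- tapply(maxclip >= cfg$min_clip_len & !segs$is_supplementary,
                       key, any)
    has_sa <- tapply(!is.na(segs$sa_tag) & nzchar(segs$sa_tag) &
                       !segs$is_supplementary, key, any)
    cand_keys <- names(has_supp)[(has_supp | has_sa) & has_clip]
    if (length(cand_keys) > 0L) {
      idx <- split(seq_len(nrow(segs)), key)
      found <- lapply(cand_keys, function(k) {
        detect_split(segs[idx[[k]], , drop = FALSE], ann, cfg)
      })
      found <- found[!vapply(found, is.null, TRUE)]
      if (length(found) > 0L) splits <- do.call(rbind, found)
    }
  }

  # --- discordant-pair classification over primary segments -------------
  pairs <- .empty_pairs()
  prim <- segs[!segs$is_supplementary, , drop = FALSE]
  if (nrow(prim) > 0L) {
    r1 <- prim[prim$read_index == 1L, , drop = FALSE]
    r2 <- prim[prim$read_index == 2L, , drop = FALSE]
    r1 <- r1[!duplicated(r1$read_name), , drop = FALSE]
    r2 <- r2[!duplicated(r2$read_name), , drop = FALSE]
    common <- intersect(r1$read_name, r2$read_name)
    if (length(common) > 0L) {
      r1 <- r1[match(common, r1$read_name), , drop = FALSE]
      r2 <- r2[match(common, r2$read_name), , drop = FALSE]
      pass <- r1$mapq >= cfg$min_mapq & r2$mapq >= cfg$min_mapq
      g1 <- .segment_gene_sets(r1, ann)
      g2 <- .segment_gene_sets(r2, ann)
      disc <- logical(length(common))
      for (i in which(pass)) {
        a <- g1[[i]]; b <- g2[[i]]
        disc[i] <- length(a) > 0L && length(b) > 0L &&
          length(intersect(a, b)) == 0L
      }
      if (any(disc)) {
        w <- which(disc)
        tx1 <- .segment_tx_sets(r1[w, , drop = FALSE], ann)
        tx2 <- .segment_tx_sets(r2[w, , drop = FALSE], ann)
        pairs <- data.frame(
          read_name = common[w],
          chrom1 = r1$chrom[w], pos1 = r1$pos[w], end1 = r1$end[w],
          mapq1 = r1$mapq[w],
          chrom2 = r2$chrom[w], pos2 = r2$pos[w], end2 = r2$end[w],
          mapq2 = r2$mapq[w], stringsAsFactors = FALSE
        )
        pairs$genes1 <- g1[w]
        pairs$genes2 <- g2[w]
        pairs$txs1 <- tx1
        pairs$txs2 <- tx2
      }
    }
  }
  rownames(pairs) <- NULL
  rownames(splits) <- NULL
  list(pairs = pairs, splits = splits)
}

#' Deduplicate evidence units
#'
#' Enforces "at most one support unit per (read name, gene pair)": repeated
#' split rows for the same read and gene pair collapse to one, and a read
#' pair that contributes both a split and a discordant signal for the same
#' gene pair is counted once, in the split tally (a split read covers the
#' junction directly and is the stronger evidence).
#'
#' @param pairs,splits Evidence tables from [scan_alignments()].
#' @return `list(pairs, splits)` with duplicates removed.
#' @export
dedup_evidence <- function(pairs, splits) {
  if (nrow(splits) > 0L) {
    skey <- vapply(seq_len(nrow(splits)), function(i) {
      paste(sort(.cross_pair_keys(splits$genes_p[[i]], splits$genes_s[[i]])),
            collapse = ";")
    }, "")
    splits <- splits[!duplicated(paste(splits$read_name, skey)), , drop = FALSE]
  }
  if (nrow(pairs) > 0L) {
    pairs <- pairs[!duplicated(pairs$read_name), , drop = FALSE]
    if (nrow(splits) > 0L) {
      split_units <- unique(unlist(lapply(seq_len(nrow(splits)), function(i) {
        paste(splits$read_name[i],
              .cross_pair_keys(splits$genes_p[[i]], splits$genes_s[[i]]))
      })))
      covered <- vapply(seq_len(nrow(pairs)), function(i) {
        keys <- .cross_pair_keys(pairs$genes1[[i]], pairs$genes2[[i]])
        length(keys) > 0L && all(paste(pairs$read_name[i], keys) %in% split_units)
      }, TRUE)
      pairs <- pairs[!covered, , drop = FALSE]
    }
  }
  rownames(pairs) <- NULL
  rownames(splits) <- NULL
  list(pairs = pairs, splits = splits)
}
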