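# Fusion equivalence classes (FEQs): each discordant read pair supports every
# combination of one transcript per mate; the class of those fusion
# transcripts captures read sharing between candidate fusion genes, and
# gene-level candidates are aggregated from FEQs plus split reads.

.feq_key <- function(members) {
  paste(sort(paste(members$tx_a, members$tx_b, sep = "\r")), collapse = ";")
}

#' Build the fusion equivalence class of one discordant read pair
#'
#' Each mate is assigned the transcripts (of its overlapped genes) whose span
#' covers the mate's alignment interval. The class members are the Cartesian
#' product of the two transcript sets, restricted to cross-gene
#' combinations: a mate hitting 2 transcripts combined with a mate hitting 3
#' yields 6 fusion transcripts.
#'
#' @param pair One row of the discordant-pair table from [scan_alignments()].
#' @param ann A [genome_annotation].
#' @return An object of class `feq`: `members` (data.frame `tx_a`, `tx_b`,
#'   `gene_a`, `gene_b`) and `reads` (supporting read table with mate
#'   coordinates).
#' @export
build_feq <- function(pair, ann) {
  stopifnot(nrow(pair) == 1L)
  g1 <- pair$genes1[[1L]]
  g2 <- pair$genes2[[1L]]
  if (length(g1) == 0L || length(g2) == 0L ||
      length(intersect(g1, g2)) > 0L) {
    stop("build_feq requires disjoint non-empty gene sets for the two mates",
         call. = FALSE)
  }
  tx1 <- pair$txs1[[1L]]
  tx2 <- pair$txs2[[1L]]
  gene_of <- function(tx) {
    ann$transcripts$gene_id[match(tx, ann$transcripts$transcript_id)]
  }
  tx1 <- tx1[gene_of(tx1) %in% g1]
  tx2 <- tx2[gene_of(tx2) %in% g2]
  if (length(tx1) == 0L || length(tx2) == 0L) {
    stop("empty transcript set for one mate of read '", pair$read_name,
         "': annotation/alignment mismatch", call. = FALSE)
  }
  grid <- expand.grid(tx_a = tx1, tx_b = tx2, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$gene_a <- gene_of(grid$tx_a)
  grid$gene_b <- gene_of(grid$tx_b)
  grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
  rownames(grid) <- NULL
  reads <- data.frame(
    read_name = pair$read_name,
    chrom1 = pair$chrom1, pos1 = pair$pos1, end1 = pair$end1,
    chrom2 = pair$chrom2, pos2 = pair$pos2, end2 = pair$end2,
    stringsAsFactors = FALSE
  )
  structure(list(members = grid, reads = reads), class = "feq")
}

#' @export
print.feq <- function(x, ...) {
  cat(sprintf("feq: %d fusion transcript(s), %d supporting read pair(s)\n",
              nrow(x$members), nrow(x$reads)))
  invisible(x)
}

#' Merge fusion equivalence classes with identical member sets
#'
#' Classes generated by different read pairs but spanning the same set of
#' fusion transcripts are merged, pooling their supporting reads. Total
#' support is conserved: the summed read counts of the output equal the
#' number of input classes' reads.
#'
#' @param feqs List of `feq` objects.
#' @return List of merged `feq` objects, one per distinct member set.
#' @export
merge_feqs <- function(feqs) {
  if (length(feqs) == 0L) return(list())
  keys <- vapply(feqs, function(f) .feq_key(f$members), "")
  out <- lapply(split(seq_along(feqs), keys), function(ix) {
    reads <- do.call(rbind, lapply(feqs[ix], `[[`, "reads"))
    reads <- reads[!duplicated(reads$read_name), , drop = FALSE]
    rownames(reads) <- NULL
    structure(list(members = feqs[[ix[1L]]]$members, reads = reads),
              class = "feq")
  })
  unname(out)
}

# order a gene pair canonically: by (chrom, start) of the gene spans,
# falling back to gene_id; DNA evidence alone cannot orient a fusion
.order_gene_pair <- function(g1, g2, ann) {
  i1 <- match(g1, ann$genes$gene_id)
  i2 <- match(g2, ann$genes$gene_id)
  key <- function(i, g) paste(ann$genes$chrom[i],
                              sprintf("%012d", ann$genes$start[i]), g)
  if (is.na(i1) || is.na(i2)) {
    if (g1 <= g2) c(g1, g2) else c(g2, g1)
  } else if (key(i1, g1) <= key(i2, g2)) {
    c(g1, g2)
  } else {
    c(g2, g1)
  }
}

# lower-middle median: deterministic, ties resolve to the smaller coordinate
.median_low <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

#' Aggregate FEQs and split reads into fusion-gene candidates
#'
#' One candidate is produced per unordered gene pair with at least one
#' deduplicated evidence unit. Discordant support counts read pairs from the
#' FEQs (excluding reads already counted as split for the same pair); split
#' support counts deduplicated split units. Breakpoints are the per-side
#' medians of the split junctions when split evidence exists, else the
#' innermost discordant mate ends. Orientation is inferred from split
#' geometry (a right-side clip marks the donating upstream segment) when
#' available.
#'
#' @param feqs List of merged `feq` objects.
#' @param splits Deduplicated split-read table.
#' @param ann A [genome_annotation].
#' @return data.frame of candidates sorted by `(gene_a, gene_b)` with
#'   columns `gene_a`, `gene_b`, `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `n_discordant`, `n_split`, `n_total`, `orientation`, `filter_flags`.
#' @export
candidates_from_evidence <- function(feqs, splits, ann) {
  units <- list()

  # split units: (read_name, gene pair) with junction coordinates
  if (nrow(splits) > 0L) {
    for (i in seq_len(nrow(splits))) {
      gp <- splits$genes_p[[i]]
      gs <- splits$genes_s[[i]]
      grid <- expand.grid(a = gp, b = gs, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      for (j in seq_len(nrow(grid))) {
        og <- .order_gene_pair(grid$a[j], grid$b[j], ann)
        flipped <- !identical(og[1L], grid$a[j])
        # upstream side: the clipped 3' end of the primary donates upstream
        orient <- if (splits$clip_side[i] == "right") {
          if (flipped) "b_up" else "a_up"
        } else {
          if (flipped) "a_up" else "b_up"
        }
        units[[length(units) + 1L]] <- data.frame(
          read_name = splits$read_name[i], gene_a = og[1L], gene_b = og[2L],
          type = "split",
          chrom_a = if (flipped) splits$chrom_s[i] else splits$chrom_p[i],
          coord_a = if (flipped) splits$junction_s[i] else splits$junction_p[i],
          chrom_b = if (flipped) splits$chrom_p[i] else splits$chrom_s[i],
          coord_b = if (flipped) splits$junction_p[i] else splits$junction_s[i],
          orientation = orient, stringsAsFactors = FALSE
        )
      }
    }
  }

  # discordant units from FEQ supporting reads
  for (f in feqs) {
    gene_pairs <- unique(f$members[, c("gene_a", "gene_b")])
    for (j in seq_len(nrow(gene_pairs))) {
      og <- .order_gene_pair(gene_pairs$gene_a[j], gene_pairs$gene_b[j], ann)
      flipped <- !identical(og[1L], gene_pairs$gene_a[j])
      for (k in seq_len(nrow(f$reads))) {
        rd <- f$reads[k, ]
        # innermost ends: the mate edge facing the partner locus
        inner <- function(chrom, pos, end, o_chrom, o_pos) {
          if (identical(chrom, o_chrom)) {
            if (pos <= o_pos) end else pos
          } else {
            end
          }
        }
        c1 <- inner(rd$chrom1, rd$pos1, rd$end1, rd$chrom2, rd$pos2)
        c2 <- inner(rd$chrom2, rd$pos2, rd$end2, rd$chrom1, rd$pos1)
        units[[length(units) + 1L]] <- data.frame(
          read_name = rd$read_name, gene_a = og[1L], gene_b = og[2L],
          type = "discordant",
          chrom_a = if (flipped) rd$chrom2 else rd$chrom1,
          coord_a = if (flipped) c2 else c1,
          chrom_b = if (flipped) rd$chrom1 else rd$chrom2,
          coord_b = if (flipped) c1 else c2,
          orientation = "unknown", stringsAsFactors = FALSE
        )
      }
    }
  }

  if (length(units) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      n_discordant = integer(), n_split = integer(),
                      n_total = integer(), orientation = character(),
                      filter_flags = character(), stringsAsFactors = FALSE))
  }
  u <- do.call(rbind, units)

  # dedup: one unit per (read, pair); mixed evidence counts as split
  u <- u[order(u$gene_a, u$gene_b, u$read_name, u$type != "split"), , drop = FALSE]
  u <- u[!duplicated(paste(u$read_name, u$gene_a, u$gene_b)), , drop = FALSE]

  pk <- paste(u$gene_a, u$gene_b, sep = "\r")
  rows <- lapply(split(seq_len(nrow(u)), pk), function(ix) {
    uu <- u[ix, , drop = FALSE]
    sp <- uu[uu$type == "split", , drop = FALSE]
    n_split <- nrow(sp)
    n_disc <- nrow(uu) - n_split
    if (n_split > 0L) {
      pos_a <- .median_low(sp$coord_a)
      pos_b <- .median_low(sp$coord_b)
      chrom_a <- sp$chrom_a[1L]
      chrom_b <- sp$chrom_b[1L]
      orient <- names(sort(table(sp$orientation), decreasing = TRUE))[1L]
    } else {
      pos_a <- .median_low(uu$coord_a)
      pos_b <- .median_low(uu$coord_b)
      chrom_a <- uu$chrom_a[1L]
      chrom_b <- uu$chrom_b[1L]
      orient <- "unknown"
    }
    data.frame(gene_a = uu$gene_a[1L], gene_b = uu$gene_b[1L],
               chrom_a = chrom_a, pos_a = as.integer(pos_a),
               chrom_b = chrom_b, pos_b = as.integer(pos_b),
               n_discordant = n_disc, n_split = n_split,
               n_total = n_disc + n_split,
               orientation = orient, filter_flags = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
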