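#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Genome annotation container
#'
#' Bundles gene, transcript and exon tables with a `GRanges` interval index
#' over gene spans. Coordinates are 1-based inclusive throughout (the GTF
#' convention); alignment positions are converted to the same convention at
#' the extraction boundary so the whole pipeline uses a single system.
#'
#' Gene assignment downstream uses the full gene span (introns included):
#' exome/panel DNA reads legitimately fall in intronic capture flanks near
#' breakpoints, and an exon-union rule would drop that evidence.
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `exon_number`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, transcripts, exons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)

  if (nrow(transcripts) > 0L) {
    bad <- setdiff(transcripts$gene_id, genes$gene_id)
    if (length(bad) > 0L) {
      stop("transcripts reference unknown gene_id(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(genes) > 0L && any(genes$start > genes$end)) {
    stop("gene with start > end", call. = FALSE)
  }
  if (nrow(exons) > 0L) {
    chk <- tapply(exons$chrom, exons$transcript_id,
                  function(ch) length(unique(ch)))
    if (any(chk > 1L)) {
      stop("transcript with exons on more than one chromosome", call. = FALSE)
    }
  }

  if (nrow(genes) > 0L) {
    gene_gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      gene_id = genes$gene_id
    )
  } else {
    gene_gr <- GenomicRanges::GRanges()
  }

  # transcript spans (min/max over exons) back the transcript-level read
  # assignment used when fusion equivalence classes are built
  if (nrow(exons) > 0L) {
    tx_start <- tapply(exons$start, exons$transcript_id, min)
    tx_end <- tapply(exons$end, exons$transcript_id, max)
    tx_chrom <- tapply(exons$chrom, exons$transcript_id, function(x) x[1L])
    tx_ids <- names(tx_start)
    tx_gene <- transcripts$gene_id[match(tx_ids, transcripts$transcript_id)]
    tx_gr <- GenomicRanges::GRanges(
      seqnames = unname(tx_chrom),
      ranges = IRanges::IRanges(start = unname(tx_start), end = unname(tx_end)),
      transcript_id = tx_ids,
      gene_id = tx_gene
    )
  } else {
    tx_gr <- GenomicRanges::GRanges()
  }

  structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         gene_gr = gene_gr, tx_gr = tx_gr),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

.empty_annotation <- function() {
  genome_annotation(
    genes = data.frame(gene_id = character(), gene_name = character(),
                       chrom = character(), start = integer(), end = integer(),
                       strand = character(), biotype = character(),
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), gene_id = character(),
                       chrom = character(), start = integer(), end = integer(),
                       strand = character(), exon_number = integer(),
                       stringsAsFactors = FALSE)
  )
}

.first_attr <- function(meta, keys) {
  for (k in keys) {
    if (k %in% names(meta)) {
      v <- as.character(meta[[k]])
      if (!all(is.na(v))) return(v)
    }
  }
  rep(NA_character_, nrow(meta))
}

#' Parse a GTF file into a genome annotation
#'
#' Reads gene models from a GTF (optionally gzip-compressed) via
#' `rtracklayer`. Gene spans come from `gene` feature lines when present;
#' genes that appear only on exon lines get their span inferred as the
#' min/max over their exons. The biotype is taken from the `gene_biotype`
#' attribute, falling back to `gene_type` (GTF dialect drift), and defaults
#' to `"unknown"` when neither is present — which fails the protein-coding
#' filter unless `assume_coding` is set in the configuration.
#'
#' Exon records lacking a `gene_id` attribute are skipped with a warning
#' naming the offending record numbers.
#'
#' @param path Path to a GTF file.
#' @return A [genome_annotation] object.
#' @export
#' @examples
#' ref <- make_toy_reference(n_genes = 2, seed = 1)
#' gtf <- tempfile(fileext = ".gtf")
#' write_gtf(ref$ann, gtf)
#' ann <- parse_gtf(gtf)
#' nrow(ann$genes)
parse_gtf <- function(path) {
  if (!file.exists(path)) {
    stop("GTF file not found: ", path, call. = FALSE)
  }
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("unreadable GTF file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    return(.empty_annotation())
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(meta$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  gene_id <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
             else rep(NA_character_, length(gr))
  tx_id <- if ("transcript_id" %in% names(meta)) as.character(meta$transcript_id)
           else rep(NA_character_, length(gr))
  biotype <- .first_attr(meta, c("gene_biotype", "gene_type"))
  gene_name <- if ("gene_name" %in% names(meta)) as.character(meta$gene_name)
               else rep(NA_character_, length(gr))

  is_exon <- type == "exon"
  bad_exon <- is_exon & (is.na(gene_id) | gene_id == "")
  if (any(bad_exon)) {
    warning("skipping ", sum(bad_exon),
            " exon record(s) without gene_id (record ",
            paste(utils::head(which(bad_exon), 5L), collapse = ", "), ")",
            call. = FALSE)
    is_exon <- is_exon & !bad_exon
  }
  bad_tx <- is_exon & (is.na(tx_id) | tx_id == "")
  if (any(bad_tx)) {
    warning("skipping ", sum(bad_tx),
            " exon record(s) without transcript_id", call. = FALSE)
    is_exon <- is_exon & !bad_tx
  }

  exn <- if ("exon_number" %in% names(meta)) {
    suppressWarnings(as.integer(as.character(meta$exon_number)))
  } else {
    rep(NA_integer_, length(gr))
  }

  exons <- data.frame(
    transcript_id = tx_id[is_exon],
    gene_id = gene_id[is_exon],
    chrom = chrom[is_exon],
    start = start[is_exon],
    end = end[is_exon],
    strand = strand[is_exon],
    exon_number = exn[is_exon],
    stringsAsFactors = FALSE
  )
  # assign missing ordinals in transcription order (5' -> 3')
  if (nrow(exons) > 0L && anyNA(exons$exon_number)) {
    sp <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in sp) {
      if (anyNA(exons$exon_number[idx])) {
        o <- order(exons$start[idx],
                   decreasing = identical(exons$strand[idx][1L], "-"))
        exons$exon_number[idx[o]] <- seq_along(idx)
      }
    }
  }

  transcripts <- unique(exons[, c("transcript_id", "gene_id")])
  rownames(transcripts) <- NULL

  is_gene <- type == "gene" & !is.na(gene_id)
  genes <- data.frame(
    gene_id = gene_id[is_gene],
    gene_name = gene_name[is_gene],
    chrom = chrom[is_gene],
    start = start[is_gene],
    end = end[is_gene],
    strand = strand[is_gene],
    biotype = biotype[is_gene],
    stringsAsFactors = FALSE
  )
  # genes present only through exon lines: span inferred from their exons
  orphan <- setdiff(unique(exons$gene_id), genes$gene_id)
  if (length(orphan) > 0L) {
    ex_bt <- biotype[is_exon]
    add <- do.call(rbind, lapply(orphan, function(g) {
      e <- exons[exons$gene_id == g, , drop = FALSE]
      bt <- ex_bt[exons$gene_id == g]
      data.frame(gene_id = g, gene_name = g, chrom = e$chrom[1L],
                 start = min(e$start), end = max(e$end),
                 strand = e$strand[1L],
                 biotype = if (all(is.na(bt))) "unknown" else bt[!is.na(bt)][1L],
                 stringsAsFactors = FALSE)
    }))
    genes <- rbind(genes, add)
  }
  genes$biotype[is.na(genes$biotype)] <- "unknown"
  genes$gene_name[is.na(genes$gene_name)] <- genes$gene_id[is.na(genes$gene_name)]
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  genome_annotation(genes, transcripts, exons)
}

#' Write a genome annotation back to GTF
#'
#' Emits gene, transcript and exon feature lines with `gene_id`,
#' `transcript_id`, `gene_name`, `gene_biotype` and `exon_number` attributes,
#' so that [parse_gtf()] round-trips the annotation.
#'
#' @param ann A [genome_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  tx <- ann$transcripts
  ex <- ann$exons
  tx_meta <- merge(tx, g[, c("gene_id", "gene_name", "biotype")], by = "gene_id")
  tx_span <- if (nrow(ex) > 0L) {
    data.frame(
      transcript_id = names(tapply(ex$start, ex$transcript_id, min)),
      start = unname(tapply(ex$start, ex$transcript_id, min)),
      end = unname(tapply(ex$end, ex$transcript_id, max)),
      chrom = unname(tapply(ex$chrom, ex$transcript_id, function(x) x[1L])),
      strand = unname(tapply(ex$strand, ex$transcript_id, function(x) x[1L])),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(transcript_id = character(), start = integer(), end = integer(),
               chrom = character(), strand = character())
  }
  tx_meta <- merge(tx_meta, tx_span, by = "transcript_id")

  ex_meta <- merge(ex, g[, c("gene_id", "gene_name", "biotype")], by = "gene_id")

  mk <- function(chrom, start, end, strand, type, gene_id, tx_id, gene_name,
                 biotype, exon_number) {
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = strand,
      type = type, gene_id = gene_id, transcript_id = tx_id,
      gene_name = gene_name, gene_biotype = biotype,
      exon_number = exon_number, source = "wesfusion"
    )
  }
  parts <- list()
  if (nrow(g) > 0L) {
    parts$gene <- mk(g$chrom, g$start, g$end, g$strand, "gene", g$gene_id,
                     NA_character_, g$gene_name, g$biotype, NA_integer_)
  }
  if (nrow(tx_meta) > 0L) {
    parts$tx <- mk(tx_meta$chrom, tx_meta$start, tx_meta$end, tx_meta$strand,
                   "transcript", tx_meta$gene_id, tx_meta$transcript_id,
                   tx_meta$gene_name, tx_meta$biotype, NA_integer_)
  }
  if (nrow(ex_meta) > 0L) {
    parts$exon <- mk(ex_meta$chrom, ex_meta$start, ex_meta$end, ex_meta$strand,
                     "exon", ex_meta$gene_id, ex_meta$transcript_id,
                     ex_meta$gene_name, ex_meta$biotype, ex_meta$exon_number)
  }
  gr <- do.call(c, unname(parts))
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Genes overlapping a genomic interval
#'
#' Interval query against the gene-span index. A gene is returned when its
#' full span (introns included) intersects `[start, end]`.
#'
#' @param ann A [genome_annotation].
#' @param chrom Chromosome name (matched literally against the annotation).
#' @param start,end 1-based inclusive interval; `start <= end`.
#' @return A data.frame of matching gene rows (possibly empty).
#' @export
genes_overlapping <- function(ann, chrom, start, end) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (start > end) stop("start must be <= end", call. = FALSE)
  if (nrow(ann$genes) == 0L) return(ann$genes)
  if (!chrom %in% ann$genes$chrom) {
    return(ann$genes[0L, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, ann$gene_gr)
  ids <- unique(S4Vectors::mcols(ann$gene_gr)$gene_id[S4Vectors::subjectHits(hits)])
  ann$genes[ann$genes$gene_id %in% ids, , drop = FALSE]
}

#' Transcripts of a gene
#'
#' @param ann A [genome_annotation].
#' @param gene_id Gene identifier; must exist in the annotation.
#' @return Character vector of transcript ids.
#' @export
transcripts_of <- function(ann, gene_id) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (!gene_id %in% ann$genes$gene_id) {
    stop("unknown gene_id: ", gene_id, call. = FALSE)
  }
  ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
}
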