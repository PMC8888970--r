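#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments explodeCigarOps explodeCigarOpLengths
#'   cigarWidthAlongReferenceSpace cigarWidthAlongQuerySpace
NULL

# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_READ1 <- 0x40L
FLAG_READ2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Build a SAM record row
#'
#' Convenience constructor for hand-built alignment fixtures: returns a
#' one-row data.frame in the column layout [write_sam()] expects. Tags are
#' given as a single pre-formatted string (e.g. `"SA:Z:chr2,100,+,40M60S,60,0;"`).
#'
#' @param qname Read name.
#' @param flag Integer SAM flag.
#' @param chrom Reference name.
#' @param pos 1-based leftmost mapped position.
#' @param mapq Mapping quality.
#' @param cigar CIGAR string.
#' @param rnext,pnext Mate reference name (`"="` allowed) and position.
#' @param seq Read sequence; defaults to all-`A` of the CIGAR query length.
#' @param tags Optional tab-joined tag string.
#' @return A one-row data.frame.
#' @export
sam_record <- function(qname, flag, chrom, pos, mapq, cigar,
                       rnext = "*", pnext = 0L, seq = NULL, tags = "") {
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  if (is.null(seq)) seq <- strrep("A", qlen)
  data.frame(qname = qname, flag = as.integer(flag), chrom = chrom,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext), tlen = 0L,
             seq = seq, qual = strrep("I", nchar(seq)), tags = tags,
             stringsAsFactors = FALSE)
}

#' Write alignment records as a SAM file
#'
#' Emits a coordinate-sorted SAM with `@HD`/`@SQ` header lines. Record rows
#' use the layout produced by [sam_record()] / [plant_fusion_reads()].
#'
#' @param records data.frame of records.
#' @param seqlens Named integer vector of reference sequence lengths.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, seqlens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)))
  if (nrow(records) > 0L) {
    o <- order(match(records$chrom, names(seqlens)), records$pos)
    records <- records[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    records$qname, records$flag, records$chrom, records$pos,
                    records$mapq, records$cigar, records$rnext, records$pnext,
                    records$tlen, records$seq, records$qual)
    has_tag <- nzchar(records$tags)
    body[has_tag] <- paste(body[has_tag], records$tags[has_tag], sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment segments from SAM/BAM
#'
#' Loads all mapped records (primary, supplementary and duplicate-flagged;
#' secondary alignments are dropped at this boundary) into a flat segment
#' table with decoded flag bits, 1-based inclusive reference coordinates and
#' the parsed `SA` tag. SAM input is converted through `Rsamtools::asBam`.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.frame with one row per alignment segment.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to read SAM (truncated or malformed?): ",
                               conditionMessage(e), call. = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos"),
    tag = "SA",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  res <- tryCatch(Rsamtools::scanBam(bam, param = p)[[1L]],
                  error = function(e) stop("failed to scan alignments: ",
                                           conditionMessage(e), call. = FALSE))
  n <- length(res$qname)
  flag <- as.integer(res$flag)
  cigar <- as.character(res$cigar)
  refw <- rep(NA_integer_, n)
  ok <- !is.na(cigar)
  refw[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  seg <- data.frame(
    read_name = as.character(res$qname),
    flag = flag,
    chrom = as.character(res$rname),
    pos = as.integer(res$pos),
    end = as.integer(res$pos) + refw - 1L,
    mapq = as.integer(res$mapq),
    cigar = cigar,
    mate_chrom = as.character(res$mrnm),
    mate_pos = as.integer(res$mpos),
    sa_tag = if (!is.null(res$tag$SA)) as.character(res$tag$SA)
             else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  seg$is_reverse <- bitwAnd(flag, FLAG_REVERSE) > 0L
  seg$is_supplementary <- bitwAnd(flag, FLAG_SUPPLEMENTARY) > 0L
  seg$is_duplicate <- bitwAnd(flag, FLAG_DUP) > 0L
  seg$read_index <- ifelse(bitwAnd(flag, FLAG_READ2) > 0L, 2L, 1L)
  seg
}

# soft-clip lengths at the two ends of a CIGAR (hard clips count as clipped
# query absent from SEQ but still mark a split end)
.clip_lens <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  t(vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    left <- 0L; right <- 0L
    k <- length(o)
    if (k > 0L && o[1L] %in% c("S", "H")) left <- l[1L]
    if (k > 0L && o[k] %in% c("S", "H")) right <- l[k]
    c(left, right)
  }, integer(2L)))
}

# parse an SA tag value "chrom,pos,strand,CIGAR,mapQ,NM;..." into a data.frame
.parse_sa <- function(sa) {
  if (is.na(sa) || !nzchar(sa)) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      cigar = character(), mapq = integer(),
                      stringsAsFactors = FALSE))
  }
  sa <- sub("^SA:Z:", "", sa)
  entries <- strsplit(sa, ";", fixed = TRUE)[[1L]]
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, ",", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    cigar = vapply(parts, `[`, "", 4L),
    mapq = as.integer(vapply(parts, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}
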