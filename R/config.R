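#' Pipeline configuration
#'
#' Collects every threshold used by the detection pipeline into a single
#' validated list. Defaults follow the published operating point of the
#' method: alignments below mapping quality 30 are discarded, same-chromosome
#' partners must be at least 10 kb apart, a single supporting read pair
#' suffices, a split read may touch at most two genes, and overlapping split
#' mates must leave strictly more than 20 non-overlapping bases.
#'
#' @param min_mapq Minimum mapping quality; applied to both mates of a pair
#'   and to every supplementary segment of a split read.
#' @param allowed_chroms Chromosome whitelist. Names are compared after
#'   stripping any `"chr"` prefix, so `"chr15"` and `"15"` are equivalent.
#' @param require_protein_coding If `TRUE`, both partner genes must carry the
#'   `protein_coding` biotype.
#' @param assume_coding If `TRUE`, genes with biotype `"unknown"` (e.g. from a
#'   GTF without biotype attributes) are treated as protein-coding instead of
#'   failing the biotype filter.
#' @param min_gene_distance Minimum nearest-edge distance in bp (end of the
#'   left gene to start of the right gene) for same-chromosome partners.
#' @param min_support Minimum number of deduplicated supporting read-pair
#'   units (discordant + split) per candidate.
#' @param max_genes_per_split Maximum number of distinct genes the segments of
#'   one split read may touch.
#' @param min_split_nonoverlap When both mates of a pair are split reads with
#'   overlapping genomic footprints, the non-overlapping part must exceed this
#'   many bases (strict `>`).
#' @param min_clip_len Minimum soft-clip length (bp) for a primary alignment
#'   to be considered split-read evidence.
#' @param read_len Read length in bp; used by the paralog simulation and the
#'   synthetic-data generator.
#' @param sim_reads_per_tx Number of reads simulated per transcript by the
#'   paralog detector.
#' @param paralog_share_frac Fraction of a transcript's simulated reads that
#'   must also map to a transcript of another gene for the two transcripts to
#'   count as sequence-sharing.
#' @param keep_duplicates If `TRUE`, records flagged as PCR/optical duplicates
#'   are retained (they are dropped by default so duplicate stacks cannot
#'   inflate support at high panel depth).
#' @param require_split If `TRUE`, candidates without split-read support are
#'   rejected; by default discordant-only candidates are accepted.
#' @param seed Integer seed for all stochastic steps (paralog simulation,
#'   fixtures, subsampling).
#'
#' @return A list of class `wes_config`.
#' @export
#' @examples
#' cfg <- wes_config(min_support = 2)
#' cfg$min_mapq
wes_config <- function(min_mapq = 30,
                       allowed_chroms = c(as.character(1:22), "X", "Y"),
                       require_protein_coding = TRUE,
                       assume_coding = FALSE,
                       min_gene_distance = 10000L,
                       min_support = 1L,
                       max_genes_per_split = 2L,
                       min_split_nonoverlap = 20L,
                       min_clip_len = 20L,
                       read_len = 100L,
                       sim_reads_per_tx = 10000L,
                       paralog_share_frac = 0.5,
                       keep_duplicates = FALSE,
                       require_split = FALSE,
                       seed = 1L) {
  cfg <- list(
    min_mapq = as.integer(min_mapq),
    allowed_chroms = as.character(allowed_chroms),
    require_protein_coding = isTRUE(require_protein_coding),
    assume_coding = isTRUE(assume_coding),
    min_gene_distance = as.integer(min_gene_distance),
    min_support = as.integer(min_support),
    max_genes_per_split = as.integer(max_genes_per_split),
    min_split_nonoverlap = as.integer(min_split_nonoverlap),
    min_clip_len = as.integer(min_clip_len),
    read_len = as.integer(read_len),
    sim_reads_per_tx = as.integer(sim_reads_per_tx),
    paralog_share_frac = as.numeric(paralog_share_frac),
    keep_duplicates = isTRUE(keep_duplicates),
    require_split = isTRUE(require_split),
    seed = as.integer(seed)
  )
  num <- c("min_mapq", "min_gene_distance", "min_support",
           "max_genes_per_split", "min_split_nonoverlap", "min_clip_len",
           "read_len", "sim_reads_per_tx")
  for (f in num) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("config field '", f, "' must be a non-negative integer", call. = FALSE)
    }
  }
  if (length(cfg$allowed_chroms) == 0L) {
    stop("allowed_chroms must be non-empty", call. = FALSE)
  }
  if (!is.finite(cfg$paralog_share_frac) ||
      cfg$paralog_share_frac <= 0 || cfg$paralog_share_frac > 1) {
    stop("paralog_share_frac must be in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "wes_config")
}

#' @export
print.wes_config <- function(x, ...) {
  cat("wesfusion configuration\n")
  for (f in setdiff(names(x), "allowed_chroms")) {
    cat(sprintf("  %-22s %s\n", f, as.character(x[[f]])))
  }
  cat(sprintf("  %-22s %s\n", "allowed_chroms",
              paste(x$allowed_chroms, collapse = ",")))
  invisible(x)
}

# Stable 32-bit FNV-1a hash of the threshold values; lands in the output
# header so a call table records the configuration that produced it.
config_hash <- function(cfg) {
  s <- paste(vapply(cfg, function(v) paste(v, collapse = ","), ""),
             collapse = "|")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

# strip an optional "chr" prefix so whitelist membership is dialect-free
norm_chrom <- function(x) sub("^chr", "", as.character(x))
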