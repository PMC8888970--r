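# End-to-end orchestration: extraction -> split-level filters -> FEQs ->
# candidate aggregation -> candidate-level filters -> call table, plus the
# call-set concordance comparison and the table writer.

#' Total support from discordant and split counts
#'
#' @param n_discordant,n_split Non-negative counts (vectorized).
#' @return `n_discordant + n_split`.
#' @export
#' @examples
#' summarize_support(5, 7)  # 12
summarize_support <- function(n_discordant, n_split) {
  if (any(n_discordant < 0) || any(n_split < 0)) {
    stop("support counts must be >= 0", call. = FALSE)
  }
  n_discordant + n_split
}

#' Run the full fusion detection pipeline
#'
#' Executes the four pipeline stages on one sample: (1) extract
#' MAPQ-filtered discordant-pair and split-read evidence, (2) apply the
#' split-read-level filters and deduplicate evidence units, (3) build and
#' merge fusion equivalence classes and aggregate gene-level candidates with
#' support counts, (4) apply the candidate-level filter cascade (optionally
#' including the simulation-based paralog filter) and return the call table.
#'
#' @param bam Path to a SAM/BAM file.
#' @param gtf Path to a GTF file, or an already-parsed [genome_annotation].
#' @param cfg A [wes_config].
#' @param tx_fasta Optional path to spliced transcript FASTA; required when
#'   `sim_paralogs = TRUE`.
#' @param paralogs Optional precomputed paralog pair data.frame (or a path
#'   to a TSV written by [write_paralogs()]).
#' @param sim_paralogs If `TRUE`, run the paralog simulation on `tx_fasta`
#'   before filtering.
#' @return Object of class `fusion_calls`: `calls` (passed candidates,
#'   sorted by `n_total` descending then gene pair), `rejected` (with
#'   `filter_flags`), `config`, and a `stage_counts` log.
#' @export
run_pipeline <- function(bam, gtf, cfg = wes_config(), tx_fasta = NULL,
                         paralogs = NULL, sim_paralogs = FALSE) {
  ann <- if (inherits(gtf, "genome_annotation")) gtf else parse_gtf(gtf)

  ev <- scan_alignments(bam, ann, cfg)
  n_raw <- c(pairs = nrow(ev$pairs), splits = nrow(ev$splits))

  splits <- filter_splits(ev$splits, cfg)
  dd <- dedup_evidence(ev$pairs, splits)

  feqs <- merge_feqs(lapply(seq_len(nrow(dd$pairs)), function(i) {
    build_feq(dd$pairs[i, , drop = FALSE], ann)
  }))
  candidates <- candidates_from_evidence(feqs, dd$splits, ann)

  if (is.character(paralogs)) paralogs <- read_paralogs(paralogs)
  if (isTRUE(sim_paralogs)) {
    if (is.null(tx_fasta)) {
      stop("sim_paralogs requires tx_fasta", call. = FALSE)
    }
    txs <- Biostrings::readDNAStringSet(tx_fasta)
    names(txs) <- sub("\\s.*", "", names(txs))
    paralogs <- detect_paralogs(txs, ann, cfg)
  }

  res <- apply_filters(candidates, ann, paralogs, cfg)
  calls <- res$passed
  calls <- calls[order(-calls$n_total, calls$gene_a, calls$gene_b), ,
                 drop = FALSE]
  rownames(calls) <- NULL

  structure(list(
    calls = calls, rejected = res$rejected, config = cfg,
    paralogs = paralogs,
    stage_counts = c(n_raw,
                     splits_kept = nrow(dd$splits),
                     pairs_kept = nrow(dd$pairs),
                     candidates = nrow(candidates),
                     passed = nrow(calls))
  ), class = "fusion_calls")
}

#' @export
print.fusion_calls <- function(x, ...) {
  cat(sprintf("fusion_calls: %d passed, %d rejected\n",
              nrow(x$calls), nrow(x$rejected)))
  if (nrow(x$calls) > 0L) {
    print(x$calls[, c("gene_a", "gene_b", "chrom_a", "pos_a", "chrom_b",
                      "pos_b", "n_discordant", "n_split", "n_total",
                      "orientation")])
  }
  invisible(x)
}

#' Write a fusion call table
#'
#' Tab-separated output with a `#`-prefixed provenance header (package
#' version and configuration hash). With `emit_rejected = TRUE` a companion
#' `<path>.rejected.tsv` carries the rejected candidates and their
#' failed-filter labels.
#'
#' @param x A `fusion_calls` object.
#' @param path Output path.
#' @param emit_rejected Also write the rejected table.
#' @return `path`, invisibly.
#' @export
write_fusion_table <- function(x, path, emit_rejected = FALSE) {
  stopifnot(inherits(x, "fusion_calls"))
  ver <- as.character(utils::packageVersion("wesfusion"))
  hdr <- c(sprintf("#wesfusion_version=%s", ver),
           sprintf("#config_hash=%s", config_hash(x$config)))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(x$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (isTRUE(emit_rejected)) {
    rej <- paste0(path, ".rejected.tsv")
    con <- file(rej, "w")
    writeLines(hdr, con)
    utils::write.table(x$rejected, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' Compare two binary call sets over a shared sample universe
#'
#' Cross-tabulates per-sample positive/negative calls from two detection
#' strategies and reports the 2x2 counts and the percentage agreement
#' `100 * (tp + tn) / n`. `tp` counts samples positive in both, `fp`
#' positive only in `a`, `fn` positive only in `b`, `tn` negative in both.
#'
#' @param calls_a,calls_b Named logical vectors (names = sample ids), or
#'   data.frames with columns `sample` and `call`.
#' @return Object of class `concordance` with fields `tp`, `fp`, `fn`,
#'   `tn`, `n`, `agreement` (exact percentage) and `agreement_pct`
#'   (rounded to the nearest integer for display).
#' @export
#' @examples
#' a <- c(rep(TRUE, 41), rep(FALSE, 24))
#' b <- c(rep(TRUE, 36), rep(FALSE, 5), TRUE, rep(FALSE, 23))
#' names(a) <- names(b) <- sprintf("s%02d", 1:65)
#' compare_callsets(a, b)$agreement_pct  # 91
compare_callsets <- function(calls_a, calls_b) {
  as_named <- function(x, who) {
    if (is.data.frame(x)) {
      v <- as.logical(x$call)
      names(v) <- as.character(x$sample)
      x <- v
    }
    if (is.null(names(x))) {
      stop("call set ", who, " must be named by sample", call. = FALSE)
    }
    x
  }
  a <- as_named(calls_a, "a")
  b <- as_named(calls_b, "b")
  if (!setequal(names(a), names(b))) {
    d1 <- setdiff(names(a), names(b))
    d2 <- setdiff(names(b), names(a))
    stop("sample universes differ; only in a: {",
         paste(d1, collapse = ","), "}; only in b: {",
         paste(d2, collapse = ","), "}", call. = FALSE)
  }
  b <- b[names(a)]
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b); tn <- sum(!a & !b)
  n <- length(a)
  agreement <- 100 * (tp + tn) / n
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 agreement = agreement,
                 agreement_pct = round(agreement)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance over %d samples: tp=%d fp=%d fn=%d tn=%d, agreement %d%%\n",
              x$n, x$tp, x$fp, x$fn, x$tn, x$agreement_pct))
  invisible(x)
}
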