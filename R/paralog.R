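# Simulation-based paralog detection. Paralogous genes with near-identical
# sequence are the dominant source of false fusion calls: reads from one gene
# map cleanly into the other and masquerade as discordant evidence. The
# detector simulates a large number of error-free reads from every
# transcript, asks which other transcripts each read also maps to (exact
# substring occurrence stands in for the aligner), and lifts heavily
# read-sharing transcript pairs to gene-level paralog pairs.

#' Simulate uniform error-free reads from transcript sequences
#'
#' Every transcript at least `read_len` long yields exactly `n_per_tx`
#' single-end reads with uniformly random start positions; shorter
#' transcripts are skipped with a warning. Deterministic under `seed`.
#'
#' @param txs Named character vector or `Biostrings::DNAStringSet` of spliced
#'   transcript sequences.
#' @param n_per_tx Reads per transcript (default 10,000 in the pipeline
#'   configuration).
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return data.frame with columns `origin`, `start`, `seq`.
#' @export
simulate_reads <- function(txs, n_per_tx, read_len = 100L, seed = 1L) {
  stopifnot(n_per_tx >= 1L)
  if (methods::is(txs, "DNAStringSet")) txs <- as.character(txs)
  if (is.null(names(txs)) || any(!nzchar(names(txs)))) {
    stop("transcript sequences must be named", call. = FALSE)
  }
  short <- nchar(txs) < read_len
  if (any(short)) {
    warning("skipping ", sum(short), " transcript(s) shorter than read length: ",
            paste(utils::head(names(txs)[short], 5L), collapse = ", "),
            call. = FALSE)
    txs <- txs[!short]
  }
  set.seed(seed)
  out <- lapply(names(txs), function(id) {
    L <- nchar(txs[[id]])
    starts <- sample.int(L - read_len + 1L, n_per_tx, replace = TRUE)
    data.frame(origin = id, start = starts,
               seq = substring(txs[[id]], starts, starts + read_len - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map simulated reads back to transcripts by exact substring occurrence
#'
#' A read "maps" to a transcript when its sequence occurs exactly as a
#' substring of the transcript (forward strand; reads are error-free, so
#' exact occurrence captures the aligner's behaviour on identical sequence).
#' Counts are tallied per (origin, target): `counts[i, i]` equals the number
#' of reads generated from transcript i.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param txs Named character vector or `DNAStringSet` of the same
#'   transcripts.
#' @return Object of class `sharing_matrix`: `counts` (dense origin x target
#'   matrix) and `reads_per_tx`.
#' @export
map_simulated <- function(reads, txs) {
  if (methods::is(txs, "DNAStringSet")) txs <- as.character(txs)
  ids <- names(txs)
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  by_origin <- split(reads$seq, factor(reads$origin, levels = ids))
  subjects <- lapply(txs, Biostrings::DNAString)
  for (i in seq_along(ids)) {
    seqs <- by_origin[[i]]
    if (length(seqs) == 0L) next
    tab <- table(seqs)
    uniq <- names(tab)
    mult <- as.integer(tab)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
    for (j in seq_along(ids)) {
      hit <- Biostrings::countPDict(pd, subjects[[j]]) > 0L
      counts[i, j] <- sum(mult[hit])
    }
  }
  structure(list(counts = counts,
                 reads_per_tx = if (nrow(counts) > 0L) max(diag(counts)) else 0L),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat(sprintf("sharing_matrix over %d transcript(s)\n", nrow(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Lift read sharing to gene-level paralog pairs
#'
#' Transcripts i and j of different genes are "sharing" when
#' `max(counts[i,j]/counts[i,i], counts[j,i]/counts[j,j]) >= share_frac`
#' (or, alternatively, when the shared read count reaches
#' `min_shared_reads`). A gene pair is paralogous as soon as any cross-gene
#' transcript pair is sharing. The result is symmetric: transposing the
#' matrix does not change it.
#'
#' @param m A `sharing_matrix` from [map_simulated()].
#' @param ann A [genome_annotation] mapping transcripts to genes.
#' @param share_frac Sharing fraction threshold in (0, 1].
#' @param min_shared_reads Optional absolute alternative: a transcript pair
#'   is sharing when either directed count reaches this value.
#' @return data.frame (`gene_a`, `gene_b`), canonically ordered, one row per
#'   paralogous pair.
#' @export
derive_paralogs <- function(m, ann, share_frac = 0.5, min_shared_reads = NULL) {
  stopifnot(inherits(m, "sharing_matrix"))
  if (is.null(min_shared_reads) &&
      (!is.finite(share_frac) || share_frac <= 0 || share_frac > 1)) {
    stop("share_frac must be in (0, 1]", call. = FALSE)
  }
  cn <- m$counts
  ids <- rownames(cn)
  gene <- ann$transcripts$gene_id[match(ids, ann$transcripts$transcript_id)]
  pairs <- character()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (is.na(gene[i]) || is.na(gene[j]) || gene[i] == gene[j]) next
      if (cn[i, i] == 0L || cn[j, j] == 0L) next
      shared <- if (!is.null(min_shared_reads)) {
        max(cn[i, j], cn[j, i]) >= min_shared_reads
      } else {
        max(cn[i, j] / cn[i, i], cn[j, i] / cn[j, j]) >= share_frac
      }
      if (shared) {
        pairs <- c(pairs, .canon_pair(gene[i], gene[j]))
      }
    }
  }
  pairs <- sort(unique(pairs))
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Full paralog detection from transcript sequences
#'
#' Convenience wrapper: simulate, map, derive.
#'
#' @param txs Named transcript sequences.
#' @param ann A [genome_annotation].
#' @param cfg A [wes_config] (supplies `sim_reads_per_tx`, `read_len`,
#'   `paralog_share_frac`, `seed`).
#' @return Paralog pair data.frame as from [derive_paralogs()].
#' @export
detect_paralogs <- function(txs, ann, cfg = wes_config()) {
  reads <- simulate_reads(txs, n_per_tx = cfg$sim_reads_per_tx,
                          read_len = cfg$read_len, seed = cfg$seed)
  m <- map_simulated(reads, txs)
  derive_paralogs(m, ann, share_frac = cfg$paralog_share_frac)
}

#' Test candidate gene pairs for paralog-set membership
#'
#' @param candidates Candidate table.
#' @param paralogs Paralog pair data.frame.
#' @return Logical vector: `TRUE` when the candidate's gene pair is in the
#'   paralog set.
#' @export
is_paralog_pair <- function(candidates, paralogs) {
  if (is.null(paralogs) || nrow(paralogs) == 0L) {
    return(rep(FALSE, nrow(candidates)))
  }
  keys <- .canon_pair(paralogs$gene_a, paralogs$gene_b)
  .canon_pair(candidates$gene_a, candidates$gene_b) %in% keys
}

#' Flag candidates whose gene pair is paralogous
#'
#' Appends `"paralog"` to the filter flags of affected candidates.
#'
#' @param candidates Candidate table.
#' @param paralogs Paralog pair data.frame.
#' @return The candidate table with updated `filter_flags`.
#' @export
filter_paralog_candidates <- function(candidates, paralogs) {
  hit <- is_paralog_pair(candidates, paralogs)
  candidates$filter_flags <- ifelse(
    hit,
    ifelse(nzchar(candidates$filter_flags),
           paste(candidates$filter_flags, "paralog", sep = ";"), "paralog"),
    candidates$filter_flags
  )
  candidates
}

#' Read / write a paralog pair table
#'
#' Two-column tab-separated cache (`gene_a`, `gene_b`) so an expensive
#' simulation can be reused across runs.
#'
#' @param paralogs Paralog pair data.frame.
#' @param path File path.
#' @return `write_paralogs`: `path` invisibly; `read_paralogs`: the pair
#'   data.frame.
#' @export
write_paralogs <- function(paralogs, path) {
  utils::write.table(paralogs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_paralogs
#' @export
read_paralogs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
}
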