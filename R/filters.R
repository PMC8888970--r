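# Filter cascade: pure candidate-level predicates (chromosome whitelist,
# protein-coding biotype, same-chromosome distance, minimum support, paralog
# membership) plus split-read-level rules that run BEFORE candidate
# aggregation, so a discarded split can never rescue a support count.

#' Chromosome whitelist filter
#'
#' Both partner genes must lie on an allowed chromosome (autosomes 1-22, X
#' and Y by default). Names are compared after stripping any `"chr"` prefix,
#' so mitochondrial contigs and unplaced scaffolds fail.
#'
#' @param cand One or more candidate rows.
#' @param cfg A [wes_config].
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_chromosome <- function(cand, cfg = wes_config()) {
  allowed <- norm_chrom(cfg$allowed_chroms)
  norm_chrom(cand$chrom_a) %in% allowed & norm_chrom(cand$chrom_b) %in% allowed
}

#' Protein-coding biotype filter
#'
#' Both partner genes must carry the `protein_coding` biotype. Genes with
#' biotype `"unknown"` (annotation without biotype attributes) fail unless
#' `assume_coding` is set. Disabled entirely when `require_protein_coding`
#' is off.
#'
#' @param cand Candidate rows.
#' @param ann A [genome_annotation].
#' @param cfg A [wes_config].
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_biotype <- function(cand, ann, cfg = wes_config()) {
  if (!cfg$require_protein_coding) return(rep(TRUE, nrow(cand)))
  bt <- function(g) ann$genes$biotype[match(g, ann$genes$gene_id)]
  ok <- function(b) {
    b == "protein_coding" | (cfg$assume_coding & b == "unknown")
  }
  a <- ok(bt(cand$gene_a))
  b <- ok(bt(cand$gene_b))
  a & b & !is.na(a) & !is.na(b)
}

# nearest-edge distance between two gene spans on the same chromosome:
# start of the right gene minus end of the left gene
.gene_gap <- function(cand, ann) {
  ia <- match(cand$gene_a, ann$genes$gene_id)
  ib <- match(cand$gene_b, ann$genes$gene_id)
  left_first <- ann$genes$start[ia] <= ann$genes$start[ib]
  lend <- ifelse(left_first, ann$genes$end[ia], ann$genes$end[ib])
  rstart <- ifelse(left_first, ann$genes$start[ib], ann$genes$start[ia])
  # overlapping genes get a non-positive gap
  rstart - lend
}

#' Same-chromosome distance filter
#'
#' Partners on different chromosomes always pass. Partners on the same
#' chromosome pass when the nearest-edge distance (start of the right gene
#' minus end of the left gene) is at least `min_gene_distance` (default
#' 10 kb, inclusive boundary): read-through neighbours and local artifacts
#' are removed this way.
#'
#' @param cand Candidate rows.
#' @param ann A [genome_annotation].
#' @param cfg A [wes_config].
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_distance <- function(cand, ann, cfg = wes_config()) {
  ia <- match(cand$gene_a, ann$genes$gene_id)
  ib <- match(cand$gene_b, ann$genes$gene_id)
  same <- ann$genes$chrom[ia] == ann$genes$chrom[ib]
  gap <- .gene_gap(cand, ann)
  !same | gap >= cfg$min_gene_distance
}

#' Minimum-support filter
#'
#' A candidate needs at least `min_support` deduplicated supporting
#' read-pair units (discordant + split; default 1).
#'
#' @param cand Candidate rows.
#' @param cfg A [wes_config].
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_support <- function(cand, cfg = wes_config()) {
  cand$n_total >= cfg$min_support
}

#' Split-read gene-count filter
#'
#' A split read whose segments touch more than `max_genes_per_split`
#' distinct genes (default 2) is discarded as multi-mapping noise.
#'
#' @param splits Split-read rows.
#' @param cfg A [wes_config].
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_split_gene_count <- function(splits, cfg = wes_config()) {
  splits$n_genes <= cfg$max_genes_per_split
}

#' Split-mate overlap filter
#'
#' When both mates of one read pair are split reads and their genomic
#' footprints overlap, the non-overlapping part of the combined footprint
#' must exceed `min_split_nonoverlap` bases (strictly more than 20 by
#' default). Non-overlapping mates are not subject to the rule.
#'
#' @param s1,s2 One-row split records for mate 1 and mate 2 of the same
#'   read pair.
#' @param cfg A [wes_config].
#' @return `TRUE` (pass) or `FALSE` (both mates discarded).
#' @export
filter_split_pair_overlap <- function(s1, s2, cfg = wes_config()) {
  if (!identical(s1$read_name, s2$read_name)) {
    stop("split mates belong to different read names", call. = FALSE)
  }
  if (!identical(s1$chrom_p, s2$chrom_p)) return(TRUE)
  lo <- max(s1$pos_p, s2$pos_p)
  hi <- min(s1$end_p, s2$end_p)
  if (lo > hi) return(TRUE)                 # no overlap: rule not applicable
  inter <- hi - lo + 1L
  uni <- max(s1$end_p, s2$end_p) - min(s1$pos_p, s2$pos_p) + 1L
  (uni - inter) > cfg$min_split_nonoverlap
}

#' Apply the split-read-level filters
#'
#' Removes splits touching too many genes and overlapping split-mate pairs
#' with insufficient non-overlap. Runs before candidate aggregation.
#'
#' @param splits Split-read table.
#' @param cfg A [wes_config].
#' @return Filtered split-read table.
#' @export
filter_splits <- function(splits, cfg = wes_config()) {
  if (nrow(splits) == 0L) return(splits)
  keep <- filter_split_gene_count(splits, cfg)
  splits <- splits[keep, , drop = FALSE]
  if (nrow(splits) > 1L) {
    drop <- rep(FALSE, nrow(splits))
    byname <- split(seq_len(nrow(splits)), splits$read_name)
    for (ix in byname) {
      if (length(ix) == 2L) {
        s1 <- splits[ix[1L], , drop = FALSE]
        s2 <- splits[ix[2L], , drop = FALSE]
        if (s1$read_index != s2$read_index &&
            !filter_split_pair_overlap(s1, s2, cfg)) {
          drop[ix] <- TRUE
        }
      }
    }
    splits <- splits[!drop, , drop = FALSE]
  }
  rownames(splits) <- NULL
  splits
}

#' Apply the candidate-level filter cascade
#'
#' Evaluates every candidate against the chromosome whitelist, biotype,
#' distance, support, paralog and (optionally) split-requirement rules. The
#' predicates are pure, so the pass set does not depend on application
#' order; each rejected candidate carries the labels of every filter it
#' failed.
#'
#' @param candidates Candidate table from [candidates_from_evidence()].
#' @param ann A [genome_annotation].
#' @param paralogs Optional paralog set (data.frame `gene_a`, `gene_b`) from
#'   [derive_paralogs()]; `NULL` disables the paralog filter.
#' @param cfg A [wes_config].
#' @return `list(passed, rejected)`; `rejected$filter_flags` holds the
#'   failed-filter labels joined with `";"`.
#' @export
apply_filters <- function(candidates, ann, paralogs = NULL,
                          cfg = wes_config()) {
  n <- nrow(candidates)
  if (n == 0L) {
    return(list(passed = candidates, rejected = candidates))
  }
  flags <- vector("list", n)
  add <- function(flags, fail, label) {
    for (i in which(fail)) flags[[i]] <- c(flags[[i]], label)
    flags
  }
  flags <- add(flags, !filter_chromosome(candidates, cfg), "chromosome")
  flags <- add(flags, !filter_biotype(candidates, ann, cfg), "biotype")
  flags <- add(flags, !filter_distance(candidates, ann, cfg), "distance")
  flags <- add(flags, !filter_support(candidates, cfg), "support")
  if (!is.null(paralogs)) {
    flags <- add(flags, is_paralog_pair(candidates, paralogs), "paralog")
  }
  if (cfg$require_split) {
    flags <- add(flags, candidates$n_split == 0L, "no_split")
  }
  candidates$filter_flags <- vapply(flags, function(f) {
    paste(f, collapse = ";")
  }, "")
  pass <- !nzchar(candidates$filter_flags)
  passed <- candidates[pass, , drop = FALSE]
  rejected <- candidates[!pass, , drop = FALSE]
  rownames(passed) <- NULL
  rownames(rejected) <- NULL
  list(passed = passed, rejected = rejected)
}
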