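# Adapter trimming, color-space matching under the seed/tail mismatch
# budget, and exclusive assignment of each mapped read to one annotation
# category.

#' Matching parameters
#'
#' The color-space mismatch budget used throughout the pipeline: at most
#' `seed_mismatch_max` color mismatches within the first `seed_len` colors
#' of the read (the "seed"), and at most `tail_mismatch_max` on the
#' following positions. Reads shorter than the seed use their full length
#' as the seed. Defaults follow the original SOLiD small-RNA mapping
#' parameterization (18/1/2) and the 15-50 nt insert range of the library
#' preparation.
#'
#' @param seed_len Seed length in colors.
#' @param seed_mismatch_max Mismatch budget within the seed.
#' @param tail_mismatch_max Mismatch budget after the seed.
#' @param min_trimmed_len Minimum retained read length (colors) after
#'   adapter trimming.
#' @param max_trimmed_len Maximum insert length considered (colors).
#' @return A list of class `match_params`.
#' @export
match_params <- function(seed_len = 18L, seed_mismatch_max = 1L,
                         tail_mismatch_max = 2L, min_trimmed_len = 15L,
                         max_trimmed_len = 50L) {
  stopifnot(seed_len >= 1L, seed_mismatch_max >= 0L, tail_mismatch_max >= 0L,
            min_trimmed_len <= max_trimmed_len, min_trimmed_len >= 2L)
  structure(list(seed_len = as.integer(seed_len),
                 seed_mismatch_max = as.integer(seed_mismatch_max),
                 tail_mismatch_max = as.integer(tail_mismatch_max),
                 min_trimmed_len = as.integer(min_trimmed_len),
                 max_trimmed_len = as.integer(max_trimmed_len)),
            class = "match_params")
}

#' Trim the 3' adapter from color-space reads
#'
#' Library inserts shorter than the fixed 35-color read length run through
#' into the 3' adapter. The trimmer works entirely in color space: it
#' removes the longest read suffix whose colors exactly match the
#' adapter's internal colors (the insert/adapter junction color, which
#' depends on the last insert base, is skipped). Working on colors rather
#' than decoded bases matters because a single color error corrupts every
#' decoded base downstream of it but leaves all other colors intact. Zero
#' mismatches are required for short overlaps; one color mismatch is
#' tolerated when the overlap is at least 10. Quality values are truncated
#' identically. Untrimmable reads are returned unchanged.
#'
#' @param reads A [color_reads()] data frame (all reads the same length).
#' @param adapter Adapter nucleotide sequence (5' end ligated at the insert
#'   3' junction, in read orientation).
#' @param min_overlap Minimum adapter overlap (bases) required to trim.
#' @param min_len Trimmed reads shorter than this are flagged `too_short`.
#' @param truncate_quals Set `FALSE` to leave the `quals` column untouched
#'   (cheaper when qualities are not used downstream).
#' @return The reads with `colors`/`quals` truncated at the insert, plus
#'   logical columns `trimmed` and `too_short`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L, min_len = 15L,
                         truncate_quals = TRUE) {
  n <- nrow(reads)
  if (n == 0L) {
    reads$trimmed <- logical(0)
    reads$too_short <- logical(0)
    return(reads)
  }
  L <- nchar(reads$colors[1L])
  stopifnot(all(nchar(reads$colors) == L), min_overlap >= 1L)
  adapter <- chartr("Uu", "Tt", adapter)
  if (grepl("[^ACGTacgt]", adapter))
    stop("adapter contains characters outside {A,C,G,T,U}")
  # tile the adapter so that adapter dimers (insert length 0) still trim
  fill <- paste(rep(adapter, ceiling((L + 1) / nchar(adapter))), collapse = "")
  a <- .color_codes(sequence_internal_colors(fill))
  C <- matrix(utf8ToInt(paste(reads$colors, collapse = "")) - 48L, nrow = L)
  t_lo <- 0L
  t_hi <- L - min_overlap
  insert_len <- rep(NA_integer_, n)
  if (t_hi >= t_lo) {
    for (t in t_lo:t_hi) {
      o <- L - t                       # adapter bases in the read
      nc <- o - 1L                     # comparable adapter colors
      mm <- if (nc > 0L)
        colSums(C[(t + 2L):L, , drop = FALSE] != a[seq_len(nc)])
      else rep(0L, n)
      ok <- is.na(insert_len) & (mm == 0L | (o >= 10L & mm <= 1L))
      insert_len[ok] <- t
    }
  }
  trimmed <- !is.na(insert_len)
  keep_len <- ifelse(trimmed, insert_len, L)
  out <- reads
  out$colors <- substr(reads$colors, 1L, keep_len)
  if (truncate_quals && !all(vapply(reads$quals, is.null, FALSE)))
    out$quals <- Map(function(q, k) if (is.null(q)) q else q[seq_len(k)],
                     reads$quals, keep_len)
  out$trimmed <- trimmed
  out$too_short <- keep_len < min_len
  out
}

#' Match color-space reads against the reference
#'
#' Finds, for every read, all reference locations (both strands) whose
#' internal colors differ from the read's internal colors by at most the
#' seed/tail mismatch budget. Matching is seed-and-extend over a color
#' k-mer index and agrees exactly with a literal brute-force scan of every
#' offset and strand. Reads sequenced `from_3p` are reversed
#' (reverse-complemented in color space) before matching, so hit
#' coordinates are always reported on the plus-strand axis with the strand
#' of the originating small RNA.
#'
#' @param reads A [color_reads()] data frame (typically after
#'   [trim_adapter()]).
#' @param catalog An `annotation_catalog`.
#' @param params A [match_params()] list.
#' @return A data frame of hits: `read` (row index into `reads`),
#'   `read_id`, `contig`, `start`, `end` (1-based inclusive), `strand`,
#'   `mm_seed`, `mm_tail`, sorted by read, then total mismatches, then
#'   position.
#' @export
match_reads <- function(reads, catalog, params = match_params()) {
  contig_cols <- .contig_internal_colors(catalog)
  internal <- .read_internal_colors(reads)
  revflag <- reads$direction == "from_3p"
  hits <- cs_match_block(internal, revflag, contig_cols,
                         Biostrings::width(catalog$contigs),
                         params$seed_len, params$seed_mismatch_max,
                         params$tail_mismatch_max)
  hits$contig <- names(catalog$contigs)[hits$contig]
  hits$read_id <- reads$read_id[hits$read]
  tot <- hits$mm_seed + hits$mm_tail
  o <- order(hits$read, tot, hits$contig, hits$start, hits$strand)
  hits <- hits[o, c("read", "read_id", "contig", "start", "end", "strand",
                    "mm_seed", "mm_tail")]
  rownames(hits) <- NULL
  hits
}

#' Assign each read to exactly one annotation category
#'
#' Implements the exclusive hierarchy: among a read's best (fewest total
#' mismatches) hits, features overlapping a hit by at least half the read
#' length (same strand) compete, and the highest-priority class in the
#' hierarchy wins; ties within a class are broken by feature specificity
#' (smallest feature first, so a mature miRNA beats its spanning
#' precursor), then by leftmost coordinate.
#' Mapped reads with no sufficiently overlapping feature are
#' `non_annotated`; reads without hits are `unmapped`.
#'
#' @param hits Hit table from [match_reads()].
#' @param reads The [color_reads()] data frame the hits refer to.
#' @param catalog An `annotation_catalog`.
#' @param min_overlap_frac Minimum fraction of the read that must overlap a
#'   feature for the feature to claim it.
#' @return A data frame (one row per read): `read_id`, `category`,
#'   `feature_id`, `contig`, `start`, `end`, `strand`, `mm_seed`,
#'   `mm_tail`.
#' @export
assign_reads <- function(hits, reads, catalog, min_overlap_frac = 0.5) {
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id,
                    category = rep("unmapped", n),
                    feature_id = NA_character_,
                    contig = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_,
                    mm_seed = NA_integer_, mm_tail = NA_integer_,
                    stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  tot <- hits$mm_seed + hits$mm_tail
  o <- order(hits$read, tot)
  firsts <- !duplicated(hits$read[o])
  minv <- tot[o][firsts]                       # per-read minimum mismatches
  best <- tot == minv[match(hits$read, hits$read[o][firsts])]
  h <- hits[best, , drop = FALSE]
  hgr <- GenomicRanges::GRanges(h$contig,
                                IRanges::IRanges(h$start, h$end), h$strand)
  ov <- GenomicRanges::findOverlaps(hgr, catalog$granges)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi)) {
    ovw <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(hgr)[qi], IRanges::ranges(catalog$granges)[si]))
    readlen <- h$end[qi] - h$start[qi] + 1L
    keep <- ovw >= min_overlap_frac * readlen
    qi <- qi[keep]; si <- si[keep]
  }
  prio <- match(catalog$features$rna_class, catalog$hierarchy)
  if (length(qi)) {
    cand <- data.frame(hit = qi, feat = si,
                       read = h$read[qi], prio = prio[si],
                       start = h$start[qi],
                       stringsAsFactors = FALSE)
    cand <- cand[!is.na(cand$prio), , drop = FALSE]
  } else {
    cand <- data.frame(hit = integer(0), feat = integer(0),
                       read = integer(0), prio = integer(0),
                       start = integer(0))
  }
  if (nrow(cand)) {
    # within a class, the most specific (smallest) feature claims the read:
    # a mature miRNA wins over the precursor that spans it
    fwidth <- catalog$features$end - catalog$features$start + 1L
    o <- order(cand$read, cand$prio, fwidth[cand$feat],
               h$contig[cand$hit], cand$start,
               catalog$features$start[cand$feat],
               catalog$features$feature_id[cand$feat])
    cand <- cand[o, , drop = FALSE]
    first <- !duplicated(cand$read)
    cw <- cand[first, , drop = FALSE]
    ri <- cw$read
    out$category[ri] <- catalog$features$rna_class[cw$feat]
    out$feature_id[ri] <- catalog$features$feature_id[cw$feat]
    out$contig[ri] <- h$contig[cw$hit]
    out$start[ri] <- h$start[cw$hit]
    out$end[ri] <- h$end[cw$hit]
    out$strand[ri] <- h$strand[cw$hit]
    out$mm_seed[ri] <- h$mm_seed[cw$hit]
    out$mm_tail[ri] <- h$mm_tail[cw$hit]
  }
  # mapped reads with no claiming feature: non_annotated at leftmost best hit
  mapped_reads <- unique(h$read)
  unassigned <- setdiff(mapped_reads, if (nrow(cand)) cand$read else integer(0))
  if (length(unassigned)) {
    hh <- h[h$read %in% unassigned, , drop = FALSE]
    o <- order(hh$read, hh$contig, hh$start, hh$strand)
    hh <- hh[o, , drop = FALSE]
    hh <- hh[!duplicated(hh$read), , drop = FALSE]
    ri <- hh$read
    out$category[ri] <- "non_annotated"
    out$contig[ri] <- hh$contig
    out$start[ri] <- hh$start
    out$end[ri] <- hh$end
    out$strand[ri] <- hh$strand
    out$mm_seed[ri] <- hh$mm_seed
    out$mm_tail[ri] <- hh$mm_tail
  }
  out
}

#' Trim, match and assign all samples of an experiment
#'
#' Runs [trim_adapter()], [match_reads()] and [assign_reads()] per sample
#' and tabulates the class distribution over mapped reads.
#'
#' @param samples Named list of [color_reads()] data frames, one per
#'   sample.
#' @param catalog An `annotation_catalog`.
#' @param params A [match_params()] list.
#' @param adapter Adapter sequence, or `NULL` to skip trimming (reads
#'   already trimmed).
#' @param min_overlap_frac See [assign_reads()].
#' @return A list of class `assignment_set`: `assignments` (one data frame
#'   per sample, too-short reads excluded), `class_fractions` (data frame
#'   sample x category fractions over mapped reads), `counts` (per-sample
#'   totals: retained, mapped, unmapped, too_short).
#' @export
assign_all <- function(samples, catalog, params = match_params(),
                       adapter = NULL, min_overlap_frac = 0.5) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  cats <- c(catalog$hierarchy, "non_annotated")
  assignments <- list()
  frac_rows <- list()
  count_rows <- list()
  for (s in names(samples)) {
    rd <- samples[[s]]
    n_in <- nrow(rd)
    too_short <- 0L
    if (!is.null(adapter)) {
      rd <- trim_adapter(rd, adapter, min_len = params$min_trimmed_len,
                         truncate_quals = FALSE)
      too_short <- sum(rd$too_short)
      rd <- rd[!rd$too_short, , drop = FALSE]
    }
    hits <- match_reads(rd, catalog, params)
    asg <- assign_reads(hits, rd, catalog, min_overlap_frac)
    asg$sample <- s
    assignments[[s]] <- asg
    mapped <- asg$category != "unmapped"
    nm <- sum(mapped)
    fr <- if (nm > 0L)
      as.numeric(table(factor(asg$category[mapped], levels = cats))) / nm
    else rep(NA_real_, length(cats))
    frac_rows[[s]] <- c(list(sample = s),
                        stats::setNames(as.list(fr), cats))
    count_rows[[s]] <- data.frame(sample = s, reads_in = n_in,
                                  too_short = too_short,
                                  retained = nrow(rd), mapped = nm,
                                  unmapped = nrow(rd) - nm,
                                  stringsAsFactors = FALSE)
  }
  class_fractions <- do.call(rbind, lapply(frac_rows, as.data.frame))
  rownames(class_fractions) <- NULL
  counts <- do.call(rbind, count_rows)
  rownames(counts) <- NULL
  structure(list(assignments = assignments,
                 class_fractions = class_fractions,
                 counts = counts),
            class = "assignment_set")
}

#' Average class distribution per condition
#'
#' Per-condition averages of the per-sample category fractions (fractions
#' are averaged across samples, not pooled over reads).
#'
#' @param assignment_set Result of [assign_all()].
#' @param sample_sheet Data frame with columns `sample` and `condition`.
#' @return Data frame: condition x category mean fractions.
#' @export
class_distribution_by_condition <- function(assignment_set, sample_sheet) {
  cf <- assignment_set$class_fractions
  cond <- sample_sheet$condition[match(cf$sample, sample_sheet$sample)]
  num <- cf[, setdiff(names(cf), "sample"), drop = FALSE]
  agg <- stats::aggregate(num, by = list(condition = cond), FUN = mean,
                          na.rm = TRUE)
  agg
}
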