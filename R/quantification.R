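# Count matrices, per-million normalization, relative abundances, pre-miR
# per-base profiles / arm usage, and the qPCR comparative-CT utility.

#' Count reads per mature miRNA
#'
#' Builds the raw count matrix (features x samples) from per-sample
#' assignment tables. Only reads assigned to the `miRNA_human` category are
#' counted; every annotated mature human miRNA keeps a row even when no
#' read was observed.
#'
#' @param assignment_set Result of [assign_all()] (or a named list of
#'   assignment data frames).
#' @param catalog The `annotation_catalog` used for assignment.
#' @param sample_sheet Data frame with columns `sample`, `condition` and
#'   optionally `replicate`, `direction`.
#' @return An object of class `count_matrix`: list with `raw` (integer
#'   matrix), `norm` (`NULL` until [normalize_cpm()]), `samples` (the
#'   sample sheet rows in column order).
#' @export
count_features <- function(assignment_set, catalog, sample_sheet) {
  asg <- if (inherits(assignment_set, "assignment_set"))
    assignment_set$assignments else assignment_set
  feats <- catalog$features$feature_id[catalog$features$rna_class == "miRNA_human"]
  snames <- sample_sheet$sample
  stopifnot(all(names(asg) %in% snames))
  raw <- matrix(0L, nrow = length(feats), ncol = length(snames),
                dimnames = list(feats, snames))
  for (s in names(asg)) {
    a <- asg[[s]]
    a <- a[a$category == "miRNA_human", , drop = FALSE]
    tb <- table(factor(a$feature_id, levels = feats))
    raw[, s] <- as.integer(tb)
  }
  structure(list(raw = raw, norm = NULL, samples = sample_sheet),
            class = "count_matrix")
}

#' Normalize counts to reads per million miRNA reads
#'
#' Each sample's miRNA counts are scaled so they total 10^6: the abundance
#' unit used throughout ("counts per million miRNA reads"). Samples with
#' zero miRNA reads get `NA` normalized values and are flagged.
#'
#' @param counts A `count_matrix` from [count_features()], or a bare
#'   feature x sample matrix.
#' @return The `count_matrix` with `norm` filled in (and an attribute
#'   `zero_samples` naming any sample without miRNA reads), or the
#'   normalized matrix when a bare matrix was given.
#' @export
normalize_cpm <- function(counts) {
  raw <- if (inherits(counts, "count_matrix")) counts$raw else counts
  tot <- colSums(raw)
  norm <- sweep(raw, 2L, tot, "/") * 1e6
  norm[, tot == 0] <- NA_real_
  if (inherits(counts, "count_matrix")) {
    counts$norm <- norm
    attr(counts, "zero_samples") <- colnames(raw)[tot == 0]
    counts
  } else norm
}

#' Relative abundance of a miRNA set
#'
#' Percentage of total miRNA reads attributable to a feature set, per
#' sample or averaged per condition (condition averages are means of the
#' per-sample percentages, not pooled counts).
#'
#' @param counts A normalized `count_matrix` (run [normalize_cpm()] first).
#' @param feature_set Character vector of feature ids (subset of the
#'   matrix rows). An empty set gives 0.
#' @param by `"sample"` or `"condition"`.
#' @return Named numeric vector of percentages.
#' @export
relative_abundance <- function(counts, feature_set, by = c("sample", "condition")) {
  by <- match.arg(by)
  stopifnot(inherits(counts, "count_matrix"), !is.null(counts$norm))
  bad <- setdiff(feature_set, rownames(counts$norm))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  pct <- colSums(counts$norm[feature_set, , drop = FALSE]) / 1e6 * 100
  if (length(feature_set) == 0L) pct <- stats::setNames(rep(0, ncol(counts$norm)),
                                                        colnames(counts$norm))
  if (by == "sample") return(pct)
  cond <- counts$samples$condition[match(names(pct), counts$samples$sample)]
  res <- tapply(pct, cond, mean)
  stats::setNames(as.numeric(res), names(res))
}

#' Per-base coverage profile and arm usage of a pre-miRNA
#'
#' Coverage of each precursor base (5' to 3' along the precursor strand)
#' by mapped reads, plus read counts for the 5p and 3p arms. A read counts
#' toward an arm when its best hit overlaps the corresponding mature
#' feature by at least `min_overlap_frac` of the read.
#'
#' @param assignment_set Result of [assign_all()], or one assignment data
#'   frame.
#' @param catalog The `annotation_catalog`.
#' @param precursor_id Feature id of the precursor; its mature children are
#'   found via their `parent` attribute (ids containing `"5p"`/`"3p"`, or
#'   ordered by strand-aware position: the 5' arm first).
#' @param min_overlap_frac Arm-claiming overlap fraction.
#' @return List of class `premir_profile`: `precursor_id`, `coverage`
#'   (integer vector, one per precursor base, 5'->3'), `arm5p_count`,
#'   `arm3p_count`, `arm3p_fraction` (NA when the precursor has no mature
#'   children).
#' @export
premir_profile <- function(assignment_set, catalog, precursor_id,
                           min_overlap_frac = 0.5) {
  asg <- if (inherits(assignment_set, "assignment_set"))
    do.call(rbind, assignment_set$assignments) else assignment_set
  fx <- catalog$features
  pi <- match(precursor_id, fx$feature_id)
  if (is.na(pi)) stop("unknown precursor: ", precursor_id)
  pre <- fx[pi, ]
  a <- asg[!is.na(asg$start) & asg$contig == pre$contig &
             asg$strand == pre$strand &
             asg$start <= pre$end & asg$end >= pre$start, , drop = FALSE]
  plen <- pre$end - pre$start + 1L
  cov <- integer(plen)
  if (nrow(a)) {
    lo <- pmax(a$start, pre$start) - pre$start + 1L
    hi <- pmin(a$end, pre$end) - pre$start + 1L
    cv <- IRanges::coverage(IRanges::IRanges(lo, hi), width = plen)
    cov <- as.integer(cv)
  }
  if (pre$strand == "-") cov <- rev(cov)
  children <- fx[!is.na(fx$parent) & fx$parent == precursor_id, , drop = FALSE]
  arm5 <- arm3 <- NA_integer_
  frac3 <- NA_real_
  if (nrow(children)) {
    # 5' arm = closest to the precursor 5' end on its strand
    ord <- if (pre$strand == "+") order(children$start) else order(-children$end)
    children <- children[ord, , drop = FALSE]
    is3p <- grepl("3p", children$feature_id)
    is5p <- grepl("5p", children$feature_id)
    if (sum(is3p) == 1L && sum(is5p) == 1L) {
      ch5 <- children[is5p, ]; ch3 <- children[is3p, ]
    } else {
      ch5 <- children[1L, ]; ch3 <- children[nrow(children), ]
    }
    count_arm <- function(ch) {
      if (nrow(a) == 0L) return(0L)
      ov <- pmin(a$end, ch$end) - pmax(a$start, ch$start) + 1L
      sum(ov >= min_overlap_frac * (a$end - a$start + 1L))
    }
    arm5 <- count_arm(ch5)
    arm3 <- count_arm(ch3)
    frac3 <- if (arm5 + arm3 > 0L) arm3 / (arm5 + arm3) else NA_real_
  }
  structure(list(precursor_id = precursor_id, coverage = cov,
                 arm5p_count = arm5, arm3p_count = arm3,
                 arm3p_fraction = frac3),
            class = "premir_profile")
}

#' Comparative-CT qPCR quantification (2^-dCT)
#'
#' Normalized expression by the comparative CT method: `dCT` is the target
#' CT minus the mean CT of the reference transcripts, and expression is
#' `2^-dCT`. The log2 fold change between two samples is
#' `-(dCT_a - dCT_b)`.
#'
#' @param ct_target CT value of the target assay (finite numeric scalar).
#' @param ct_refs Numeric vector of reference-gene CT values (non-empty).
#' @return `2^-(ct_target - mean(ct_refs))`.
#' @examples
#' comparative_ct(25, 20)        # 2^-5 = 0.03125
#' comparative_ct(25, c(19, 21)) # same reference mean
#' @export
comparative_ct <- function(ct_target, ct_refs) {
  if (length(ct_refs) == 0L) stop("at least one reference CT is required")
  stopifnot(is.finite(ct_target), all(is.finite(ct_refs)))
  2^-(ct_target - mean(ct_refs))
}
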