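# Resolving near-identical miRNA candidates by exact color-space census
# over the raw read files and by positional quality inspection. The
# motivating situation: two annotated mature sequences that differ by a
# single 3'-terminal base, where the rarer one may simply be sequencing
# errors of the abundant one. Because a single terminal base difference is
# exactly one color, a perfect-match census in color space plus the quality
# values at the discriminating positions settles the question.

#' Color positions discriminating two candidate sequences
#'
#' Encodes both sequences with a shared anchor base and reports every color
#' position at which the encodings differ. Positions are 1-based over the
#' post-anchor colors, i.e. they line up with read color positions (color 1
#' being the anchor/primer-adjacent color). A single internal base
#' difference yields exactly two adjacent positions; a single 3'-terminal
#' base difference yields exactly one. Candidates of unequal length are
#' compared over the shorter length, the trailing colors being additional
#' discriminating evidence (attribute `trailing`).
#'
#' @param seq_a,seq_b Nucleotide sequences (RNA accepted; U -> T).
#' @param anchor Shared anchor base for encoding.
#' @return Sorted integer vector of differing color positions, with
#'   attribute `trailing` = number of colors beyond the common length.
#' @export
discriminating_positions <- function(seq_a, seq_b, anchor = "T") {
  ca <- .color_codes(substring(encode_colorspace(seq_a, anchor), 2L))
  cb <- .color_codes(substring(encode_colorspace(seq_b, anchor), 2L))
  nmin <- min(length(ca), length(cb))
  pos <- which(ca[seq_len(nmin)] != cb[seq_len(nmin)])
  structure(as.integer(pos),
            trailing = abs(length(ca) - length(cb)))
}

#' Perfect-match color-space census of candidate sequences in raw reads
#'
#' Converts each candidate sequence into color space and counts, per sample
#' and per candidate, the raw reads whose internal colors contain the
#' candidate's internal colors exactly (no mismatches). By default the
#' match is required at read offset 0 (immediately after the
#' primer-adjacent color), since small-RNA inserts start at the adapter
#' junction; `at_start_only = FALSE` allows any offset. For samples
#' sequenced `from_3p` the candidate's colors are reversed
#' (reverse-complemented in color space) before searching.
#'
#' @param samples Named list of raw (untrimmed) [color_reads()] data
#'   frames.
#' @param candidates Named character vector of candidate sequences
#'   (RNA accepted).
#' @param at_start_only Require the match at offset 0 (default) or
#'   anywhere in the read.
#' @return A list of class `census_result`: `counts` (candidate x sample
#'   integer matrix) and `matches` (nested list
#'   `[[candidate]][[sample]]` of matching read ids).
#' @export
perfect_match_census <- function(samples, candidates, at_start_only = TRUE) {
  stopifnot(is.list(samples), !is.null(names(samples)),
            !is.null(names(candidates)))
  counts <- matrix(0L, nrow = length(candidates), ncol = length(samples),
                   dimnames = list(names(candidates), names(samples)))
  matches <- stats::setNames(vector("list", length(candidates)),
                             names(candidates))
  for (cn in names(candidates)) {
    cc <- sequence_internal_colors(candidates[[cn]])
    rc <- reverse_complement_colors(cc)
    matches[[cn]] <- stats::setNames(vector("list", length(samples)),
                                     names(samples))
    for (sn in names(samples)) {
      rd <- samples[[sn]]
      pat <- if (all(rd$direction == "from_3p")) rc else cc
      internal <- .read_internal_colors(rd)
      hit <- if (at_start_only) startsWith(internal, pat)
      else grepl(pat, internal, fixed = TRUE)
      counts[cn, sn] <- sum(hit)
      matches[[cn]][[sn]] <- rd$read_id[hit]
    }
  }
  structure(list(counts = counts, matches = matches,
                 at_start_only = at_start_only),
            class = "census_result")
}

#' Quality values at selected color positions of matched reads
#'
#' Mean (and spread) of the per-color quality values at given positions
#' over a set of reads, compared with the read-wide mean — used to check
#' that the positions discriminating two near-identical candidates were
#' sequenced at high quality.
#'
#' @param reads A [color_reads()] data frame with quality values.
#' @param read_ids Ids of the reads to inspect (e.g. census matches).
#' @param positions Color positions (1-based, read coordinates).
#' @return List: `per_position` (data frame `position`, `mean_q`, `sd_q`,
#'   `n`), `read_wide_mean`. Empty matched sets give `NA` means.
#' @export
positional_quality <- function(reads, read_ids, positions) {
  sel <- reads[reads$read_id %in% read_ids, , drop = FALSE]
  positions <- as.integer(positions)
  if (nrow(sel) == 0L) {
    return(list(per_position = data.frame(position = positions,
                                          mean_q = NA_real_, sd_q = NA_real_,
                                          n = 0L),
                read_wide_mean = NA_real_))
  }
  if (any(vapply(sel$quals, is.null, FALSE)))
    stop("reads carry no quality values")
  L <- lengths(sel$quals)
  if (any(positions < 1L | positions > min(L)))
    stop("positions outside read length")
  Q <- matrix(unlist(lapply(sel$quals, `[`, seq_len(min(L)))),
              nrow = min(L))
  per <- data.frame(position = positions,
                    mean_q = rowMeans(Q)[positions],
                    sd_q = apply(Q[positions, , drop = FALSE], 1L, stats::sd),
                    n = nrow(sel))
  list(per_position = per, read_wide_mean = mean(Q))
}
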