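# Synthetic reference, truth and color-space reads with the statistical
# structure of a SOLiD small-RNA differentiation experiment: highly skewed
# miRNA abundances with a couple of dominating species, a planted
# up-regulated miRNA family, a condition-specific novel 3p arm with an
# opposite-strand decoy differing at one 3'-terminal base, 5'-tRNA
# fragments, an intronic un-annotated locus, degradation background, and
# quality-linked color sequencing errors. Every pipeline stage is testable
# against the generated truth without any external download.

#' Simulation configuration
#'
#' All knobs of the synthetic study. Defaults describe the emulated
#' experiment: two conditions (baseline `ND`, differentiated `AD8`), two
#' biological replicates each sequenced in both adapter orientations
#' (`from_5p`, `from_3p`) as technical replicates, 35-color reads from
#' 15-50 nt inserts, about 150 mature miRNAs with two dominating at
#' roughly 30% and 14% of miRNA reads, a 5-member family rising from
#' about 1% to 5% of miRNA reads, 21 planted up- and 5 planted
#' down-regulated miRNAs, a novel 3p arm absent at baseline, and a decoy
#' planted at 1/14 of its twin's abundance.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param structure_seed Optional separate seed for the study structure
#'   (reference genome and planted abundances). When set, different master
#'   seeds re-sequence the same underlying study, so estimates can be
#'   averaged across sequencing replications against one fixed truth;
#'   `NULL` (default) ties the structure to `seed`.
#' @param n_mirnas Number of ordinary miRNA precursor loci (one expressed
#'   arm each).
#' @param n_background Number of un-annotated background windows
#'   (degradation-like mass).
#' @param transcript_len Length of each annotated transcript locus.
#' @param genome_size Bases on the main contig.
#' @param conditions Condition labels (first = baseline).
#' @param n_biological Biological replicates per condition.
#' @param directions Sequencing orientations used as technical replicates.
#' @param depth Reads per sample.
#' @param read_len Read length in colors.
#' @param adapter 3' adapter sequence (read orientation).
#' @param class_mix Named fractions of read mass per annotation class
#'   (the `miRNA_human` share is the remainder to 1).
#' @param dominant_fracs Fractions of miRNA reads taken by the two
#'   dominating species at baseline.
#' @param family_frac_nd,family_frac_ad Fraction of miRNA reads for the
#'   planted 5-member family at baseline / differentiated.
#' @param novel_frac_ad Differentiated-condition fraction of miRNA reads
#'   for the novel 3p arm (zero at baseline).
#' @param twin_frac Baseline fraction for the decoy's abundant twin.
#' @param decoy_ratio Twin:decoy abundance ratio.
#' @param up_lfc,down_lfc Planted log2 fold changes for the generic
#'   regulated miRNAs.
#' @param abund_sdlog Log-normal spread of the remaining miRNA
#'   abundances.
#' @param replicate_sdlog2 Biological replicate variability: each
#'   biological replicate's source-unit abundances are the condition
#'   abundances perturbed by `2^N(0, replicate_sdlog2)` and renormalized
#'   (technical replicates of the same biological replicate share the
#'   perturbation).
#' @param jitter_probs End-jitter probabilities for offsets -2..2
#'   (isomiR model, applied to each insert end).
#' @param qual_start,qual_slope,qual_sd,qual_min,qual_max Quality model:
#'   linear decline along the read with Gaussian noise, clamped.
#' @param error_cap Ceiling on the per-color error probability
#'   `10^(-q/10)`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              structure_seed = NULL,
                              n_mirnas = 150L,
                              n_background = 60L,
                              transcript_len = 800L,
                              genome_size = 60000L,
                              conditions = c("ND", "AD8"),
                              n_biological = 2L,
                              directions = c("from_5p", "from_3p"),
                              depth = 1e5,
                              read_len = 35L,
                              adapter = "CGCCTTGGCCGTACAGCAGAAGGCT",
                              class_mix = c(non_annotated = 0.37,
                                            transcript = 0.08,
                                            tRNA = 0.045,
                                            rRNA = 0.02,
                                            snoRNA = 0.015,
                                            piRNA = 0.01,
                                            other_ncRNA = 0.01,
                                            miRNA_other_species = 0.005),
                              dominant_fracs = c(0.302, 0.138),
                              family_frac_nd = 0.011,
                              family_frac_ad = 0.049,
                              novel_frac_ad = 5e-4,
                              twin_frac = 0.005,
                              decoy_ratio = 14,
                              up_lfc = c(1.25, 1.4, 1.5, 1.6, 1.8, 2.0, 2.2,
                                         2.5, 2.8, 3.0, 3.2, 3.6, 4.0, 4.3,
                                         4.5),
                              down_lfc = c(-1.3, -1.5, -1.6, -1.8, -2.1),
                              abund_sdlog = 1.6,
                              replicate_sdlog2 = 0.25,
                              jitter_probs = c(0.03, 0.12, 0.70, 0.12, 0.03),
                              qual_start = 28, qual_slope = 0.35,
                              qual_sd = 3, qual_min = 4, qual_max = 33,
                              error_cap = 0.25) {
  stopifnot(depth > 0, read_len > 0, n_mirnas >= 0,
            sum(class_mix) < 1, all(class_mix >= 0),
            abs(sum(jitter_probs) - 1) < 1e-9,
            length(conditions) >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

## deterministic substream seeds from the master seed
.stage_seed <- function(seed, stage) {
  offs <- c(reference = 11L, abundance = 23L, reads = 37L, errors = 53L,
            biorep = 71L)
  s <- (as.numeric(seed) * 7919 + offs[[stage]] * 104729) %% 2147483629
  as.integer(s)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate the synthetic reference (genome + class-tagged features)
#'
#' Deterministically (for a fixed seed) builds a toy genome whose feature
#' content mirrors the real annotation hierarchy: miRNA precursors with
#' mature 5p/3p children, a novel-arm precursor, a twin/decoy pair on
#' opposite strands of one locus whose mature sequences differ at exactly
#' one 3'-terminal base, tRNAs (whose 5' halves will be over-sampled),
#' rRNA/snoRNA/piRNA/other ncRNA loci, transcripts, plus un-annotated
#' regions: an intronic-style 21-nt small RNA locus and background windows
#' (degradation), none of which enter the GFF3.
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_reference`: `catalog` (an
#'   `annotation_catalog`), `units` (source-unit truth: template
#'   coordinates, class, feature ids), `special` (named ids of the
#'   distinguished loci), and `sequences` (mature sequences of the
#'   twin/decoy pair and novel arms).
#' @export
generate_reference <- function(config) {
  sseed <- if (is.null(config$structure_seed)) config$seed else
    config$structure_seed
  set.seed(.stage_seed(sseed, "reference"))
  gsize <- config$genome_size
  feat <- list()
  units <- list()
  pos <- 200L
  gseq <- strsplit(.random_dna(gsize), "")[[1L]]

  place <- function(len) {
    if (pos + len + 40L > gsize)
      stop("infeasible packing: genome too small for requested features")
    s <- pos
    pos <<- pos + len + sample(30:60, 1L)
    c(s, s + len - 1L)
  }
  add_feat <- function(id, class, start, end, strand, parent = NA) {
    feat[[length(feat) + 1L]] <<- data.frame(
      feature_id = id, rna_class = class, contig = "chr1",
      start = start, end = end, strand = strand, parent = parent,
      stringsAsFactors = FALSE)
  }
  add_unit <- function(id, feature_id, class, start, end, strand,
                       contig = "chr1") {
    units[[length(units) + 1L]] <<- data.frame(
      unit = id, feature_id = feature_id, rna_class = class,
      contig = contig, start = start, end = end, strand = strand,
      stringsAsFactors = FALSE)
  }

  ## ordinary miRNA precursors: one expressed arm each
  for (i in seq_len(config$n_mirnas)) {
    span <- place(70L)
    strand <- sample(c("+", "-"), 1L)
    pre_id <- sprintf("mir%03d", i)
    add_feat(pre_id, "miRNA_human", span[1L], span[2L], strand)
    mlen <- sample(20:23, 1L)
    m5 <- c(span[1L] + 4L, span[1L] + 4L + mlen - 1L)
    m3 <- c(span[2L] - 4L - mlen + 1L, span[2L] - 4L)
    if (strand == "-") { tmp <- m5; m5 <- m3; m3 <- tmp }
    add_feat(paste0(pre_id, "-5p"), "miRNA_human", m5[1L], m5[2L], strand, pre_id)
    add_feat(paste0(pre_id, "-3p"), "miRNA_human", m3[1L], m3[2L], strand, pre_id)
    arm <- sample(c("5p", "3p"), 1L)
    mm <- if (arm == "5p") m5 else m3
    add_unit(paste0(pre_id, "-", arm), paste0(pre_id, "-", arm),
             "miRNA_human", mm[1L], mm[2L], strand)
  }

  ## novel-arm precursor: both arms expressed at AD8, absent at baseline
  span <- place(70L)
  add_feat("mir-novel", "miRNA_human", span[1L], span[2L], "+")
  add_feat("mir-novel-5p", "miRNA_human", span[1L] + 4L, span[1L] + 25L, "+",
           "mir-novel")
  add_feat("mir-novel-3p", "miRNA_human", span[2L] - 25L, span[2L] - 4L, "+",
           "mir-novel")
  add_unit("mir-novel-5p", "mir-novel-5p", "miRNA_human",
           span[1L] + 4L, span[1L] + 25L, "+")
  add_unit("mir-novel-3p", "mir-novel-3p", "miRNA_human",
           span[2L] - 25L, span[2L] - 4L, "+")

  ## twin/decoy pair: opposite strands of one locus, mature sequences
  ## differing at exactly one 3'-terminal base
  span <- place(80L)
  twin_seq <- .random_dna(21L)
  twin_lo <- span[1L] + 4L
  gseq[twin_lo:(twin_lo + 20L)] <- strsplit(twin_seq, "")[[1L]]
  last <- substr(twin_seq, 21L, 21L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), last), 1L)
  decoy_seq <- paste0(substr(twin_seq, 1L, 20L), alt)
  decoy_lo <- span[1L] + 45L
  gseq[decoy_lo:(decoy_lo + 20L)] <- strsplit(.revcomp_chr(decoy_seq), "")[[1L]]
  add_feat("mir-twin", "miRNA_human", span[1L], span[2L], "+")
  add_feat("mir-twin-3p", "miRNA_human", twin_lo, twin_lo + 20L, "+",
           "mir-twin")
  add_feat("mir-decoy", "miRNA_human", span[1L], span[2L], "-")
  add_feat("mir-decoy-3p", "miRNA_human", decoy_lo, decoy_lo + 20L, "-",
           "mir-decoy")
  add_unit("mir-twin-3p", "mir-twin-3p", "miRNA_human", twin_lo,
           twin_lo + 20L, "+")
  add_unit("mir-decoy-3p", "mir-decoy-3p", "miRNA_human", decoy_lo,
           decoy_lo + 20L, "-")

  ## other annotated classes
  other_spec <- list(
    list(class = "miRNA_other_species", n = 4L, len = 22L, tmpl = "full"),
    list(class = "transcript", n = 4L, len = config$transcript_len,
         tmpl = "window"),
    list(class = "piRNA", n = 6L, len = 28L, tmpl = "full"),
    list(class = "tRNA", n = 6L, len = 72L, tmpl = "head"),
    list(class = "rRNA", n = 2L, len = 120L, tmpl = "window"),
    list(class = "snoRNA", n = 6L, len = 80L, tmpl = "window"),
    list(class = "other_ncRNA", n = 6L, len = 60L, tmpl = "window"))
  for (sp in other_spec) {
    for (i in seq_len(sp$n)) {
      span <- place(sp$len)
      strand <- sample(c("+", "-"), 1L)
      id <- sprintf("%s%02d", tolower(sp$class), i)
      add_feat(id, sp$class, span[1L], span[2L], strand)
      tm <- switch(sp$tmpl,
        full = span,
        # 5'-tRNA fragments: the first ~18 nt of the mature tRNA
        head = if (strand == "+") c(span[1L], span[1L] + 17L)
               else c(span[2L] - 17L, span[2L]),
        window = {
          # windows stay short enough that the adapter overlap remains
          # detectable inside the fixed-length read
          wl <- sample(18:24, 1L)
          ws <- span[1L] + sample.int(sp$len - wl, 1L) - 1L
          c(ws, ws + wl - 1L)
        })
      add_unit(id, id, sp$class, tm[1L], tm[2L], strand)
    }
  }

  ## un-annotated mass: intronic-style 21-nt locus + background windows
  span <- place(21L)
  add_unit("intronic-smallrna", NA_character_, "non_annotated",
           span[1L], span[2L], "+")
  for (i in seq_len(config$n_background)) {
    wl <- sample(16:24, 1L)
    span <- place(wl)
    add_unit(sprintf("background%02d", i), NA_character_, "non_annotated",
             span[1L], span[2L], sample(c("+", "-"), 1L))
  }

  genome <- paste(gseq, collapse = "")
  features <- do.call(rbind, feat)
  catalog <- build_catalog(Biostrings::DNAStringSet(c(chr1 = genome)),
                           features)
  units <- do.call(rbind, units)
  rownames(units) <- NULL
  contig_chr <- as.character(catalog$contigs)
  useq <- substring(contig_chr[units$contig], units$start, units$end)
  neg <- units$strand == "-"
  useq[neg] <- .revcomp_chr(useq[neg])
  units$template_seq <- useq
  structure(list(catalog = catalog, units = units,
                 special = list(twin = "mir-twin-3p", decoy = "mir-decoy-3p",
                                novel_3p = "mir-novel-3p",
                                novel_5p = "mir-novel-5p",
                                intronic = "intronic-smallrna"),
                 sequences = c(`mir-twin-3p` = twin_seq,
                               `mir-decoy-3p` = decoy_seq)),
            class = "sim_reference")
}

## condition-specific unit weights (global simplex over all source units)
## and the per-unit truth table
.build_truth <- function(config, reference) {
  sseed <- if (is.null(config$structure_seed)) config$seed else
    config$structure_seed
  set.seed(.stage_seed(sseed, "abundance"))
  units <- reference$units
  nu <- nrow(units)
  is_mir <- units$rna_class == "miRNA_human"
  mir_ids <- units$unit[is_mir]

  ## within-miRNA composition at baseline
  special <- c(dom1 = mir_ids[1L], dom2 = mir_ids[2L])
  family <- mir_ids[3:7]
  ordinary <- setdiff(mir_ids, c(special, family, "mir-novel-5p",
                                 "mir-novel-3p", "mir-twin-3p",
                                 "mir-decoy-3p"))
  w <- stats::setNames(numeric(length(mir_ids)), mir_ids)
  raw <- stats::rlnorm(length(ordinary), meanlog = 0,
                       sdlog = config$abund_sdlog)
  twin_w <- config$twin_frac
  decoy_w <- twin_w / config$decoy_ratio
  rest <- 1 - sum(config$dominant_fracs) - config$family_frac_nd -
    twin_w - decoy_w
  w[ordinary] <- raw / sum(raw) * rest
  w[special["dom1"]] <- config$dominant_fracs[1L]
  w[special["dom2"]] <- config$dominant_fracs[2L]
  fam_split <- stats::rlnorm(5L, 0, 0.4)
  w[family] <- fam_split / sum(fam_split) * config$family_frac_nd
  w["mir-twin-3p"] <- twin_w
  w["mir-decoy-3p"] <- decoy_w
  w["mir-novel-5p"] <- 0
  w["mir-novel-3p"] <- 0

  ## planted regulation for the differentiated condition; small scenarios
  ## scale the planted sets down with the number of available miRNAs
  up_lfc <- config$up_lfc[seq_len(min(length(config$up_lfc),
                                      floor(length(ordinary) * 0.5)))]
  down_lfc <- config$down_lfc[seq_len(min(length(config$down_lfc),
                                          length(ordinary) - length(up_lfc)))]
  up_pool <- ordinary[w[ordinary] >= 5e-4 & w[ordinary] <= 0.02]
  if (length(up_pool) < length(up_lfc)) up_pool <- ordinary
  up_generic <- sample(up_pool, length(up_lfc))
  down_pool <- setdiff(ordinary[w[ordinary] >= 5e-4 & w[ordinary] <= 0.03],
                       up_generic)
  if (length(down_pool) < length(down_lfc))
    down_pool <- setdiff(ordinary, up_generic)
  down_generic <- sample(down_pool, length(down_lfc))
  w2 <- w
  w2[up_generic] <- w[up_generic] * 2^up_lfc
  w2[down_generic] <- w[down_generic] * 2^down_lfc
  w2[family] <- w[family] / sum(w[family]) * config$family_frac_ad
  w2["mir-novel-3p"] <- config$novel_frac_ad
  w2["mir-novel-5p"] <- config$novel_frac_ad / 5
  w2 <- w2 / sum(w2)

  ## first condition is baseline; all later conditions share the
  ## differentiated composition
  ncond <- length(config$conditions)
  mir_w <- matrix(rep(w2, ncond), ncol = ncond,
                  dimnames = list(mir_ids, config$conditions))
  mir_w[, 1L] <- w

  ## other classes: composition fixed across conditions
  class_mix <- config$class_mix
  mir_frac <- 1 - sum(class_mix)
  wt_all <- matrix(0, nrow = nu, ncol = length(config$conditions),
                   dimnames = list(units$unit, config$conditions))
  wt_all[is_mir, ] <- mir_w * mir_frac
  for (cls in names(class_mix)) {
    sel <- units$rna_class == cls
    if (!any(sel)) next
    ww <- stats::rlnorm(sum(sel), 0, 1)
    if (cls == "non_annotated") # the intronic locus carries a solid share
      ww[units$unit[sel] == "intronic-smallrna"] <- sum(ww) * 0.12
    ww <- ww / sum(ww) * class_mix[[cls]]
    wt_all[sel, ] <- ww
  }

  truth <- units
  for (j in seq_along(config$conditions))
    truth[[paste0("abund_", config$conditions[j])]] <- wt_all[, j]
  if (length(config$conditions) >= 2L) {
    a <- config$conditions[length(config$conditions)]
    b <- config$conditions[1L]
    lfc <- log2(wt_all[, a] / wt_all[, b])
    truth$true_log2fc <- lfc
    truth$true_cpm_base <- ifelse(is_mir, mir_w[, b] * 1e6, NA_real_)
    truth$true_cpm_diff <- ifelse(is_mir,
                                  mir_w[, length(config$conditions)] * 1e6,
                                  NA_real_)
  }
  planted <- list(up = c(up_generic, family, "mir-novel-3p"),
                  down = down_generic)
  list(weights = wt_all, truth = truth, planted = planted)
}

#' Simulate color-space reads for every sample of the study
#'
#' Draws reads multinomially from the condition-specific source-unit
#' abundances, applies isomiR end jitter, appends the adapter when the
#' insert is shorter than the read, encodes to SOLiD colors, draws
#' position-dependent quality values and injects color errors at the
#' quality-linked rate `min(10^(-q/10), cap)`. Each biological replicate
#' is sequenced once per direction (`from_3p` reads are the reverse
#' complement of the insert), giving
#' `conditions x n_biological x directions` samples.
#'
#' @param config A [simulation_config()].
#' @param reference Result of [generate_reference()] for the same config.
#' @param keep_quals Attach the per-read quality vectors to the output
#'   reads (default). Setting `FALSE` skips only that attachment; the
#'   quality draws, error injection and therefore the read colors are
#'   identical either way.
#' @return List of class `sim_reads`: `samples` (named list of
#'   [color_reads()]), `sample_sheet` (sample, condition, replicate,
#'   direction), `truth` (per-unit truth table with condition abundances
#'   and true log2 fold changes), `planted` (ids of up/down regulated
#'   units), `read_truth` (per-sample data frames: origin unit and error
#'   count per read).
#' @export
simulate_reads <- function(config, reference, keep_quals = TRUE) {
  tr <- .build_truth(config, reference)
  units <- reference$units
  contig_chr <- as.character(reference$catalog$contigs)
  clen <- stats::setNames(nchar(contig_chr), names(contig_chr))
  sheet <- expand.grid(direction = config$directions,
                       replicate = seq_len(config$n_biological),
                       condition = config$conditions,
                       stringsAsFactors = FALSE)[, 3:1]
  sheet$sample <- sprintf("%s.%d.%s", sheet$condition, sheet$replicate,
                          sub("from_", "", sheet$direction))
  sheet <- sheet[, c("sample", "condition", "replicate", "direction")]
  L <- config$read_len
  adapter <- config$adapter
  # adapter tail long enough to always fill the read
  adapter_fill <- paste(rep(adapter, ceiling((L + 2) / nchar(adapter))),
                        collapse = "")
  samples <- list()
  read_truth <- list()
  joff <- -2:2
  ## biological replicate abundance perturbations, shared by the technical
  ## (direction) replicates of each biological replicate
  set.seed(.stage_seed(config$seed, "biorep"))
  nu <- nrow(units)
  biorep_w <- list()
  for (cc in config$conditions) {
    for (r in seq_len(config$n_biological)) {
      ww <- tr$weights[, cc] *
        2^stats::rnorm(nu, 0, config$replicate_sdlog2)
      ww[tr$weights[, cc] == 0] <- 0
      biorep_w[[paste(cc, r)]] <- ww / sum(ww)
    }
  }
  ptab <- pmin(10^(-(0:100) / 10), config$error_cap)
  base_q <- config$qual_start - config$qual_slope * (seq_len(L) - 1L)
  for (i in seq_len(nrow(sheet))) {
    sm <- sheet[i, ]
    n <- as.integer(config$depth)
    set.seed((.stage_seed(config$seed, "reads") + 977 * i) %% 2147483629)
    ui <- sample.int(nrow(units), n, replace = TRUE,
                     prob = biorep_w[[paste(sm$condition, sm$replicate)]])
    d5 <- sample(joff, n, replace = TRUE, prob = config$jitter_probs)
    d3 <- sample(joff, n, replace = TRUE, prob = config$jitter_probs)
    us <- units$start[ui]; ue <- units$end[ui]
    neg <- units$strand[ui] == "-"
    # jitter in transcript orientation: d5 moves the 5' end, d3 the 3' end
    s <- ifelse(neg, us - d3, us + d5)
    e <- ifelse(neg, ue - d5, ue + d3)
    s <- pmax(1L, s); e <- pmin(clen[units$contig[ui]], e)
    insert <- substring(contig_chr[units$contig[ui]], s, e)
    flip <- xor(neg, sm$direction == "from_3p")
    if (any(flip)) insert[flip] <- .revcomp_chr(insert[flip])
    bases <- substr(paste0(insert, adapter_fill), 1L, L)
    B <- .CS_CODE[utf8ToInt(paste(bases, collapse = ""))]
    dim(B) <- c(L, n)
    ## colors
    C <- matrix(0L, nrow = L, ncol = n)
    C[1L, ] <- bitwXor(3L, B[1L, ])  # primer T
    C[2:L, ] <- bitwXor(B[1:(L - 1L), ], B[2:L, ])
    ## qualities and quality-linked color errors
    set.seed((.stage_seed(config$seed, "errors") + 977 * i) %% 2147483629)
    qv <- round(rep.int(base_q, n) + stats::rnorm(L * n, 0, config$qual_sd))
    qv[qv < config$qual_min] <- config$qual_min
    qv[qv > config$qual_max] <- config$qual_max
    qv <- as.integer(qv)
    hit <- which(stats::runif(L * n) < ptab[qv + 1L])
    if (length(hit))
      C[hit] <- bitwXor(C[hit], sample(1:3, length(hit), replace = TRUE))
    sall <- intToUtf8(as.vector(C) + 48L)
    colstr <- substring(sall, seq(1L, by = L, length.out = n),
                        seq(L, by = L, length.out = n))
    ids <- sprintf("%s_%06d", sm$sample, seq_len(n))
    quals <- if (keep_quals) {
      Q <- qv; dim(Q) <- c(L, n)
      lapply(seq_len(n), function(k) Q[, k])
    } else rep(list(NULL), n)
    rd <- .new_color_reads(ids, "T", colstr, quals, sm$direction)
    samples[[sm$sample]] <- rd
    nerr <- integer(n)
    if (length(hit)) {
      tb <- table((hit - 1L) %/% L + 1L)
      nerr[as.integer(names(tb))] <- as.integer(tb)
    }
    read_truth[[sm$sample]] <- data.frame(
      read_id = ids, unit = units$unit[ui], n_errors = nerr,
      insert_len = e - s + 1L, stringsAsFactors = FALSE)
  }
  structure(list(samples = samples, sample_sheet = sheet,
                 truth = tr$truth, planted = tr$planted,
                 read_truth = read_truth),
            class = "sim_reads")
}

#' The default study scenario
#'
#' One call bundles the emulated experiment: [simulation_config()] with
#' its defaults and the given seed, the generated reference, and the
#' simulated reads for all samples.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [simulation_config()].
#' @param keep_quals Passed to [simulate_reads()].
#' @return List: `config`, `reference`, `reads` (a `sim_reads` object).
#' @export
default_study_scenario <- function(seed = 1L, ..., keep_quals = TRUE) {
  config <- simulation_config(seed = seed, ...)
  reference <- generate_reference(config)
  reads <- simulate_reads(config, reference, keep_quals = keep_quals)
  list(config = config, reference = reference, reads = reads)
}

#' Simulate reads from explicit sequences at a fixed error rate
#'
#' A lightweight generator for focused experiments (e.g. the census of a
#' twin/decoy pair): reads are drawn multinomially from the given
#' sequences, encoded to colors with primer `T`, and each color is flipped
#' with the stated probability. Quality values are set uniformly to
#' `-10*log10(error_rate)`.
#'
#' @param seqs Named character vector of insert sequences.
#' @param weights Sampling weights, one per sequence.
#' @param n Number of reads.
#' @param error_rate Per-color error probability.
#' @param seed Seed.
#' @param read_len Read length in colors.
#' @param adapter Adapter appended after the insert.
#' @param direction Sequencing orientation of the simulated sample.
#' @return A list: `reads` (a [color_reads()] data frame), `origin`
#'   (integer vector: source sequence of each read).
#' @export
simulate_reads_from_sequences <- function(seqs, weights, n, error_rate = 0,
                                          seed = 1L, read_len = 35L,
                                          adapter = "CGCCTTGGCCGTACAGCAGAAGGCT",
                                          direction = "from_5p") {
  stopifnot(length(seqs) == length(weights), n >= 1)
  set.seed(as.integer(seed))
  L <- as.integer(read_len)
  ui <- sample.int(length(seqs), n, replace = TRUE, prob = weights)
  ins <- unname(seqs[ui])
  if (direction == "from_3p") ins <- .revcomp_chr(ins)
  fill <- paste(rep(adapter, ceiling((L + 2) / nchar(adapter))),
                collapse = "")
  bases <- substr(paste0(ins, fill), 1L, L)
  B <- matrix(.CS_CODE[utf8ToInt(paste(bases, collapse = ""))], nrow = L)
  C <- matrix(0L, nrow = L, ncol = n)
  C[1L, ] <- bitwXor(3L, B[1L, ])
  if (L > 1L) C[2:L, ] <- bitwXor(B[1:(L - 1L), ], B[2:L, ])
  if (error_rate > 0) {
    hit <- which(matrix(stats::runif(L * n), nrow = L) < error_rate)
    if (length(hit))
      C[hit] <- bitwXor(C[hit], sample(1:3, length(hit), replace = TRUE))
  }
  sall <- intToUtf8(as.vector(C) + 48L)
  colstr <- substring(sall, seq(1L, by = L, length.out = n),
                      seq(L, by = L, length.out = n))
  q <- if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 40L
  rd <- .new_color_reads(sprintf("read_%06d", seq_len(n)), "T", colstr,
                         rep(list(rep(q, L)), n), direction)
  list(reads = rd, origin = ui)
}
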