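test_that("adapter trimming removes the adapter suffix in color space", {
  set.seed(31)
  adapter <- "CGCCTTGGCCGTACAGCAGAAGGCT"
  insert <- rand_dna(20)
  read35 <- substr(paste0(insert, adapter), 1, 35)
  rd <- color_reads("r1", "T", substring(encode_colorspace(read35, "T"), 2),
                    list(rep(20L, 35)))
  tr <- trim_adapter(rd, adapter)
  expect_true(tr$trimmed)
  expect_identical(nchar(tr$colors), 20L)
  expect_identical(tr$colors, substring(encode_colorspace(insert, "T"), 2))
  expect_identical(lengths(tr$quals), 20L)
  expect_false(tr$too_short)

  # read with no adapter: unchanged
  full <- rand_dna(35)
  rd2 <- color_reads("r2", "T", substring(encode_colorspace(full, "T"), 2))
  tr2 <- trim_adapter(rd2, adapter)
  expect_false(tr2$trimmed)
  expect_identical(tr2$colors, rd2$colors)

  # adapter dimer: trimmed to (almost) nothing and flagged too_short
  rd3 <- color_reads("r3", "T", substring(encode_colorspace(
    substr(paste0(adapter, adapter), 1, 35), "T"), 2))
  tr3 <- trim_adapter(rd3, adapter)
  expect_true(tr3$too_short)
})

test_that("trimming tolerates one color error in a long adapter overlap", {
  set.seed(32)
  adapter <- "CGCCTTGGCCGTACAGCAGAAGGCT"
  insert <- rand_dna(18)
  read35 <- substr(paste0(insert, adapter), 1, 35)
  colors <- substring(encode_colorspace(read35, "T"), 2)
  # flip one color inside the adapter region (overlap 17 >= 10)
  colors <- paste0(substr(colors, 1, 24),
                   as.character((as.integer(substr(colors, 25, 25)) + 1) %% 4),
                   substring(colors, 26))
  tr <- trim_adapter(color_reads("r1", "T", colors), adapter)
  expect_true(tr$trimmed)
  expect_identical(nchar(tr$colors), 18L)
  # an error inside the insert must not block trimming either
  colors2 <- substring(encode_colorspace(read35, "T"), 2)
  colors2 <- paste0(as.character((as.integer(substr(colors2, 1, 1)) + 2) %% 4),
                    substring(colors2, 2))
  tr2 <- trim_adapter(color_reads("r2", "T", colors2), adapter)
  expect_identical(nchar(tr2$colors), 18L)
})

test_that("matching obeys the seed/tail color mismatch budget", {
  cat0 <- tiny_catalog()
  rd <- window_read(cat0, "chr1", 105, 126)
  h <- match_reads(rd, cat0)
  expect_identical(h$start[1], 105L)
  expect_identical(h$end[1], 126L)
  expect_identical(h$mm_seed[1] + h$mm_tail[1], 0L)

  # one altered color at color 5 of the seed: still a hit
  cv <- corrupt_one <- rd
  internal <- substring(rd$colors, 2)
  v <- as.integer(strsplit(internal, "")[[1]])
  v[5] <- (v[5] + 1L) %% 4L
  rd1 <- color_reads("r1", "T", paste0("0", paste(v, collapse = "")))
  h1 <- match_reads(rd1, cat0)
  expect_true(any(h1$start == 105 & h1$mm_seed == 1L))

  # two altered colors in the seed (colors 3 and 9): over budget, no hit there
  v2 <- as.integer(strsplit(internal, "")[[1]])
  v2[c(3, 9)] <- (v2[c(3, 9)] + 1L) %% 4L
  rd2 <- color_reads("r2", "T", paste0("0", paste(v2, collapse = "")))
  h2 <- match_reads(rd2, cat0)
  expect_false(any(h2$start == 105 & h2$strand == "+"))
})

test_that("seed-and-extend equals the brute-force oracle on random genomes", {
  set.seed(33)
  for (rep in 1:4) {
    contigs <- c(chr1 = rand_dna(1500), chr2 = rand_dna(700))
    cat1 <- build_catalog(contigs, data.frame(
      feature_id = character(0), rna_class = character(0),
      contig = character(0), start = integer(0), end = integer(0),
      strand = character(0), parent = character(0)))
    for (t in 1:25) {
      cn <- sample(names(contigs), 1)
      len <- sample(16:35, 1)
      st <- sample(nchar(contigs[[cn]]) - len, 1)
      internal <- sequence_internal_colors(substr(contigs[[cn]], st, st + len - 1))
      ne <- sample(0:3, 1)
      if (ne > 0) internal <- corrupt_colors(internal, ne)
      rd <- color_reads("r", "T", paste0("0", internal))
      got <- sort_hits(match_reads(rd, cat1))
      want <- sort_hits(oracle_match_one(internal, as.list(contigs)))
      expect_identical(got, want)
    }
  }
})

test_that("reads sequenced from the 3' end match after color reversal", {
  cat0 <- tiny_catalog()
  rd <- window_read(cat0, "chr1", 145, 166, direction = "from_3p")
  h <- match_reads(rd, cat0)
  expect_identical(h$start[1], 145L)
  expect_identical(h$strand[1], "+")
})

test_that("assignment is exclusive and follows the hierarchy", {
  cat0 <- tiny_catalog()
  # a read overlapping the mature miRNA: category miRNA_human, mature wins
  # over its spanning precursor
  rd <- window_read(cat0, "chr1", 105, 126)
  asg <- assign_reads(match_reads(rd, cat0), rd, cat0)
  expect_identical(asg$category, "miRNA_human")
  expect_identical(asg$feature_id, "mat-a-5p")
  # read in open genome: mapped but non_annotated
  rd2 <- window_read(cat0, "chr1", 520, 545)
  asg2 <- assign_reads(match_reads(rd2, cat0), rd2, cat0)
  expect_identical(asg2$category, "non_annotated")
  expect_true(is.na(asg2$feature_id))
  # unmappable random read
  set.seed(34)
  rd3 <- color_reads("r3", "T", paste(sample(0:3, 30, TRUE), collapse = ""))
  asg3 <- assign_reads(match_reads(rd3, cat0), rd3, cat0)
  expect_identical(asg3$category, "unmapped")
  # minus-strand feature claims only minus-strand hits
  rd4 <- window_read(cat0, "chr1", 401, 428, strand = "-")
  asg4 <- assign_reads(match_reads(rd4, cat0), rd4, cat0)
  expect_identical(asg4$category, "piRNA")
  expect_identical(asg4$strand, "-")
})

test_that("hierarchy priority decides reads overlapping two classes", {
  set.seed(35)
  g <- rand_dna(500)
  # a miRNA and a tRNA overlapping the same window
  feats <- data.frame(
    feature_id = c("mir-x", "trna-x"),
    rna_class = c("miRNA_human", "tRNA"),
    contig = "chr1", start = c(101L, 95L), end = c(122L, 170L),
    strand = "+", parent = NA, stringsAsFactors = FALSE)
  cat1 <- build_catalog(c(chr1 = g), feats)
  rd <- window_read(cat1, "chr1", 101, 122)
  asg <- assign_reads(match_reads(rd, cat1), rd, cat1)
  expect_identical(asg$category, "miRNA_human")
  # with a tRNA-first hierarchy the same read flips class
  cat2 <- build_catalog(c(chr1 = g), feats,
                        hierarchy = c("tRNA", "miRNA_human"))
  asg2 <- assign_reads(match_reads(rd, cat2), rd, cat2)
  expect_identical(asg2$category, "tRNA")
})

test_that("assign_all conserves reads and fractions sum to one", {
  set.seed(36)
  # two planted 22-mers in a genome: one annotated as a miRNA, one not
  sa <- rand_dna(22); sb <- rand_dna(22)
  g <- paste0(rand_dna(100), sa, rand_dna(60), sb, rand_dna(100))
  cat1 <- build_catalog(c(chr1 = g), data.frame(
    feature_id = "mir-a", rna_class = "miRNA_human", contig = "chr1",
    start = 101L, end = 122L, strand = "+", parent = NA))
  sim <- simulate_reads_from_sequences(c(a = sa, b = sb), c(6, 4), 400,
                                       error_rate = 0, seed = 37)
  aset <- assign_all(list(s1 = sim$reads), cat1,
                     adapter = "CGCCTTGGCCGTACAGCAGAAGGCT")
  cnt <- aset$counts
  expect_identical(cnt$reads_in, 400L)
  expect_identical(cnt$too_short + cnt$unmapped + cnt$mapped, cnt$reads_in)
  fr <- as.numeric(aset$class_fractions[1, -1])
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # zero-error reads from planted windows: fractions equal planted mixture
  expect_equal(aset$class_fractions$miRNA_human[1], mean(sim$origin == 1),
               tolerance = 1e-12)
  expect_equal(aset$class_fractions$non_annotated[1], mean(sim$origin == 2),
               tolerance = 1e-12)
})

test_that("loosening the mismatch budget never unmaps a read", {
  set.seed(38)
  g <- rand_dna(2000)
  cat1 <- build_catalog(c(chr1 = g), data.frame(
    feature_id = character(0), rna_class = character(0), contig = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    parent = character(0)))
  n_mapped <- function(smax, tmax) {
    set.seed(39)
    cnt <- 0L
    for (t in 1:60) {
      len <- sample(18:35, 1)
      st <- sample(nchar(g) - len, 1)
      internal <- sequence_internal_colors(substr(g, st, st + len - 1))
      internal <- corrupt_colors(internal, sample(0:4, 1))
      rd <- color_reads("r", "T", paste0("0", internal))
      h <- match_reads(rd, cat1, match_params(seed_mismatch_max = smax,
                                              tail_mismatch_max = tmax))
      cnt <- cnt + (nrow(h) > 0L)
    }
    cnt
  }
  tight <- n_mapped(0, 1)
  base <- n_mapped(1, 2)
  loose <- n_mapped(2, 3)
  expect_true(tight <= base)
  expect_true(base <= loose)
})
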