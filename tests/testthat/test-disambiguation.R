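# exact color-space census and positional quality for near-identical
# miRNA candidates

test_that("discriminating positions reflect the di-base geometry", {
  s <- "ACGTACGTACGTACGTACGTA"
  expect_length(discriminating_positions(s, s), 0)
  # single internal base difference: exactly two adjacent color positions
  s2 <- paste0(substr(s, 1, 9), "A", substring(s, 11))
  d <- discriminating_positions(s, s2)
  expect_identical(as.integer(d), c(10L, 11L))
  # single 3'-terminal base difference: exactly one color position
  s3 <- paste0(substr(s, 1, 20), "G")
  d3 <- discriminating_positions(s, s3)
  expect_identical(as.integer(d3), 21L)
  # unequal lengths: compared over the shorter, trailing colors recorded
  d4 <- discriminating_positions(s, substr(s, 1, 18))
  expect_length(d4, 0)
  expect_identical(attr(d4, "trailing"), 3L)
})

test_that("census counts planted candidates exactly at zero error", {
  set.seed(51)
  twin <- rand_dna(21)
  decoy <- paste0(substr(twin, 1, 20),
                  setdiff(c("A", "C", "G", "T"), substr(twin, 21, 21))[1])
  other <- rand_dna(21)
  sim <- simulate_reads_from_sequences(
    c(twin = twin, decoy = decoy, other = other), c(120, 40, 240), 400,
    error_rate = 0, seed = 51)
  cen <- perfect_match_census(list(s1 = sim$reads),
                              c(twin = twin, decoy = decoy,
                                absent = rand_dna(21)))
  expect_identical(cen$counts["twin", "s1"], sum(sim$origin == 1))
  expect_identical(cen$counts["decoy", "s1"], sum(sim$origin == 2))
  expect_identical(cen$counts["absent", "s1"], 0L)
  # counts are monotone non-increasing in candidate length
  c_short <- perfect_match_census(list(s1 = sim$reads),
                                  c(t = substr(twin, 1, 15)))$counts[1, 1]
  c_long <- perfect_match_census(list(s1 = sim$reads),
                                 c(t = twin))$counts[1, 1]
  expect_true(c_long <= c_short)
})

test_that("census respects sequencing direction and the any-offset mode", {
  set.seed(52)
  twin <- rand_dna(21)
  sim3p <- simulate_reads_from_sequences(c(twin = twin), 1, 50,
                                         error_rate = 0, seed = 52,
                                         direction = "from_3p")
  cen <- perfect_match_census(list(s1 = sim3p$reads), c(twin = twin))
  expect_identical(cen$counts["twin", "s1"], 50L)
  # a candidate that is an internal fragment is found only in any-offset mode
  frag <- substr(twin, 4, 18)
  sim5p <- simulate_reads_from_sequences(c(twin = twin), 1, 50,
                                         error_rate = 0, seed = 53)
  at0 <- perfect_match_census(list(s1 = sim5p$reads), c(frag = frag))
  any <- perfect_match_census(list(s1 = sim5p$reads), c(frag = frag),
                              at_start_only = FALSE)
  expect_identical(at0$counts["frag", "s1"], 0L)
  expect_identical(any$counts["frag", "s1"], 50L)
})

test_that("a 14x twin dominates its one-base decoy in the census despite errors", {
  set.seed(54)
  twin <- rand_dna(21)
  decoy <- paste0(substr(twin, 1, 20),
                  setdiff(c("A", "C", "G", "T"), substr(twin, 21, 21))[1])
  sim <- simulate_reads_from_sequences(c(twin = twin, decoy = decoy),
                                       c(14, 1), 3000, error_rate = 0.01,
                                       seed = 54)
  cen <- perfect_match_census(list(s1 = sim$reads),
                              c(twin = twin, decoy = decoy))
  ratio <- cen$counts["twin", 1] / max(1L, cen$counts["decoy", 1])
  expect_gt(ratio, 5)
})

test_that("positional quality summarises the discriminating positions", {
  n <- 40
  quals <- lapply(1:n, function(i) rep(25L, 30))
  rd <- color_reads(sprintf("r%02d", 1:n), "T",
                    replicate(n, paste(sample(0:3, 30, TRUE), collapse = "")),
                    quals)
  pq <- positional_quality(rd, rd$read_id, c(5, 21))
  expect_equal(pq$per_position$mean_q, c(25, 25))
  expect_equal(pq$read_wide_mean, 25)
  # planted dip at one position shows up below the read-wide mean
  quals2 <- lapply(quals, function(q) { q[20] <- 8L; q })
  rd2 <- color_reads(rd$read_id, "T", rd$colors, quals2)
  pq2 <- positional_quality(rd2, rd2$read_id, 20)
  expect_lt(pq2$per_position$mean_q[1], pq2$read_wide_mean)
  # empty matched set reports missing values
  pq0 <- positional_quality(rd, character(0), 5)
  expect_true(is.na(pq0$read_wide_mean))
  expect_error(positional_quality(rd, rd$read_id, 31), "outside")
})

test_that("quality-linked errors: high-quality positions are the reliable ones", {
  scn <- default_study_scenario(seed = 6, depth = 4000,
                                n_mirnas = 20, genome_size = 20000)
  rt <- scn$reads$read_truth[[1]]
  rd <- scn$reads$samples[[1]]
  # reads without injected errors decode to their planted insert + adapter
  clean <- which(rt$n_errors == 0)[1:50]
  units <- scn$reference$units
  for (i in clean[1:10]) {
    u <- units[units$unit == rt$unit[i], ]
    dec <- decode_colorspace(paste0(rd$primer[i], rd$colors[i]))
    tmpl <- u$template_seq
    # jittered insert still sits inside the decoded read start
    expect_true(startsWith(dec, substr(tmpl, 3, 12)) ||
                  grepl(substr(tmpl, 3, 12), substr(dec, 1, 15), fixed = TRUE))
  }
  # empirical error rate at high-quality colors is below the low-quality rate
  Q <- do.call(cbind, rd$quals[1:2000])
  expect_gt(mean(Q[1:10, ]), mean(Q[26:35, ]))
})
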