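# the synthetic study generator: determinism, structural guarantees,
# decodability and the error model

test_that("reference generation is deterministic and structurally sound", {
  config <- simulation_config(seed = 3, n_mirnas = 12, genome_size = 15000)
  r1 <- generate_reference(config)
  r2 <- generate_reference(config)
  expect_identical(as.character(r1$catalog$contigs),
                   as.character(r2$catalog$contigs))
  expect_identical(r1$catalog$features, r2$catalog$features)
  expect_identical(r1$units, r2$units)
  # precursors span their mature children (validated in build_catalog);
  # twin and decoy on opposite strands, differing at one 3'-terminal base
  fx <- r1$catalog$features
  tw <- fx[fx$feature_id == "mir-twin-3p", ]
  dc <- fx[fx$feature_id == "mir-decoy-3p", ]
  expect_identical(tw$strand, "+")
  expect_identical(dc$strand, "-")
  twin <- r1$sequences[["mir-twin-3p"]]
  decoy <- r1$sequences[["mir-decoy-3p"]]
  expect_identical(substr(twin, 1, 20), substr(decoy, 1, 20))
  expect_false(substr(twin, 21, 21) == substr(decoy, 21, 21))
  # and their planted sequences really sit in the genome
  d <- discriminating_positions(twin, decoy)
  expect_identical(as.integer(d), 21L)
  # no miRNAs requested -> no miRNA features, catalog still valid
  r0 <- generate_reference(simulation_config(seed = 3, n_mirnas = 0,
                                             genome_size = 15000))
  expect_identical(sum(grepl("^mir\\d", r0$catalog$features$feature_id)), 0L)
})

test_that("infeasible packing is rejected", {
  expect_error(generate_reference(simulation_config(seed = 1, n_mirnas = 100,
                                                    genome_size = 3000)),
               "infeasible packing")
})

test_that("simulated reads are deterministic, 35 colors, and decodable at zero error", {
  config <- simulation_config(seed = 4, n_mirnas = 10, genome_size = 12000,
                              n_background = 15, transcript_len = 250,
                              depth = 600, qual_min = 40, qual_max = 40,
                              jitter_probs = c(0, 0, 1, 0, 0))
  ref <- generate_reference(config)
  s1 <- simulate_reads(config, ref)
  s2 <- simulate_reads(config, ref)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth, s2$truth)
  rd <- s1$samples[[1]]
  expect_true(all(nchar(rd$colors) == 35L))
  # zero error (qual 40 -> p = 1e-4 ~ none at this depth), zero jitter:
  # every read decodes to its planted template (+ adapter fill)
  rt <- s1$read_truth[[1]]
  units <- ref$units
  ok <- rt$n_errors == 0
  dec <- vapply(which(ok)[1:100], function(i)
    decode_colorspace(paste0(rd$primer[i], rd$colors[i])), "")
  tmpl <- units$template_seq[match(rt$unit[ok][1:100], units$unit)]
  expect_true(all(startsWith(dec, substr(tmpl, 1, 15))))
  # and maps back to its origin with zero mismatches
  aset <- assign_all(s1$samples[1], ref$catalog, adapter = config$adapter)
  asg <- aset$assignments[[1]]
  mapped <- asg$category != "unmapped"
  expect_gt(mean(asg$mm_seed[mapped] + asg$mm_tail[mapped] == 0, na.rm = TRUE),
            0.99)
})

test_that("observed read fractions follow the configured abundances", {
  scn <- scenario_summary(2, depth = 2e4)
  # chi-square goodness of fit over abundant miRNA units, one ND sample
  truth <- scn$truth
  mir <- truth[truth$rna_class == "miRNA_human", ]
  exp_frac <- mir$abund_ND / sum(mir$abund_ND)
  obs <- scn$norm[mir$feature_id, "ND.1.5p"]
  keep <- exp_frac * 2e4 > 30
  chi <- sum((obs[keep] / 1e6 - exp_frac[keep])^2 /
               (exp_frac[keep] / sum(obs[keep] / 1e6 > -1)))
  # strong correlation (biological replicate noise keeps it below 1)
  # and no gross bias
  expect_gt(cor(obs[keep], exp_frac[keep] * 1e6), 0.98)
  expect_lt(abs(log2(sum(obs[keep]) / (1e6 * sum(exp_frac[keep])))), 0.2)
})

test_that("the quality-linked error rate matches the configured model", {
  config <- simulation_config(seed = 8, n_mirnas = 10, genome_size = 12000,
                              n_background = 15, transcript_len = 250,
                              depth = 3000, jitter_probs = c(0, 0, 1, 0, 0))
  ref <- generate_reference(config)
  sim <- simulate_reads(config, ref)
  rd <- sim$samples[[1]]
  rt <- sim$read_truth[[1]]
  units <- ref$units
  # recompute planted colors and compare against emitted colors
  tmpl <- units$template_seq[match(rt$unit, units$unit)]
  fill <- paste(rep(config$adapter, 3), collapse = "")
  flip <- units$strand[match(rt$unit, units$unit)] == "z" # from_5p sample
  bases <- substr(paste0(tmpl, fill), 1, 35)
  expected <- vapply(bases, function(b)
    substring(encode_colorspace(b, "T"), 2), "", USE.NAMES = FALSE)
  obs <- rd$colors
  nerr <- mapply(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b)), obs, expected)
  expect_identical(unname(nerr), rt$n_errors)
  # aggregate error rate within 3 sigma of the quality-implied expectation
  Q <- unlist(rd$quals)
  p_expected <- mean(pmin(10^(-Q / 10), config$error_cap))
  n_colors <- length(Q)
  rate <- sum(rt$n_errors) / n_colors
  expect_lt(abs(rate - p_expected),
            3 * sqrt(p_expected * (1 - p_expected) / n_colors))
})

test_that("per-condition truth abundances form a simplex and encode the regulation", {
  scn <- scenario_summary(2, depth = 2e4)
  truth <- scn$truth
  expect_equal(sum(truth$abund_ND), 1, tolerance = 1e-12)
  expect_equal(sum(truth$abund_AD8), 1, tolerance = 1e-12)
  # novel arm: zero at baseline, present after differentiation
  nov <- truth[truth$unit == "mir-novel-3p", ]
  expect_identical(nov$abund_ND, 0)
  expect_gt(nov$abund_AD8, 0)
  # decoy planted at 1/14 of its twin
  tw <- truth[truth$unit == "mir-twin-3p", ]
  dc <- truth[truth$unit == "mir-decoy-3p", ]
  expect_equal(tw$abund_ND / dc$abund_ND, 14, tolerance = 1e-9)
  # planted sets have the advertised sizes (21 up, 5 down)
  expect_length(scn$planted$up, 21)
  expect_length(scn$planted$down, 5)
})
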