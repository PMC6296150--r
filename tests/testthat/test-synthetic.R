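test_that("synthetic reference genomes hit the requested CpG census exactly", {
  g <- synthetic_reference_genome(length = 16569L, n_cpg = 435L, seed = 3L)
  expect_equal(length(g), 16569L)
  expect_equal(nrow(cpg_sites(g)), 870L)

  g2 <- synthetic_reference_genome(length = 5000L, n_cpg = 50L, seed = 9L)
  expect_equal(nrow(cpg_sites(g2)), 100L)

  free <- c(1000L, 1001L, 2500L, 2501L)
  g3 <- synthetic_reference_genome(length = 5000L, n_cpg = 50L, seed = 9L,
                                   cpg_free = free)
  s3 <- cpg_sites(g3)
  expect_false(any(s3$position %in% free))
  # deterministic under seed
  expect_identical(synthetic_reference_genome(seed = 3L)$sequence,
                   synthetic_reference_genome(seed = 3L)$sequence)
})

test_that("genotype substitutions create exactly the intended CpG changes", {
  base <- test_reference(cpg_free = c(100L, 101L))
  expect_identical(simulate_genotype(base, data.frame())$sequence,
                   base$sequence)

  ch <- strsplit(base$sequence, "")[[1]]
  subs <- data.frame(position = c(100L, 101L), base = c("C", "G"))
  subs <- subs[subs$base != ch[subs$position], ]  # only real changes
  var <- simulate_genotype(base, subs, name = "variant")
  expect_equal(length(var), length(base))
  d <- cpg_diff(var, base)
  expect_equal(d$change, c("gained", "gained"))
  expect_equal(d$position, c(100L, 101L))

  expect_error(simulate_genotype(base, data.frame(position = 0L, base = "A")),
               "out of range")
  same <- data.frame(position = 1L, base = ch[1])
  expect_error(simulate_genotype(base, same), "does not change")
})

test_that("methylome draws follow the specified Beta regime", {
  g <- test_reference()
  zero <- draw_methylome(g, methylome_spec(cpg_mean = 0, non_cpg_level = 0),
                         seed = 1)
  expect_true(all(zero$true_p == 0))

  # law-of-large-numbers check on >= 10,000 CpG draws at mean 0.10
  big <- synthetic_reference_genome(length = 40000L, n_cpg = 5000L, seed = 5L)
  m <- draw_methylome(big, methylome_spec(cpg_mean = 0.10,
                                          cpg_concentration = 20),
                      seed = 8)
  cpg <- m$true_p[m$context == "CpG"]
  expect_gte(length(cpg), 10000L)
  expect_lt(abs(mean(cpg) - 0.10), 0.01)
  expect_true(all(m$true_p[m$context == "non-CpG"] == 0.002))

  # additive group effect before clamping
  site <- cpg_sites(g)[1, ]
  spec <- methylome_spec(group_effects = list(
    hi = list(sites = site, shift = 0.15)
  ))
  base_m <- draw_methylome(g, spec, seed = 4)
  hi_m <- draw_methylome(g, spec, seed = 4, group = "hi")
  i <- which(base_m$position == site$position & base_m$strand == site$strand)
  expect_equal(hi_m$true_p[i], min(1, base_m$true_p[i] + 0.15))
  expect_equal(hi_m$true_p[-i], base_m$true_p[-i])
})

test_that("bisulfite conversion logic is exact in the degenerate limits", {
  g <- test_reference()
  zero <- draw_methylome(g, methylome_spec(cpg_mean = 0, non_cpg_level = 0),
                         seed = 1)
  cfg <- quick_cfg(conversion_efficiency = 1, methylation_protection = 1,
                   seq_error = 0, duplicate_fraction = 0)
  sim <- simulate_bisulfite_reads(g, zero, cfg, seed = 2)
  expect_true(all(sim$truth$n_meth == 0))
  # complete conversion: an OT first mate is the converted top strand and
  # carries no C at all
  ot <- sim$sidecar$strand_class == "OT"
  expect_false(any(grepl("C", sim$reads$seq1[ot], fixed = TRUE)))

  one <- zero
  one$true_p <- 1
  sim1 <- simulate_bisulfite_reads(g, one, cfg, seed = 2)
  expect_true(all(sim1$truth$n_unmeth == 0))
  # complete protection: OT first mates equal the genomic top strand
  ot1 <- which(sim1$sidecar$strand_class == "OT")[1:20]
  dbl <- paste0(g$sequence, g$sequence)
  expect_identical(
    sim1$reads$seq1[ot1],
    substring(dbl, sim1$sidecar$position[ot1],
              sim1$sidecar$position[ot1] + cfg$read_length - 1L)
  )
})

test_that("fragment count follows the coverage identity", {
  g <- synthetic_reference_genome(length = 16569L, n_cpg = 435L, seed = 3L)
  m <- draw_methylome(g, methylome_spec(), seed = 1)
  cfg <- read_sim_config(mean_coverage = 40, duplicate_fraction = 0)
  sim <- simulate_bisulfite_reads(g, m, cfg, seed = 6)
  expected <- 40 * 16569 / 300
  expect_lt(abs(nrow(sim$sidecar) - expected) / expected, 0.01)
  expect_lt(abs(sim$coverage - 40) / 40, 0.05)
})

test_that("truth-table fractions converge to the methylome probabilities", {
  g <- test_reference()
  m <- draw_methylome(g, methylome_spec(cpg_mean = 0.2), seed = 3)
  cfg <- read_sim_config(mean_coverage = 150, seq_error = 0,
                         duplicate_fraction = 0, conversion_efficiency = 1,
                         methylation_protection = 1)
  sim <- simulate_bisulfite_reads(g, m, cfg, seed = 4)
  tr <- sim$truth
  cov <- tr$n_meth + tr$n_unmeth
  keep <- cov >= 30
  frac <- tr$n_meth[keep] / cov[keep]
  # binomial standard error bound: nearly all sites within 4 SE
  se <- sqrt(pmax(tr$true_p[keep] * (1 - tr$true_p[keep]), 0.002) / cov[keep])
  expect_gt(mean(abs(frac - tr$true_p[keep]) <= 4 * se), 0.99)
})

test_that("same seed reproduces FASTQ byte for byte", {
  g <- test_reference()
  m <- draw_methylome(g, methylome_spec(), seed = 1)
  cfg <- quick_cfg()
  f1 <- c(tempfile(fileext = "_1.fastq"), tempfile(fileext = "_2.fastq"))
  f2 <- c(tempfile(fileext = "_1.fastq"), tempfile(fileext = "_2.fastq"))
  simulate_bisulfite_reads(g, m, cfg, seed = 77, fastq = f1)
  simulate_bisulfite_reads(g, m, cfg, seed = 77, fastq = f2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  # and the FASTQ round-trips through the reader
  rd <- read_fastq_pair(f1[1], f1[2])
  sim <- simulate_bisulfite_reads(g, m, cfg, seed = 77)
  expect_equal(rd$seq1, sim$reads$seq1)
  expect_equal(rd$read_id, sim$reads$read_id)
})

test_that("control simulation enforces amplicon coverage and truth", {
  g <- test_reference()
  bad <- control_spec(amplicons = list(c(1L, 2000L), c(2500L, 4000L)))
  expect_error(simulate_controls(g, bad, quick_cfg(), seed = 1),
               "coverage gap")

  spec <- control_spec(amplicons = list(c(1L, 2200L), c(2000L, 4000L)),
                       positive_enzyme_mean = 1)
  cfg <- quick_cfg(conversion_efficiency = 1, methylation_protection = 1,
                   seq_error = 0)
  ctrl <- simulate_controls(g, spec, cfg, seed = 2)
  expect_true(all(ctrl$negative$truth$n_meth == 0))
  pos_cpg <- ctrl$positive$truth[
    ctrl$positive$truth$true_p == 1 &
      (ctrl$positive$truth$n_meth + ctrl$positive$truth$n_unmeth) > 0, ]
  expect_true(all(pos_cpg$n_unmeth == 0))  # enzyme at 1.0 => fully methylated
  # fragments never span amplicon ends
  amp_ok <- function(sc, amps) {
    ends <- sc$position + sc$fragment_length - 1L
    all(vapply(seq_len(nrow(sc)), function(i) {
      any(vapply(amps, function(a) {
        sc$position[i] >= a[1] && ends[i] <= a[2]
      }, logical(1)))
    }, logical(1)))
  }
  expect_true(amp_ok(ctrl$negative$sidecar, spec$amplicons))
})

test_that("qPCR simulation follows the Ct model", {
  cfg <- qpcr_sim_config(intercept_ct = 24, noise_sd = 0)
  ct <- simulate_qpcr_ct(c(a = 1), cfg, seed = 1)
  expect_equal(ct$ct, rep(24, 3))
  ct2 <- simulate_qpcr_ct(c(a = 2, b = 1), cfg, seed = 1)
  expect_equal(mean(ct2$ct[ct2$sample == "b"]) - mean(ct2$ct[ct2$sample == "a"]),
               1)  # doubling the template saves exactly one cycle
  expect_error(simulate_qpcr_ct(c(a = 0), cfg), "positive")

  noisy <- qpcr_sim_config(noise_sd = 0.15, replicates = 1000L)
  ct3 <- simulate_qpcr_ct(c(a = 1), noisy, seed = 5)
  expect_lt(abs(sd(ct3$ct) - 0.15), 0.02)
})
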