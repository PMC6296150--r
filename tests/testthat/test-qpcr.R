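test_that("MeDIP ratios follow the per-cycle efficiency model", {
  tbl <- tibble::tibble(
    sample = "s", region = "O_H",
    antibody = rep(c("5mC", "5hmC"), each = 3),
    ct = c(24.1, 24.0, 23.9, 24.1, 24.0, 23.9)
  )
  expect_equal(medip_ratio(tbl)$ratio, 1)  # identical Cts
  tbl$ct[4:6] <- tbl$ct[4:6] + 1
  expect_equal(medip_ratio(tbl)$ratio, 2)  # one cycle apart doubles
  expect_equal(medip_ratio(tbl, efficiency = 1.9)$ratio, 1.9)

  expect_error(medip_ratio(dplyr::mutate(tbl, antibody = "x")), "antibody")
  expect_error(
    medip_ratio(tbl[tbl$antibody == "5mC", ]),
    "both a 5mC and a 5hmC"
  )
})

test_that("MeDIP ratio inverts the qPCR simulator", {
  # 5mC fraction 3x the 5hmC fraction, noise-free
  ct <- simulate_qpcr_ct(c(m = 3, h = 1), qpcr_sim_config(noise_sd = 0),
                         seed = 1)
  tbl <- tibble::tibble(
    sample = "s", region = "HSP",
    antibody = rep(c("5mC", "5hmC"), each = 3),
    ct = c(ct$ct[ct$sample == "m"], ct$ct[ct$sample == "h"])
  )
  expect_equal(medip_ratio(tbl)$ratio, 3, tolerance = 1e-12)
  # self-ratio is exactly 1
  self <- tibble::tibble(sample = "s", region = "HSP",
                         antibody = c("5mC", "5hmC"), ct = c(24.3, 24.3))
  expect_equal(medip_ratio(self)$ratio, 1)
})

expr_table <- function(trt_shift_all = 0, trt_target_shift = 0) {
  dplyr::bind_rows(lapply(c("ctrl", "trt"), function(g) {
    shift_all <- if (g == "trt") trt_shift_all else 0
    shift_t <- if (g == "trt") trt_target_shift else 0
    tibble::tibble(
      sample = rep(paste0(g, 1:3), each = 4), group = g,
      gene = rep(c("18SrRNA", "OAZ1", "HPRT1", "ND5"), 3),
      ct = rep(c(15, 20, 22, 24), 3) + shift_all +
        rep(c(0, 0, 0, shift_t), 3)
    )
  }))
}

test_that("delta-delta-Ct fold changes behave like the definition", {
  r <- ddct_fold_change(expr_table(), "ctrl")
  expect_equal(r$per_group$fold, c(1, 1))  # control vs itself is 1

  # target one cycle lower in treatment, references unchanged: fold 2
  r2 <- ddct_fold_change(expr_table(trt_target_shift = -1), "ctrl")
  expect_equal(r2$per_group$fold[r2$per_group$group == "trt"], 2)

  # shifting every Ct of a sample leaves folds unchanged
  r3 <- ddct_fold_change(expr_table(trt_shift_all = 2), "ctrl")
  expect_equal(r3$per_group$fold[r3$per_group$group == "trt"], 1)

  # a sample missing a reference gene is excluded with a warning
  broken <- expr_table()
  broken <- broken[!(broken$sample == "trt1" & broken$gene == "OAZ1"), ]
  expect_warning(r4 <- ddct_fold_change(broken, "ctrl"), "trt1")
  expect_false("trt1" %in% r4$per_sample$sample)
  expect_equal(r4$per_group$n[r4$per_group$group == "trt"], 2L)

  expect_error(ddct_fold_change(expr_table(), "nope"), "not present")
})

test_that("ddct inverts the qPCR simulator exactly when noise-free", {
  genes <- c("18SrRNA", "OAZ1", "HPRT1", "ND5")
  mk_sample <- function(s, group, nd5_q) {
    cts <- simulate_qpcr_ct(
      setNames(c(1000, 30, 8, nd5_q), genes),
      qpcr_sim_config(noise_sd = 0, replicates = 1L), seed = 1
    )
    tibble::tibble(sample = s, group = group, gene = cts$sample, ct = cts$ct)
  }
  tab <- dplyr::bind_rows(
    lapply(1:3, function(i) mk_sample(paste0("c", i), "ctrl", 2)),
    lapply(1:3, function(i) mk_sample(paste0("t", i), "trt", 4))
  )
  r <- ddct_fold_change(tab, "ctrl")
  expect_equal(r$per_group$fold[r$per_group$group == "trt"], 2,
               tolerance = 1e-12)
  expect_equal(r$per_group$sem, c(0, 0))
})

test_that("Pearson correlation matches a hand-computed oracle", {
  # fixed 9-point dataset: brute-force covariance / sd formula
  x <- c(12.1, 8.4, 15.9, 10.2, 9.8, 14.4, 11.7, 13.3, 7.6)
  y <- c(1.9, 2.8, 1.1, 2.2, 2.6, 1.4, 2.0, 1.6, 3.1)
  n <- length(x)
  r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    ((n - 1) * sd(x) * sd(y))
  t_oracle <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_oracle), n - 2)

  groups <- paste0("g", seq_len(n))
  cm <- correlate_methylation_expression(
    setNames(x, groups), tibble::tibble(group = groups, fold = y)
  )
  expect_equal(cm$r, r_oracle, tolerance = 1e-10)
  expect_equal(cm$r_squared, r_oracle^2, tolerance = 1e-10)
  expect_equal(cm$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(cm$slope_sign, -1L)

  td <- tidy(cm)
  expect_equal(td$r_squared, r_oracle^2, tolerance = 1e-10)
  gl <- glance(cm)
  expect_equal(gl$n, 9L)
})

test_that("perfect and degenerate correlations are handled", {
  perfect <- correlate_methylation_expression(
    c(a = 10, b = 20, c = 30),
    tibble::tibble(group = c("a", "b", "c"), fold = c(5, 3, 1))
  )
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope_sign, -1L)

  flat <- correlate_methylation_expression(
    c(a = 10, b = 10, c = 10),
    tibble::tibble(group = c("a", "b", "c"), fold = c(5, 3, 1))
  )
  expect_true(flat$undefined)
  expect_true(is.na(flat$r_squared))

  expect_error(
    correlate_methylation_expression(
      c(a = 1, b = 2), tibble::tibble(group = c("a", "b"), fold = c(1, 2))
    ),
    "at least 3"
  )
})

test_that("expression replicates pair with group-mean methylation", {
  # three groups, three expression replicates each, methylation at one site
  meth <- c(early = 20, mid = 15, late = 10)
  expr <- tibble::tibble(
    group = rep(names(meth), each = 3),
    fold = c(1.0, 1.1, 0.9, 1.4, 1.5, 1.6, 2.0, 2.1, 1.9)
  )
  cm <- correlate_methylation_expression(meth, expr)
  expect_equal(cm$n, 9L)
  expect_equal(cm$slope_sign, -1L)
  expect_gt(cm$r_squared, 0.8)
})

test_that("qPCR CSV readers ingest the documented layouts", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = "s", region = "O_H", antibody = "5mC",
                       ct = 24.2, replicate = 1), p, row.names = FALSE)
  m <- read_medip_ct(p)
  expect_equal(m$ct, 24.2)
  p2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = "s", group = "g", gene = "ND5", ct = 25.5),
            p2, row.names = FALSE)
  e <- read_expression_ct(p2)
  expect_equal(e$gene, "ND5")
})
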