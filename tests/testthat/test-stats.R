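make_profiles <- function(values_by_sample, position = 1L, strand = "+") {
  dplyr::bind_rows(lapply(names(values_by_sample), function(s) {
    tibble::tibble(sample = s, position = position, strand = strand,
                   raw_pct = values_by_sample[[s]],
                   normalized_pct = values_by_sample[[s]])
  }))
}

test_that("per-site ANOVA matches the textbook sums-of-squares oracle", {
  prof <- make_profiles(list(a1 = 1, a2 = 2, a3 = 3, b1 = 4, b2 = 5, b3 = 6,
                             c1 = 7, c2 = 8, c3 = 9))
  des <- tibble::tibble(sample = unique(prof$sample),
                        group = rep(c("A", "B", "C"), each = 3))
  res <- anova_per_site(prof, des)
  # independent oracle: explicit sums of squares for {1,2,3},{4,5,6},{7,8,9}
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  p_oracle <- pf(f_oracle, 2, 6, lower.tail = FALSE)
  expect_equal(res$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  # and against R's own fitter as a second, independent route
  fit <- summary(aov(normalized_pct ~ group,
                     data = merge(prof, des, by = "sample")))[[1]]
  expect_equal(res$f_statistic, fit[["F value"]][1], tolerance = 1e-6)
  expect_equal(res$p_value, fit[["Pr(>F)"]][1], tolerance = 1e-6)
})

test_that("degenerate and identical-group sites follow the p = 1 convention", {
  des <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "b2", "b3"),
                        group = rep(c("A", "B"), each = 3))
  ident <- make_profiles(list(a1 = 1, a2 = 2, a3 = 3, b1 = 1, b2 = 2, b3 = 3))
  res <- anova_per_site(ident, des)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)

  flat <- make_profiles(list(a1 = 10, a2 = 10, a3 = 10,
                             b1 = 10, b2 = 10, b3 = 10))
  res2 <- anova_per_site(flat, des)
  expect_equal(res2$p_value, 1)
  expect_true(res2$degenerate)
})

test_that("pairwise contrasts apply the joint significance rule", {
  des <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "b2", "b3"),
                        group = rep(c("A", "B"), each = 3))
  # diff +7 with small within-group noise: significant and above 5 points
  prof <- make_profiles(list(a1 = 20, a2 = 21, a3 = 19,
                             b1 = 13, b2 = 14, b3 = 12))
  r <- pairwise_contrasts(prof, des, list(c("A", "B")))
  expect_equal(r$mean_difference, 7)
  expect_equal(r$p_value,
               t.test(c(20, 21, 19), c(13, 14, 12))$p.value,
               tolerance = 1e-10)
  expect_true(r$passes)

  # diff +3: fails with the 5-point rule, passes without
  prof3 <- make_profiles(list(a1 = 16, a2 = 16.1, a3 = 15.9,
                              b1 = 13, b2 = 13.1, b3 = 12.9))
  r3 <- pairwise_contrasts(prof3, des, list(c("A", "B")))
  expect_lt(r3$p_value, 0.05)
  expect_false(r3$passes)
  r3b <- pairwise_contrasts(prof3, des, list(c("A", "B")),
                            difference_rule = FALSE)
  expect_true(r3b$passes)

  # large diff but noisy: p above alpha fails regardless
  noisy <- make_profiles(list(a1 = 30, a2 = 6, a3 = 24,
                              b1 = 10, b2 = 19, b3 = 2))
  rn <- pairwise_contrasts(noisy, des, list(c("A", "B")))
  expect_gt(rn$p_value, 0.05)
  expect_false(rn$passes)

  expect_error(pairwise_contrasts(prof, des, list(c("A", "Z"))),
               "unknown group")
})

test_that("contrasts are antisymmetric in the group order", {
  des <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "b2", "b3"),
                        group = rep(c("A", "B"), each = 3))
  set.seed(9)
  prof <- make_profiles(as.list(setNames(rnorm(6, 15, 4), des$sample)))
  ab <- pairwise_contrasts(prof, des, list(c("A", "B")))
  ba <- pairwise_contrasts(prof, des, list(c("B", "A")))
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("ANOVA type-I error is controlled under the null", {
  set.seed(2024)
  n_sites <- 2000L
  samples <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("c", 1:3))
  des <- tibble::tibble(sample = samples, group = rep(c("A", "B", "C"), each = 3))
  prof <- tibble::tibble(
    sample = rep(samples, each = n_sites),
    position = rep(seq_len(n_sites), times = 9),
    strand = "+",
    raw_pct = 0,
    normalized_pct = rnorm(9 * n_sites, mean = 10, sd = 3)
  )
  res <- anova_per_site(prof, des)
  rate <- mean(res$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("star annotation uses strict thresholds", {
  expect_equal(star_annotation(c(0.04, 0.0005, 0.05, 0.009, 0.2, 0.00099)),
               c("*", "***", "", "**", "", "***"))
  expect_equal(star_annotation(0.001), "**")
  expect_error(star_annotation(1.2), "0, 1")
})

test_that("sites are annotated by containing feature with circular wrap", {
  ann <- tibble::tibble(
    feature = c("CYTB", "DLOOP"),
    start = c(14747L, 16024L), end = c(15887L, 576L)  # DLOOP wraps the origin
  )
  sites <- tibble::tibble(position = c(14802L, 5L, 16500L, 8000L),
                          strand = c("+", "+", "-", "+"))
  lab <- annotate_sites(sites, ann)
  expect_equal(lab$annotation, c("CYTB", "DLOOP", "DLOOP", "Non-coding"))

  # overlapping features: first match wins with a warning
  ann2 <- tibble::tibble(feature = c("X", "Y"), start = c(1L, 50L),
                         end = c(100L, 150L))
  expect_warning(lab2 <- annotate_sites(tibble::tibble(position = 60L), ann2),
                 "first match wins")
  expect_equal(lab2$annotation, "X")
})

test_that("annotation maps load from headered TSV and BED-like files", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(feature = "ND1", start = 3307, end = 4262), p,
              sep = "\t", quote = FALSE, row.names = FALSE)
  a <- read_annotation(p)
  expect_equal(a$start, 3307)
  p2 <- tempfile(fileext = ".bed")
  writeLines("chrM\t3306\t4262\tND1", p2)
  b <- read_annotation(p2)
  expect_equal(b$start, 3307L)  # BED start converted to 1-based
  expect_equal(b$feature, "ND1")
})

test_that("injected group effects are recovered through the joint rule", {
  # statistics-level recovery on synthetic normalized profiles
  set.seed(55)
  n_sites <- 200L
  eff_sites <- sample(n_sites, 10L)
  samples <- c(paste0("a", 1:3), paste0("b", 1:3))
  des <- tibble::tibble(sample = samples, group = rep(c("A", "B"), each = 3))
  base <- rep(10, n_sites)
  prof <- dplyr::bind_rows(lapply(samples, function(s) {
    shift <- if (grepl("^b", s)) {
      ifelse(seq_len(n_sites) %in% eff_sites, 15, 0)
    } else 0
    tibble::tibble(sample = s, position = seq_len(n_sites), strand = "+",
                   raw_pct = 0,
                   normalized_pct = base + shift + rnorm(n_sites, 0, 2.5))
  }))
  r <- pairwise_contrasts(prof, des, list(c("B", "A")))
  hits <- r$position[r$passes]
  expect_gte(length(intersect(hits, eff_sites)), 8L)
  fp <- setdiff(hits, eff_sites)
  expect_lt(length(fp) / (n_sites - 10L), 0.05)
})
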