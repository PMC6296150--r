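# Per-site group comparisons of normalised methylation profiles: one-way
# ANOVA across groups, pairwise contrasts with the joint significance rule
# (p below alpha AND absolute difference above a minimum number of
# percentage points), and gene annotation of sites.

#' Combine normalized profiles into one long table
#'
#' @param profiles A list of `normalized_profile` tibbles, or a single long
#'   tibble with a `sample` column.
#' @return One long tibble.
#' @export
bind_profiles <- function(profiles) {
  if (is.data.frame(profiles)) return(tibble::as_tibble(profiles))
  dplyr::bind_rows(profiles)
}

#' Per-site one-way ANOVA
#'
#' Classical (equal-variance) one-way ANOVA of normalised methylation across
#' groups, computed per site from group sums of squares. Sites with zero
#' total variance are degenerate by convention: `p = 1`, flagged. Sites
#' missing from any sample are skipped.
#'
#' @param profiles Normalized profiles (list or long tibble; see
#'   [bind_profiles()]).
#' @param design Tibble mapping `sample` to a grouping column.
#' @param group Name of the grouping column in `design`.
#' @return Tibble with `position`, `strand`, `f_statistic`, `p_value`,
#'   `degenerate`.
#' @export
anova_per_site <- function(profiles, design, group = "group") {
  long <- bind_profiles(profiles)
  stopifnot(group %in% names(design), "sample" %in% names(design))
  n_samples <- dplyr::n_distinct(design$sample)
  long <- dplyr::inner_join(long, design[c("sample", group)], by = "sample")
  long$grp <- long[[group]]
  counts <- dplyr::count(long, .data$position, .data$strand)
  incomplete <- counts$n < n_samples
  if (any(incomplete)) {
    rlang::warn(sprintf("%d site(s) missing in at least one sample; skipped",
                        sum(incomplete)))
  }
  long <- dplyr::semi_join(long, counts[!incomplete, ],
                           by = c("position", "strand"))

  per_group <- dplyr::summarise(
    dplyr::group_by(long, .data$position, .data$strand, .data$grp),
    n = dplyr::n(), mean = mean(.data$normalized_pct),
    ss = sum((.data$normalized_pct - mean(.data$normalized_pct))^2),
    .groups = "drop"
  )
  overall <- dplyr::summarise(
    dplyr::group_by(long, .data$position, .data$strand),
    grand = mean(.data$normalized_pct), n_tot = dplyr::n(),
    .groups = "drop"
  )
  agg <- dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(per_group, overall, by = c("position", "strand")),
      .data$position, .data$strand
    ),
    k = dplyr::n(),
    ssb = sum(.data$n * (.data$mean - .data$grand[1])^2),
    ssw = sum(.data$ss),
    n_tot = .data$n_tot[1],
    .groups = "drop"
  )
  if (any(agg$k < 2L)) rlang::abort("at least two groups are required")
  dfb <- agg$k - 1L
  dfw <- agg$n_tot - agg$k
  degenerate <- (agg$ssb + agg$ssw) <= .Machine$double.eps * 1e3
  f <- (agg$ssb / dfb) / (agg$ssw / dfw)
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  p[degenerate] <- 1
  f[degenerate] <- 0
  tibble::tibble(
    position = agg$position, strand = agg$strand,
    f_statistic = f, p_value = p, degenerate = degenerate
  )
}

# vectorised two-sample t test on per-site group summaries
t_test_sites <- function(mean_a, var_a, n_a, mean_b, var_b, n_b,
                         var_equal = FALSE) {
  diff <- mean_a - mean_b
  if (var_equal) {
    sp2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- var_a / n_a
    vb <- var_b / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  degenerate <- !is.finite(se) | se <= 0
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate] <- 1
  list(p = p, t = t, df = df, degenerate = degenerate)
}

#' Pairwise per-site contrasts with the joint significance rule
#'
#' For each contrast (A, B) and site: the mean difference in normalised
#' methylation (A - B, percentage points) and a two-sample t test (Welch by
#' default, robust at n = 3 per group). A site passes when `p < alpha` and,
#' if the difference rule is enabled for the contrast, the absolute mean
#' difference exceeds `min_difference` points. Star annotation follows the
#' usual thresholds (see [star_annotation()]).
#'
#' @param profiles Normalized profiles (list or long tibble).
#' @param design Tibble mapping `sample` to a grouping column.
#' @param contrasts List of `c(A, B)` group label pairs.
#' @param group Name of the grouping column in `design`.
#' @param alpha Significance level.
#' @param min_difference Minimum absolute difference in percentage points.
#' @param difference_rule Logical, recycled over contrasts: apply the
#'   `min_difference` rule to that contrast family? (Genotype contrasts use
#'   it; stage contrasts conventionally do not.)
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @param p_adjust Optional multiple-testing correction method passed to
#'   [stats::p.adjust()] across sites within each contrast (e.g. `"BH"`).
#'   None is applied by default; when set, the adjusted p values replace the
#'   raw ones and a message is emitted.
#' @param annotation Optional annotation map (see [annotate_sites()]).
#' @return Tibble of class `differential_result`: `position`, `strand`,
#'   (`annotation` if requested), `contrast`, `group_a`, `group_b`,
#'   `mean_a`, `mean_b`, `mean_difference`, `p_value`, `stars`, `passes`.
#' @export
pairwise_contrasts <- function(profiles, design, contrasts, group = "group",
                               alpha = 0.05, min_difference = 5,
                               difference_rule = TRUE, var_equal = FALSE,
                               p_adjust = NULL, annotation = NULL) {
  long <- bind_profiles(profiles)
  stopifnot(group %in% names(design))
  long <- dplyr::inner_join(long, design[c("sample", group)], by = "sample")
  long$grp <- long[[group]]
  difference_rule <- rep_len(difference_rule, length(contrasts))

  stats_tbl <- dplyr::summarise(
    dplyr::group_by(long, .data$position, .data$strand, .data$grp),
    n = dplyr::n(), mean = mean(.data$normalized_pct),
    var = stats::var(.data$normalized_pct), .groups = "drop"
  )
  res <- purrr::map2(contrasts, difference_rule, function(ab, use_rule) {
    if (!all(ab %in% stats_tbl$grp)) {
      rlang::abort(sprintf("unknown group label in contrast (%s vs %s)",
                           ab[1], ab[2]))
    }
    a <- dplyr::filter(stats_tbl, .data$grp == ab[1])
    b <- dplyr::filter(stats_tbl, .data$grp == ab[2])
    j <- dplyr::inner_join(a, b, by = c("position", "strand"),
                           suffix = c("_a", "_b"))
    tt <- t_test_sites(j$mean_a, j$var_a, j$n_a, j$mean_b, j$var_b, j$n_b,
                       var_equal = var_equal)
    p <- tt$p
    if (!is.null(p_adjust)) {
      p <- stats::p.adjust(p, method = p_adjust)
      rlang::inform(sprintf(
        "multiple-testing correction '%s' applied across %d sites (%s vs %s)",
        p_adjust, length(p), ab[1], ab[2]
      ))
    }
    diff <- j$mean_a - j$mean_b
    tibble::tibble(
      position = j$position, strand = j$strand,
      contrast = paste(ab[1], "vs", ab[2]),
      group_a = ab[1], group_b = ab[2],
      mean_a = j$mean_a, mean_b = j$mean_b,
      mean_difference = diff,
      p_value = p,
      stars = star_annotation(p),
      passes = p < alpha & (!use_rule | abs(diff) > min_difference)
    )
  })
  out <- dplyr::bind_rows(res)
  if (!is.null(annotation)) {
    lab <- annotate_sites(dplyr::distinct(out[c("position", "strand")]),
                          annotation)
    out <- dplyr::left_join(out, lab, by = c("position", "strand"))
    out <- dplyr::relocate(out, "annotation", .after = "strand")
  }
  out <- dplyr::arrange(out, .data$contrast, .data$position,
                        dplyr::desc(.data$strand))
  class(out) <- c("differential_result", class(out))
  out
}

#' Star annotation of p values
#'
#' `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05 (strict
#' inequalities), otherwise an empty string.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of the same length.
#' @export
star_annotation <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("p values must lie in [0, 1]")
  }
  out <- character(length(p))
  out[which(p < 0.05)] <- "*"
  out[which(p < 0.01)] <- "**"
  out[which(p < 0.001)] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Annotate sites with gene features
#'
#' Each site is labelled by the first feature interval containing its
#' position (1-based, inclusive; intervals may wrap the origin when
#' `start > end`). Sites in no interval are labelled `"Non-coding"`.
#' Matching ignores the site's strand: mitochondrial gene labels apply to
#' CpG sites on either strand.
#'
#' @param sites Tibble with `position` (and optionally `strand`).
#' @param annotation Tibble with `feature`, `start`, `end` (1-based
#'   inclusive plus-strand coordinates).
#' @return `sites` with an added `annotation` column.
#' @export
annotate_sites <- function(sites, annotation) {
  stopifnot(all(c("feature", "start", "end") %in% names(annotation)))
  lab <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(annotation))) {
    s <- annotation$start[i]
    e <- annotation$end[i]
    inside <- if (s <= e) {
      sites$position >= s & sites$position <= e
    } else {  # wraps the origin
      sites$position >= s | sites$position <= e
    }
    clash <- inside & !is.na(lab)
    if (any(clash)) {
      rlang::warn(sprintf(
        "feature '%s' overlaps an earlier feature at %d site(s); first match wins",
        annotation$feature[i], sum(clash)
      ))
    }
    lab[inside & is.na(lab)] <- annotation$feature[i]
  }
  lab[is.na(lab)] <- "Non-coding"
  dplyr::mutate(sites, annotation = lab)
}

#' Read an annotation map from BED-like or GFF-lite TSV
#'
#' Accepts either a headered TSV with columns `feature`, `start`, `end`
#' (1-based inclusive) or a 4-column headerless BED-like file
#' (chrom, 0-based start, end, feature).
#'
#' @param path Input path.
#' @return Annotation tibble with `feature`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  head <- readLines(path, n = 1L)
  if (grepl("feature", head)) {
    tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE))
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    tibble::tibble(feature = raw[[4]], start = raw[[2]] + 1L, end = raw[[3]])
  }
}
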