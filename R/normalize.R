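# Control-anchored "full potential" normalisation: untreated long-PCR
# amplicons (fully unmethylated) give the per-site background, M.SssI-treated
# amplicons the per-site ceiling; the difference defines 100% of the
# achievable methylation at each CpG site.

meth_pct <- function(table) {
  cov <- table$count_methylated + table$count_unmethylated
  ifelse(cov > 0, 100 * table$count_methylated / cov, NA_real_)
}

#' Validate CpG sites against control coverage
#'
#' A CpG site is validated when it is covered by at least `min_reads` calls
#' in every control table (all negative and positive long-PCR samples).
#'
#' @param control_tables List of `cytosine_calls` tibbles (at least one
#'   negative and one positive control).
#' @param min_reads Minimum coverage per control (default 10, inclusive).
#' @return Tibble of validated sites: `position`, `strand`.
#' @export
validate_sites <- function(control_tables, min_reads = 10L) {
  stopifnot(is.list(control_tables), length(control_tables) >= 2L)
  keep <- lapply(control_tables, function(tbl) {
    tbl <- dplyr::filter(tbl, .data$context == "CpG")
    tbl <- coverage_filter(tbl, min_reads)
    tbl[c("position", "strand")]
  })
  out <- purrr::reduce(keep, dplyr::semi_join, by = c("position", "strand"))
  if (nrow(out) == 0L) {
    rlang::warn("no CpG site passed the coverage criterion in every control")
  }
  dplyr::arrange(out, .data$position, dplyr::desc(.data$strand))
}

#' Compute the per-site full methylation potential
#'
#' For each validated site, the difference in percentage methylation between
#' the positive (M.SssI-treated) and negative (untreated) control defines the
#' full potential (100%) of that site. Sites whose potential falls below
#' `min_potential` percentage points are marked invalid: their denominator is
#' too small to normalise against.
#'
#' @param negative,positive `cytosine_calls` tibbles for the two controls.
#' @param valid_sites Tibble of sites from [validate_sites()].
#' @param min_potential Minimum potential in percentage points.
#' @return A tibble of class `full_potential`: `position`, `strand`,
#'   `negative_pct`, `positive_pct`, `potential_points`, `valid`.
#' @export
compute_full_potential <- function(negative, positive, valid_sites,
                                   min_potential = 10) {
  neg <- dplyr::mutate(negative, negative_pct = meth_pct(negative))
  pos <- dplyr::mutate(positive, positive_pct = meth_pct(positive))
  out <- dplyr::left_join(
    valid_sites,
    neg[c("position", "strand", "negative_pct")],
    by = c("position", "strand")
  )
  out <- dplyr::left_join(
    out, pos[c("position", "strand", "positive_pct")],
    by = c("position", "strand")
  )
  missing <- is.na(out$negative_pct) | is.na(out$positive_pct)
  if (any(missing)) {
    rlang::warn(sprintf(
      "%d validated site(s) missing from a control table; marked invalid",
      sum(missing)
    ))
  }
  out$potential_points <- out$positive_pct - out$negative_pct
  out$valid <- !missing & out$potential_points >= min_potential
  class(out) <- c("full_potential", class(out))
  out
}

#' Normalize a sample methylation profile by its full potential
#'
#' At every valid site, the default (`mode = "subtract"`) normalisation is
#' `(raw - negative) / (positive - negative) * 100`, clamped to \[0, 100\]:
#' the negative control estimates the conversion-failure background, the
#' positive control the achievable ceiling. `mode = "ratio"` divides the raw
#' percentage by the potential directly, for sensitivity analysis. Invalid
#' sites are dropped; sites with non-positive potential are skipped with a
#' warning.
#'
#' @param sample A `cytosine_calls` tibble, typically after
#'   [coverage_filter()].
#' @param potentials A `full_potential` tibble.
#' @param sample_id Identifier stored in the output.
#' @param mode `"subtract"` (default) or `"ratio"`.
#' @return A tibble of class `normalized_profile`: `sample`, `position`,
#'   `strand`, `raw_pct`, `normalized_pct`.
#' @export
normalize_profile <- function(sample, potentials, sample_id = "sample",
                              mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  pot <- dplyr::filter(potentials, .data$valid)
  bad <- pot$potential_points <= 0
  if (any(bad)) {
    rlang::warn(sprintf("%d site(s) with non-positive potential skipped",
                        sum(bad)))
    pot <- pot[!bad, ]
  }
  smp <- dplyr::mutate(sample, raw_pct = meth_pct(sample))
  out <- dplyr::inner_join(
    pot[c("position", "strand", "negative_pct", "potential_points")],
    smp[c("position", "strand", "raw_pct")],
    by = c("position", "strand")
  )
  norm <- if (mode == "subtract") {
    (out$raw_pct - out$negative_pct) / out$potential_points * 100
  } else {
    out$raw_pct / out$potential_points * 100
  }
  out <- tibble::tibble(
    sample = sample_id,
    position = out$position,
    strand = out$strand,
    raw_pct = out$raw_pct,
    normalized_pct = pmin(100, pmax(0, norm))
  )
  class(out) <- c("normalized_profile", class(out))
  out
}

#' Write / read the full-potential and normalized-profile TSVs
#'
#' @param x A `full_potential` or `normalized_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
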