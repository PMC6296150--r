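# qPCR-based quantification: MeDIP 5mC/5hmC ratios, delta-delta-Ct relative
# expression with averaged reference genes, and Pearson correlation between
# site methylation and gene expression.

#' MeDIP 5mC/5hmC ratio from Ct values
#'
#' Replicate Cts are averaged per sample, region and antibody, then the
#' ratio of methylated to hydroxymethylated template is
#' `efficiency^(mean Ct_5hmC - mean Ct_5mC)`: one cycle of difference is a
#' factor of `efficiency` (2 by default, perfect doubling). No input-fraction
#' normalisation is applied by default; `input_ct` columns, when present and
#' `use_input = TRUE`, are subtracted from each antibody's mean Ct first.
#'
#' @param ct_table Tibble with columns `sample`, `region`, `antibody`
#'   (values `"5mC"` and `"5hmC"`), `ct`, and optionally `input_ct`.
#' @param efficiency Amplification factor per cycle.
#' @param use_input Subtract matched input Cts before forming the ratio.
#' @return Tibble with `sample`, `region`, `ct_5mC`, `ct_5hmC`, `ratio`.
#' @export
medip_ratio <- function(ct_table, efficiency = 2.0, use_input = FALSE) {
  need <- c("sample", "region", "antibody", "ct")
  stopifnot(all(need %in% names(ct_table)))
  if (!all(ct_table$antibody %in% c("5mC", "5hmC"))) {
    rlang::abort("antibody must be '5mC' or '5hmC'")
  }
  if (any(ct_table$ct <= 0)) rlang::abort("Ct values must be positive")
  means <- dplyr::summarise(
    dplyr::group_by(ct_table, .data$sample, .data$region, .data$antibody),
    ct = mean(.data$ct),
    input_ct = if (use_input) mean(.data$input_ct) else NA_real_,
    .groups = "drop"
  )
  if (use_input) means$ct <- means$ct - means$input_ct
  wide <- tidyr::pivot_wider(means[c("sample", "region", "antibody", "ct")],
                             names_from = "antibody", values_from = "ct")
  if (!all(c("5mC", "5hmC") %in% names(wide)) ||
      any(is.na(wide[["5mC"]])) || any(is.na(wide[["5hmC"]]))) {
    rlang::abort("every sample/region needs both a 5mC and a 5hmC measurement")
  }
  tibble::tibble(
    sample = wide$sample, region = wide$region,
    ct_5mC = wide$`5mC`, ct_5hmC = wide$`5hmC`,
    ratio = efficiency^(wide$`5hmC` - wide$`5mC`)
  )
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Per sample and gene, `dCt = Ct_gene - mean(Ct of the reference genes)`
#' (arithmetic mean of the three reference-gene Cts, matching the use of
#' averaged internal controls); `ddCt = dCt - mean(dCt over control-group
#' samples)`; `fold = efficiency^(-ddCt)`. Samples missing any reference gene
#' are excluded with a warning. Group-level summaries report the mean fold
#' and its standard error over replicate samples.
#'
#' @param table Tibble with columns `sample`, `group`, `gene`, `ct`.
#' @param control_group Label of the reference (calibrator) group.
#' @param reference_genes Character vector of internal-control genes.
#' @param efficiency Amplification factor per cycle.
#' @return A list of class `ddct_result`: `per_sample` (tibble `sample`,
#'   `group`, `gene`, `dct`, `ddct`, `fold`) and `per_group` (tibble `gene`,
#'   `group`, `fold`, `sem`, `n`).
#' @export
ddct_fold_change <- function(table, control_group,
                             reference_genes = c("18SrRNA", "OAZ1", "HPRT1"),
                             efficiency = 2.0) {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(all(need %in% names(table)))
  if (!control_group %in% table$group) {
    rlang::abort(sprintf("control group '%s' not present", control_group))
  }
  refs <- dplyr::filter(table, .data$gene %in% reference_genes)
  ref_n <- dplyr::summarise(
    dplyr::group_by(refs, .data$sample),
    n_ref = dplyr::n_distinct(.data$gene),
    ref_ct = mean(.data$ct), .groups = "drop"
  )
  complete <- ref_n$sample[ref_n$n_ref == length(reference_genes)]
  dropped <- setdiff(unique(table$sample), complete)
  if (length(dropped) > 0L) {
    rlang::warn(sprintf(
      "sample(s) missing a reference gene excluded: %s",
      paste(dropped, collapse = ", ")
    ))
  }
  targets <- dplyr::filter(table, !.data$gene %in% reference_genes,
                           .data$sample %in% complete)
  targets <- dplyr::inner_join(targets, ref_n[c("sample", "ref_ct")],
                               by = "sample")
  targets$dct <- targets$ct - targets$ref_ct
  calib <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(targets, .data$group == control_group), .data$gene
    ),
    calib_dct = mean(.data$dct), .groups = "drop"
  )
  targets <- dplyr::inner_join(targets, calib, by = "gene")
  targets$ddct <- targets$dct - targets$calib_dct
  targets$fold <- efficiency^(-targets$ddct)
  per_sample <- tibble::as_tibble(
    targets[c("sample", "group", "gene", "dct", "ddct", "fold")]
  )
  per_group <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$gene, .data$group),
    n = dplyr::n(),
    sem = stats::sd(.data$fold) / sqrt(dplyr::n()),
    fold = mean(.data$fold),
    .groups = "drop"
  )
  structure(
    list(per_sample = per_sample,
         per_group = per_group[c("gene", "group", "fold", "sem", "n")]),
    class = "ddct_result"
  )
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("<ddct_result>\n")
  print(x$per_group)
  invisible(x)
}

#' Correlate site methylation with gene expression
#'
#' Pairs each expression replicate with its group's mean methylation at a
#' site and computes the Pearson correlation over the paired points,
#' reporting R squared, the two-sided correlation-test p value and the slope
#' sign (to state, e.g., that methylation and transcription are negatively
#' correlated). Zero variance in either variable leaves the correlation
#' undefined and flagged.
#'
#' @param methylation Named numeric vector (or tibble with `group`,
#'   `methylation_pct`): group-level mean methylation at the site.
#' @param expression Tibble with `group` and `fold` (one row per expression
#'   replicate).
#' @return A list of class `meth_expr_cor`: `r`, `r_squared`, `p_value`,
#'   `slope_sign` (+1/-1/0), `n`, `undefined`.
#' @export
correlate_methylation_expression <- function(methylation, expression) {
  if (is.data.frame(methylation)) {
    m <- methylation$methylation_pct
    names(m) <- methylation$group
    methylation <- m
  }
  stopifnot(all(c("group", "fold") %in% names(expression)))
  if (!all(expression$group %in% names(methylation))) {
    rlang::abort("every expression group needs a methylation value")
  }
  x <- unname(methylation[expression$group])
  y <- expression$fold
  if (length(x) < 3L) {
    rlang::abort("at least 3 paired points are required")
  }
  undefined <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (undefined) {
    out <- list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                slope_sign = NA_integer_, n = length(x), undefined = TRUE)
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate)
    out <- list(r = r, r_squared = r^2, p_value = ct$p.value,
                slope_sign = as.integer(sign(r)), n = length(x),
                undefined = FALSE)
  }
  structure(out, class = "meth_expr_cor")
}

#' @export
print.meth_expr_cor <- function(x, ...) {
  if (x$undefined) {
    cat("<meth_expr_cor> undefined (zero variance), n =", x$n, "\n")
  } else {
    cat(sprintf(
      "<meth_expr_cor> R^2 = %.4f, p = %.4g, slope %s, n = %d\n",
      x$r_squared, x$p_value,
      if (x$slope_sign < 0) "negative" else if (x$slope_sign > 0) "positive" else "flat",
      x$n
    ))
  }
  invisible(x)
}

#' Broom-style tidiers for methylation-expression correlations
#'
#' @param x A `meth_expr_cor` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate`, `r_squared`,
#'   `p_value`, `slope_sign`; `glance()`: a one-row tibble with `r_squared`,
#'   `p_value`, `n`, `undefined`.
#' @method tidy meth_expr_cor
#' @export
tidy.meth_expr_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, r_squared = x$r_squared,
                 p_value = x$p_value, slope_sign = x$slope_sign)
}

#' @rdname tidy.meth_expr_cor
#' @method glance meth_expr_cor
#' @export
glance.meth_expr_cor <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, n = x$n,
                 undefined = x$undefined)
}

#' Read qPCR CSV inputs
#'
#' `read_medip_ct()` expects columns sample, region, antibody, ct (and
#' optionally replicate, input_ct); `read_expression_ct()` expects sample,
#' group, gene, ct.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_medip_ct <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_medip_ct
#' @export
read_expression_ct <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
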