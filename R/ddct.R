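#' Relative expression by the 2^-ddCt method
#'
#' Livak-style relative quantification of qPCR cycle-threshold tables.
#' Within each replicate, `dCt = Ct(gene) - Ct(ref_gene)`; the
#' normalization anchor is the mean `dCt` of the control group per gene;
#' `ddCt = dCt - mean dCt(control)` and the fold change is `2^-ddCt`.
#' Amplification efficiency is fixed at 2 (no efficiency correction).
#'
#' @param ct_table A tibble/data frame with columns `gene`, `group`,
#'   `replicate`, `ct` (cycles, finite and positive). The reference gene
#'   must be present in every (group, replicate) cell that carries a test
#'   gene.
#' @param ref_gene Reference (housekeeping) gene name, default `"actin"`.
#' @param control_group Label of the negative-control group.
#' @return A tibble with one row per (gene, group, replicate):
#'   `gene`, `group`, `replicate`, `dct`, `ddct`, `fold`. The reference
#'   gene itself is not reported.
#' @examples
#' tab <- tibble::tibble(
#'   gene = rep(c("geneX", "actin"), 2),
#'   group = rep(c("treated", "NC"), each = 2),
#'   replicate = 1L, ct = c(20, 15, 24, 15))
#' delta_delta_ct(tab, ref_gene = "actin", control_group = "NC")
#' @export
delta_delta_ct <- function(ct_table, ref_gene = "actin", control_group) {
  need <- c("gene", "group", "replicate", "ct")
  if (!all(need %in% names(ct_table))) {
    abort("`ct_table` needs columns gene, group, replicate, ct.",
          class = "fibrilkin_domain_error")
  }
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    abort("Ct values must be finite and positive.",
          class = "fibrilkin_domain_error")
  }
  if (!ref_gene %in% ct_table$gene) {
    abort(sprintf("Reference gene '%s' absent from the table.", ref_gene),
          class = "fibrilkin_missing_reference_error")
  }
  if (!control_group %in% ct_table$group) {
    abort(sprintf("Control group '%s' absent from the table.", control_group),
          class = "fibrilkin_domain_error")
  }
  ref <- ct_table |>
    dplyr::filter(.data$gene == ref_gene) |>
    dplyr::select("group", "replicate", ct_ref = "ct")
  tests <- dplyr::filter(ct_table, .data$gene != ref_gene)
  joined <- dplyr::left_join(tests, ref, by = c("group", "replicate"))
  if (any(is.na(joined$ct_ref))) {
    bad <- joined |>
      dplyr::filter(is.na(.data$ct_ref)) |>
      dplyr::distinct(.data$group, .data$replicate)
    abort(sprintf(
      "Reference gene '%s' missing for: %s.",
      ref_gene,
      paste(sprintf("(%s, rep %s)", bad$group, bad$replicate), collapse = ", ")),
      class = "fibrilkin_missing_reference_error")
  }
  joined |>
    dplyr::mutate(dct = .data$ct - .data$ct_ref) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(ddct = .data$dct -
                    mean(.data$dct[.data$group == control_group])) |>
    dplyr::ungroup() |>
    dplyr::mutate(fold = 2^(-.data$ddct)) |>
    dplyr::select("gene", "group", "replicate", "dct", "ddct", "fold")
}

#' Per-group fold-change summary
#'
#' @param folds Output of [delta_delta_ct()].
#' @return A tibble per (gene, group): `mean_fold`, `sd_fold` (`NA`, not 0,
#'   for a single replicate), `n`.
#' @export
fold_change_summary <- function(folds) {
  if (!all(c("gene", "group", "fold") %in% names(folds))) {
    abort("`folds` must come from delta_delta_ct().",
          class = "fibrilkin_domain_error")
  }
  folds |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(
      mean_fold = mean(.data$fold),
      sd_fold = if (dplyr::n() > 1L) sd(.data$fold) else NA_real_,
      n = dplyr::n(),
      .groups = "drop")
}
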