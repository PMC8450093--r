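#' Percent input from IP and input Ct values
#'
#' ChIP/RIP enrichment as the percentage of the dilution-corrected input
#' recovered, assuming an amplification efficiency of 2 (one doubling
#' per cycle): the input Ct is first shifted down by
#' `log2(1/fraction_input)` to represent undiluted input, then
#' `100 * 2^(ct_input_adjusted - ct_ip)`.
#'
#' @param ct_ip,ct_input Ct values (cycles); vectorized.
#' @param fraction_input Input dilution in (0,1), e.g. 0.01 for 1%
#'   input.
#' @return Percent input (>= 0).
#' @examples
#' percent_input(20 - log2(100), 20, 0.01)  # 100
#' @export
percent_input <- function(ct_ip, ct_input, fraction_input = 0.01) {
  if (any(fraction_input <= 0 | fraction_input >= 1))
    stop("fraction_input must be in (0,1)")
  stopifnot(all(is.finite(ct_ip)), all(is.finite(ct_input)))
  100 * 2^((ct_input - log2(1 / fraction_input)) - ct_ip)
}

#' Fold change of an enrichment versus a control
#'
#' @param enrichment_case,enrichment_control Enrichments (e.g. percent
#'   input) for case and control; control must be > 0. Vectorized.
#' @return `case / control`.
#' @export
fold_change_vs_control <- function(enrichment_case, enrichment_control) {
  if (any(enrichment_control <= 0))
    stop("control enrichment must be > 0")
  enrichment_case / enrichment_control
}

#' Two-stage ChIP ratio: locus over reference gene, then treatment over
#' control
#'
#' ChIP signals at an rDNA locus are first normalized to the level of a
#' reference gene (*eft-3*) within each condition, and the data
#' expressed as the ratio of the +dsRNA to the -dsRNA condition.
#'
#' @param enrichment_locus,enrichment_ref Signals at the locus of
#'   interest and the reference amplicon within one condition.
#' @return `locus_ratio_vs_reference`: the within-condition ratio;
#'   `treatment_ratio`: plus over minus.
#' @export
locus_ratio_vs_reference <- function(enrichment_locus, enrichment_ref) {
  if (any(enrichment_ref <= 0)) stop("reference enrichment must be > 0")
  enrichment_locus / enrichment_ref
}

#' @rdname locus_ratio_vs_reference
#' @param ratio_plus,ratio_minus Within-condition ratios for the
#'   +dsRNA and -dsRNA conditions.
#' @export
treatment_ratio <- function(ratio_plus, ratio_minus) {
  if (any(ratio_minus <= 0)) stop("control (-dsRNA) ratio must be > 0")
  ratio_plus / ratio_minus
}

#' Relative expression by delta-delta-Ct
#'
#' `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl -
#' ct_ref_ctrl))` with efficiency fixed at 2. The reference gene is a
#' required argument — pick a transcript unaffected by the perturbation.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct
#'   values; vectorized.
#' @return Fold change of the target in case versus control.
#' @export
relative_expression <- function(ct_target_case, ct_ref_case,
                                ct_target_ctrl, ct_ref_ctrl) {
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' Classic equal-variance two-sample t-test. Degenerate input with zero
#' pooled variance returns `t = 0, p = 1` when the means are equal and
#' errors otherwise (no finite statistic exists).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return `list(t, df, p)`.
#' @export
t_test_two_tailed <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  ma <- mean(group_a); mb <- mean(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2L, p = 1))
    stop("zero pooled variance with unequal means: t undefined")
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Percent input per replicate from a Ct table
#'
#' Pairs IP and input wells by (sample, treatment, locus, replicate) and
#' computes percent input for each pairing.
#'
#' @param ct_table Long-format Ct table as from [simulate_qpcr()] /
#'   [read_ct_table()].
#' @return `data.frame(sample, treatment, locus, replicate,
#'   percent_input)`.
#' @export
percent_input_table <- function(ct_table) {
  ip <- ct_table[ct_table$role == "IP", , drop = FALSE]
  input <- ct_table[ct_table$role == "input", , drop = FALSE]
  key <- function(x) paste(x$sample, x$treatment, x$locus, x$replicate,
                           sep = "\r")
  m <- match(key(ip), key(input))
  if (anyNA(m)) stop("IP well without matching input well")
  data.frame(sample = ip$sample, treatment = ip$treatment,
             locus = ip$locus, replicate = ip$replicate,
             percent_input = percent_input(ip$ct, input$ct[m],
                                           input$fraction_input[m]),
             stringsAsFactors = FALSE)
}

#' Replicate summary and comparisons for enrichment tables
#'
#' Aggregates per-replicate enrichments to mean, sd and n per
#' (sample, treatment, locus), and evaluates requested comparisons as
#' per-replicate fold changes (mean-of-ratios, replicates paired by
#' index; `ratio_of_means = TRUE` switches to the ratio of replicate
#' means) with a two-tailed Student's t-test between the case and
#' control replicate values.
#'
#' @param enrichments Output of [percent_input_table()], or any table
#'   with the same keys and a `value` column named by `value_col`.
#' @param comparisons Optional `data.frame(case_sample, control_sample,
#'   locus)` (a `treatment` pair via `case_treatment` /
#'   `control_treatment` columns is also honoured).
#' @param value_col Name of the value column (default
#'   `"percent_input"`).
#' @param ratio_of_means Combine replicates as ratio-of-means instead of
#'   mean-of-ratios.
#' @return `list(summary = per-group data.frame, comparisons =
#'   data.frame with fold_change mean/sd and p_value)` (the second
#'   element only when comparisons were requested).
#' @export
summarize_enrichment <- function(enrichments, comparisons = NULL,
                                 value_col = "percent_input",
                                 ratio_of_means = FALSE) {
  v <- enrichments[[value_col]]
  g <- interaction(enrichments$sample, enrichments$treatment,
                   enrichments$locus, drop = TRUE, sep = " | ")
  summ <- do.call(rbind, lapply(split(seq_along(v), g), function(i) {
    data.frame(sample = enrichments$sample[i[1]],
               treatment = enrichments$treatment[i[1]],
               locus = enrichments$locus[i[1]],
               n = length(i), mean = mean(v[i]),
               sd = if (length(i) >= 2L) stats::sd(v[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  out <- list(summary = summ)
  if (!is.null(comparisons)) {
    comparisons <- as.data.frame(comparisons)
    pick <- function(sample, treatment, locus) {
      i <- enrichments$sample == sample & enrichments$locus == locus
      if (!is.null(treatment)) i <- i & enrichments$treatment == treatment
      enrichments[i, , drop = FALSE][order(
        enrichments$replicate[i]), , drop = FALSE][[value_col]]
    }
    out$comparisons <- do.call(rbind, lapply(seq_len(nrow(comparisons)),
                                             function(r) {
      cmp <- comparisons[r, ]
      case <- pick(cmp$case_sample,
                   if ("case_treatment" %in% names(cmp))
                     cmp$case_treatment else NULL, cmp$locus)
      ctrl <- pick(cmp$control_sample,
                   if ("control_treatment" %in% names(cmp))
                     cmp$control_treatment else NULL, cmp$locus)
      if (length(case) < 2L || length(ctrl) < 2L)
        stop("comparison needs >= 2 replicates per side")
      fc <- if (ratio_of_means) mean(case) / mean(ctrl)
            else {
              k <- min(length(case), length(ctrl))
              mean(fold_change_vs_control(case[seq_len(k)],
                                          ctrl[seq_len(k)]))
            }
      fc_sd <- if (!ratio_of_means) {
        k <- min(length(case), length(ctrl))
        stats::sd(case[seq_len(k)] / ctrl[seq_len(k)])
      } else NA_real_
      # noise-free designs have zero within-group variance; the t
      # statistic is undefined there, so report NA rather than abort
      tt <- tryCatch(t_test_two_tailed(case, ctrl),
                     error = function(e) list(t = NA_real_, p = NA_real_))
      data.frame(case_sample = cmp$case_sample,
                 control_sample = cmp$control_sample, locus = cmp$locus,
                 fold_change = fc, fold_change_sd = fc_sd,
                 n_case = length(case), n_control = length(ctrl),
                 t = tt$t, p_value = tt$p, stringsAsFactors = FALSE)
    }))
    rownames(out$comparisons) <- NULL
  }
  out
}
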