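#' Microarray spot quality control
#'
#' Per spot: the background mean is subtracted from each replicate signal;
#' the spot is `removed_qc` when the corrected mean signal is below three
#' times the background SD or the replicate CV (sd/mean of
#' background-subtracted replicates) exceeds `max_cv`; otherwise
#' `non_expressed` when below `min_signal_expressed`, `low_abundance` when
#' below `min_signal_variance` (kept but excluded from variance analysis),
#' else `expressed`.
#'
#' @param spots data.frame: `probe_id`, replicate columns `rep1..repN`,
#'   `bg_mean`, `bg_sd`.
#' @param bsd_factor background-SD multiple (default 3).
#' @param max_cv maximum replicate CV (default 0.5).
#' @param min_signal_expressed signal below which a spot is
#'   non-expressing (default 30).
#' @param min_signal_variance signal below which a spot is low-abundance
#'   (default 100).
#' @return data.frame: `probe_id`, `signal` (background-subtracted mean),
#'   `cv`, `status`.
#' @export
microarray_qc <- function(spots, bsd_factor = 3, max_cv = 0.5,
                          min_signal_expressed = 30,
                          min_signal_variance = 100) {
  rep_cols <- grep("^rep[0-9]+$", names(spots), value = TRUE)
  if (!length(rep_cols)) stop("microarray_qc: no replicate columns")
  sig <- as.matrix(spots[, rep_cols, drop = FALSE]) - spots$bg_mean
  mu <- rowMeans(sig)
  cv <- apply(sig, 1L, stats::sd) / mu
  cv[!is.finite(cv)] <- Inf
  status <- ifelse(mu < bsd_factor * spots$bg_sd | cv > max_cv, "removed_qc",
            ifelse(mu < min_signal_expressed, "non_expressed",
            ifelse(mu < min_signal_variance, "low_abundance", "expressed")))
  data.frame(probe_id = spots$probe_id, signal = mu, cv = cv,
             status = status, stringsAsFactors = FALSE)
}

#' LOWESS intensity normalization of single-channel arrays
#'
#' MA-style locally weighted regression of each channel's log-ratio
#' against the per-probe mean log-signal (the mean pseudo-array), removing
#' intensity-dependent bias. Identical channels are returned unchanged;
#' already-normalized data are a fixed point (to numerical tolerance).
#'
#' @param signals numeric matrix, probes x channels (raw positive signals).
#' @param span lowess smoother span (default 0.3).
#' @return normalized signal matrix of the same dimensions.
#' @export
lowess_normalize <- function(signals, span = 0.3) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 2L) stop("lowess_normalize: need >= 2 channels")
  if (nrow(signals) < 10L) {
    stop("lowess_normalize: need >= 10 shared probes for a stable fit")
  }
  if (any(signals <= 0)) stop("lowess_normalize: signals must be positive")
  lg <- log2(signals)
  a <- rowMeans(lg)
  out <- lg
  for (ch in seq_len(ncol(lg))) {
    m <- lg[, ch] - a
    if (all(abs(m) < 1e-12)) next
    fit <- stats::lowess(a, m, f = span)
    adj <- stats::approx(fit$x, fit$y, xout = a, rule = 2)$y
    out[, ch] <- lg[, ch] - adj
  }
  2^out
}

# mean Ct over replicates for one (sample, gene)
mean_ct <- function(ct_table, sample, gene) {
  rows <- ct_table$sample == sample & ct_table$gene == gene
  if (!any(rows)) {
    stop(sprintf("Ct table: no rows for gene '%s' in sample '%s'",
                 gene, sample))
  }
  mean(ct_table$ct[rows])
}

#' Relative expression by the 2^dCt method
#'
#' `2^(Ct_control - Ct_gene)`: abundance of a gene relative to the
#' internal control (U6 for miRNAs), larger = more abundant.
#'
#' @param ct_table data.frame: `sample`, `gene`, `replicate`, `ct`.
#' @param gene gene of interest.
#' @param sample sample name.
#' @param control internal control gene (default `"U6"`).
#' @return numeric relative expression.
#' @export
rel_expression_dct <- function(ct_table, gene, sample, control = "U6") {
  2^(mean_ct(ct_table, sample, control) - mean_ct(ct_table, sample, gene))
}

#' Fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_gene - Ct_control)_sample - (Ct_gene - Ct_control)_reference`;
#' the reference sample maps to exactly 1.
#'
#' @param ct_table data.frame: `sample`, `gene`, `replicate`, `ct`.
#' @param gene gene of interest.
#' @param sample sample to quantify.
#' @param reference_sample reference sample (fold 1).
#' @param control internal control gene (default `"U6"`).
#' @return numeric fold change.
#' @export
fold_change_ddct <- function(ct_table, gene, sample, reference_sample,
                             control = "U6") {
  dct_s <- mean_ct(ct_table, sample, gene) -
    mean_ct(ct_table, sample, control)
  dct_r <- mean_ct(ct_table, reference_sample, gene) -
    mean_ct(ct_table, reference_sample, control)
  2^(-(dct_s - dct_r))
}

#' Correlate miRNA and target expression profiles
#'
#' @param mirna_profile,target_profile equal-length numeric vectors
#'   (n >= 3) of per-tissue expression.
#' @return list: `pearson_r`, `spearman_rho`, `direction` (`"negative"`,
#'   `"positive"`, or `"undefined"`), `error` (TRUE when either profile
#'   has zero variance).
#' @export
correlate_pairs <- function(mirna_profile, target_profile) {
  stopifnot(length(mirna_profile) == length(target_profile),
            length(mirna_profile) >= 3L)
  if (stats::sd(mirna_profile) == 0 || stats::sd(target_profile) == 0) {
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                direction = "undefined", error = TRUE))
  }
  r <- stats::cor(mirna_profile, target_profile, method = "pearson")
  rho <- stats::cor(mirna_profile, target_profile, method = "spearman")
  list(pearson_r = r, spearman_rho = rho,
       direction = if (r < 0) "negative" else "positive", error = FALSE)
}
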