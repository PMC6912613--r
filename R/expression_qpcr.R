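# Relative expression by the 2^-ddCt method with replicate statistics.

#' Read a qPCR Ct table from CSV
#'
#' Expects columns `sample`, `gene`, `replicate`, `ct`.
#'
#' @param path CSV file.
#' @return data frame of class `CtTable`.
#' @export
read_ct_table <- function(path) {
  d <- read_table_csv(path)
  as_ct_table(d)
}

#' Validate a Ct table
#'
#' @param d data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @return the validated data frame with class `CtTable`.
#' @export
as_ct_table <- function(d) {
  need <- c("sample", "gene", "replicate", "ct")
  stop_if_not(all(need %in% names(d)),
              paste("Ct table must have columns:", paste(need, collapse = ", ")))
  stop_if_not(all(is.finite(d$ct)), "all Ct values must be finite")
  if (!inherits(d, "CtTable")) class(d) <- c("CtTable", class(d))
  d
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate `i` of each (sample, gene):
#' `dCt_i = Ct(gene)_i - Ct(reference)_i` (replicates paired by index),
#' `ddCt_i = dCt_i - mean(dCt in the control sample)`, and
#' `fold_i = 2^-ddCt_i`. The reported fold change is `2^-mean(ddCt)` (the
#' geometric mean of the per-replicate folds, so the control sample scores
#' exactly 1), with the SD taken over the per-replicate folds. The p-value
#' compares the sample's dCt values against the control's with
#' [two_sample_test()] — dCt is approximately normal, fold changes are not.
#'
#' Because dCt subtracts the reference gene within each replicate, a plate
#' offset added to every Ct of one sample cancels exactly.
#'
#' @param table a `CtTable` (see [as_ct_table()]).
#' @param reference_gene housekeeping gene present in every sample (e.g.
#'   `"ACTB"`).
#' @param control_sample baseline condition (e.g. `"WT"`).
#' @param variance_rule forwarded to [two_sample_test()].
#' @return data frame of class `FoldChangeResult` with columns `gene`,
#'   `sample`, `fold_change`, `sd`, `p_value`, `n_replicates`; attribute
#'   `replicate_folds` holds the per-replicate folds.
#' @export
ddct_fold_change <- function(table, reference_gene, control_sample,
                             variance_rule = "f_test") {
  table <- as_ct_table(table)
  samples <- unique(table$sample)
  stop_if_not(control_sample %in% samples,
              paste0("control sample not in table: ", control_sample))
  for (s in samples)
    if (!reference_gene %in% table$gene[table$sample == s])
      stop("reference gene ", reference_gene, " missing in sample: ", s,
           call. = FALSE)
  genes <- setdiff(unique(table$gene), reference_gene)
  stop_if_not(length(genes) > 0, "no target gene besides the reference")

  dct <- function(s, g) {
    tg <- table[table$sample == s & table$gene == g, ]
    rf <- table[table$sample == s & table$gene == reference_gene, ]
    mm <- merge(tg[, c("replicate", "ct")], rf[, c("replicate", "ct")],
                by = "replicate", suffixes = c("_g", "_r"))
    stop_if_not(nrow(mm) >= 1,
                paste0("no paired replicates for ", g, " in sample ", s))
    mm$ct_g - mm$ct_r
  }

  rows <- list(); rep_folds <- list()
  for (g in genes) {
    d0 <- dct(control_sample, g)
    for (s in samples) {
      ds <- dct(s, g)
      ddct <- ds - mean(d0)
      folds <- 2^(-ddct)
      p <- if (s == control_sample) NA_real_ else
        if (length(ds) >= 2 && length(d0) >= 2)
          two_sample_test(ds, d0, variance_rule = variance_rule)$p_value
        else NA_real_
      rows[[paste(g, s)]] <- data.frame(
        gene = g, sample = s, fold_change = 2^(-mean(ddct)),
        sd = if (length(folds) > 1) sd(folds) else 0,
        p_value = p, n_replicates = length(folds))
      rep_folds[[paste(g, s)]] <- folds
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicate_folds") <- rep_folds
  class(out) <- c("FoldChangeResult", class(out))
  out
}
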