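# Relative quantification of RT-qPCR data by 2^-dCt: dCt = Ct(target) -
# Ct(reference); fold change = 2^-dCt; per-(gene, condition, timepoint)
# replicate means +/- SD on the fold-change scale; heat relative to the
# matched control cell (control := 1); log10 of the relative value for
# display.

#' Read a Ct table
#'
#' TSV with columns `gene_id`, `condition` (`control`/`heat`),
#' `timepoint`, `replicate`, `ct_target`, `ct_reference`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "condition", "timepoint",
                                 "replicate", "ct_target", "ct_reference"))
  if (!all(df$condition %in% c("control", "heat"))) {
    stop("condition must be 'control' or 'heat'")
  }
  if (any(!is.finite(df$ct_target)) || any(!is.finite(df$ct_reference)) ||
      any(df$ct_target <= 0) || any(df$ct_reference <= 0)) {
    stop("Ct values must be finite and positive")
  }
  df
}

#' Delta-Ct of a record
#' @param record data.frame with `ct_target`, `ct_reference` (vectorized).
#' @return ct_target - ct_reference.
#' @export
delta_ct <- function(record) {
  if (is.null(record$ct_reference) || anyNA(record$ct_reference)) {
    stop("delta_ct: missing reference Ct")
  }
  record$ct_target - record$ct_reference
}

#' Fold change from delta-Ct
#' @param delta dCt value(s). @return 2^(-delta).
#' @export
fold_change <- function(delta) {
  if (any(!is.finite(delta))) stop("fold_change: non-finite delta")
  2^(-delta)
}

#' Summarize replicated Ct records into fold changes
#'
#' Per (gene, timepoint): the mean and SD of 2^-dCt over replicates in
#' each condition (SD on the fold-change scale), the heat/control ratio
#' of means (`relative_to_control`; the control cell is the "1"
#' standard), and `log10_fold = log10(relative_to_control)`. With
#' `method = "ddct"` the relative value is instead
#' 2^-(mean heat dCt - mean control dCt).
#'
#' @param records Ct data.frame (see [read_ct_table()]).
#' @param method `"ratio_of_means"` (default) or `"ddct"`.
#' @return data.frame with one row per (gene_id, timepoint):
#'   `fold_change_mean`, `fold_change_sd` (heat cell),
#'   `control_mean`, `control_sd`, `relative_to_control`, `log10_fold`,
#'   `n_heat`, `n_control`.
#' @export
summarize_fold_changes <- function(records,
                                   method = c("ratio_of_means", "ddct")) {
  method <- match.arg(method)
  records$fc <- fold_change(delta_ct(records))
  cells <- split(records, list(records$gene_id, records$timepoint),
                 drop = TRUE)
  rows <- lapply(cells, function(cell) {
    heat <- cell[cell$condition == "heat", ]
    ctrl <- cell[cell$condition == "control", ]
    if (nrow(ctrl) == 0L || nrow(heat) == 0L) {
      stop("summarize_fold_changes: missing matched ",
           if (nrow(ctrl) == 0L) "control" else "heat",
           " cell for gene ", cell$gene_id[1], " at timepoint ",
           cell$timepoint[1])
    }
    if (nrow(heat) == 1L || nrow(ctrl) == 1L) {
      warning("single replicate for gene ", cell$gene_id[1],
              " at timepoint ", cell$timepoint[1], "; SD reported as 0")
    }
    sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    rel <- if (method == "ratio_of_means") {
      mean(heat$fc) / mean(ctrl$fc)
    } else {
      2^(-(mean(delta_ct(heat)) - mean(delta_ct(ctrl))))
    }
    data.frame(gene_id = cell$gene_id[1], timepoint = cell$timepoint[1],
               fold_change_mean = mean(heat$fc),
               fold_change_sd = sd0(heat$fc),
               control_mean = mean(ctrl$fc), control_sd = sd0(ctrl$fc),
               relative_to_control = rel, log10_fold = log10(rel),
               n_heat = nrow(heat), n_control = nrow(ctrl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
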